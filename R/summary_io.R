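#' Describe the columns of a GWAS summary-statistics file
#'
#' Public GWAS summary files rarely agree on column naming, so every reader in
#' this package goes through a column map that translates source headers to
#' the canonical fields: `snp_id`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval`, `n`, and optionally `n_case`.
#'
#' @param snp_id,effect_allele,other_allele,eaf,beta,se,pval,n Source column
#'   headers for the canonical fields.
#' @param n_case Optional source header for the number of cases (binary
#'   traits); `NULL` when absent.
#' @param delimiter Field delimiter of the file; tab by default.
#' @param na Missing-value sentinel string.
#' @return A `column_map` object (a named list).
#' @examples
#' column_map(snp_id = "rsid", beta = "b", se = "standard_error")
#' @export
column_map <- function(snp_id = "snp_id", effect_allele = "effect_allele",
                       other_allele = "other_allele", eaf = "eaf",
                       beta = "beta", se = "se", pval = "pval", n = "n",
                       n_case = NULL, delimiter = "\t", na = "NA") {
  fields <- list(
    snp_id = snp_id, effect_allele = effect_allele,
    other_allele = other_allele, eaf = eaf, beta = beta, se = se,
    pval = pval, n = n, n_case = n_case
  )
  required <- setdiff(names(fields), "n_case")
  for (f in required) {
    if (!is.character(fields[[f]]) || length(fields[[f]]) != 1L || is.na(fields[[f]])) {
      abort(sprintf("column_map field '%s' must be a single column name", f))
    }
  }
  structure(
    list(fields = fields, delimiter = delimiter, na = na),
    class = "column_map"
  )
}

canonical_gwas_cols <- c(
  "snp_id", "effect_allele", "other_allele", "eaf", "beta", "se",
  "pval", "n", "n_case"
)

valid_bases <- c("A", "C", "G", "T")

#' Construct a GWAS summary-statistics table from an in-memory data frame
#'
#' Validates per-SNP records and attaches trait metadata. Rows failing
#' validation (invalid or duplicated alleles, non-positive SE, p-value outside
#' (0, 1], EAF outside \[0, 1\], non-positive N, n_case > n) are dropped with a
#' warning. Duplicate SNP ids keep the first occurrence.
#'
#' @param data Data frame with the canonical columns (`n_case` optional).
#' @param trait_name Label for the trait.
#' @param trait_type `"continuous"` or `"binary"`.
#' @return A tibble with canonical columns and attributes `trait_name`,
#'   `trait_type`.
#' @export
as_gwas <- function(data, trait_name, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(setdiff(canonical_gwas_cols, "n_case"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing canonical columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"n_case" %in% names(data)) data$n_case <- NA_real_
  data <- data[canonical_gwas_cols]
  data$snp_id <- as.character(data$snp_id)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n", "n_case")) {
    data[[col]] <- as.numeric(data[[col]])
  }

  bad <- gwas_row_problems(data)
  if (any(bad)) {
    warn(sprintf("dropped %d of %d rows failing record validation", sum(bad), nrow(data)))
    data <- data[!bad, ]
  }
  dup <- duplicated(data$snp_id)
  if (any(dup)) {
    warn(sprintf("dropped %d rows with duplicated snp_id (first kept)", sum(dup)))
    data <- data[!dup, ]
  }
  structure(data, trait_name = trait_name, trait_type = trait_type,
            class = class(tibble::tibble()))
}

# one logical per row: TRUE when the record violates an invariant
gwas_row_problems <- function(data) {
  with(data, {
    bad_allele <- !(effect_allele %in% valid_bases) |
      !(other_allele %in% valid_bases) |
      effect_allele == other_allele
    bad_se <- is.na(se) | !is.finite(se) | se <= 0
    bad_beta <- is.na(beta) | !is.finite(beta)
    bad_p <- is.na(pval) | pval <= 0 | pval > 1
    bad_eaf <- !is.na(eaf) & (eaf < 0 | eaf > 1)
    bad_n <- is.na(n) | n <= 0
    bad_ncase <- !is.na(n_case) & (n_case <= 0 | n_case > n)
    bad_id <- is.na(snp_id) | snp_id == ""
    bad_allele | bad_se | bad_beta | bad_p | bad_eaf | bad_n | bad_ncase | bad_id
  })
}

#' Metadata of a GWAS table
#'
#' @param data A table created by [as_gwas()] or [read_gwas()].
#' @return List with `trait_name` and `trait_type` (possibly `NULL`).
#' @export
gwas_meta <- function(data) {
  list(
    trait_name = attr(data, "trait_name", exact = TRUE),
    trait_type = attr(data, "trait_type", exact = TRUE)
  )
}

#' Read GWAS summary statistics from a delimited file
#'
#' @inheritParams as_gwas
#' @param path Path to a delimited text file with one header row.
#' @param colmap A [column_map()] describing the source columns.
#' @return A validated GWAS tibble (see [as_gwas()]).
#' @export
read_gwas <- function(path, colmap = column_map(), trait_name,
                      trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!inherits(colmap, "column_map")) abort("colmap must be a column_map()")
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(
    path, delim = colmap$delimiter, na = colmap$na,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  mapped <- purrr::compact(colmap$fields)
  missing_cols <- setdiff(unlist(mapped), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("mapped columns absent from header: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(setNames(raw[unlist(mapped)], names(mapped)))
  as_gwas(out, trait_name = trait_name, trait_type = trait_type)
}

#' Write a GWAS table to a delimited file
#'
#' Writes the canonical columns in canonical order so that a written table can
#' be read back with the default [column_map()] without loss.
#'
#' @param data GWAS tibble.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(data, path, delimiter = "\t") {
  readr::write_delim(data[canonical_gwas_cols], path, delim = delimiter, na = "NA")
  invisible(path)
}

#' Select genetic instruments at a p-value threshold
#'
#' Retains SNPs whose exposure p-value is strictly below `p_threshold`
#' (genome-wide significance 5e-8 by default); boundary values are excluded.
#'
#' @param exposure GWAS tibble for the exposure.
#' @param p_threshold Strict upper bound on the association p-value.
#' @return The subset of rows passing the threshold, metadata preserved.
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8) {
  if (nrow(exposure) == 0) abort("exposure dataset is empty")
  keep <- exposure$pval < p_threshold
  if (!any(keep)) {
    abort(sprintf("no instruments at p < %g for trait '%s'",
                  p_threshold, attr(exposure, "trait_name") %||% "?"))
  }
  out <- exposure[keep, ]
  attributes(out)$trait_name <- attr(exposure, "trait_name", exact = TRUE)
  attributes(out)$trait_type <- attr(exposure, "trait_type", exact = TRUE)
  out
}
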