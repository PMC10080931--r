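#' Is an allele pair palindromic?
#'
#' A palindromic SNP is its own reverse complement (A/T or C/G), so strand
#' cannot be inferred from the allele letters alone.
#'
#' @param effect_allele,other_allele Vectors of single-base alleles.
#' @return Logical vector.
#' @examples
#' is_palindromic(c("A", "A", "C"), c("T", "G", "G"))
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  (effect_allele == "A" & other_allele == "T") |
    (effect_allele == "T" & other_allele == "A") |
    (effect_allele == "C" & other_allele == "G") |
    (effect_allele == "G" & other_allele == "C")
}

base_complement <- c(A = "T", T = "A", C = "G", G = "C")

complement_alleles <- function(x) unname(base_complement[x])

pair_cols <- c(
  "snp_id", "effect_allele", "other_allele",
  "beta_exp", "se_exp", "eaf_exp", "pval_exp", "n_exp",
  "beta_out", "se_out", "eaf_out", "pval_out", "n_out",
  "proxy_snp", "status", "exclusion_reason"
)

#' Align exposure and outcome effects onto a common effect allele
#'
#' Joins exposure and outcome records by SNP id and expresses both effects on
#' the exposure's effect allele. Outcome records reported on the opposite
#' allele have their beta negated and EAF reflected; records reported on the
#' opposite strand are complemented first (non-palindromic SNPs only).
#' Palindromic SNPs, for which the strand is unidentifiable from alleles, are
#' oriented by effect-allele-frequency concordance: the orientation whose
#' outcome EAF falls on the same side of 0.5 as the exposure EAF is kept; if
#' either EAF is missing the pair is excluded as `palindromic-ambiguous`.
#' Irreconcilable allele pairs are excluded as `allele-mismatch`.
#'
#' @param exposure,outcome GWAS tibbles sharing SNP ids. When both hold a
#'   single record their SNP ids must agree.
#' @return A tibble of harmonized pairs, one row per joined SNP, with columns
#'   `beta_exp`/`se_exp`/`eaf_exp`/`n_exp`, `beta_out`/`se_out`/`eaf_out`/
#'   `pval_out`/`n_out`, a `status` (`kept`, `flipped` or `proxy-substituted`)
#'   and an `exclusion_reason` (`NA` for usable pairs).
#' @export
align_alleles <- function(exposure, outcome) {
  if (nrow(exposure) == 1 && nrow(outcome) == 1 &&
      exposure$snp_id != outcome$snp_id) {
    abort("snp_id mismatch between exposure and outcome records")
  }
  exp_part <- tibble::tibble(
    snp_id = exposure$snp_id,
    effect_allele = exposure$effect_allele,
    other_allele = exposure$other_allele,
    beta_exp = exposure$beta, se_exp = exposure$se,
    eaf_exp = exposure$eaf, pval_exp = exposure$pval, n_exp = exposure$n
  )
  out_part <- tibble::tibble(
    snp_id = outcome$snp_id,
    ea_out = outcome$effect_allele, oa_out = outcome$other_allele,
    beta_out = outcome$beta, se_out = outcome$se,
    eaf_out = outcome$eaf, pval_out = outcome$pval, n_out = outcome$n,
    proxy_snp = if ("proxy_snp" %in% names(outcome)) outcome$proxy_snp else NA_character_
  )
  d <- dplyr::inner_join(exp_part, out_part, by = "snp_id")
  if (nrow(d) == 0) {
    proto <- tibble::tibble(
      snp_id = character(0), effect_allele = character(0),
      other_allele = character(0),
      beta_exp = numeric(0), se_exp = numeric(0), eaf_exp = numeric(0),
      pval_exp = numeric(0), n_exp = numeric(0),
      beta_out = numeric(0), se_out = numeric(0), eaf_out = numeric(0),
      pval_out = numeric(0), n_out = numeric(0),
      proxy_snp = character(0), status = character(0),
      exclusion_reason = character(0)
    )
    return(proto)
  }

  pal <- is_palindromic(d$effect_allele, d$other_allele)
  same <- d$ea_out == d$effect_allele & d$oa_out == d$other_allele
  swap <- d$ea_out == d$other_allele & d$oa_out == d$effect_allele
  cea <- complement_alleles(d$ea_out)
  coa <- complement_alleles(d$oa_out)
  csame <- cea == d$effect_allele & coa == d$other_allele
  cswap <- cea == d$other_allele & coa == d$effect_allele

  flip <- rep(FALSE, nrow(d))
  reason <- rep(NA_character_, nrow(d))

  npal <- !pal
  flip[npal & swap] <- TRUE
  flip[npal & !same & !swap & cswap] <- TRUE
  reason[npal & !(same | swap | csame | cswap)] <- "allele-mismatch"

  # palindromic: letters always "match"; orientation decided by EAF sides
  if (any(pal)) {
    p_match <- pal & (same | swap)
    reason[pal & !p_match] <- "allele-mismatch"
    eaf_known <- !is.na(d$eaf_exp) & !is.na(d$eaf_out)
    amb <- p_match & !eaf_known
    reason[amb] <- "palindromic-ambiguous"
    res <- p_match & eaf_known
    # nominal orientation from allele order, then strand-correct on discordance
    nominal_eaf <- ifelse(swap, 1 - d$eaf_out, d$eaf_out)
    discord <- (d$eaf_exp < 0.5) != (nominal_eaf < 0.5)
    flip[res] <- xor(swap[res], discord[res])
  }

  beta_out <- ifelse(flip, -d$beta_out, d$beta_out)
  eaf_out <- ifelse(flip, 1 - d$eaf_out, d$eaf_out)

  tibble::tibble(
    snp_id = d$snp_id,
    effect_allele = d$effect_allele,
    other_allele = d$other_allele,
    beta_exp = d$beta_exp, se_exp = d$se_exp, eaf_exp = d$eaf_exp,
    pval_exp = d$pval_exp, n_exp = d$n_exp,
    beta_out = beta_out, se_out = d$se_out, eaf_out = eaf_out,
    pval_out = d$pval_out, n_out = d$n_out,
    proxy_snp = d$proxy_snp,
    status = dplyr::case_when(
      !is.na(reason) ~ NA_character_,
      !is.na(d$proxy_snp) ~ "proxy-substituted",
      flip ~ "flipped",
      TRUE ~ "kept"
    ),
    exclusion_reason = reason
  )
}

#' Exclude palindromic pairs with ambiguous allele frequency
#'
#' Palindromic SNPs whose exposure-side minor allele frequency
#' `min(eaf, 1 - eaf)` exceeds `maf_threshold` sit too close to 0.5 for the
#' EAF-concordance strand call to be trusted and are excluded with reason
#' `palindromic-ambiguous`. A MAF exactly at the threshold is retained
#' (exclusion requires MAF strictly above it).
#'
#' @param pairs Harmonized pair tibble from [align_alleles()].
#' @param maf_threshold Exclusion bound on the exposure minor allele frequency.
#' @return `pairs` with the `exclusion_reason` column updated.
#' @export
filter_palindromic <- function(pairs, maf_threshold = 0.42) {
  pal <- is_palindromic(pairs$effect_allele, pairs$other_allele)
  maf <- pmin(pairs$eaf_exp, 1 - pairs$eaf_exp)
  hit <- pal & is.na(pairs$exclusion_reason) &
    (is.na(maf) | maf > maf_threshold)
  pairs$exclusion_reason[hit] <- "palindromic-ambiguous"
  pairs$status[hit] <- NA_character_
  pairs
}

#' Exclude SNPs primarily associated with the outcome
#'
#' Instruments reaching genome-wide significance in the outcome GWAS are more
#' plausibly outcome loci than exposure instruments and are excluded with
#' reason `outcome-associated`.
#'
#' @param pairs Harmonized pair tibble carrying `pval_out`.
#' @param p_threshold Strict exclusion bound on the outcome p-value.
#' @return `pairs` with the `exclusion_reason` column updated.
#' @export
exclude_outcome_associated <- function(pairs, p_threshold = 5e-8) {
  hit <- is.na(pairs$exclusion_reason) & !is.na(pairs$pval_out) &
    pairs$pval_out < p_threshold
  pairs$exclusion_reason[hit] <- "outcome-associated"
  pairs$status[hit] <- NA_character_
  pairs
}

#' Validate a user-supplied LD proxy table
#'
#' Expected columns: `query_snp`, `proxy_snp`, `r2`, and the allele
#' correspondence `query_a1`, `proxy_a1`, `query_a2`, `proxy_a2` (a bijection
#' over the query SNP's two alleles).
#'
#' @param proxies Data frame of proxy records.
#' @return The validated tibble.
#' @export
validate_proxies <- function(proxies) {
  proxies <- tibble::as_tibble(proxies)
  need <- c("query_snp", "proxy_snp", "r2", "query_a1", "proxy_a1",
            "query_a2", "proxy_a2")
  missing_cols <- setdiff(need, names(proxies))
  if (length(missing_cols) > 0) {
    abort(paste0("proxy table missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(proxies$r2 < 0 | proxies$r2 > 1, na.rm = TRUE)) {
    abort("proxy r2 must lie in [0, 1]")
  }
  bad_map <- proxies$query_a1 == proxies$query_a2 |
    proxies$proxy_a1 == proxies$proxy_a2
  if (any(bad_map)) abort("proxy allele_map must be a bijection over two distinct alleles")
  proxies
}

#' Substitute LD proxies for instruments missing from the outcome GWAS
#'
#' For each missing instrument, the proxy with the highest LD `r2` strictly
#' above `r2_min` that is present in the outcome dataset is substituted; its
#' alleles are remapped to the query SNP's alleles through the proxy record's
#' allele correspondence. Ties in `r2` break lexicographically by proxy rsID.
#' Proxies whose allele map is inconsistent with the outcome record's alleles
#' are skipped with a warning.
#'
#' @param missing Character vector of instrument rsIDs absent from the outcome.
#' @param proxies Proxy table (see [validate_proxies()]).
#' @param outcome Outcome GWAS tibble.
#' @param r2_min Strict lower bound on the LD r-squared.
#' @return List with `substitutions` (outcome-format tibble whose `snp_id` is
#'   the query rsID, plus a `proxy_snp` column) and `unresolved` (rsIDs with
#'   no usable proxy).
#' @export
substitute_proxies <- function(missing, proxies, outcome, r2_min = 0.60) {
  proxies <- validate_proxies(proxies)
  subs <- list()
  unresolved <- character(0)
  for (snp in missing) {
    cand <- proxies[proxies$query_snp == snp & proxies$r2 > r2_min &
                      proxies$proxy_snp %in% outcome$snp_id, , drop = FALSE]
    cand <- cand[order(-cand$r2, cand$proxy_snp), , drop = FALSE]
    found <- FALSE
    for (i in seq_len(nrow(cand))) {
      px <- cand[i, ]
      rec <- outcome[outcome$snp_id == px$proxy_snp, ][1, ]
      if (rec$effect_allele == px$proxy_a1 && rec$other_allele == px$proxy_a2) {
        ea <- px$query_a1; oa <- px$query_a2
      } else if (rec$effect_allele == px$proxy_a2 && rec$other_allele == px$proxy_a1) {
        ea <- px$query_a2; oa <- px$query_a1
      } else {
        warn(sprintf("proxy %s for %s skipped: allele map inconsistent with outcome record",
                     px$proxy_snp, snp))
        next
      }
      rec$snp_id <- snp
      rec$effect_allele <- ea
      rec$other_allele <- oa
      rec$proxy_snp <- px$proxy_snp
      subs[[length(subs) + 1L]] <- rec
      found <- TRUE
      break
    }
    if (!found) unresolved <- c(unresolved, snp)
  }
  list(
    substitutions = if (length(subs)) dplyr::bind_rows(subs) else NULL,
    unresolved = unresolved
  )
}

#' Harmonize an instrument set against an outcome GWAS
#'
#' Full harmonization pass: allele alignment ([align_alleles()]), LD-proxy
#' substitution for instruments absent from the outcome
#' ([substitute_proxies()]), palindromic-ambiguity exclusion
#' ([filter_palindromic()]), and outcome-association exclusion
#' ([exclude_outcome_associated()]). Excluded pairs are retained in the output
#' with their reason; use [kept_pairs()] to extract the usable subset.
#'
#' @param exposure Instrument GWAS tibble (typically from
#'   [select_instruments()]).
#' @param outcome Outcome GWAS tibble.
#' @param maf_threshold Palindromic minor-allele-frequency exclusion bound.
#' @param outcome_p_threshold Outcome-association exclusion bound; `NULL`
#'   disables the rule.
#' @param proxies Optional proxy table for missing instruments.
#' @param r2_min Strict lower bound on proxy LD r-squared.
#' @return Harmonized pair tibble with an attrition log in
#'   `attr(, "log")` and unresolved missing SNPs in `attr(, "unresolved")`.
#' @export
harmonize <- function(exposure, outcome, maf_threshold = 0.42,
                      outcome_p_threshold = 5e-8, proxies = NULL,
                      r2_min = 0.60) {
  missing_ids <- setdiff(exposure$snp_id, outcome$snp_id)
  unresolved <- missing_ids
  out_use <- outcome
  if (length(missing_ids) > 0 && !is.null(proxies)) {
    sub <- substitute_proxies(missing_ids, proxies, outcome, r2_min = r2_min)
    if (!is.null(sub$substitutions)) {
      out_use <- dplyr::bind_rows(
        dplyr::mutate(outcome, proxy_snp = NA_character_),
        sub$substitutions
      )
    }
    unresolved <- sub$unresolved
  }
  pairs <- align_alleles(exposure, out_use)
  pairs <- filter_palindromic(pairs, maf_threshold = maf_threshold)
  if (!is.null(outcome_p_threshold)) {
    pairs <- exclude_outcome_associated(pairs, p_threshold = outcome_p_threshold)
  }
  if (length(unresolved) > 0) {
    miss <- exposure[exposure$snp_id %in% unresolved, ]
    miss_pairs <- tibble::tibble(
      snp_id = miss$snp_id,
      effect_allele = miss$effect_allele, other_allele = miss$other_allele,
      beta_exp = miss$beta, se_exp = miss$se, eaf_exp = miss$eaf,
      pval_exp = miss$pval, n_exp = miss$n,
      beta_out = NA_real_, se_out = NA_real_, eaf_out = NA_real_,
      pval_out = NA_real_, n_out = NA_real_,
      proxy_snp = NA_character_,
      status = NA_character_, exclusion_reason = "missing-no-proxy"
    )
    pairs <- dplyr::bind_rows(pairs, miss_pairs)
  }
  reasons <- table(pairs$exclusion_reason[!is.na(pairs$exclusion_reason)])
  attr(pairs, "log") <- list(
    n_instruments = nrow(exposure),
    n_harmonized = sum(is.na(pairs$exclusion_reason)),
    excluded = as.list(reasons)
  )
  attr(pairs, "unresolved") <- unresolved
  pairs
}

#' Usable subset of a harmonized pair table
#'
#' @param pairs Harmonized pair tibble.
#' @return Rows with no exclusion reason.
#' @export
kept_pairs <- function(pairs) {
  pairs[is.na(pairs$exclusion_reason), , drop = FALSE]
}
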