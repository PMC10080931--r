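#' Assemble a multivariable MR input
#'
#' Builds the SNP-by-exposure effect matrix for multivariable MR. The
#' instrument set is, by default, the union of each exposure's genome-wide
#' significant SNPs (optionally overridden via `instruments`, e.g. a
#' mediator's own instruments in two-step mediation). All datasets are
#' harmonized to a common effect allele using the first dataset that carries
#' each SNP as the allele reference; SNPs absent from any dataset, or excluded
#' during harmonization (allele mismatch, ambiguous palindrome), are dropped
#' and logged.
#'
#' @param exposures Named list of GWAS tibbles (at least 2 for a multivariable
#'   fit; the first is conventionally the exposure of interest).
#' @param outcome Outcome GWAS tibble.
#' @param p_threshold Instrument-selection threshold applied per exposure.
#' @param maf_threshold Palindromic minor-allele-frequency exclusion bound.
#' @param instruments Optional character vector of SNP ids overriding the
#'   union rule.
#' @return Object of class `mvmr_input`: list with `snps`, `beta_exp`
#'   (SNP x exposure matrix), `se_exp`, `beta_out`, `se_out`,
#'   `exposure_names`, and a `dropped` log.
#' @export
assemble_mvmr_input <- function(exposures, outcome, p_threshold = 5e-8,
                                maf_threshold = 0.42, instruments = NULL) {
  if (!is.list(exposures) || length(exposures) < 1) {
    abort("exposures must be a non-empty named list of GWAS tables")
  }
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    names(exposures) <- paste0("exposure", seq_along(exposures))
  }
  if (is.null(instruments)) {
    instruments <- unique(unlist(lapply(exposures, function(e) {
      select_instruments(e, p_threshold = p_threshold)$snp_id
    })))
  }
  instruments <- sort(unique(instruments))

  datasets <- c(exposures, list(.outcome = outcome))
  present <- Reduce(intersect, lapply(datasets, function(d) d$snp_id))
  dropped <- setdiff(instruments, present)
  snps <- intersect(instruments, present)
  if (length(snps) == 0) abort("no instrument present in every dataset")

  # allele reference: first dataset carrying each SNP (exposures first)
  ref <- NULL
  remaining <- snps
  for (d in datasets) {
    take <- d[d$snp_id %in% remaining, , drop = FALSE]
    ref <- dplyr::bind_rows(ref, take)
    remaining <- setdiff(remaining, take$snp_id)
    if (length(remaining) == 0) break
  }
  ref <- ref[match(snps, ref$snp_id), ]

  aligned <- lapply(datasets, function(d) {
    p <- align_alleles(ref, d[d$snp_id %in% snps, , drop = FALSE])
    p <- filter_palindromic(p, maf_threshold = maf_threshold)
    p[match(snps, p$snp_id), c("snp_id", "beta_out", "se_out", "exclusion_reason")]
  })
  excluded <- Reduce(`|`, lapply(aligned, function(a) !is.na(a$exclusion_reason)))
  dropped <- c(dropped, snps[excluded])
  keep <- !excluded
  snps <- snps[keep]

  k <- length(exposures)
  beta_exp <- vapply(aligned[seq_len(k)], function(a) a$beta_out[keep],
                     numeric(sum(keep)))
  se_exp <- vapply(aligned[seq_len(k)], function(a) a$se_out[keep],
                   numeric(sum(keep)))
  beta_exp <- matrix(beta_exp, ncol = k,
                     dimnames = list(snps, names(exposures)))
  se_exp <- matrix(se_exp, ncol = k,
                   dimnames = list(snps, names(exposures)))
  out_al <- aligned[[k + 1L]]
  if (length(snps) <= k + 1L) {
    abort(sprintf("only %d complete instruments for %d exposures; need more than %d",
                  length(snps), k, k + 1L))
  }
  if (length(dropped) > 0) {
    inform(sprintf("multivariable input: %d SNP(s) dropped (missing or unharmonizable)",
                   length(dropped)))
  }
  structure(
    list(
      snps = snps, beta_exp = beta_exp, se_exp = se_exp,
      beta_out = out_al$beta_out[keep], se_out = out_al$se_out[keep],
      exposure_names = names(exposures), dropped = dropped
    ),
    class = "mvmr_input"
  )
}

#' Multivariable inverse-variance weighted MR
#'
#' Weighted multiple regression of outcome betas on all exposure-beta columns
#' without an intercept, weights `1/se_out^2`. Each coefficient is the direct
#' effect of that exposure conditional on the others. Standard errors use the
#' weighted-regression covariance with multiplicative overdispersion floored
#' at 1, mirroring the univariable random-effects IVW; a single-exposure fit
#' therefore reproduces univariable IVW exactly.
#'
#' @param input An `mvmr_input` from [assemble_mvmr_input()].
#' @return Object of class `mvmr_fit`; [tidy()] gives one row per exposure,
#'   [glance()] the residual heterogeneity.
#' @export
mvmr_ivw <- function(input) {
  if (!inherits(input, "mvmr_input")) abort("input must be an mvmr_input")
  X <- input$beta_exp
  y <- input$beta_out
  w <- 1 / input$se_out^2
  L <- nrow(X)
  k <- ncol(X)
  XtWX <- crossprod(X, w * X)
  cond <- kappa(XtWX, exact = TRUE)
  if (!is.finite(cond) || cond > 1e12) {
    abort(sprintf("exposure-beta matrix is rank deficient (condition number %.3g)", cond))
  }
  coef <- drop(solve(XtWX, crossprod(X, w * y)))
  resid <- y - drop(X %*% coef)
  Q <- sum(w * resid^2)
  df <- L - k
  sigma <- sqrt(Q / df)
  se <- sqrt(diag(solve(XtWX))) * max(1, sigma)
  pval <- 2 * pnorm(-abs(coef / se))
  structure(
    list(
      exposure_names = input$exposure_names, n_snp = L,
      beta = setNames(coef, input$exposure_names),
      se = setNames(se, input$exposure_names),
      pval = setNames(pval, input$exposure_names),
      heterogeneity = het_stats(Q, df),
      condition_number = cond
    ),
    class = "mvmr_fit"
  )
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat(sprintf("Multivariable IVW, %d SNPs, %d exposures\n", x$n_snp,
              length(x$exposure_names)))
  print(tidy(x))
  invisible(x)
}

#' Tidy a multivariable MR fit
#'
#' @param x An `mvmr_fit`.
#' @param exponentiate Report on the odds-ratio scale.
#' @param ... Unused.
#' @return Tibble with one row per exposure: `exposure`, `n_snp`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`, `p.value`.
#' @method tidy mvmr_fit
#' @export
tidy.mvmr_fit <- function(x, exponentiate = FALSE, ...) {
  z <- qnorm(0.975)
  out <- tibble::tibble(
    exposure = x$exposure_names,
    n_snp = x$n_snp,
    estimate = unname(x$beta),
    std.error = unname(x$se),
    conf.low = unname(x$beta - z * x$se),
    conf.high = unname(x$beta + z * x$se),
    p.value = unname(x$pval)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' @rdname glance.mr_fit
#' @method glance mvmr_fit
#' @export
glance.mvmr_fit <- function(x, ...) {
  h <- x$heterogeneity
  tibble::tibble(Q = h$Q, df = as.integer(h$df), Q.p.value = h$pval,
                 i2 = h$i2, band = h$band)
}
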