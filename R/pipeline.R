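#' Analysis configuration
#'
#' Bundles the thresholds and method settings of a full study run. Defaults
#' are the conventional ones for this design: instrument selection at
#' p < 5e-8, palindromic minor-allele-frequency exclusion above 0.42, LD
#' proxies at r2 > 0.60, overall alpha 0.05 with a Bonferroni family of 5
#' primary outcomes (threshold 0.01) or 4 secondary outcomes (0.0125,
#' conventionally reported as 0.013).
#'
#' @param instrument_p Instrument-selection p-value threshold.
#' @param palindromic_maf Palindromic MAF exclusion bound.
#' @param proxy_r2 LD proxy r-squared bound.
#' @param alpha Overall two-sided significance level.
#' @param family_size Number of outcomes in the Bonferroni family.
#' @param methods Estimators to run per outcome.
#' @param n_boot Weighted-median bootstrap replicates.
#' @param seed Integer seed for all stochastic steps.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(instrument_p = 5e-8, palindromic_maf = 0.42,
                            proxy_r2 = 0.60, alpha = 0.05, family_size = 5,
                            methods = c("ivw", "weighted_median", "egger"),
                            n_boot = 1000, seed) {
  if (missing(seed)) abort("a seed is required in analysis_config()")
  methods <- match.arg(methods, c("ivw", "weighted_median", "egger"),
                       several.ok = TRUE)
  structure(
    list(instrument_p = instrument_p, palindromic_maf = palindromic_maf,
         proxy_r2 = proxy_r2, alpha = alpha, family_size = family_size,
         methods = methods, n_boot = n_boot, seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Classify p-values against a Bonferroni family
#'
#' `significant` when `p < alpha / family_size`, `suggestive` when
#' `alpha / family_size <= p < alpha`, otherwise `null`. The comparison uses
#' the full-precision threshold (e.g. 0.0125 for a family of 4, even though
#' it is conventionally reported rounded to 0.013).
#'
#' @param pval Two-sided p-values.
#' @param family_size Number of outcomes in the family.
#' @param alpha Overall significance level.
#' @return Character vector in `c("significant", "suggestive", "null")`.
#' @examples
#' classify_significance(c(4.48e-4, 0.012, 0.083), family_size = 5)
#' @export
classify_significance <- function(pval, family_size, alpha = 0.05) {
  if (any(is.na(pval) | pval < 0 | pval > 1)) abort("pval must lie in [0, 1]")
  thr <- alpha / family_size
  dplyr::case_when(
    pval < thr ~ "significant",
    pval < alpha ~ "suggestive",
    TRUE ~ "null"
  )
}

#' Run the univariable MR workflow across outcomes
#'
#' For each outcome: select instruments, harmonize (with optional LD-proxy
#' substitution), fit the random-effects IVW (primary) plus the requested
#' sensitivity estimators, and classify significance against the Bonferroni
#' family. A fatal error in one outcome aborts that outcome only and is
#' recorded; the other outcomes still run.
#'
#' @param exposure Exposure GWAS tibble.
#' @param outcomes Named list of outcome GWAS tibbles.
#' @param config An [analysis_config()].
#' @param proxies Optional LD proxy table.
#' @return Tibble of class `mr_results`, one row per outcome x method, with
#'   estimate, standard error, odds-ratio scale, heterogeneity and
#'   significance columns; per-outcome exclusion logs in `attr(, "logs")` and
#'   failures in `attr(, "errors")`.
#' @export
run_univariable <- function(exposure, outcomes, config, proxies = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    abort("outcomes must be a named list")
  }
  instruments <- select_instruments(exposure, p_threshold = config$instrument_p)
  rows <- list()
  logs <- list()
  errors <- list()
  for (nm in names(outcomes)) {
    res <- tryCatch({
      pairs <- harmonize(
        instruments, outcomes[[nm]],
        maf_threshold = config$palindromic_maf,
        outcome_p_threshold = config$instrument_p,
        proxies = proxies, r2_min = config$proxy_r2
      )
      logs[[nm]] <- attr(pairs, "log")
      fits <- list()
      if ("ivw" %in% config$methods) fits$ivw <- mr_ivw(pairs)
      if ("weighted_median" %in% config$methods) {
        fits$weighted_median <- mr_weighted_median(
          pairs, n_boot = config$n_boot, seed = config$seed
        )
      }
      if ("egger" %in% config$methods) fits$egger <- mr_egger(pairs)
      dplyr::bind_rows(lapply(fits, function(f) {
        est <- tidy(f)
        hg <- glance(f)
        if (nrow(hg) == 0) {
          hg <- tibble::tibble(Q = NA_real_, df = NA_integer_,
                               Q.p.value = NA_real_, i2 = NA_real_,
                               band = NA_character_)
        }
        est$outcome <- nm
        dplyr::bind_cols(est, hg[rep(1, nrow(est)), ])
      }))
    }, error = function(e) {
      errors[[nm]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) rows[[nm]] <- res
  }
  if (length(rows) == 0) abort("every outcome failed; see attr(, 'errors')")
  out <- dplyr::bind_rows(rows)
  ors <- to_odds_ratio(out$estimate, out$std.error)
  out$or <- ors$or
  out$or_ci_low <- ors$ci_low
  out$or_ci_high <- ors$ci_high
  out$significance <- classify_significance(
    out$p.value, family_size = config$family_size, alpha = config$alpha
  )
  out <- out[, c("outcome", "method", "n_snp", "estimate", "std.error",
                 "conf.low", "conf.high", "p.value", "or", "or_ci_low",
                 "or_ci_high", "Q", "df", "Q.p.value", "i2", "band",
                 "significance")]
  class(out) <- c("mr_results", class(out))
  attr(out, "logs") <- logs
  attr(out, "errors") <- errors
  out
}

#' Format results as a report table
#'
#' Deterministic, publication-style rendering of an [run_univariable()]
#' result: odds ratios and confidence limits to 3 decimals as
#' `"OR (low-high)"`, p-values in scientific notation with 2 decimal digits
#' of mantissa, I-squared to 1 decimal. Rows are ordered by outcome then
#' method so reruns on the same inputs are byte-identical.
#'
#' @param results An `mr_results` tibble.
#' @param path Optional path; when given the table is written as
#'   tab-delimited text.
#' @return The formatted tibble (invisibly when `path` is given).
#' @export
run_report <- function(results, path = NULL) {
  cols <- c("outcome", "method", "n_snp", "or_ci", "p", "Q", "Q_p", "i2",
            "significance")
  if (nrow(results) == 0) {
    out <- tibble::as_tibble(setNames(
      rep(list(character(0)), length(cols)), cols
    ))
  } else {
    out <- tibble::tibble(
      outcome = results$outcome,
      method = results$method,
      n_snp = results$n_snp,
      or_ci = sprintf("%.3f (%.3f–%.3f)", results$or,
                      results$or_ci_low, results$or_ci_high),
      p = formatC(results$p.value, format = "e", digits = 2),
      Q = ifelse(is.na(results$Q), "", sprintf("%.2f", results$Q)),
      Q_p = ifelse(is.na(results$Q.p.value), "",
                   formatC(results$Q.p.value, format = "e", digits = 2)),
      i2 = ifelse(is.na(results$i2), "", sprintf("%.1f", results$i2)),
      significance = results$significance
    )
    out <- dplyr::arrange(out, .data$outcome, .data$method)
  }
  if (!is.null(path)) {
    readr::write_tsv(out, path)
    return(invisible(out))
  }
  out
}
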