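#' Variance in the exposure explained by a SNP
#'
#' Computes, per SNP, R-squared =
#' `2 EAF (1-EAF) beta^2 / (2 EAF (1-EAF) beta^2 + 2 EAF (1-EAF) N se^2)`,
#' the proportion of trait variance captured by the variant under
#' Hardy-Weinberg genotype variance and a standardized trait. Algebraically
#' this equals `z^2 / (z^2 + N)` with `z = beta/se`. SNPs with missing EAF
#' return `NA` and are skipped in aggregate sums.
#'
#' @param eaf Effect-allele frequency, strictly inside (0, 1).
#' @param beta Per-allele effect estimate.
#' @param se Standard error of `beta`, positive.
#' @param n GWAS sample size, at least 3.
#' @return Numeric vector of R-squared values in \[0, 1).
#' @examples
#' variance_explained(0.5, 0.1, 0.014142, 10000)
#' @export
variance_explained <- function(eaf, beta, se, n) {
  k <- max(length(eaf), length(beta), length(se), length(n))
  eaf <- rep_len(eaf, k); beta <- rep_len(beta, k)
  se <- rep_len(se, k); n <- rep_len(n, k)
  if (any(se <= 0, na.rm = TRUE)) abort("se must be positive")
  if (any(n < 3, na.rm = TRUE)) abort("n must be at least 3")
  known <- !is.na(eaf)
  if (any(eaf[known] <= 0 | eaf[known] >= 1)) {
    abort("eaf must lie strictly inside (0, 1)")
  }
  num <- 2 * eaf * (1 - eaf) * beta^2
  den <- num + 2 * eaf * (1 - eaf) * n * se^2
  out <- num / den
  out[!known] <- NA_real_
  out
}

#' Instrument-strength F-statistic
#'
#' `F = R^2 (N - 2) / (1 - R^2)`. Values of 10 or more are conventionally
#' taken to indicate low weak-instrument bias.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n GWAS sample size, at least 3.
#' @return Numeric vector of F-statistics (>= 0).
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 >= 1, na.rm = TRUE)) abort("r2 must be below 1")
  if (any(r2 < 0, na.rm = TRUE)) abort("r2 must be non-negative")
  if (any(n < 3, na.rm = TRUE)) abort("n must be at least 3")
  r2 * (n - 2) / (1 - r2)
}

#' Statistical power of an MR analysis with a binary outcome
#'
#' Normal-approximation power for detecting an odds ratio `odds_ratio` per
#' unit of exposure in a two-sample MR with a case-control outcome GWAS. The
#' non-centrality is `z = |ln OR| * sqrt(N R2 K (1 - K))` where `N` is the
#' outcome GWAS size, `K` its case fraction and `R2` the variance in the
#' exposure explained by the instruments; power is
#' `Phi(z - z_c) + Phi(-z - z_c)` at the two-sided level `alpha`. This is the
#' stated-inputs approximation to the standard online MR power calculators.
#'
#' @param n_total Outcome GWAS sample size (cases + controls).
#' @param case_fraction Proportion of cases, in (0, 1).
#' @param r2_exposure Variance explained in the exposure by the instruments,
#'   in (0, 1).
#' @param odds_ratio Detectable odds ratio per unit exposure, positive.
#' @param alpha Two-sided significance level.
#' @return Power as a probability in \[`alpha`, 1\].
#' @examples
#' mr_power_binary(977323, 47309 / 977323, 0.058, 0.90)
#' @export
mr_power_binary <- function(n_total, case_fraction, r2_exposure, odds_ratio,
                            alpha = 0.05) {
  if (any(case_fraction <= 0 | case_fraction >= 1)) {
    abort("case_fraction must lie strictly inside (0, 1)")
  }
  if (any(r2_exposure <= 0 | r2_exposure >= 1)) {
    abort("r2_exposure must lie strictly inside (0, 1)")
  }
  if (any(odds_ratio <= 0)) abort("odds_ratio must be positive")
  z <- abs(log(odds_ratio)) *
    sqrt(n_total * r2_exposure * case_fraction * (1 - case_fraction))
  zc <- qnorm(1 - alpha / 2)
  pnorm(z - zc) + pnorm(-z - zc)
}

#' Per-SNP instrument quality-control table
#'
#' @param data GWAS tibble of instruments.
#' @return Tibble with `snp_id`, `r2` (variance explained, `NA` when EAF is
#'   missing), `f` (F-statistic) and `z` (Wald z-score), one row per SNP.
#' @export
instrument_qc <- function(data) {
  r2 <- variance_explained(data$eaf, data$beta, data$se, data$n)
  tibble::tibble(
    snp_id = data$snp_id,
    r2 = r2,
    f = f_statistic(r2, data$n),
    z = data$beta / data$se
  )
}

#' Summarize instrument strength
#'
#' Aggregate R-squared is the sum of per-SNP values (instruments are assumed
#' independent after LD pruning in the source GWAS); SNPs with missing EAF are
#' skipped in the sum and counted.
#'
#' @param data GWAS tibble of instruments.
#' @return One-row tibble: `n_snp`, `n_missing_eaf`, `total_r2`, `mean_f`,
#'   `min_f`.
#' @export
qc_summary <- function(data) {
  qc <- instrument_qc(data)
  tibble::tibble(
    n_snp = nrow(qc),
    n_missing_eaf = sum(is.na(qc$r2)),
    total_r2 = sum(qc$r2, na.rm = TRUE),
    mean_f = mean(qc$f, na.rm = TRUE),
    min_f = suppressWarnings(min(qc$f, na.rm = TRUE))
  )
}

#' Published case/control structure of the five cardiovascular outcome GWAS
#'
#' Sample sizes of the large public GWAS meta-analyses used as outcome data:
#' heart failure (47,309 cases / 930,014 controls), coronary artery disease
#' (60,801 / 123,504), myocardial infarction (43,676 / 123,504), stroke
#' (European-ancestry subset, 40,585 / 406,111) and atrial fibrillation
#' (European-ancestry subset, 55,114 / 482,295).
#'
#' @return Tibble with `outcome`, `n_case`, `n_control`, `n_total`,
#'   `case_fraction`.
#' @export
cvd_outcome_counts <- function() {
  out <- tibble::tibble(
    outcome = c("heart_failure", "coronary_artery_disease",
                "myocardial_infarction", "stroke", "atrial_fibrillation"),
    n_case = c(47309, 60801, 43676, 40585, 55114),
    n_control = c(930014, 123504, 123504, 406111, 482295)
  )
  out$n_total <- out$n_case + out$n_control
  out$case_fraction <- out$n_case / out$n_total
  out
}

#' Power table across outcomes
#'
#' @param outcomes Tibble with `outcome`, `n_total`, `case_fraction` (defaults
#'   to [cvd_outcome_counts()]).
#' @param r2_exposure Variance explained by the exposure instruments.
#' @param odds_ratio Detectable odds ratio(s).
#' @param alpha Two-sided significance level.
#' @return Tibble with one row per outcome x odds ratio, `power` in percent.
#' @export
power_table <- function(outcomes = cvd_outcome_counts(), r2_exposure,
                        odds_ratio = 0.90, alpha = 0.05) {
  grid <- tidyr::expand_grid(outcomes, odds_ratio = odds_ratio)
  grid$power <- 100 * mr_power_binary(
    grid$n_total, grid$case_fraction, r2_exposure, grid$odds_ratio, alpha
  )
  grid
}
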