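#' Configuration for the synthetic GWAS generator
#'
#' Describes a two-sample (or, with a mediator, three-sample) summary-level
#' GWAS experiment with known ground truth. Defaults emulate the study design
#' the package targets: an exposure GWAS the size of a large UK Biobank
#' behavioural trait (N = 397,338, standardized units) and a binary outcome
#' GWAS the size of a large heart-failure meta-analysis (N = 977,323 with
#' 47,309 cases), with a protective causal effect of -0.3 on the log-odds
#' scale. Per-SNP standard errors follow the standard asymptotic model for
#' standardized traits under Hardy-Weinberg variance, `1/sqrt(2 f (1-f) N)`,
#' with the `K(1-K)` case-fraction efficiency factor for binary outcomes.
#'
#' @param n_snps Number of instrument SNPs (L >= 3).
#' @param theta True causal effect of exposure on outcome.
#' @param gamma_mean,gamma_sd Distribution of true SNP-exposure effects.
#' @param pleio_frac Fraction of invalid (pleiotropic) instruments.
#' @param pleio_mean,pleio_sd Mean (directional) and SD (balanced) of the
#'   pleiotropic direct effects among invalid instruments.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param case_fraction Case fraction K of a binary outcome GWAS.
#' @param maf_range Range of the uniform minor-allele-frequency distribution.
#' @param swap_frac Fraction of outcome records reported on the opposite
#'   effect allele (beta negated, EAF reflected).
#' @param flip_frac Fraction of outcome records reported on the opposite
#'   strand (alleles complemented).
#' @param palindromic_frac Fraction of SNPs with palindromic allele pairs.
#' @param alpha_true,beta_m_true,direct_true Mediation block: true
#'   exposure-to-mediator effect, mediator-to-outcome effect, and direct
#'   exposure-to-outcome effect. The implied total effect is
#'   `direct_true + alpha_true * beta_m_true`.
#' @param n_mediator Mediator GWAS sample size (an independent third sample).
#' @param n_snps_mediator Number of mediator-specific instrument SNPs.
#' @param sampling_noise Draw effect estimates from their sampling
#'   distributions (`TRUE`, the realistic default); `FALSE` returns the
#'   noise-free expectations, useful for exact decomposition checks.
#' @param seed Integer seed; mandatory, every draw is derived from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_snps = 100, theta = -0.3,
                         gamma_mean = 0.03, gamma_sd = 0.01,
                         pleio_frac = 0, pleio_mean = 0, pleio_sd = 0,
                         n_exposure = 397338, n_outcome = 977323,
                         outcome_type = c("binary", "continuous"),
                         case_fraction = 47309 / 977323,
                         maf_range = c(0.05, 0.5),
                         swap_frac = 0.2, flip_frac = 0.2,
                         palindromic_frac = 0.15,
                         alpha_true = 0.3, beta_m_true = -0.25,
                         direct_true = -0.225,
                         n_mediator = 400000, n_snps_mediator = 100,
                         sampling_noise = TRUE, seed) {
  if (missing(seed)) abort("a seed is mandatory in synth_config()")
  outcome_type <- match.arg(outcome_type)
  if (n_snps < 3) abort("n_snps must be at least 3")
  fr <- c(pleio_frac, swap_frac, flip_frac, palindromic_frac)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (length(maf_range) != 2 || maf_range[1] >= maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    abort("maf_range must be an increasing pair inside (0, 0.5]")
  }
  structure(
    list(
      n_snps = as.integer(n_snps), theta = theta,
      gamma_mean = gamma_mean, gamma_sd = gamma_sd,
      pleio_frac = pleio_frac, pleio_mean = pleio_mean, pleio_sd = pleio_sd,
      n_exposure = n_exposure, n_outcome = n_outcome,
      outcome_type = outcome_type, case_fraction = case_fraction,
      maf_range = maf_range, swap_frac = swap_frac, flip_frac = flip_frac,
      palindromic_frac = palindromic_frac,
      alpha_true = alpha_true, beta_m_true = beta_m_true,
      direct_true = direct_true, n_mediator = n_mediator,
      n_snps_mediator = as.integer(n_snps_mediator),
      sampling_noise = isTRUE(sampling_noise), seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# random allele pairs; palindromic pairs ({A,T} or {C,G}) for flagged SNPs
draw_alleles <- function(pal) {
  n <- length(pal)
  ea <- character(n); oa <- character(n)
  pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  np_pairs <- rbind(
    c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
    c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
  )
  ip <- sample.int(4, n, replace = TRUE)
  inp <- sample.int(8, n, replace = TRUE)
  ea[pal] <- pal_pairs[ip[pal], 1]; oa[pal] <- pal_pairs[ip[pal], 2]
  ea[!pal] <- np_pairs[inp[!pal], 1]; oa[!pal] <- np_pairs[inp[!pal], 2]
  list(ea = ea, oa = oa)
}

se_standardized <- function(eaf, n, case_fraction = NULL) {
  eff <- 2 * eaf * (1 - eaf) * n
  if (!is.null(case_fraction)) eff <- eff * case_fraction * (1 - case_fraction)
  1 / sqrt(eff)
}

pval_from_z <- function(beta, se) 2 * pnorm(-abs(beta / se))

# corrupt outcome-side allele orientation; returns modified columns + flags
corrupt_orientation <- function(df, swap_frac, flip_frac) {
  n <- nrow(df)
  swapped <- runif(n) < swap_frac
  flipped <- runif(n) < flip_frac
  ea <- df$effect_allele; oa <- df$other_allele
  tmp <- ea[swapped]; ea[swapped] <- oa[swapped]; oa[swapped] <- tmp
  df$beta[swapped] <- -df$beta[swapped]
  df$eaf[swapped] <- 1 - df$eaf[swapped]
  ea[flipped] <- complement_alleles(ea[flipped])
  oa[flipped] <- complement_alleles(oa[flipped])
  df$effect_allele <- ea; df$other_allele <- oa
  list(data = df, swapped = swapped, flipped = flipped)
}

#' Simulate a two-sample GWAS summary-statistics experiment
#'
#' Generates exposure and outcome summary datasets with known per-SNP truth.
#' For SNP j with minor allele frequency `f_j ~ U(maf_range)` and true effect
#' `gamma_j ~ N(gamma_mean, gamma_sd)`, the exposure estimate is drawn from
#' `N(gamma_j, se_x^2)` with `se_x = 1/sqrt(2 f (1-f) n_exposure)`, and the
#' outcome estimate from `N(theta gamma_j + a_j, se_y^2)` where `a_j` is the
#' pleiotropic direct effect (zero for valid instruments) and `se_y` carries
#' the binary-outcome `K(1-K)` factor. P-values are two-sided normal.
#' Allele-orientation corruption (swaps and strand flips) is applied to the
#' outcome dataset last; the truth record retains the uncorrupted orientation.
#'
#' @param config A [synth_config()].
#' @return List with `exposure` and `outcome` GWAS tibbles and a `truth`
#'   tibble (per-SNP `gamma`, `pleio`, corruption flags, uncorrupted betas)
#'   carrying the generating parameters in `attr(, "params")`.
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, simulate_two_sample_impl(config))
}

simulate_two_sample_impl <- function(config) {
  L <- config$n_snps
  snp_id <- sprintf("rs%06d", seq_len(L))
  maf <- runif(L, config$maf_range[1], config$maf_range[2])
  eaf <- ifelse(runif(L) < 0.5, maf, 1 - maf)
  pal <- runif(L) < config$palindromic_frac
  al <- draw_alleles(pal)
  gamma <- rnorm(L, config$gamma_mean, config$gamma_sd)
  invalid <- runif(L) < config$pleio_frac
  pleio <- ifelse(invalid, rnorm(L, config$pleio_mean, config$pleio_sd), 0)

  se_x <- se_standardized(eaf, config$n_exposure)
  k_fac <- if (config$outcome_type == "binary") config$case_fraction else NULL
  se_y <- se_standardized(eaf, config$n_outcome, k_fac)
  beta_x <- if (config$sampling_noise) rnorm(L, gamma, se_x) else gamma
  mu_y <- config$theta * gamma + pleio
  beta_y <- if (config$sampling_noise) rnorm(L, mu_y, se_y) else mu_y

  exposure <- as_gwas(tibble::tibble(
    snp_id = snp_id, effect_allele = al$ea, other_allele = al$oa,
    eaf = eaf, beta = beta_x, se = se_x, pval = pval_from_z(beta_x, se_x),
    n = config$n_exposure, n_case = NA_real_
  ), trait_name = "exposure", trait_type = "continuous")

  out_df <- tibble::tibble(
    snp_id = snp_id, effect_allele = al$ea, other_allele = al$oa,
    eaf = eaf, beta = beta_y, se = se_y, pval = pval_from_z(beta_y, se_y),
    n = config$n_outcome,
    n_case = if (config$outcome_type == "binary") {
      round(config$case_fraction * config$n_outcome)
    } else NA_real_
  )
  cor <- corrupt_orientation(out_df, config$swap_frac, config$flip_frac)
  outcome <- as_gwas(cor$data, trait_name = "outcome",
                     trait_type = config$outcome_type)

  truth <- tibble::tibble(
    snp_id = snp_id, maf = maf, eaf = eaf, palindromic = pal,
    gamma = gamma, pleio = pleio, invalid = invalid,
    beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y,
    swapped = cor$swapped, flipped = cor$flipped
  )
  attr(truth, "params") <- config
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate a three-sample mediation chain
#'
#' Extends [simulate_two_sample()] with a mediator measured in its own,
#' independent GWAS sample (honouring the two-sample independence the
#' delta-method standard errors assume). Exposure instruments act on the
#' mediator through `alpha_true`; the mediator adds `n_snps_mediator` SNPs of
#' its own with no exposure effect. Outcome effects are
#' `direct_true * gamma_j + beta_m_true * gamma_Mj` plus noise, so the true
#' total effect is `direct_true + alpha_true * beta_m_true`. No allele
#' corruption is applied along the chain.
#'
#' @param config A [synth_config()] with the mediation block set.
#' @return List with `exposure`, `mediator` and `outcome` GWAS tibbles and a
#'   `truth` tibble whose `attr(, "params")` also records `total_true` and
#'   `proportion_true` (percent mediated).
#' @export
simulate_mediation_chain <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed + 1L, simulate_mediation_chain_impl(config))
}

simulate_mediation_chain_impl <- function(config) {
  L <- config$n_snps
  M <- config$n_snps_mediator
  n_all <- L + M
  snp_id <- sprintf("rs%06d", seq_len(n_all))
  maf <- runif(n_all, config$maf_range[1], config$maf_range[2])
  eaf <- ifelse(runif(n_all) < 0.5, maf, 1 - maf)
  pal <- runif(n_all) < config$palindromic_frac
  al <- draw_alleles(pal)

  # exposure signal lives on the first L SNPs, mediator-own signal on the rest
  gamma <- c(rnorm(L, config$gamma_mean, config$gamma_sd), rep(0, M))
  gamma_m <- config$alpha_true * gamma +
    c(rep(0, L), rnorm(M, config$gamma_mean, config$gamma_sd))
  mu_y <- config$direct_true * gamma + config$beta_m_true * gamma_m

  se_x <- se_standardized(eaf, config$n_exposure)
  se_m <- se_standardized(eaf, config$n_mediator)
  k_fac <- if (config$outcome_type == "binary") config$case_fraction else NULL
  se_y <- se_standardized(eaf, config$n_outcome, k_fac)

  noisy <- config$sampling_noise
  beta_x <- if (noisy) rnorm(n_all, gamma, se_x) else gamma
  beta_m <- if (noisy) rnorm(n_all, gamma_m, se_m) else gamma_m
  beta_y <- if (noisy) rnorm(n_all, mu_y, se_y) else mu_y

  mk <- function(beta, se, n, name, type, n_case = NA_real_) {
    as_gwas(tibble::tibble(
      snp_id = snp_id, effect_allele = al$ea, other_allele = al$oa,
      eaf = eaf, beta = beta, se = se, pval = pval_from_z(beta, se),
      n = n, n_case = n_case
    ), trait_name = name, trait_type = type)
  }
  exposure <- mk(beta_x, se_x, config$n_exposure, "exposure", "continuous")
  mediator <- mk(beta_m, se_m, config$n_mediator, "mediator", "continuous")
  outcome <- mk(
    beta_y, se_y, config$n_outcome, "outcome", config$outcome_type,
    n_case = if (config$outcome_type == "binary") {
      round(config$case_fraction * config$n_outcome)
    } else NA_real_
  )

  truth <- tibble::tibble(
    snp_id = snp_id, maf = maf, eaf = eaf, palindromic = pal,
    gamma = gamma, gamma_m = gamma_m,
    exposure_instrument = c(rep(TRUE, L), rep(FALSE, M)),
    se_x = se_x, se_m = se_m, se_y = se_y
  )
  params <- config
  params$total_true <- config$direct_true +
    config$alpha_true * config$beta_m_true
  params$proportion_true <-
    100 * config$alpha_true * config$beta_m_true / params$total_true
  attr(truth, "params") <- params
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       truth = truth)
}
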