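#' Delta-method standard error of a product of coefficients
#'
#' First-order standard error of `alpha * beta_m`:
#' `sqrt(alpha^2 se_beta_m^2 + beta_m^2 se_alpha^2)`, with the covariance
#' between the two estimates set to zero (they come from non-overlapping
#' two-sample designs).
#'
#' @param alpha Exposure-to-mediator estimate.
#' @param se_alpha Its standard error (non-negative).
#' @param beta_m Mediator-to-outcome estimate (adjusted for the exposure).
#' @param se_beta_m Its standard error (non-negative).
#' @return Standard error of the indirect effect.
#' @examples
#' indirect_se(0.5, 0.1, 0.4, 0.1)
#' @export
indirect_se <- function(alpha, se_alpha, beta_m, se_beta_m) {
  if (any(se_alpha < 0) || any(se_beta_m < 0)) abort("standard errors must be non-negative")
  sqrt(alpha^2 * se_beta_m^2 + beta_m^2 * se_alpha^2)
}

#' Mediated proportion with a delta-method confidence interval
#'
#' The proportion mediated is `indirect / total`, reported in percent. Its
#' standard error comes from the first-order delta method for a ratio,
#' ignoring numerator-denominator covariance:
#' `SE = sqrt(se_ind^2 / total^2 + indirect^2 se_total^2 / total^4)`.
#' The interval is symmetric (`proportion +/- 1.96 SE`) and is not clamped;
#' intervals straddling 0% or exceeding 100% (including sign-discordant
#' direct/indirect effects) are flagged rather than truncated.
#'
#' @param indirect Indirect (mediated) effect, log scale.
#' @param se_ind Its standard error.
#' @param total Total effect, log scale (non-zero).
#' @param se_total Its standard error.
#' @param conf_level Confidence level.
#' @return One-row tibble: `proportion`, `se`, `conf.low`, `conf.high` (all in
#'   percent) and `flag` (`"ok"`, `"straddles-zero"`, `"exceeds-100"` or both,
#'   comma-separated).
#' @export
proportion_ci <- function(indirect, se_ind, total, se_total,
                          conf_level = 0.95) {
  if (total == 0) abort("total effect is zero: proportion undefined")
  z <- qnorm(1 - (1 - conf_level) / 2)
  prop <- indirect / total
  se_prop <- sqrt(se_ind^2 / total^2 + indirect^2 * se_total^2 / total^4)
  lo <- prop - z * se_prop
  hi <- prop + z * se_prop
  flags <- character(0)
  if (lo < 0 && hi > 0) flags <- c(flags, "straddles-zero")
  if (hi > 1 || prop > 1) flags <- c(flags, "exceeds-100")
  if (prop < 0) flags <- c(flags, "sign-discordant")
  tibble::tibble(
    proportion = 100 * prop, se = 100 * se_prop,
    conf.low = 100 * lo, conf.high = 100 * hi,
    flag = if (length(flags)) paste(flags, collapse = ",") else "ok"
  )
}

#' Two-step MR mediation analysis
#'
#' Decomposes the exposure-to-outcome effect through a mediator:
#' \enumerate{
#'   \item the total effect `theta_T` is the random-effects IVW estimate of
#'     exposure on outcome using the exposure's instruments;
#'   \item the exposure-to-mediator effect `alpha` is the random-effects IVW
#'     estimate using the same instruments;
#'   \item the mediator-to-outcome effect adjusted for the exposure, `beta_m`,
#'     is the mediator's direct effect from a multivariable IVW of
#'     (mediator, exposure) on the outcome using the mediator's own
#'     instruments.
#' }
#' The indirect effect is the product `alpha * beta_m` with delta-method
#' standard error ([indirect_se()]); the mediated proportion divides it by the
#' total effect ([proportion_ci()]).
#'
#' @param exposure,mediator,outcome GWAS tibbles.
#' @param p_threshold Instrument-selection threshold.
#' @param maf_threshold Palindromic exclusion bound.
#' @param outcome_p_threshold Outcome-association exclusion bound for the
#'   univariable steps; `NULL` disables.
#' @param proxies Optional LD proxy table.
#' @param denominator `"total"` divides the indirect effect by the estimated
#'   total effect (default, matching how mediated proportions of a total
#'   association are reported); `"direct-plus-indirect"` uses the
#'   recomposition `direct + indirect` instead.
#' @return Object of class `mediation_result`; see [tidy.mediation_result()].
#' @export
mr_mediate <- function(exposure, mediator, outcome, p_threshold = 5e-8,
                       maf_threshold = 0.42, outcome_p_threshold = 5e-8,
                       proxies = NULL,
                       denominator = c("total", "direct-plus-indirect")) {
  denominator <- match.arg(denominator)
  exp_inst <- select_instruments(exposure, p_threshold = p_threshold)
  med_inst <- select_instruments(mediator, p_threshold = p_threshold)
  if (nrow(exp_inst) < 3 || nrow(med_inst) < 3) {
    abort("exposure and mediator each require at least 3 instruments")
  }

  total <- mr_ivw(harmonize(exp_inst, outcome, maf_threshold = maf_threshold,
                            outcome_p_threshold = outcome_p_threshold,
                            proxies = proxies))
  alpha <- mr_ivw(harmonize(exp_inst, mediator, maf_threshold = maf_threshold,
                            outcome_p_threshold = NULL, proxies = proxies))
  mv <- mvmr_ivw(assemble_mvmr_input(
    list(mediator = mediator, exposure = exposure), outcome,
    p_threshold = p_threshold, maf_threshold = maf_threshold,
    instruments = med_inst$snp_id
  ))
  beta_m <- mv$beta[["mediator"]]
  se_beta_m <- mv$se[["mediator"]]
  direct <- mv$beta[["exposure"]]

  ind <- alpha$beta * beta_m
  se_ind <- indirect_se(alpha$beta, alpha$se, beta_m, se_beta_m)
  denom <- if (denominator == "total") total$beta else direct + ind
  prop <- if (abs(denom) < sqrt(.Machine$double.eps)) {
    tibble::tibble(proportion = NA_real_, se = NA_real_, conf.low = NA_real_,
                   conf.high = NA_real_, flag = "total-effect-near-zero")
  } else {
    proportion_ci(ind, se_ind, denom, if (denominator == "total") total$se else NA_real_)
  }
  if (denominator != "total" && !is.na(prop$proportion)) {
    # recomposed denominator has no simple SE; report the point estimate only
    prop$se <- NA_real_; prop$conf.low <- NA_real_; prop$conf.high <- NA_real_
  }

  structure(
    list(
      total = total, alpha = alpha, mvmr = mv,
      beta_m = beta_m, se_beta_m = se_beta_m,
      direct = direct, se_direct = mv$se[["exposure"]],
      indirect = ind, se_indirect = se_ind,
      proportion = prop, denominator = denominator
    ),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step MR mediation\n")
  cat(sprintf("  total effect     %.4f (SE %.4f)\n", x$total$beta, x$total$se))
  cat(sprintf("  exposure->mediator %.4f (SE %.4f)\n", x$alpha$beta, x$alpha$se))
  cat(sprintf("  mediator->outcome  %.4f (SE %.4f)  [exposure-adjusted]\n",
              x$beta_m, x$se_beta_m))
  cat(sprintf("  direct effect    %.4f (SE %.4f)\n", x$direct, x$se_direct))
  cat(sprintf("  indirect effect  %.4f (SE %.4f)\n", x$indirect, x$se_indirect))
  p <- x$proportion
  cat(sprintf("  proportion mediated %.1f%% (95%% CI %.1f to %.1f) [%s]\n",
              p$proportion, p$conf.low, p$conf.high, p$flag))
  invisible(x)
}

#' Tidy a mediation result
#'
#' @param x A `mediation_result`.
#' @param ... Unused.
#' @return One-row tibble with the total, exposure-to-mediator,
#'   mediator-to-outcome, direct and indirect effects (each with its standard
#'   error) and the mediated proportion in percent with its confidence
#'   interval and flag.
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    total = x$total$beta, se_total = x$total$se,
    alpha = x$alpha$beta, se_alpha = x$alpha$se,
    beta_m = x$beta_m, se_beta_m = x$se_beta_m,
    direct = x$direct, se_direct = x$se_direct,
    indirect = x$indirect, se_indirect = x$se_indirect,
    proportion = x$proportion$proportion,
    prop.conf.low = x$proportion$conf.low,
    prop.conf.high = x$proportion$conf.high,
    flag = x$proportion$flag
  )
}
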