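#' Per-SNP Wald ratio estimates
#'
#' The Wald ratio is the SNP-outcome beta divided by the SNP-exposure beta.
#' Its standard error is first-order `se_out / |beta_exp|` by default; the
#' second-order form adds the exposure uncertainty term
#' `beta_out^2 se_exp^2 / beta_exp^4`. SNPs with a zero exposure beta are
#' dropped with a warning.
#'
#' @param pairs Harmonized pair tibble (excluded rows are ignored).
#' @param second_order Use the second-order delta-method standard error.
#' @return Tibble: `snp_id`, `ratio`, `se_ratio`, `weight` (1/se_ratio^2).
#' @export
wald_ratios <- function(pairs, second_order = FALSE) {
  pairs <- kept_pairs(pairs)
  zero <- pairs$beta_exp == 0
  if (any(zero)) {
    warn(sprintf("%d SNP(s) with zero exposure beta dropped from ratio estimates",
                 sum(zero)))
    pairs <- pairs[!zero, ]
  }
  se <- if (second_order) {
    sqrt(pairs$se_out^2 / pairs$beta_exp^2 +
           pairs$beta_out^2 * pairs$se_exp^2 / pairs$beta_exp^4)
  } else {
    pairs$se_out / abs(pairs$beta_exp)
  }
  tibble::tibble(
    snp_id = pairs$snp_id,
    ratio = pairs$beta_out / pairs$beta_exp,
    se_ratio = se,
    weight = 1 / se^2
  )
}

new_mr_fit <- function(method, n_snp, beta, se, pval, heterogeneity = NULL,
                       df = NULL) {
  structure(
    list(
      method = method, n_snp = n_snp, beta = beta, se = se,
      ci_low = beta - qnorm(0.975) * se, ci_high = beta + qnorm(0.975) * se,
      pval = pval, heterogeneity = heterogeneity, df = df
    ),
    class = "mr_fit"
  )
}

het_stats <- function(Q, df) {
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  band <- if (i2 <= 25) "low" else if (i2 < 50) "moderate" else "high"
  list(
    Q = Q, df = df,
    pval = if (df > 0) pchisq(Q, df, lower.tail = FALSE) else NA_real_,
    i2 = i2, band = band
  )
}

#' Wald-ratio causal estimate from a single SNP
#'
#' @param pair One-row harmonized pair tibble.
#' @param second_order Use the second-order delta-method standard error.
#' @return An `mr_fit` object (method `"wald-ratio"`).
#' @export
mr_wald_ratio <- function(pair, second_order = FALSE) {
  wr <- wald_ratios(pair, second_order = second_order)
  if (nrow(wr) < 1) abort("no usable pair for the Wald ratio")
  wr <- wr[1, ]
  new_mr_fit("wald-ratio", 1L, wr$ratio, wr$se_ratio,
             2 * pnorm(-abs(wr$ratio / wr$se_ratio)))
}

#' Random-effects inverse-variance weighted causal estimate
#'
#' Weighted least squares of outcome betas on exposure betas through the
#' origin with weights `1/se_out^2`: the point estimate is
#' `sum(w bx by) / sum(w bx^2)` and the fixed-effect standard error
#' `1 / sqrt(sum(w bx^2))`. Heterogeneity is quantified by Cochran's
#' `Q = sum(w (by - theta bx)^2)` on `L - 1` degrees of freedom and
#' `I^2 = max(0, (Q - df)/Q) * 100`. The multiplicative random-effects
#' standard error inflates the fixed-effect one by `sqrt(Q/df)`, floored at 1
#' so the random-effects interval is never narrower than the fixed-effect
#' interval. With a single usable SNP the estimate falls back to the Wald
#' ratio.
#'
#' @param pairs Harmonized pair tibble.
#' @param second_order Use second-order Wald-ratio standard errors (affects
#'   only the single-SNP fallback).
#' @return An `mr_fit` with method `"ivw-re"` and a `heterogeneity` element
#'   (`Q`, `df`, `pval`, `i2`, `band`); see [glance.mr_fit()].
#' @export
mr_ivw <- function(pairs, second_order = FALSE) {
  pairs <- kept_pairs(pairs)
  pairs <- pairs[pairs$beta_exp != 0, ]
  L <- nrow(pairs)
  if (L < 1) abort("no usable harmonized pairs")
  if (L == 1) return(mr_wald_ratio(pairs, second_order = second_order))
  w <- 1 / pairs$se_out^2
  bx <- pairs$beta_exp
  by <- pairs$beta_out
  theta <- sum(w * bx * by) / sum(w * bx^2)
  se_fe <- 1 / sqrt(sum(w * bx^2))
  Q <- sum(w * (by - theta * bx)^2)
  df <- L - 1
  se_re <- se_fe * sqrt(max(1, Q / df))
  new_mr_fit("ivw-re", L, theta, se_re, 2 * pnorm(-abs(theta / se_re)),
             heterogeneity = het_stats(Q, df))
}

#' Weighted median of a set of values
#'
#' Linear-interpolation weighted median: with values sorted and normalized
#' weights `w_i`, the cumulative midpoints are `p_i = cumsum(w)_i - w_i/2`;
#' the estimate interpolates the sorted values at `p = 0.5`.
#'
#' @param x Numeric values.
#' @param w Positive weights.
#' @return The weighted median.
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(x[1])
  n <- length(x)
  if (0.5 >= p[n]) return(x[n])
  hi <- which(p >= 0.5)[1]
  lo <- hi - 1L
  x[lo] + (x[hi] - x[lo]) * (0.5 - p[lo]) / (p[hi] - p[lo])
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios, weighted by their inverse
#' variance, is consistent when at least half of the instrument weight comes
#' from valid instruments. The standard error is obtained by a seeded
#' parametric bootstrap: exposure and outcome betas are redrawn from their
#' sampling distributions and the weighted median recomputed `n_boot` times.
#'
#' @param pairs Harmonized pair tibble with at least 3 usable SNPs.
#' @param n_boot Bootstrap replicates (values below 100 trigger a warning).
#' @param seed Integer seed for the bootstrap (required, for reproducibility).
#' @param second_order Use second-order Wald-ratio standard errors.
#' @return An `mr_fit` with method `"weighted-median"`.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed, second_order = FALSE) {
  if (missing(seed)) abort("a bootstrap seed is required")
  if (n_boot < 100) warn("n_boot < 100: bootstrap SE will be unstable")
  pairs <- kept_pairs(pairs)
  pairs <- pairs[pairs$beta_exp != 0, ]
  L <- nrow(pairs)
  if (L < 3) abort("weighted median requires at least 3 usable SNPs")
  wr <- wald_ratios(pairs, second_order = second_order)
  est <- weighted_median(wr$ratio, wr$weight)
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(L, pairs$beta_exp, pairs$se_exp)
      by <- rnorm(L, pairs$beta_out, pairs$se_out)
      ok <- bx != 0
      r <- by[ok] / bx[ok]
      se_r <- if (second_order) {
        sqrt(pairs$se_out[ok]^2 / bx[ok]^2 + by[ok]^2 * pairs$se_exp[ok]^2 / bx[ok]^4)
      } else {
        pairs$se_out[ok] / abs(bx[ok])
      }
      weighted_median(r, 1 / se_r^2)
    }, numeric(1))
  })
  se <- sd(boots)
  new_mr_fit("weighted-median", L, est, se, 2 * pnorm(-abs(est / se)))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with an
#' intercept, weights `1/se_out^2`, after orienting all exposure betas
#' non-negative (flipping both betas of a pair changes nothing downstream and
#' makes the intercept interpretable). The intercept estimates the average
#' directional pleiotropy; its test is the directional-pleiotropy check. The
#' residual standard deviation is floored at 1 (multiplicative overdispersion,
#' as in the IVW random-effects model) and p-values use the t distribution on
#' `L - 2` degrees of freedom.
#'
#' @param pairs Harmonized pair tibble with at least 3 usable SNPs.
#' @return Object of class `mr_egger_fit` with elements `slope` and
#'   `intercept` (each an `mr_fit`) and `heterogeneity` on `L - 2` degrees of
#'   freedom.
#' @export
mr_egger <- function(pairs) {
  pairs <- kept_pairs(pairs)
  pairs <- pairs[pairs$beta_exp != 0, ]
  L <- nrow(pairs)
  if (L < 3) abort("MR-Egger requires at least 3 usable SNPs")
  flip <- pairs$beta_exp < 0
  bx <- abs(pairs$beta_exp)
  by <- ifelse(flip, -pairs$beta_out, pairs$beta_out)
  w <- 1 / pairs$se_out^2
  if (isTRUE(all.equal(stats::var(bx), 0)) || length(unique(bx)) == 1L) {
    abort("all exposure betas equal: Egger slope unidentifiable")
  }
  # weighted normal equations for [intercept, slope]
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coef <- drop(solve(XtWX, crossprod(X, w * by)))
  resid <- by - drop(X %*% coef)
  Q <- sum(w * resid^2)
  df <- L - 2
  sigma <- sqrt(Q / df)
  se <- unname(sqrt(diag(solve(XtWX)))) * max(1, sigma)
  coef <- unname(coef)
  pvals <- 2 * pt(-abs(coef / se), df)
  slope <- new_mr_fit("egger-slope", L, coef[2], se[2], pvals[2], df = df)
  intercept <- new_mr_fit("egger-intercept", L, coef[1], se[1], pvals[1], df = df)
  structure(
    list(slope = slope, intercept = intercept,
         heterogeneity = het_stats(Q, df), n_snp = L),
    class = "mr_egger_fit"
  )
}

#' Convert a log-scale estimate to an odds ratio with 95% CI
#'
#' @param beta Log-odds-ratio estimate.
#' @param se Its standard error (positive).
#' @return Tibble with `or`, `ci_low`, `ci_high`.
#' @examples
#' to_odds_ratio(-0.3567, 0.0466)
#' @export
to_odds_ratio <- function(beta, se) {
  if (any(se <= 0)) abort("se must be positive")
  z <- qnorm(0.975)
  tibble::tibble(
    or = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se)
  )
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method, x$n_snp))
  cat(sprintf("  beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  if (!is.null(x$heterogeneity)) {
    h <- x$heterogeneity
    cat(sprintf("  Cochran Q = %.2f (df %d, p = %.3g), I2 = %.1f%% (%s)\n",
                h$Q, h$df, h$pval, h$i2, h$band))
  }
  invisible(x)
}

#' @export
print.mr_egger_fit <- function(x, ...) {
  cat("MR-Egger regression\n")
  print(x$slope)
  print(x$intercept)
  invisible(x)
}

#' Tidy an MR fit
#'
#' @param x An `mr_fit`.
#' @param exponentiate Report on the odds-ratio scale (for binary outcomes).
#' @param ... Unused.
#' @return One-row tibble: `method`, `n_snp`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `p.value`.
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, exponentiate = FALSE, ...) {
  out <- tibble::tibble(
    method = x$method, n_snp = x$n_snp,
    estimate = x$beta, std.error = x$se,
    conf.low = x$ci_low, conf.high = x$ci_high,
    p.value = x$pval
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' @rdname tidy.mr_fit
#' @method tidy mr_egger_fit
#' @export
tidy.mr_egger_fit <- function(x, exponentiate = FALSE, ...) {
  dplyr::bind_rows(
    tidy(x$slope, exponentiate = exponentiate),
    tidy(x$intercept)
  )
}

#' Heterogeneity summary of an MR fit
#'
#' @param x An `mr_fit` or `mr_egger_fit`.
#' @param ... Unused.
#' @return One-row tibble: `Q`, `df`, `Q.p.value`, `i2`, `band` (the 25%/50%
#'   qualitative heterogeneity bands), or a zero-row tibble when the method
#'   carries no heterogeneity statistic.
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  h <- x$heterogeneity
  if (is.null(h)) {
    return(tibble::tibble(
      Q = numeric(0), df = integer(0), Q.p.value = numeric(0),
      i2 = numeric(0), band = character(0)
    ))
  }
  tibble::tibble(Q = h$Q, df = as.integer(h$df), Q.p.value = h$pval,
                 i2 = h$i2, band = h$band)
}

#' @rdname glance.mr_fit
#' @method glance mr_egger_fit
#' @export
glance.mr_egger_fit <- function(x, ...) {
  h <- x$heterogeneity
  tibble::tibble(Q = h$Q, df = as.integer(h$df), Q.p.value = h$pval,
                 i2 = h$i2, band = h$band)
}
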