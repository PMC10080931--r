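# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately built on different code paths than the package:
# stats::lm / lm.wfit for weighted least squares, stats::approx for the
# interpolated weighted quantile.

make_pairs <- function(beta_exp, beta_out, se_exp, se_out,
                       snp_id = sprintf("rs%04d", seq_along(beta_exp))) {
  tibble::tibble(
    snp_id = snp_id,
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = se_exp, eaf_exp = 0.3,
    pval_exp = 2 * stats::pnorm(-abs(beta_exp / se_exp)),
    n_exp = 1e5,
    beta_out = beta_out, se_out = se_out, eaf_out = 0.3,
    pval_out = 2 * stats::pnorm(-abs(beta_out / se_out)),
    n_out = 1e5,
    proxy_snp = NA_character_,
    status = "kept", exclusion_reason = NA_character_
  )
}

random_pairs <- function(L, seed) {
  withr::with_seed(seed, {
    bx <- stats::rnorm(L, 0.1, 0.05)
    bx[abs(bx) < 1e-3] <- 0.05
    make_pairs(
      beta_exp = bx,
      beta_out = stats::rnorm(L, 0.05, 0.05),
      se_exp = stats::runif(L, 0.005, 0.03),
      se_out = stats::runif(L, 0.01, 0.05)
    )
  })
}

make_gwas <- function(snp_id, effect_allele, other_allele, beta, se, pval,
                      eaf = 0.3, n = 1e5, n_case = NA_real_,
                      trait_name = "trait", trait_type = "continuous") {
  as_gwas(tibble::tibble(
    snp_id = snp_id, effect_allele = effect_allele,
    other_allele = other_allele, eaf = eaf, beta = beta, se = se,
    pval = pval, n = n, n_case = n_case
  ), trait_name = trait_name, trait_type = trait_type)
}

# weighted least squares through the origin (fixed-effect IVW oracle)
oracle_ivw <- function(pairs) {
  d <- pairs[is.na(pairs$exclusion_reason), ]
  w <- 1 / d$se_out^2
  fit <- stats::lm(beta_out ~ 0 + beta_exp, data = d, weights = w)
  sm <- summary(fit)
  theta <- unname(stats::coef(fit))
  se_fe <- unname(sm$coefficients[, 2] / sm$sigma)
  Q <- sum(w * stats::resid(fit)^2)
  df <- nrow(d) - 1
  list(theta = theta, se_fe = se_fe,
       se_re = se_fe * sqrt(max(1, Q / df)), Q = Q, df = df)
}

oracle_egger <- function(pairs) {
  d <- pairs[is.na(pairs$exclusion_reason), ]
  flip <- d$beta_exp < 0
  bx <- abs(d$beta_exp)
  by <- ifelse(flip, -d$beta_out, d$beta_out)
  w <- 1 / d$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  se_unscaled <- sm$coefficients[, 2] / sm$sigma
  list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    se = unname(se_unscaled * max(1, sm$sigma)),
    Q = sum(w * stats::resid(fit)^2)
  )
}

oracle_mvmr <- function(X, y, w) {
  fit <- stats::lm.wfit(X, y, w)
  sigma2 <- sum(w * fit$residuals^2) / (length(y) - ncol(X))
  R <- qr.R(fit$qr)
  cov_unscaled <- chol2inv(R)
  list(coef = unname(fit$coefficients),
       se = sqrt(diag(cov_unscaled)) * max(1, sqrt(sigma2)))
}

# interpolated weighted quantile via stats::approx
oracle_weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  stats::approx(p, x, xout = 0.5)$y
}
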