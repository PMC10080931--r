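test_that("Wald ratio follows the ratio formula with sign handling", {
  p1 <- make_pairs(0.5, 0.05, 0.01, 0.02)
  f1 <- mr_wald_ratio(p1)
  expect_equal(f1$beta, 0.1)
  expect_equal(f1$se, 0.04)
  p2 <- make_pairs(-0.5, 0.05, 0.01, 0.02)
  f2 <- mr_wald_ratio(p2)
  expect_equal(f2$beta, -0.1)
  expect_equal(f2$se, 0.04)
})

test_that("first-order ratio SE matches a finite-difference delta oracle", {
  pairs <- random_pairs(1000, seed = 17)
  wr <- wald_ratios(pairs)
  # gradient of by/bx in by is 1/bx; first-order propagation of se_out only
  eps <- 1e-6
  grad <- ((pairs$beta_out + eps) / pairs$beta_exp -
             (pairs$beta_out - eps) / pairs$beta_exp) / (2 * eps)
  expect_equal(wr$se_ratio, abs(grad) * pairs$se_out, tolerance = 1e-6)
})

test_that("zero exposure betas are dropped from ratio estimates with a warning", {
  pairs <- make_pairs(c(0.5, 0), c(0.05, 0.01), 0.01, 0.02)
  expect_warning(wr <- wald_ratios(pairs), "zero exposure beta")
  expect_equal(nrow(wr), 1)
})

test_that("IVW reproduces the homogeneous and frozen worked examples", {
  hom <- make_pairs(c(1, 2), c(0.5, 1.0), 0.01, c(0.1, 0.1))
  f <- mr_ivw(hom)
  expect_equal(f$beta, 0.5)
  expect_equal(f$heterogeneity$Q, 0)
  expect_equal(f$heterogeneity$i2, 0)

  tri <- make_pairs(c(1, 1, 2), c(0.4, 0.6, 1.0), 0.01, c(0.1, 0.1, 0.2))
  f3 <- mr_ivw(tri)
  expect_equal(f3$beta, 0.5, tolerance = 1e-12)
  expect_equal(f3$heterogeneity$Q, 2, tolerance = 1e-12)
  expect_equal(f3$heterogeneity$df, 2)
  expect_equal(f3$se, 1 / sqrt(300), tolerance = 1e-12)  # Q/df = 1: RE = FE
})

test_that("IVW is order-invariant and duplication scales Q with its df", {
  pairs <- random_pairs(25, seed = 23)
  f <- mr_ivw(pairs)
  perm <- withr::with_seed(1, sample.int(25))
  expect_equal(mr_ivw(pairs[perm, ])$beta, f$beta, tolerance = 1e-12)
  dup <- dplyr::bind_rows(pairs, pairs)
  fd <- mr_ivw(dup)
  expect_equal(fd$beta, f$beta, tolerance = 1e-12)
  expect_equal(fd$heterogeneity$Q, 2 * f$heterogeneity$Q, tolerance = 1e-10)
  expect_equal(fd$heterogeneity$df, 2 * 25 - 1)
  # I2 from the duplicated set moves only by the O(1/Q) df correction
  expect_lt(abs(fd$heterogeneity$i2 - f$heterogeneity$i2), 2)
})

test_that("single-instrument IVW equals the Wald ratio exactly", {
  p <- make_pairs(0.37, -0.11, 0.012, 0.021)
  expect_identical(mr_ivw(p)[c("beta", "se", "pval")],
                   mr_wald_ratio(p)[c("beta", "se", "pval")])
})

test_that("weighted median interpolates the 0.5 cumulative-weight point", {
  expect_equal(weighted_median(c(0.1, 0.2, 0.3), rep(1, 3)), 0.2)
  expect_equal(weighted_median(c(0.3, 0.1, 0.2), rep(2, 3)), 0.2)
  # dominant-weight value wins (up to the interpolation step)
  expect_lt(weighted_median(c(0, 1), c(100, 1)), 0.01)
  expect_equal(weighted_median(5, 1), 5)
})

test_that("weighted median resists a minority of invalid instruments", {
  pairs <- make_pairs(
    beta_exp = rep(1, 14),
    beta_out = c(rep(0.5, 10), rep(5, 4)),
    se_exp = 0.01,
    se_out = c(rep(0.05, 10), rep(0.05, 4))
  )
  wm <- mr_weighted_median(pairs, n_boot = 200, seed = 2)
  ivw <- mr_ivw(pairs)
  expect_lt(abs(wm$beta - 0.5), 0.05)
  expect_gt(abs(ivw$beta - 0.5), 0.5)  # IVW dragged by the outliers
})

test_that("bootstrap SE is seed-deterministic and seed-stable", {
  pairs <- random_pairs(20, seed = 29)
  a <- mr_weighted_median(pairs, n_boot = 300, seed = 7)
  b <- mr_weighted_median(pairs, n_boot = 300, seed = 7)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(pairs, n_boot = 300, seed = 8)
  expect_false(identical(a$se, c$se))
  expect_lt(abs(a$se - c$se) / a$se, 0.5)  # Monte-Carlo tolerance
  expect_warning(mr_weighted_median(pairs, n_boot = 50, seed = 1), "unstable")
})

test_that("Egger recovers an exact affine relation with zero residual Q", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  pairs <- make_pairs(bx, 0.1 + 0.5 * bx, 0.01, 0.02)
  f <- mr_egger(pairs)
  expect_equal(f$intercept$beta, 0.1, tolerance = 1e-10)
  expect_equal(f$slope$beta, 0.5, tolerance = 1e-10)
  expect_equal(f$heterogeneity$Q, 0, tolerance = 1e-16)
  expect_equal(f$heterogeneity$df, 2)
})

test_that("Egger is unidentifiable when all exposure betas coincide", {
  pairs <- make_pairs(rep(0.2, 5), rnorm(5, 0.1, 0.01), 0.01, 0.02)
  expect_error(mr_egger(pairs), "unidentifiable")
})

test_that("Egger p-values use the t distribution on L-2 df", {
  pairs <- random_pairs(10, seed = 37)
  f <- mr_egger(pairs)
  expect_equal(f$slope$pval,
               2 * pt(-abs(f$slope$beta / f$slope$se), 8), tolerance = 1e-12)
})

test_that("odds-ratio transform round-trips the log scale", {
  o0 <- to_odds_ratio(0, 0.1)
  expect_equal(o0$or, 1)
  expect_equal(o0$ci_low, exp(-qnorm(0.975) * 0.1))
  # log-transform round trip of a printed protective association
  o <- to_odds_ratio(-0.3567, 0.0466)
  expect_equal(o$or, 0.700, tolerance = 5e-4)
  expect_equal(o$ci_low, 0.639, tolerance = 5e-4)
  expect_equal(o$ci_high, 0.767, tolerance = 5e-4)
  ors <- to_odds_ratio(c(-0.2, -0.1, 0.3), 0.05)$or
  expect_true(all(diff(ors) > 0))
})

test_that("rescaling the exposure divides every causal estimate by the factor", {
  pairs <- random_pairs(30, seed = 43)
  k <- 2.5
  scaled <- pairs
  scaled$beta_exp <- scaled$beta_exp * k
  scaled$se_exp <- scaled$se_exp * k
  expect_equal(mr_ivw(scaled)$beta, mr_ivw(pairs)$beta / k, tolerance = 1e-12)
  expect_equal(mr_egger(scaled)$slope$beta, mr_egger(pairs)$slope$beta / k,
               tolerance = 1e-12)
  wm <- mr_weighted_median(pairs, n_boot = 200, seed = 4)
  wm_k <- mr_weighted_median(scaled, n_boot = 200, seed = 4)
  expect_equal(wm_k$beta, wm$beta / k, tolerance = 1e-12)
  expect_equal(wm_k$se, wm$se / k, tolerance = 1e-12)
})

test_that("tidy and glance expose broom-shaped summaries", {
  pairs <- random_pairs(15, seed = 47)
  f <- mr_ivw(pairs)
  td <- tidy(f)
  expect_named(td, c("method", "n_snp", "estimate", "std.error", "conf.low",
                     "conf.high", "p.value"))
  expect_equal(tidy(f, exponentiate = TRUE)$estimate, exp(td$estimate))
  gl <- glance(f)
  expect_named(gl, c("Q", "df", "Q.p.value", "i2", "band"))
  eg <- mr_egger(pairs)
  expect_equal(nrow(tidy(eg)), 2)
  expect_setequal(tidy(eg)$method, c("egger-slope", "egger-intercept"))
})
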