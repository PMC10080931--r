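test_that("palindromic allele pairs are exactly A/T and C/G", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("A", "G"))
  expect_equal(is_palindromic(c("T", "G", "C"), c("A", "C", "A")),
               c(TRUE, TRUE, FALSE))
})

test_that("swapped outcome alleles are flipped onto the exposure orientation", {
  exp <- make_gwas("rs1", "A", "G", beta = 0.10, se = 0.01, pval = 1e-9,
                   eaf = 0.25)
  out <- make_gwas("rs1", "G", "A", beta = -0.05, se = 0.02, pval = 0.01,
                   eaf = 0.70)
  pair <- align_alleles(exp, out)
  expect_equal(pair$beta_out, 0.05)
  expect_equal(pair$eaf_out, 0.30)
  expect_equal(pair$status, "flipped")
  expect_true(is.na(pair$exclusion_reason))
})

test_that("alignment matches an exhaustive rule-table over all 16 configurations", {
  # independent enumeration: for each ordered outcome allele pair, decide by
  # first principles whether it is the same orientation, the swapped one,
  # either of those on the opposite strand, or irreconcilable
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  exp <- make_gwas("rs1", "A", "G", beta = 0.10, se = 0.01, pval = 1e-9,
                   eaf = 0.25)
  combos <- expand.grid(ea = c("A", "C", "G", "T"), oa = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ea != combos$oa, ]
  for (i in seq_len(nrow(combos))) {
    ea <- combos$ea[i]; oa <- combos$oa[i]
    out <- make_gwas("rs1", ea, oa, beta = 0.05, se = 0.02, pval = 0.01,
                     eaf = 0.70)
    pair <- align_alleles(exp, out)
    expected <-
      if (ea == "A" && oa == "G") list(beta = 0.05, status = "kept")
      else if (ea == "G" && oa == "A") list(beta = -0.05, status = "flipped")
      else if (comp[ea] == "A" && comp[oa] == "G") list(beta = 0.05, status = "kept")
      else if (comp[ea] == "G" && comp[oa] == "A") list(beta = -0.05, status = "flipped")
      else list(beta = NA, status = NA)
    if (is.na(expected$status)) {
      expect_equal(pair$exclusion_reason, "allele-mismatch",
                   label = paste(ea, oa))
    } else {
      expect_true(is.na(pair$exclusion_reason), label = paste(ea, oa))
      expect_equal(pair$beta_out, expected$beta, label = paste(ea, oa))
      expect_equal(pair$status, expected$status, label = paste(ea, oa))
    }
  }
})

test_that("palindromic orientation is resolved by allele-frequency concordance", {
  exp <- make_gwas("rs1", "A", "T", beta = 0.10, se = 0.01, pval = 1e-9,
                   eaf = 0.20)
  concordant <- make_gwas("rs1", "A", "T", beta = 0.05, se = 0.02, pval = 0.01,
                          eaf = 0.25)
  p1 <- align_alleles(exp, concordant)
  expect_equal(p1$beta_out, 0.05)
  expect_equal(p1$status, "kept")
  # reported EAF on the other side of 0.5: the record is on the other strand
  discordant <- make_gwas("rs1", "A", "T", beta = 0.05, se = 0.02, pval = 0.01,
                          eaf = 0.75)
  p2 <- align_alleles(exp, discordant)
  expect_equal(p2$beta_out, -0.05)
  expect_equal(p2$eaf_out, 0.25)
  expect_equal(p2$status, "flipped")
  # missing EAF leaves the strand undecidable
  no_eaf <- make_gwas("rs1", "A", "T", beta = 0.05, se = 0.02, pval = 0.01,
                      eaf = NA_real_)
  p3 <- align_alleles(exp, no_eaf)
  expect_equal(p3$exclusion_reason, "palindromic-ambiguous")
})

test_that("single-record alignment with mismatched snp ids is fatal", {
  exp <- make_gwas("rs1", "A", "G", beta = 0.1, se = 0.01, pval = 1e-9)
  out <- make_gwas("rs2", "A", "G", beta = 0.1, se = 0.01, pval = 0.5)
  expect_error(align_alleles(exp, out), "snp_id mismatch")
})

test_that("palindromic MAF filter excludes strictly above 0.42", {
  pairs <- dplyr::bind_rows(
    make_pairs(0.1, 0.05, 0.01, 0.02, snp_id = "rs_pal_high"),
    make_pairs(0.1, 0.05, 0.01, 0.02, snp_id = "rs_pal_low"),
    make_pairs(0.1, 0.05, 0.01, 0.02, snp_id = "rs_nonpal"),
    make_pairs(0.1, 0.05, 0.01, 0.02, snp_id = "rs_pal_border")
  )
  pairs$effect_allele <- c("A", "C", "A", "A")
  pairs$other_allele <- c("T", "G", "G", "T")
  pairs$eaf_exp <- c(0.45, 0.10, 0.50, 0.42)
  res <- filter_palindromic(pairs)
  expect_equal(res$exclusion_reason[res$snp_id == "rs_pal_high"],
               "palindromic-ambiguous")
  expect_true(is.na(res$exclusion_reason[res$snp_id == "rs_pal_low"]))
  expect_true(is.na(res$exclusion_reason[res$snp_id == "rs_nonpal"]))
  expect_true(is.na(res$exclusion_reason[res$snp_id == "rs_pal_border"]))
})

test_that("outcome-associated instruments are excluded strictly below 5e-8", {
  pairs <- make_pairs(c(0.1, 0.1, 0.1), c(0.05, 0.05, 0.05), 0.01, 0.02)
  pairs$pval_out <- c(1e-9, 1e-7, 5e-8)
  res <- exclude_outcome_associated(pairs)
  expect_equal(res$exclusion_reason, c("outcome-associated", NA, NA))
  empty <- exclude_outcome_associated(pairs[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("proxy substitution honours the r2 threshold and the max-r2 rule", {
  outcome <- make_gwas(
    c("rs_px1", "rs_px2", "rs_px3"), "A", "G",
    beta = c(0.02, 0.03, 0.04), se = 0.02, pval = 0.5, eaf = 0.3
  )
  proxies <- tibble::tibble(
    query_snp = c("rs_q", "rs_q", "rs_q", "rs_lowld"),
    proxy_snp = c("rs_px1", "rs_px2", "rs_px3", "rs_px1"),
    r2 = c(0.65, 0.90, 0.55, 0.55),
    query_a1 = "C", proxy_a1 = "A", query_a2 = "T", proxy_a2 = "G"
  )
  res <- substitute_proxies(c("rs_q", "rs_lowld"), proxies, outcome)
  expect_equal(nrow(res$substitutions), 1)
  expect_equal(res$substitutions$proxy_snp, "rs_px2")  # 0.90 beats 0.65
  expect_equal(res$substitutions$snp_id, "rs_q")
  expect_equal(res$substitutions$effect_allele, "C")   # remapped through the bijection
  expect_equal(res$unresolved, "rs_lowld")             # 0.55 is below 0.60
})

test_that("inconsistent proxy allele maps are skipped with a warning", {
  outcome <- make_gwas("rs_px", "A", "G", beta = 0.02, se = 0.02, pval = 0.5)
  proxies <- tibble::tibble(
    query_snp = "rs_q", proxy_snp = "rs_px", r2 = 0.9,
    query_a1 = "C", proxy_a1 = "T", query_a2 = "G", proxy_a2 = "C"
  )
  expect_warning(res <- substitute_proxies("rs_q", proxies, outcome),
                 "inconsistent")
  expect_equal(res$unresolved, "rs_q")
})

test_that("re-harmonizing an already-harmonized set changes nothing", {
  sim <- simulate_two_sample(synth_config(n_snps = 150, seed = 5))
  inst <- select_instruments(sim$exposure)
  pairs <- kept_pairs(harmonize(inst, sim$outcome))
  # re-express the harmonized outcome side as a dataset and harmonize again
  out2 <- as_gwas(tibble::tibble(
    snp_id = pairs$snp_id, effect_allele = pairs$effect_allele,
    other_allele = pairs$other_allele, eaf = pairs$eaf_out,
    beta = pairs$beta_out, se = pairs$se_out, pval = pairs$pval_out,
    n = pairs$n_out, n_case = NA_real_
  ), "outcome", "binary")
  inst2 <- inst[inst$snp_id %in% pairs$snp_id, ]
  pairs2 <- kept_pairs(harmonize(inst2, out2))
  expect_equal(nrow(pairs2), nrow(pairs))
  expect_true(all(pairs2$status %in% "kept"))
  expect_equal(pairs2$beta_out[match(pairs$snp_id, pairs2$snp_id)],
               pairs$beta_out)
})

test_that("negating both betas of every pair leaves causal estimates unchanged", {
  pairs <- random_pairs(30, seed = 9)
  neg <- pairs
  neg$beta_exp <- -neg$beta_exp
  neg$beta_out <- -neg$beta_out
  expect_equal(mr_ivw(neg)$beta, mr_ivw(pairs)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(neg)$slope$beta, mr_egger(pairs)$slope$beta,
               tolerance = 1e-12)
  expect_equal(mr_egger(neg)$intercept$beta, mr_egger(pairs)$intercept$beta,
               tolerance = 1e-12)
  wm1 <- mr_weighted_median(pairs, n_boot = 200, seed = 3)
  wm2 <- mr_weighted_median(neg, n_boot = 200, seed = 3)
  expect_equal(wm1$beta, wm2$beta, tolerance = 1e-12)
})

test_that("missing instruments without proxies are logged, pipeline continues", {
  sim <- simulate_two_sample(synth_config(n_snps = 50, seed = 13))
  inst <- select_instruments(sim$exposure)
  out_missing <- sim$outcome[-(1:3), ]
  pairs <- harmonize(inst, out_missing)
  miss <- pairs[pairs$exclusion_reason %in% "missing-no-proxy", ]
  expect_equal(sort(miss$snp_id),
               sort(setdiff(inst$snp_id, out_missing$snp_id)))
  expect_s3_class(mr_ivw(pairs), "mr_fit")
})
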