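test_that("anti-SD registry covers gram-negative and gram-positive hosts", {
  expect_equal(anti_sd_for("E. coli"), "ACCUCCUUA")
  expect_equal(anti_sd_for("C. glutamicum"), "ACCUCCUUU")
  expect_equal(anti_sd_for("B. subtilis"), "ACCUCCUUU")
  expect_error(anti_sd_for("M. musculus"), "registered")
  register_organism("V. natriegens", "ACCUCCUUA")
  expect_equal(anti_sd_for("V. natriegens"), "ACCUCCUUA")
})

test_that("spacing penalty is zero at the optimum and grows monotonically", {
  m <- ribosome_model()
  expect_equal(spacing_penalty(5, m), 0)
  expect_gt(spacing_penalty(0, m), 0)
  pen <- spacing_penalty(0:20, m)
  expect_true(all(pen >= 0))
  expect_true(all(diff(pen[6:21]) >= 0))   # stretched branch non-decreasing
  expect_true(all(diff(pen[1:6]) <= 0))    # compressed branch falls to 0
})

test_that("free-energy bookkeeping matches arithmetic oracles", {
  # all-zero configuration: every term 0 -> dG_total 0, rate = rate_scale
  m0 <- ribosome_model(start_codon_energies = c(AUG = 0), dG_standby = 0)
  bd0 <- delta_g_total(test_context("AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA"),
                       model = m0, engine = fixed_engine(0, 0))
  expect_equal(bd0$dG_total, 0)
  expect_equal(bd0$aligned_spacing, 5)
  # hand-set energies: dG_pair = hyb + refold = -5 + -3 = -8; start -1;
  # spacing 0 (tie-break picks the optimum); standby +1; initial mfe -3
  m1 <- ribosome_model(start_codon_energies = c(AUG = -1), dG_standby = 1)
  bd1 <- delta_g_total(test_context("AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA"),
                       model = m1, engine = fixed_engine(-3, -5))
  expect_equal(bd1$dG_mRNA_rRNA, -8)
  expect_equal(bd1$dG_total, -8 - 1 + 0 + 1 - (-3))
  # breakdown-sum identity on arbitrary contexts (toy engine)
  set.seed(21)
  eng <- toy_engine()
  for (i in 1:25) {
    bd <- delta_g_total(test_context(), engine = eng)
    expect_equal(bd$dG_total,
                 bd$dG_mRNA_rRNA + bd$dG_start + bd$dG_spacing +
                   bd$dG_standby - bd$dG_mRNA,
                 tolerance = 1e-9)
    expect_lte(bd$dG_mRNA, 0)
    expect_gte(bd$dG_spacing, 0)
  }
})

test_that("a perfect Shine-Dalgarno at optimal spacing is found", {
  rbs <- paste0(strrep("A", 18), "UAAGGAGGU", strrep("A", 5))
  bd <- delta_g_total(mrna_context(rbs, TEST_CDS), engine = toy_engine())
  expect_equal(bd$aligned_spacing, 5)
  # full 9-bp hybrid plus the residual fold of the unoccluded mRNA
  expect_lte(bd$dG_mRNA_rRNA, -1.2 * 9)
})

test_that("degenerate or malformed inputs are rejected", {
  expect_error(delta_g_total(mrna_context("AAA", "GCUAGC")), "start codon")
  expect_error(mrna_context("AXA", TEST_CDS), "invalid IUPAC")
})

test_that("the rate law is exponential with slope -beta", {
  m <- ribosome_model()
  expect_equal(translation_rate(0, m), 2500)
  expect_equal(round(translation_rate(0, m) / translation_rate(1.74, m), 1), 2.2)
  expect_equal(round(translation_rate(0, m) / translation_rate(1.61, m), 1), 2.1)
  grid <- seq(-18, 25, by = 0.5)
  r <- translation_rate(grid, m)
  expect_true(all(r > 0 & is.finite(r)))
  expect_true(all(diff(r) < 0))
  slopes <- diff(log(r)) / diff(grid)
  expect_equal(slopes, rep(-m$beta, length(slopes)), tolerance = 1e-9)
  # the au scale spans the physiological range without under/overflow
  expect_gt(translation_rate(-18, m), 5e6)
  expect_lt(translation_rate(23, m), 0.10)
})

test_that("library predictions agree with per-variant predictions", {
  eng <- toy_engine()
  ctx <- test_context()
  lib <- predict_library_rates(ctx, "AVNCCAUCGGCUAAGGAGGUAAAAAGCAAUAACAA",
                               engine = eng)
  expect_equal(nrow(lib), count_variants("AVNCCAUCGGCUAAGGAGGUAAAAAGCAAUAACAA"))
  expect_false(attr(lib, "sampled"))
  for (i in sample(nrow(lib), 5)) {
    ctx_i <- ctx
    ctx_i$rbs <- lib$variant_rbs[i]
    bd <- delta_g_total(ctx_i, engine = eng)
    expect_equal(lib$rate_au[i], translation_rate(bd$dG_total))
  }
  # singleton consistency
  one <- predict_library_rates(ctx, ctx$rbs, engine = eng)
  expect_equal(nrow(one), 1L)
  bd <- delta_g_total(ctx, engine = eng)
  expect_equal(one$rate_au, translation_rate(bd$dG_total))
})

test_that("oversized libraries fall back to a flagged seeded subsample", {
  eng <- toy_engine()
  set.seed(5)
  lib <- predict_library_rates(test_context(), strrep("N", 35),
                               engine = eng, limit = 100, sample_n = 40L)
  expect_true(attr(lib, "sampled"))
  expect_lte(nrow(lib), 40L)
})

test_that("the ViennaRNA engine satisfies the folding-engine contract", {
  eng <- vienna_engine()
  s <- "GGGGAAAACCCCAAGGAGGUAAAAA"
  free <- eng$mfe_fold(s)$energy
  expect_lte(free, 0)
  cons <- eng$mfe_fold(s, unpaired = 1:12)$energy
  expect_gte(cons, free)
  hyb <- eng$hybridize("UAAGGAGGU", "ACCUCCUUA")$energy
  expect_lt(hyb, -5)
  # deterministic
  expect_equal(eng$mfe_fold(s)$energy, free)
  # full pipeline runs under the production engine
  bd <- delta_g_total(test_context("AGCUAAGGAGGUAAAAAGCAAUAACAAGCUAGCAA"),
                      engine = eng)
  expect_true(is.finite(bd$dG_total))
})
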