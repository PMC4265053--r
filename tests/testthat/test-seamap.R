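net <- build_crtebi_network()
truth <- default_true_params()
sm <- seamap(truth, net)

test_that("the SEAMAP reproduces the reference productivity by construction", {
  ref <- pathway_variant(c(72268, 20496, 203462))
  expect_equal(predict_productivity(sm, ref), 196, tolerance = 1e-9)
  expect_match(sm$params_hash, "^[0-9a-f]+$")
})

test_that("flux control coefficients behave like log-sensitivities", {
  v <- pathway_variant(c(5000, 20496, 203462))  # crtE strongly limiting
  f <- fcc(sm, v, "crtE")
  expect_gt(f$fcc, 0.3)
  # Richardson step-halving: estimate stable to < 1% relative
  f2 <- fcc(sm, v, "crtE", rel_step = 0.005)
  expect_lt(abs(f2$fcc - f$fcc) / abs(f$fcc), 0.01)
  expect_identical(f$params_hash, sm$params_hash)
})

test_that("a single-conversion enzyme on boundary substrate has FCC exactly one", {
  # synthetic proportional-control network: boundary IPP -> (CrtI) ->
  # neurosporene through one bind/release chain, so flux is proportional to
  # total enzyme and the log-sensitivity is analytically 1
  lin <- build_crtebi_network()
  lin$reactions <- tibble::tibble(
    reaction = 1:2, enzyme = "CrtI", conversion = 1L,
    r1 = c("CrtI", "CrtI_x"), r2 = c("IPP", NA),
    p1 = c("CrtI_x", "CrtI"), p2 = c(NA, "neurosporene"),
    kf = c("kf1", "kf2"), kr = c("kr1", "kr2"))
  lin$species <- tibble::tibble(
    species = c("IPP", "neurosporene", "CrtI", "CrtI_x"),
    type = c("metabolite", "metabolite", "enzyme", "complex"),
    enzyme = c(NA, NA, "CrtI", "CrtI"),
    boundary = c(TRUE, FALSE, FALSE, FALSE))
  lin$param_ids <- c("kf1", "kf2", "kr1", "kr2")
  p_lin <- c(kf1 = 5, kf2 = 2, kr1 = 1, kr2 = 0.01)
  sm_lin <- seamap(p_lin, lin)
  f_lin <- fcc(sm_lin, pathway_variant(c(72268, 20496, 203462)), "crtI")
  expect_equal(f_lin$fcc, 1, tolerance = 0.01)
})

test_that("FCCs vanish at an interior productivity maximum", {
  # locate the maximum along the crtE axis by golden-section-style refinement
  ref <- c(crtE = 72268, crtB = 20496, crtI = 203462)
  prod_at <- function(m) {
    r <- ref
    r["crtE"] <- ref[["crtE"]] * m
    predict_productivity(sm, pathway_variant(r))
  }
  mult <- 10^seq(0, 1.6, length.out = 17)
  prods <- vapply(mult, prod_at, numeric(1))
  stopifnot(which.max(prods) > 1, which.max(prods) < length(mult))
  opt <- stats::optimize(prod_at, interval = range(mult), maximum = TRUE,
                         tol = 1e-4)
  v_opt <- pathway_variant(c(ref[["crtE"]] * opt$maximum, ref[["crtB"]],
                             ref[["crtI"]]))
  expect_lt(abs(fcc(sm, v_opt, "crtE")$fcc), 0.02)
})

test_that("FCCs over the three crt enzymes nearly sum to one in the controlled regime", {
  # batch-model analogue of the summation theorem, checked as a band
  for (s in list(c(1, 1, 1), c(0.5, 0.2, 0.8))) {
    v <- pathway_variant(c(72268, 20496, 203462) * s)
    total <- sum(vapply(c("crtE", "crtB", "crtI"), function(e) {
      fcc(sm, v, e)$fcc
    }, numeric(1)))
    expect_gte(total, 0)
    expect_lte(total, 1.05)
  }
})

test_that("induction response curves rise and fall through an interior optimum", {
  ind <- induction_model(basal = 0.05, max = 8, K = 40, n = 2)
  expect_equal(ind(0), 0.05)
  expect_lt(ind(1e6), 8 + 1e-9)
  expect_true(all(diff(ind(seq(0, 500, by = 10))) >= 0))
  v <- pathway_variant(c(72268, 20496, 203462))
  rc <- response_curve(sm, v, ind, inducers = c(0, 5, 10, 20, 40, 80, 160, 320))
  expect_equal(nrow(rc), 8L)
  peak <- which.max(rc$productivity)
  expect_gt(peak, 1)
  expect_lt(peak, nrow(rc))   # excess enzyme lowers productivity
  # flat induction gives a flat curve
  flat <- response_curve(sm, v, induction_model(basal = 1, max = 1),
                         inducers = c(0, 10, 100))
  expect_equal(diff(range(flat$productivity)), 0, tolerance = 1e-6)
})

test_that("coincident curves shift by the translation/transcription trade-off", {
  v1 <- pathway_variant(c(30000, 9000, 90000))
  v2 <- pathway_variant(c(60000, 18000, 180000))  # lambda = 2
  ind <- induction_model(basal = 0.2, max = 4, K = 30, n = 1.5)
  rc1 <- response_curve(sm, v1, ind, inducers = c(0, 10, 30, 100))
  # v2 at multiplier m equals v1 at multiplier 2m
  for (i in seq_len(nrow(rc1))) {
    m <- rc1$transcription_multiplier[i]
    v2m <- v2
    v2m$transcription_multiplier <- m / 2
    expect_equal(predict_productivity(sm, v2m), rc1$productivity[i],
                 tolerance = 1e-6)
  }
})

test_that("precursor supply helps a balanced pathway more than an imbalanced one", {
  sw_base <- precursor_sweep(sm, pathway_variant(c(72268, 20496, 203462)),
                             supplies = c(1, 4))
  expect_equal(sw_base$fold_improvement[1], 1, tolerance = 1e-9)
  # balanced: near the interior optimum; imbalanced: crtE rate-limiting
  balanced <- pathway_variant(c(72268 * 8, 20496, 203462))
  imbalanced <- pathway_variant(c(1046, 20496, 200300))
  fold_bal <- precursor_sweep(sm, balanced, supplies = 4)$fold_improvement
  fold_imb <- precursor_sweep(sm, imbalanced, supplies = 4)$fold_improvement
  expect_gt(fold_bal, fold_imb)
})

test_that("zoom targeting returns shrinking windows containing the optimum", {
  start <- pathway_variant(c(72268, 20496, 203462))
  zt <- zoom_target(sm, start, expansion = 1, n_grid = 5L)
  expect_true(all(zt$r_min < zt$r_max))
  expect_true(all(zt$r_min > 0))
  grid <- attr(zt, "grid")
  best_row <- grid[which.max(grid$productivity), ]
  # window contains the grid optimum per gene
  for (g in c("crtE", "crtB", "crtI")) {
    expect_gte(best_row[[g]], zt$r_min[zt$gene == g] * (1 - 1e-9))
    expect_lte(best_row[[g]], zt$r_max[zt$gene == g] * (1 + 1e-9))
  }
  # applying it again around the refined center stabilizes or shrinks
  center2 <- pathway_variant(sqrt(zt$r_min * zt$r_max))
  zt2 <- zoom_target(sm, center2, expansion = 0.5, n_grid = 5L)
  width1 <- log10(zt$r_max / zt$r_min)
  width2 <- log10(zt2$r_max / zt2$r_min)
  expect_true(all(width2 <= width1 + 1e-9))
})

test_that("the evolutionary landscape is seeded, cached, and sane at zero mutations", {
  ctxs <- list(test_context(), test_context(), test_context())
  rbs3 <- c(paste0(strrep("A", 18), "UAAGGAGGU", strrep("C", 8)),
            paste0(strrep("C", 18), "UAAGGAGGU", strrep("A", 8)),
            paste0(strrep("A", 8), "UAAGGAGGU", strrep("C", 18)))
  zero <- evolutionary_landscape(sm, ctxs, rbs3, n_mutations = 0, samples = 50,
                                 seed = 2)
  expect_true(all(zero$samples$productivity_ratio == 1))
  one_a <- evolutionary_landscape(sm, ctxs, rbs3, n_mutations = 1, samples = 200,
                                  seed = 3)
  one_b <- evolutionary_landscape(sm, ctxs, rbs3, n_mutations = 1, samples = 200,
                                  seed = 3)
  expect_identical(one_a$samples, one_b$samples)
  expect_true(all(one_a$samples$productivity_ratio > 0))
})
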