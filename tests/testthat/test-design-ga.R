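toy_design_spec <- function(seed, mode = "search", ...) {
  design_spec(mode = mode, r_min = 40, r_max = 120000, resolution = 0.6,
              population_size = 40L, max_iterations = 150L,
              stagnation_limit = 30L, seed = seed, rbs_length = 3L,
              expand_limit = 256, ...)
}

test_that("the GA finds the exhaustive-search optimum on a toy landscape", {
  rate_fn <- additive_rate_fn(toy_energy_matrix())
  oracle <- brute_force_design_optimum(3L, rate_fn, 40, 120000, 0.6)
  res <- optimize_rbs_library(toy_design_spec(seed = 101), rate_fn = rate_fn)
  expect_equal(res$solutions$objective[1], oracle$objective, tolerance = 1e-12)
})

test_that("design runs are deterministic and monotone in the best objective", {
  rate_fn <- additive_rate_fn(toy_energy_matrix())
  a <- optimize_rbs_library(toy_design_spec(seed = 7), rate_fn = rate_fn)
  b <- optimize_rbs_library(toy_design_spec(seed = 7), rate_fn = rate_fn)
  expect_identical(a$solutions, b$solutions)
  expect_identical(a$variant_rates, b$variant_rates)
  expect_true(all(diff(a$history$best_objective) >= 0))
  expect_lte(nrow(a$solutions), 5L)
  # stored metrics are reproducible from the degenerate sequence alone
  audit <- audit_solution(a, rank = 1L, rate_fn = rate_fn)
  expect_equal(audit$coverage, a$solutions$coverage[1])
  expect_equal(audit$objective, a$solutions$objective[1])
  expect_equal(audit$n_variants, a$solutions$n_variants[1])
})

test_that("zoom mode is a pure re-parameterization of search", {
  rate_fn <- additive_rate_fn(toy_energy_matrix())
  zoomed <- optimize_rbs_library(
    toy_design_spec(seed = 5, mode = "zoom"), rate_fn = rate_fn)
  expect_equal(zoomed$spec$mode, "zoom")
  expect_true(all(zoomed$solutions$coverage >= 0))
  # narrowed range + finer resolution changes only the grid
  expect_equal(zoomed$grid$W, 0.6)
})

test_that("genome-edit feasibility finds the minimal mutation window", {
  wt <- random_rbs(35)
  same <- genome_edit_feasible(wt, wt, 10)
  expect_true(same$feasible)
  expect_equal(same$window_length, 0L)
  far <- wt
  substr(far, 3, 3) <- if (substr(wt, 3, 3) == "A") "C" else "A"
  substr(far, 30, 30) <- if (substr(wt, 30, 30) == "A") "C" else "A"
  spread <- genome_edit_feasible(far, wt, 10)
  expect_false(spread$feasible)
  expect_equal(spread$window_length, 28L)
  near <- wt
  for (p in 10:14) substr(near, p, p) <- "N"
  ok <- genome_edit_feasible(near, wt, 6)
  expect_true(ok$feasible)
  expect_equal(ok$window_start, 10L)
  expect_equal(ok$window_length, 5L)
  expect_error(genome_edit_feasible("AAA", "AAAA", 3), "equal length")
})

test_that("genome-edit mode only returns solutions within the edit window", {
  rate_fn <- additive_rate_fn(toy_energy_matrix(6L))
  wt <- "AAAAAA"
  spec <- design_spec(mode = "genome_edit", r_min = 40, r_max = 120000,
                      resolution = 0.6, population_size = 30L,
                      max_iterations = 80L, stagnation_limit = 20L,
                      seed = 17, wild_type_rbs = wt, max_window = 3L,
                      expand_limit = 256)
  res <- optimize_rbs_library(spec, rate_fn = rate_fn)
  for (d in res$solutions$degenerate_rbs) {
    expect_true(genome_edit_feasible(d, wt, 3L)$feasible)
  }
  expect_true(all(res$solutions$window_length <= 3L, na.rm = TRUE))
})

test_that("an unreachable rate ceiling is flagged rather than fatal", {
  rate_fn <- additive_rate_fn(toy_energy_matrix())  # tops out around 1.5e5
  spec <- design_spec(mode = "search", r_min = 1e7, r_max = 1e9,
                      resolution = 0.5, population_size = 20L,
                      max_iterations = 30L, stagnation_limit = 10L,
                      seed = 3, rbs_length = 3L, expand_limit = 256)
  res <- optimize_rbs_library(spec, rate_fn = rate_fn)
  expect_true(all(res$solutions$range_unreached))
})

test_that("library design over the biophysics pipeline returns consistent rates", {
  eng <- toy_engine()
  ctx <- test_context()
  spec <- design_spec(mode = "search", r_min = 2000, r_max = 250000,
                      resolution = 0.5, population_size = 25L,
                      max_iterations = 25L, stagnation_limit = 10L,
                      seed = 29, rbs_length = 35L, expand_limit = 128)
  res <- optimize_rbs_library(spec, context = ctx, engine = eng)
  top <- res$variant_rates[res$variant_rates$rank == 1, ]
  for (i in seq_len(min(3, nrow(top)))) {
    ctx_i <- ctx
    ctx_i$rbs <- top$variant_rbs[i]
    expect_equal(top$rate_au[i],
                 translation_rate(delta_g_total(ctx_i, engine = eng)$dG_total))
  }
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(glance(res)), 1L)
})
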