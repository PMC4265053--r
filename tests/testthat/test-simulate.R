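net <- build_crtebi_network()
params <- default_true_params()

test_that("simulation conserves enzymes and produces positive flux", {
  sim <- simulate_pathway(net, params, c(crtE = 1, crtB = 1, crtI = 1),
                          times = seq(0, 7, by = 0.5))
  expect_gt(sim$r_p, 0)
  expect_lt(sim$conservation_drift, 1e-6)
  expect_true(all(as.matrix(sim$trajectory[, -1]) >= -1e-8))
  # broken chain: no CrtE, no neurosporene
  expect_equal(simulate_pathway(net, params, c(crtE = 0, crtB = 1, crtI = 1))$r_p, 0)
  expect_equal(simulate_pathway(net, params, c(crtE = 1, crtB = 0, crtI = 1))$r_p, 0)
  expect_equal(simulate_pathway(net, params, c(crtE = 1, crtB = 1, crtI = 0))$r_p, 0)
})

test_that("solutions are stable under tolerance halving", {
  a <- simulate_pathway(net, params, c(crtE = 2, crtB = 0.5, crtI = 1))$r_p
  b <- simulate_pathway(net, params, c(crtE = 2, crtB = 0.5, crtI = 1),
                        rtol = 5e-9, atol = 5e-11)$r_p
  expect_lt(abs(a - b) / a, 1e-3)
})

test_that("rescaling the de-dimensionalization reference leaves the flux unchanged", {
  base <- simulate_pathway(net, params, c(crtE = 1.5, crtB = 0.7, crtI = 1.2))$r_p
  set.seed(55)
  scale <- stats::setNames(10^stats::runif(nrow(net$species), -1, 1),
                           net$species$species)
  rescaled <- simulate_pathway(net, params, c(crtE = 1.5, crtB = 0.7, crtI = 1.2),
                               ref_scale = scale)$r_p
  expect_lt(abs(rescaled - base) / base, 1e-6)
  # doubling every reference concentration, specifically
  doubled <- simulate_pathway(net, params, c(crtE = 1.5, crtB = 0.7, crtI = 1.2),
                              ref_scale = stats::setNames(
                                rep(2, nrow(net$species)), net$species$species))$r_p
  expect_lt(abs(doubled - base) / base, 1e-6)
})

test_that("a single reversible binding reaction reaches its analytic equilibrium", {
  # sub-network A + E <-> C with boundary A: equilibrium C/E = kf*A/kr
  sub <- build_crtebi_network()
  sub$reactions <- sub$reactions[1, ]         # Idi + IPP <-> Idi_IPP
  sub$param_ids <- c("kf1", "kr1")
  keep <- c("IPP", "Idi", "Idi_IPP")
  sub$species <- sub$species[sub$species$species %in% keep, ]
  p <- c(kf1 = 3, kr1 = 0.7)
  sim <- simulate_pathway(sub, p, c(crtE = 0, crtB = 0, crtI = 0),
                          idi_ratio = 1, precursor_supply = 2,
                          horizon = 50, times = c(0, 50))
  final <- sim$trajectory[nrow(sim$trajectory), ]
  expect_equal(final$Idi_IPP / final$Idi, 3 * 2 / 0.7, tolerance = 1e-5)
})

test_that("productivity maps flux linearly through the reference anchor", {
  expect_equal(flux_to_productivity(2, 2), 196)
  expect_equal(flux_to_productivity(1, 2), 98)
  expect_equal(flux_to_productivity(0, 2), 0)
  expect_error(flux_to_productivity(1, 0), "not initialized")
})

test_that("enzyme ratios are transcription-scaled rate ratios", {
  ref <- c(crtE = 72268, crtB = 20496, crtI = 203462)
  expect_equal(enzyme_ratio(pathway_variant(ref)), c(crtE = 1, crtB = 1, crtI = 1))
  expect_equal(enzyme_ratio(pathway_variant(ref, transcription_multiplier = 2)),
               c(crtE = 2, crtB = 2, crtI = 2))
  v <- pathway_variant(c(144536, 20496, 203462))
  expect_equal(unname(enzyme_ratio(v)["crtE"]), 2.0)
  expect_error(pathway_variant(c(-1, 1, 1)), "rates > 0")
})

test_that("transcription and translation enter only through their product", {
  v1 <- pathway_variant(c(30000, 9000, 90000), transcription_multiplier = 3)
  v2 <- pathway_variant(c(90000, 27000, 270000), transcription_multiplier = 1)
  r1 <- simulate_pathway(net, params, v1)$r_p
  r2 <- simulate_pathway(net, params, v2)$r_p
  expect_lt(abs(r1 - r2) / r1, 1e-6)
})

test_that("with irreversible kinetics flux is non-decreasing in each enzyme", {
  irr <- params
  irr[grepl("^kr", names(irr))] <- 1e-9
  base <- simulate_pathway(net, irr, c(crtE = 1, crtB = 1, crtI = 1),
                           precursor_supply = 5)$r_p
  for (enz in c("crtE", "crtB", "crtI")) {
    ratios <- c(crtE = 1, crtB = 1, crtI = 1)
    ratios[enz] <- 4
    up <- simulate_pathway(net, irr, ratios, precursor_supply = 5)$r_p
    if (enz == "crtB") {
      # the GGPP dimerization step is the one exception at a finite horizon:
      # extra CrtB ends the batch holding more half-loaded CrtB:GGPP
      # complexes, costing a percent-level amount of end-point product
      expect_gte(up, base * 0.98)
    } else {
      expect_gte(up, base * (1 - 1e-9))
    }
  }
})
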