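test_that("variant counts are products of per-position cardinalities", {
  expect_equal(count_variants("NNNGGANNN"), 4096)
  expect_equal(count_variants("DDRRRRRDDDD"), 23328)
  expect_equal(count_variants("ATG"), 1)
  expect_equal(count_variants("N"), 4)
  # multiplicative under concatenation
  set.seed(42)
  alphabet <- c("A", "C", "G", "U", "W", "S", "M", "K", "R", "Y",
                "B", "D", "H", "V", "N")
  for (i in 1:25) {
    a <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(count_variants(paste0(a, b)),
                 count_variants(a) * count_variants(b))
  }
})

test_that("validation names the offending position and character", {
  expect_error(count_variants("ACXG"), "'X' at position 3")
  expect_error(validate_dseq(""), "empty")
  # T is accepted and normalized to U
  expect_equal(validate_dseq("atg"), "AUG")
})

test_that("expansion is exact, deduplicated, and lexicographic", {
  expect_equal(expand_dseq("R"), c("A", "G"))
  expect_equal(expand_dseq("AS"), c("AC", "AG"))
  # brute-force cross-product oracle on random degenerate sequences
  set.seed(7)
  alphabet <- c("A", "C", "G", "U", "W", "S", "M", "K", "R", "Y",
                "B", "D", "H", "V", "N")
  iupac <- list(A = "A", C = "C", G = "G", U = "U", W = c("A", "U"),
                S = c("C", "G"), M = c("A", "C"), K = c("G", "U"),
                R = c("A", "G"), Y = c("C", "U"), B = c("C", "G", "U"),
                D = c("A", "G", "U"), H = c("A", "C", "U"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "U"))
  for (i in 1:20) {
    d <- paste(sample(alphabet, 4, replace = TRUE), collapse = "")
    got <- expand_dseq(d)
    sets <- lapply(strsplit(d, "")[[1]], function(ch) iupac[[ch]])
    want <- sort(apply(do.call(expand.grid, rev(sets)), 1,
                       function(r) paste(rev(r), collapse = "")))
    expect_equal(got, unname(want))
    expect_equal(length(got), count_variants(d))
    expect_false(is.unsorted(got))
  }
})

test_that("expansion above the limit is refused with the count", {
  expect_error(expand_dseq("NNNNN", limit = 100), "1024")
})

test_that("variant sampling is uniform over the expansion and seeded", {
  expect_equal(sample_variant("AUG"), "AUG")
  set.seed(11)
  a <- sample_variant("NRY", n = 50)
  set.seed(11)
  b <- sample_variant("NRY", n = 50)
  expect_identical(a, b)
  # chi-square uniformity over the 16 concrete expansions of NRY
  set.seed(12)
  draws <- sample_variant("NRY", n = 2e4)
  tab <- table(factor(draws, levels = expand_dseq("NRY")))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 1e-4)
  # per-base frequency of N within binomial 3-sigma of 0.25
  set.seed(13)
  base_draws <- sample_variant("N", n = 2e4)
  freq <- table(factor(base_draws, levels = c("A", "C", "G", "U"))) / 2e4
  tol <- 3 * sqrt(0.25 * 0.75 / 2e4)
  expect_true(all(abs(freq - 0.25) < tol))
})

test_that("edit operators follow their definitions", {
  set.seed(3)
  # increase on A yields a strict superset code containing A
  up <- edit_dseq("A", "increase_degeneracy", pos = 1)
  expect_true(up %in% c("W", "M", "R", "D", "H", "V", "N"))
  # decrease on N yields one of the 14 strict subset codes
  subs <- replicate(200, edit_dseq("N", "decrease_degeneracy", pos = 1))
  expect_true(all(subs != "N"))
  expect_equal(sort(unique(subs)),
               sort(c("A", "C", "G", "U", "W", "S", "M", "K", "R", "Y",
                      "B", "D", "H", "V")))
  expect_equal(edit_dseq("AAAA", "recombine", partner = "CCCC", junction = 2),
               "AACC")
  # no-op cases report NULL so the caller can redraw
  expect_null(edit_dseq("N", "increase_degeneracy", pos = 1))
  expect_null(edit_dseq("NN", "increase_degeneracy"))
  expect_null(edit_dseq("A", "decrease_degeneracy"))
  expect_null(edit_dseq("NNN", "substitute"))
  expect_error(edit_dseq("AAAA", "recombine", partner = "CC"), "equal length")
})

test_that("every edit output is a valid sequence of unchanged length", {
  set.seed(9)
  ops <- c("increase_degeneracy", "decrease_degeneracy", "substitute",
           "recombine", "fresh_random")
  for (i in 1:100) {
    L <- sample(3:12, 1)
    d <- paste(sample(names(seamapr:::IUPAC_SETS), L, replace = TRUE),
               collapse = "")
    op <- sample(ops, 1)
    out <- edit_dseq(d, op, partner = random_rbs(L))
    if (!is.null(out)) {
      expect_equal(nchar(out), L)
      expect_silent(validate_dseq(out))
    }
  }
})
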