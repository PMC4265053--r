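# Coverage metrics for library design: the translation-rate axis is
# log10-discretized into bins of width W (the search resolution); a bin at
# center y is filled when some variant's rate falls within [y/10^W, y*10^W].

#' Total number of coverage bins
#'
#' `ceiling(log10(r_max / r_min) / W)`: e.g. 17 bins for a rate space from 1
#' to 100,000 au at resolution `W = 0.30`.
#'
#' @param r_min,r_max Translation-rate range, au (`0 < r_min < r_max`).
#' @param W Search resolution (bin width), log10 units.
#' @return Integer bin count (`>= 1`).
#' @export
total_bins <- function(r_min, r_max, W) {
  if (!(r_min > 0 && r_min < r_max)) stop("need 0 < r_min < r_max")
  if (!(W > 0)) stop("search resolution W must be positive")
  max(1L, as.integer(ceiling(log10(r_max / r_min) / W - 1e-9)))
}

#' Log-spaced coverage bin grid
#'
#' Bin centers are placed at `r_min * 10^(W * (k + 1/2))` for
#' `k = 0 .. B_total - 1`; each bin's fill window is `[y/10^W, y*10^W]`
#' (inclusive on both ends), so windows of adjacent bins overlap and a single
#' rate can fill several bins.
#'
#' @inheritParams total_bins
#' @return An object of class `bin_grid` with fields `centers`, `W`,
#'   `B_total`, `r_min`, `r_max`.
#' @export
bin_grid <- function(r_min, r_max, W) {
  B <- total_bins(r_min, r_max, W)
  centers <- r_min * 10^(W * (seq_len(B) - 0.5))
  structure(list(centers = centers, W = W, B_total = B,
                 r_min = r_min, r_max = r_max),
            class = "bin_grid")
}

# index vector of bins filled by each rate (list parallel to rates)
bins_filled_by <- function(rates, grid) {
  lapply(rates, function(r) {
    which(grid$centers / 10^grid$W <= r & r <= grid$centers * 10^grid$W)
  })
}

#' Library coverage
#'
#' Fraction of bins filled by at least one rate in `rates`.
#'
#' @param rates Numeric vector of predicted translation rates, au.
#' @param grid A [bin_grid()].
#' @return Coverage fraction in `[0, 1]`.
#' @export
coverage <- function(rates, grid) {
  if (length(rates) == 0) return(0)
  filled <- unique(unlist(bins_filled_by(rates, grid)))
  length(filled) / grid$B_total
}

#' Library-design objective function
#'
#' `F = C - 0.02 * N_variants`: maximize coverage while minimizing library
#' size. Its maximum value, `1 - 0.02 * B_total`, is attained when every bin
#' is filled by exactly one variant.
#'
#' @param C Coverage fraction in `[0, 1]`.
#' @param n_variants Number of concrete variants in the library (`>= 1`).
#' @param variant_penalty Weight on library size (default 0.02).
#' @return Objective value `F`.
#' @export
design_objective <- function(C, n_variants, variant_penalty = 0.02) {
  stopifnot(C >= 0, C <= 1 + 1e-12, n_variants >= 1)
  C - variant_penalty * n_variants
}

#' Multi-dimensional search coverage
#'
#' For a D-protein expression space discretized per dimension, a Cartesian
#' grid cell is filled when a single expression tuple simultaneously falls in
#' every coordinate's fill window. Returns filled cells over total cells; with
#' `D = 1` this reduces to [coverage()].
#'
#' @param tuples A numeric matrix or data frame with one row per clone and one
#'   column per protein (rates in au).
#' @param grids List of [bin_grid()] objects, one per column.
#' @return Coverage fraction in `[0, 1]`.
#' @export
multi_dim_coverage <- function(tuples, grids) {
  tuples <- as.matrix(tuples)
  D <- length(grids)
  if (ncol(tuples) != D) stop("tuple dimension does not match number of grids")
  if (nrow(tuples) == 0) return(0)
  total <- prod(vapply(grids, function(g) g$B_total, numeric(1)))
  cells <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(tuples))) {
    per_dim <- lapply(seq_len(D), function(d) {
      bins_filled_by(tuples[r, d], grids[[d]])[[1]]
    })
    if (any(lengths(per_dim) == 0)) next
    keys <- do.call(expand.grid, per_dim)
    for (k in seq_len(nrow(keys))) {
      assign(paste(unlist(keys[k, ]), collapse = ","), TRUE, envir = cells)
    }
  }
  length(ls(cells)) / total
}

#' Monte Carlo search coverage of combinatorial RBS libraries
#'
#' Estimates the multi-dimensional coverage achieved when `n_clones` random
#' clones are drawn from the combinatorial library defined by one degenerate
#' RBS per gene: each clone draws one concrete variant per gene uniformly,
#' rates are predicted with the biophysics model, and coverage of the
#' Cartesian bin grid is computed; repeated over `replicates` draws.
#'
#' @param dseqs Character vector of degenerate RBSs, one per gene.
#' @param contexts List of [mrna_context()] objects, parallel to `dseqs`.
#' @param grids List of [bin_grid()] objects, parallel to `dseqs`.
#' @param n_clones Clones sampled per replicate (`>= 1`).
#' @param replicates Number of independent replicates.
#' @param model,engine Biophysics model and folding engine.
#' @param replace Sample clones with replacement (the combinatorial-assembly
#'   situation). With `replace = FALSE` distinct clones are drawn from the
#'   full combination space (which must be enumerable); drawing the whole
#'   space recovers the exact library coverage.
#' @param cache Optional [new_rate_cache()] shared across replicates.
#' @return A one-row tibble with `mean_coverage`, `sd_coverage`, `n_clones`,
#'   `replicates`; attribute `per_replicate` holds the replicate coverages.
#' @export
monte_carlo_coverage <- function(dseqs, contexts, grids, n_clones,
                                 replicates = 10L, model = ribosome_model(),
                                 engine = toy_engine(), replace = TRUE,
                                 cache = new_rate_cache()) {
  stopifnot(n_clones >= 1, length(dseqs) == length(contexts),
            length(dseqs) == length(grids))
  D <- length(dseqs)
  rate_of <- function(v, d) {
    predict_one_variant(v, contexts[[d]], model, engine, cache)$rate_au
  }
  combos <- NULL
  if (!replace) {
    per_gene <- lapply(dseqs, expand_dseq)
    combos <- as.matrix(do.call(expand.grid,
                                c(per_gene, stringsAsFactors = FALSE)))
    if (n_clones > nrow(combos)) {
      stop("n_clones exceeds the number of distinct clones in the library")
    }
  }
  covs <- vapply(seq_len(replicates), function(rep) {
    tuples <- matrix(NA_real_, nrow = n_clones, ncol = D)
    if (is.null(combos)) {
      for (d in seq_len(D)) {
        vars <- sample_variant(dseqs[[d]], n = n_clones)
        tuples[, d] <- vapply(vars, rate_of, numeric(1), d = d)
      }
    } else {
      pick <- combos[sample.int(nrow(combos), n_clones), , drop = FALSE]
      for (d in seq_len(D)) {
        tuples[, d] <- vapply(pick[, d], rate_of, numeric(1), d = d)
      }
    }
    multi_dim_coverage(tuples, grids)
  }, numeric(1))
  out <- tibble::tibble(mean_coverage = mean(covs),
                        sd_coverage = stats::sd(covs),
                        n_clones = n_clones, replicates = replicates)
  attr(out, "per_replicate") <- covs
  out
}
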