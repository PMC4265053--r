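# The sequence-expression-activity map (SEAMAP): the identified kinetic model
# plus the reference anchor, exposed as a predictor from (transcription
# multiplier, crtEBI translation rates, precursor supply) to neurosporene
# productivity, and the downstream analyses built on it.

#' Construct a SEAMAP
#'
#' Binds a reaction network and an identified (or known) parameter set to the
#' reference pathway anchor. The reference flux `r_p_ref` is simulated once;
#' by construction `predict_productivity()` of the reference variant returns
#' the reference productivity (196 ug/gDCW/h).
#'
#' @param params Full 48-constant named vector (e.g. `fit$best_params` from
#'   [identify_parameters()] or [default_true_params()]).
#' @param network A [build_crtebi_network()] result.
#' @param reference_rates Reference translation-rate triple, au.
#' @param reference_productivity Measured reference productivity, ug/gDCW/h.
#' @return An object of class `seamap` with a `params_hash` carried onto all
#'   downstream outputs for traceability.
#' @export
seamap <- function(params, network = build_crtebi_network(),
                   reference_rates = REFERENCE_TRANSLATION_RATES,
                   reference_productivity = REFERENCE_PRODUCTIVITY) {
  stopifnot(all(network$param_ids %in% names(params)))
  r_p_ref <- simulate_pathway(network, params,
                              c(crtE = 1, crtB = 1, crtI = 1))$r_p
  if (!isTRUE(r_p_ref > 0)) stop("reference variant carries no flux under these parameters")
  structure(
    list(network = network, params = params,
         reference_rates = reference_rates,
         reference_productivity = reference_productivity,
         r_p_ref = r_p_ref,
         params_hash = rlang::hash(params)),
    class = "seamap"
  )
}

#' @export
print.seamap <- function(x, ...) {
  cat(sprintf("<seamap: r_p_ref = %.5g, params %s>\n", x$r_p_ref,
              substr(x$params_hash, 1, 8)))
  invisible(x)
}

#' Predict a pathway variant's neurosporene productivity
#'
#' Maps the variant's translation rates (and transcription multiplier and
#' precursor supply) to enzyme concentration ratios, simulates the kinetic
#' model, and normalizes the resulting flux to the reference pathway.
#'
#' @param map A [seamap()].
#' @param variant A [pathway_variant()].
#' @return Productivity in ug/gDCW/h.
#' @export
predict_productivity <- function(map, variant) {
  stopifnot(inherits(map, "seamap"))
  v <- variant
  sim <- simulate_pathway(map$network, map$params,
                          enzyme_ratio(v, map$reference_rates),
                          precursor_supply = v$precursor_supply)
  flux_to_productivity(sim$r_p, map$r_p_ref, map$reference_productivity)
}

#' Flux control coefficient of one crt enzyme
#'
#' FCC = d ln(productivity) / d ln(enzyme level), estimated by a central
#' finite difference in log space with relative step `rel_step`, holding the
#' other enzyme ratios fixed. Near zero at an optimally balanced expression
#' point; near one for a proportionally rate-limiting enzyme; negative where
#' excess enzyme sequesters intermediates.
#'
#' @param map A [seamap()].
#' @param variant A [pathway_variant()].
#' @param enzyme One of `"crtE"`, `"crtB"`, `"crtI"`.
#' @param rel_step Relative step (default 1%).
#' @return A one-row tibble with `enzyme`, `fcc`, `productivity`,
#'   `params_hash`. `fcc` is `NA` (undefined) when productivity vanishes at
#'   the evaluation point.
#' @export
fcc <- function(map, variant, enzyme = c("crtE", "crtB", "crtI"),
                rel_step = 0.01) {
  enzyme <- match.arg(enzyme)
  stopifnot(rel_step > 0, rel_step < 1)
  p0 <- predict_productivity(map, variant)
  bump <- function(f) {
    v <- variant
    v$translation_rates[enzyme] <- v$translation_rates[enzyme] * f
    predict_productivity(map, v)
  }
  h <- 1 + rel_step
  p_up <- bump(h)
  p_dn <- bump(1 / h)
  val <- if (p0 <= 0 || p_up <= 0 || p_dn <= 0) {
    NA_real_
  } else {
    (log(p_up) - log(p_dn)) / (2 * log(h))
  }
  tibble::tibble(enzyme = enzyme, fcc = val, productivity = p0,
                 rel_step = rel_step, params_hash = map$params_hash)
}

#' Hill model of promoter induction
#'
#' Maps inducer concentration to a transcription-rate multiplier:
#' `basal + (max - basal) * I^n / (K^n + I^n)`; monotone non-decreasing with
#' values in `[basal, max]`.
#'
#' @param basal,max Multiplier at zero and saturating inducer.
#' @param K Half-maximal inducer concentration.
#' @param n Hill coefficient.
#' @return An object of class `induction_model` (callable).
#' @export
induction_model <- function(basal = 0.1, max = 4, K = 50, n = 2) {
  stopifnot(basal >= 0, max >= basal, K > 0, n > 0)
  f <- function(inducer) {
    stopifnot(all(inducer >= 0))
    basal + (max - basal) * inducer^n / (K^n + inducer^n)
  }
  structure(f, class = c("induction_model", "function"),
            basal = basal, max = max, K = K, n = n)
}

#' Transcription-induction response curve
#'
#' Evaluates the SEAMAP along an induction curve: for each inducer level the
#' transcription multiplier scales all three enzyme expression levels
#' together (a diagonal shift in expression space), and productivity is
#' predicted. For sufficiently reversible product-release kinetics the curve
#' rises to a maximum and then falls, because excess enzyme sequesters
#' intermediates as enzyme-substrate complex.
#'
#' @param map A [seamap()].
#' @param variant A [pathway_variant()] (its own multiplier is replaced by
#'   the induction model's).
#' @param induction An [induction_model()].
#' @param inducers Numeric grid of inducer concentrations (non-empty).
#' @return A tibble (class `response_curve`) with columns `inducer`,
#'   `transcription_multiplier`, `productivity`, `params_hash`; attribute
#'   `argmax_multiplier`.
#' @export
response_curve <- function(map, variant, induction = induction_model(),
                           inducers = c(0, 2^(0:10))) {
  stopifnot(length(inducers) >= 1)
  mult <- induction(inducers)
  prods <- vapply(mult, function(m) {
    v <- variant
    v$transcription_multiplier <- m
    predict_productivity(map, v)
  }, numeric(1))
  out <- tibble::tibble(inducer = inducers, transcription_multiplier = mult,
                        productivity = prods, params_hash = map$params_hash)
  attr(out, "argmax_multiplier") <- mult[which.max(prods)]
  class(out) <- c("response_curve", class(out))
  out
}

#' Precursor-supply sweep
#'
#' Sweeps the boundary IPP/DMAPP supply (emulating tuned dxs expression) and
#' reports productivity and fold-improvement over supply = 1. An optimally
#' balanced pathway (FCCs near zero) gains more from increased precursor
#' supply than an imbalanced one, because activity control has shifted to the
#' upstream precursor module.
#'
#' @param map A [seamap()].
#' @param variant A [pathway_variant()].
#' @param supplies Positive numeric grid of supply levels.
#' @return A tibble with `supply`, `productivity`, `fold_improvement`,
#'   `params_hash`.
#' @export
precursor_sweep <- function(map, variant, supplies = 2^seq(-2, 3)) {
  stopifnot(all(supplies > 0))
  prods <- vapply(supplies, function(s) {
    v <- variant
    v$precursor_supply <- s
    predict_productivity(map, v)
  }, numeric(1))
  v1 <- variant
  v1$precursor_supply <- 1
  base <- predict_productivity(map, v1)
  tibble::tibble(supply = supplies, productivity = prods,
                 fold_improvement = prods / base,
                 params_hash = map$params_hash)
}

#' Evolutionary landscape of random RBS mutations
#'
#' Starting from three concrete 35-nt RBS sequences controlling crtE, crtB,
#' and crtI, introduces `n_mutations` random point mutations per sample
#' (positions uniform over the 3 x 35 nucleotides, bases uniform over the 3
#' alternatives), re-predicts the three translation rates with the
#' biophysics model, re-predicts productivity with the SEAMAP, and records
#' the ratio to the unmutated pathway.
#'
#' @param map A [seamap()].
#' @param contexts List of three [mrna_context()] objects (crtE, crtB, crtI
#'   coding sequences and leaders).
#' @param rbs Character vector of the three starting RBS sequences.
#' @param n_mutations Mutations per sample (0 gives all ratios exactly 1).
#' @param samples Number of random samples.
#' @param model,engine Biophysics model and folding engine.
#' @param seed Integer seed.
#' @return An object of class `evolutionary_landscape`: tibble `samples`
#'   (sample, productivity_ratio), `fraction_decreased`, `baseline`
#'   (rates and productivity), `params_hash`.
#' @export
evolutionary_landscape <- function(map, contexts, rbs, n_mutations = 1L,
                                   samples = 1e4, model = ribosome_model(),
                                   engine = toy_engine(), seed = 1L) {
  stopifnot(length(contexts) == 3, length(rbs) == 3, samples >= 1,
            n_mutations >= 0)
  set.seed(seed)
  rbs <- vapply(rbs, validate_dseq, "")
  L <- nchar(rbs)
  rate_cache <- new_rate_cache()
  gene_rate <- function(g, seq) {
    predict_one_variant(seq, contexts[[g]], model, engine, rate_cache)$rate_au
  }
  base_rates <- vapply(1:3, function(g) gene_rate(g, rbs[g]), numeric(1))
  base_prod <- predict_productivity(map, pathway_variant(base_rates))

  offsets <- c(0, cumsum(L))
  prod_cache <- new.env(parent = emptyenv())
  ratios <- vapply(seq_len(samples), function(s) {
    if (n_mutations == 0) return(1)
    pos <- sample.int(sum(L), n_mutations)
    seqs <- rbs
    for (p in pos) {
      g <- findInterval(p, offsets, left.open = TRUE)
      at <- p - offsets[g]
      old <- substr(seqs[g], at, at)
      new <- sample(setdiff(c("A", "C", "G", "U"), old), 1L)
      substr(seqs[g], at, at) <- new
    }
    key <- paste(seqs, collapse = "|")
    hit <- prod_cache[[key]]
    if (is.null(hit)) {
      rates <- vapply(1:3, function(g) {
        if (seqs[g] == rbs[g]) base_rates[g] else gene_rate(g, seqs[g])
      }, numeric(1))
      hit <- predict_productivity(map, pathway_variant(rates))
      prod_cache[[key]] <- hit
    }
    hit / base_prod
  }, numeric(1))

  structure(
    list(samples = tibble::tibble(sample = seq_len(samples),
                                  productivity_ratio = ratios),
         fraction_decreased = mean(ratios < 1),
         n_mutations = as.integer(n_mutations),
         baseline = list(rates = base_rates, productivity = base_prod),
         params_hash = map$params_hash),
    class = "evolutionary_landscape"
  )
}

#' @export
print.evolutionary_landscape <- function(x, ...) {
  cat(sprintf("<evolutionary_landscape: %d-nt mutations, %d samples, %.1f%% decreased>\n",
              x$n_mutations, nrow(x$samples), 100 * x$fraction_decreased))
  invisible(x)
}

#' Target a translation-rate window for Zoom-mode design
#'
#' Grid-searches the SEAMAP over an expanded log-space box around the current
#' best variant and returns, per gene, the translation-rate window spanned by
#' the top decile of predicted productivities — the region a Zoom-mode
#' library design should target. Applied repeatedly on a fixed SEAMAP the
#' window shrinks or stabilizes around the optimum.
#'
#' @param map A [seamap()].
#' @param best_variant The current best [pathway_variant()] (box center).
#' @param expansion Half-width of the box around the center, in log10 units.
#' @param n_grid Grid points per dimension.
#' @param top_fraction Fraction of grid points defining the targeted region.
#' @return A tibble with one row per gene: `gene`, `r_min`, `r_max`,
#'   `params_hash`; attribute `grid` holds the evaluated grid, attribute
#'   `flat` is `TRUE` when the landscape was flat over the box (the box is
#'   returned expanded, with a warning).
#' @export
zoom_target <- function(map, best_variant, expansion = 1, n_grid = 7L,
                        top_fraction = 0.1) {
  center <- log10(best_variant$translation_rates)
  axes <- lapply(1:3, function(d) {
    10^seq(center[d] - expansion, center[d] + expansion, length.out = n_grid)
  })
  grid <- expand.grid(crtE = axes[[1]], crtB = axes[[2]], crtI = axes[[3]])
  grid$productivity <- vapply(seq_len(nrow(grid)), function(i) {
    predict_productivity(map, pathway_variant(as.numeric(grid[i, 1:3])))
  }, numeric(1))
  flat <- diff(range(grid$productivity)) <=
    1e-9 * max(abs(grid$productivity), 1e-12)
  if (flat) {
    warning("flat productivity landscape over the search box; returning the expanded box")
    top <- grid
  } else {
    cutoff <- stats::quantile(grid$productivity, 1 - top_fraction)
    top <- grid[grid$productivity >= cutoff, ]
  }
  out <- tibble::tibble(
    gene = c("crtE", "crtB", "crtI"),
    r_min = vapply(c("crtE", "crtB", "crtI"), function(g) min(top[[g]]), numeric(1)),
    r_max = vapply(c("crtE", "crtB", "crtI"), function(g) max(top[[g]]), numeric(1)),
    params_hash = map$params_hash
  )
  out$r_max <- pmax(out$r_max, out$r_min * 1.0001) # guard degenerate windows
  attr(out, "grid") <- tibble::as_tibble(grid)
  attr(out, "flat") <- flat
  out
}
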