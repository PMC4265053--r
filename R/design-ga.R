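# The library-design genetic algorithm: iterative in-silico mutation,
# recombination, and selection over degenerate RBS sequences, maximizing
# F = coverage - 0.02 * N_variants on a log-binned translation-rate grid.

GA_OPERATOR_PROBS <- c(recombine = 0.40, increase_degeneracy = 0.15,
                       decrease_degeneracy = 0.15, substitute = 0.15,
                       elite = 0.10, fresh_random = 0.05)

#' Draw genetic-algorithm mutation operators
#'
#' Operators are drawn with the fixed frequencies used by each generation of
#' the design algorithm: 40% recombination, 15% increase degeneracy, 15%
#' decrease degeneracy, 15% non-degenerate substitution, 10% unmodified
#' (elites), 5% fresh random sequence.
#'
#' @param n Number of draws.
#' @return Character vector of operator names.
#' @export
sample_ga_operators <- function(n) {
  sample(names(GA_OPERATOR_PROBS), n, replace = TRUE, prob = GA_OPERATOR_PROBS)
}

#' Library design specification
#'
#' @param mode One of `"search"` (wide range), `"zoom"` (narrowed range at
#'   finer resolution; a pure re-parameterization of search), or
#'   `"genome_edit"` (candidates must differ from a wild-type RBS only within
#'   one short contiguous window).
#' @param r_min,r_max Targeted translation-rate range, au
#'   (`0.10 <= r_min < r_max`).
#' @param resolution Search resolution `W`, log10 units.
#' @param population_size GA population size.
#' @param max_iterations Iteration cap.
#' @param stagnation_limit Terminate after this many iterations without
#'   improvement of the best objective.
#' @param seed Integer seed; the whole run is deterministic given it.
#' @param wild_type_rbs Wild-type RBS (genome_edit mode only).
#' @param max_window Largest allowed contiguous mutation window, nt
#'   (genome_edit mode only).
#' @param rbs_length Designed RBS length, nt (35 by convention).
#' @param expand_limit Per-candidate expansion cap; larger candidates are
#'   evaluated on a seeded subsample and flagged.
#' @param variant_penalty Weight on library size in the objective.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(mode = c("search", "zoom", "genome_edit"),
                        r_min, r_max, resolution,
                        population_size = 100L, max_iterations = 500L,
                        stagnation_limit = 50L, seed = 1L,
                        wild_type_rbs = NULL, max_window = 10L,
                        rbs_length = 35L, expand_limit = 1e4,
                        variant_penalty = 0.02) {
  mode <- match.arg(mode)
  if (!(r_min >= 0.10 && r_min < r_max)) {
    stop("need 0.10 <= r_min < r_max")
  }
  if (resolution <= 0) stop("resolution must be positive")
  if (mode == "genome_edit") {
    if (is.null(wild_type_rbs)) stop("genome_edit mode requires wild_type_rbs")
    wild_type_rbs <- validate_dseq(wild_type_rbs)
    rbs_length <- nchar(wild_type_rbs)
  }
  structure(
    list(mode = mode, r_min = r_min, r_max = r_max, resolution = resolution,
         population_size = as.integer(population_size),
         max_iterations = as.integer(max_iterations),
         stagnation_limit = as.integer(stagnation_limit),
         seed = as.integer(seed), wild_type_rbs = wild_type_rbs,
         max_window = as.integer(max_window),
         rbs_length = as.integer(rbs_length), expand_limit = expand_limit,
         variant_penalty = variant_penalty),
    class = "design_spec"
  )
}

#' Genome-editing feasibility of a candidate degenerate RBS
#'
#' A candidate is feasible when every position where it differs from (or is
#' degenerate relative to) the wild type lies within one contiguous window of
#' at most `max_window` nucleotides — the sequences a single degenerate
#' editing oligo can realize.
#'
#' @param candidate Degenerate candidate sequence.
#' @param wild_type Wild-type RBS (equal length, concrete).
#' @param max_window Largest allowed window, nt.
#' @return A list with `feasible` (logical), `window_start`, `window_length`
#'   (the minimal window; length 0 when identical).
#' @export
genome_edit_feasible <- function(candidate, wild_type, max_window) {
  cl <- dseq_letters(candidate)
  wl <- dseq_letters(wild_type)
  if (length(cl) != length(wl)) stop("candidate and wild type must have equal length")
  diffs <- which(cl != wl)
  if (length(diffs) == 0) {
    return(list(feasible = TRUE, window_start = NA_integer_, window_length = 0L))
  }
  span <- max(diffs) - min(diffs) + 1L
  list(feasible = span <= max_window, window_start = min(diffs),
       window_length = span)
}

# evaluate one degenerate candidate: expand (or subsample), predict rates,
# coverage, objective
evaluate_candidate <- function(dseq, spec, grid, rate_fn) {
  n <- count_variants(dseq)
  sampled <- n > spec$expand_limit
  variants <- if (sampled) {
    unique(sample_variant(dseq, n = 200L))
  } else {
    expand_dseq(dseq, limit = spec$expand_limit)
  }
  rates <- rate_fn(variants)
  C <- coverage(rates, grid)
  list(dseq = dseq, n_variants = n, coverage = C,
       objective = design_objective(C, n, spec$variant_penalty),
       variants = variants, rates = rates, sampled = sampled)
}

default_rate_fn <- function(context, model, engine, cache) {
  function(variants) {
    vapply(variants, function(v) {
      predict_one_variant(v, context, model, engine, cache)$rate_au
    }, numeric(1))
  }
}

#' Design an optimized degenerate RBS library
#'
#' Runs the design genetic algorithm: a population of degenerate RBS
#' sequences, initialized from random non-degenerate sequences (or from the
#' wild type in genome-editing mode), evolves by fitness-proportional
#' selection and the operator schedule of [sample_ga_operators()] until the
#' objective reaches its maximum, stagnates, or the iteration cap is hit.
#' Zoom mode is the same search over a narrowed range at finer resolution.
#'
#' @param spec A [design_spec()].
#' @param context An [mrna_context()] providing leader, CDS and organism;
#'   ignored when `rate_fn` is supplied.
#' @param model A [ribosome_model()].
#' @param engine A folding engine.
#' @param rate_fn Optional function `character vector of concrete RBSs ->
#'   numeric rates (au)`, replacing the biophysics pipeline (used for toy
#'   problems and testing).
#' @param n_solutions Number of top solutions to return (default 5).
#' @param quiet Suppress per-generation progress.
#' @return An object of class `rbs_library_design`: a list with `solutions`
#'   (tibble: rank, degenerate_rbs, n_variants, coverage, objective,
#'   range_unreached, sampled), `variant_rates` (tibble: rank, variant_rbs,
#'   rate_au), `history` (tibble: iteration, best_objective), `spec`, and
#'   `iterations`.
#' @export
optimize_rbs_library <- function(spec, context = NULL, model = ribosome_model(),
                                 engine = toy_engine(), rate_fn = NULL,
                                 n_solutions = 5L, quiet = TRUE) {
  stopifnot(inherits(spec, "design_spec"))
  set.seed(spec$seed)
  grid <- bin_grid(spec$r_min, spec$r_max, spec$resolution)
  if (is.null(rate_fn)) {
    if (is.null(context)) stop("either a context or a rate_fn is required")
    rate_fn <- default_rate_fn(context, model, engine, new_rate_cache())
  }
  L <- spec$rbs_length
  F_max <- 1 - spec$variant_penalty * grid$B_total

  init_seq <- function() {
    if (spec$mode == "genome_edit") spec$wild_type_rbs else random_rbs(L)
  }
  feasible <- function(dseq) {
    spec$mode != "genome_edit" ||
      genome_edit_feasible(dseq, spec$wild_type_rbs, spec$max_window)$feasible
  }

  pop <- replicate(spec$population_size, init_seq())
  evals <- lapply(pop, evaluate_candidate, spec = spec, grid = grid, rate_fn = rate_fn)
  eval_cache <- new.env(parent = emptyenv())
  for (e in evals) eval_cache[[e$dseq]] <- e
  get_eval <- function(dseq) {
    hit <- eval_cache[[dseq]]
    if (is.null(hit)) {
      hit <- evaluate_candidate(dseq, spec, grid, rate_fn)
      eval_cache[[dseq]] <- hit
    }
    hit
  }

  history <- numeric(0)
  best_F <- -Inf
  stagnation <- 0L
  iter <- 0L

  while (iter < spec$max_iterations) {
    iter <- iter + 1L
    F_vals <- vapply(evals, `[[`, numeric(1), "objective")
    sel_w <- F_vals - min(F_vals) + 1e-6
    select_parent <- function() pop[[sample.int(length(pop), 1L, prob = sel_w)]]

    # always carry the incumbent best forward, then fill by the operator draw
    best_idx <- which.max(F_vals)
    new_pop <- pop[best_idx]
    while (length(new_pop) < spec$population_size) {
      child <- NULL
      attempts <- 0L
      while (is.null(child) && attempts < 25L) {
        attempts <- attempts + 1L
        op <- sample_ga_operators(1L)
        child <- switch(op,
          recombine = edit_dseq(select_parent(), "recombine", partner = select_parent()),
          elite = select_parent(),
          fresh_random = if (spec$mode == "genome_edit") spec$wild_type_rbs else random_rbs(L),
          edit_dseq(select_parent(), op)
        )
        if (!is.null(child) && !feasible(child)) child <- NULL
      }
      if (is.null(child)) child <- select_parent()
      new_pop <- c(new_pop, child)
    }
    pop <- new_pop
    evals <- lapply(pop, get_eval)
    F_now <- max(vapply(evals, `[[`, numeric(1), "objective"))
    history <- c(history, F_now)
    if (!quiet) message(sprintf("iteration %d: best F = %.4f", iter, F_now))
    if (F_now > best_F + 1e-12) {
      best_F <- F_now
      stagnation <- 0L
    } else {
      stagnation <- stagnation + 1L
    }
    if (best_F >= F_max - 1e-12 || stagnation >= spec$stagnation_limit) break
  }

  all_evals <- mget(ls(eval_cache), envir = eval_cache)
  all_evals <- all_evals[order(vapply(all_evals, `[[`, numeric(1), "objective"),
                               decreasing = TRUE)]
  if (spec$mode == "genome_edit") {
    all_evals <- Filter(function(e) feasible(e$dseq), all_evals)
  }
  top <- unname(utils::head(all_evals, n_solutions))

  top_bin <- grid$centers[grid$B_total]
  solutions <- purrr::imap_dfr(top, function(e, i) {
    ge <- if (spec$mode == "genome_edit") {
      genome_edit_feasible(e$dseq, spec$wild_type_rbs, spec$max_window)
    } else {
      list(window_start = NA_integer_, window_length = NA_integer_)
    }
    tibble::tibble(
      rank = as.integer(i), degenerate_rbs = e$dseq,
      n_variants = e$n_variants, coverage = e$coverage,
      objective = e$objective,
      range_unreached = !any(e$rates >= top_bin / 10^grid$W &
                             e$rates <= top_bin * 10^grid$W),
      sampled = e$sampled,
      window_start = ge$window_start, window_length = ge$window_length
    )
  })
  variant_rates <- purrr::imap_dfr(top, function(e, i) {
    tibble::tibble(rank = as.integer(i), variant_rbs = e$variants,
                   rate_au = unname(e$rates))
  })

  structure(
    list(solutions = solutions, variant_rates = variant_rates,
         history = tibble::tibble(iteration = seq_along(history),
                                  best_objective = history),
         spec = spec, grid = grid, iterations = iter),
    class = "rbs_library_design"
  )
}

#' @export
print.rbs_library_design <- function(x, ...) {
  cat(sprintf("<rbs_library_design: %s mode, %d iterations, best F = %.4f>\n",
              x$spec$mode, x$iterations, max(x$solutions$objective)))
  print(x$solutions)
  invisible(x)
}

#' Write a designed library to TSV
#'
#' One row per solution (rank, degenerate_rbs, n_variants, coverage,
#' objective) followed by one row per variant with its predicted rate, in a
#' single long table.
#'
#' @param design An [optimize_rbs_library()] result.
#' @param path Output path.
#' @export
write_library_design <- function(design, path) {
  tbl <- dplyr::left_join(design$variant_rates, design$solutions,
                          by = "rank")
  tbl <- dplyr::select(tbl, "rank", "degenerate_rbs", "n_variants",
                       "coverage", "objective", "variant_rbs", "rate_au")
  readr::write_tsv(tbl, path)
  invisible(path)
}
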