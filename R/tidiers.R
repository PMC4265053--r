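# broom-style tidiers for the package's fitted objects.

#' Tidy a designed RBS library
#'
#' @param x An [optimize_rbs_library()] result.
#' @param ... Unused.
#' @return The solutions tibble (one row per returned degenerate RBS).
#' @export
tidy.rbs_library_design <- function(x, ...) x$solutions

#' One-row summary of a library-design run
#'
#' @param x An [optimize_rbs_library()] result.
#' @param ... Unused.
#' @export
glance.rbs_library_design <- function(x, ...) {
  best <- x$solutions[1, ]
  tibble::tibble(mode = x$spec$mode, iterations = x$iterations,
                 B_total = x$grid$B_total,
                 best_objective = best$objective,
                 best_coverage = best$coverage,
                 best_n_variants = best$n_variants)
}

#' Tidy an identified kinetic parameter set
#'
#' @param x An [identify_parameters()] result.
#' @param ... Unused.
#' @return One row per free parameter: `parameter`, `estimate`, and
#'   `log10_dispersion` (sd of the log10 estimate across runs, the
#'   uniqueness diagnostic).
#' @export
tidy.seamap_fit <- function(x, ...) {
  tibble::tibble(parameter = names(x$best_reduced),
                 estimate = unname(x$best_reduced),
                 log10_dispersion = unname(x$dispersion))
}

#' One-row summary of a kinetic identification
#'
#' @param x An [identify_parameters()] result.
#' @param ... Unused.
#' @export
glance.seamap_fit <- function(x, ...) {
  tibble::tibble(runs = nrow(x$runs), best_error = x$best_error,
                 median_error = stats::median(x$runs$error),
                 n_variants_fit = sum(!x$dataset$is_reference))
}

#' Predicted vs measured productivities of a fit
#'
#' Re-simulates every dataset row under the identified parameters.
#'
#' @param x An [identify_parameters()] result.
#' @param ... Unused.
#' @return Tibble with `label`, `measured`, `predicted`, `relative_error`,
#'   `is_reference`.
#' @export
augment.seamap_fit <- function(x, ...) {
  network <- x$map$network
  sm <- seamap(x$best_params, network,
               reference_rates = with(x$dataset[x$dataset$is_reference, ],
                                      c(crtE = rate_crtE_au, crtB = rate_crtB_au,
                                        crtI = rate_crtI_au)),
               reference_productivity =
                 x$dataset$productivity_ug_gDCW_h[x$dataset$is_reference])
  pred <- vapply(seq_len(nrow(x$dataset)), function(i) {
    predict_productivity(sm, pathway_variant(c(
      x$dataset$rate_crtE_au[i], x$dataset$rate_crtB_au[i],
      x$dataset$rate_crtI_au[i])))
  }, numeric(1))
  tibble::tibble(label = x$dataset$label,
                 measured = x$dataset$productivity_ug_gDCW_h,
                 predicted = pred,
                 relative_error = abs(pred - x$dataset$productivity_ug_gDCW_h) /
                   x$dataset$productivity_ug_gDCW_h,
                 is_reference = x$dataset$is_reference)
}

#' @export
generics::augment

#' Recompute a returned library solution from scratch
#'
#' Audit helper: re-expands a solution's degenerate RBS, re-predicts rates,
#' and recomputes coverage and objective on the specification's bin grid, so
#' stored solution metrics can be verified independently of the optimizer.
#'
#' @param design An [optimize_rbs_library()] result.
#' @param rank Solution rank to audit.
#' @param rate_fn Rate function used for the design (or `NULL` to use the
#'   stored per-variant rates).
#' @return One-row tibble with recomputed `n_variants`, `coverage`,
#'   `objective`.
#' @export
audit_solution <- function(design, rank = 1L, rate_fn = NULL) {
  sol <- design$solutions[design$solutions$rank == rank, ]
  grid <- design$grid
  variants <- expand_dseq(sol$degenerate_rbs, limit = design$spec$expand_limit)
  rates <- if (is.null(rate_fn)) {
    vr <- design$variant_rates[design$variant_rates$rank == rank, ]
    vr$rate_au[match(variants, vr$variant_rbs)]
  } else {
    rate_fn(variants)
  }
  C <- coverage(rates, grid)
  tibble::tibble(n_variants = count_variants(sol$degenerate_rbs),
                 coverage = C,
                 objective = design_objective(C, count_variants(sol$degenerate_rbs),
                                              design$spec$variant_penalty))
}
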