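# Parameter reduction for the 48-constant kinetic model. Ten constants are
# non-independent: one detailed-balance relation per overall conversion fixes
# the reverse constant of the conversion chain's last elementary reaction,
# given the conversion's overall equilibrium constant. Five more are
# constrained to configured values from biochemical data (the first
# substrate-binding forward constant of each enzyme, taken diffusion-limited).
# 48 - 10 - 5 = 33 free parameters.

conversion_chains <- function(network) {
  split(network$reactions$reaction, network$reactions$conversion)
}

#' Reduction map for the kinetic parameter set
#'
#' The map is a documented, versioned configuration: which 5 constants are
#' pinned (and to what), and the overall equilibrium constant of each of the
#' 10 conversions used by the detailed-balance eliminations. Changing the map
#' never changes the free-parameter count (33).
#'
#' @param network A [build_crtebi_network()] result.
#' @param pinned Named numeric: the 5 constrained constants.
#' @param keq Named numeric: overall equilibrium constant per conversion
#'   (`keq1..keq10`).
#' @return An object of class `reduction_map` with `pinned`, `keq`,
#'   `dependent` (the 10 eliminated constant ids), `free` (the 33 free ids).
#' @export
reduction_map <- function(network = build_crtebi_network(),
                          pinned = c(kf1 = 100, kf3 = 100, kf9 = 100,
                                     kf15 = 100, kf19 = 100),
                          keq = stats::setNames(rep(50, 10), paste0("keq", 1:10))) {
  chains <- conversion_chains(network)
  dependent <- vapply(chains, function(ids) paste0("kr", max(ids)), "")
  names(dependent) <- paste0("keq", names(chains))
  free <- setdiff(network$param_ids, c(names(pinned), unname(dependent)))
  stopifnot(length(free) == length(network$param_ids) - length(pinned) -
              length(dependent))
  structure(list(network = network, pinned = pinned, keq = keq,
                 dependent = unname(dependent), free = free),
            class = "reduction_map")
}

#' @export
print.reduction_map <- function(x, ...) {
  cat(sprintf("<reduction_map: %d free, %d pinned, %d eliminated>\n",
              length(x$free), length(x$pinned), length(x$dependent)))
  invisible(x)
}

#' Reduce a full 48-constant set to its 33 free parameters
#'
#' Pinned constants deviating from the map's values by more than `tol`
#' (relative) raise a warning and are projected onto the pinned values;
#' dependent constants are dropped (they are recomputed on inverse
#' reduction).
#'
#' @param full Named numeric vector of all 48 constants.
#' @param map A [reduction_map()].
#' @param tol Relative tolerance for the pinned check.
#' @return Named numeric vector of the 33 free constants (class
#'   `reduced_params`).
#' @export
reduce_parameters <- function(full, map = reduction_map(), tol = 1e-6) {
  stopifnot(all(map$network$param_ids %in% names(full)), all(full > 0))
  dev <- abs(full[names(map$pinned)] - map$pinned) / map$pinned
  if (any(dev > tol)) {
    warning("pinned constants deviate from the reduction map; projecting: ",
            paste(names(map$pinned)[dev > tol], collapse = ", "))
  }
  structure(unclass(full[map$free]), class = "reduced_params")
}

#' Reconstruct the full 48-constant set from 33 free parameters
#'
#' Sets the 5 pinned constants and recomputes the 10 dependent reverse
#' constants so each conversion chain's overall equilibrium constant (the
#' product of elementary kf/kr along the chain) equals the map's value
#' exactly.
#'
#' @param reduced Named numeric vector of the 33 free constants.
#' @param map A [reduction_map()].
#' @return Named numeric vector of all 48 constants.
#' @export
inverse_reduce <- function(reduced, map = reduction_map()) {
  reduced <- unclass(reduced)
  stopifnot(all(map$free %in% names(reduced)), all(reduced > 0))
  full <- stats::setNames(rep(NA_real_, length(map$network$param_ids)),
                          map$network$param_ids)
  full[map$free] <- reduced[map$free]
  full[names(map$pinned)] <- map$pinned
  chains <- conversion_chains(map$network)
  for (conv in names(chains)) {
    ids <- chains[[conv]]
    last <- max(ids)
    others <- setdiff(ids, last)
    keq_others <- prod(full[paste0("kf", others)] / full[paste0("kr", others)])
    full[paste0("kr", last)] <- full[paste0("kf", last)] * keq_others /
      map$keq[[paste0("keq", conv)]]
  }
  stopifnot(!anyNA(full), all(full > 0))
  full
}

#' Default synthetic-truth kinetic parameter set
#'
#' A fixed, fully documented parameter set satisfying the reduction map's
#' constraints, used as ground truth by the synthetic-data generator and in
#' examples. Binding steps are fast (pinned at 100), bound-state conversions
#' and product releases are slower, and release steps are appreciably
#' reversible, so excess enzyme sequesters intermediates — the mechanism that
#' makes productivity non-monotone in expression and gives the activity
#' landscape an interior optimum.
#'
#' @param map A [reduction_map()].
#' @return Named numeric vector of all 48 constants.
#' @export
default_true_params <- function(map = reduction_map()) {
  reduced <- stats::setNames(rep(NA_real_, length(map$free)), map$free)
  is_kf <- grepl("^kf", map$free)
  reduced[is_kf] <- 40   # free forward constants (binding / conversion / release)
  reduced[!is_kf] <- 20  # free reverse constants (unbinding / re-binding)
  inverse_reduce(reduced, map)
}
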