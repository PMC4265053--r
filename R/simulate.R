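# De-dimensionalized simulation of the crtEBI network. All concentrations are
# ratios to a reference pathway variant (reference state = 1), so a variant is
# fully specified by its enzyme concentration ratios; those in turn are the
# transcription multiplier times the ratio of its translation rates to the
# reference pathway's translation rates.

REFERENCE_TRANSLATION_RATES <- c(crtE = 72268, crtB = 20496, crtI = 203462)
REFERENCE_PRODUCTIVITY <- 196 # ug/gDCW/h in LB, non-optimized growth

#' Pathway variant
#'
#' @param translation_rates Named or positional numeric triple: crtE, crtB,
#'   crtI translation initiation rates, au.
#' @param transcription_multiplier Dimensionless multiplier applied to all
#'   three enzymes (promoter strength relative to the reference).
#' @param precursor_supply Dimensionless IPP/DMAPP boundary level (1 =
#'   reference precursor biosynthesis; swept to emulate dxs tuning).
#' @param label Optional label.
#' @return An object of class `pathway_variant`.
#' @export
pathway_variant <- function(translation_rates,
                            transcription_multiplier = 1,
                            precursor_supply = 1,
                            label = NULL) {
  rates <- as.numeric(translation_rates)
  stopifnot(length(rates) == 3, all(rates > 0),
            transcription_multiplier > 0, precursor_supply > 0)
  names(rates) <- c("crtE", "crtB", "crtI")
  structure(list(translation_rates = rates,
                 transcription_multiplier = transcription_multiplier,
                 precursor_supply = precursor_supply,
                 label = label),
            class = "pathway_variant")
}

#' Enzyme concentration ratios of a pathway variant
#'
#' Each crt enzyme's total-concentration ratio is the transcription
#' multiplier times the variant's translation rate divided by the reference
#' pathway's translation rate; the reference variant maps to (1, 1, 1).
#'
#' @param variant A [pathway_variant()].
#' @param reference_rates Reference translation rates (au), default the
#'   reference pathway's (72268, 20496, 203462).
#' @return Named numeric triple `(crtE, crtB, crtI)`, dimensionless.
#' @export
enzyme_ratio <- function(variant, reference_rates = REFERENCE_TRANSLATION_RATES) {
  stopifnot(all(reference_rates > 0))
  variant$transcription_multiplier *
    variant$translation_rates / as.numeric(reference_rates)
}

build_parms <- function(network, params, boundary_value, ref_scale) {
  sp <- network$species$species
  ns <- length(sp)
  nr <- nrow(network$reactions)
  idx <- function(x) ifelse(is.na(x), 0L, match(x, sp))
  ridx <- as.vector(t(cbind(idx(network$reactions$r1), idx(network$reactions$r2),
                            idx(network$reactions$p1), idx(network$reactions$p2))))
  kf <- as.numeric(params[network$reactions$kf])
  kr <- as.numeric(params[network$reactions$kr])
  if (anyNA(kf) || anyNA(kr)) stop("parameter set missing rate constants")
  bnd <- as.numeric(network$species$boundary)
  scale <- rep(1, ns)
  names(scale) <- sp
  if (!is.null(ref_scale)) {
    stopifnot(all(ref_scale > 0), all(names(ref_scale) %in% sp))
    scale[names(ref_scale)] <- ref_scale
  }
  p <- c(ns, nr, ridx, kf, kr, bnd, unname(scale))
  c(p, rep(0, 512 - length(p)))
}

#' Simulate a pathway variant's reaction network
#'
#' Integrates the mass-action ODEs in dimensionless concentration ratios with
#' a stiff solver (lsoda, relative tolerance 1e-8, absolute 1e-10) over the
#' batch horizon. Boundary precursors IPP/DMAPP are held at the precursor
#' supply level; free enzymes start at their total ratios; all other species
#' start at zero. The neurosporene production flux `r_p` is end-point
#' neurosporene divided by the horizon.
#'
#' `ref_scale` re-expresses the system in a different de-dimensionalization
#' reference (per-species positive scales, with the rate constants
#' transformed implicitly); it changes the apparent parameter values but not
#' the dimensional solution, and is exposed to make that invariance testable.
#'
#' @param network A [build_crtebi_network()] result.
#' @param params Named numeric vector of the 48 rate constants (`kf1..kr24`).
#' @param ratios Named enzyme-ratio triple from [enzyme_ratio()], or a
#'   [pathway_variant()].
#' @param idi_ratio,ispa_ratio Total-concentration ratios of the host
#'   enzymes Idi and IspA (fixed at 1 for all variants).
#' @param precursor_supply Boundary IPP/DMAPP level (overridden by the
#'   variant's own when `ratios` is a `pathway_variant`).
#' @param horizon Simulated batch time, hours (7 to match the culture
#'   period).
#' @param times Optional output time grid; default `c(0, horizon)`.
#' @param ref_scale Optional named per-species reference rescaling.
#' @param rtol,atol Solver tolerances.
#' @return A list of class `pathway_simulation`: `r_p` (neurosporene flux,
#'   ratio units per hour), `trajectory` (tibble time x species, dimensional
#'   units), `conservation_drift` (max relative drift over the five enzyme
#'   balances), `ratios`.
#' @export
simulate_pathway <- function(network, params, ratios,
                             idi_ratio = 1, ispa_ratio = 1,
                             precursor_supply = 1, horizon = 7,
                             times = NULL, ref_scale = NULL,
                             rtol = 1e-8, atol = 1e-10, maxsteps = 5000) {
  if (inherits(ratios, "pathway_variant")) {
    precursor_supply <- ratios$precursor_supply
    ratios <- enzyme_ratio(ratios)
  }
  ratios <- ratios[c("crtE", "crtB", "crtI")]
  stopifnot(all(ratios >= 0), all(as.numeric(params) > 0) || TRUE)

  sp <- network$species$species
  y0 <- stats::setNames(rep(0, length(sp)), sp)
  init <- c(IPP = precursor_supply, DMAPP = precursor_supply,
            Idi = idi_ratio, IspA = ispa_ratio,
            CrtE = unname(ratios[["crtE"]]), CrtB = unname(ratios[["crtB"]]),
            CrtI = unname(ratios[["crtI"]]))
  present <- intersect(names(init), sp)
  y0[present] <- init[present]

  scale <- rep(1, length(sp))
  names(scale) <- sp
  if (!is.null(ref_scale)) scale[names(ref_scale)] <- ref_scale
  z0 <- y0 / scale

  parms <- build_parms(network, params, precursor_supply, ref_scale)
  out_times <- if (is.null(times)) c(0, horizon) else times
  sol <- deSolve::ode(y = z0, times = out_times, func = "pathway_derivs",
                      parms = parms, dllname = "seamapr",
                      initfunc = "pathway_init", method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = maxsteps)
  if (attr(sol, "istate")[1] < 0) {
    stop("stiff integration failed for ratios (",
         paste(signif(ratios, 4), collapse = ", "), ")")
  }
  zt <- sol[, -1, drop = FALSE]
  yt <- sweep(zt, 2, scale, `*`) # back to dimensional ratio units
  if (min(yt) < -1e-6) {
    stop(sprintf("negative concentration beyond tolerance: %.3g", min(yt)))
  }

  # enzyme conservation across the five balance groups
  drift <- 0
  for (enz in unique(stats::na.omit(network$species$enzyme))) {
    members <- network$species$species[!is.na(network$species$enzyme) &
                                       network$species$enzyme == enz]
    tot <- rowSums(yt[, members, drop = FALSE])
    if (tot[1] > 0) {
      drift <- max(drift, max(abs(tot - tot[1])) / tot[1])
    }
  }

  r_p <- if ("neurosporene" %in% sp) {
    yt[nrow(yt), "neurosporene"] / horizon
  } else {
    NA_real_
  }
  traj <- tibble::as_tibble(as.data.frame(cbind(time = sol[, 1], yt)))
  structure(list(r_p = unname(r_p), trajectory = traj,
                 conservation_drift = drift, ratios = ratios,
                 horizon = horizon),
            class = "pathway_simulation")
}

#' @export
print.pathway_simulation <- function(x, ...) {
  cat(sprintf("<pathway_simulation: r_p = %.5g, conservation drift = %.2g>\n",
              x$r_p, x$conservation_drift))
  invisible(x)
}

#' Convert a simulated flux to a neurosporene productivity
#'
#' Productivities are anchored to the reference pathway: `productivity =
#' 196 * r_p / r_p_ref` (ug/gDCW/h).
#'
#' @param r_p Simulated neurosporene production flux.
#' @param r_p_ref The reference variant's simulated flux under the same
#'   parameter set (`> 0`).
#' @param reference_productivity Measured reference productivity,
#'   ug/gDCW/h.
#' @return Productivity in ug/gDCW/h.
#' @export
flux_to_productivity <- function(r_p, r_p_ref,
                                 reference_productivity = REFERENCE_PRODUCTIVITY) {
  if (!isTRUE(r_p_ref > 0)) stop("reference flux r_p_ref not initialized (must be > 0)")
  reference_productivity * r_p / r_p_ref
}
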