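# Thermodynamic model of bacterial translation initiation: the ribosome's
# binding free energy to an mRNA is a five-term sum, and initiation rate is an
# exponential (Boltzmann-like) function of that free energy on a proportional
# "au" scale.

.organisms <- new.env(parent = emptyenv())

register_default_organisms <- function() {
  defaults <- c(
    "E. coli"          = "ACCUCCUUA",
    "Escherichia coli" = "ACCUCCUUA",
    "S. typhimurium"   = "ACCUCCUUA",
    "P. fluorescens"   = "ACCUCCUUA",
    "B. subtilis"      = "ACCUCCUUU",
    "C. glutamicum"    = "ACCUCCUUU"
  )
  for (org in names(defaults)) assign(org, defaults[[org]], envir = .organisms)
}

#' Register an organism's 16S rRNA anti-Shine-Dalgarno tail
#'
#' @param organism Organism identifier.
#' @param anti_sd The 9-nt 3' tail of the organism's 16S rRNA, written 5'->3'
#'   (e.g. `"ACCUCCUUA"` for gram-negative enterics).
#' @export
register_organism <- function(organism, anti_sd) {
  anti_sd <- validate_dseq(anti_sd)
  stopifnot(nchar(anti_sd) == 9L)
  assign(organism, anti_sd, envir = .organisms)
  invisible(anti_sd)
}

#' Look up the anti-Shine-Dalgarno sequence for an organism
#'
#' Gram-negative hosts (E. coli, S. typhimurium, P. fluorescens) use
#' `ACCUCCUUA`; gram-positive hosts (B. subtilis, C. glutamicum) use
#' `ACCUCCUUU`. The registry is extensible via [register_organism()].
#'
#' @param organism Organism identifier.
#' @return The 9-nt anti-SD sequence (5'->3').
#' @export
anti_sd_for <- function(organism) {
  if (!exists(organism, envir = .organisms, inherits = FALSE)) {
    stop(sprintf(
      "unknown organism '%s'; registered: %s",
      organism, paste(sort(ls(.organisms)), collapse = ", ")
    ))
  }
  get(organism, envir = .organisms, inherits = FALSE)
}

#' Ribosome model constants
#'
#' Bundles the organism-independent constants of the translation-initiation
#' model: the apparent Boltzmann constant beta (mol/kcal), the proportionality
#' constant putting rates on the `au` scale (dG_total = 0 maps to 2500 au),
#' the preferred 5-nt aligned spacing and its distortion-penalty coefficients,
#' start-codon energies (most negative for AUG and GUG), the ribosome
#' footprint, and the standby-site penalty (0 by default; a hook for refined
#' standby models).
#'
#' @param beta Apparent Boltzmann constant, mol/kcal.
#' @param rate_scale Proportionality constant of the rate law.
#' @param optimal_spacing Preferred SD-to-start-codon distance, nt.
#' @param spacing_compressed Quadratic coefficient for spacings below the
#'   optimum (kcal/mol/nt^2).
#' @param spacing_stretch_max,spacing_stretch_k Saturating-penalty parameters
#'   for spacings above the optimum: `max * d^2 / (d^2 + k^2)`.
#' @param start_codon_energies Named kcal/mol map of recognized start codons.
#' @param footprint Nucleotides of coding sequence occluded by the bound
#'   ribosome (kept unfolded in the final state).
#' @param dG_standby Standby-site penalty, kcal/mol.
#' @return An object of class `ribosome_model`.
#' @export
ribosome_model <- function(beta = 0.45,
                           rate_scale = 2500,
                           optimal_spacing = 5L,
                           spacing_compressed = 0.4,
                           spacing_stretch_max = 6,
                           spacing_stretch_k = 4,
                           start_codon_energies = c(AUG = -1.19, GUG = -1.19,
                                                    UUG = -0.37, CUG = 0),
                           footprint = 13L,
                           dG_standby = 0) {
  stopifnot(beta > 0, rate_scale > 0, optimal_spacing >= 0,
            spacing_compressed >= 0, spacing_stretch_max >= 0)
  structure(
    list(beta = beta, rate_scale = rate_scale,
         optimal_spacing = as.integer(optimal_spacing),
         spacing_compressed = spacing_compressed,
         spacing_stretch_max = spacing_stretch_max,
         spacing_stretch_k = spacing_stretch_k,
         start_codon_energies = start_codon_energies,
         footprint = as.integer(footprint),
         dG_standby = dG_standby),
    class = "ribosome_model"
  )
}

#' Spacing distortion penalty
#'
#' The 30S subunit prefers a five-nucleotide distance between the 16S
#' rRNA-binding site and the start codon; non-optimal distances distort the
#' initiation complex and incur a free-energy penalty. The penalty is zero at
#' the optimum, quadratic on the compressed branch, and saturating on the
#' stretched branch; it is non-decreasing away from the optimum.
#'
#' @param s Aligned spacing, nt (vectorized, `>= 0`).
#' @param model A [ribosome_model()].
#' @return Penalty in kcal/mol (`>= 0`).
#' @export
spacing_penalty <- function(s, model = ribosome_model()) {
  stopifnot(all(s >= 0))
  d <- s - model$optimal_spacing
  ifelse(d < 0,
         model$spacing_compressed * d^2,
         model$spacing_stretch_max * d^2 / (d^2 + model$spacing_stretch_k^2))
}

#' mRNA context for translation-initiation prediction
#'
#' @param rbs The ribosome-binding site: by convention the 35 nucleotides
#'   immediately upstream of the start codon.
#' @param cds Protein-coding sequence, beginning with a recognized start codon.
#' @param pre_sequence Promoter-derived 5' leader upstream of the RBS (may be
#'   empty).
#' @param organism Organism identifier (selects the anti-SD tail).
#' @return An object of class `mrna_context`.
#' @export
mrna_context <- function(rbs, cds, pre_sequence = "", organism = "E. coli") {
  rbs <- validate_dseq(rbs)
  cds <- validate_dseq(cds)
  if (nchar(pre_sequence) > 0) pre_sequence <- validate_dseq(pre_sequence)
  anti_sd <- anti_sd_for(organism)
  structure(
    list(pre_sequence = normalize_seq(pre_sequence), rbs = rbs, cds = cds,
         organism = organism, anti_sd = anti_sd),
    class = "mrna_context"
  )
}

#' Ribosome binding free energy of an mRNA
#'
#' Computes the total Gibbs free energy change of 30S ribosome binding as a
#' five-term sum: `dG_total = dG_mRNA_rRNA + dG_start + dG_spacing +
#' dG_standby - dG_mRNA`. The initial state is the folded mRNA (`dG_mRNA`,
#' negative); in the final state the 16S tail is hybridized to the mRNA and
#' any structure clashing with the hybrid or the ribosome footprint is kept
#' unfolded. Candidate 16S binding sites are enumerated over all alignments
#' with aligned spacing in `[0, 20]` nt; the minimum-total-energy candidate is
#' selected, with ties broken toward the spacing closest to the optimum and
#' then the most-upstream site.
#'
#' @param context An [mrna_context()] (the `rbs` must be concrete, not
#'   degenerate).
#' @param model A [ribosome_model()].
#' @param engine A folding engine ([vienna_engine()], [toy_engine()], ...).
#' @param max_spacing Largest aligned spacing considered, nt.
#' @return A one-row tibble (class `energy_breakdown`) with columns
#'   `dG_mRNA_rRNA`, `dG_start`, `dG_spacing`, `dG_standby`, `dG_mRNA`,
#'   `dG_total`, `binding_site`, `aligned_spacing`.
#' @export
delta_g_total <- function(context, model = ribosome_model(),
                          engine = toy_engine(), max_spacing = 20L) {
  best <- dg_total_core(context, model, engine, max_spacing)
  tibble::new_tibble(tibble::as_tibble(best), class = "energy_breakdown")
}

# plain-list fast path used by the optimizer loops
dg_total_core <- function(context, model, engine, max_spacing = 20L) {
  stopifnot(inherits(context, "mrna_context"))
  start_codon <- substr(context$cds, 1, 3)
  if (!start_codon %in% names(model$start_codon_energies)) {
    stop(sprintf("CDS must begin with a recognized start codon (%s), got '%s'",
                 paste(names(model$start_codon_energies), collapse = ", "),
                 start_codon))
  }
  if (nchar(context$rbs) == 0) stop("empty RBS")

  cds_head <- substr(context$cds, 1, min(35L, nchar(context$cds)))
  mrna <- paste0(context$pre_sequence, context$rbs, cds_head)
  L <- nchar(mrna)
  start_pos <- nchar(context$pre_sequence) + nchar(context$rbs) + 1L
  sd_len <- nchar(context$anti_sd)

  dG_mRNA <- engine$mfe_fold(mrna)$energy
  dG_start <- unname(model$start_codon_energies[start_codon])

  spacings <- 0:max_spacing
  starts <- start_pos - sd_len - spacings
  keep <- starts >= 1L
  if (!any(keep)) stop("RBS too short to place a 16S binding site")
  spacings <- spacings[keep]
  starts <- starts[keep]

  best <- NULL
  for (k in seq_along(starts)) {
    i <- starts[k]
    s <- spacings[k]
    window <- substr(mrna, i, i + sd_len - 1L)
    hyb <- engine$hybridize(window, context$anti_sd)$energy
    occluded <- i:min(L, start_pos + 2L + model$footprint)
    refold <- engine$mfe_fold(mrna, unpaired = occluded)$energy
    dG_pair <- hyb + refold
    dG_sp <- spacing_penalty(s, model)
    total <- dG_pair + dG_start + dG_sp + model$dG_standby - dG_mRNA
    cand <- list(total = total, dG_pair = dG_pair, dG_sp = dG_sp, i = i, s = s)
    if (is.null(best) ||
        total < best$total - 1e-12 ||
        (abs(total - best$total) <= 1e-12 &&
         (abs(s - model$optimal_spacing) < abs(best$s - model$optimal_spacing) ||
          (abs(s - model$optimal_spacing) == abs(best$s - model$optimal_spacing) &&
           i < best$i)))) {
      best <- cand
    }
  }

  list(
    dG_mRNA_rRNA = best$dG_pair,
    dG_start = dG_start,
    dG_spacing = best$dG_sp,
    dG_standby = model$dG_standby,
    dG_mRNA = dG_mRNA,
    dG_total = best$total,
    binding_site = best$i,
    aligned_spacing = best$s
  )
}

#' Translation initiation rate from binding free energy
#'
#' `rate = rate_scale * exp(-beta * dG_total)`: strictly positive and strictly
#' decreasing in `dG_total`. With the defaults (`beta = 0.45` mol/kcal,
#' `rate_scale = 2500`), a free energy of 0 kcal/mol maps to 2500 au and
#' physiological rates span roughly 0.1 to over 5,000,000 au.
#'
#' @param dG_total Total binding free energy, kcal/mol (vectorized).
#' @param model A [ribosome_model()].
#' @return Translation initiation rate(s), au.
#' @export
translation_rate <- function(dG_total, model = ribosome_model()) {
  stopifnot(all(is.finite(dG_total)))
  model$rate_scale * exp(-model$beta * dG_total)
}

#' Create a prediction cache
#'
#' Memoizes per-variant free-energy evaluations keyed by (variant, leader,
#' CDS head, organism, engine), so library evaluation inside the genetic
#' algorithm never re-folds a variant it has already seen.
#'
#' @return An environment usable as the `cache` argument of
#'   [predict_library_rates()].
#' @export
new_rate_cache <- function() new.env(parent = emptyenv())

predict_one_variant <- function(variant, context, model, engine, cache = NULL) {
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(engine$name, context$organism, context$pre_sequence,
                 substr(context$cds, 1, 38), variant, sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  ctx <- context
  ctx$rbs <- variant
  bd <- dg_total_core(ctx, model, engine)
  bd$rate_au <- translation_rate(bd$dG_total, model)
  if (!is.null(key)) cache[[key]] <- bd
  bd
}

#' Predict translation rates for every variant of a degenerate RBS
#'
#' Expands the degenerate sequence (or, above `limit`, evaluates a seeded
#' uniform subsample and flags the result), computes the full free-energy
#' breakdown for each concrete variant, and returns one row per variant.
#'
#' @param context An [mrna_context()]; its `rbs` field is ignored in favor of
#'   the variants.
#' @param dseq Degenerate RBS sequence.
#' @param model A [ribosome_model()].
#' @param engine A folding engine.
#' @param limit Expansion cap; larger libraries are subsampled to `sample_n`
#'   draws.
#' @param sample_n Subsample size used above the cap.
#' @param cache Optional cache from [new_rate_cache()].
#' @return A tibble with columns `variant_rbs`, the five energy terms,
#'   `dG_total`, and `rate_au`; attribute `sampled` is `TRUE` when the library
#'   was subsampled.
#' @export
predict_library_rates <- function(context, dseq, model = ribosome_model(),
                                  engine = toy_engine(), limit = 1e6,
                                  sample_n = 500L, cache = NULL) {
  n <- count_variants(dseq)
  sampled <- n > limit
  variants <- if (sampled) {
    unique(sample_variant(dseq, n = sample_n))
  } else {
    expand_dseq(dseq, limit = limit)
  }
  rows <- purrr::map(variants, function(v) {
    bd <- predict_one_variant(v, context, model, engine, cache)
    dplyr::bind_cols(tibble::tibble(variant_rbs = v), tibble::as_tibble(bd))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "sampled") <- sampled
  out
}

#' Write translation-rate predictions to TSV
#'
#' @param predictions Tibble from [predict_library_rates()].
#' @param path Output path.
#' @export
write_rate_predictions <- function(predictions, path) {
  cols <- c("variant_rbs", "dG_mRNA_rRNA", "dG_start", "dG_spacing",
            "dG_standby", "dG_mRNA", "dG_total", "rate_au")
  readr::write_tsv(predictions[, cols], path)
  invisible(path)
}
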