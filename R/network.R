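# The canonical crtEBI reaction network: enzymatic conversion of the
# isoprenoid precursors IPP and DMAPP to neurosporene by Idi, IspA, CrtE,
# CrtB, and CrtI. Ten overall reversible conversions are decomposed into
# bind / convert / release chains of reversible elementary reactions,
# totalling exactly 24 elementary reactions and 48 rate constants, with one
# mole balance per enzyme (5 balance groups).

crt_reaction <- function(id, enzyme, conversion, r1, r2, p1, p2) {
  tibble::tibble(reaction = id, enzyme = enzyme, conversion = conversion,
                 r1 = r1, r2 = r2, p1 = p1, p2 = p2,
                 kf = paste0("kf", id), kr = paste0("kr", id))
}

#' Build the canonical crtEBI reaction network
#'
#' Metabolites: IPP, DMAPP, GPP, FPP, GGPP, phytoene, phytofluene,
#' zeta-carotene, neurosporene. Enzymes: Idi, IspA, CrtE, CrtB, CrtI.
#' Conversions: Idi isomerizes IPP to DMAPP (1); IspA condenses DMAPP+IPP to
#' GPP and GPP+IPP to FPP (2); CrtE condenses GPP+IPP to FPP and FPP+IPP to
#' GGPP (2); CrtB condenses two GGPP to enzyme-bound prephytoene and converts
#' it to phytoene (2); CrtI desaturates phytoene to phytofluene to
#' zeta-carotene to neurosporene (3). Prephytoene occurs only enzyme-bound
#' (processive CrtB). Each conversion is decomposed into reversible substrate
#' binding, bound-state conversion where applicable, and reversible product
#' release, giving 24 reversible elementary reactions and 48 rate constants.
#' IPP and DMAPP are boundary species held at the precursor-supply level.
#'
#' @return An object of class `reaction_network`: list with tibbles
#'   `reactions` (reaction, enzyme, conversion, reactants r1/r2, products
#'   p1/p2, kf/kr constant ids) and `species` (species, type, enzyme balance
#'   group, boundary flag), plus `param_ids`.
#' @export
build_crtebi_network <- function() {
  reactions <- dplyr::bind_rows(
    # Idi: IPP <-> DMAPP
    crt_reaction(1L,  "Idi",  1L, "Idi", "IPP", "Idi_IPP", NA),
    crt_reaction(2L,  "Idi",  1L, "Idi_IPP", NA, "Idi", "DMAPP"),
    # IspA: DMAPP + IPP <-> GPP
    crt_reaction(3L,  "IspA", 2L, "IspA", "DMAPP", "IspA_DMAPP", NA),
    crt_reaction(4L,  "IspA", 2L, "IspA_DMAPP", "IPP", "IspA_DMAPP_IPP", NA),
    crt_reaction(5L,  "IspA", 2L, "IspA_DMAPP_IPP", NA, "IspA", "GPP"),
    # IspA: GPP + IPP <-> FPP
    crt_reaction(6L,  "IspA", 3L, "IspA", "GPP", "IspA_GPP", NA),
    crt_reaction(7L,  "IspA", 3L, "IspA_GPP", "IPP", "IspA_GPP_IPP", NA),
    crt_reaction(8L,  "IspA", 3L, "IspA_GPP_IPP", NA, "IspA", "FPP"),
    # CrtE: GPP + IPP <-> FPP
    crt_reaction(9L,  "CrtE", 4L, "CrtE", "GPP", "CrtE_GPP", NA),
    crt_reaction(10L, "CrtE", 4L, "CrtE_GPP", "IPP", "CrtE_GPP_IPP", NA),
    crt_reaction(11L, "CrtE", 4L, "CrtE_GPP_IPP", NA, "CrtE", "FPP"),
    # CrtE: FPP + IPP <-> GGPP
    crt_reaction(12L, "CrtE", 5L, "CrtE", "FPP", "CrtE_FPP", NA),
    crt_reaction(13L, "CrtE", 5L, "CrtE_FPP", "IPP", "CrtE_FPP_IPP", NA),
    crt_reaction(14L, "CrtE", 5L, "CrtE_FPP_IPP", NA, "CrtE", "GGPP"),
    # CrtB: GGPP + GGPP <-> prephytoene (enzyme-bound)
    crt_reaction(15L, "CrtB", 6L, "CrtB", "GGPP", "CrtB_GGPP", NA),
    crt_reaction(16L, "CrtB", 6L, "CrtB_GGPP", "GGPP", "CrtB_PPPP", NA),
    # CrtB: bound prephytoene <-> phytoene
    crt_reaction(17L, "CrtB", 7L, "CrtB_PPPP", NA, "CrtB_phytoene", NA),
    crt_reaction(18L, "CrtB", 7L, "CrtB_phytoene", NA, "CrtB", "phytoene"),
    # CrtI desaturation chain
    crt_reaction(19L, "CrtI", 8L, "CrtI", "phytoene", "CrtI_phytoene", NA),
    crt_reaction(20L, "CrtI", 8L, "CrtI_phytoene", NA, "CrtI", "phytofluene"),
    crt_reaction(21L, "CrtI", 9L, "CrtI", "phytofluene", "CrtI_phytofluene", NA),
    crt_reaction(22L, "CrtI", 9L, "CrtI_phytofluene", NA, "CrtI", "zeta_carotene"),
    crt_reaction(23L, "CrtI", 10L, "CrtI", "zeta_carotene", "CrtI_zeta", NA),
    crt_reaction(24L, "CrtI", 10L, "CrtI_zeta", NA, "CrtI", "neurosporene")
  )

  metabolites <- c("IPP", "DMAPP", "GPP", "FPP", "GGPP", "phytoene",
                   "phytofluene", "zeta_carotene", "neurosporene")
  enzymes <- c("Idi", "IspA", "CrtE", "CrtB", "CrtI")
  complexes <- c("Idi_IPP",
                 "IspA_DMAPP", "IspA_DMAPP_IPP", "IspA_GPP", "IspA_GPP_IPP",
                 "CrtE_GPP", "CrtE_GPP_IPP", "CrtE_FPP", "CrtE_FPP_IPP",
                 "CrtB_GGPP", "CrtB_PPPP", "CrtB_phytoene",
                 "CrtI_phytoene", "CrtI_phytofluene", "CrtI_zeta")
  complex_enzyme <- sub("_.*$", "", complexes)
  species <- tibble::tibble(
    species = c(metabolites, enzymes, complexes),
    type = c(rep("metabolite", length(metabolites)),
             rep("enzyme", length(enzymes)),
             rep("complex", length(complexes))),
    enzyme = c(rep(NA_character_, length(metabolites)), enzymes, complex_enzyme),
    boundary = c(metabolites, enzymes, complexes) %in% c("IPP", "DMAPP")
  )

  used <- unique(stats::na.omit(c(reactions$r1, reactions$r2,
                                  reactions$p1, reactions$p2)))
  stopifnot(setequal(used, species$species))

  structure(
    list(reactions = reactions, species = species,
         param_ids = c(reactions$kf, reactions$kr)),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network: %d species, %d reversible reactions, %d conversions, %d rate constants>\n",
              nrow(x$species), nrow(x$reactions),
              length(unique(x$reactions$conversion)), length(x$param_ids)))
  invisible(x)
}

#' Structural counts of a reaction network
#'
#' @param network A [build_crtebi_network()] result.
#' @return A one-row tibble with `n_species`, `n_reactions`, `n_constants`,
#'   `n_conversions`, `n_enzyme_balances`.
#' @export
network_counts <- function(network) {
  tibble::tibble(
    n_species = nrow(network$species),
    n_reactions = nrow(network$reactions),
    n_constants = length(network$param_ids),
    n_conversions = length(unique(network$reactions$conversion)),
    n_enzyme_balances = length(unique(stats::na.omit(network$species$enzyme)))
  )
}

#' Write / read a reaction network definition file
#'
#' Human-readable, one reversible reaction per line:
#' `reactants <-> products | kf_id kr_id | enzyme conversion`.
#'
#' @param network A reaction network.
#' @param path File path.
#' @return `read_network()` returns a `reaction_network`.
#' @export
write_network <- function(network, path) {
  fmt_side <- function(a, b) paste(stats::na.omit(c(a, b)), collapse = " + ")
  lines <- purrr::pmap_chr(network$reactions, function(reaction, enzyme,
                                                       conversion, r1, r2,
                                                       p1, p2, kf, kr) {
    sprintf("%s <-> %s | %s %s | %s %d",
            fmt_side(r1, r2), fmt_side(p1, p2), kf, kr, enzyme, conversion)
  })
  writeLines(c("# crtEBI elementary reaction network", lines), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  parse_side <- function(s) {
    parts <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    c(parts, NA_character_)[1:2]
  }
  rows <- purrr::imap_dfr(lines, function(line, i) {
    bits <- trimws(strsplit(line, "|", fixed = TRUE)[[1]])
    sides <- trimws(strsplit(bits[1], "<->", fixed = TRUE)[[1]])
    ks <- strsplit(bits[2], "\\s+")[[1]]
    meta <- strsplit(bits[3], "\\s+")[[1]]
    r <- parse_side(sides[1]); p <- parse_side(sides[2])
    tibble::tibble(reaction = as.integer(i), enzyme = meta[1],
                   conversion = as.integer(meta[2]),
                   r1 = r[1], r2 = r[2], p1 = p[1], p2 = p[2],
                   kf = ks[1], kr = ks[2])
  })
  canonical <- build_crtebi_network()
  net <- canonical
  net$reactions <- rows
  net$param_ids <- c(rows$kf, rows$kr)
  # species table rebuilt from the reaction list, keeping canonical roles
  used <- unique(stats::na.omit(c(rows$r1, rows$r2, rows$p1, rows$p2)))
  net$species <- canonical$species[canonical$species$species %in% used, ]
  net
}
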