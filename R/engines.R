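# RNA folding engines. An engine is a list with two closures:
#   mfe_fold(seq, unpaired = NULL)  -> list(energy, structure)
#   hybridize(seq_window, anti_sd)  -> list(energy)
# `unpaired` is an integer vector of 1-based positions forced single-stranded
# (the ribosome-clashing constraint). Energies are kcal/mol; an unconstrained
# minimum-free-energy fold is never higher in energy than a constrained one.

new_folding_engine <- function(name, mfe_fold, hybridize) {
  structure(list(name = name, mfe_fold = mfe_fold, hybridize = hybridize),
            class = "folding_engine")
}

#' @export
print.folding_engine <- function(x, ...) {
  cat("<folding_engine:", x$name, ">\n")
  invisible(x)
}

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Deterministic toy folding engine
#'
#' A fast, fully deterministic stand-in for a thermodynamic folding engine,
#' used to test the design pipeline's logic independently of nearest-neighbor
#' energetics. Folding energy is `-fold_weight` per G or C outside the
#' constrained region (so constrained folds are never lower in energy than
#' unconstrained ones), and hybridization energy is `-pair_energy` per
#' Watson-Crick match in the antiparallel alignment of the anti-SD tail
#' against the window.
#'
#' @param fold_weight kcal/mol contributed (negatively) by each G/C.
#' @param pair_energy kcal/mol per matched base pair in the hybrid.
#' @return A folding engine.
#' @export
toy_engine <- function(fold_weight = 0.2, pair_energy = 1.2) {
  gc_memo <- new.env(parent = emptyenv())
  gc_mask <- function(seq) {
    hit <- gc_memo[[seq]]
    if (is.null(hit)) {
      hit <- strsplit(normalize_seq(seq), "")[[1]] %in% c("G", "C")
      gc_memo[[seq]] <- hit
    }
    hit
  }
  mfe_fold <- function(seq, unpaired = NULL) {
    gc <- gc_mask(seq)
    n_gc <- if (is.null(unpaired)) sum(gc) else sum(gc) - sum(gc[unpaired])
    list(energy = -fold_weight * n_gc, structure = NULL)
  }
  hyb_memo <- new.env(parent = emptyenv())
  hybridize <- function(seq_window, anti_sd) {
    key <- paste0(seq_window, "|", anti_sd)
    hit <- hyb_memo[[key]]
    if (is.null(hit)) {
      w <- strsplit(normalize_seq(seq_window), "")[[1]]
      a <- strsplit(normalize_seq(anti_sd), "")[[1]]
      n <- min(length(w), length(a))
      # antiparallel: window 5'->3' against reversed anti-SD complement
      target <- RNA_COMPLEMENT[rev(a)][seq_len(n)]
      hit <- list(energy = -pair_energy * sum(w[seq_len(n)] == target))
      hyb_memo[[key]] <- hit
    }
    hit
  }
  new_folding_engine("toy", mfe_fold, hybridize)
}

#' Fixed-energy engine
#'
#' Returns hand-set constant energies regardless of sequence; used to verify
#' the free-energy bookkeeping against arithmetic oracles.
#'
#' @param mfe Constant folding energy (kcal/mol, must be `<= 0`).
#' @param hyb Constant hybridization energy (kcal/mol).
#' @return A folding engine.
#' @export
fixed_engine <- function(mfe = 0, hyb = 0) {
  stopifnot(mfe <= 0)
  new_folding_engine(
    "fixed",
    function(seq, unpaired = NULL) list(energy = mfe, structure = NULL),
    function(seq_window, anti_sd) list(energy = hyb)
  )
}

run_vienna <- function(cmd, args, input) {
  out <- suppressWarnings(system2(cmd, args = args, input = input, stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop(sprintf("%s exited with status %d", cmd, status))
  }
  out
}

parse_vienna_energy <- function(line) {
  m <- regmatches(line, regexpr("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", line))
  if (length(m) == 0) stop("could not parse energy from ViennaRNA output: ", line)
  as.numeric(gsub("[() ]", "", m))
}

#' ViennaRNA folding engine
#'
#' Production engine backed by the ViennaRNA command-line suite (`RNAfold` for
#' minimum-free-energy folding with hard single-stranded constraints,
#' `RNAduplex` for mRNA/16S-tail hybridization). Requires the ViennaRNA
#' executables on the `PATH`.
#'
#' @return A folding engine.
#' @export
vienna_engine <- function() {
  if (Sys.which("RNAfold") == "") stop("RNAfold not found on PATH")
  mfe_fold <- function(seq, unpaired = NULL) {
    s <- normalize_seq(seq)
    if (is.null(unpaired) || length(unpaired) == 0) {
      out <- run_vienna("RNAfold", c("--noPS"), s)
    } else {
      cons <- rep(".", nchar(s))
      cons[unpaired] <- "x"
      out <- run_vienna("RNAfold", c("--noPS", "-C"), c(s, paste(cons, collapse = "")))
    }
    list(energy = parse_vienna_energy(out[2]), structure = substr(out[2], 1, nchar(s)))
  }
  hybridize <- function(seq_window, anti_sd) {
    out <- run_vienna("RNAduplex", character(0),
                      c(normalize_seq(seq_window), normalize_seq(anti_sd)))
    list(energy = parse_vienna_energy(out[1]))
  }
  new_folding_engine("vienna", mfe_fold, hybridize)
}
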