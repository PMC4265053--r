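# Algebra over IUPAC-degenerate nucleotide sequences. Internally everything is
# RNA (T is normalized to U on input); serialization is uppercase IUPAC.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  W = c("A", "U"), S = c("C", "G"), M = c("A", "C"),
  K = c("G", "U"), R = c("A", "G"), Y = c("C", "U"),
  B = c("C", "G", "U"), D = c("A", "G", "U"),
  H = c("A", "C", "U"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "U")
)

# code for an arbitrary non-empty base subset, keyed by sorted, collapsed bases
IUPAC_OF_SET <- local({
  keys <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(IUPAC_SETS), keys)
})

IUPAC_CARDINALITY <- lengths(IUPAC_SETS)

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Uppercases and converts `T` to `U`. Accepts DNA or RNA input; all other
#' functions in the package call this before interpreting a sequence.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector over the 16-letter IUPAC RNA alphabet.
#' @export
normalize_seq <- function(x) {
  chartr("tT", "uU", toupper(x))
}

#' Validate a degenerate sequence
#'
#' Checks that every letter is one of the 16 IUPAC nucleotide codes. The error
#' message names the first offending position and character.
#'
#' @param dseq A single degenerate sequence (character scalar).
#' @return The normalized sequence, invisibly usable downstream.
#' @export
validate_dseq <- function(dseq) {
  stopifnot(is.character(dseq), length(dseq) == 1L, !is.na(dseq))
  s <- normalize_seq(dseq)
  if (nchar(s) == 0L) stop("degenerate sequence is empty")
  letters <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!letters %in% names(IUPAC_SETS))
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid IUPAC letter '%s' at position %d of '%s'",
      letters[bad[1]], bad[1], s
    ))
  }
  s
}

dseq_letters <- function(dseq) strsplit(validate_dseq(dseq), "", fixed = TRUE)[[1]]

#' Number of concrete variants encoded by a degenerate sequence
#'
#' The variant count is the product over positions of each IUPAC code's
#' cardinality (1, 2, 3, or 4). Returned as a double because degenerate RBS
#' spaces are astronomically large (a fully degenerate 35-mer encodes 4^35
#' concrete sequences out of 16^35 possible degenerate designs).
#'
#' @param dseq Degenerate sequence.
#' @return Variant count (double).
#' @examples
#' count_variants("NNNGGANNN") # 4096
#' count_variants("ATG")       # 1
#' @export
count_variants <- function(dseq) {
  prod(as.numeric(IUPAC_CARDINALITY[dseq_letters(dseq)]))
}

#' Expand a degenerate sequence into its concrete variants
#'
#' Returns every concrete sequence matching the pattern, deduplicated and in
#' lexicographic order (A < C < G < U), so expansions are byte-reproducible.
#'
#' @param dseq Degenerate sequence.
#' @param limit Refuse expansion when the variant count exceeds this (callers
#'   should switch to [sample_variant()] for larger spaces). Default `1e6`.
#' @return Character vector of concrete sequences.
#' @examples
#' expand_dseq("AS") # "AC" "AG"
#' @export
expand_dseq <- function(dseq, limit = 1e6) {
  n <- count_variants(dseq)
  if (n > limit) {
    stop(sprintf(
      "degenerate sequence encodes %.0f variants, above the expansion limit %.0f; use sampling",
      n, limit
    ))
  }
  out <- ""
  for (code in dseq_letters(dseq)) {
    bases <- sort(IUPAC_SETS[[code]])
    out <- paste0(rep(out, each = length(bases)), bases)
  }
  unique(out)
}

#' Sample concrete variants uniformly from a degenerate sequence
#'
#' Each concrete expansion has equal probability; draws are deterministic under
#' a fixed RNG state (`set.seed()` before calling).
#'
#' @param dseq Degenerate sequence.
#' @param n Number of draws.
#' @return Character vector of `n` concrete sequences (with replacement).
#' @export
sample_variant <- function(dseq, n = 1L) {
  letters <- dseq_letters(dseq)
  draws <- vapply(letters, function(code) {
    bases <- IUPAC_SETS[[code]]
    if (length(bases) == 1L) rep(bases, n) else sample(bases, n, replace = TRUE)
  }, character(n))
  if (n == 1L) paste(draws, collapse = "") else apply(draws, 1L, paste, collapse = "")
}

iupac_code_for <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- IUPAC_OF_SET[[key]]
  if (is.null(code)) stop("no IUPAC code for base set ", key)
  code
}

# strict superset / subset codes of a given code
superset_codes <- function(code) {
  bases <- IUPAC_SETS[[code]]
  names(Filter(function(b) length(b) > length(bases) && all(bases %in% b), IUPAC_SETS))
}

subset_codes <- function(code) {
  bases <- IUPAC_SETS[[code]]
  names(Filter(function(b) length(b) < length(bases) && all(b %in% bases), IUPAC_SETS))
}

#' Edit operators over degenerate sequences
#'
#' The elementary moves composed by the library-design genetic algorithm:
#' \describe{
#'   \item{increase_degeneracy}{replace one position's code with a uniformly
#'     chosen strict superset code;}
#'   \item{decrease_degeneracy}{replace one degenerate position's code with a
#'     uniformly chosen strict subset code;}
#'   \item{substitute}{swap one non-degenerate base for another base;}
#'   \item{recombine}{splice a prefix of `dseq` onto the suffix of `partner`
#'     at a random junction;}
#'   \item{fresh_random}{a new random non-degenerate sequence of equal length.}
#' }
#' Output length is always preserved. When the drawn (or given) position admits
#' no move — increasing an `N`, decreasing or substituting where no position
#' qualifies — the operator returns `NULL` ("no-op possible") and the caller
#' redraws.
#'
#' @param dseq Degenerate sequence.
#' @param operator One of `"increase_degeneracy"`, `"decrease_degeneracy"`,
#'   `"substitute"`, `"recombine"`, `"fresh_random"`.
#' @param partner Second parent, required for `"recombine"` (equal length).
#' @param pos Optional 1-based position; drawn uniformly among eligible
#'   positions when `NULL`.
#' @param junction Optional recombination junction (prefix length, in
#'   `1..length-1`); random when `NULL`.
#' @return An edited degenerate sequence, or `NULL` if no move is possible.
#' @export
edit_dseq <- function(dseq, operator, partner = NULL, pos = NULL, junction = NULL) {
  letters <- dseq_letters(dseq)
  L <- length(letters)
  pick_pos <- function(eligible) {
    if (!is.null(pos)) {
      if (!pos %in% eligible) return(NA_integer_)
      return(pos)
    }
    if (length(eligible) == 0L) return(NA_integer_)
    eligible[sample.int(length(eligible), 1L)]
  }
  switch(operator,
    increase_degeneracy = {
      p <- pick_pos(which(letters != "N"))
      if (is.na(p)) return(NULL)
      sup <- superset_codes(letters[p])
      letters[p] <- sup[sample.int(length(sup), 1L)]
      paste(letters, collapse = "")
    },
    decrease_degeneracy = {
      p <- pick_pos(which(IUPAC_CARDINALITY[letters] > 1L))
      if (is.na(p)) return(NULL)
      sub <- subset_codes(letters[p])
      letters[p] <- sub[sample.int(length(sub), 1L)]
      paste(letters, collapse = "")
    },
    substitute = {
      p <- pick_pos(which(IUPAC_CARDINALITY[letters] == 1L))
      if (is.na(p)) return(NULL)
      alt <- setdiff(c("A", "C", "G", "U"), letters[p])
      letters[p] <- alt[sample.int(3L, 1L)]
      paste(letters, collapse = "")
    },
    recombine = {
      stopifnot(!is.null(partner))
      pletters <- dseq_letters(partner)
      if (length(pletters) != L) stop("recombination partners must have equal length")
      if (L < 2L) return(NULL)
      j <- if (is.null(junction)) sample.int(L - 1L, 1L) else junction
      stopifnot(j >= 1L, j <= L - 1L)
      paste(c(letters[seq_len(j)], pletters[(j + 1L):L]), collapse = "")
    },
    fresh_random = random_rbs(L),
    stop("unknown edit operator: ", operator)
  )
}

#' Random non-degenerate sequence
#'
#' @param length Sequence length in nucleotides.
#' @return A random RNA sequence with bases drawn uniformly.
#' @export
random_rbs <- function(length = 35L) {
  paste(sample(c("A", "C", "G", "U"), length, replace = TRUE), collapse = "")
}
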