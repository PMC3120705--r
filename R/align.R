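# Alignment primitives: pairwise global / free-end-gap alignment under unit
# edit costs, approximate motif location, and the identity/coverage measure
# used for OTU clustering. The dynamic programming kernels live in src/.

#' Global pairwise alignment under unit edit costs
#'
#' Needleman-Wunsch alignment minimising edits (substitution = 1, indel = 1).
#' With `free_end_gaps`, leading and trailing gaps in either sequence are
#' free and excluded from `edits`, `matches` and `columns`; the reported
#' alignment then maximises `matches - edits` over all overlap placements
#' (pure edit minimisation is degenerate when both ends are free, because an
#' empty overlap costs nothing). Ties prefer match over substitution over a
#' gap in `b` over a gap in `a` during traceback.
#'
#' @param a,b non-empty nucleotide strings (matched literally, uppercased).
#' @param free_end_gaps logical; free terminal gaps in both sequences.
#' @return list with `edits`, `matches`, `columns` and the 0-based half-open
#'   aligned intervals `span_a`, `span_b`.
#' @export
#' @examples
#' global_align("ACGT", "ACGA")$edits
global_align <- function(a, b, free_end_gaps = FALSE) {
  stopifnot(is.character(a), length(a) == 1, is.character(b), length(b) == 1)
  if (!nzchar(a) || !nzchar(b)) stop("global_align requires non-empty sequences")
  cpp_align(toupper(a), toupper(b), isTRUE(free_end_gaps))
}

#' Locate a motif (tag, primer or adaptor) in a read
#'
#' Finds the placement of `motif` within `read` (or within `window`) with the
#' fewest edits; the whole motif must be aligned. IUPAC degeneracy letters in
#' the motif match their expansion sets at zero cost (so primers such as
#' ITS1-F with degenerate positions behave as in PCR); read letters are
#' matched literally apart from this set intersection. Ties are broken
#' towards the smallest start, then the smallest end.
#'
#' @param read nucleotide string searched.
#' @param motif non-empty motif; IUPAC letters allowed.
#' @param max_edits maximum edits tolerated; the best placement is discarded
#'   when it exceeds this.
#' @param window 0-based half-open interval `c(start, end)` restricting the
#'   search, or `NULL` for the whole read.
#' @param anchored_start logical; require the hit to start at the window's
#'   first position (used for tags at the 5' terminus).
#' @param motif_name optional label carried into the hit.
#' @return `NULL`, or a list with `start`, `end` (0-based half-open on the
#'   read), `edits` and `motif_name`.
#' @export
find_motif <- function(read, motif, max_edits, window = NULL,
                       anchored_start = FALSE, motif_name = NULL) {
  stopifnot(is.character(read), length(read) == 1, nzchar(motif),
            max_edits >= 0)
  read <- toupper(read); motif <- toupper(motif)
  n <- nchar(read)
  if (is.null(window)) window <- c(0L, n)
  if (window[1] < 0 || window[2] > n || window[1] >= window[2])
    stop("window outside read")
  text <- substr(read, window[1] + 1, window[2])
  hit <- cpp_find_motif(text, motif, isTRUE(anchored_start), TRUE)
  if (is.na(hit$edits) || hit$edits > max_edits) return(NULL)
  list(start = window[1] + hit$start, end = window[1] + hit$end,
       edits = hit$edits, motif_name = motif_name)
}

#' Identity and coverage of a sequence pair
#'
#' The pair is aligned with free end gaps (terminal overhangs excluded);
#' `identity` is matches / alignment columns over the aligned region and
#' `coverage` is the aligned span of the shorter sequence divided by its
#' length (so a sequence nested inside a longer one has coverage 1). The
#' measure is symmetric: inputs are canonically ordered before alignment.
#'
#' @param a,b non-empty nucleotide strings (or single rows of a
#'   [seq_records] frame, from which the sequence is taken).
#' @return list with `identity` and `coverage`, both in `[0, 1]`.
#' @export
pairwise_similarity <- function(a, b) {
  if (is.data.frame(a)) a <- a$sequence[1]
  if (is.data.frame(b)) b <- b$sequence[1]
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  # canonical order: longer first, ties lexicographically
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)) {
    tmp <- a; a <- b; b <- tmp
  }
  cpp_similarity(a, b)
}

#' All-pairs identity and coverage matrices
#'
#' Computes [pairwise_similarity()] for every pair of input sequences in
#' compiled code. Both matrices are exactly symmetric with unit diagonal.
#'
#' @param sequences character vector of nucleotide strings.
#' @return list of two numeric matrices, `identity` and `coverage`.
#' @export
similarity_matrix <- function(sequences) {
  stopifnot(is.character(sequences), all(nzchar(sequences)))
  cpp_similarity_matrix(toupper(sequences))
}
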