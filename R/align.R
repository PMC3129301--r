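#' Scoring scheme for pairwise global alignment
#'
#' Penalties are stored as magnitudes. A gap run of length L costs
#' `gap_open + gap_extend * (L - 1)`, so `gap_open == gap_extend` reduces to
#' linear gap costs. The defaults discourage spurious terminal gaps between
#' near-identical LTR copies; pass `free_end_gaps = TRUE` to leave terminal
#' gaps unpenalised.
#'
#' @param match Positive reward per identical column.
#' @param mismatch Penalty magnitude per mismatching column.
#' @param gap_open Penalty magnitude for opening a gap run.
#' @param gap_extend Penalty magnitude per additional gap position.
#' @param free_end_gaps Leave leading/trailing gaps free of charge?
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2L, mismatch = 1L, gap_open = 5L,
                           gap_extend = 1L, free_end_gaps = FALSE) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0)
  structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         free_end_gaps = isTRUE(free_end_gaps)),
    class = "scoring_scheme"
  )
}

#' Exact affine-gap global alignment of two nucleotide sequences
#'
#' Needleman–Wunsch/Gotoh alignment returning a maximum-score global alignment
#' under the affine scheme. Traceback ties are resolved deterministically
#' (diagonal, then up, then left), so identical inputs always give identical
#' alignments. Used to align the two LTR copies of one element before
#' divergence estimation.
#'
#' @param a,b Nucleotide strings (or single-row sequence tibbles with a `seq`
#'   column) over `A,C,G,T,N`; `N` never counts as a match.
#' @param scheme A [scoring_scheme()].
#' @return An `aligned_pair` list with elements `gapped_a`, `gapped_b`,
#'   `score` and `identity` (fraction identical over columns where both rows
#'   hold a residue).
#' @examples
#' global_align("ACGT", "AGT", scoring_scheme(1, 1, 1, 1))
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  a <- as_seq_string(a)
  b <- as_seq_string(b)
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence", call. = FALSE)
  stopifnot(inherits(scheme, "scoring_scheme"))
  res <- align_affine_cpp(a, b, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend,
                          scheme$free_end_gaps)
  p <- structure(
    list(gapped_a = res$a, gapped_b = res$b, score = res$score, identity = NA_real_),
    class = "aligned_pair"
  )
  p$identity <- pair_identity(p)
  p
}

as_seq_string <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("seq" %in% names(x), nrow(x) == 1L)
    x <- x$seq
  }
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

#' Identity of an aligned pair
#'
#' Fraction of matching columns among columns where both rows carry a residue;
#' gap columns are excluded from the denominator. Returns 0 when no such
#' column exists.
#'
#' @param p An `aligned_pair` from [global_align()].
#' @return A fraction in `[0, 1]`.
#' @export
pair_identity <- function(p) {
  stopifnot(inherits(p, "aligned_pair"))
  ca <- strsplit(p$gapped_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(p$gapped_b, "", fixed = TRUE)[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both)) return(0)
  sum(ca[both] == cb[both]) / sum(both)
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair> %d columns, score %s, identity %.3f\n",
              nchar(x$gapped_a), format(x$score), x$identity))
  invisible(x)
}

# Recompute the column-wise score of an alignment under a scheme; used to
# check the aligner's reported score.
score_alignment <- function(p, scheme) {
  ca <- strsplit(p$gapped_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(p$gapped_b, "", fixed = TRUE)[[1]]
  gap_a <- ca == "-"
  gap_b <- cb == "-"
  res <- sum(ifelse(ca[!gap_a & !gap_b] == cb[!gap_a & !gap_b] &
                      ca[!gap_a & !gap_b] != "N", scheme$match, -scheme$mismatch))
  gap_cost <- function(gaps) {
    if (!any(gaps)) return(0)
    r <- rle(gaps)
    runs <- r$lengths[r$values]
    if (scheme$free_end_gaps) {
      # drop terminal runs
      if (r$values[1]) runs <- runs[-1]
      if (length(r$values) > 1 && r$values[length(r$values)] && length(runs) > 0 &&
          gaps[length(gaps)]) runs <- runs[-length(runs)]
    }
    sum(scheme$gap_open + scheme$gap_extend * (runs - 1))
  }
  res - gap_cost(gap_a) - gap_cost(gap_b)
}
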