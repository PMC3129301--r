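#' Find candidate terminal direct repeats by self-comparison
#'
#' Compares an element with itself by exact k-mer seeding on off-main
#' diagonals followed by ungapped X-drop extension, keeping high-identity
#' direct-repeat pairs whose 5' copy lies in the 5' window of the element and
#' whose 3' copy lies in the 3' window. This recovers the two LTRs of a
#' full-length LTR retrotransposon; the main diagonal (trivial self-match) is
#' never considered. Candidates are ranked by terminality (combined distance
#' of the repeat ends from the element termini), then identity, then length —
#' LTRs are terminal by definition, so the most terminal high-identity repeat
#' wins over a longer internal one.
#'
#' @param element A single-row sequence tibble or a nucleotide string.
#' @param min_len Minimum repeat length (bp).
#' @param min_identity Minimum repeat identity.
#' @param max_ltr_frac Maximum LTR length as a fraction of the element length;
#'   also sets the terminal windows in which the two copies must lie.
#' @param seed_k Seed k-mer length for the self-comparison.
#' @param xdrop X-drop threshold terminating diagonal extension.
#' @return A tibble of candidates, best first: `start5`, `end5`, `start3`,
#'   `end3` (1-based inclusive), `length`, `identity`, `terminality`,
#'   `motif5`, `motif3` (NA until [anchor_motifs()] is applied). Zero rows
#'   when nothing meets the thresholds.
#' @export
find_terminal_repeats <- function(element, min_len = 80L, min_identity = 0.80,
                                  max_ltr_frac = 0.40, seed_k = 12L,
                                  xdrop = 30L) {
  s <- as_seq_string(element)
  n <- nchar(s)
  if (n < 2L * min_len) stop("element shorter than twice the minimum LTR length", call. = FALSE)
  max_ltr <- floor(max_ltr_frac * n)

  k <- as.integer(seed_k)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  pos_by_kmer <- split(starts[keep], kmers[keep])
  pos_by_kmer <- pos_by_kmer[lengths(pos_by_kmer) >= 2L]

  # candidate seed pairs: 5' copy within the leading window, 3' copy within
  # the trailing window
  seed_i <- integer(0); seed_j <- integer(0)
  for (pos in pos_by_kmer) {
    lead <- pos[pos <= max_ltr]
    trail <- pos[pos + k - 1L >= n - max_ltr + 1L]
    if (length(lead) && length(trail)) {
      grid <- expand.grid(i = lead, j = trail)
      grid <- grid[grid$j > grid$i, , drop = FALSE]
      seed_i <- c(seed_i, grid$i); seed_j <- c(seed_j, grid$j)
    }
  }
  empty <- tibble::tibble(
    start5 = integer(), end5 = integer(), start3 = integer(), end3 = integer(),
    length = integer(), identity = double(), terminality = integer(),
    motif5 = logical(), motif3 = logical()
  )
  if (length(seed_i) == 0L) return(empty)

  # one extension per diagonal per non-overlapping seed cluster
  diag <- seed_j - seed_i
  ord <- order(diag, seed_i)
  seed_i <- seed_i[ord]; seed_j <- seed_j[ord]; diag <- diag[ord]
  cand <- list()
  covered_to <- -1L; covered_diag <- -1L
  for (idx in seq_along(seed_i)) {
    d <- diag[idx]; i <- seed_i[idx]
    if (d == covered_diag && i <= covered_to) next
    ext <- extend_diagonal_cpp(s, i - 1L, seed_i[idx] + d - 1L, k, 1L, as.integer(xdrop))
    start5 <- ext[1] + 1L; end5 <- ext[2] + 1L
    covered_diag <- d; covered_to <- end5
    len <- end5 - start5 + 1L
    ident <- ext[3] / len
    start3 <- start5 + d; end3 <- end5 + d
    if (len < min_len || len > max_ltr || ident < min_identity) next
    if (end5 >= start3 || end3 > n) next
    cand[[length(cand) + 1L]] <- tibble::tibble(
      start5 = start5, end5 = end5, start3 = start3, end3 = end3,
      length = len, identity = ident,
      terminality = (start5 - 1L) + (n - end3),
      motif5 = NA, motif3 = NA
    )
  }
  if (length(cand) == 0L) return(empty)
  out <- dplyr::distinct(dplyr::bind_rows(cand))
  dplyr::arrange(out, .data$terminality, dplyr::desc(.data$identity),
                 dplyr::desc(.data$length))
}

#' Anchor LTR boundaries on the canonical TG...CA motifs
#'
#' LTRs characteristically start with `5'-TG` and end with `CA-3'`. Within
#' `window` bp of the candidate boundaries this searches for the nearest shift
#' making the 5' LTR start `TG` and the 3' LTR end `CA`. Because the two LTRs
#' are copies of the same repeat, a shift applied to the 5' start is applied
#' to the 3' start as well (and likewise for the ends), so the two LTR lengths
#' stay exactly equal. When no anchoring is found the candidate is returned
#' unchanged with the corresponding `motif` flag set to `FALSE`.
#'
#' @param element A single-row sequence tibble or nucleotide string.
#' @param candidate A one-row candidate tibble from [find_terminal_repeats()].
#' @param window Search half-width around each boundary (bp).
#' @return The (possibly shifted) candidate with `motif5`/`motif3` set.
#' @export
anchor_motifs <- function(element, candidate, window = 5L) {
  s <- as_seq_string(element)
  n <- nchar(s)
  stopifnot(nrow(candidate) == 1L)
  cd <- candidate
  shifts <- order(abs(seq(-window, window)))  # 0, -1, 1, -2, 2, ...
  deltas <- seq(-window, window)[shifts]

  d5 <- NA_integer_
  for (dd in deltas) {
    p <- cd$start5 + dd
    if (p >= 1L && p + 1L <= n && substr(s, p, p + 1L) == "TG") { d5 <- dd; break }
  }
  d3 <- NA_integer_
  for (dd in deltas) {
    p <- cd$end3 + dd
    if (p <= n && p - 1L >= 1L && substr(s, p - 1L, p) == "CA") { d3 <- dd; break }
  }
  if (!is.na(d5)) {
    cd$start5 <- cd$start5 + d5
    cd$start3 <- cd$start3 + d5
  }
  if (!is.na(d3)) {
    cd$end3 <- cd$end3 + d3
    cd$end5 <- cd$end5 + d3
  }
  # reject shifts that break the candidate's internal geometry
  if (!(cd$start5 >= 1 && cd$start5 <= cd$end5 && cd$end5 < cd$start3 &&
        cd$start3 <= cd$end3 && cd$end3 <= n)) {
    cd <- candidate
    d5 <- NA_integer_; d3 <- NA_integer_
  }
  cd$length <- cd$end5 - cd$start5 + 1L
  cd$motif5 <- !is.na(d5)
  cd$motif3 <- !is.na(d3)
  cd
}

#' Detect and anchor the LTR pair of every element
#'
#' Batch wrapper: for each sequence, runs [find_terminal_repeats()] and
#' anchors the top-ranked candidate with [anchor_motifs()]. Elements with no
#' acceptable repeat (e.g. truncated copies carrying a single LTR) get a row
#' of NA coordinates.
#'
#' @param seqs Sequence tibble (columns `id`, `seq`).
#' @param ... Passed to [find_terminal_repeats()].
#' @param window Motif-anchoring window, passed to [anchor_motifs()].
#' @return A tibble with one row per input sequence: `id`, coordinates,
#'   `length`, `identity`, `motif5`, `motif3`, `n_candidates`.
#' @export
detect_ltrs <- function(seqs, ..., window = 5L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  rows <- purrr::map(seq_len(nrow(seqs)), function(i) {
    cands <- tryCatch(find_terminal_repeats(seqs$seq[i], ...),
                      error = function(e) NULL)
    if (is.null(cands) || nrow(cands) == 0L) {
      return(tibble::tibble(
        id = seqs$id[i], start5 = NA_integer_, end5 = NA_integer_,
        start3 = NA_integer_, end3 = NA_integer_, length = NA_integer_,
        identity = NA_real_, motif5 = NA, motif3 = NA, n_candidates = 0L
      ))
    }
    best <- anchor_motifs(seqs$seq[i], cands[1, ], window = window)
    dplyr::bind_cols(tibble::tibble(id = seqs$id[i]),
                     dplyr::select(best, -"terminality"),
                     tibble::tibble(n_candidates = nrow(cands)))
  })
  dplyr::bind_rows(rows)
}
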