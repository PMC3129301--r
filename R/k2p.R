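#' Default substitution rate for plant LTR retrotransposons
#'
#' Substitutions per site per year used to convert LTR–LTR divergence into an
#' insertion age via `T = D / (2 r)`.
#' @export
DEFAULT_RATE <- 1.3e-8

#' Count transition/transversion site patterns in an aligned pair
#'
#' Applies complete deletion: every column holding a gap or an `N` in either
#' row is excluded. Among the remaining `n` columns, `P` is the proportion of
#' transition differences (A<->G, C<->T) and `Q` the proportion of
#' transversion differences.
#'
#' @param p An `aligned_pair` from [global_align()], or a list with
#'   `gapped_a`/`gapped_b` strings of equal length.
#' @return A tibble with one row: `n`, `P`, `Q`.
#' @export
count_site_patterns <- function(p) {
  cnt <- site_patterns_cpp(toupper(p$gapped_a), toupper(p$gapped_b))
  n <- cnt[1]
  if (n == 0L) stop("no comparable sites after complete deletion", call. = FALSE)
  tibble::tibble(n = n, P = cnt[2] / n, Q = cnt[3] / n)
}

#' Kimura two-parameter distance with standard error
#'
#' Closed-form K2P divergence
#' `D = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with the delta-method
#' standard error of Kimura (1980): with `c1 = 1/(1-2P-Q)`, `c2 = 1/(1-2Q)`,
#' `c3 = (c1 + c2)/2`,
#' `SE = sqrt((c1^2 P + c3^2 Q - (c1 P + c3 Q)^2) / n)`.
#'
#' @param counts A one-row tibble/list with `n`, `P`, `Q` (from
#'   [count_site_patterns()]).
#' @return A tibble with one row: `D`, `SE`, plus the input `n`, `P`, `Q`.
#' @export
k2p_distance <- function(counts) {
  n <- counts$n; P <- counts$P; Q <- counts$Q
  stopifnot(length(n) == 1L, n >= 0, P >= 0, Q >= 0, P + Q <= 1 + 1e-12)
  if (n == 0L) stop("no comparable sites", call. = FALSE)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop(sprintf("K2P distance saturated (P = %.4g, Q = %.4g): log argument <= 0", P, Q),
         call. = FALSE)
  }
  D <- -0.5 * log(w1) - 0.25 * log(w2)
  c1 <- 1 / w1
  c2 <- 1 / w2
  c3 <- (c1 + c2) / 2
  v <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n
  tibble::tibble(D = D, SE = sqrt(max(v, 0)), n = n, P = P, Q = Q)
}

#' Convert LTR divergence to an insertion date
#'
#' `T = D / (2 r)` where `r` is the substitution rate per site per year; the
#' two LTR copies diverge independently after insertion, hence the factor 2.
#' The standard error propagates linearly: `T_se = SE / (2 r)`.
#'
#' @param k A one-row tibble/list with `D` and `SE` (from [k2p_distance()]).
#' @param rate Substitution rate per site per year (> 0).
#' @return A tibble with one row: `T_years`, `T_se_years`, `T_mya`, `rate`.
#' @export
date_insertion <- function(k, rate = DEFAULT_RATE) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("substitution rate must be a single positive number", call. = FALSE)
  }
  T_years <- k$D / (2 * rate)
  se <- if (!is.null(k$SE)) k$SE / (2 * rate) else NA_real_
  tibble::tibble(T_years = T_years, T_se_years = se,
                 T_mya = T_years / 1e6, rate = rate)
}

#' Date one element from its two LTRs
#'
#' Composes the dating pipeline for a single element: extract the two LTR
#' subsequences at the given coordinates, globally align them, count site
#' patterns under complete deletion, compute the K2P divergence, and convert
#' to years. Elements carrying only one LTR (truncated copies) are not
#' datable and raise an error.
#'
#' @param element A single-row sequence tibble (columns `id`, `seq`) or a
#'   plain sequence string.
#' @param ltr A one-row tibble with 1-based inclusive coordinates `start5`,
#'   `end5`, `start3`, `end3` (NA for a missing LTR).
#' @param scheme A [scoring_scheme()] for the LTR–LTR alignment.
#' @param rate Substitution rate per site per year.
#' @return A one-row tibble: `id`, `ltr5`, `ltr3` (coordinate strings), `n`,
#'   `P`, `Q`, `D`, `SE`, `T_years`, `T_se_years`, `T_mya`.
#' @export
date_element <- function(element, ltr, scheme = scoring_scheme(),
                         rate = DEFAULT_RATE) {
  id <- if (is.data.frame(element) && "id" %in% names(element)) element$id else NA_character_
  s <- as_seq_string(element)
  need <- c("start5", "end5", "start3", "end3")
  stopifnot(all(need %in% names(ltr)))
  co <- vapply(need, function(f) as.numeric(ltr[[f]][1]), numeric(1))
  if (anyNA(co)) {
    stop(sprintf("element %s is not datable: both LTRs are required", id %||% "?"),
         call. = FALSE)
  }
  if (!(co["start5"] >= 1 && co["start5"] <= co["end5"] &&
        co["end5"] < co["start3"] && co["start3"] <= co["end3"] &&
        co["end3"] <= nchar(s))) {
    stop("invalid LTR coordinates for element ", id %||% "?", call. = FALSE)
  }
  ltr5 <- substr(s, co["start5"], co["end5"])
  ltr3 <- substr(s, co["start3"], co["end3"])
  aln <- global_align(ltr5, ltr3, scheme)
  k <- k2p_distance(count_site_patterns(aln))
  d <- date_insertion(k, rate)
  tibble::tibble(
    id = id,
    ltr5 = sprintf("%d-%d", co["start5"], co["end5"]),
    ltr3 = sprintf("%d-%d", co["start3"], co["end3"]),
    n = k$n, P = k$P, Q = k$Q, D = k$D, SE = k$SE,
    T_years = d$T_years, T_se_years = d$T_se_years, T_mya = d$T_mya
  )
}

#' Date every element in a collection
#'
#' Batch wrapper over [date_element()]: joins a sequence tibble with an LTR
#' coordinate table by `id` and dates every element where both LTRs are
#' present. Undatable elements (truncated, saturated, or without comparable
#' sites) are reported with NA estimates and the reason in `status`.
#'
#' @param seqs Sequence tibble (columns `id`, `seq`).
#' @param ltrs LTR coordinate tibble (columns `id`, `start5`, `end5`,
#'   `start3`, `end3`), e.g. from [detect_ltrs()].
#' @param scheme A [scoring_scheme()].
#' @param rate Substitution rate per site per year.
#' @return A tibble with one row per element; class `retro_dates`.
#' @export
date_elements <- function(seqs, ltrs, scheme = scoring_scheme(),
                          rate = DEFAULT_RATE) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  rows <- purrr::map(seq_len(nrow(seqs)), function(i) {
    el <- seqs[i, ]
    lt <- ltrs[ltrs$id == el$id, , drop = FALSE]
    if (nrow(lt) == 0L) {
      lt <- tibble::tibble(start5 = NA_real_, end5 = NA_real_,
                           start3 = NA_real_, end3 = NA_real_)
    }
    out <- tryCatch(
      dplyr::mutate(date_element(el, lt[1, ], scheme, rate), status = "dated"),
      error = function(e) {
        tibble::tibble(
          id = el$id, ltr5 = NA_character_, ltr3 = NA_character_,
          n = NA_integer_, P = NA_real_, Q = NA_real_, D = NA_real_,
          SE = NA_real_, T_years = NA_real_, T_se_years = NA_real_,
          T_mya = NA_real_, status = conditionMessage(e)
        )
      }
    )
    out
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("retro_dates", class(res))
  res
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
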