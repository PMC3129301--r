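#' Tidy a batch dating result
#'
#' One row per element with the estimated insertion age and its standard
#' error, in the units of the input table.
#'
#' @param x A `retro_dates` tibble from [date_elements()].
#' @param ... Unused.
#' @return A tibble (columns `id`, `n`, `D`, `SE`, `T_mya`, `status`).
#' @method tidy retro_dates
#' @export
tidy.retro_dates <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), "id", "n", "D", "SE", "T_mya", "status")
}

#' One-row summary of a batch dating result
#'
#' @param x A `retro_dates` tibble from [date_elements()].
#' @param ... Unused.
#' @return A tibble with `n_elements`, `n_dated`, `n_undatable`,
#'   `mean_T_mya`, `median_T_mya`, `min_T_mya`, `max_T_mya`.
#' @method glance retro_dates
#' @export
glance.retro_dates <- function(x, ...) {
  dated <- x$T_mya[x$status == "dated"]
  tibble::tibble(
    n_elements = nrow(x),
    n_dated = length(dated),
    n_undatable = nrow(x) - length(dated),
    mean_T_mya = mean(dated),
    median_T_mya = stats::median(dated),
    min_T_mya = if (length(dated)) min(dated) else NA_real_,
    max_T_mya = if (length(dated)) max(dated) else NA_real_
  )
}

#' Tidy a genome-group classification
#'
#' Expands the list column of members into one row per tip.
#'
#' @param x A `genome_groups` tibble from [classify_genome_groups()].
#' @param ... Unused.
#' @return A tibble with `group_label`, `genome`, `purity`, `id`.
#' @method tidy genome_groups
#' @export
tidy.genome_groups <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(tibble::as_tibble(x), "group_label", "genome", "purity",
                  id = "members"),
    "id"
  )
}

#' One-row summary of a genome-group classification
#'
#' @param x A `genome_groups` tibble.
#' @param ... Unused.
#' @return A tibble with group counts and sizes.
#' @method glance genome_groups
#' @export
glance.genome_groups <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x),
    n_specific = sum(x$group_label != "mixed"),
    n_mixed = sum(x$group_label == "mixed"),
    n_tips = sum(x$size),
    largest_group = x$group_label[which.max(x$size)]
  )
}

#' Tidy a composition report
#'
#' @param x A `composition_report` from [composition_report()].
#' @param ... Unused.
#' @return The report as a plain tibble.
#' @method tidy composition_report
#' @export
tidy.composition_report <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$total_len <- attr(x, "total_len")
  out
}
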