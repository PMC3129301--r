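CATEGORY_PATHS <- c(
  "class_I/LTR/gypsy", "class_I/LTR/copia", "class_I/LTR/unknown",
  "class_I/non-LTR", "class_II/CACTA", "MITE", "tandem_repeat", "gene",
  "unassigned"
)

#' Read a TE/gene annotation table
#'
#' Tab-separated columns `name`, `category`, `copies`, `length_bp`; `#` lines
#' are comments. Categories must be one of the enumerated paths
#' (`class_I/LTR/gypsy`, `class_I/LTR/copia`, `class_I/LTR/unknown`,
#' `class_I/non-LTR`, `class_II/CACTA`, `MITE`, `tandem_repeat`, `gene`,
#' `unassigned`).
#'
#' @param path TSV path.
#' @return A tibble of annotation records.
#' @export
read_annotation <- function(path) {
  tbl <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "category", "copies", "length_bp") %in% names(tbl)))
  bad <- setdiff(unique(tbl$category), CATEGORY_PATHS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown annotation category: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  stopifnot(all(tbl$copies >= 1), all(tbl$length_bp >= 0))
  tibble::as_tibble(tbl)
}

#' Read a gene coordinate table
#'
#' Tab-separated columns `name`, `start`, `end`, `strand` with 1-based
#' inclusive coordinates.
#'
#' @param path TSV path.
#' @return A tibble of gene records.
#' @export
read_genes <- function(path) {
  tbl <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end", "strand") %in% names(tbl)))
  stopifnot(all(tbl$start >= 1), all(tbl$start <= tbl$end),
            all(tbl$strand %in% c("+", "-")))
  tibble::as_tibble(tbl)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Category composition report for an annotated sequence
#'
#' Sums copy numbers and base pairs per annotation category and per rollup
#' (class I, LTR retrotransposons, gypsy, copia, unknown LTR, non-LTR, class
#' II, MITE, tandem repeats, genes, all TEs, unassigned), and reports each as
#' a percentage of the total sequence length, rounded half-up to 0.1. The
#' unassigned balance is computed as total length minus everything assigned.
#'
#' @param records Annotation tibble (columns `name`, `category`, `copies`,
#'   `length_bp`), e.g. from [read_annotation()].
#' @param total_len Total sequence length in bp (> 0).
#' @return A tibble of class `composition_report` with columns `category`,
#'   `copies`, `length_bp`, `fraction_pct`, plus attribute `total_len`.
#' @export
composition_report <- function(records, total_len) {
  stopifnot(total_len > 0,
            all(records$category %in% CATEGORY_PATHS))
  assigned <- sum(records$length_bp[records$category != "unassigned"])
  if (assigned > total_len) {
    stop(sprintf("assigned length (%d bp) exceeds total length (%d bp)",
                 assigned, total_len), call. = FALSE)
  }
  rollups <- list(
    class_I            = "^class_I/",
    LTR_retrotransposons = "^class_I/LTR/",
    gypsy              = "^class_I/LTR/gypsy$",
    copia              = "^class_I/LTR/copia$",
    unknown_LTR        = "^class_I/LTR/unknown$",
    non_LTR            = "^class_I/non-LTR$",
    class_II           = "^class_II/",
    MITE               = "^MITE$",
    tandem_repeats     = "^tandem_repeat$",
    genes              = "^gene$",
    TE_total           = "^(class_I/|class_II/|MITE$)"
  )
  sums <- purrr::imap(rollups, function(rx, nm) {
    sel <- grepl(rx, records$category)
    tibble::tibble(category = nm,
                   copies = sum(records$copies[sel]),
                   length_bp = sum(records$length_bp[sel]))
  })
  out <- dplyr::bind_rows(sums)
  out <- dplyr::bind_rows(out, tibble::tibble(
    category = "unassigned", copies = NA_integer_,
    length_bp = total_len - assigned
  ))
  out$fraction_pct <- round_half_up(100 * out$length_bp / total_len, 1)
  attr(out, "total_len") <- total_len
  class(out) <- c("composition_report", class(out))
  out
}

#' Share of one family within a composition category
#'
#' Percentage of the base pairs in `within`-category records that belong to
#' records whose name matches `family_regex` — e.g. the share of one
#' retrotransposon family among all LTR retrotransposons of a BAC.
#'
#' @param records Annotation tibble.
#' @param family_regex Regular expression matched against record names.
#' @param within Regular expression selecting the reference category paths.
#' @return Percentage rounded half-up to 0.1.
#' @export
family_fraction <- function(records, family_regex, within = "^class_I/LTR/") {
  ref <- grepl(within, records$category)
  denom <- sum(records$length_bp[ref])
  if (denom == 0) stop("no records in the reference category", call. = FALSE)
  num <- sum(records$length_bp[ref & grepl(family_regex, records$name)])
  round_half_up(100 * num / denom, 1)
}

#' Gene-island geometry
#'
#' Offset of the first gene from the 5' end (its start coordinate) and the
#' island span measured as `max(end) - min(start)` — the coordinate
#' difference, not the inclusive width.
#'
#' @param genes Gene tibble (columns `start`, `end`).
#' @return A one-row tibble: `offset_5prime`, `span`, `n_genes`.
#' @export
gene_island <- function(genes) {
  stopifnot(nrow(genes) >= 1L)
  tibble::tibble(
    offset_5prime = min(genes$start),
    span = max(genes$end) - min(genes$start),
    n_genes = nrow(genes)
  )
}

#' Gene density in kb per gene
#'
#' @param total_len Sequence length in bp.
#' @param n_genes Number of genes (>= 1).
#' @return Nearest-integer kb per gene.
#' @export
gene_density <- function(total_len, n_genes) {
  stopifnot(n_genes >= 1)
  round_half_up(total_len / n_genes / 1000)
}

#' Protein length from an intronless CDS span
#'
#' `(end - start + 1) / 3 - 1` residues: one codon per triplet, terminal stop
#' excluded. Errors when the span is not a multiple of three.
#'
#' @param genes Gene tibble (columns `start`, `end`); vectorised.
#' @return The input with a `protein_len` column appended.
#' @export
protein_length_from_cds <- function(genes) {
  span <- genes$end - genes$start + 1
  if (any(span %% 3 != 0)) {
    bad <- which(span %% 3 != 0)[1]
    stop(sprintf("CDS span of '%s' (%d bp) is not a multiple of 3",
                 genes$name[bad] %||% bad, span[bad]), call. = FALSE)
  }
  dplyr::mutate(genes, protein_len = span / 3 - 1)
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(s), "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

#' In-silico PCR on a template sequence
#'
#' Finds exact, case-insensitive matches of the forward primer on the forward
#' strand and of the reverse complement of the reverse primer downstream, and
#' reports every product length `end(reverse site) - start(forward site) + 1`
#' up to `max_product`. Primers may be written with hyphens or whitespace
#' (stripped on input) and must be at least 15 nt after cleaning.
#'
#' @param template A sequence string or single-row sequence tibble.
#' @param fwd,rev Primer sequences, 5'->3'.
#' @param max_product Longest product reported (bp).
#' @return Sorted integer vector of product lengths (empty when no site).
#' @export
insilico_pcr <- function(template, fwd, rev, max_product = 5000L) {
  s <- as_seq_string(template)
  clean <- function(p) {
    p <- toupper(gsub("[^A-Za-z]", "", p))
    if (nchar(p) < 15L) stop("primer shorter than 15 nt after cleaning", call. = FALSE)
    if (grepl("[^ACGT]", p)) stop("primer contains non-ACGT characters", call. = FALSE)
    p
  }
  fwd <- clean(fwd)
  rev <- clean(rev)
  find_all <- function(pat) {
    hits <- gregexpr(pat, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits)
  }
  f_starts <- find_all(fwd)
  r_starts <- find_all(revcomp(rev))
  if (length(f_starts) == 0L || length(r_starts) == 0L) return(integer(0))
  r_ends <- r_starts + nchar(rev) - 1L
  prods <- as.vector(outer(r_ends, f_starts, `-`)) + 1L
  sort(prods[prods >= nchar(fwd) + nchar(rev) & prods <= max_product])
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("<composition_report> total %d bp\n", attr(x, "total_len")))
  NextMethod()
}
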