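#' Read nucleotide sequences from a FASTA file
#'
#' Reads a plain (ungapped) nucleotide FASTA file into a tibble with one row
#' per record. Residues are uppercased on input; only `A`, `C`, `G`, `T` and
#' `N` are accepted. Gap characters are rejected here — use
#' [read_aligned_fasta()] for gapped input. `N` is legal but is treated as
#' missing data by every distance computation in the package.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character) and `seq` (character,
#'   uppercase). An optional `genome` column can be joined on later with
#'   [read_genome_labels()].
#' @seealso [write_fasta()], [read_aligned_fasta()]
#' @export
read_fasta <- function(path) {
  recs <- parse_fasta_records(path)
  seqs <- toupper(recs$seq)
  validate_seq_ids(recs$id, path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop(sprintf(
      "illegal characters in FASTA record '%s' in %s (allowed: A,C,G,T,N; gapped input belongs in read_aligned_fasta())",
      recs$id[which(bad)[1]], path
    ), call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop(sprintf("empty sequence for record '%s' in %s", recs$id[which(!nzchar(seqs))[1]], path), call. = FALSE)
  }
  tibble::tibble(id = recs$id, seq = seqs)
}

#' Read a gapped FASTA multiple alignment
#'
#' All rows must have equal gapped length; `-` is the gap character. Returns a
#' tibble of class `retro_alignment` with one row per aligned sequence.
#'
#' @param path Path to an aligned FASTA file.
#' @return A tibble with columns `id` and `seq` (gapped, uppercase), class
#'   `retro_alignment`, with the column count in `attr(, "n_cols")`.
#' @export
read_aligned_fasta <- function(path) {
  recs <- parse_fasta_records(path)
  seqs <- toupper(recs$seq)
  validate_seq_ids(recs$id, path)
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop(sprintf("illegal characters in aligned record '%s' in %s", recs$id[which(bad)[1]], path), call. = FALSE)
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    stop(sprintf(
      "ragged alignment in %s: row lengths %s", path,
      paste(unique(widths), collapse = ", ")
    ), call. = FALSE)
  }
  if (widths[1] == 0L) stop(sprintf("empty alignment rows in %s", path), call. = FALSE)
  degapped <- gsub("-", "", seqs, fixed = TRUE)
  if (any(!nzchar(degapped))) {
    stop(sprintf("row '%s' in %s is all gaps", recs$id[which(!nzchar(degapped))[1]], path), call. = FALSE)
  }
  new_alignment(tibble::tibble(id = recs$id, seq = seqs))
}

new_alignment <- function(tbl) {
  attr(tbl, "n_cols") <- nchar(tbl$seq[1])
  class(tbl) <- c("retro_alignment", class(tbl))
  tbl
}

#' Number of columns of an alignment
#' @param aln A `retro_alignment` (or any tibble with equal-length `seq`).
#' @return Integer column count.
#' @export
aln_ncol <- function(aln) {
  nc <- attr(aln, "n_cols")
  if (is.null(nc)) nc <- nchar(aln$seq[1])
  as.integer(nc)
}

# Low-level FASTA record parser shared by the two readers. Biostrings is the
# natural reader for big files but rejects nothing; validation here is the
# point, so the splitting is done directly on the text.
parse_fasta_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop(sprintf("%s does not start with a FASTA header", path), call. = FALSE)
  grp <- cumsum(is_hdr)
  ids <- sub("^>\\s*", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(
    split(lines[!is_hdr], grp[!is_hdr]),
    function(x) paste(x, collapse = ""), character(1)
  )
  seq_out <- character(length(ids))
  present <- as.integer(names(seqs))
  seq_out[present] <- seqs
  list(id = ids, seq = seq_out)
}

validate_seq_ids <- function(ids, path) {
  if (any(!nzchar(ids))) stop(sprintf("empty record id in %s", path), call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate id '%s' in %s", dup[1], path), call. = FALSE)
  }
  invisible(ids)
}

#' Write sequences to FASTA
#'
#' @param seqs A tibble with columns `id` and `seq` (gapped rows allowed).
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read genome labels from a two-column TSV
#'
#' The table maps sequence ids to genome-of-origin labels (e.g. `A`, `B`, `D`,
#' `S`, `Au`). Lines starting with `#` are comments. Duplicated ids are
#' tolerated only when the repeated label agrees.
#'
#' @param path Path to a tab-separated file with columns id, label.
#' @return A tibble with columns `id` and `genome`.
#' @export
read_genome_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) return(tibble::tibble(id = character(), genome = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop(sprintf("line without two tab-separated fields in %s", path), call. = FALSE)
  }
  tbl <- tibble::tibble(
    id = vapply(parts, `[[`, character(1), 1L),
    genome = vapply(parts, `[[`, character(1), 2L)
  )
  tbl <- dplyr::distinct(tbl)
  if (anyDuplicated(tbl$id)) {
    bad <- tbl$id[duplicated(tbl$id)][1]
    stop(sprintf("conflicting genome labels for id '%s' in %s", bad, path), call. = FALSE)
  }
  tbl
}

#' Serialise a tree to Newick text
#'
#' Deterministic Newick writer: branch lengths with six decimals, integer
#' bootstrap supports (node labels) on internal nodes, and children ordered
#' lexicographically by the smallest tip label in each subtree, so the same
#' tree always serialises to the same string.
#'
#' @param tree An [ape::phylo] tree; `node.label` (if present) is written as
#'   internal node labels.
#' @param path Optional output file; when given the string (plus newline) is
#'   written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  edge_len <- tree$edge.length
  node_lab <- tree$node.label

  min_tip <- character(ntip + tree$Nnode)
  fill_min <- function(node) {
    if (node <= ntip) {
      min_tip[node] <<- tree$tip.label[node]
    } else {
      kids <- tree$edge[children[[as.character(node)]], 2]
      for (k in kids) fill_min(k)
      min_tip[node] <<- min(min_tip[kids])
    }
  }
  root <- ntip + 1L
  fill_min(root)

  fmt_len <- function(x) {
    if (is.null(x) || is.na(x)) "" else sprintf(":%.6f", x)
  }
  ser <- function(node, blen) {
    if (node <= ntip) {
      return(paste0(tree$tip.label[node], fmt_len(blen)))
    }
    eidx <- children[[as.character(node)]]
    kids <- tree$edge[eidx, 2]
    ord <- order(min_tip[kids], method = "radix")
    inner <- vapply(ord, function(o) {
      ser(kids[o], if (is.null(edge_len)) NA_real_ else edge_len[eidx[o]])
    }, character(1))
    lab <- ""
    if (!is.null(node_lab)) {
      l <- node_lab[node - ntip]
      if (!is.na(l) && nzchar(l)) lab <- as.character(l)
    }
    paste0("(", paste(inner, collapse = ","), ")", lab, fmt_len(blen))
  }
  out <- paste0(ser(root, NA_real_), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
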