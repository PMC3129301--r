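#' K2P distance matrix from a multiple alignment
#'
#' Pairwise Kimura two-parameter distances between all rows of an alignment.
#' Under `pairwise` deletion each pair drops only its own gap/`N` columns;
#' under `complete` deletion every column containing a gap or `N` in any row
#' is removed first, so all pairs use the same columns. Tree building uses
#' pairwise deletion by default; LTR dating uses complete deletion.
#'
#' @param aln A `retro_alignment` (tibble with `id`, gapped `seq`).
#' @param deletion `"pairwise"` or `"complete"`.
#' @return A symmetric numeric matrix with dimnames set to the row ids.
#' @export
k2p_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(all(c("id", "seq") %in% names(aln)), nrow(aln) >= 3L)
  chars <- do.call(rbind, strsplit(toupper(aln$seq), "", fixed = TRUE))
  valid <- matrix(chars %in% c("A", "C", "G", "T"), nrow = nrow(chars))
  if (deletion == "complete") {
    keep <- colSums(valid) == nrow(chars)
    chars <- chars[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  nseq <- nrow(chars)
  d <- matrix(0, nseq, nseq, dimnames = list(aln$id, aln$id))
  purine <- matrix(chars %in% c("A", "G"), nrow = nseq)
  bad_pairs <- character(0)
  for (i in seq_len(nseq - 1L)) {
    for (j in seq((i + 1L), nseq)) {
      ok <- valid[i, ] & valid[j, ]
      n <- sum(ok)
      res <- tryCatch({
        if (n == 0L) stop("no comparable sites")
        diff <- ok & (chars[i, ] != chars[j, ])
        ts <- sum(diff & (purine[i, ] == purine[j, ]))
        tv <- sum(diff) - ts
        k2p_distance(list(n = n, P = ts / n, Q = tv / n))$D
      }, error = function(e) NA_real_)
      if (is.na(res)) {
        bad_pairs <- c(bad_pairs, sprintf("%s/%s", aln$id[i], aln$id[j]))
      } else {
        d[i, j] <- d[j, i] <- res
      }
    }
  }
  if (length(bad_pairs) > 0L) {
    stop(sprintf("K2P distance undefined (saturated or no comparable sites) for pair(s): %s",
                 paste(bad_pairs, collapse = ", ")), call. = FALSE)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei agglomeration with the Studier–Keppler criterion
#' `Q(i,j) = (N-2) d(i,j) - R_i - R_j`. Ties are broken deterministically by
#' taking the first minimal pair with the active nodes held in sorted-label
#' order (new internal nodes appended last), so the result is invariant to
#' permutations of the input matrix. Negative branch-length estimates are
#' clamped to zero with the deficit moved to the sister branch, preserving
#' path lengths through the joined node.
#'
#' @param m Symmetric distance matrix with labelled dimnames (>= 3 taxa).
#' @return An unrooted [ape::phylo] tree (trifurcating root node).
#' @export
neighbor_joining <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) >= 3L,
            !is.null(rownames(m)))
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix is not symmetric", call. = FALSE)
  ord <- order(rownames(m), method = "radix")
  m <- m[ord, ord, drop = FALSE]
  labels <- rownames(m)

  # nodes held as newick fragments; lengths formatted at full precision
  frag <- labels
  act <- seq_along(labels)     # active indices into d
  d <- m
  fmt <- function(x) sprintf("%.16g", x)
  clamp2 <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0) + 0, max(lj, 0) + 0)  # +0 normalises IEEE negative zero
  }
  while (length(act) > 3L) {
    N <- length(act)
    dm <- d[act, act, drop = FALSE]
    R <- rowSums(dm)
    Q <- (N - 2) * dm - outer(R, R, `+`)
    diag(Q) <- Inf
    best <- c(1L, 2L); bestq <- Inf
    for (i in seq_len(N - 1L)) {
      for (j in seq((i + 1L), N)) {
        if (Q[i, j] < bestq - 1e-12) { bestq <- Q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    dij <- dm[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (N - 2))
    lj <- dij - li
    ll <- clamp2(li, lj)
    newfrag <- paste0("(", frag[act[i]], ":", fmt(ll[1]), ",",
                      frag[act[j]], ":", fmt(ll[2]), ")")
    # distances from the new node
    others <- act[-c(i, j)]
    dnew <- (d[act[i], others] + d[act[j], others] - dij) / 2
    d <- rbind(cbind(d, 0), 0)
    newidx <- nrow(d)
    d[newidx, others] <- dnew
    d[others, newidx] <- dnew
    frag <- c(frag, newfrag)
    act <- c(others, newidx)
  }
  a <- act[1]; b <- act[2]; c3 <- act[3]
  la <- (d[a, b] + d[a, c3] - d[b, c3]) / 2
  lb <- (d[a, b] + d[b, c3] - d[a, c3]) / 2
  lc <- (d[a, c3] + d[b, c3] - d[a, b]) / 2
  la <- max(la, 0) + 0; lb <- max(lb, 0) + 0; lc <- max(lc, 0) + 0
  nwk <- paste0("(", frag[a], ":", fmt(la), ",", frag[b], ":", fmt(lb), ",",
                frag[c3], ":", fmt(lc), ");")
  ape::read.tree(text = nwk)
}

# canonical split keys for unrooted comparison: each internal edge splits the
# tips in two; the key is the sorted side containing the overall smallest label
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label, method = "radix")
  anchor <- tips[1]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts[-1]) {          # first partition is the root (all tips)
    side <- sort(tree$tip.label[p], method = "radix")
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    if (!(anchor %in% side)) side <- setdiff(tips, side)
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

#' Neighbor-joining tree with column-resampling bootstrap supports
#'
#' Builds the point-estimate NJ tree on the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds distance matrix
#' and tree for each replicate, and reports for every internal edge the
#' percentage of replicates containing the same bipartition. Replicates whose
#' resampled matrix is saturated (or has a pair with no comparable sites) are
#' skipped and counted; more than 50% skipped is an error.
#'
#' @param aln A `retro_alignment`.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the whole procedure is reproducible given it.
#' @param deletion Deletion mode for [k2p_matrix()].
#' @return The point-estimate [ape::phylo] tree with integer percentage
#'   supports in `node.label` (empty for the root) and attributes
#'   `n_reps_used`, `n_reps_skipped`.
#' @export
bootstrap_support <- function(aln, n_reps = 500L, seed = 1L,
                              deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(n_reps >= 1L)
  point <- neighbor_joining(k2p_matrix(aln, deletion))
  nc <- aln_ncol(aln)
  chars <- do.call(rbind, strsplit(toupper(aln$seq), "", fixed = TRUE))

  counts <- integer(0)
  keys_point <- tree_splits(point)
  tally <- stats::setNames(integer(length(keys_point)), keys_point)
  skipped <- 0L
  with_local_seed(seed, {
    for (rep in seq_len(n_reps)) {
      cols <- sample.int(nc, nc, replace = TRUE)
      raln <- new_alignment(tibble::tibble(
        id = aln$id,
        seq = apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
      ))
      tr <- tryCatch(neighbor_joining(k2p_matrix(raln, deletion)),
                     error = function(e) NULL)
      if (is.null(tr)) { skipped <- skipped + 1L; next }
      hit <- intersect(tree_splits(tr), keys_point)
      tally[hit] <- tally[hit] + 1L
    }
  })
  used <- n_reps - skipped
  if (skipped > n_reps / 2) {
    stop(sprintf("%d of %d bootstrap replicates were saturated", skipped, n_reps),
         call. = FALSE)
  }
  support <- round(100 * tally / used)

  # attach supports to internal nodes of the point tree
  ntip <- length(point$tip.label)
  node_lab <- character(point$Nnode)
  parts <- ape::prop.part(point)
  tips <- sort(point$tip.label, method = "radix")
  anchor <- tips[1]
  for (k in seq_along(parts)) {
    node <- ntip + k
    if (node == ntip + 1L) { node_lab[k] <- ""; next }  # root
    side <- sort(point$tip.label[parts[[k]]], method = "radix")
    if (!(anchor %in% side)) side <- setdiff(tips, side)
    key <- paste(side, collapse = "|")
    node_lab[k] <- if (key %in% names(support)) as.character(support[[key]]) else ""
  }
  point$node.label <- node_lab
  attr(point, "n_reps_used") <- used
  attr(point, "n_reps_skipped") <- skipped
  point
}

#' Classify tree clades into genome-specific and mixed groups
#'
#' Evaluates both tip-sets of every internal edge of the tree. A side is
#' genome-specific for genome `G` when at least `purity_threshold` of its
#' labelled tips carry `G` and it holds at least `min_size` tips. The maximal
#' non-nested genome-specific sides are reported (largest first, overlapping
#' candidates discarded); every remaining tip falls into a single `mixed`
#' group — the residue of a tree after removing subtrees stays connected.
#' Unlabelled tips never enter purity computations.
#'
#' @param tree An [ape::phylo] tree.
#' @param labels Tibble with columns `id`, `genome` (or a named character
#'   vector id -> genome).
#' @param purity_threshold Minimum fraction of labelled tips sharing a genome.
#' @param min_size Minimum tips in a genome-specific group.
#' @return A tibble of class `genome_groups`: `group_label`, `genome`, `size`,
#'   `purity`, `members` (list column of sorted tip ids).
#' @export
classify_genome_groups <- function(tree, labels, purity_threshold = 0.90,
                                   min_size = 5L) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(labels)) {
    lab <- stats::setNames(labels$genome, labels$id)
  } else {
    lab <- labels
  }
  tips <- tree$tip.label
  all_sides <- list()
  parts <- ape::prop.part(tree)
  for (k in seq_along(parts)[-1]) {
    clade <- tips[parts[[k]]]
    all_sides <- c(all_sides, list(clade), list(setdiff(tips, clade)))
  }
  # single tips can also be sides of an edge
  for (tp in tips) all_sides <- c(all_sides, list(tp), list(setdiff(tips, tp)))
  all_sides <- unique(lapply(all_sides, function(x) sort(x, method = "radix")))

  cands <- purrr::map(all_sides, function(side) {
    if (length(side) < min_size) return(NULL)
    g <- lab[side]
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(NULL)
    tb <- sort(table(g), decreasing = TRUE)
    purity <- as.numeric(tb[1]) / length(g)
    if (purity < purity_threshold) return(NULL)
    tibble::tibble(genome = names(tb)[1], size = length(side), purity = purity,
                   members = list(side))
  })
  cands <- dplyr::bind_rows(cands)
  accepted <- list()
  if (nrow(cands) > 0L) {
    cands <- dplyr::arrange(cands, dplyr::desc(.data$size),
                            dplyr::desc(.data$purity), .data$genome)
    taken <- character(0)
    for (i in seq_len(nrow(cands))) {
      mem <- cands$members[[i]]
      if (length(intersect(mem, taken)) > 0L) next
      accepted <- c(accepted, list(cands[i, ]))
      taken <- c(taken, mem)
    }
  }
  out <- dplyr::bind_rows(accepted)
  if (nrow(out) > 0L) {
    out$group_label <- paste0(out$genome, "-specific")
    grouped <- unlist(out$members)
  } else {
    grouped <- character(0)
  }
  rest <- setdiff(tips, grouped)
  if (length(rest) > 0L) {
    g <- lab[rest]; g <- g[!is.na(g)]
    purity <- if (length(g) > 0) max(table(g)) / length(g) else NA_real_
    out <- dplyr::bind_rows(out, tibble::tibble(
      genome = NA_character_, size = length(rest), purity = purity,
      members = list(sort(rest, method = "radix")), group_label = "mixed"
    ))
  }
  out <- dplyr::select(out, "group_label", "genome", "size", "purity", "members")
  class(out) <- c("genome_groups", class(out))
  out
}

# run expr with a temporary RNG state seeded from `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
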