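# Shared helpers: random sequence generation and an exhaustive alignment
# oracle, independent of the package's DP implementation.

rand_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Enumerates every global alignment of a and b recursively, scoring affine gap
# runs (open + extend * (len-1)) incrementally, and returns the maximum score.
# Exponential: only for strings of length <= ~6.
brute_force_align_score <- function(a, b, match, mismatch, gap_open, gap_extend) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j, last) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[i] == cb[j]) match else -mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(ca)) {
      cost <- if (last == "x") gap_extend else gap_open
      best <- max(best, -cost + rec(i + 1, j, "x"))
    }
    if (j <= length(cb)) {
      cost <- if (last == "y") gap_extend else gap_open
      best <- max(best, -cost + rec(i, j + 1, "y"))
    }
    best
  }
  rec(1, 1, "m")
}

# Small caterpillar trees used by the grouping tests
caterpillar_newick <- function(tips) {
  out <- tips[1]
  for (t in tips[-1]) out <- sprintf("(%s,%s)", out, t)
  paste0(out, ";")
}
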