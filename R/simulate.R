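#' Simulation configuration for synthetic LTR retrotransposon families
#'
#' Bundles the knobs of the K80 forward simulator. The defaults emulate the
#' elements the dating method targets: 1.5-kb LTRs (the scale of solo LTRs in
#' wheat BAC annotation), a 6-kb internal region, the plant LTR
#' retrotransposon substitution rate 1.3e-8 per site per year, a
#' transition/transversion rate ratio kappa of 2, and uniform base
#' composition.
#'
#' @param ltr_len LTR length in bp (>= 80).
#' @param internal_len Internal-region length in bp.
#' @param rate Substitution rate per site per year.
#' @param kappa Transition/transversion rate ratio (alpha/beta).
#' @param base_freqs Numeric length-4 vector of A,C,G,T frequencies (sums to 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(ltr_len = 1500L, internal_len = 6000L,
                       rate = DEFAULT_RATE, kappa = 2,
                       base_freqs = c(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(ltr_len >= 80L, internal_len >= 0L, rate > 0, kappa > 0,
            length(base_freqs) == 4L, abs(sum(base_freqs) - 1) < 1e-9)
  structure(list(ltr_len = as.integer(ltr_len),
                 internal_len = as.integer(internal_len),
                 rate = rate, kappa = kappa, base_freqs = base_freqs),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

random_seq <- function(len, base_freqs = rep(0.25, 4)) {
  paste(sample(BASES, len, replace = TRUE, prob = base_freqs), collapse = "")
}

#' Evolve a sequence under the K80 substitution model
#'
#' Substitutes each site independently using the closed-form K80 transition
#' probabilities at total elapsed time `t_total`, with transition rate
#' `alpha` and transversion rate `beta` satisfying `alpha + 2 beta = rate`
#' and `alpha / beta = kappa`. No indels are introduced, so evolved copies of
#' one ancestor remain natively aligned. Uses the current RNG stream; seed at
#' a higher level for reproducibility.
#'
#' @param seq Nucleotide string over A,C,G,T.
#' @param t_total Elapsed time in years (>= 0).
#' @param rate Substitution rate per site per year.
#' @param kappa Transition/transversion rate ratio.
#' @return The mutated sequence string.
#' @export
evolve_copy <- function(seq, t_total, rate = DEFAULT_RATE, kappa = 2) {
  stopifnot(t_total >= 0, rate > 0, kappa > 0)
  if (t_total == 0) return(seq)
  beta <- rate / (kappa + 2)
  alpha <- kappa * beta
  t <- t_total
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1          # each of the two transversion targets
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  outcome <- sample.int(4L, length(ch), replace = TRUE,
                        prob = c(p_same, p_ts, p_tv, p_tv))
  # columns: same, transition, first transversion target, second
  subs <- rbind(A = c("A", "G", "C", "T"),
                C = c("C", "T", "A", "G"),
                G = c("G", "A", "C", "T"),
                T = c("T", "C", "A", "G"))
  mut <- ch
  known <- ch %in% BASES
  mut[known] <- subs[cbind(match(ch[known], BASES), outcome[known])]
  paste(mut, collapse = "")
}

#' Simulate one full-length (or truncated) element with known truth
#'
#' Draws an ancestral LTR forced to start `TG` and end `CA` plus a random
#' internal region, then emits `LTR5' + internal + LTR3'` where the two LTR
#' copies evolve independently for `T_years` under K80 — so their expected
#' divergence is `2 r T`, exactly what the dating estimator inverts. The
#' terminal `TG`/`CA` dinucleotides of each copy are held invariant, matching
#' their strict conservation in elements that survive intact. With
#' `truncated = TRUE` the 5' LTR is dropped, modelling "-1p" copies that the
#' dating method must refuse.
#'
#' @param id Element id.
#' @param T_years True time since insertion in years.
#' @param cfg A [sim_config()].
#' @param truncated Drop the 5' LTR?
#' @return A list with `seq` (single-row sequence tibble) and `truth` (a
#'   one-row tibble: id, coordinates, `T_years`, `truncated`).
#' @export
simulate_element <- function(id = "elem1", T_years = 1.6e6, cfg = sim_config(),
                             truncated = FALSE) {
  anc <- random_seq(cfg$ltr_len, cfg$base_freqs)
  substr(anc, 1L, 2L) <- "TG"
  substr(anc, cfg$ltr_len - 1L, cfg$ltr_len) <- "CA"
  internal <- random_seq(cfg$internal_len, cfg$base_freqs)
  # terminal TG/CA dinucleotides are required in cis for transposition and are
  # strictly conserved in surviving elements: hold them invariant
  fix_termini <- function(x) {
    substr(x, 1L, 2L) <- "TG"
    substr(x, cfg$ltr_len - 1L, cfg$ltr_len) <- "CA"
    x
  }
  ltr5 <- fix_termini(evolve_copy(anc, T_years, cfg$rate, cfg$kappa))
  ltr3 <- fix_termini(evolve_copy(anc, T_years, cfg$rate, cfg$kappa))
  if (truncated) {
    s <- paste0(internal, ltr3)
    truth <- tibble::tibble(
      id = id, start5 = NA_integer_, end5 = NA_integer_,
      start3 = cfg$internal_len + 1L,
      end3 = cfg$internal_len + cfg$ltr_len,
      T_years = T_years, truncated = TRUE
    )
  } else {
    s <- paste0(ltr5, internal, ltr3)
    truth <- tibble::tibble(
      id = id, start5 = 1L, end5 = cfg$ltr_len,
      start3 = cfg$ltr_len + cfg$internal_len + 1L,
      end3 = 2L * cfg$ltr_len + cfg$internal_len,
      T_years = T_years, truncated = FALSE
    )
  }
  list(seq = tibble::tibble(id = id, seq = s), truth = truth)
}

#' Simulate a batch of elements
#'
#' @param n Number of elements.
#' @param T_years True insertion time(s) in years, recycled over elements.
#' @param cfg A [sim_config()].
#' @param truncated Logical, recycled: which elements lack the 5' LTR.
#' @param seed Integer seed; the emitted sequences are byte-identical given it.
#' @param prefix Id prefix.
#' @return A list with `seqs` (sequence tibble) and `truth` (tibble).
#' @export
simulate_elements <- function(n, T_years = 1.6e6, cfg = sim_config(),
                              truncated = FALSE, seed = NULL,
                              prefix = "elem") {
  T_years <- rep_len(T_years, n)
  truncated <- rep_len(truncated, n)
  run <- function() {
    res <- purrr::map(seq_len(n), function(i) {
      simulate_element(sprintf("%s%03d", prefix, i), T_years[i], cfg,
                       truncated[i])
    })
    list(seqs = dplyr::bind_rows(purrr::map(res, "seq")),
         truth = dplyr::bind_rows(purrr::map(res, "truth")))
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Simulate an aligned domain family with planted genome groups
#'
#' Evolves a shared ancestral domain sequence down a two-level tree: each
#' group's ancestor diverges from the family ancestor for `stem_time` years,
#' then every member diverges from its group ancestor for `crown_time` years,
#' all under K80 with no indels — so the emitted family is natively aligned.
#' Per-member genome labels come from the group's `genome` entry (a vector is
#' recycled across members, giving mixed groups), and per-member insertion
#' times are drawn uniformly from `time_range`.
#'
#' @param groups A tibble/data.frame with columns `group_id`, `genome`
#'   (character or list column of label vectors), `n_members`, `stem_time`,
#'   `crown_time` (years). At least 2 groups of >= 2 members.
#' @param domain_len Length of the simulated domain alignment (bp).
#' @param cfg A [sim_config()] (rate, kappa, base composition are used).
#' @param time_range Range (years) for the uniform per-member insertion times
#'   recorded in the truth table.
#' @param seed Integer seed.
#' @return A list with `aln` (a `retro_alignment`), `labels` (tibble id,
#'   genome) and `truth` (tibble id, group_id, genome, T_years).
#' @export
simulate_family <- function(groups, domain_len = 600L, cfg = sim_config(),
                            time_range = c(0.5e6, 2.5e6), seed = NULL) {
  stopifnot(is.data.frame(groups),
            all(c("group_id", "genome", "n_members", "stem_time", "crown_time")
                %in% names(groups)),
            nrow(groups) >= 2L, all(groups$n_members >= 2L))
  run <- function() {
    anc <- random_seq(domain_len, cfg$base_freqs)
    rows <- purrr::map(seq_len(nrow(groups)), function(g) {
      gr <- groups[g, ]
      ganc <- evolve_copy(anc, gr$stem_time, cfg$rate, cfg$kappa)
      genomes <- rep_len(unlist(gr$genome), gr$n_members)
      purrr::map(seq_len(gr$n_members), function(i) {
        tibble::tibble(
          id = sprintf("%s_%02d", gr$group_id, i),
          seq = evolve_copy(ganc, gr$crown_time, cfg$rate, cfg$kappa),
          group_id = gr$group_id,
          genome = genomes[i],
          T_years = stats::runif(1, time_range[1], time_range[2])
        )
      })
    })
    tbl <- dplyr::bind_rows(purrr::flatten(rows))
    list(
      aln = new_alignment(tibble::tibble(id = tbl$id, seq = tbl$seq)),
      labels = tibble::tibble(id = tbl$id, genome = tbl$genome),
      truth = dplyr::select(tbl, "id", "group_id", "genome", "T_years")
    )
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}
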