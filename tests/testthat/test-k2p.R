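pair <- function(a, b) structure(list(gapped_a = a, gapped_b = b),
                                 class = "aligned_pair")

test_that("site patterns classify transitions/transversions under complete deletion", {
  c1 <- count_site_patterns(pair("ACGT", "ACGT"))
  expect_equal(unlist(c1), c(n = 4, P = 0, Q = 0))

  c2 <- count_site_patterns(pair("AG-T", "AGCT"))
  expect_equal(c2$n, 3)  # gap column dropped
  expect_equal(c2$P + c2$Q, 0)

  c3 <- count_site_patterns(pair("AANA", "AAAA"))
  expect_equal(c3$n, 3)  # N column dropped like a gap

  # A->G is a transition, A->C a transversion
  expect_equal(count_site_patterns(pair("AAAA", "GAAA"))$P, 0.25)
  expect_equal(count_site_patterns(pair("AAAA", "GAAA"))$Q, 0)
  expect_equal(count_site_patterns(pair("AAAA", "CAAA"))$P, 0)
  expect_equal(count_site_patterns(pair("AAAA", "CAAA"))$Q, 0.25)
  # C<->T transition, purine<->pyrimidine transversion
  expect_equal(count_site_patterns(pair("CCCC", "TCCC"))$P, 0.25)
  expect_equal(count_site_patterns(pair("GGGG", "TGGG"))$Q, 0.25)

  expect_error(count_site_patterns(pair("--", "AA")), "no comparable sites")
})

test_that("K2P distance and standard error match the closed forms", {
  r0 <- k2p_distance(list(n = 100, P = 0, Q = 0))
  expect_equal(r0$D, 0)
  expect_equal(r0$SE, 0)

  r1 <- k2p_distance(list(n = 100, P = 0.1, Q = 0.05))
  expect_equal(r1$D, 0.170181, tolerance = 1e-5)
  expect_equal(r1$SE, 0.046331, tolerance = 1e-4)

  r2 <- k2p_distance(list(n = 1000, P = 0.3, Q = 0.25))
  expect_equal(r2$D, 1.121845, tolerance = 1e-5)

  expect_error(k2p_distance(list(n = 100, P = 0.4, Q = 0.2)), "saturated")
  expect_error(k2p_distance(list(n = 100, P = 0.1, Q = 0.5)), "saturated")
  expect_error(k2p_distance(list(n = 0, P = 0, Q = 0)), "no comparable sites")
})

test_that("K2P distance is monotone in P and Q and linear near zero", {
  grid <- seq(0, 0.15, by = 0.01)
  for (Q in c(0, 0.05, 0.1)) {
    D <- vapply(grid, function(P) k2p_distance(list(n = 100, P = P, Q = Q))$D, numeric(1))
    expect_true(all(diff(D) >= 0))
  }
  for (P in c(0, 0.05, 0.1)) {
    D <- vapply(grid, function(Q) k2p_distance(list(n = 100, P = P, Q = Q))$D, numeric(1))
    expect_true(all(diff(D) >= 0))
  }
  for (P in c(0, 0.002, 0.005)) {
    for (Q in c(0, 0.002, 0.005)) {
      if (P + Q > 0.01) next
      D <- k2p_distance(list(n = 1e6, P = P, Q = Q))$D
      expect_lt(abs(D - (P + Q)), 1e-3)
    }
  }
})

test_that("divergence converts to years as T = D / (2 r)", {
  expect_equal(date_insertion(list(D = 0, SE = 0))$T_years, 0)
  d <- date_insertion(list(D = 0.0416, SE = 0.0052), rate = 1.3e-8)
  expect_equal(d$T_years, 1.6e6)
  expect_equal(d$T_se_years, 0.2e6)
  expect_equal(date_insertion(list(D = 0.026, SE = 0), rate = 1.3e-8)$T_mya, 1.0)
  expect_error(date_insertion(list(D = 0.1, SE = 0), rate = 0), "positive")
})

test_that("date_element composes extraction, alignment, counting and dating", {
  set.seed(408)
  cfg <- sim_config(ltr_len = 300, internal_len = 500)
  e0 <- simulate_element("young", T_years = 0, cfg = cfg)
  d0 <- date_element(e0$seq, e0$truth)
  expect_equal(d0$T_years, 0)
  expect_equal(d0$n, 300)

  e1 <- simulate_element("mid", T_years = 1.6e6, cfg = sim_config())
  d1 <- date_element(e1$seq, e1$truth)
  expect_lt(abs(d1$T_years - 1.6e6), 3 * d1$T_se_years)

  etr <- simulate_element("trunc", T_years = 1e6, cfg = cfg, truncated = TRUE)
  expect_error(date_element(etr$seq, etr$truth), "not datable")
})

test_that("batch dating flags undatable elements instead of failing", {
  set.seed(409)
  cfg <- sim_config(ltr_len = 200, internal_len = 300)
  sims <- simulate_elements(3, T_years = 1e6, cfg = cfg,
                            truncated = c(FALSE, TRUE, FALSE))
  det <- detect_ltrs(sims$seqs, min_len = 80)
  res <- date_elements(sims$seqs, det)
  expect_equal(nrow(res), 3)
  expect_equal(sum(res$status == "dated"), 2)
  expect_true(all(is.na(res$T_years[res$status != "dated"])))
})
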