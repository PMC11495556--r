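# Frozen oracle values for the toy table (10, 90, 100, 9900), computed by
# direct evaluation of the printed formulas before the implementation:
#   ROR = 11, CI (5.559515, 21.76449); PRR = 10, chi2 = 74.44717;
#   EBGM = 9.181818, EBGM05 = 4.640587; IC = log2(9.181818) = 3.198780;
#   IC025 (Bate moment approximation, all hyperparameters 1) = 2.243709.

test_that("the four algorithms reproduce the frozen toy-table oracle", {
  ct <- contingency_table(10, 90, 100, 9900, term = "toy")
  s <- signal_stats(ct)
  expect_equal(s$ror, 11, tolerance = 1e-12)
  expect_equal(s$ror_lo, 5.559515, tolerance = 1e-6)
  expect_equal(s$ror_hi, 21.76449, tolerance = 1e-6)
  expect_equal(s$prr, 10, tolerance = 1e-12)
  expect_equal(s$chi2, 74.44717, tolerance = 1e-6)
  expect_equal(s$ebgm, 9.181818, tolerance = 1e-6)
  expect_equal(s$ebgm05, 4.640587, tolerance = 1e-6)
  expect_equal(s$ic, log2(9.1818181818), tolerance = 1e-9)
  expect_equal(s$ic025, 2.243709, tolerance = 1e-6)

  crit <- evaluate_criteria(s, a = 10)
  expect_true(crit$pass_ror)
  expect_true(crit$pass_prr)
  expect_true(crit$pass_mgps)
  expect_true(crit$pass_bcpnn)
  expect_true(crit$significant)
})

test_that("IC025 closed form tracks a Monte-Carlo Dirichlet posterior oracle", {
  # Posterior of the simplified IC under a flat Dirichlet prior (all
  # hyperparameters 1); the moment approximation is known to be mildly
  # conservative for small a, so the band is 0.3 bits.
  set.seed(42)
  M <- 2e5
  g1 <- rgamma(M, 11); g2 <- rgamma(M, 91)
  g3 <- rgamma(M, 101); g4 <- rgamma(M, 9901)
  s <- g1 + g2 + g3 + g4
  p11 <- g1 / s; p1. <- (g1 + g2) / s; p.1 <- (g1 + g3) / s
  mc_q <- unname(quantile(log2(p11 / (p1. * p.1)), 0.025))
  closed <- bcpnn_stats(10, 90, 100, 9900)$ic025
  expect_lt(abs(closed - mc_q), 0.3)
  expect_lt(closed, mc_q + 0.02)  # conservative: below the exact quantile
})

test_that("symmetric and independence tables behave as expected", {
  s <- signal_stats(contingency_table(5, 5, 5, 5))
  expect_equal(s$ror, 1)
  expect_true(s$ror_lo < 1 && s$ror_hi > 1)
  # exact independence: ad = bc
  s2 <- signal_stats(contingency_table(5, 10, 15, 30))
  expect_equal(s2$chi2, 0)
  expect_equal(s2$ic, 0)
  expect_equal(s2$ebgm, 1)
  expect_false(evaluate_criteria(s2, 5)$significant)
})

test_that("N >= 3 rule blocks small counts regardless of strength", {
  s <- signal_stats(contingency_table(2, 1, 1, 100000))
  crit <- evaluate_criteria(s, a = 2)
  expect_false(crit$pass_ror)
  expect_false(crit$pass_prr)
})

test_that("zero-cell policy: undefined flags rows, haldane smooths them", {
  s <- signal_stats(contingency_table(3, 0, 5, 100), zero_cell = "undefined")
  expect_true(all(is.na(s)))
  expect_false(evaluate_criteria(s, 3)$significant)
  sh <- signal_stats(contingency_table(3, 0, 5, 100), zero_cell = "haldane")
  expect_false(any(is.na(sh)))
  expect_equal(sh$ror, (3.5 * 100.5) / (0.5 * 5.5))
  # a = 0 is never computable under either policy
  for (mode in c("undefined", "haldane")) {
    s0 <- signal_stats(contingency_table(0, 10, 5, 100), zero_cell = mode)
    expect_true(all(is.na(s0)), label = mode)
  }
})

test_that("build_contingency matches the hand enumeration in both units", {
  ac <- fixture_acases_contingency()
  ctr <- build_contingency(ac, "P1", level = "PT", unit = "report")
  expect_equal(c(ctr$a, ctr$b, ctr$c, ctr$d), c(2, 0, 1, 2))
  ctp <- build_contingency(ac, "P1", level = "PT", unit = "drug_event_pair")
  expect_equal(c(ctp$a, ctp$b, ctp$c, ctp$d), c(2, 1, 1, 2))
  expect_equal(ctp$N, 6)
  # absent term: a = 0 with intact margins
  ct0 <- build_contingency(ac, "P9", level = "PT", unit = "report")
  expect_equal(ct0$a, 0)
  expect_equal(ct0$b, 2)
  # SOC level: R1 contributes once to S1 though P1 and P2 both map there
  cts <- build_contingency(ac, "S1", level = "SOC", unit = "report")
  expect_equal(c(cts$a, cts$b, cts$c, cts$d), c(2, 0, 2, 1))
})

test_that("screen_signals rows, exclusions and pair-count conservation", {
  ac <- fixture_acases_contingency()
  sig <- screen_signals(ac, level = "PT", unit = "drug_event_pair")
  expect_setequal(sig$term, c("P1", "P2", "P3"))
  # conservation: sum of a over PT rows equals total target (report, PT) pairs
  expect_equal(sum(sig$a), 3)
  # per-term cells agree with build_contingency
  r1 <- sig[sig$term == "P1", ]
  expect_equal(c(r1$a, r1$b, r1$c, r1$d), c(2, 1, 1, 2))
  # excluding P2's SOC (S1) removes P1 and P2 but keeps P3
  sig_ex <- screen_signals(ac, level = "PT", unit = "drug_event_pair",
                           exclusions = "S1")
  expect_equal(sig_ex$term, "P3")
  # excluding by PT name works too
  sig_ex2 <- screen_signals(ac, level = "PT", exclusions = "P2")
  expect_setequal(sig_ex2$term, c("P1", "P3"))
})

test_that("vectorised screen equals the scalar brute-force oracle", {
  set.seed(202)
  n <- 1000
  a <- sample(1:10000, n, TRUE); b <- sample(1:10000, n, TRUE)
  c_ <- sample(1:10000, n, TRUE); d <- sample(1:10000, n, TRUE)
  stats <- cbind(ror_stats(a, b, c_, d), prr_stats(a, b, c_, d),
                 bcpnn_stats(a, b, c_, d), ebgm_stats(a, b, c_, d))
  crit <- evaluate_criteria(stats, a)
  for (i in sample(n, 200)) {
    o <- oracle_stats_scalar(a[i], b[i], c_[i], d[i])
    for (nm in c("ror", "ror_lo", "ror_hi", "prr", "chi2", "ic", "ic025",
                 "ebgm", "ebgm05")) {
      expect_equal(stats[[nm]][i], o[[nm]], tolerance = 1e-9,
                   label = sprintf("%s at row %d", nm, i))
    }
    expect_equal(crit$pass_ror[i], o$pass_ror)
    expect_equal(crit$pass_prr[i], o$pass_prr)
    expect_equal(crit$pass_bcpnn[i], o$pass_bcpnn)
    expect_equal(crit$pass_mgps[i], o$pass_mgps)
  }
})

test_that("structural identities hold on random tables", {
  set.seed(77)
  n <- 500
  a <- sample(1:5000, n, TRUE); b <- sample(1:5000, n, TRUE)
  c_ <- sample(1:5000, n, TRUE); d <- sample(1:5000, n, TRUE)
  ror <- ror_stats(a, b, c_, d)
  prr <- prr_stats(a, b, c_, d)
  bc <- bcpnn_stats(a, b, c_, d)
  eb <- ebgm_stats(a, b, c_, d)
  # IC == log2(EBGM) always
  expect_equal(bc$ic, log2(eb$ebgm), tolerance = 1e-12)
  # ROR > PRR  <=>  ad > bc (strict, off the independence manifold)
  off <- a * d != b * c_
  expect_equal((ror$ror > prr$prr)[off], (a * d > b * c_)[off])
  # point estimates are geometric means of their own CI bounds
  expect_equal(sqrt(ror$ror_lo * ror$ror_hi), ror$ror, tolerance = 1e-12)
  # monotonicity in a (b, c, d fixed): exact for ROR and PRR on any table
  r2 <- ror_stats(a + 1, b, c_, d); p2 <- prr_stats(a + 1, b, c_, d)
  expect_true(all(r2$ror > ror$ror))
  expect_true(all(p2$prr > prr$prr))
  # For the observed/expected ratio (EBGM, hence IC) monotonicity in a only
  # holds when a is small against the comparator margins (d(log ebgm)/da =
  # 1/a + 1/N - 1/(a+b) - 1/(a+c) can turn negative when d dwarfs b) -- the
  # regime every real spontaneous-report table lives in, so the property is
  # asserted there.
  aa <- sample(1:100, n, TRUE); bb <- aa + sample(1:2000, n, TRUE)
  cc <- aa + sample(1:2000, n, TRUE); dd <- 10 * (bb + cc) +
    sample(1:100000, n, TRUE)
  e1 <- ebgm_stats(aa, bb, cc, dd); e2 <- ebgm_stats(aa + 1, bb, cc, dd)
  b1 <- bcpnn_stats(aa, bb, cc, dd); b2 <- bcpnn_stats(aa + 1, bb, cc, dd)
  expect_true(all(e2$ebgm > e1$ebgm))
  expect_true(all(b2$ic > b1$ic))
})

test_that("flag_unexpected combines significance and the label list", {
  sig <- data.frame(term = c("Pollakiuria", "Hot flush", "Nausea"),
                    significant = c(TRUE, TRUE, FALSE))
  out <- flag_unexpected(sig, label_pts = c("HOT FLUSH", "Fatigue"))
  expect_equal(out$unexpected, c(TRUE, FALSE, FALSE))
  out2 <- flag_unexpected(sig, label_pts = NULL)
  expect_true(all(is.na(out2$unexpected)))
})
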