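test_that("euclidean_delta closed forms and homogeneity", {
  expect_equal(euclidean_delta(rep(1.3, 45), rep(1.3, 45)), 0)
  expect_equal(euclidean_delta(rep(0, 45), c(3, 4, rep(0, 43))), 5)
  set.seed(1)
  a <- rnorm(45); b <- rnorm(45)
  expect_equal(euclidean_delta(2.7 * a, 2.7 * b),
               2.7 * euclidean_delta(a, b), tolerance = 1e-12)
  expect_error(euclidean_delta(rnorm(10), rnorm(25)), "mismatch")
})

test_that("degenerate all-identical groups give p = 1", {
  M <- matrix(0.5, 6, 45)
  pt <- delta_pattern_test(patterns_from_matrix(M[1:4, ], prefix = "A"),
                           patterns_from_matrix(M[5:6, ], prefix = "B"),
                           B = 100, seed = 1)
  expect_equal(pt$observed_delta, 0)
  expect_true(all(pt$null_distribution == 0))
  expect_equal(pt$p_value, 1)
})

test_that("a subject in both groups is rejected", {
  g <- draw_patterns(3, seed = 2, prefix = "X")
  expect_error(delta_pattern_test(g, g[2], B = 10), "X02")
})

test_that("Monte-Carlo p matches exhaustive enumeration (3 vs 2)", {
  set.seed(3)
  A <- matrix(rnorm(3 * 45, sd = 0.5), 3, 45)
  B <- matrix(rnorm(2 * 45, sd = 0.5), 2, 45)
  ex <- exhaustive_delta_p(A, B)
  pt <- delta_pattern_test(A, B, B = 4000, seed = 4)
  expect_equal(pt$observed_delta, ex$observed, tolerance = 1e-12)
  tol <- 3 * sqrt(ex$p * (1 - ex$p) / 4000) + 1e-12
  expect_lt(abs(pt$p_value - ex$p), max(tol, 0.02))
})

test_that("permutation results are seed-deterministic", {
  gA <- draw_patterns(5, seed = 5, prefix = "A")
  gB <- draw_patterns(4, seed = 6, prefix = "B")
  p1 <- delta_pattern_test(gA, gB, B = 300, seed = 9)
  p2 <- delta_pattern_test(gA, gB, B = 300, seed = 9)
  expect_identical(p1$null_distribution, p2$null_distribution)
  expect_identical(p1$p_value, p2$p_value)
  e1 <- equivalence_test(gA, gB, B = 200, seed = 9,
                         delta_grid = seq(0.1, 2, 0.1))
  e2 <- equivalence_test(gA, gB, B = 200, seed = 9,
                         delta_grid = seq(0.1, 2, 0.1))
  expect_identical(e1$delta_star_rejectable, e2$delta_star_rejectable)
  expect_identical(e1$quantiles, e2$quantiles)
})

test_that("zero within-group variance makes every positive norm rejectable", {
  A <- matrix(0.4, 4, 45); B <- matrix(0.4, 3, 45)
  eq <- equivalence_test(patterns_from_matrix(A, prefix = "A"),
                         patterns_from_matrix(B, prefix = "B"),
                         B = 100, delta_grid = seq(0.05, 1, 0.05), seed = 1)
  expect_true(eq$determinable)
  expect_equal(eq$observed_delta, 0)
  expect_true(all(eq$rejected))
  expect_equal(eq$delta_star_rejectable, 0.05)
})

test_that("no rejectable grid value is flagged, not invented", {
  # huge within-group spread, tiny grid: nothing should be rejectable
  set.seed(7)
  A <- matrix(rnorm(4 * 45, sd = 3), 4, 45)
  B <- matrix(rnorm(3 * 45, sd = 3), 3, 45)
  eq <- equivalence_test(A, B, B = 200, delta_grid = c(0.01, 0.02), seed = 2)
  expect_false(eq$determinable)
  expect_true(is.na(eq$delta_star_rejectable))
  expect_true(is.na(eq$cohens_d_equivalent))
})

test_that("shrinking subject noise shrinks the equivalence bound", {
  stars <- sapply(1:6, function(s) {
    hi <- equivalence_test(draw_patterns(8, sd = 0.6, seed = s, prefix = "A"),
                           draw_patterns(6, sd = 0.6, seed = s + 50,
                                         prefix = "B"),
                           B = 300, seed = s, n_d_draws = 10)
    lo <- equivalence_test(draw_patterns(8, sd = 0.15, seed = s,
                                         prefix = "A"),
                           draw_patterns(6, sd = 0.15, seed = s + 50,
                                         prefix = "B"),
                           B = 300, seed = s, n_d_draws = 10)
    c(hi = hi$delta_star_rejectable, lo = lo$delta_star_rejectable)
  })
  expect_gt(mean(stars["hi", ] - stars["lo", ]), 0)
})

test_that("cohens_d_from_delta: zero, linearity, zero-SD guard", {
  gA <- draw_patterns(5, seed = 8, prefix = "A")
  gB <- draw_patterns(4, seed = 9, prefix = "B")
  expect_equal(cohens_d_from_delta(0, gA, gB), 0)
  d1 <- cohens_d_from_delta(0.7, gA, gB, n_draws = 200, seed = 3)
  d2 <- cohens_d_from_delta(1.4, gA, gB, n_draws = 200, seed = 3)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  Z <- matrix(0.2, 3, 45); Z2 <- matrix(0.2, 3, 45)
  expect_error(cohens_d_from_delta(1, Z, Z2), "S1_ipsi|M1_ipsi",
               fixed = TRUE)
  # heuristic and expectation agree for unit SDs
  set.seed(10)
  U1 <- matrix(rnorm(40 * 45), 40, 45)
  U2 <- matrix(rnorm(40 * 45), 40, 45)
  s <- sqrt(((39) * apply(U1, 2, var) + 39 * apply(U2, 2, var)) / 78)
  d_exp <- cohens_d_from_delta(1, U1, U2, n_draws = 3000, seed = 4)
  d_heu <- cohens_d_from_delta(1, U1, U2, method = "heuristic")
  expect_equal(d_exp, d_heu, tolerance = 0.05)
})

test_that("variability test: degenerate groups, antisymmetry, guards", {
  A <- matrix(0.3, 4, 45)
  set.seed(11)
  B <- matrix(rnorm(4 * 45), 4, 45)
  vt <- variability_test(A, B, B = 100, seed = 1)
  expect_equal(vt$group_variability_A, 0)
  expect_gt(vt$group_variability_B, 0)
  vt_swap <- variability_test(B, A, B = 100, seed = 1)
  expect_equal(vt_swap$delta_variability, -vt$delta_variability)
  expect_error(variability_test(A[1, , drop = FALSE], B, B = 10), "size")
})

test_that("larger patient spread is detected as positive delta_variability", {
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    P <- matrix(rnorm(15 * 45, sd = 0.8), 15, 45)
    C <- matrix(rnorm(15 * 45, sd = 0.4), 15, 45)
    vt <- variability_test(P, C, B = 200, seed = s)
    c(pos = vt$delta_variability > 0, sig = vt$p_value < 0.05)
  })
  expect_true(all(hits["pos", ]))
  expect_gt(mean(hits["sig", ]), 0.8)
})

test_that("longitudinal deltas: identity, step change, pairing", {
  base <- draw_patterns(10, sd = 0.3, group = "patient", week = "W1",
                        seed = 12, prefix = "P")
  same <- lapply(base, function(p) {
    q <- p; q$week <- "W4"; q
  })
  res <- longitudinal_deltas(c(base, same), reference_week = "W1", B = 200,
                             seed = 1)
  expect_equal(res$W4$observed_delta, 0)
  expect_equal(res$W4$p_value, 1)

  step <- 3 * inject_direction(45, seed = 13)
  moved <- lapply(base, function(p) {
    q <- conn_pattern(p$weights + step, subject_id = p$subject_id,
                      group = p$group, week = "W12")
    q
  })
  res2 <- longitudinal_deltas(c(base, same, moved), reference_week = "W1",
                              B = 400, seed = 2)
  # paired sign-flip null: only the all-flip/no-flip states reach a norm-3
  # step, so p approaches 2 / 2^n (here 10 subjects)
  expect_lt(res2$W12$p_value, res2$W4$p_value)
  expect_lte(res2$W12$p_value, 0.02)

  other <- draw_patterns(3, group = "patient", week = "W24", seed = 14,
                         prefix = "Q")
  expect_error(longitudinal_deltas(c(base, other), reference_week = "W1",
                                   B = 10), "both W1 and W24")
})

test_that("week ANOVA surface: degenerate F, df, null uniformity", {
  x <- matrix(rep(c(1, 2, 3, 4, 5), each = 4), 5, 4, byrow = TRUE)
  an0 <- week_variability_anova(x)   # constant across weeks per subject
  expect_equal(an0$F, 0)
  an <- week_variability_anova(matrix(rnorm(40), 10, 4))
  expect_equal(c(an$df1, an$df2), c(3L, 36L))  # one-way: (k-1, N-k)
  expect_error(week_variability_anova(matrix(c(1, NA, 2, 3), 2, 2)),
               "complete")
  # distribution of p under a Gaussian null is uniform
  set.seed(15)
  ps <- replicate(4000, week_variability_anova(matrix(rnorm(40), 10, 4))$p_value)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("null distance estimate is positively biased, shrinking with n", {
  mean_obs <- function(n) {
    mean(sapply(1:40, function(s) {
      set.seed(s)
      A <- matrix(rnorm(n * 45, sd = 0.4), n, 45)
      B <- matrix(rnorm(n * 45, sd = 0.4), n, 45)
      euclidean_delta(colMeans(A), colMeans(B))
    }))
  }
  m_small <- mean_obs(5); m_big <- mean_obs(20)
  expect_gt(m_small, 0)
  expect_gt(m_small, m_big)  # bias decreases with group size
})
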