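# shared fixtures, built in code

# a small, fast cohort configuration; override any field via ...
tiny_config <- function(...) {
  args <- list(n_patients = 4, n_controls = 3, sessions = "W1",
               n_volumes = 60, missing_rate = 0, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

# conn_pattern list from an n x 45 weight matrix
patterns_from_matrix <- function(M, group = "control", week = "W1",
                                 prefix = "S") {
  lapply(seq_len(nrow(M)), function(i) {
    conn_pattern(M[i, ], subject_id = sprintf("%s%02d", prefix, i),
                 group = group, week = week,
                 lesion_side = if (group == "patient") "left" else "none")
  })
}

# draw n patterns as ground truth + iid N(0, sd) perturbation
draw_patterns <- function(n, sd = 0.4, group = "control", week = "W1",
                          offset = 0, seed = 1, prefix = "S") {
  set.seed(seed)
  gt <- default_ground_truth()
  M <- t(replicate(n, gt + offset + rnorm(45, sd = sd)))
  patterns_from_matrix(M, group = group, week = week, prefix = prefix)
}

# patterns of the W1 patients and controls of a generated cohort
cohort_patterns <- function(cohort, group, week = NULL) {
  keep <- vapply(cohort, function(ts) {
    ts$group == group && (is.null(week) || ts$week == week)
  }, logical(1))
  lapply(cohort[keep], compute_pattern)
}

# K exchangeable columns with exactly equal pairwise correlation rho:
# x_j = a*h + b*e_j with h, e_1..e_K orthonormal and centered
exchangeable_voxels <- function(K, rho, T_len = K + 6, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(T_len * (K + 1)), T_len))))
  h <- Q[, 2]
  E <- Q[, 3:(K + 2)]
  a <- sqrt(rho); b <- sqrt(1 - rho)
  a * matrix(h, T_len, K) + b * E
}

# exhaustive permutation p-value for the group-distance test
exhaustive_delta_p <- function(A, B) {
  X <- rbind(A, B)
  nA <- nrow(A)
  observed <- sqrt(sum((colMeans(A) - colMeans(B))^2))
  picks <- utils::combn(nrow(X), nA)
  nulls <- apply(picks, 2, function(idx) {
    sqrt(sum((colMeans(X[idx, , drop = FALSE]) -
                colMeans(X[-idx, , drop = FALSE]))^2))
  })
  list(observed = observed, p = mean(nulls >= observed), nulls = nulls)
}
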