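#' Euclidean distance between two pattern vectors
#'
#' @param meanA,meanB Numeric vectors of equal length (or [conn_pattern()]s).
#' @return Nonnegative L2 norm of the difference.
#' @export
#' @examples
#' euclidean_delta(rep(0, 45), c(3, 4, rep(0, 43)))  # 5
euclidean_delta <- function(meanA, meanB) {
  a <- as_weights(meanA); b <- as_weights(meanB)
  if (length(a) != length(b)) {
    stop("pattern length mismatch: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  sqrt(sum((a - b)^2))
}

perm_test_result <- function(observed_delta, null_distribution, n_shuffles,
                             subset, comparison_label, nA, nB, seed) {
  structure(list(observed_delta = observed_delta,
                 null_distribution = null_distribution,
                 p_value = mean(null_distribution >= observed_delta),
                 n_shuffles = n_shuffles, subset = subset,
                 comparison_label = comparison_label,
                 n_groupA = nA, n_groupB = nB, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> ", x$comparison_label, " [", x$subset, "]\n",
      "  observed delta = ", signif(x$observed_delta, 4),
      ", p = ", signif(x$p_value, 4), " (", x$n_shuffles, " shuffles, n = ",
      x$n_groupA, " vs ", x$n_groupB, ")\n", sep = "")
  invisible(x)
}

# shared label-shuffle machinery: X is the pooled n x K matrix, nA the size
# of pseudo-group A; returns B mean-difference vectors (B x K)
shuffled_mean_diffs <- function(X, nA, B) {
  n <- nrow(X); nB <- n - nA
  tot <- colSums(X)
  G <- matrix(0, B, ncol(X))
  for (b in seq_len(B)) {
    idx <- sample.int(n, nA)
    sa <- colSums(X[idx, , drop = FALSE])
    G[b, ] <- sa / nA - (tot - sa) / nB
  }
  G
}

#' Permutation test on the Euclidean distance between group mean patterns
#'
#' The observed statistic is the Euclidean distance between the two group
#' mean patterns. Group labels are shuffled `B` times preserving group
#' sizes; the p-value is the proportion of null distances greater than or
#' equal to the observed one (ties count as extreme, so the degenerate
#' all-identical case gives p = 1 and the test is never anti-conservative).
#' Note the distance estimate is systematically positively biased under the
#' null; the permutation reference accounts for this.
#'
#' @param groupA,groupB Lists of [conn_pattern()] (conventionally patients
#'   and controls), or numeric weight matrices with one row per subject.
#' @param subset Pattern subset to test (`"full"`, `"interhemispheric"`,
#'   `"intra_ipsilesional"`, `"intra_contralesional"`).
#' @param B Number of shuffles (default 10000).
#' @param seed RNG seed.
#' @param comparison_label Free-text label stored in the result.
#' @return A `perm_test` object (observed delta, null distribution,
#'   p-value, shuffle count).
#' @export
delta_pattern_test <- function(groupA, groupB, subset = "full", B = 10000,
                               seed = 1,
                               comparison_label = "groupA vs groupB") {
  subset <- match.arg(subset, subset_choices())
  stopifnot_scalar_number(B, "B", min = 1)
  idsA <- pattern_ids(groupA); idsB <- pattern_ids(groupB)
  both <- intersect(idsA, idsB)
  if (length(both) > 0L) {
    stop("subject(s) in both groups: ", paste(both, collapse = ", "),
         call. = FALSE)
  }
  A <- pattern_matrix(groupA, subset); Bm <- pattern_matrix(groupB, subset)
  if (nrow(A) == 0L || nrow(Bm) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  observed <- euclidean_delta(colMeans(A), colMeans(Bm))
  X <- rbind(A, Bm)
  nulls <- with_seed(seed, {
    G <- shuffled_mean_diffs(X, nrow(A), B)
    sqrt(rowSums(G^2))
  })
  perm_test_result(observed, nulls, B, subset, comparison_label,
                   nrow(A), nrow(Bm), seed)
}

# subject ids of a pattern collection (empty for bare matrices)
pattern_ids <- function(x) {
  if (is.matrix(x)) return(character(0))
  if (inherits(x, "conn_pattern")) x <- list(x)
  vapply(x, function(p) p$subject_id, character(1))
}

#' Permutation-based equivalence test with injected ground-truth patterns
#'
#' Bounds the effect size still compatible with an observed (non-significant)
#' group distance. Per-subject deviations from their own group mean are
#' pooled; for each of `B` simulations the labels are shuffled and a random
#' Gaussian pattern scaled to Euclidean norm Delta* is added to every
#' pseudo-member of group A, giving the sampling distribution of the
#' distance under a true difference of size Delta*. A candidate Delta* is
#' rejected (at level `alpha`) when the observed distance falls at or below
#' the alpha-quantile of that distribution. The reported bound is the
#' smallest grid value from which every larger value is rejected (the same
#' shuffles and directions are reused across the grid, which makes the
#' rejection boundary monotone). Its average univariate Cohen's d is
#' attached via [cohens_d_from_delta()].
#'
#' @param groupA,groupB Pattern collections (group A receives the injection).
#' @param observed_delta Observed distance; computed from the groups when
#'   `NULL`.
#' @param B Simulations per grid value (default 10000).
#' @param alpha Level of the equivalence test (default 0.05).
#' @param delta_grid Strictly increasing nonnegative candidate norms.
#' @param seed RNG seed.
#' @param subset Pattern subset.
#' @param redraw_direction Draw a fresh injected direction per simulation
#'   (default); `FALSE` fixes a single direction for all simulations.
#' @param d_method,n_d_draws Passed to [cohens_d_from_delta()].
#' @return An `equiv_test` object with `delta_star_rejectable` (NA, flagged
#'   `determinable = FALSE`, when no grid value is rejected),
#'   `cohens_d_equivalent`, the grid and its rejection indicator.
#' @export
equivalence_test <- function(groupA, groupB, observed_delta = NULL,
                             B = 10000, alpha = 0.05,
                             delta_grid = seq(0.05, 3, by = 0.05),
                             seed = 1, subset = "full",
                             redraw_direction = TRUE,
                             d_method = c("expected", "single", "heuristic"),
                             n_d_draws = 1000) {
  subset <- match.arg(subset, subset_choices())
  d_method <- match.arg(d_method)
  stopifnot(length(delta_grid) >= 1, all(delta_grid >= 0),
            !is.unsorted(delta_grid, strictly = TRUE))
  A <- pattern_matrix(groupA, subset); Bm <- pattern_matrix(groupB, subset)
  if (nrow(A) == 0L || nrow(Bm) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (is.null(observed_delta)) {
    observed_delta <- euclidean_delta(colMeans(A), colMeans(Bm))
  }
  k <- ncol(A)
  # deviations from own group mean, pooled
  D <- rbind(sweep(A, 2, colMeans(A)), sweep(Bm, 2, colMeans(Bm)))
  sims <- with_seed(seed, {
    G <- shuffled_mean_diffs(D, nrow(A), B)
    U <- if (redraw_direction) {
      t(vapply(seq_len(B), function(b) inject_direction(k), numeric(k)))
    } else {
      matrix(inject_direction(k), B, k, byrow = TRUE)
    }
    list(G = G, U = U)
  })
  q_alpha <- vapply(delta_grid, function(d) {
    dist_d <- sqrt(rowSums((sims$G + d * sims$U)^2))
    stats::quantile(dist_d, alpha, names = FALSE)
  }, numeric(1))
  rejected <- observed_delta <= q_alpha
  # smallest grid value from which all larger values are rejected
  delta_star <- NA_real_
  determinable <- FALSE
  if (rejected[length(rejected)]) {
    i <- length(rejected)
    while (i > 1L && rejected[i - 1L]) i <- i - 1L
    delta_star <- delta_grid[i]
    determinable <- TRUE
  }
  # d conversion needs nonzero pooled SDs; degenerate (constant) groups
  # keep their Delta* but carry no effect-size equivalent
  d_equiv <- if (determinable) {
    tryCatch(cohens_d_from_delta(delta_star, A, Bm, n_draws = n_d_draws,
                                 seed = seed + 1L, method = d_method),
             error = function(e) NA_real_)
  } else NA_real_
  structure(list(delta_star_rejectable = delta_star,
                 determinable = determinable, alpha = alpha,
                 cohens_d_equivalent = d_equiv,
                 observed_delta = observed_delta, delta_grid = delta_grid,
                 rejected = rejected, quantiles = q_alpha,
                 n_shuffles = B, subset = subset, seed = seed,
                 d_method = d_method),
            class = "equiv_test")
}

#' @export
print.equiv_test <- function(x, ...) {
  cat("<equiv_test> [", x$subset, "] observed delta = ",
      signif(x$observed_delta, 4), "\n", sep = "")
  if (x$determinable) {
    cat("  reject any true difference > ", x$delta_star_rejectable,
        " at alpha = ", x$alpha, " (average univariate d = ",
        signif(x$cohens_d_equivalent, 3), ")\n", sep = "")
  } else {
    cat("  no grid value rejectable at alpha = ", x$alpha,
        " (Delta* not determinable on this grid)\n", sep = "")
  }
  invisible(x)
}

#' Average univariate Cohen's d of an injected pattern of given norm
#'
#' Converts a multivariate pattern-difference norm into the mean univariate
#' effect size per connection: for an injected pattern delta of norm
#' `delta_star`, d = mean_i |delta_i| / s_i with s_i the pooled
#' across-group SD of connection i. The default takes the expectation over
#' random unit directions (Monte-Carlo with `n_draws` draws); `"single"`
#' uses one random draw; `"heuristic"` uses the asymptotic
#' `delta_star * sqrt(2/pi) / sqrt(K) * mean(1/s_i)`.
#'
#' @param delta_star Nonnegative pattern norm.
#' @param groupA,groupB Pattern collections or weight matrices defining the
#'   pooled SDs.
#' @param n_draws Monte-Carlo draws for the default method.
#' @param seed RNG seed.
#' @param subset Pattern subset.
#' @param method `"expected"`, `"single"`, or `"heuristic"`.
#' @return Nonnegative effect size (scalar).
#' @export
cohens_d_from_delta <- function(delta_star, groupA, groupB, n_draws = 1000,
                                seed = 1, subset = "full",
                                method = c("expected", "single",
                                           "heuristic")) {
  method <- match.arg(method)
  stopifnot_scalar_number(delta_star, "delta_star", min = 0)
  A <- pattern_matrix(groupA, subset); Bm <- pattern_matrix(groupB, subset)
  nA <- nrow(A); nB <- nrow(Bm); k <- ncol(A)
  sA <- apply(A, 2, stats::var); sB <- apply(Bm, 2, stats::var)
  s <- sqrt(((nA - 1) * sA + (nB - 1) * sB) / (nA + nB - 2))
  if (any(s == 0)) {
    lbl <- if (k == 45L) {
      paste(pair_labels()$roiA, pair_labels()$roiB, sep = "|")
    } else {
      as.character(seq_len(k))
    }
    stop("zero pooled SD for connection(s): ",
         paste(lbl[s == 0], collapse = ", "), call. = FALSE)
  }
  if (delta_star == 0) return(0)
  if (method == "heuristic") {
    return(delta_star * sqrt(2 / pi) / sqrt(k) * mean(1 / s))
  }
  nd <- if (method == "single") 1L else n_draws
  with_seed(seed, {
    ds <- vapply(seq_len(nd), function(i) {
      u <- inject_direction(k)
      mean(abs(delta_star * u) / s)
    }, numeric(1))
    mean(ds)
  })
}

#' Permutation test on within-group pattern variability
#'
#' A group's variability is the mean Euclidean distance of its members'
#' patterns to the group mean pattern (an idiosyncrasy measure). The test
#' statistic is `delta_variability = variability(A) - variability(B)`; its
#' null distribution comes from label shuffles preserving group sizes. The
#' null is generally not symmetric around zero when group sizes differ, so
#' the default p-value is one-sided in the direction of the observed sign
#' against the empirical null; `alternative = "two.sided"` doubles the
#' smaller tail (capped at 1).
#'
#' @param groupA,groupB Pattern collections, each with at least 2 members.
#' @param B Shuffles (default 10000).
#' @param seed RNG seed.
#' @param subset Pattern subset.
#' @param alternative `"observed"` (one-sided, default) or `"two.sided"`.
#' @return A `variability_test` object with fields
#'   `group_variability_A` / `group_variability_B`, `delta_variability`,
#'   `p_value`, `null_distribution`, `direction`.
#' @export
variability_test <- function(groupA, groupB, B = 10000, seed = 1,
                             subset = "full",
                             alternative = c("observed", "two.sided")) {
  subset <- match.arg(subset, subset_choices())
  alternative <- match.arg(alternative)
  A <- pattern_matrix(groupA, subset); Bm <- pattern_matrix(groupB, subset)
  if (nrow(A) < 2L || nrow(Bm) < 2L) {
    stop("variability undefined for a group of size < 2", call. = FALSE)
  }
  grp_var <- function(M) {
    mu <- colMeans(M)
    mean(sqrt(rowSums(sweep(M, 2, mu)^2)))
  }
  vA <- grp_var(A); vB <- grp_var(Bm)
  observed <- vA - vB
  X <- rbind(A, Bm); n <- nrow(X); nA <- nrow(A)
  nulls <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, nA)
      grp_var(X[idx, , drop = FALSE]) - grp_var(X[-idx, , drop = FALSE])
    }, numeric(1))
  })
  p_hi <- mean(nulls >= observed); p_lo <- mean(nulls <= observed)
  direction <- if (observed >= 0) "greater" else "less"
  p <- switch(alternative,
              observed = if (observed >= 0) p_hi else p_lo,
              two.sided = min(1, 2 * min(p_hi, p_lo)))
  structure(list(group_variability_A = vA, group_variability_B = vB,
                 delta_variability = observed, p_value = p,
                 null_distribution = nulls, n_shuffles = B,
                 direction = direction, alternative = alternative,
                 subset = subset, seed = seed),
            class = "variability_test")
}

#' @export
print.variability_test <- function(x, ...) {
  cat("<variability_test> [", x$subset, "] delta_variability = ",
      signif(x$delta_variability, 4), " (", signif(x$group_variability_A, 4),
      " - ", signif(x$group_variability_B, 4), "), p = ",
      signif(x$p_value, 4), " (", x$alternative, ", ", x$direction, ")\n",
      sep = "")
  invisible(x)
}

# split a flat list of conn_pattern into a named list by week
split_by_week <- function(patterns) {
  if (!is.null(names(patterns)) && all(nzchar(names(patterns))) &&
        all(vapply(patterns, is.list, logical(1))) &&
        !inherits(patterns[[1]], "conn_pattern")) {
    return(patterns)  # already a named list of collections
  }
  wk <- vapply(patterns, function(p) p$week, character(1))
  split(patterns, factor(wk, levels = unique(wk)))
}

#' Longitudinal pattern-change permutation tests
#'
#' For each week after the reference week, compares that week's patterns to
#' the reference-week patterns, restricted to subjects observed at both
#' weeks (complete-case matching per comparison). Because the same subjects
#' appear at both weeks, the default null permutes the week label within
#' each subject pair (paired design); `paired = FALSE` pools all patterns
#' and reassigns them freely.
#'
#' @param patterns_by_week Either a flat list of [conn_pattern()] (split by
#'   their `week` field) or a named list of per-week collections.
#' @param reference_week Reference week label (default `"W1"`).
#' @param B,seed,subset As in [delta_pattern_test()].
#' @param paired Permute week labels within subject (default `TRUE`).
#' @return Named list of `perm_test` objects, one per non-reference week.
#' @export
longitudinal_deltas <- function(patterns_by_week, reference_week = "W1",
                                B = 10000, seed = 1, subset = "full",
                                paired = TRUE) {
  subset <- match.arg(subset, subset_choices())
  by_week <- split_by_week(patterns_by_week)
  if (!reference_week %in% names(by_week)) {
    stop("reference week '", reference_week, "' not present", call. = FALSE)
  }
  ref <- by_week[[reference_week]]
  ref_ids <- pattern_ids(ref)
  weeks <- setdiff(names(by_week), reference_week)
  out <- list()
  for (wi in seq_along(weeks)) {
    w <- weeks[wi]
    cur <- by_week[[w]]
    cur_ids <- pattern_ids(cur)
    common <- intersect(ref_ids, cur_ids)
    if (length(common) == 0L) {
      stop("no subjects observed at both ", reference_week, " and ", w,
           call. = FALSE)
    }
    R <- pattern_matrix(ref[match(common, ref_ids)], subset)
    C <- pattern_matrix(cur[match(common, cur_ids)], subset)
    observed <- euclidean_delta(colMeans(R), colMeans(C))
    n <- length(common)
    nulls <- with_seed(seed + wi - 1L, {
      if (paired) {
        vapply(seq_len(B), function(b) {
          flip <- stats::runif(n) < 0.5
          Ra <- R; Ca <- C
          Ra[flip, ] <- C[flip, , drop = FALSE]
          Ca[flip, ] <- R[flip, , drop = FALSE]
          euclidean_delta(colMeans(Ra), colMeans(Ca))
        }, numeric(1))
      } else {
        X <- rbind(R, C)
        G <- shuffled_mean_diffs(X, n, B)
        sqrt(rowSums(G^2))
      }
    })
    out[[w]] <- perm_test_result(observed, nulls, B, subset,
                                 paste0(reference_week, " vs ", w), n, n,
                                 seed + wi - 1L)
  }
  out
}

#' Per-subject distance-to-reference table across weeks
#'
#' For each subject and each non-reference week, the Euclidean distance
#' between the subject's pattern at that week and their own pattern at the
#' reference week. Feeds [week_variability_anova()].
#'
#' @param patterns A flat list of [conn_pattern()] or a named per-week list.
#' @param reference_week Reference week label.
#' @param subset Pattern subset.
#' @param complete_cases Keep only subjects observed at every week.
#' @return Numeric matrix, subjects x weeks (reference excluded); `NA` for
#'   missing cells when `complete_cases = FALSE`.
#' @export
week_distance_table <- function(patterns, reference_week = "W1",
                                subset = "full", complete_cases = TRUE) {
  by_week <- split_by_week(patterns)
  if (!reference_week %in% names(by_week)) {
    stop("reference week '", reference_week, "' not present", call. = FALSE)
  }
  ref <- by_week[[reference_week]]
  ref_ids <- pattern_ids(ref)
  weeks <- setdiff(names(by_week), reference_week)
  tab <- matrix(NA_real_, length(ref_ids), length(weeks),
                dimnames = list(ref_ids, weeks))
  for (w in weeks) {
    cur <- by_week[[w]]
    cur_ids <- pattern_ids(cur)
    for (id in intersect(ref_ids, cur_ids)) {
      tab[id, w] <- euclidean_delta(
        as_weights(ref[[match(id, ref_ids)]], subset),
        as_weights(cur[[match(id, cur_ids)]], subset))
    }
  }
  if (complete_cases) tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  tab
}

#' One-way ANOVA over the week factor on per-subject distances
#'
#' Tests whether per-subject pattern distances change across weeks, on a
#' complete subjects x weeks table. The week factor is the only model term
#' (subjects enter as replicates within each week cell), so the degrees of
#' freedom are (k - 1, N - k): 10 subjects x 4 weeks gives F(3, 36).
#'
#' @param per_subject_distances Complete numeric matrix or data.frame,
#'   subjects in rows, weeks in columns.
#' @return A `week_anova` object: `F`, `df1`, `df2`, `p_value` plus sums of
#'   squares.
#' @export
week_variability_anova <- function(per_subject_distances) {
  x <- as.matrix(per_subject_distances)
  if (anyNA(x)) {
    stop("table has missing cells; filter to complete cases upstream ",
         "(see week_distance_table(complete_cases = TRUE))", call. = FALSE)
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 weeks",
                             call. = FALSE)
  grand <- mean(x)
  ss_week <- n * sum((colMeans(x) - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_within <- ss_tot - ss_week
  df1 <- k - 1L; df2 <- n * k - k
  # no week effect at all (e.g. identical values per subject) -> F = 0
  f <- if (ss_week == 0) 0 else (ss_week / df1) / (ss_within / df2)
  structure(list(F = f, df1 = df1, df2 = df2,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 ss_week = ss_week, ss_within = ss_within,
                 n_subjects = n, n_weeks = k),
            class = "week_anova")
}

#' @export
print.week_anova <- function(x, ...) {
  cat("<week_anova> F(", x$df1, ",", x$df2, ") = ", signif(x$F, 4),
      ", p = ", signif(x$p_value, 4), " (", x$n_subjects, " subjects x ",
      x$n_weeks, " weeks)\n", sep = "")
  invisible(x)
}
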