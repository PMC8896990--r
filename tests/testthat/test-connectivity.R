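test_that("fisher_z matches the closed form and clamps degenerate r", {
  expect_identical(fisher_z(0), 0)
  # independent oracle: 0.5 * (log1p(r) - log1p(-r))
  r <- c(0.7218, -0.7218, 0.1, 0.99)
  expect_equal(fisher_z(r), 0.5 * (log1p(r) - log1p(-r)),
               tolerance = 1e-12)
  expect_equal(fisher_z(0.7218), 0.9113926, tolerance = 1e-6)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_warning(z <- fisher_z(c(1, -1, 0.5)), "clamped")
  expect_true(all(is.finite(z)))
  expect_equal(z[1], -z[2])
})

test_that("compute_pattern yields the canonical 45-weight decomposition", {
  set.seed(1)
  X <- matrix(rnorm(5000 * 10), 5000, 10,
              dimnames = list(NULL, acquisition_roi_names()))
  ts <- roi_timeseries(X, "sub", "control")
  p <- compute_pattern(ts)
  expect_s3_class(p, "conn_pattern")
  expect_length(p$weights, 45L)
  expect_equal(table(p$subsets)[["interhemispheric"]], 25L)
  expect_equal(table(p$subsets)[["intra_ipsilesional"]], 10L)
  # mutually independent white noise -> all weights near zero
  expect_lt(max(abs(p$weights)), 0.06)
})

test_that("an engineered dependency produces the maximal weight", {
  set.seed(2)
  X <- matrix(rnorm(400 * 10), 400, 10,
              dimnames = list(NULL, acquisition_roi_names()))
  X[, "M1_left"] <- 2 * X[, "S1_left"] + 0.2 * rnorm(400)
  p <- compute_pattern(roi_timeseries(X, "s", "control"))
  expect_equal(names(which.max(p$weights)), "S1_ipsi|M1_ipsi")
})

test_that("patterns are invariant to affine rescaling of a column", {
  set.seed(3)
  X <- matrix(rnorm(200 * 10), 200, 10,
              dimnames = list(NULL, acquisition_roi_names()))
  p1 <- compute_pattern(roi_timeseries(X, "s", "control"))
  X2 <- X
  X2[, "PMd_right"] <- 5 + 3.7 * X2[, "PMd_right"]
  p2 <- compute_pattern(roi_timeseries(X2, "s", "control"))
  expect_equal(p1$weights, p2$weights, tolerance = 1e-12)
})

test_that("lesion-side flip relabels blocks but preserves the weights", {
  set.seed(4)
  X <- matrix(rnorm(150 * 10), 150, 10,
              dimnames = list(NULL, acquisition_roi_names()))
  pL <- compute_pattern(roi_timeseries(X, "s", "patient",
                                       lesion_side = "left"))
  pR <- compute_pattern(roi_timeseries(X, "s", "patient",
                                       lesion_side = "right"))
  expect_equal(unname(sort(pL$weights)), unname(sort(pR$weights)),
               tolerance = 1e-12)
  # ipsi block of the left-lesion view is the contra block of the right
  m <- subset_masks()
  expect_equal(unname(sort(pL$weights[m$intra_ipsilesional])),
               unname(sort(pR$weights[m$intra_contralesional])),
               tolerance = 1e-12)
})

test_that("zero-variance ROI fails loudly with its name", {
  X <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(NULL, acquisition_roi_names()))
  X[, "SMA_left"] <- 1
  expect_error(roi_timeseries(X, "s", "control"), "SMA_left")
})

test_that("average_pattern: identity, cancellation, mixed-group guard", {
  p <- draw_patterns(1, sd = 0.2, seed = 5)[[1]]
  expect_equal(average_pattern(list(p))$weights, p$weights)
  q <- conn_pattern(-p$weights, subject_id = "q", group = p$group)
  expect_equal(unname(average_pattern(list(p, q))$weights), rep(0, 45))
  pat <- draw_patterns(1, group = "patient", seed = 6)[[1]]
  expect_error(average_pattern(list(p, pat)), "mixed")
  avg <- average_pattern(list(p, pat), allow_mixed = TRUE)
  expect_equal(avg$weights, (p$weights + pat$weights) / 2)
})

test_that("control hemisphere-averaging symmetrizes the convention", {
  z <- default_ground_truth()
  z[connpattern:::pair_index("S1_ipsi", "M1_ipsi")] <- 0.8
  z[connpattern:::pair_index("S1_contra", "M1_contra")] <- 1.0
  z[connpattern:::pair_index("S1_ipsi", "M1_contra")] <- 0.2
  z[connpattern:::pair_index("M1_ipsi", "S1_contra")] <- 0.6
  hom_before <- z[connpattern:::pair_index("M1_ipsi", "M1_contra")]
  p <- conn_pattern(z, group = "control")
  a <- average_pattern(list(p), control_hemisphere_average = TRUE)
  expect_equal(extract_weight(a, "S1_ipsi", "M1_ipsi"), 0.9)
  expect_equal(extract_weight(a, "S1_contra", "M1_contra"), 0.9)
  # heterologous interhemispheric weights are orientation-averaged
  expect_equal(extract_weight(a, "S1_ipsi", "M1_contra"), 0.4)
  expect_equal(extract_weight(a, "M1_ipsi", "S1_contra"), 0.4)
  # homologous interhemispheric weights are untouched
  expect_equal(extract_weight(a, "M1_ipsi", "M1_contra"),
               unname(hom_before))
})

test_that("extract_weight is order-insensitive and validates labels", {
  p <- conn_pattern(rep(0.3, 45))
  expect_equal(extract_weight(p, "M1_ipsi", "M1_contra"), 0.3)
  expect_equal(extract_weight(p, "PMv_contra", "S1_ipsi"),
               extract_weight(p, "S1_ipsi", "PMv_contra"))
  expect_error(extract_weight(p, "V1_ipsi", "M1_ipsi"), "unknown ROI pair")
})

test_that("extract_roi_means averages voxels within labels", {
  img <- array(0, dim = c(2, 2, 1, 3))
  msk <- array(c(1L, 1L, 2L, 0L), dim = c(2, 2, 1))
  img[1, 1, 1, ] <- c(1, 5, 7)   # label 1
  img[2, 1, 1, ] <- c(3, 5, 7)   # label 1
  img[1, 2, 1, ] <- c(9, 2, 4)   # label 2 (single voxel)
  out <- extract_roi_means(img, msk, c(A = 1L, B = 2L))
  expect_equal(out[, "A"], c(2, 5, 7))          # mean of (1,3), identical
  expect_equal(out[, "B"], c(9, 2, 4))          # single voxel unchanged
  expect_error(extract_roi_means(img, msk, c(A = 1L, C = 9L)), "'C'")
  expect_error(extract_roi_means(img, array(0L, c(3, 2, 1)),
                                 c(A = 1L)), "dimensions")
})

test_that("a 10-label volume comes back as a full roi_timeseries", {
  set.seed(7)
  img <- array(rnorm(10 * 1 * 1 * 30), dim = c(10, 1, 1, 30))
  msk <- array(1:10, dim = c(10, 1, 1))
  lm <- structure(1:10, names = acquisition_roi_names())
  ts <- extract_roi_means(img, msk, lm, subject_id = "x", group = "control")
  expect_s3_class(ts, "roi_timeseries")
  expect_equal(ts$data[, "S1_left"], img[1, 1, 1, ])
})

test_that("null-cohort patterns average back to the ground truth", {
  cfg <- cohort_config(n_patients = 4, n_controls = 4, sessions = "W1",
                       n_volumes = 2000, subject_sd_patient = 0,
                       subject_sd_control = 0, session_sd = 0,
                       missing_rate = 0, seed = 12)
  co <- generate_cohort(cfg)
  M <- connpattern:::pattern_matrix(lapply(co, compute_pattern))
  expect_lt(max(abs(colMeans(M) - default_ground_truth())), 0.06)
})
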