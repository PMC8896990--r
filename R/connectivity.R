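#' Fisher-Z transform of a correlation coefficient
#'
#' Variance-stabilizing `atanh(r)`. Correlations with `|r| >= 1 - 1e-7`
#' (degenerate, near-duplicate series) are clamped to `+/- (1 - 1e-7)` with
#' a warning rather than returning infinity.
#'
#' @param r Numeric vector of correlations.
#' @return Numeric vector of Fisher-Z values, always finite.
#' @export
#' @examples
#' fisher_z(c(0, 0.7218, -0.7218))
fisher_z <- function(r) {
  eps <- 1e-7
  bad <- is.finite(r) & abs(r) >= 1 - eps
  if (any(bad)) {
    warning(sum(bad), " correlation(s) with |r| >= 1 - 1e-7 clamped",
            call. = FALSE)
    r[bad] <- sign(r[bad]) * (1 - eps)
  }
  atanh(r)
}

#' Construct a connectivity pattern from raw weights
#'
#' Low-level constructor used by [compute_pattern()] and by tests that need
#' patterns with known weights. The 45 weights must be in canonical
#' upper-triangle order.
#'
#' @param weights Finite numeric 45-vector of Fisher-Z weights.
#' @param subject_id,group,week Metadata carried along.
#' @param lesion_side Lesion side of the source subject.
#' @return An object of class `conn_pattern` with fields `weights` (named),
#'   `pair_labels`, `subsets`, and the metadata.
#' @export
conn_pattern <- function(weights, subject_id = "sub", group = "control",
                         week = "W1", lesion_side = "none") {
  weights <- as.numeric(weights)
  if (length(weights) != 45L) {
    stop("a connectivity pattern has exactly 45 weights", call. = FALSE)
  }
  if (!all(is.finite(weights))) {
    stop("all pattern weights must be finite", call. = FALSE)
  }
  pl <- pair_labels()
  names(weights) <- paste(pl$roiA, pl$roiB, sep = "|")
  structure(list(weights = weights, pair_labels = pl,
                 subsets = pair_subsets(),
                 subject_id = as.character(subject_id), group = group,
                 week = as.character(week), lesion_side = lesion_side),
            class = "conn_pattern")
}

#' @export
print.conn_pattern <- function(x, ...) {
  cat("<conn_pattern> ", x$subject_id, " [", x$group, "] ", x$week,
      ": 45 Fisher-Z weights (10 ipsi + 10 contra + 25 inter)\n",
      "  range [", round(min(x$weights), 3), ", ",
      round(max(x$weights), 3), "]\n", sep = "")
  invisible(x)
}

#' Compute the Fisher-Z connectivity pattern of one scan
#'
#' Pearson-correlates every unordered pair of the 10 ROI-mean series,
#' Fisher-Z transforms, and vectorizes the upper triangle of the 10 x 10
#' matrix in canonical order. Hemisphere blocks are flipped so that block 1
#' is the ipsilesional hemisphere for patients and the left reference
#' hemisphere for controls, making pattern vectors comparable across
#' subjects.
#'
#' @param ts A [roi_timeseries()].
#' @return A [conn_pattern()] (45 weights: 10 intra-ipsilesional,
#'   10 intra-contralesional, 25 interhemispheric).
#' @export
compute_pattern <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  X <- aligned_data(ts)
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance ROI: ", paste(colnames(X)[v == 0], collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(X)
  z <- fisher_z(mat_to_vec(r))
  conn_pattern(z, subject_id = ts$subject_id, group = ts$group,
               week = ts$week, lesion_side = ts$lesion_side)
}

# coerce a pattern/vector to its numeric weights, optionally a subset
as_weights <- function(x, subset = "full") {
  w <- if (inherits(x, "conn_pattern")) x$weights else as.numeric(x)
  if (subset == "full") return(w)
  subset <- match.arg(subset, subset_choices())
  if (length(w) != 45L) {
    stop("subset extraction needs a full 45-weight pattern", call. = FALSE)
  }
  w[subset_masks()[[subset]]]
}

# stack a list of patterns into an n x K weight matrix for one subset
pattern_matrix <- function(patterns, subset = "full") {
  if (inherits(patterns, "conn_pattern")) patterns <- list(patterns)
  if (is.matrix(patterns)) return(patterns)
  do.call(rbind, lapply(patterns, as_weights, subset = subset))
}

#' Average connectivity patterns
#'
#' Entrywise mean of a collection of patterns. With
#' `control_hemisphere_average = TRUE` (the convention for lesion-free
#' controls) the result is additionally symmetrized across hemispheres:
#' each intrahemispheric weight is replaced by the mean of the two
#' homologous within-hemisphere weights, and each heterologous
#' interhemispheric weight by the mean of its two orientations
#' (A_ipsi-B_contra with B_ipsi-A_contra). Homologous interhemispheric
#' weights are orientation-free and left untouched.
#'
#' @param patterns List of [conn_pattern()] (or a single one).
#' @param control_hemisphere_average Apply the control symmetrization.
#' @param allow_mixed Permit averaging across groups (otherwise an error).
#' @return A [conn_pattern()] with averaged metadata.
#' @export
average_pattern <- function(patterns, control_hemisphere_average = FALSE,
                            allow_mixed = FALSE) {
  if (inherits(patterns, "conn_pattern")) patterns <- list(patterns)
  if (length(patterns) == 0L) stop("empty pattern collection", call. = FALSE)
  groups <- unique(vapply(patterns, function(p) p$group, character(1)))
  if (length(groups) > 1L && !allow_mixed) {
    stop("patterns from mixed groups (", paste(groups, collapse = ", "),
         "); set allow_mixed = TRUE to override", call. = FALSE)
  }
  w <- colMeans(pattern_matrix(patterns))
  if (control_hemisphere_average) {
    pl <- pair_labels()
    base <- sub("_(ipsi|contra)$", "", c(pl$roiA, pl$roiB))
    baseA <- base[seq_len(45)]
    baseB <- base[45 + seq_len(45)]
    ss <- pair_subsets()
    done <- logical(45)
    for (i in seq_len(45)) {
      if (done[i]) next
      if (ss[i] == "interhemispheric" && baseA[i] == baseB[i]) {
        done[i] <- TRUE
        next
      }
      # mirror pair: same base areas, other hemisphere block / orientation
      j <- which(!done & seq_len(45) != i &
                   ((baseA == baseA[i] & baseB == baseB[i]) |
                      (baseA == baseB[i] & baseB == baseA[i])) &
                   ((ss[i] == "interhemispheric") ==
                      (ss == "interhemispheric")))
      j <- setdiff(j, i)[1]
      m <- mean(c(w[i], w[j]))
      w[i] <- w[j] <- m
      done[c(i, j)] <- TRUE
    }
  }
  ids <- unique(vapply(patterns, function(p) p$subject_id, character(1)))
  weeks <- unique(vapply(patterns, function(p) p$week, character(1)))
  conn_pattern(w,
               subject_id = if (length(ids) == 1L) ids else "average",
               group = if (length(groups) == 1L) groups else "control",
               week = if (length(weeks) == 1L) weeks else
                 paste(weeks, collapse = "+"))
}

#' Look up a single connectivity weight
#'
#' Order-insensitive lookup of one ROI-pair weight, e.g. the homologous
#' interhemispheric M1-M1 weight that feeds per-subject longitudinal
#' tables.
#'
#' @param pattern A [conn_pattern()].
#' @param roiA,roiB Canonical ROI names (e.g. `"M1_ipsi"`, `"M1_contra"`).
#' @return The Fisher-Z weight (numeric scalar).
#' @export
extract_weight <- function(pattern, roiA, roiB) {
  stopifnot(inherits(pattern, "conn_pattern"))
  unname(pattern$weights[pair_index(roiA, roiB)])
}

#' Extract ROI-mean time series from a labeled image
#'
#' Averages, per volume, all voxels sharing an integer label, yielding one
#' BOLD time-course per ROI. Operates on in-memory arrays (x, y, z, T) and
#' a 3D integer label array on the same grid.
#'
#' @param image Numeric 4D array (x, y, z, T).
#' @param mask Integer 3D array with the same spatial dimensions.
#' @param label_map Named integer vector mapping ROI name -> label value.
#' @param subject_id,group,lesion_side,week,tr_seconds Metadata used when
#'   the mapped ROIs are the full acquisition set of 10.
#' @return A [roi_timeseries()] when `label_map` covers exactly the 10
#'   acquisition ROI names; otherwise the bare T x K matrix of ROI means.
#' @export
extract_roi_means <- function(image, mask, label_map, subject_id = "sub",
                              group = "control", lesion_side = "none",
                              week = "W1", tr_seconds = 2) {
  di <- dim(image); dm <- dim(mask)
  if (length(di) != 4L || length(dm) != 3L || !all(di[1:3] == dm)) {
    stop("image (x,y,z,T) and mask (x,y,z) dimensions do not match",
         call. = FALSE)
  }
  stopifnot(!is.null(names(label_map)))
  n_t <- di[4]
  vox <- matrix(image, ncol = n_t)  # voxels x T
  out <- matrix(NA_real_, n_t, length(label_map),
                dimnames = list(NULL, names(label_map)))
  for (nm in names(label_map)) {
    sel <- which(as.vector(mask) == label_map[[nm]])
    if (length(sel) == 0L) {
      stop("ROI '", nm, "' (label ", label_map[[nm]],
           ") has no voxels in the mask", call. = FALSE)
    }
    out[, nm] <- colMeans(vox[sel, , drop = FALSE])
  }
  if (setequal(names(label_map), acquisition_roi_names())) {
    roi_timeseries(out[, acquisition_roi_names(), drop = FALSE],
                   subject_id = subject_id, group = group,
                   lesion_side = lesion_side, week = week,
                   tr_seconds = tr_seconds)
  } else {
    out
  }
}
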