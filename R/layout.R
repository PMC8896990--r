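#' @keywords internal
"_PACKAGE"

# Canonical ROI layout
#
# Five sensorimotor areas per hemisphere. After lesion alignment, hemisphere
# block 1 is ipsilesional (patients) or the left reference hemisphere
# (controls), block 2 contralesional. All vectorized patterns use the upper
# triangle of the 10x10 matrix in this fixed order, so Euclidean distances
# are comparable across subjects and sessions.

#' Base names of the five sensorimotor ROIs
#'
#' @return Character vector `c("S1","M1","PMd","PMv","SMA")`.
#' @export
roi_base_names <- function() c("S1", "M1", "PMd", "PMv", "SMA")

#' Canonical (lesion-aligned) ROI names
#'
#' Hemisphere block 1 (`_ipsi`) is the ipsilesional hemisphere for patients
#' and the left reference hemisphere for controls; block 2 is `_contra`.
#'
#' @return Character vector of 10 ROI names.
#' @export
canonical_roi_names <- function() {
  c(paste0(roi_base_names(), "_ipsi"), paste0(roi_base_names(), "_contra"))
}

#' Acquisition-order (left/right) ROI names
#'
#' @return Character vector of 10 ROI names, left hemisphere first.
#' @export
acquisition_roi_names <- function() {
  c(paste0(roi_base_names(), "_left"), paste0(roi_base_names(), "_right"))
}

#' Canonical ROI-pair labels of the 45-weight pattern
#'
#' @return A data.frame with columns `roiA`, `roiB` (45 rows), upper-triangle
#'   order of the 10x10 canonical matrix.
#' @export
pair_labels <- function() {
  nm <- canonical_roi_names()
  idx <- which(upper.tri(matrix(0, 10, 10)), arr.ind = TRUE)
  # column-major upper triangle: (1,2), (1,3), (2,3), (1,4), ...
  data.frame(roiA = nm[idx[, "row"]], roiB = nm[idx[, "col"]],
             stringsAsFactors = FALSE)
}

#' Subset membership of each of the 45 ROI pairs
#'
#' @return Character vector of length 45 with values
#'   `"intra_ipsilesional"`, `"intra_contralesional"`, `"interhemispheric"`.
#' @export
pair_subsets <- function() {
  idx <- which(upper.tri(matrix(0, 10, 10)), arr.ind = TRUE)
  i <- idx[, "row"]; j <- idx[, "col"]
  out <- rep("interhemispheric", nrow(idx))
  out[i <= 5 & j <= 5] <- "intra_ipsilesional"
  out[i > 5 & j > 5] <- "intra_contralesional"
  out
}

#' Logical masks for the pattern subsets
#'
#' The three masks are disjoint and together cover all 45 weights
#' (10 + 10 + 25).
#'
#' @return Named list of three logical vectors of length 45.
#' @export
subset_masks <- function() {
  s <- pair_subsets()
  list(intra_ipsilesional = s == "intra_ipsilesional",
       intra_contralesional = s == "intra_contralesional",
       interhemispheric = s == "interhemispheric")
}

# names of the valid pattern subsets, "full" first
subset_choices <- function() {
  c("full", "interhemispheric", "intra_ipsilesional", "intra_contralesional")
}

# index of a pair in the canonical 45-vector; order-insensitive
pair_index <- function(roiA, roiB) {
  pl <- pair_labels()
  hit <- which((pl$roiA == roiA & pl$roiB == roiB) |
                 (pl$roiA == roiB & pl$roiB == roiA))
  if (length(hit) != 1L) {
    stop("unknown ROI pair: (", roiA, ", ", roiB, ")", call. = FALSE)
  }
  hit
}

# 45-vector -> symmetric 10x10 matrix with `diag_value` on the diagonal
vec_to_mat <- function(z, diag_value = 0) {
  m <- matrix(diag_value, 10, 10,
              dimnames = list(canonical_roi_names(), canonical_roi_names()))
  m[upper.tri(m)] <- z
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# symmetric 10x10 matrix -> 45-vector (canonical upper triangle)
mat_to_vec <- function(m) m[upper.tri(m)]
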