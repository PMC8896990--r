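#' Relative interhemispheric connectivity (RelCon) of sensorimotor cortex
#'
#' Voxel-level connectivity ratio: the mean Pearson correlation over all
#' ipsilesional x contralesional voxel pairs of SM1, divided by the mean
#' correlation over all distinct within-ipsilesional voxel pairs.
#' Self-correlations (identically 1) are excluded from the within average,
#' which would otherwise inflate the denominator. Correlations are averaged
#' raw by default; `fisher_average = TRUE` averages in Fisher-Z space and
#' back-transforms.
#'
#' @param voxels_ipsi Numeric T x V1 matrix of ipsilesional SM1 voxel
#'   series (V1 >= 2).
#' @param voxels_contra Numeric T x V2 matrix of contralesional SM1 voxel
#'   series (V2 >= 1).
#' @param subject_id,week Metadata carried into the result.
#' @param fisher_average Average correlations in Fisher-Z space.
#' @return A `relcon_result` with fields `inter_mean`, `within_mean`,
#'   `relcon = inter_mean / within_mean`.
#' @export
relcon <- function(voxels_ipsi, voxels_contra, subject_id = NA_character_,
                   week = NA_character_, fisher_average = FALSE) {
  voxels_ipsi <- as.matrix(voxels_ipsi)
  voxels_contra <- as.matrix(voxels_contra)
  if (nrow(voxels_ipsi) != nrow(voxels_contra)) {
    stop("voxel sets must share the number of volumes", call. = FALSE)
  }
  if (nrow(voxels_ipsi) < 3L) stop("need T >= 3 volumes", call. = FALSE)
  if (ncol(voxels_ipsi) < 2L) {
    stop("within-hemisphere mean undefined: need >= 2 ipsilesional voxels",
         call. = FALSE)
  }
  if (ncol(voxels_contra) < 1L) {
    stop("need >= 1 contralesional voxel", call. = FALSE)
  }
  zero_v <- function(m) which(apply(m, 2, stats::var) == 0)
  if (length(zero_v(voxels_ipsi)) || length(zero_v(voxels_contra))) {
    stop("zero-variance voxel series present", call. = FALSE)
  }
  avg <- function(r) {
    if (fisher_average) tanh(mean(fisher_z(r))) else mean(r)
  }
  cross <- stats::cor(voxels_ipsi, voxels_contra)
  within <- stats::cor(voxels_ipsi)
  inter_mean <- avg(as.vector(cross))
  within_mean <- avg(within[upper.tri(within)])
  if (abs(within_mean) < 1e-6) {
    stop("within-hemisphere mean correlation ~ 0; RelCon ratio unstable",
         call. = FALSE)
  }
  structure(list(subject_id = subject_id, week = week,
                 inter_mean = inter_mean, within_mean = within_mean,
                 relcon = inter_mean / within_mean,
                 n_voxels_ipsi = ncol(voxels_ipsi),
                 n_voxels_contra = ncol(voxels_contra),
                 fisher_average = fisher_average),
            class = "relcon_result")
}

#' @export
print.relcon_result <- function(x, ...) {
  cat("<relcon_result> ",
      if (!is.na(x$subject_id)) paste0(x$subject_id, " "),
      if (!is.na(x$week)) paste0(x$week, " "),
      "inter = ", signif(x$inter_mean, 4), ", within = ",
      signif(x$within_mean, 4), ", RelCon = ", signif(x$relcon, 4), "\n",
      sep = "")
  invisible(x)
}

#' RelCon from a voxel-mode subject-session
#'
#' Builds the ipsilesional and contralesional SM1 voxel sets (union of the
#' S1 and M1 voxel series of the respective hemisphere; controls use left
#' as the reference hemisphere) and calls [relcon()].
#'
#' @param ts A [roi_timeseries()] carrying `voxel_data`.
#' @param fisher_average Passed to [relcon()].
#' @return A `relcon_result`.
#' @export
relcon_from_timeseries <- function(ts, fisher_average = FALSE) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (is.null(ts$voxel_data)) {
    stop("subject-session has no voxel-level data", call. = FALSE)
  }
  ipsi_side <- if (ts$lesion_side == "right") "right" else "left"
  contra_side <- if (ipsi_side == "left") "right" else "left"
  sm1 <- function(side) {
    do.call(cbind, ts$voxel_data[paste0(c("S1", "M1"), "_", side)])
  }
  relcon(sm1(ipsi_side), sm1(contra_side), subject_id = ts$subject_id,
         week = ts$week, fisher_average = fisher_average)
}
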