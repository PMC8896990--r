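#' Construct a single subject-session set of ROI BOLD time series
#'
#' Container for one resting-state scan: a T x 10 matrix of ROI-averaged
#' BOLD samples in acquisition order (left hemisphere first), plus subject
#' metadata. Optionally carries per-ROI voxel-level series for RelCon.
#'
#' @param data Numeric T x 10 matrix; columns must be named with the
#'   acquisition ROI names (see [acquisition_roi_names()]). T >= 2 and every
#'   column must have nonzero variance.
#' @param subject_id Character scalar.
#' @param group `"patient"` or `"control"`.
#' @param lesion_side `"left"` or `"right"` for patients, `"none"` for
#'   controls.
#' @param week Session label, e.g. `"W1"`.
#' @param tr_seconds Sampling interval (TR) in seconds.
#' @param voxel_data Optional named list of T x V numeric matrices, one per
#'   acquisition ROI name, carrying voxel-level series.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, subject_id, group,
                           lesion_side = c("none", "left", "right"),
                           week = "W1", tr_seconds = 2,
                           voxel_data = NULL) {
  group <- match.arg(group, c("patient", "control"))
  lesion_side <- match.arg(lesion_side)
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("need at least 2 volumes (T >= 2)", call. = FALSE)
  if (ncol(data) != 10L) {
    stop("expected exactly 10 ROI columns, got ", ncol(data), call. = FALSE)
  }
  if (is.null(colnames(data))) colnames(data) <- acquisition_roi_names()
  if (!setequal(colnames(data), acquisition_roi_names())) {
    stop("ROI columns must be named ",
         paste(acquisition_roi_names(), collapse = ", "), call. = FALSE)
  }
  data <- data[, acquisition_roi_names(), drop = FALSE]
  v <- apply(data, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance ROI column: ",
         paste(colnames(data)[v == 0], collapse = ", "), call. = FALSE)
  }
  if (group == "patient" && lesion_side == "none") {
    stop("patients must have lesion_side 'left' or 'right'", call. = FALSE)
  }
  if (group == "control" && lesion_side != "none") {
    stop("controls must have lesion_side 'none'", call. = FALSE)
  }
  stopifnot_scalar_number(tr_seconds, "tr_seconds", min = 0)
  if (!is.null(voxel_data)) {
    stopifnot(is.list(voxel_data), !is.null(names(voxel_data)))
    for (nm in names(voxel_data)) {
      if (nrow(voxel_data[[nm]]) != nrow(data)) {
        stop("voxel_data[['", nm, "']] must have the same number of volumes",
             call. = FALSE)
      }
    }
  }
  structure(list(subject_id = as.character(subject_id), group = group,
                 lesion_side = lesion_side, week = as.character(week),
                 tr_seconds = tr_seconds, roi_names = colnames(data),
                 data = data, voxel_data = voxel_data),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("<roi_timeseries> ", x$subject_id, " [", x$group,
      if (x$lesion_side != "none") paste0(", lesion ", x$lesion_side),
      "] ", x$week, ": ", nrow(x$data), " volumes x ", ncol(x$data),
      " ROIs, TR = ", x$tr_seconds, " s",
      if (!is.null(x$voxel_data)) paste0(", voxel data for ",
                                         length(x$voxel_data), " ROIs"),
      "\n", sep = "")
  invisible(x)
}

# reorder the acquisition-order columns into canonical lesion-aligned order;
# controls use the left hemisphere as the fixed reference ("ipsi") block
aligned_data <- function(ts) {
  base <- roi_base_names()
  ipsi_side <- if (ts$lesion_side == "right") "right" else "left"
  contra_side <- if (ipsi_side == "left") "right" else "left"
  cols <- c(paste0(base, "_", ipsi_side), paste0(base, "_", contra_side))
  out <- ts$data[, cols, drop = FALSE]
  colnames(out) <- canonical_roi_names()
  out
}
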