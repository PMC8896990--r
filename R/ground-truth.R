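#' Default ground-truth Fisher-Z connectivity pattern
#'
#' A fixed 45-weight Fisher-Z pattern over the 10 sensorimotor ROIs used as
#' the population connectivity structure of the synthetic cohort. Four
#' anchors come from published control-group values: intrahemispheric
#' S1--M1 = 0.91 (strongest within-hemisphere coupling) and M1--PMv = 0.58
#' (weakest); interhemispheric homologous S1--S1 = 0.90 and heterologous
#' M1--PMv = 0.59. The remaining intrahemispheric weights interpolate
#' between the anchors following anatomical adjacency; homologous
#' interhemispheric weights lie in [0.82, 0.90] and every heterologous
#' interhemispheric weight (0.59 + 0.5 * (z_intra - 0.58), max 0.755) is
#' strictly below every homologous one, reflecting the stronger coupling of
#' homotopic areas. The implied correlation matrix `tanh(Z)` is positive
#' definite as shipped (minimum eigenvalue ~0.20), so no projection is
#' applied here.
#'
#' The pattern is hemisphere-symmetric, so the ipsi/contra orientation of
#' the canonical order does not affect it.
#'
#' @return Named numeric vector of 45 Fisher-Z weights in canonical
#'   upper-triangle order (names `"roiA|roiB"`).
#' @seealso [pair_labels()], [cohort_config()]
#' @export
#' @examples
#' z <- default_ground_truth()
#' z[["S1_ipsi|M1_ipsi"]]   # 0.91
default_ground_truth <- function() {
  roi <- roi_base_names()
  intra <- matrix(0, 5, 5, dimnames = list(roi, roi))
  vals <- c("S1.M1" = 0.91, "S1.PMd" = 0.72, "S1.PMv" = 0.65,
            "S1.SMA" = 0.68, "M1.PMd" = 0.75, "M1.PMv" = 0.58,
            "M1.SMA" = 0.78, "PMd.PMv" = 0.70, "PMd.SMA" = 0.74,
            "PMv.SMA" = 0.66)
  for (nm in names(vals)) {
    p <- strsplit(nm, ".", fixed = TRUE)[[1]]
    intra[p[1], p[2]] <- intra[p[2], p[1]] <- vals[[nm]]
  }
  hom <- c(S1 = 0.90, M1 = 0.88, PMd = 0.84, PMv = 0.82, SMA = 0.86)
  inter <- matrix(0, 5, 5, dimnames = list(roi, roi))
  for (a in roi) for (b in roi) {
    inter[a, b] <- if (a == b) hom[[a]] else 0.59 + 0.5 * (intra[a, b] - 0.58)
  }
  Z <- matrix(0, 10, 10,
              dimnames = list(canonical_roi_names(), canonical_roi_names()))
  Z[1:5, 1:5] <- intra
  Z[6:10, 6:10] <- intra
  Z[1:5, 6:10] <- inter
  Z[6:10, 1:5] <- t(inter)
  z <- mat_to_vec(Z)
  pl <- pair_labels()
  names(z) <- paste(pl$roiA, pl$roiB, sep = "|")
  z
}
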