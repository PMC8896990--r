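# Cohort TSV dialect: one file per subject-session (columns = 10 ROI names,
# rows = volumes) plus a manifest tying files to metadata. Voxel mode adds
# one TSV per ROI (columns = voxels) referenced by prefix from the manifest.

#' Write a cohort to TSV files plus a manifest
#'
#' @param cohort List of [roi_timeseries()] (e.g. from [generate_cohort()]).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(ts) {
    stem <- paste0("sub-", ts$subject_id, "_", ts$week)
    f <- paste0(stem, ".tsv")
    utils::write.table(ts$data, file.path(dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    voxel_prefix <- ""
    if (!is.null(ts$voxel_data)) {
      voxel_prefix <- paste0(stem, "_voxels_")
      for (nm in names(ts$voxel_data)) {
        vm <- ts$voxel_data[[nm]]
        colnames(vm) <- paste0("v", seq_len(ncol(vm)))
        utils::write.table(vm, file.path(dir,
                                         paste0(voxel_prefix, nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    data.frame(subject_id = ts$subject_id, group = ts$group,
               lesion_side = ts$lesion_side, week = ts$week, file = f,
               tr_seconds = ts$tr_seconds, voxel_prefix = voxel_prefix,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cohort from a manifest
#'
#' @param manifest_path Path to a `manifest.tsv` written by [write_cohort()]
#'   (or user-supplied files in the same dialect).
#' @return List of [roi_timeseries()].
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "lesion_side", "week", "file",
              "tr_seconds")
  if (!all(needed %in% names(man))) {
    stop("manifest must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  dir <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    f <- file.path(dir, man$file[i])
    if (!file.exists(f)) {
      stop("missing session file for ", man$subject_id[i], " ",
           man$week[i], ": ", f, call. = FALSE)
    }
    data <- as.matrix(utils::read.delim(f, check.names = FALSE))
    voxel_data <- NULL
    vp <- if ("voxel_prefix" %in% names(man)) man$voxel_prefix[i] else ""
    if (!is.na(vp) && nzchar(vp)) {
      voxel_data <- lapply(acquisition_roi_names(), function(nm) {
        vf <- file.path(dir, paste0(vp, nm, ".tsv"))
        if (!file.exists(vf)) {
          stop("missing voxel file for ", man$subject_id[i], " ",
               man$week[i], ": ", vf, call. = FALSE)
        }
        as.matrix(utils::read.delim(vf, check.names = FALSE))
      })
      names(voxel_data) <- acquisition_roi_names()
    }
    roi_timeseries(data, subject_id = man$subject_id[i],
                   group = man$group[i], lesion_side = man$lesion_side[i],
                   week = man$week[i], tr_seconds = man$tr_seconds[i],
                   voxel_data = voxel_data)
  })
}

#' Long-format weight table of a pattern collection
#'
#' @param patterns List of [conn_pattern()].
#' @return data.frame with columns `subject_id`, `group`, `week`, `roiA`,
#'   `roiB`, `subset`, `z`.
#' @export
pattern_table <- function(patterns) {
  if (inherits(patterns, "conn_pattern")) patterns <- list(patterns)
  do.call(rbind, lapply(patterns, function(p) {
    data.frame(subject_id = p$subject_id, group = p$group, week = p$week,
               roiA = p$pair_labels$roiA, roiB = p$pair_labels$roiB,
               subset = p$subsets, z = unname(p$weights),
               stringsAsFactors = FALSE)
  }))
}
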