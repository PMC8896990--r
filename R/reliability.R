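#' Split-half intrasession reliability of connectivity patterns
#'
#' Computes the connectivity pattern independently on the first and second
#' `half_length` volumes of a scan and Pearson-correlates the two
#' half-patterns, per subset. Volumes beyond `2 * half_length` are ignored
#' (a 210-volume scan is split 100 + 100 by default).
#'
#' @param ts A [roi_timeseries()] with at least `2 * half_length` volumes.
#' @param half_length Volumes per half (default 100).
#' @return data.frame with one row per subset (`full`, `interhemispheric`,
#'   `intra_ipsilesional`, `intra_contralesional`) and columns
#'   `subject_id`, `group`, `week`, `subset`, `r_split`.
#' @export
split_half <- function(ts, half_length = 100) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n_t <- nrow(ts$data)
  if (n_t < 2 * half_length) {
    stop("split-half needs at least ", 2 * half_length,
         " volumes, scan has ", n_t, call. = FALSE)
  }
  halves <- lapply(list(seq_len(half_length),
                        half_length + seq_len(half_length)),
                   function(idx) {
                     h <- ts
                     h$data <- ts$data[idx, , drop = FALSE]
                     h$voxel_data <- NULL
                     compute_pattern(h)
                   })
  out <- lapply(subset_choices(), function(ss) {
    a <- as_weights(halves[[1]], ss)
    b <- as_weights(halves[[2]], ss)
    data.frame(subject_id = ts$subject_id, group = ts$group,
               week = ts$week, subset = ss,
               r_split = stats::cor(a, b), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize reliability records per group with a bootstrap CI
#'
#' Group-level mean split-half reliability with a percentile bootstrap CI,
#' resampling subjects (clusters of records) with replacement.
#'
#' @param records data.frame as returned by (row-bound) [split_half()].
#' @param n_boot Bootstrap resamples (default 10000).
#' @param conf Confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with columns `group`, `subset`, `n_subjects`,
#'   `mean_r`, `ci_lo`, `ci_hi`.
#' @export
summarize_reliability <- function(records, n_boot = 10000, conf = 0.95,
                                  seed = 1) {
  stopifnot(all(c("subject_id", "group", "subset", "r_split") %in%
                  names(records)))
  with_seed(seed, {
    combos <- unique(records[, c("group", "subset")])
    out <- lapply(seq_len(nrow(combos)), function(i) {
      rec <- records[records$group == combos$group[i] &
                       records$subset == combos$subset[i], ]
      subj <- split(rec$r_split, rec$subject_id)
      means <- replicate(n_boot, {
        pick <- sample(length(subj), replace = TRUE)
        mean(unlist(subj[pick]))
      })
      qs <- stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                            names = FALSE)
      data.frame(group = combos$group[i], subset = combos$subset[i],
                 n_subjects = length(subj), mean_r = mean(rec$r_split),
                 ci_lo = qs[1], ci_hi = qs[2], stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
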