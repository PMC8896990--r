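#' Configuration of a synthetic longitudinal rs-fMRI cohort
#'
#' Describes the generative world the analysis assumes: every subject owns a
#' Fisher-Z connectivity pattern equal to the population ground truth plus a
#' Gaussian idiosyncratic perturbation (larger SD in patients), optionally
#' plus a fixed group-difference pattern of given Euclidean norm for
#' patients; each session re-perturbs the pattern, and the scan itself is a
#' zero-mean multivariate AR(1) process whose stationary correlation is the
#' back-transformed (and, if needed, positive-definite-repaired) pattern.
#'
#' Defaults mirror the emulated study design: 19 patients, 11 controls,
#' five sessions at weeks 1/4/12/24/52, 210 volumes at TR = 2 s, and ~11%
#' of non-enrollment sessions missing. The subject/session SDs are
#' calibrated so that the within-group pattern variabilities (mean member
#' distance to the group mean, 45-weight patterns) match the published
#' week-1 values of ~2.96 (patients) and ~2.81 (controls).
#'
#' @param n_patients,n_controls Group sizes.
#' @param sessions Ordered character vector of week labels.
#' @param n_volumes Volumes per scan (T).
#' @param tr_seconds TR in seconds.
#' @param ground_truth_z Numeric 45-vector of population Fisher-Z weights;
#'   every `tanh(z)` must lie in (-1, 1).
#' @param subject_sd_patient,subject_sd_control SD of the per-subject
#'   Fisher-Z perturbation.
#' @param session_sd SD of the additional per-session perturbation.
#' @param ar1_phi Temporal AR(1) coefficient, in [0, 1), common to all ROIs.
#' @param injected_difference_norm Euclidean norm of the fixed
#'   patient-minus-control Fisher-Z offset pattern; 0 is the null world.
#' @param missing_rate Probability that a non-first session is absent; the
#'   first (enrollment) session is never dropped.
#' @param roi_noise_sd SD of additive white observation noise on the ROI
#'   means, relative to the unit-variance latent signal. 0 (default) keeps
#'   the generator unbiased; positive values lower the effective SNR and
#'   with it split-half reliability.
#' @param voxels_per_roi Voxels per ROI for voxel mode (0 = ROI mode only).
#' @param voxel_signal_fraction Fraction of voxel variance carried by the
#'   ROI signal in voxel mode, in (0, 1].
#' @param seed RNG seed; identical seeds give bit-identical cohorts.
#' @return An object of class `cohort_config` (validated list).
#' @seealso [generate_cohort()], [default_ground_truth()]
#' @export
cohort_config <- function(n_patients = 19, n_controls = 11,
                          sessions = c("W1", "W4", "W12", "W24", "W52"),
                          n_volumes = 210, tr_seconds = 2,
                          ground_truth_z = default_ground_truth(),
                          subject_sd_patient = 0.43,
                          subject_sd_control = 0.42,
                          session_sd = 0.1, ar1_phi = 0.3,
                          injected_difference_norm = 0,
                          missing_rate = 0.11,
                          roi_noise_sd = 0,
                          voxels_per_roi = 0,
                          voxel_signal_fraction = 0.7,
                          seed = 1) {
  stopifnot_scalar_number(n_patients, "n_patients", min = 1)
  stopifnot_scalar_number(n_controls, "n_controls", min = 1)
  stopifnot(is.character(sessions), length(sessions) >= 1,
            !anyDuplicated(sessions))
  stopifnot_scalar_number(n_volumes, "n_volumes", min = 2)
  stopifnot_scalar_number(tr_seconds, "tr_seconds", min = 0)
  if (length(ground_truth_z) != 45L || !all(is.finite(ground_truth_z))) {
    stop("`ground_truth_z` must be a finite 45-vector", call. = FALSE)
  }
  if (any(abs(tanh(ground_truth_z)) >= 1)) {
    stop("every tanh(ground_truth_z) must lie in (-1, 1)", call. = FALSE)
  }
  stopifnot_scalar_number(subject_sd_patient, "subject_sd_patient", min = 0)
  stopifnot_scalar_number(subject_sd_control, "subject_sd_control", min = 0)
  stopifnot_scalar_number(session_sd, "session_sd", min = 0)
  stopifnot_scalar_number(ar1_phi, "ar1_phi", min = 0)
  if (ar1_phi >= 1) stop("`ar1_phi` must be in [0, 1)", call. = FALSE)
  stopifnot_scalar_number(injected_difference_norm,
                          "injected_difference_norm", min = 0)
  stopifnot_scalar_number(missing_rate, "missing_rate", min = 0)
  if (missing_rate >= 1) stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  stopifnot_scalar_number(roi_noise_sd, "roi_noise_sd", min = 0)
  stopifnot_scalar_number(voxels_per_roi, "voxels_per_roi", min = 0)
  stopifnot_scalar_number(voxel_signal_fraction, "voxel_signal_fraction",
                          min = 0)
  if (voxel_signal_fraction <= 0 || voxel_signal_fraction > 1) {
    stop("`voxel_signal_fraction` must be in (0, 1]", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 sessions = sessions, n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds, ground_truth_z = ground_truth_z,
                 subject_sd_patient = subject_sd_patient,
                 subject_sd_control = subject_sd_control,
                 session_sd = session_sd, ar1_phi = ar1_phi,
                 injected_difference_norm = injected_difference_norm,
                 missing_rate = missing_rate, roi_noise_sd = roi_noise_sd,
                 voxels_per_roi = as.integer(voxels_per_roi),
                 voxel_signal_fraction = voxel_signal_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$n_patients, " patients + ", x$n_controls,
      " controls, sessions ", paste(x$sessions, collapse = "/"),
      ", T = ", x$n_volumes, " @ TR ", x$tr_seconds, " s\n",
      "  subject SD p/c = ", x$subject_sd_patient, "/", x$subject_sd_control,
      ", session SD = ", x$session_sd, ", AR(1) phi = ", x$ar1_phi, "\n",
      "  injected norm = ", x$injected_difference_norm,
      ", missing rate = ", x$missing_rate,
      ", voxels/ROI = ", x$voxels_per_roi, ", seed = ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Random unit direction in pattern space
#'
#' Standard-normal draw scaled to Euclidean norm 1; used as the direction of
#' an injected group-difference pattern ("normally distributed across all
#' connection weights").
#'
#' @param dim Dimension (>= 1).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Numeric unit vector of length `dim`.
#' @export
inject_direction <- function(dim, seed = NULL) {
  if (!is.numeric(dim) || length(dim) != 1L || dim < 1) {
    stop("`dim` must be >= 1", call. = FALSE)
  }
  with_seed(seed, {
    repeat {
      g <- stats::rnorm(dim)
      n <- sqrt(sum(g^2))
      if (n > 0) break  # astronomically unlikely to loop
    }
    g / n
  })
}

# Project a symmetric matrix to a positive-definite correlation matrix by
# eigenvalue clipping at `floor_ev` followed by re-normalization to unit
# diagonal, iterated. The re-normalization can keep the smallest eigenvalue
# marginally below the clip floor, so after the loop any numerically
# positive-definite result (min eigenvalue >= floor_ev / 100) is accepted.
nearest_pd_corr <- function(m, floor_ev = 1e-6, max_iter = 200L,
                            context = "matrix") {
  for (i in seq_len(max_iter)) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) >= floor_ev && max(abs(diag(m) - 1)) < 1e-12) return(m)
    ev <- pmax(e$values, floor_ev)
    m <- e$vectors %*% (ev * t(e$vectors))
    m <- stats::cov2cor(m)
    m <- (m + t(m)) / 2
  }
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) >=
        floor_ev / 100) {
    return(m)
  }
  stop("could not repair ", context,
       " to a positive-definite correlation matrix", call. = FALSE)
}

# Fisher-Z 45-vector -> PD correlation matrix (tanh entrywise, repair)
z_to_corr <- function(z, context = "pattern") {
  r <- vec_to_mat(tanh(z), diag_value = 1)
  e <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (e < 1e-6) r <- nearest_pd_corr(r, context = context)
  r
}

# T samples of a zero-mean multivariate AR(1) process with stationary
# correlation `R` and common coefficient `phi`.
sim_ar1 <- function(n_volumes, R, phi) {
  L <- chol(R)
  k <- ncol(R)
  E <- matrix(stats::rnorm(n_volumes * k), n_volumes, k) %*% L
  if (phi == 0) return(E)
  X <- matrix(0, n_volumes, k)
  X[1, ] <- E[1, ]
  s <- sqrt(1 - phi^2)
  for (t in 2:n_volumes) X[t, ] <- phi * X[t - 1, ] + s * E[t, ]
  X
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws every subject's Fisher-Z pattern, per-session re-perturbations, and
#' ROI-level (optionally voxel-level) BOLD time series according to a
#' [cohort_config()]. Patients additionally receive a fixed offset pattern:
#' one unit direction per cohort scaled to `injected_difference_norm`.
#' Lesion side alternates left/right across patients. Sessions after the
#' first are dropped independently with probability `missing_rate`.
#' Bit-reproducible given the config seed.
#'
#' @param config A [cohort_config()].
#' @return List of [roi_timeseries()] objects, one per emitted
#'   subject-session, with attribute `"config"` (the config) and
#'   `"injected_offset"` (the 45-vector added to patients, all zero in the
#'   null world).
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 2, n_controls = 2, sessions = "W1",
#'                      n_volumes = 40, seed = 7)
#' cohort <- generate_cohort(cfg)
#' length(cohort)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    offset <- if (config$injected_difference_norm > 0) {
      config$injected_difference_norm * inject_direction(45L)
    } else {
      numeric(45)
    }
    subjects <- data.frame(
      subject_id = c(sprintf("P%02d", seq_len(config$n_patients)),
                     sprintf("C%02d", seq_len(config$n_controls))),
      group = rep(c("patient", "control"),
                  c(config$n_patients, config$n_controls)),
      lesion_side = c(rep_len(c("left", "right"), config$n_patients),
                      rep("none", config$n_controls)),
      stringsAsFactors = FALSE)
    out <- list()
    for (s in seq_len(nrow(subjects))) {
      grp <- subjects$group[s]
      sd_subj <- if (grp == "patient") config$subject_sd_patient else
        config$subject_sd_control
      subj_z <- config$ground_truth_z + stats::rnorm(45, sd = sd_subj)
      if (grp == "patient") subj_z <- subj_z + offset
      for (w in seq_along(config$sessions)) {
        drop_it <- w > 1L &&
          stats::runif(1) < config$missing_rate
        sess_z <- subj_z + stats::rnorm(45, sd = config$session_sd)
        if (drop_it) next
        R <- z_to_corr(sess_z,
                       context = paste0("subject ", subjects$subject_id[s],
                                        " session ",
                                        config$sessions[w], " pattern"))
        X <- sim_ar1(config$n_volumes, R, config$ar1_phi)
        if (config$roi_noise_sd > 0) {
          X <- X + matrix(stats::rnorm(length(X), sd = config$roi_noise_sd),
                          nrow(X), ncol(X))
        }
        voxel_data <- NULL
        if (config$voxels_per_roi > 0) {
          f <- config$voxel_signal_fraction
          voxel_data <- lapply(seq_len(10), function(k) {
            noise <- matrix(stats::rnorm(config$n_volumes *
                                           config$voxels_per_roi),
                            config$n_volumes, config$voxels_per_roi)
            sqrt(f) * X[, k] + sqrt(1 - f) * noise
          })
          names(voxel_data) <- acquisition_roi_names()
        }
        # canonical (ipsi-first) simulation columns -> acquisition order
        side <- subjects$lesion_side[s]
        data <- X
        colnames(data) <- if (side == "right") {
          c(paste0(roi_base_names(), "_right"),
            paste0(roi_base_names(), "_left"))
        } else {
          acquisition_roi_names()
        }
        if (!is.null(voxel_data)) names(voxel_data) <- colnames(data)
        out[[length(out) + 1L]] <- roi_timeseries(
          data = data[, acquisition_roi_names(), drop = FALSE],
          subject_id = subjects$subject_id[s], group = grp,
          lesion_side = side, week = config$sessions[w],
          tr_seconds = config$tr_seconds,
          voxel_data = if (is.null(voxel_data)) NULL else
            voxel_data[acquisition_roi_names()])
      }
    }
    attr(out, "config") <- config
    attr(out, "injected_offset") <- offset
    out
  })
}
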