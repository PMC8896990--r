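#' Configuration of a full analysis run
#'
#' @param manifest Path to a cohort manifest (see [read_cohort()]); may be
#'   `NULL` when a cohort list is handed to [run_pipeline()] directly.
#' @param subsets Pattern subsets to analyze.
#' @param comparisons Analyses to run; any of `"group"` (patients vs
#'   controls per week), `"week"` (within-patient change from the reference
#'   week), `"variability"`, `"equivalence"` (attached to the group tests),
#'   `"reliability"`, `"weights"` (per-subject M1-M1 table), `"relcon"`.
#' @param B Permutation count.
#' @param alpha Significance / equivalence level.
#' @param delta_grid Candidate injected norms for the equivalence test.
#' @param reference_week Reference session for longitudinal comparisons.
#' @param half_length Split-half length for reliability.
#' @param seed RNG seed recorded in every output.
#' @param out_dir Optional output directory for TSV tables and the run log.
#' @param verbose Print stage progress.
#' @return An object of class `run_config`.
#' @export
run_config <- function(manifest = NULL,
                       subsets = subset_choices(),
                       comparisons = c("group", "week", "variability",
                                       "equivalence", "reliability",
                                       "weights"),
                       B = 10000, alpha = 0.05,
                       delta_grid = seq(0.05, 3, by = 0.05),
                       reference_week = "W1", half_length = 100,
                       seed = 1, out_dir = NULL, verbose = TRUE) {
  subsets <- match.arg(subsets, subset_choices(), several.ok = TRUE)
  comparisons <- match.arg(comparisons,
                           c("group", "week", "variability", "equivalence",
                             "reliability", "weights", "relcon"),
                           several.ok = TRUE)
  if (!is.null(manifest) && !file.exists(manifest)) {
    stop("manifest not found: ", manifest, call. = FALSE)
  }
  stopifnot_scalar_number(B, "B", min = 1)
  stopifnot_scalar_number(alpha, "alpha", min = 0)
  structure(list(manifest = manifest, subsets = subsets,
                 comparisons = comparisons, B = as.integer(B),
                 alpha = alpha, delta_grid = delta_grid,
                 reference_week = reference_week,
                 half_length = half_length, seed = as.integer(seed),
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "run_config")
}

stage <- function(name, verbose, expr) {
  if (verbose) message("[connpattern] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full connectivity-pattern analysis pipeline
#'
#' Orchestrates connectivity extraction, reliability, the permutation
#' statistics, and (in voxel mode) RelCon over a cohort, producing tidy
#' result tables: group comparisons per week and subset (with equivalence
#' bounds and effect sizes), within-patient week comparisons, variability
#' tests per week, the week-variability ANOVA on complete-case patients,
#' reliability summaries, and the per-subject M1-M1 / RelCon longitudinal
#' tables. Controls' patterns are hemisphere-averaged and session-averaged
#' for group comparisons. Results are unadjusted for multiplicity across
#' subsets and weeks. Deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @param cohort Optional list of [roi_timeseries()]; when `NULL` the
#'   cohort is read from `config$manifest`.
#' @return A `connpattern_report`: list of data.frames (`group_tests`,
#'   `week_tests`, `variability_tests`, `week_anova`, `reliability`,
#'   `reliability_summary`, `m1_weights`, `relcon`), the serialized null
#'   distributions (`nulls`), and a `log` with seed, B and version. When
#'   `config$out_dir` is set the tables are also written as TSV.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  vb <- config$verbose
  cohort <- stage("read_cohort", vb, {
    if (is.null(cohort)) {
      if (is.null(config$manifest)) {
        stop("no cohort given and no manifest configured")
      }
      read_cohort(config$manifest)
    } else cohort
  })

  patterns <- stage("connectivity", vb, lapply(cohort, compute_pattern))
  groups <- vapply(patterns, function(p) p$group, character(1))
  weeks <- vapply(patterns, function(p) p$week, character(1))
  week_levels <- unique(weeks)
  pat <- patterns[groups == "patient"]
  ctl <- patterns[groups == "control"]

  nulls <- list()
  keep_null <- function(label, subset, x) {
    nulls[[paste(label, subset, sep = "|")]] <<- x
    invisible(NULL)
  }

  # controls: one hemisphere-averaged pattern per subject, averaged over
  # sessions (stability across sessions is assumed established)
  ctl_avg <- stage("control_averaging", vb, {
    ids <- unique(pattern_ids(ctl))
    lapply(ids, function(id) {
      own <- ctl[pattern_ids(ctl) == id]
      average_pattern(own, control_hemisphere_average = TRUE)
    })
  })

  group_tests <- NULL
  if ("group" %in% config$comparisons && length(pat) && length(ctl_avg)) {
    group_tests <- stage("group_tests", vb, {
      rows <- list()
      for (w in week_levels) {
        pw <- pat[vapply(pat, function(p) p$week, character(1)) == w]
        if (!length(pw)) next
        for (ss in config$subsets) {
          pt <- delta_pattern_test(pw, ctl_avg, subset = ss, B = config$B,
                                   seed = config$seed,
                                   comparison_label =
                                     paste0("patients-vs-controls ", w))
          keep_null(pt$comparison_label, ss, pt$null_distribution)
          row <- data.frame(comparison = pt$comparison_label, week = w,
                            subset = ss, delta = pt$observed_delta,
                            p = pt$p_value, n_patients = pt$n_groupA,
                            n_controls = pt$n_groupB,
                            delta_star = NA_real_, d = NA_real_,
                            stringsAsFactors = FALSE)
          if ("equivalence" %in% config$comparisons) {
            eq <- equivalence_test(pw, ctl_avg,
                                   observed_delta = pt$observed_delta,
                                   B = config$B, alpha = config$alpha,
                                   delta_grid = config$delta_grid,
                                   seed = config$seed, subset = ss)
            row$delta_star <- eq$delta_star_rejectable
            row$d <- eq$cohens_d_equivalent
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
      do.call(rbind, rows)
    })
  }

  week_tests <- NULL
  if ("week" %in% config$comparisons && length(pat)) {
    week_tests <- stage("week_tests", vb, {
      rows <- list()
      for (ss in config$subsets) {
        res <- longitudinal_deltas(pat,
                                   reference_week = config$reference_week,
                                   B = config$B, seed = config$seed,
                                   subset = ss)
        for (w in names(res)) {
          pt <- res[[w]]
          keep_null(paste0("patients ", pt$comparison_label), ss,
                    pt$null_distribution)
          rows[[length(rows) + 1L]] <- data.frame(
            comparison = paste0("patients ", pt$comparison_label),
            week = w, subset = ss, delta = pt$observed_delta,
            p = pt$p_value, n = pt$n_groupA, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
  }

  variability_tests <- NULL
  week_anova <- NULL
  if ("variability" %in% config$comparisons && length(pat) &&
        length(ctl_avg) >= 2) {
    variability_tests <- stage("variability_tests", vb, {
      rows <- list()
      for (w in week_levels) {
        pw <- pat[vapply(pat, function(p) p$week, character(1)) == w]
        if (length(pw) < 2) next
        for (ss in config$subsets) {
          vt <- variability_test(pw, ctl_avg, B = config$B,
                                 seed = config$seed, subset = ss)
          keep_null(paste0("variability ", w), ss, vt$null_distribution)
          rows[[length(rows) + 1L]] <- data.frame(
            week = w, subset = ss,
            p_variability = vt$group_variability_A,
            c_variability = vt$group_variability_B,
            delta_variability = vt$delta_variability, p = vt$p_value,
            direction = vt$direction, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
    week_anova <- stage("week_anova", vb, {
      rows <- list()
      for (ss in config$subsets) {
        tab <- week_distance_table(pat,
                                   reference_week = config$reference_week,
                                   subset = ss)
        if (nrow(tab) >= 2 && ncol(tab) >= 2) {
          an <- week_variability_anova(tab)
          rows[[length(rows) + 1L]] <- data.frame(
            subset = ss, F = an$F, df1 = an$df1, df2 = an$df2,
            p = an$p_value, n_complete = an$n_subjects,
            stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
  }

  reliability_records <- NULL
  reliability_summary <- NULL
  if ("reliability" %in% config$comparisons) {
    reliability_records <- stage("reliability", vb, {
      ok <- vapply(cohort, function(ts)
        nrow(ts$data) >= 2 * config$half_length, logical(1))
      if (!any(ok)) NULL else
        do.call(rbind, lapply(cohort[ok], split_half,
                              half_length = config$half_length))
    })
    if (!is.null(reliability_records)) {
      reliability_summary <- stage("reliability_summary", vb,
        summarize_reliability(reliability_records,
                              n_boot = min(config$B, 10000),
                              seed = config$seed))
    }
  }

  m1_weights <- NULL
  if ("weights" %in% config$comparisons) {
    m1_weights <- stage("m1_weights", vb, {
      do.call(rbind, lapply(patterns, function(p) {
        data.frame(subject_id = p$subject_id, group = p$group,
                   week = p$week,
                   m1_m1_z = extract_weight(p, "M1_ipsi", "M1_contra"),
                   stringsAsFactors = FALSE)
      }))
    })
  }

  relcon_table <- NULL
  has_vox <- any(vapply(cohort, function(ts) !is.null(ts$voxel_data),
                        logical(1)))
  if ("relcon" %in% config$comparisons && has_vox) {
    relcon_table <- stage("relcon", vb, {
      do.call(rbind, lapply(cohort, function(ts) {
        if (is.null(ts$voxel_data)) return(NULL)
        r <- relcon_from_timeseries(ts)
        data.frame(subject_id = r$subject_id, group = ts$group,
                   week = r$week, inter_mean = r$inter_mean,
                   within_mean = r$within_mean, relcon = r$relcon,
                   stringsAsFactors = FALSE)
      }))
    })
  }

  log <- list(seed = config$seed, B = config$B, alpha = config$alpha,
              package_version =
                as.character(utils::packageVersion("connpattern")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              n_sessions = length(cohort),
              multiplicity = "p-values unadjusted across subsets and weeks",
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  report <- structure(list(group_tests = group_tests,
                           week_tests = week_tests,
                           variability_tests = variability_tests,
                           week_anova = week_anova,
                           reliability = reliability_records,
                           reliability_summary = reliability_summary,
                           m1_weights = m1_weights, relcon = relcon_table,
                           nulls = nulls, patterns = patterns, log = log),
                      class = "connpattern_report")

  if (!is.null(config$out_dir)) {
    stage("write_outputs", vb, write_report(report, config$out_dir))
  }
  report
}

# write the report's tables, null distributions and run log as text files
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("group_tests", "week_tests", "variability_tests", "week_anova",
            "reliability", "reliability_summary", "m1_weights", "relcon")
  for (nm in tabs) {
    if (!is.null(report[[nm]])) {
      utils::write.table(report[[nm]],
                         file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (length(report$patterns)) {
    utils::write.table(pattern_table(report$patterns),
                       file.path(out_dir, "pattern_weights.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(report$nulls)) {
    long <- do.call(rbind, lapply(names(report$nulls), function(k) {
      data.frame(key = k, value = report$nulls[[k]],
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(long, file.path(out_dir, "null_distributions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(jsonlite::toJSON(report$log, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "run_log.json"))
  invisible(out_dir)
}

#' @export
print.connpattern_report <- function(x, ...) {
  cat("<connpattern_report> seed ", x$log$seed, ", B = ", x$log$B,
      ", ", x$log$n_sessions, " sessions\n", sep = "")
  for (nm in c("group_tests", "week_tests", "variability_tests",
               "week_anova", "reliability_summary")) {
    if (!is.null(x[[nm]])) {
      cat("-- ", nm, " (", nrow(x[[nm]]), " rows)\n", sep = "")
    }
  }
  cat("note: ", x$log$multiplicity, "\n", sep = "")
  invisible(x)
}
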