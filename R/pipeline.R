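#' Pipeline run configuration
#'
#' Describes one full analysis run: the cohort source (either a preset +
#' size + seed, or paths to an events file and a scored-cohort table),
#' the diagnostic horizons, the cut-off probabilities, the positivity
#' convention, an optional subgroup filter and the output directory.
#'
#' @param preset_label Optional `"training_like"`/`"validation_like"`:
#'   generate the cohort instead of reading files.
#' @param n_patients,seed Size and seed for the generated cohort.
#' @param events_path,cohort_path Input files when not using a preset
#'   (see [read_cohort]).
#' @param horizons Diagnostic horizons in days (default 90 and 365).
#' @param cutoff_probs Cut-off probabilities, strictly in (0, 1), sorted
#'   (default quartiles + ninth decile).
#' @param ge Positivity at `score >= cutoff` (default `FALSE`: strict
#'   `>`).
#' @param subgroup Optional filter expression over cohort columns, as a
#'   character string (e.g. `"donor_age >= 70"` for the aged-donor
#'   sub-analysis).
#' @param out_dir Output directory for the report bundle.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(preset_label = NULL, n_patients = 2000, seed = 1L,
                       events_path = NULL, cohort_path = NULL,
                       horizons = c(90, 365),
                       cutoff_probs = c(0.25, 0.5, 0.75, 0.90),
                       ge = FALSE, subgroup = NULL, out_dir = NULL) {
  if (is.null(preset_label) && (is.null(events_path) ||
                                is.null(cohort_path))) {
    stop("either 'preset_label' or both input paths must be given")
  }
  if (any(horizons <= 0)) stop("horizons must be positive")
  if (any(cutoff_probs <= 0 | cutoff_probs >= 1) ||
      is.unsorted(cutoff_probs, strictly = TRUE)) {
    stop("cutoff_probs must be strictly between 0 and 1 and increasing")
  }
  structure(list(preset_label = preset_label, n_patients = n_patients,
                 seed = as.integer(seed), events_path = events_path,
                 cohort_path = cohort_path, horizons = horizons,
                 cutoff_probs = cutoff_probs, ge = ge,
                 subgroup = subgroup, out_dir = out_dir),
            class = "run_config")
}

#' Read and validate cohort tables
#'
#' Reads the complication-events file and the scored-cohort table,
#' collecting every schema violation (unknown grades, negative times,
#' duplicated patient ids in the outcome table, missing columns) and
#' reporting them together; any violation aborts. Event days exceeding a
#' patient's follow-up time produce a warning, not an error.
#'
#' @param events_path CSV with columns patient_id, grade, optional
#'   label/day. Lines starting with `#` are ignored.
#' @param cohort_path CSV with columns patient_id, time_days, graft_loss
#'   and any score/covariate columns (cci is recomputed from the events,
#'   never trusted from the file).
#' @return List with validated `events` and `cohort` data frames.
#' @export
read_cohort <- function(events_path, cohort_path) {
  errs <- character(0)
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE,
                        comment.char = "#")
  co <- utils::read.csv(cohort_path, stringsAsFactors = FALSE,
                        comment.char = "#")
  for (col in c("patient_id", "grade")) {
    if (!col %in% names(ev)) {
      errs <- c(errs, sprintf("events file: missing column '%s'", col))
    }
  }
  for (col in c("patient_id", "time_days", "graft_loss")) {
    if (!col %in% names(co)) {
      errs <- c(errs, sprintf("cohort file: missing column '%s'", col))
    }
  }
  if ("grade" %in% names(ev)) {
    bad <- which(!ev$grade %in% cd_grade_levels())
    if (length(bad)) {
      errs <- c(errs, sprintf(
        "events file row %d: unknown grade '%s'", bad, ev$grade[bad]))
    }
  }
  if ("day" %in% names(ev)) {
    bad <- which(!is.na(ev$day) & ev$day < 0)
    if (length(bad)) {
      errs <- c(errs,
                sprintf("events file row %d: negative day %s", bad,
                        ev$day[bad]))
    }
  }
  if ("time_days" %in% names(co)) {
    bad <- which(!is.na(co$time_days) & co$time_days <= 0)
    if (length(bad)) {
      errs <- c(errs, sprintf(
        "cohort file row %d: non-positive follow-up time %s", bad,
        co$time_days[bad]))
    }
  }
  if ("patient_id" %in% names(co)) {
    dup <- unique(co$patient_id[duplicated(co$patient_id)])
    if (length(dup)) {
      errs <- c(errs, sprintf(
        "cohort file: duplicated patient id '%s'", dup))
    }
  }
  if (length(errs)) {
    stop("cohort input validation failed:\n  ",
         paste(errs, collapse = "\n  "))
  }
  if (all(c("day", "patient_id") %in% names(ev)) &&
      "time_days" %in% names(co)) {
    fu <- co$time_days[match(ev$patient_id, co$patient_id)]
    late <- which(!is.na(ev$day) & !is.na(fu) & ev$day > fu)
    if (length(late)) {
      warning(length(late),
              " event(s) recorded after the patient's follow-up time")
    }
  }
  list(events = ev, cohort = co)
}

#' Run the full scoring / diagnostics / survival pipeline
#'
#' Composes the whole analysis on a real or synthetic cohort: (a) CCI per
#' patient from the event table; (b) per-horizon diagnostic tables for
#' CCI, MELD, D-MELD, BAR and the EAD flag, with quantile cut-off rows
#' for the CCI; (c) the same re-run on a subgroup when requested; (d)
#' Kaplan-Meier curves and a log-rank test over the five CCI risk strata;
#' (e) univariable and backward-Wald multivariable Cox summaries; (f) a
#' run log with seed and exclusion counts. Reports are written as
#' delimited text only after every stage succeeded, so a failed run
#' leaves no partial bundle.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with components `scores`, `diagnostics` (one
#'   list of [diagnostic_table]s per horizon), `km`, `logrank`,
#'   `cox_univariable`, `cox_multivariable`, `subgroup` (same shape,
#'   or NULL), `log` (character). Written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- c(sprintf("ccindex pipeline run, seed=%d", config$seed),
                 sprintf("R %s, ccindex %s", getRversion(),
                         as.character(utils::packageVersion("ccindex"))))
  if (!is.null(config$preset_label)) {
    cc <- preset(config$preset_label, n_patients = config$n_patients,
                 seed = config$seed)
    syn <- generate_cohort(cc)
    events <- syn$events
    cohort <- syn$cohort
    log_lines <- c(log_lines, sprintf("cohort: preset %s, n=%d",
                                      config$preset_label,
                                      config$n_patients))
  } else {
    inp <- read_cohort(config$events_path, config$cohort_path)
    events <- inp$events
    cohort <- inp$cohort
    log_lines <- c(log_lines, sprintf("cohort: %s (%d patients)",
                                      config$cohort_path, nrow(cohort)))
  }

  # single scoring path: CCI always (re)computed from the events
  scored <- score_cohort(events, patient_ids = cohort$patient_id)
  cohort$cci <- scored$cci[match(cohort$patient_id, scored$patient_id)]

  if (!is.null(config$subgroup)) {
    keep <- eval(parse(text = config$subgroup),
                 envir = cohort, enclos = baseenv())
    if (!any(keep)) {
      stop("empty subgroup: no patient satisfies '", config$subgroup, "'")
    }
    log_lines <- c(log_lines,
                   sprintf("subgroup '%s': %d of %d patients",
                           config$subgroup, sum(keep), nrow(cohort)))
  }

  analyse <- function(co) {
    score_cols <- intersect(c("cci", "meld", "d_meld", "bar", "ead"),
                            names(co))
    cci_cuts <- quantile_cutoffs(co$cci, config$cutoff_probs)
    diags <- lapply(config$horizons, function(h) {
      compare_scores(co[score_cols], co$time_days, co$graft_loss, h,
                     cutoffs = list(cci = cci_cuts), ge = config$ge)
    })
    names(diags) <- paste0("day", config$horizons)
    strata <- cci_strata(co$cci)
    km <- km_fit(co$time_days, co$graft_loss, group = strata)
    lr <- if (nlevels(droplevels(strata)) >= 2) {
      logrank_test(co$time_days, co$graft_loss, strata)
    } else NULL
    covs <- intersect(c("donor_age", "meld", "d_meld", "bar", "ead",
                        "cci"), names(co))
    sdf <- data.frame(time = co$time_days, event = co$graft_loss, co)
    sdf$d_meld <- sdf$d_meld / 100   # HR reported per 100 D-MELD points
    uni <- cox_univariable(sdf, covs)
    cand <- uni$covariate[uni$p_value < 0.20]
    multi <- if (length(cand)) backward_wald_select(sdf, cand) else NULL
    list(diagnostics = diags, km = km, logrank = lr, strata = strata,
         cox_univariable = uni, cox_multivariable = multi,
         cutoffs = cci_cuts)
  }

  main <- analyse(cohort)
  sub <- if (!is.null(config$subgroup)) {
    keep <- eval(parse(text = config$subgroup),
                 envir = cohort, enclos = baseenv())
    analyse(cohort[keep, , drop = FALSE])
  } else NULL

  for (h in names(main$diagnostics)) {
    excl <- main$diagnostics[[h]][[1]]
    log_lines <- c(log_lines,
                   sprintf("%s: %d events / %d non-events", h,
                           excl$n_events, excl$n_nonevents))
  }

  result <- list(scores = scored, cohort = cohort,
                 diagnostics = main$diagnostics, km = main$km,
                 logrank = main$logrank, strata = main$strata,
                 cox_univariable = main$cox_univariable,
                 cox_multivariable = main$cox_multivariable,
                 cutoffs = main$cutoffs, subgroup = sub, log = log_lines)
  if (!is.null(config$out_dir)) write_reports(result, config)
  invisible(result)
}

# Format a diagnostic-table list as one data frame (report shape:
# AUC to 2 decimals, percentages and DOR to 1).
diagnostics_report <- function(tabs) {
  do.call(rbind, lapply(tabs, function(t) {
    head <- data.frame(score = t$name,
                       auc = sprintf("%.2f", t$auc),
                       se = sprintf("%.2f", t$se),
                       ci = sprintf("%.2f-%.2f", t$ci[1], t$ci[2]),
                       cutoff = NA_character_, sens = NA_character_,
                       spec = NA_character_, dor = NA_character_,
                       stringsAsFactors = FALSE)
    if (nrow(t$rows)) {
      rows <- data.frame(score = t$name, auc = NA_character_,
                         se = NA_character_, ci = NA_character_,
                         cutoff = sprintf("%.1f", t$rows$cutoff),
                         sens = sprintf("%.1f", 100 * t$rows$sensitivity),
                         spec = sprintf("%.1f", 100 * t$rows$specificity),
                         dor = sprintf("%.1f", t$rows$dor),
                         stringsAsFactors = FALSE)
      head <- rbind(head, rows)
    }
    head
  }))
}

write_reports <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
  }
  wr(result$scores, "cci_scores.csv")
  for (h in names(result$diagnostics)) {
    wr(diagnostics_report(result$diagnostics[[h]]),
       paste0("diagnostics_", h, ".csv"))
  }
  km <- as.data.frame(result$km)
  wr(km, "km_strata.csv")
  wr(result$cox_univariable, "cox_univariable.csv")
  if (!is.null(result$cox_multivariable) &&
      !is.null(result$cox_multivariable$model)) {
    wr(result$cox_multivariable$model$table, "cox_multivariable.csv")
  }
  if (!is.null(result$subgroup)) {
    for (h in names(result$subgroup$diagnostics)) {
      wr(diagnostics_report(result$subgroup$diagnostics[[h]]),
         paste0("diagnostics_subgroup_", h, ".csv"))
    }
  }
  if (!is.null(result$logrank)) {
    writeLines(sprintf("logrank chisq=%.4f df=%d p=%.3g",
                       result$logrank$chisq, result$logrank$df,
                       result$logrank$p_value),
               file.path(config$out_dir, "logrank.txt"))
  }
  writeLines(result$log, file.path(config$out_dir, "run_log.txt"))
  invisible(NULL)
}
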