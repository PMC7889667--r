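# Round half away from zero, the convention used for displayed index
# values (base round() rounds half to even).
round_display <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Comprehensive complication index for one patient
#'
#' Computes CCI = sqrt(wC1 + wC2 + ... + wCx) / 2 over every graded
#' complication of a single patient's course, where wC is the per-grade
#' weight of `cci_weights()`. Every event counts, including repeats of the
#' same complication or treatment. The index lives on a 0 (no
#' complication) to 100 (death) scale: any grade V event forces the value
#' 100 exactly, and sums that would exceed the scale are capped at 100.
#'
#' The returned value is unrounded; reports display it at one decimal
#' (`round_display`), which reproduces the printed single-event values
#' 8.7, 20.9, 26.2, 33.7, 42.4, 46.2 and 100 for the seven grades.
#'
#' @param events Data frame of the patient's complications with columns
#'   `patient_id`, `grade` and optionally `day` (days post-transplant);
#'   or a bare character vector of grades. Zero rows mean an uneventful
#'   course.
#' @param weights A `cci_weights` table.
#' @param day_cutoff Optional non-negative number: when given and `events`
#'   has a `day` column, only events with `day <= day_cutoff` (or missing
#'   day) are scored. Used to restrict scoring to the first post-transplant
#'   hospitalization.
#' @return Object of class `"cci_score"`: list with `patient_id`, `value`
#'   (unrounded, in \[0, 100\]), `display` (one decimal) and `n_events`.
#' @export
#' @examples
#' compute_cci(c("II", "II"))          # 29.6 at one decimal
#' compute_cci(c("IVa", "IIIb"))       # retransplantation composite, 54.2
#' compute_cci(character(0))           # 0: no complication
compute_cci <- function(events, weights = cci_weights(), day_cutoff = NULL) {
  if (is.character(events) || is.factor(events)) {
    events <- data.frame(patient_id = rep(NA_character_, length(events)),
                         grade = as.character(events),
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(events), "grade" %in% names(events))
  if (!inherits(weights, "cci_weights")) {
    stop("'weights' must be a cci_weights table")
  }
  ids <- unique(events$patient_id[!is.na(events$patient_id)])
  if (length(ids) > 1L) {
    stop("events mix patient ids: ", paste(ids, collapse = ", "),
         "; compute_cci scores one patient at a time")
  }
  pid <- if (length(ids) == 1L) ids else NA_character_
  if (!is.null(day_cutoff) && "day" %in% names(events)) {
    if (day_cutoff < 0) stop("'day_cutoff' must be non-negative")
    keep <- is.na(events$day) | events$day <= day_cutoff
    events <- events[keep, , drop = FALSE]
  }
  g <- cd_grade(events$grade)
  if (anyNA(g)) stop("missing grade in events")
  n <- length(g)
  if (n == 0L) {
    value <- 0
  } else if (any(g == "V")) {
    value <- 100   # death override: the scale ends at 100 (death)
  } else {
    w <- weights$weight[match(as.character(g), weights$grade)]
    value <- min(100, sqrt(sum(w)) / 2)
  }
  structure(list(patient_id = pid, value = value,
                 display = round_display(value, 1), n_events = n),
            class = "cci_score")
}

#' @export
print.cci_score <- function(x, ...) {
  id <- if (is.na(x$patient_id)) "" else paste0(" [", x$patient_id, "]")
  cat(sprintf("CCI%s: %.1f (%d complication%s)\n", id, x$display,
              x$n_events, if (x$n_events == 1L) "" else "s"))
  invisible(x)
}

#' Score a whole cohort
#'
#' Applies `compute_cci` per patient over a long event table. Patients
#' listed in `patient_ids` but absent from the event table receive CCI 0
#' (no complication).
#'
#' @param events Data frame with columns `patient_id`, `grade`, optional
#'   `day`.
#' @param patient_ids Optional vector of all patient ids in the cohort
#'   (defaults to the ids present in `events`).
#' @inheritParams compute_cci
#' @return Data frame with one row per patient: `patient_id`, `cci`
#'   (unrounded), `cci_display`, `n_events`, `highest_grade`.
#' @export
score_cohort <- function(events, patient_ids = NULL,
                         weights = cci_weights(), day_cutoff = NULL) {
  stopifnot(is.data.frame(events),
            all(c("patient_id", "grade") %in% names(events)))
  if (is.null(patient_ids)) patient_ids <- unique(events$patient_id)
  patient_ids <- as.character(patient_ids)
  split_ev <- split(events, factor(as.character(events$patient_id),
                                   levels = patient_ids))
  rows <- lapply(patient_ids, function(pid) {
    ev <- split_ev[[pid]]
    if (is.null(ev)) ev <- events[0, , drop = FALSE]
    sc <- compute_cci(ev, weights = weights, day_cutoff = day_cutoff)
    hg <- highest_grade(ev$grade)
    data.frame(patient_id = pid, cci = sc$value, cci_display = sc$display,
               n_events = sc$n_events,
               highest_grade = as.character(hg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a complication-event table
#'
#' Reads a delimited text file with columns `patient_id`, `grade` and
#' optionally `label` and `day`, validating grades and day values.
#'
#' @param path Path to a CSV file.
#' @return Validated data frame of complication events.
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "grade")
  miss <- setdiff(req, names(ev))
  if (length(miss)) {
    stop("events file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  cd_grade(ev$grade)  # validates, error names the offending labels
  if ("day" %in% names(ev) && any(!is.na(ev$day) & ev$day < 0)) {
    stop("events file ", path, " has negative day values")
  }
  ev
}

#' Expand clinical-event shorthand into graded complications
#'
#' Turns a table of named clinical events (columns `patient_id`,
#' `event_kind`, optional `day`) into graded complication rows via
#' `grade_clinical_event`, e.g. one `retransplantation` row becomes a
#' grade IVa and a grade IIIb row.
#'
#' @param clinical Data frame with columns `patient_id`, `event_kind`,
#'   optional `day`.
#' @return Data frame with columns `patient_id`, `grade`, `label`, `day`.
#' @export
expand_clinical_events <- function(clinical) {
  stopifnot(is.data.frame(clinical),
            all(c("patient_id", "event_kind") %in% names(clinical)))
  day <- if ("day" %in% names(clinical)) clinical$day else
    rep(NA_real_, nrow(clinical))
  rows <- lapply(seq_len(nrow(clinical)), function(i) {
    g <- grade_clinical_event(clinical$event_kind[i])
    data.frame(patient_id = clinical$patient_id[i],
               grade = as.character(g),
               label = clinical$event_kind[i],
               day = day[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), grade = character(0),
                      label = character(0), day = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out
}
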