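#' Dichotomize graft loss at a horizon
#'
#' Builds the binary outcome used for diagnostic evaluation of a score at
#' a fixed horizon (90 days or 1 year): a patient is an event if graft
#' loss occurred at or before the horizon, a non-event if followed beyond
#' the horizon without loss, and excluded if censored loss-free before the
#' horizon (the exclusion count is kept for the run log).
#'
#' @param scores Numeric score per patient (e.g. CCI).
#' @param times Follow-up time in days.
#' @param events Logical/0-1 graft-loss indicator.
#' @param horizon Horizon in days (> 0), typically 90 or 365.
#' @param ids Optional patient ids, carried through.
#' @return Object of class `"outcome_set"`: list with `score`, `outcome`
#'   (logical event indicator), `horizon`, `ids` and `n_excluded`.
#' @export
dichotomize_graft_loss <- function(scores, times, events, horizon,
                                   ids = NULL) {
  stopifnot(length(scores) == length(times),
            length(times) == length(events), horizon > 0)
  if (any(times < 0)) stop("follow-up times must be non-negative")
  events <- as.logical(events)
  is_event <- events & times <= horizon
  keep <- is_event | times > horizon
  excluded <- sum(!keep)
  if (!any(keep)) {
    stop("all ", length(scores), " patients censored loss-free before day ",
         horizon, "; no outcome set can be formed")
  }
  structure(list(score = scores[keep], outcome = is_event[keep],
                 horizon = horizon,
                 ids = if (is.null(ids)) NULL else ids[keep],
                 n_excluded = excluded),
            class = "outcome_set")
}

# Internal constructor for pre-dichotomized data.
outcome_set <- function(score, outcome, horizon = NA_real_) {
  structure(list(score = score, outcome = as.logical(outcome),
                 horizon = horizon, ids = NULL, n_excluded = 0L),
            class = "outcome_set")
}

#' ROC area under the curve with DeLong standard error
#'
#' The AUC (C-statistic) is computed as the pairwise concordance
#' probability: the probability that a randomly chosen event-patient
#' outscores a randomly chosen non-event patient, ties counting one half.
#' The standard error uses the DeLong covariance construction on placement
#' values; the 95% CI is AUC +/- 1.96 * SE truncated to \[0, 1\].
#'
#' @param set An `outcome_set` (see [dichotomize_graft_loss]), or a
#'   numeric score vector if `outcome` is supplied.
#' @param outcome Optional logical event indicator when `set` is a bare
#'   numeric vector.
#' @return List with `auc`, `se`, `ci` (length-2), `n_events`,
#'   `n_nonevents`.
#' @export
#' @examples
#' roc_auc(c(3, 1, 2, 0), outcome = c(TRUE, TRUE, FALSE, FALSE))$auc
roc_auc <- function(set, outcome = NULL) {
  if (!inherits(set, "outcome_set")) set <- outcome_set(set, outcome)
  x <- set$score[set$outcome]     # events
  y <- set$score[!set$outcome]    # non-events
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) {
    stop("ROC needs at least one event and one non-event (got ",
         m, " events, ", n, " non-events)")
  }
  # Placement values: V10[i] = P-hat(x_i > Y), V01[j] = P-hat(X > y_j).
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  auc <- mean(psi)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * 1.96 * se))
  list(auc = auc, se = se, ci = ci, n_events = m, n_nonevents = n)
}

#' Quantile cut-offs of a score
#'
#' Sample quantiles by linear interpolation of the order statistics at
#' fractional rank 1 + (n - 1) p (type-7 quantiles), the convention used
#' for the first-quartile / median / third-quartile / ninth-decile
#' cut-offs.
#'
#' @param scores Numeric vector (length >= 2).
#' @param probs Probabilities in (0, 1); default the four report cut-offs.
#' @return Named numeric vector of cut-off values.
#' @export
#' @examples
#' quantile_cutoffs(c(0, 10, 20, 30, 40))
quantile_cutoffs <- function(scores, probs = c(0.25, 0.50, 0.75, 0.90)) {
  if (length(scores) < 2L) stop("need at least two scores for quantiles")
  if (any(probs <= 0 | probs >= 1)) {
    stop("'probs' must lie strictly between 0 and 1")
  }
  stats::quantile(scores, probs = probs, type = 7, names = TRUE)
}

#' Confusion counts at a cut-off
#'
#' Cross-tabulates test positivity against the outcome. By convention a
#' patient is test-positive when the score strictly exceeds the cut-off;
#' set `ge = TRUE` for score >= cut-off instead.
#'
#' @param set An `outcome_set`.
#' @param cutoff Numeric threshold.
#' @param ge Positivity at `score >= cutoff` instead of `>` (default
#'   `FALSE`).
#' @return List with integer counts `tp`, `fp`, `tn`, `fn` and the derived
#'   `sensitivity` and `specificity` proportions.
#' @export
confusion_at_cutoff <- function(set, cutoff, ge = FALSE) {
  stopifnot(inherits(set, "outcome_set"))
  pos <- if (ge) set$score >= cutoff else set$score > cutoff
  tp <- sum(pos & set$outcome)
  fp <- sum(pos & !set$outcome)
  fn <- sum(!pos & set$outcome)
  tn <- sum(!pos & !set$outcome)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Diagnostic odds ratio
#'
#' DOR = (sens * spec) / ((1 - sens) * (1 - spec)), equivalently
#' (tp * tn) / (fp * fn): the odds of test positivity among events over
#' the odds among non-events. Higher values mean greater discriminative
#' power. At boundary sensitivity/specificity (0 or 1) the DOR is reported
#' as `Inf` or `0` with a `boundary` flag; no continuity correction is
#' applied unless `haldane = TRUE` requests the +0.5 adjustment of the
#' underlying counts (only possible when counts are supplied).
#'
#' @param sens,spec Sensitivity and specificity as proportions in
#'   \[0, 1\], or `counts` instead.
#' @param counts Optional list with `tp`, `fp`, `tn`, `fn` (as returned by
#'   [confusion_at_cutoff]); overrides `sens`/`spec`.
#' @param haldane Apply the Haldane-Anscombe +0.5 correction to counts
#'   (default `FALSE`).
#' @return Numeric DOR, with attribute `boundary = TRUE` when a boundary
#'   proportion made it 0 or infinite.
#' @export
#' @examples
#' diagnostic_odds_ratio(0.888, 0.859)  # ~ 48.3
diagnostic_odds_ratio <- function(sens = NULL, spec = NULL, counts = NULL,
                                  haldane = FALSE) {
  if (!is.null(counts)) {
    k <- if (haldane) 0.5 else 0
    tp <- counts$tp + k; fp <- counts$fp + k
    tn <- counts$tn + k; fn <- counts$fn + k
    dor <- (tp * tn) / (fp * fn)
    boundary <- !haldane && (counts$fp == 0 || counts$fn == 0 ||
                             counts$tp == 0 || counts$tn == 0)
  } else {
    stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
    dor <- (sens * spec) / ((1 - sens) * (1 - spec))
    boundary <- sens %in% c(0, 1) || spec %in% c(0, 1)
  }
  if (is.nan(dor)) dor <- NaN
  structure(dor, boundary = boundary)
}

#' Diagnostic table for one score
#'
#' Builds the per-score report block: AUC with DeLong SE and 95% CI, and
#' one row per cut-off with sensitivity, specificity and diagnostic odds
#' ratio. Percentages are in percent at one decimal in the `display`
#' component; the `rows` component is unrounded.
#'
#' @param set An `outcome_set`.
#' @param cutoffs Numeric cut-off values; rows are sorted by cut-off.
#'   Defaults to the quartile/ninth-decile cut-offs of the observed
#'   scores.
#' @param name Score name for the report.
#' @param ge Positivity convention passed to [confusion_at_cutoff].
#' @return Object of class `"diagnostic_table"`: list with `name`, `auc`,
#'   `se`, `ci`, `rows` (data frame cutoff/sensitivity/specificity/dor)
#'   and `n_events`, `n_nonevents`.
#' @export
diagnostic_table <- function(set, cutoffs = NULL, name = "score",
                             ge = FALSE) {
  stopifnot(inherits(set, "outcome_set"))
  if (is.null(cutoffs)) cutoffs <- quantile_cutoffs(set$score)
  cutoffs <- sort(as.numeric(cutoffs))
  a <- roc_auc(set)
  rows <- do.call(rbind, lapply(cutoffs, function(ct) {
    cc <- confusion_at_cutoff(set, ct, ge = ge)
    data.frame(cutoff = ct, sensitivity = cc$sensitivity,
               specificity = cc$specificity,
               dor = as.numeric(diagnostic_odds_ratio(counts = cc)))
  }))
  structure(list(name = name, auc = a$auc, se = a$se, ci = a$ci,
                 rows = rows, n_events = a$n_events,
                 n_nonevents = a$n_nonevents),
            class = "diagnostic_table")
}

#' @export
print.diagnostic_table <- function(x, ...) {
  cat(sprintf("%s: AUC %.2f +/- %.2f (95%% CI %.2f-%.2f), %d events / %d non-events\n",
              x$name, x$auc, x$se, x$ci[1], x$ci[2],
              x$n_events, x$n_nonevents))
  r <- x$rows
  cat(sprintf("  cutoff %6.1f: sens %5.1f  spec %5.1f  DOR %8.1f\n",
              r$cutoff, 100 * r$sensitivity, 100 * r$specificity,
              round_display(r$dor, 1)), sep = "")
  invisible(x)
}

#' Compare the diagnostic ability of several scores
#'
#' Evaluates each score against the same dichotomized outcome and returns
#' the diagnostic tables ranked by AUC, descending. Binary scores (such as
#' the EAD flag) are handled by the same concordance construction, which
#' for a two-point ROC reduces to (sens + spec) / 2.
#'
#' @param scores Named list or data frame of numeric score columns, all
#'   over the same patients.
#' @param times,events,horizon As in [dichotomize_graft_loss]; patients
#'   censored loss-free before the horizon are excluded from every score's
#'   evaluation alike.
#' @param cutoffs Optional named list: per-score cut-off vectors (scores
#'   missing from the list get no cut-off rows, AUC only).
#' @param ge Positivity convention.
#' @return List of `diagnostic_table` objects sorted by AUC descending.
#' @export
compare_scores <- function(scores, times, events, horizon, cutoffs = NULL,
                           ge = FALSE) {
  scores <- as.data.frame(scores)
  if (nrow(scores) != length(times)) {
    stop("score columns and outcome vectors cover different patient sets (",
         nrow(scores), " vs ", length(times), " patients)")
  }
  tabs <- lapply(names(scores), function(nm) {
    set <- dichotomize_graft_loss(scores[[nm]], times, events, horizon)
    ct <- if (!is.null(cutoffs) && nm %in% names(cutoffs))
      cutoffs[[nm]] else NULL
    if (is.null(ct)) {
      a <- roc_auc(set)
      structure(list(name = nm, auc = a$auc, se = a$se, ci = a$ci,
                     rows = data.frame(cutoff = numeric(0),
                                       sensitivity = numeric(0),
                                       specificity = numeric(0),
                                       dor = numeric(0)),
                     n_events = a$n_events, n_nonevents = a$n_nonevents),
                class = "diagnostic_table")
    } else {
      diagnostic_table(set, cutoffs = ct, name = nm, ge = ge)
    }
  })
  tabs[order(vapply(tabs, `[[`, numeric(1), "auc"), decreasing = TRUE)]
}

#' Two-group comparison of a baseline variable
#'
#' Compares a variable between two cohorts the way baseline tables are
#' built: the Mann-Whitney U test (normal approximation with tie
#' correction) for continuous variables, Fisher's exact test (two-sided,
#' hypergeometric) for binary/categorical variables.
#'
#' @param x,y The variable in the two groups. Logical or factor input
#'   selects Fisher's exact test; numeric input the Mann-Whitney U test.
#' @param type Force `"continuous"` or `"categorical"`; default inferred.
#' @return List with `method`, `statistic`, `p_value`.
#' @export
compare_cohorts <- function(x, y, type = NULL) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty")
  }
  if (is.null(type)) {
    type <- if (is.logical(x) || is.factor(x) || is.character(x))
      "categorical" else "continuous"
  }
  if (type == "continuous") {
    ht <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    list(method = "Mann-Whitney U", statistic = unname(ht$statistic),
         p_value = ht$p.value)
  } else {
    tab <- rbind(table(factor(as.logical(x), levels = c(FALSE, TRUE))),
                 table(factor(as.logical(y), levels = c(FALSE, TRUE))))
    ht <- stats::fisher.test(tab)
    list(method = "Fisher exact", statistic = unname(ht$estimate),
         p_value = ht$p.value)
  }
}
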