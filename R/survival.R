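#' Kaplan-Meier fit of graft survival
#'
#' Product-limit estimator S(t) = prod(1 - d_i/n_i) over event times up to
#' t, with events resolved before censorings at tied times. A thin wrapper
#' over [survival::survfit] returning the curve as plain vectors.
#'
#' @param time Follow-up in days (> 0).
#' @param event Graft-loss indicator (logical or 0/1).
#' @param group Optional stratum label per patient; when given, one curve
#'   per stratum is returned.
#' @return Object of class `"km_curve"`: data frame with columns `group`
#'   (if any), `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_fit <- function(time, event, group = NULL) {
  if (any(time <= 0)) stop("survival times must be strictly positive")
  event <- as.integer(as.logical(event))
  df <- data.frame(time = time, event = event)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
    out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  } else {
    df$group <- group
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
    g <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
    out <- data.frame(group = g, time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  }
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability at a time point
#'
#' Reads S(t) off a Kaplan-Meier curve (step function, right-continuous).
#'
#' @param curve A `km_curve`.
#' @param at Time (days).
#' @param group Stratum label when the curve is stratified.
#' @return Survival probability in \[0, 1\].
#' @export
km_surv_at <- function(curve, at, group = NULL) {
  stopifnot(inherits(curve, "km_curve"))
  if (!is.null(group)) curve <- curve[curve$group == group, , drop = FALSE]
  s <- curve$surv[curve$time <= at & curve$n_event > 0]
  if (length(s) == 0L) 1 else min(s)
}

#' Log-rank test across strata
#'
#' Standard observed-minus-expected chi-square over k groups with k - 1
#' degrees of freedom, via [survival::survdiff].
#'
#' @inheritParams km_fit
#' @param group Stratum label per patient (>= 2 distinct values).
#' @return List with `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop("log-rank needs at least two non-empty groups")
  }
  df <- data.frame(time = time, event = as.integer(as.logical(event)),
                   group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(sd$n)
  list(chisq = sd$chisq, df = k - 1L,
       p_value = stats::pchisq(sd$chisq, df = k - 1L, lower.tail = FALSE))
}

#' CCI risk strata
#'
#' Assigns each CCI value to one of the five risk bands used for survival
#' stratification: 0.0-12.2, 12.3-29.6, 29.7-47.3, 47.4-84.9 and
#' 85.0-100.0 — i.e. intervals closed on the right at the quartile /
#' ninth-decile cut-offs: \[0, 12.2\], (12.2, 29.6\], (29.6, 47.3\],
#' (47.3, 84.9\], (84.9, 100\].
#'
#' @param cci Numeric CCI values in \[0, 100\].
#' @param cutoffs The four interior cut-offs (default
#'   `c(12.2, 29.6, 47.3, 84.9)`).
#' @return Factor of stratum labels ("0.0-12.2", ..., "85.0-100.0"),
#'   ordered by risk.
#' @export
#' @examples
#' cci_strata(c(0, 12.2, 12.3, 47.35, 100))
cci_strata <- function(cci, cutoffs = c(12.2, 29.6, 47.3, 84.9)) {
  if (any(cci < 0 | cci > 100)) {
    stop("CCI values must lie in [0, 100]")
  }
  stopifnot(length(cutoffs) >= 1, !is.unsorted(cutoffs))
  br <- c(0, cutoffs, 100)
  labs <- paste0(formatC(c(0, cutoffs + 0.1), format = "f", digits = 1),
                 "-",
                 formatC(c(cutoffs, 100), format = "f", digits = 1))
  cut(cci, breaks = br, labels = labs, include.lowest = TRUE, right = TRUE,
      ordered_result = TRUE)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with the Breslow tie approximation (Efron
#' available), reported per covariate as beta, SE, the Wald statistic
#' (beta/SE)^2, HR = exp(beta) with 95% CI exp(beta +/- 1.96 SE), and the
#' Wald p-value; plus the model -2 log-likelihood. Covariates that are
#' identically zero contribute nothing and are reported with beta 0 and
#' HR 1; collinear covariates are rejected naming the offender.
#'
#' @param data Data frame holding `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return Object of class `"cox_fit"`: list with `table` (one row per
#'   covariate: beta, se, wald, hr, ci_lower, ci_upper, p_value),
#'   `loglik`, `minus2loglik`, `n`, `n_events` and the underlying
#'   [survival::coxph] fit in `$fit` (NULL when no covariate is
#'   informative).
#' @export
cox_fit <- function(data, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(data),
            all(c("time", "event") %in% names(data)))
  miss <- setdiff(covariates, names(data))
  if (length(miss)) {
    stop("covariate(s) absent from data: ", paste(miss, collapse = ", "))
  }
  if (any(data$time <= 0)) stop("survival times must be strictly positive")
  if (sum(data$event) < 1) stop("need at least one event to fit")
  zero <- vapply(covariates, function(v) all(data[[v]] == 0), logical(1))
  active <- covariates[!zero]
  n <- nrow(data)
  if (length(active) == 0L) {
    tab <- data.frame(covariate = covariates, beta = 0, se = NA_real_,
                      wald = NA_real_, hr = 1, ci_lower = NA_real_,
                      ci_upper = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab, loglik = NA_real_,
                          minus2loglik = NA_real_, n = n,
                          n_events = sum(data$event), fit = NULL),
                     class = "cox_fit"))
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(active, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("collinear covariate(s) dropped by the fit: ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(covariate = names(beta), beta = unname(beta),
                    se = unname(se), wald = unname((beta / se)^2),
                    hr = unname(exp(beta)),
                    ci_lower = unname(exp(beta - 1.96 * se)),
                    ci_upper = unname(exp(beta + 1.96 * se)),
                    p_value = unname(stats::pchisq((beta / se)^2, 1,
                                                   lower.tail = FALSE)),
                    stringsAsFactors = FALSE)
  if (any(zero)) {
    zt <- data.frame(covariate = covariates[zero], beta = 0, se = NA_real_,
                     wald = NA_real_, hr = 1, ci_lower = NA_real_,
                     ci_upper = NA_real_, p_value = NA_real_,
                     stringsAsFactors = FALSE)
    tab <- rbind(tab, zt)
    tab <- tab[match(covariates, tab$covariate), ]
    rownames(tab) <- NULL
  }
  ll <- fit$loglik[length(fit$loglik)]
  structure(list(table = tab, loglik = ll, minus2loglik = -2 * ll,
                 n = n, n_events = sum(data$event), fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: %d patients, %d events, -2logLik %.2f\n",
              x$n, x$n_events,
              x$minus2loglik))
  t <- x$table
  cat(sprintf("  %-14s beta %+6.3f +/- %5.3f  HR %5.2f (%.2f-%.2f)  p %.3g\n",
              t$covariate, t$beta, t$se, t$hr, t$ci_lower, t$ci_upper,
              t$p_value))
  invisible(x)
}

#' Univariable Cox screen
#'
#' Fits one single-covariate Cox model per candidate and reports the
#' usual univariable block (beta, SE, HR, CI, p); used to pre-screen
#' covariates at p < 0.20 before multivariable modelling.
#'
#' @inheritParams cox_fit
#' @return Data frame, one row per covariate, same columns as the
#'   `cox_fit` table.
#' @export
cox_univariable <- function(data, covariates, ties = "breslow") {
  do.call(rbind, lapply(covariates, function(v) {
    cox_fit(data, v, ties = ties)$table
  }))
}

#' Backward Wald covariate selection for the Cox model
#'
#' Starting from the candidate set (conventionally those with
#' univariable p < 0.20), iteratively removes the covariate with the
#' largest Wald p-value at or above the removal threshold and refits,
#' until every remaining covariate has p below the threshold.
#'
#' A collinearity guard keeps MELD and D-MELD (donor age x MELD) out of
#' the same model: when both are candidates, two parallel selections are
#' run — one seeded with D-MELD, one with MELD — and both final models are
#' returned.
#'
#' @inheritParams cox_fit
#' @param candidates Candidate covariate names.
#' @param p_remove Removal threshold on the Wald p-value (default 0.10).
#' @param exclusive List of character vectors; covariates within one
#'   vector never enter the same model (default `list(c("meld",
#'   "d_meld"))`, applied only to names actually present).
#' @return Object of class `"backward_fit"`: list with `model` (final
#'   `cox_fit`), `removed` (removal order), `retained`, and `alternates`
#'   (list of parallel `backward_fit`s when an exclusivity split
#'   occurred).
#' @export
backward_wald_select <- function(data, candidates, p_remove = 0.10,
                                 ties = "breslow",
                                 exclusive = list(c("meld", "d_meld"))) {
  if (length(candidates) == 0L) {
    stop("empty candidate set: nothing to select from")
  }
  for (pair in exclusive) {
    inset <- intersect(pair, candidates)
    if (length(inset) > 1L) {
      variants <- lapply(inset, function(keep) {
        backward_wald_select(data, setdiff(candidates,
                                           setdiff(inset, keep)),
                             p_remove = p_remove, ties = ties,
                             exclusive = exclusive)
      })
      names(variants) <- inset
      primary <- variants[[1L]]
      primary$alternates <- variants[-1L]
      return(primary)
    }
  }
  current <- candidates
  removed <- character(0)
  fit <- cox_fit(data, current, ties = ties)
  repeat {
    pv <- fit$table$p_value
    pv[is.na(pv)] <- 1  # uninformative (zero-variance) covariates go first
    worst <- which.max(pv)
    if (pv[worst] < p_remove || length(current) == 0L) break
    removed <- c(removed, fit$table$covariate[worst])
    current <- setdiff(current, fit$table$covariate[worst])
    if (length(current) == 0L) {
      fit <- NULL
      break
    }
    fit <- cox_fit(data, current, ties = ties)
  }
  structure(list(model = fit, removed = removed, retained = current,
                 p_remove = p_remove, alternates = list()),
            class = "backward_fit")
}

#' @export
print.backward_fit <- function(x, ...) {
  cat("Backward Wald selection (remove at p >= ", x$p_remove, ")\n",
      sep = "")
  cat("  removed:  ",
      if (length(x$removed)) paste(x$removed, collapse = ", ") else "none",
      "\n")
  cat("  retained: ",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "none",
      "\n")
  if (!is.null(x$model)) print(x$model)
  if (length(x$alternates)) {
    cat("-- parallel model(s) from the collinearity guard --\n")
    for (a in x$alternates) print(a)
  }
  invisible(x)
}
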