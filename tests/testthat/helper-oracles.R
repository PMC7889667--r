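# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit loops, enumeration) so they share no code
# path with the implementation they check.

# CCI by explicit weight summation.
oracle_cci <- function(grades) {
  w <- c(I = 300, II = 1750, IIIa = 2750, IIIb = 4550,
         IVa = 7200, IVb = 8550, V = 39940)
  if (length(grades) == 0) return(0)
  if (any(grades == "V")) return(100)
  total <- 0
  for (g in grades) total <- total + w[[g]]
  min(100, sqrt(total) / 2)
}

# AUC by exhaustive pairwise concordance counting.
oracle_auc_pairs <- function(ev, ne) {
  s <- 0
  for (x in ev) for (y in ne) {
    s <- s + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  s / (length(ev) * length(ne))
}

# AUC by the trapezoidal rule over the empirical ROC curve.
oracle_auc_trapezoid <- function(scores, outcome) {
  ths <- sort(unique(scores))
  sens <- spec <- numeric(length(ths) + 2)
  cuts <- c(-Inf, ths, Inf)
  for (i in seq_along(cuts)) {
    pos <- scores >= cuts[i]
    sens[i] <- sum(pos & outcome) / sum(outcome)
    spec[i] <- sum(!pos & !outcome) / sum(!outcome)
  }
  fpr <- 1 - spec
  o <- order(fpr, sens)
  fpr <- fpr[o]; sens <- sens[o]
  sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
}

# Kaplan-Meier by hand: product over event times, events before
# censorings at ties.
oracle_km <- function(time, event, at) {
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]
  s <- 1
  for (t in sort(unique(time[event == 1]))) {
    if (t > at) break
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# One-covariate Cox beta by grid search over the Breslow partial
# log-likelihood.
oracle_cox_grid <- function(time, event, x, lo = -3, hi = 3, step = 1e-4) {
  pl <- function(beta) {
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      dead <- which(time == t & event == 1)
      risk <- which(time >= t)
      ll <- ll + sum(x[dead]) * beta -
        length(dead) * log(sum(exp(x[risk] * beta)))
    }
    ll
  }
  grid <- seq(lo, hi, by = step)
  vals <- vapply(grid, pl, numeric(1))
  grid[which.max(vals)]
}

# Two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# enumeration.
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Quick one-patient event table.
ev_tab <- function(grades, id = "p1", day = NA_real_) {
  data.frame(patient_id = rep(id, length(grades)),
             grade = grades,
             day = rep(day, length.out = max(1, length(grades)))[
               seq_along(grades)],
             stringsAsFactors = FALSE)
}
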