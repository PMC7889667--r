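test_that("dichotomization classifies events, survivors and censored patients", {
  sc <- c(10, 20, 30)
  # lost at day 30 -> event; followed to 400 -> non-event; censored at 40 -> out
  set90 <- dichotomize_graft_loss(sc, c(30, 400, 40), c(1, 0, 0), 90)
  expect_equal(set90$outcome, c(TRUE, FALSE))
  expect_equal(set90$n_excluded, 1L)
  set365 <- dichotomize_graft_loss(sc, c(30, 400, 40), c(1, 0, 0), 365)
  expect_equal(set365$outcome, c(TRUE, FALSE))
  # loss after the horizon counts as a non-event at that horizon
  late <- dichotomize_graft_loss(5, 200, 1, 90)
  expect_false(late$outcome)
  expect_error(dichotomize_graft_loss(sc, c(10, 20, 30), c(0, 0, 0), 90),
               "censored loss-free")
})

test_that("AUC equals pairwise concordance, with ties counting one half", {
  expect_equal(roc_auc(c(3, 4, 1, 2),
                       outcome = c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(5, 6),
                       outcome = rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_equal(roc_auc(c(3, 1, 2, 0),
                       outcome = c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_error(roc_auc(1:4, outcome = rep(TRUE, 4)), "non-event")
})

test_that("concordance AUC agrees with pairwise and trapezoidal oracles", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    out <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    sc <- sample(0:9, n, replace = TRUE)  # heavy ties on purpose
    a <- roc_auc(sc, outcome = out)$auc
    expect_equal(a, oracle_auc_pairs(sc[out], sc[!out]))
    expect_equal(a, oracle_auc_trapezoid(sc, out))
  }
})

test_that("DeLong SE and CI match the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (i in 1:10) {
    n <- 60
    out <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    sc <- round(rnorm(n) + out, 1)
    mine <- roc_auc(sc, outcome = out)
    ref <- pROC::roc(response = out, predictor = sc, quiet = TRUE,
                     direction = "<")
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
    expect_equal(mine$se, sqrt(pROC::var(ref, method = "delong")))
    expect_true(mine$ci[1] <= mine$auc && mine$auc <= mine$ci[2])
  }
})

test_that("AUC of a score and of its negation sum to one", {
  set.seed(5)
  out <- runif(40) < 0.3
  out[1:2] <- c(TRUE, FALSE)
  sc <- sample(0:5, 40, replace = TRUE)
  expect_equal(roc_auc(sc, outcome = out)$auc +
                 roc_auc(-sc, outcome = out)$auc, 1)
})

test_that("quantile cut-offs interpolate order statistics at rank 1+(n-1)p", {
  expect_equal(unname(quantile_cutoffs(c(0, 10, 20, 30, 40),
                                       probs = 0.5)), 20)
  expect_equal(unname(quantile_cutoffs(c(0, 100), probs = 0.25)), 25)
  expect_equal(unname(quantile_cutoffs(c(5, 5, 5), probs = c(0.25, 0.9))),
               c(5, 5))
  expect_error(quantile_cutoffs(3), "at least two")
  expect_error(quantile_cutoffs(1:5, probs = c(0, 0.5)), "strictly")
})

test_that("confusion counts partition the set under both positivity rules", {
  set <- ccindex:::outcome_set(c(50, 10), c(TRUE, FALSE))
  cc <- confusion_at_cutoff(set, 30)
  expect_equal(cc[c("tp", "tn", "fp", "fn")],
               list(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  cc <- confusion_at_cutoff(set, 60)
  expect_equal(cc[c("fn", "tn")], list(fn = 1L, tn = 1L))
  # tied scores at the cut-off: enumerate by hand; > excludes the tie,
  # >= includes it
  sc <- c(3, 3, 5, 1, 3, 7); out <- c(T, F, T, F, F, T)
  strict <- confusion_at_cutoff(ccindex:::outcome_set(sc, out), 3)
  expect_equal(strict[c("tp", "fp", "tn", "fn")],
               list(tp = 2L, fp = 0L, tn = 3L, fn = 1L))
  ge <- confusion_at_cutoff(ccindex:::outcome_set(sc, out), 3, ge = TRUE)
  expect_equal(ge[c("tp", "fp", "tn", "fn")],
               list(tp = 3L, fp = 2L, tn = 1L, fn = 0L))
  expect_equal(strict$tp + strict$fn, sum(out))
  expect_equal(strict$tn + strict$fp, sum(!out))
})

test_that("DOR from proportions equals DOR from counts and flags boundaries", {
  expect_equal(round(as.numeric(diagnostic_odds_ratio(0.888, 0.859)), 1),
               48.3)
  expect_equal(diagnostic_odds_ratio(0.5, 0.5), 1, ignore_attr = TRUE)
  expect_equal(round(as.numeric(diagnostic_odds_ratio(0.535, 0.999)), 1),
               1149.4)
  set.seed(9)
  for (i in 1:20) {
    cts <- list(tp = sample(1:30, 1), fp = sample(1:30, 1),
                tn = sample(1:30, 1), fn = sample(1:30, 1))
    sens <- cts$tp / (cts$tp + cts$fn)
    spec <- cts$tn / (cts$tn + cts$fp)
    expect_equal(as.numeric(diagnostic_odds_ratio(sens, spec)),
                 as.numeric(diagnostic_odds_ratio(counts = cts)))
  }
  b <- diagnostic_odds_ratio(1, 0.5)
  expect_true(is.infinite(b) && attr(b, "boundary"))
  h <- diagnostic_odds_ratio(counts = list(tp = 5, fp = 0, tn = 5, fn = 0),
                             haldane = TRUE)
  expect_equal(as.numeric(h), (5.5 * 5.5) / (0.5 * 0.5))
})

test_that("sensitivity falls and specificity rises across increasing cut-offs", {
  set.seed(21)
  sc <- c(rexp(120, 1 / 30), rep(0, 60))  # heavily tied low scores
  out <- runif(180) < plogis((sc - 25) / 8)
  out[1] <- TRUE; out[180] <- FALSE
  set <- ccindex:::outcome_set(sc, out)
  tab <- diagnostic_table(set, cutoffs = quantile_cutoffs(sc))
  expect_true(all(diff(tab$rows$sensitivity) <= 0))
  expect_true(all(diff(tab$rows$specificity) >= 0))
  expect_true(all(tab$rows$dor >= 0))
  expect_true(all(diff(tab$rows$cutoff) > 0))
})

test_that("score comparison ranks a generative score above noise", {
  set.seed(31)
  co <- generate_cohort(preset("training_like", 600, seed = 31))$cohort
  scores <- data.frame(cci = co$cci, meld = co$meld, noise = rnorm(600))
  tabs <- compare_scores(scores, co$time_days, co$graft_loss, 90,
                         cutoffs = list(cci = quantile_cutoffs(co$cci)))
  expect_equal(tabs[[1]]$name, "cci")
  aucs <- vapply(tabs, `[[`, numeric(1), "auc")
  expect_true(all(diff(aucs) <= 0))
  # identical columns give identical AUCs
  twin <- compare_scores(data.frame(a = co$cci, b = co$cci),
                         co$time_days, co$graft_loss, 90)
  expect_equal(twin[[1]]$auc, twin[[2]]$auc)
  expect_error(compare_scores(scores, co$time_days[1:10],
                              co$graft_loss[1:10], 90),
               "different patient sets")
})

test_that("a binary score's AUC reduces to (sens + spec) / 2", {
  # flag with sensitivity 0.8 and specificity 0.8 by construction
  out <- rep(c(TRUE, FALSE), each = 10)
  flag <- c(rep(1, 8), rep(0, 2), rep(0, 8), rep(1, 2))
  expect_equal(roc_auc(flag, outcome = out)$auc, 0.8)
})

test_that("cohort comparison uses Mann-Whitney for continuous, Fisher for flags", {
  same <- compare_cohorts(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$method, "Mann-Whitney U")
  expect_gt(same$p_value, 0.9)
  f <- compare_cohorts(rep(c(TRUE, FALSE), c(10, 0)),
                       rep(c(TRUE, FALSE), c(0, 10)))
  expect_equal(f$method, "Fisher exact")
  expect_equal(f$p_value, oracle_fisher2x2(10, 0, 0, 10), tolerance = 1e-8)
  set.seed(17)
  shifted <- compare_cohorts(rnorm(100), rnorm(100) + 3)
  expect_lt(shifted$p_value, 0.001)
  expect_error(compare_cohorts(numeric(0), 1:3), "non-empty")
})
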