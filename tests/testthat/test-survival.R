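test_that("Kaplan-Meier estimates match hand-computed product limits", {
  # no events: S identically 1
  km <- km_fit(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  # n = 4, one event at t = 10
  km <- km_fit(c(10, 12, 20, 30), c(1, 0, 0, 0))
  expect_equal(km_surv_at(km, 10), 0.75)
  # n = 5 with interleaved censoring: after the event at t=10 (risk 5)
  # and censorings at 15 and 20, only 2 remain at risk for the event at
  # t=25, so S(25) = (1 - 1/5)(1 - 1/2)
  tm <- c(10, 15, 20, 25, 30); evn <- c(1, 0, 0, 1, 0)
  km <- km_fit(tm, evn)
  expect_equal(km_surv_at(km, 25), (4 / 5) * (1 / 2))
  expect_equal(km_surv_at(km, 25), oracle_km(tm, evn, 25))
  expect_error(km_fit(c(0, 5), c(1, 0)), "strictly positive")
})

test_that("uncensored KM equals the empirical survival function", {
  set.seed(13)
  tm <- sample(1:40, 25, replace = TRUE)
  km <- km_fit(tm, rep(1, 25))
  for (at in c(5, 10, 20, 39)) {
    expect_equal(km_surv_at(km, at), mean(tm > at))
    expect_equal(km_surv_at(km, at), oracle_km(tm, rep(1, 25), at))
  }
  expect_true(all(diff(km$surv) <= 0))
  expect_true(all(diff(km$n_risk) <= 0))
})

test_that("log-rank is null on duplicated groups and detects real separation", {
  tm <- c(5, 8, 12, 20, 25); evn <- c(1, 0, 1, 1, 0)
  dup <- logrank_test(c(tm, tm), c(evn, evn), rep(c("a", "b"), each = 5))
  expect_equal(dup$chisq, 0, tolerance = 1e-10)
  expect_equal(dup$p_value, 1, tolerance = 1e-6)
  expect_equal(dup$df, 1L)
  set.seed(19)
  t1 <- rexp(200, 1); t2 <- rexp(200, 3)
  lr <- logrank_test(c(t1, t2), rep(1, 400), rep(c("lo", "hi"), each = 200))
  expect_lt(lr$p_value, 0.001)
  # invariant to group relabeling
  lr2 <- logrank_test(c(t1, t2), rep(1, 400),
                      rep(c("zzz", "aaa"), each = 200))
  expect_equal(lr$chisq, lr2$chisq)
  expect_error(logrank_test(t1, rep(1, 200), rep("only", 200)),
               "two non-empty groups")
})

test_that("CCI strata use right-closed bands at the reported cut-offs", {
  s <- cci_strata(c(0, 12.2, 12.3, 29.6, 29.7, 47.3, 47.35, 84.9, 85, 100))
  expect_equal(as.integer(s), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
  expect_equal(levels(s), c("0.0-12.2", "12.3-29.6", "29.7-47.3",
                            "47.4-84.9", "85.0-100.0"))
  expect_error(cci_strata(c(50, 101)), "\\[0, 100\\]")
  expect_error(cci_strata(-1), "\\[0, 100\\]")
})

test_that("five ordered-hazard strata separate on the log-rank test", {
  set.seed(23)
  co <- generate_cohort(preset("training_like", 800, seed = 23))$cohort
  strata <- cci_strata(co$cci)
  lr <- logrank_test(co$time_days, co$graft_loss, strata)
  expect_lt(lr$p_value, 0.001)
  expect_equal(lr$df, nlevels(droplevels(strata)) - 1L)
  # survival at one year is ordered across strata (worst band lowest)
  km <- km_fit(co$time_days, co$graft_loss, group = strata)
  s1y <- vapply(levels(droplevels(strata)), function(g)
    km_surv_at(km, 365, group = g), numeric(1))
  expect_lt(s1y[[5]], s1y[[1]])
  expect_lt(s1y[[5]], 0.5)
})

test_that("Cox beta matches a 1-D grid-search oracle on the partial likelihood", {
  set.seed(29)
  x <- rep(c(0, 1), each = 25)
  tm <- rexp(50, exp(0.9 * x))
  tm <- tm + seq_along(tm) * 1e-6  # break ties so Breslow = exact
  d <- data.frame(time = tm, event = 1, x = x)
  fit <- cox_fit(d, "x")
  expect_equal(fit$table$beta, oracle_cox_grid(tm, rep(1, 50), x),
               tolerance = 1e-3)
  expect_equal(fit$table$hr, exp(fit$table$beta))
  expect_equal(fit$table$wald, (fit$table$beta / fit$table$se)^2)
  expect_equal(fit$table$ci_lower,
               exp(fit$table$beta - 1.96 * fit$table$se))
  # beta sign agrees with the log-rank direction
  lr <- logrank_test(tm, rep(1, 50), x)
  expect_gt(fit$table$beta, 0)
  expect_lt(lr$p_value, 0.05)
})

test_that("degenerate covariates are handled as specified", {
  d <- data.frame(time = c(2, 4, 6, 8, 3, 5, 7, 9),
                  event = c(1, 0, 1, 1, 1, 0, 1, 0),
                  zero = 0, x = c(0, 1, 0, 1, 1, 0, 1, 0))
  fit <- cox_fit(d, c("zero", "x"))
  expect_equal(fit$table$beta[fit$table$covariate == "zero"], 0)
  expect_equal(fit$table$hr[fit$table$covariate == "zero"], 1)
  d$dup <- d$x * 2
  expect_error(suppressWarnings(cox_fit(d, c("x", "dup"))), "collinear")
  expect_error(cox_fit(d[d$event == 0, ], "x"), "at least one event")
  expect_error(cox_fit(d, "missing_col"), "absent")
})

test_that("a training-like cohort recovers the generative CCI hazard ratio", {
  set.seed(37)
  co <- generate_cohort(preset("training_like", 2000, seed = 37))$cohort
  d <- data.frame(time = co$time_days, event = co$graft_loss, co)
  fit <- cox_fit(d, c("cci", "donor_age", "bar"))
  hr <- fit$table$hr[fit$table$covariate == "cci"]
  expect_gt(hr, 1.04)
  expect_lt(hr, 1.06)
})

test_that("backward Wald keeps true effects and drops noise", {
  set.seed(41)
  retained_true <- 0
  for (r in 1:10) {
    n <- 500
    x <- rnorm(n)
    noise1 <- rnorm(n); noise2 <- rnorm(n); noise3 <- rnorm(n)
    tm <- rexp(n, 0.01 * exp(0.8 * x))
    cens <- runif(n, 50, 400)
    d <- data.frame(time = pmin(tm, cens), event = as.integer(tm <= cens),
                    x = x, noise1 = noise1, noise2 = noise2,
                    noise3 = noise3)
    sel <- backward_wald_select(d, c("x", "noise1", "noise2", "noise3"))
    if ("x" %in% sel$retained) retained_true <- retained_true + 1
  }
  expect_gte(retained_true, 9)
  # single strong candidate is retained unchanged
  set.seed(43)
  x <- rep(c(0, 1), 100)
  tm <- rexp(200, 0.02 * exp(1.2 * x))
  d <- data.frame(time = tm, event = 1, x = x)
  sel <- backward_wald_select(d, "x")
  expect_equal(sel$retained, "x")
  expect_length(sel$removed, 0)
  expect_error(backward_wald_select(d, character(0)), "empty candidate")
})

test_that("MELD and D-MELD never share a model: parallel fits are returned", {
  set.seed(47)
  co <- generate_cohort(preset("training_like", 700, seed = 47))$cohort
  d <- data.frame(time = co$time_days, event = co$graft_loss, co)
  d$d_meld <- d$d_meld / 100
  sel <- backward_wald_select(d, c("cci", "meld", "d_meld", "donor_age"))
  expect_false(all(c("meld", "d_meld") %in% sel$retained))
  expect_length(sel$alternates, 1)
  alt <- sel$alternates[[1]]
  expect_false(all(c("meld", "d_meld") %in% alt$retained))
  expect_true("cci" %in% sel$retained)
})

test_that("univariable screen reports one single-covariate fit per candidate", {
  set.seed(53)
  co <- generate_cohort(preset("training_like", 400, seed = 53))$cohort
  d <- data.frame(time = co$time_days, event = co$graft_loss, co)
  uni <- cox_univariable(d, c("cci", "donor_age", "bar"))
  expect_equal(uni$covariate, c("cci", "donor_age", "bar"))
  solo <- cox_fit(d, "donor_age")$table
  expect_equal(uni[uni$covariate == "donor_age", ], solo,
               ignore_attr = TRUE)
})
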