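test_that("incidence rates are person-time arithmetic", {
  rec <- data.frame(risk_group = rep("high", 15),
                    months_followed = rep(480, 15),
                    incident_diabetes = c(rep(1, 15)))
  # 15 cases over 600 person-years -> 25 per 1000 py (no censoring)
  inc <- incidence_by_group(rec, censor_at_diagnosis = FALSE)
  expect_equal(inc$rate_per_1000py[inc$group == "overall"], 25)
  # zero cases in a group
  rec2 <- data.frame(risk_group = c("low", "low", "high"),
                     months_followed = c(12, 12, 12),
                     incident_diabetes = c(0, 0, 1),
                     months_to_diagnosis = c(NA, NA, 6))
  inc2 <- incidence_by_group(rec2)
  expect_equal(inc2$rate_per_1000py[inc2$group == "low"], 0)
  # censoring uses months_to_diagnosis for cases
  expect_equal(inc2$person_years[inc2$group == "high"], 0.5)
  # a case without a diagnosis date cannot be censored
  rec2$months_to_diagnosis[3] <- NA
  expect_error(incidence_by_group(rec2), class = "drs_validation")
  # 13 cases among 199 persons at 22.66 months, uncensored
  rec3 <- data.frame(risk_group = "high", months_followed = 22.66,
                     incident_diabetes = rep(c(1, 0), c(13, 186)))
  inc3 <- incidence_by_group(rec3, censor_at_diagnosis = FALSE)
  expect_equal(inc3$rate_per_1000py[inc3$group == "high"],
               13 / (199 * 22.66 / 12) * 1000, tolerance = 1e-12)
  expect_equal(round_half_up(inc3$rate_per_1000py[1], 1), 34.6)
})

test_that("2x2 analysis gives the cross-product OR, Wald CI and Fisher p", {
  r <- two_by_two_analysis(13, 186, 2, 125)
  expect_equal(r$or, 13 * 125 / (186 * 2), tolerance = 1e-12)
  expect_equal(round_half_up(r$or, 2), 4.37)
  expect_equal(round_half_up(unname(r$ci), 2), c(0.97, 19.69))
  expect_equal(round_report(r$fisher_p), 0.06)
  sym <- two_by_two_analysis(8, 8, 8, 8)
  expect_equal(sym$or, 1)
  expect_equal(sym$fisher_p, 1)
  expect_error(two_by_two_analysis(0, 10, 2, 8), class = "drs_zero_cell")
  h <- two_by_two_analysis(0, 10, 2, 8, zero_cell_policy = "haldane")
  expect_true(h$haldane_applied)
  expect_equal(h$or, (0.5 * 8.5) / (10.5 * 2.5))
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(8:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    if (cells[1] + cells[2] == 0 || cells[3] + cells[4] == 0) next
    if (any(cells == 0)) {
      r <- two_by_two_analysis(cells[1], cells[2], cells[3], cells[4],
                               "haldane")
    } else {
      r <- two_by_two_analysis(cells[1], cells[2], cells[3], cells[4])
    }
    expect_equal(r$fisher_p,
                 fisher_enumerate(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
    expect_gt(r$fisher_p, 0)
    expect_lte(r$fisher_p, 1)
  }
})

test_that("logistic fit on a 2x2 reproduces the cross-product OR exactly", {
  rec <- cohort_factors(expand_two_by_two(13, 186, 2, 125))
  fit <- fit_logistic(rec, "incident_diabetes", "risk_group")
  tb <- two_by_two_analysis(13, 186, 2, 125)
  i <- match("risk_grouphigh", fit$coef$term)
  expect_equal(fit$coef$or[i], tb$or, tolerance = 1e-8)
  expect_equal(fit$coef$or_lower[i], unname(tb$ci[1]), tolerance = 1e-8)
  expect_equal(fit$coef$or_upper[i], unname(tb$ci[2]), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("intercept-only-like fits match closed forms", {
  # constant predictor column is singular alongside the intercept
  rec <- data.frame(y = rep(c(1, 0), c(4, 12)), x = 1)
  expect_error(fit_logistic(rec, "y", "x"), class = "drs_singular")
  # binary predictor: each cell's log-odds are saturated
  rec2 <- data.frame(y = rep(c(1, 0, 1, 0), c(3, 7, 2, 18)),
                     x = rep(c("b", "a"), c(10, 20)))
  fit <- fit_logistic(rec2, "y", "x")
  expect_equal(fit$coef$estimate[1], log(2 / 18), tolerance = 1e-8)
  expect_equal(fit$coef$estimate[2], log(3 / 7) - log(2 / 18),
               tolerance = 1e-8)
})

test_that("IRLS solution matches grid-search likelihood maximisation", {
  set.seed(5)
  for (i in 1:5) {
    n <- 50
    x <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-1 + 1.2 * x))
    if (length(unique(y)) < 2 || length(unique(y[x == 1])) < 2 ||
        length(unique(y[x == 0])) < 2) next
    fit <- fit_logistic(data.frame(y = y, x = x), "y", "x")
    ref <- grid_logistic(y, x)
    expect_equal(fit$coef$estimate, unname(ref), tolerance = 1e-4)
  }
})

test_that("complete separation is flagged, not silently reported", {
  rec <- data.frame(y = rep(c(1, 0), c(5, 15)),
                    x = rep(c("hi", "lo"), c(5, 15)))
  fit <- fit_logistic(rec, "y", "x")
  expect_true(fit$separation)
})

test_that("Hosmer-Lemeshow is zero for a saturated fit and collapses ties", {
  rec <- cohort_factors(expand_two_by_two(13, 186, 2, 125))
  fit <- fit_logistic(rec, "incident_diabetes", "risk_group")
  # one binary predictor: fitted risks equal group frequencies exactly
  expect_equal(fit$hosmer_lemeshow$statistic, 0, tolerance = 1e-12)
  # only two distinct fitted values -> collapsed groups, df floored at 1
  expect_lte(nrow(fit$hosmer_lemeshow$groups), 2)
  # calibrated continuous fit: HL statistic is modest, p not tiny
  set.seed(31)
  x <- rnorm(400)
  y <- rbinom(400, 1, plogis(-0.5 + 0.8 * x))
  fit2 <- fit_logistic(data.frame(y = y, x = x), "y", "x")
  expect_equal(fit2$hosmer_lemeshow$df, 8)
  expect_gt(fit2$hosmer_lemeshow$p, 0.001)
})

test_that("paired binary change reproduces discordant-pair arithmetic", {
  v <- behavior_vectors(82, 62, 15, 1)
  r <- paired_binary_change(v$before, v$after)
  expect_equal(round_half_up(c(r$baseline_mean, r$baseline_sd,
                               r$followup_mean, r$followup_sd), 2),
               c(0.76, 0.43, 0.93, 0.26))
  expect_equal(round_half_up(r$t, 2), -3.77)
  expect_equal(r$df, 81)
  # cross-check against t.test
  tt <- t.test(v$before, v$after, paired = TRUE)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)
  # antisymmetry
  r2 <- paired_binary_change(v$after, v$before)
  expect_equal(r2$t, -r$t)
  # zero discordance -> undefined t, flagged
  r3 <- paired_binary_change(c(1, 0, 1), c(1, 0, 1))
  expect_true(r3$undefined)
  expect_true(is.na(r3$t))
})
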