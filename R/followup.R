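#' Person-time incidence by risk group
#'
#' Sums person-time as months/12 and reports events per 1000 person-years,
#' per risk group and overall. Two person-time conventions are supported:
#' with `censor_at_diagnosis = TRUE` (default) incident cases contribute
#' follow-up only until `months_to_diagnosis`; otherwise every subject
#' contributes the full `months_followed`.
#'
#' @param records Data frame with columns `risk_group` (`"low"`/`"high"`),
#'   `months_followed`, logical/0-1 `incident_diabetes`, and (needed under
#'   censoring, for cases) `months_to_diagnosis`.
#' @param censor_at_diagnosis Logical; see above.
#' @return Data frame of class `incidence_result` with one row per group
#'   plus `"overall"`: `cases`, `person_years`, `rate_per_1000py`.
#' @export
incidence_by_group <- function(records, censor_at_diagnosis = TRUE) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (any(records$months_followed <= 0))
    stop_drs("months_followed must be positive", "drs_validation")
  ev <- as.logical(records$incident_diabetes)
  months <- records$months_followed
  if (censor_at_diagnosis) {
    mtd <- records$months_to_diagnosis
    if (is.null(mtd) || any(ev & is.na(mtd)))
      stop_drs("censoring requires months_to_diagnosis for every case",
               "drs_validation")
    if (any(ev & mtd > months))
      stop_drs("months_to_diagnosis exceeds months_followed",
               "drs_validation")
    months <- ifelse(ev, mtd, months)
  }
  one <- function(idx, label) {
    py <- sum(months[idx]) / 12
    data.frame(group = label, cases = sum(ev[idx]), person_years = py,
               rate_per_1000py = 1000 * sum(ev[idx]) / py)
  }
  out <- rbind(one(records$risk_group == "low", "low"),
               one(records$risk_group == "high", "high"),
               one(rep(TRUE, nrow(records)), "overall"))
  out <- out[!is.nan(out$rate_per_1000py) | out$cases > 0, ]
  class(out) <- c("incidence_result", "data.frame")
  out
}

#' Odds ratio, Wald interval and Fisher exact test for a 2x2 cohort table
#'
#' Cells follow the exposure layout: `a` events and `b` non-events in the
#' exposed (high-risk) group, `c` and `d` in the unexposed. The odds ratio
#' is the sample cross-product ad/bc with the Wald interval
#' exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d)). The two-sided Fisher exact
#' p sums hypergeometric probabilities no larger than the observed table's
#' (the probability-mass rule, as in [stats::fisher.test()]).
#'
#' @param a,b,c,d Non-negative integer cells.
#' @param zero_cell_policy `"error"` (default) or `"haldane"` (add 0.5 to
#'   every cell for the OR and interval; the Fisher p always uses the raw
#'   counts).
#' @param conf_level Confidence level.
#' @return List of class `two_by_two_result` with `or`, `ci`, `fisher_p`,
#'   `cells`, and `haldane_applied`.
#' @export
two_by_two_analysis <- function(a, b, c, d,
                                zero_cell_policy = c("error", "haldane"),
                                conf_level = 0.95) {
  zero_cell_policy <- match.arg(zero_cell_policy)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_drs("cells must be non-negative integers", "drs_validation")
  if (a + b == 0 || c + d == 0)
    stop_drs("both group sizes must be positive", "drs_validation")
  haldane <- FALSE
  w <- cells
  if (any(cells == 0)) {
    if (zero_cell_policy == "error")
      stop_drs("zero cell; use zero_cell_policy = 'haldane'",
               "drs_zero_cell")
    w <- cells + 0.5
    haldane <- TRUE
  }
  or <- (w["a"] * w["d"]) / (w["b"] * w["c"])
  se <- sqrt(sum(1 / w))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  p <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
  structure(list(or = unname(or),
                 ci = c(lower = unname(ci[1]), upper = unname(ci[2])),
                 se_log_or = unname(se), fisher_p = p, cells = cells,
                 haldane_applied = haldane, conf_level = conf_level),
            class = "two_by_two_result")
}

#' @export
print.two_by_two_result <- function(x, ...) {
  cat(sprintf("OR %.2f (%.0f%% CI %.2f-%.2f), Fisher exact p = %.3f%s\n",
              x$or, 100 * x$conf_level, x$ci[1], x$ci[2], x$fisher_p,
              if (x$haldane_applied) " [Haldane 0.5 correction]" else ""))
  invisible(x)
}

#' Expand a 2x2 table into subject-level records
#'
#' @param a,b,c,d Cells as in [two_by_two_analysis()].
#' @return Data frame with `risk_group` and logical `incident_diabetes`,
#'   one row per subject.
#' @export
expand_two_by_two <- function(a, b, c, d) {
  data.frame(
    risk_group = rep(c("high", "low"), c(a + b, c + d)),
    incident_diabetes = c(rep(c(TRUE, FALSE), c(a, b)),
                          rep(c(TRUE, FALSE), c(c, d)))
  )
}

#' Multivariable logistic regression with Hosmer-Lemeshow calibration
#'
#' Fits a binomial-logit GLM by iteratively reweighted least squares
#' (convergence when the relative deviance change is below 1e-13, at most
#' 50 iterations -- tight enough that a saturated binary-exposure fit
#' reproduces the analytic 2x2 odds ratio to 1e-8), with Wald standard
#' errors from the inverse observed
#' information. Character/factor predictors are reference-coded; supply
#' factors with the desired reference as the first level (see
#' [cohort_factors()] for the study coding: low risk, female, tertiary or
#' higher). Complete separation is reported via `separation` rather than an
#' error; a singular design is an error.
#'
#' @param records Data frame.
#' @param outcome Name of the logical/0-1 outcome column.
#' @param predictors Character vector of predictor column names.
#' @param hl_groups Number of Hosmer-Lemeshow groups (default 10).
#' @param conf_level Confidence level for the Wald intervals.
#' @return List of class `logistic_fit`: `coef` table (estimate, se, z, p,
#'   or, or_lower, or_upper), `converged`, `iterations`, `separation`,
#'   `hosmer_lemeshow` (statistic, df, p), `loglik`, `n`, and the underlying
#'   `glm` object as `fit`.
#' @export
fit_logistic <- function(records, outcome = "incident_diabetes",
                         predictors, hl_groups = 10, conf_level = 0.95) {
  stopifnot(is.data.frame(records), length(predictors) >= 1)
  y <- as.integer(as.logical(records[[outcome]]))
  if (sum(y) == 0 || sum(y) == length(y))
    stop_drs("need at least one event and one non-event", "drs_validation")
  dat <- records[, predictors, drop = FALSE]
  dat[[outcome]] <- y
  form <- stats::as.formula(paste(outcome, "~",
                                  paste(predictors, collapse = " + ")))
  mm <- stats::model.matrix(form, dat)
  if (qr(mm)$rank < ncol(mm))
    stop_drs("singular design matrix (aliased coefficients)",
             "drs_singular")
  sep_warning <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-10, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warning <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(is.na(stats::coef(fit))))
    stop_drs("singular design matrix (aliased coefficients)",
             "drs_singular")
  separation <- sep_warning || !fit$converged ||
    any(abs(stats::coef(fit)) > 15)
  est <- stats::coef(fit)
  vc <- stats::vcov(fit)
  fitted_p <- stats::fitted(fit)
  if (!separation) {
    # Newton polish on the analytic score: glm's deviance-based stopping
    # rule leaves ~1e-7 in the coefficients; the Wald interval of a
    # saturated binary-exposure fit should match the 2x2 closed form.
    beta <- est
    for (k in 1:5) {
      p_hat <- stats::plogis(drop(mm %*% beta))
      H <- crossprod(mm * (p_hat * (1 - p_hat)), mm)
      step <- tryCatch(solve(H, crossprod(mm, y - p_hat)),
                       error = function(e) NULL)
      if (is.null(step)) break
      beta <- beta + drop(step)
      if (max(abs(step)) < 1e-12) break
    }
    p_hat <- stats::plogis(drop(mm %*% beta))
    H <- crossprod(mm * (p_hat * (1 - p_hat)), mm)
    vc_new <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc_new)) {
      est[] <- beta
      vc <- vc_new
      fitted_p <- p_hat
    }
  }
  se <- sqrt(diag(vc))
  z <- est / se
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  coef_tab <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
    or = unname(exp(est)),
    or_lower = unname(exp(est - zq * se)),
    or_upper = unname(exp(est + zq * se)))
  hl <- hosmer_lemeshow(y, fitted_p, g = hl_groups)
  structure(list(coef = coef_tab, converged = fit$converged,
                 iterations = fit$iter, separation = separation,
                 hosmer_lemeshow = hl,
                 loglik = as.numeric(stats::logLik(fit)),
                 n = length(y), fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  tab <- x$coef
  tab[-1] <- lapply(tab[-1], function(v) round_half_up(v, 3))
  print(tab, row.names = FALSE)
  cat(sprintf(
    "n = %d; %sconverged in %d IRLS iterations%s\nHosmer-Lemeshow chi2 = %.3f, df = %d, p = %.3f\n",
    x$n, if (x$converged) "" else "NOT ", x$iterations,
    if (x$separation) "; possible separation" else "",
    x$hosmer_lemeshow$statistic, x$hosmer_lemeshow$df,
    x$hosmer_lemeshow$p))
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations by quantiles of fitted risk (deciles by default),
#' collapsing groups whose boundary fitted values tie, and reduces the
#' degrees of freedom accordingly (df = groups - 2).
#'
#' @param y 0/1 outcomes.
#' @param fitted Fitted probabilities.
#' @param g Requested number of groups.
#' @return List with `statistic`, `df`, `p`, and the group table.
#' @export
hosmer_lemeshow <- function(y, fitted, g = 10) {
  stopifnot(length(y) == length(fitted))
  qs <- unique(stats::quantile(fitted, probs = seq(0, 1, length.out = g + 1),
                               type = 7))
  grp <- cut(fitted, breaks = qs, include.lowest = TRUE)
  obs <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  exp_g <- tapply(fitted, grp, sum)
  pbar <- exp_g / n_g
  denom <- n_g * pbar * (1 - pbar)
  keep <- denom > 1e-12
  stat <- sum((obs[keep] - exp_g[keep])^2 / denom[keep])
  df <- max(1L, sum(keep) - 2L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       groups = data.frame(n = as.vector(n_g), observed = as.vector(obs),
                           expected = as.vector(exp_g)))
}

#' Factor coding used in the follow-up cohort models
#'
#' Sets reference levels to low risk, female sex, and tertiary-or-higher
#' education, so reported odds ratios contrast high vs low risk, male vs
#' female, and lower vs tertiary education.
#'
#' @param records Follow-up data frame with `risk_group`, `sex`, `education`.
#' @return The data frame with those columns as ordered-reference factors.
#' @export
cohort_factors <- function(records) {
  if (!is.null(records$risk_group))
    records$risk_group <- factor(records$risk_group, c("low", "high"))
  if (!is.null(records$sex))
    records$sex <- factor(records$sex, c("female", "male"))
  if (!is.null(records$education))
    records$education <- factor(records$education,
                                c("tertiary_or_higher", "secondary",
                                  "primary_or_below"))
  records
}

#' Paired t test on binary before/after indicators
#'
#' Means and SDs are ordinary sample statistics of the 0/1 vectors (n - 1
#' denominator); the t statistic is mean(before - after) / (SD(before -
#' after)/sqrt(n)) with df = n - 1, so only discordant pairs contribute.
#' A negative t indicates improvement (more 1s at follow-up).
#'
#' @param before,after Equal-length logical/0-1 vectors.
#' @return List of class `paired_change_result` with `n`, `baseline_mean`,
#'   `baseline_sd`, `followup_mean`, `followup_sd`, `t`, `df`, `p`,
#'   `gains`, `losses`, and `undefined` (TRUE when the difference variance
#'   is zero, leaving t undefined).
#' @export
paired_binary_change <- function(before, after) {
  if (length(before) == 0 || length(before) != length(after))
    stop_drs("before and after must be nonempty and of equal length",
             "drs_validation")
  before <- as.integer(as.logical(before))
  after <- as.integer(as.logical(after))
  n <- length(before)
  d <- before - after
  sd_d <- stats::sd(d)
  undefined <- sd_d == 0
  t_stat <- if (undefined) NA_real_ else mean(d) / (sd_d / sqrt(n))
  structure(list(
    n = n,
    baseline_mean = mean(before), baseline_sd = stats::sd(before),
    followup_mean = mean(after), followup_sd = stats::sd(after),
    t = t_stat, df = n - 1L,
    p = if (undefined) NA_real_ else
      2 * stats::pt(-abs(t_stat), n - 1),
    gains = sum(d == -1L), losses = sum(d == 1L),
    undefined = undefined
  ), class = "paired_change_result")
}

#' @export
print.paired_change_result <- function(x, ...) {
  cat(sprintf(
    "baseline mean %.2f (SD %.2f); follow-up mean %.2f (SD %.2f); t(%d) = %.2f, p = %.3g\n",
    x$baseline_mean, x$baseline_sd, x$followup_mean, x$followup_sd,
    x$df, x$t, x$p))
  invisible(x)
}
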