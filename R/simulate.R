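#' Configuration for the synthetic study generator
#'
#' Defines every distributional knob of a synthetic screening study:
#' app-user demographics, age-linked item marginals for the 8-item risk
#' score, the score-to-UDPD logistic link, the follow-up model, and
#' behaviour-change transition rates.
#'
#' Defaults emulate the study conditions the analysis pipeline targets:
#' demographic marginals of a large app-user cohort (n = 4549; 60.2% male;
#' age bands 22.1/13.4/29.2/35.3%; education 20.1/37.9/42.0%), a score
#' distribution with mean 9.10 and SD 4.85, an assessed subsample
#' (fraction 188/4549) with UDPD prevalence 0.42 and score-vs-UDPD AUC
#' 0.67, follow-up duration 22.66 (SD 5.83) months truncated to \[1, 28\],
#' a 2-year event probability of 0.016 in the low-risk group with the odds
#' multiplied by `or_true` = 4.59 in the high-risk group, and behaviour
#' transition rates (vegetables gain .18 / loss .01, exercise .24/.11,
#' smoking .01/.06, alcohol .005/.03). Item marginals rise with age band;
#' their values were calibrated once, deterministically, so the expected
#' score moments match the targets.
#'
#' @param n_users Number of app users to simulate.
#' @param p_male Probability of male sex.
#' @param age_band_probs Probabilities of age bands (<45, 45-54, 55-64,
#'   >=65); must sum to 1.
#' @param education_probs Probabilities of primary-or-below, secondary,
#'   tertiary-or-higher; must sum to 1.
#' @param item_probs List of per-band (length-4) probabilities: `gluc`,
#'   `fam`, `bp`, `act_no`, `fv_no` (flag items), `bmi1`, `bmi3`, `w3`,
#'   `w4` (category items).
#' @param hba1c_intercept,hba1c_slope Logistic link P(UDPD | score) =
#'   plogis(intercept + slope * score).
#' @param p_diabetes_given_udpd Probability that a UDPD-positive subject is
#'   in the diabetes (HbA1c >= 48) rather than prediabetes range.
#' @param assessed_fraction Fraction of users with an HbA1c assessment.
#' @param followup_fraction Fraction of users with follow-up records.
#' @param followup_mean_months,followup_sd_months,followup_range Truncated
#'   normal parameters for follow-up duration.
#' @param p_event_low 2-year incident-diabetes probability, low-risk group.
#' @param or_true Odds ratio multiplying the low-risk odds for the
#'   high-risk group.
#' @param behavior List per flag of `c(base, gain, loss)` unconditional
#'   baseline prevalence and transition rates.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(
    n_users = 4549,
    p_male = 2738 / 4549,
    age_band_probs = c(1005, 610, 1328, 1606) / 4549,
    education_probs = c(914, 1724, 1911) / 4549,
    item_probs = list(
      gluc   = c(0.107, 0.186, 0.296, 0.421),
      fam    = c(0.250, 0.232, 0.214, 0.197),
      bp     = c(0.065, 0.134, 0.250, 0.400),
      act_no = c(0.408, 0.436, 0.464, 0.492),
      fv_no  = c(0.373, 0.391, 0.409, 0.428),
      bmi1   = c(0.297, 0.339, 0.382, 0.428),
      bmi3   = c(0.059, 0.078, 0.102, 0.132),
      w3     = c(0.166, 0.225, 0.298, 0.383),
      w4     = c(0.060, 0.104, 0.170, 0.262)),
    hba1c_intercept = -1.5468, hba1c_slope = 0.13152,
    p_diabetes_given_udpd = 0.177,
    assessed_fraction = 188 / 4549,
    followup_fraction = 326 / 4549,
    followup_mean_months = 22.66, followup_sd_months = 5.83,
    followup_range = c(1, 28),
    p_event_low = 0.016, or_true = 4.59,
    behavior = list(
      vegetables = c(base = 0.76, gain = 0.18,  loss = 0.01),
      exercise   = c(base = 0.40, gain = 0.24,  loss = 0.11),
      smoking    = c(base = 0.15, gain = 0.01,  loss = 0.06),
      alcohol    = c(base = 0.07, gain = 0.005, loss = 0.03))) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_male, cfg$age_band_probs, cfg$education_probs,
             unlist(cfg$item_probs), cfg$p_event_low,
             cfg$assessed_fraction, cfg$followup_fraction,
             cfg$p_diabetes_given_udpd, unlist(cfg$behavior))
  if (any(probs < 0 | probs > 1))
    stop_drs("all probabilities must lie in [0, 1]", "drs_invalid_config")
  if (abs(sum(cfg$age_band_probs) - 1) > 1e-6 ||
      abs(sum(cfg$education_probs) - 1) > 1e-6)
    stop_drs("age band and education probabilities must each sum to 1",
             "drs_invalid_config")
  if (any(cfg$item_probs$bmi1 + cfg$item_probs$bmi3 > 1) ||
      any(cfg$item_probs$w3 + cfg$item_probs$w4 > 1))
    stop_drs("category probabilities exceed 1 within a band",
             "drs_invalid_config")
  structure(cfg, class = "generator_config")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

rcat <- function(n, probs, values) {
  # probs: n x k matrix of per-row category probabilities
  u <- stats::runif(n)
  cum <- t(apply(probs, 1, cumsum))
  cum[, ncol(cum)] <- 1
  values[1L + rowSums(u > cum)]
}

#' Generate a complete synthetic screening study
#'
#' Produces three linked tables: `profiles` (scoreable risk profiles with
#' raw anthropometry consistent with the intended score categories),
#' `hba1c` (an assessed subsample with integer HbA1c in mmol/mol drawn to
#' match the configured score-UDPD link), and `followup` (a respondent
#' subsample with risk group, follow-up duration, incident diabetes and
#' baseline/follow-up behaviour flags). All randomness flows from `seed`
#' through a named stream per table, so each table is reproducible
#' independently of the others.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return List of class `synthetic_study` with elements `profiles`,
#'   `hba1c`, `followup`, plus the `config` and `seed` used.
#' @export
generate_study <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_users
  ip <- config$item_probs

  set.seed(seed + 101L)  # stream: profiles
  band <- sample.int(4L, n, TRUE, config$age_band_probs)
  age <- c(18L, 45L, 55L, 65L)[band] +
    floor(stats::runif(n) * c(27, 10, 10, 26)[band])
  sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  education <- sample(c("primary_or_below", "secondary",
                        "tertiary_or_higher"), n, TRUE,
                      config$education_probs)
  bern <- function(p) stats::runif(n) < p[band]
  gluc <- bern(ip$gluc); fam <- bern(ip$fam); bp <- bern(ip$bp)
  act_no <- bern(ip$act_no); fv_no <- bern(ip$fv_no)
  bmi_cat <- rcat(n, cbind(1 - ip$bmi1[band] - ip$bmi3[band],
                           ip$bmi1[band], ip$bmi3[band]), c(0L, 1L, 3L))
  w_cat <- rcat(n, cbind(1 - ip$w3[band] - ip$w4[band],
                         ip$w3[band], ip$w4[band]), c(0L, 3L, 4L))
  # raw anthropometry consistent with the drawn categories; band interiors
  # leave margin so rounding weight/height cannot cross a category edge
  bmi <- ifelse(bmi_cat == 0L, stats::runif(n, 19, 24.8),
                ifelse(bmi_cat == 1L, stats::runif(n, 25.1, 29.9),
                       stats::runif(n, 30.2, 40)))
  w_lo <- ifelse(sex == "male", 94, 80)
  w_hi <- ifelse(sex == "male", 102, 88)
  waist <- ifelse(w_cat == 0L, stats::runif(n, 60, w_lo - 0.5),
                  ifelse(w_cat == 3L, stats::runif(n, w_lo, w_hi),
                         stats::runif(n, w_hi + 0.5, w_hi + 25)))
  waist <- round(waist * 2) / 2  # instrument records to 0.5 cm
  height <- round(stats::rnorm(n, ifelse(sex == "male", 1.71, 1.58), 0.06), 2)
  weight <- round(bmi * height^2, 1)
  profiles <- data.frame(
    id = seq_len(n), age = age, sex = sex, education = education,
    weight = weight, weight_unit = "kg", height = height, height_unit = "m",
    waist_cm = waist,
    bp_med = as.integer(bp), high_glucose_hist = as.integer(gluc),
    daily_activity = as.integer(!act_no),
    daily_fruit_veg = as.integer(!fv_no),
    family_diabetes = as.integer(fam))
  total <- c(0L, 2L, 3L, 4L)[band] + bmi_cat + w_cat +
    2L * bp + 5L * gluc + 2L * act_no +
    1L * fv_no + 5L * fam

  set.seed(seed + 202L)  # stream: hba1c
  n_assessed <- max(1L, round(config$assessed_fraction * n))
  assessed <- sort(sample.int(n, n_assessed))
  p_udpd <- stats::plogis(config$hba1c_intercept +
                            config$hba1c_slope * total[assessed])
  udpd <- stats::runif(n_assessed) < p_udpd
  dm <- udpd & stats::runif(n_assessed) < config$p_diabetes_given_udpd
  hba1c_val <- integer(n_assessed)
  hba1c_val[!udpd] <- sample(28:38, sum(!udpd), TRUE,
                             prob = stats::dnorm(28:38, 35, 2.5))
  hba1c_val[udpd & !dm] <- sample(39:47, sum(udpd & !dm), TRUE,
                                  prob = stats::dnorm(39:47, 41, 3))
  hba1c_val[dm] <- sample(48:70, sum(dm), TRUE,
                          prob = stats::dexp(0:22, rate = 0.25))
  hba1c <- data.frame(id = assessed, hba1c_value = hba1c_val,
                      hba1c_unit = "mmol/mol")

  set.seed(seed + 303L)  # stream: followup
  n_fu <- max(1L, round(config$followup_fraction * n))
  fu_ids <- sort(sample.int(n, n_fu))
  months <- round(rtruncnorm1(n_fu, config$followup_mean_months,
                              config$followup_sd_months,
                              config$followup_range[1],
                              config$followup_range[2]), 1)
  risk_group <- classify_risk(total[fu_ids])
  odds_low <- config$p_event_low / (1 - config$p_event_low)
  p_event <- ifelse(risk_group == "high",
                    odds_low * config$or_true / (1 + odds_low * config$or_true),
                    config$p_event_low)
  event <- stats::runif(n_fu) < p_event
  # diagnoses are reported in whole months within the follow-up window
  mtd <- ifelse(event, pmax(1, ceiling(stats::runif(n_fu) * floor(months))),
                NA_real_)
  followup <- data.frame(
    id = fu_ids, risk_group = risk_group,
    months_followed = months,
    incident_diabetes = as.integer(event),
    months_to_diagnosis = mtd,
    sex = sex[fu_ids], education = education[fu_ids])
  for (nm in names(config$behavior)) {
    b <- config$behavior[[nm]]
    base <- stats::runif(n_fu) < b["base"]
    p01 <- min(1, b["gain"] / max(1e-9, 1 - b["base"]))
    p10 <- min(1, b["loss"] / max(1e-9, b["base"]))
    u <- stats::runif(n_fu)
    fu <- ifelse(base, ifelse(u < p10, 0L, 1L), ifelse(u < p01, 1L, 0L))
    followup[[paste0(nm, "_baseline")]] <- as.integer(base)
    followup[[paste0(nm, "_followup")]] <- as.integer(fu)
  }

  structure(list(profiles = profiles, hba1c = hba1c, followup = followup,
                 config = config, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic study (seed %d): %d profiles, %d assessed, %d followed\n",
    x$seed, nrow(x$profiles), nrow(x$hba1c), nrow(x$followup)))
  invisible(x)
}

#' Calibrate the score-to-UDPD logistic link
#'
#' Finds (intercept, slope) of P(UDPD | score) = plogis(a + b score) such
#' that, over a supplied score distribution, the expected UDPD prevalence
#' equals `target_prevalence` and the expected score-vs-UDPD AUC equals
#' `target_auc`. Both quantities are computed deterministically from the
#' score counts (no simulation noise): the inner root finds the intercept
#' matching the prevalence for a given slope, the outer root finds the
#' slope matching the AUC.
#'
#' @param target_auc Target AUC in (0.5, 1).
#' @param target_prevalence Target UDPD prevalence in (0, 1).
#' @param scores Integer score sample defining the distribution; defaults
#'   to the totals of a large generated cohort (n = 50000, fixed seed).
#' @param config Generator configuration used when `scores` is NULL.
#' @return List with `intercept`, `slope`, and the achieved `auc` and
#'   `prevalence`.
#' @export
calibrate_hba1c_link <- function(target_auc, target_prevalence,
                                 scores = NULL,
                                 config = generator_config()) {
  if (target_auc <= 0.5 || target_auc >= 1)
    stop_drs("target_auc must lie in (0.5, 1)", "drs_validation")
  if (is.null(scores)) {
    big <- generator_config(n_users = 50000)
    study <- generate_study(big, seed = 760814L)
    scores <- score_profiles(study$profiles)$total
  }
  s_max <- max(scores)
  cnt <- tabulate(scores + 1L, s_max + 1L)
  s_vals <- 0:s_max
  prev_link <- function(a, b)
    sum(cnt * stats::plogis(a + b * s_vals)) / sum(cnt)
  auc_link <- function(a, b) {
    w <- stats::plogis(a + b * s_vals)
    npos <- cnt * w; nneg <- cnt * (1 - w)
    cum_neg <- cumsum(c(0, nneg[-length(nneg)]))
    (sum(npos * cum_neg) + 0.5 * sum(npos * nneg)) /
      (sum(npos) * sum(nneg))
  }
  solve_a <- function(b)
    stats::uniroot(function(a) prev_link(a, b) - target_prevalence,
                   c(-20 - b * s_max, 20), tol = 1e-12)$root
  b_max <- 5
  if (auc_link(solve_a(b_max), b_max) < target_auc)
    stop_drs("target AUC unattainable given the score spread",
             "drs_infeasible")
  slope <- stats::uniroot(function(b) auc_link(solve_a(b), b) - target_auc,
                          c(1e-6, b_max), tol = 1e-10)$root
  intercept <- solve_a(slope)
  list(intercept = intercept, slope = slope,
       auc = auc_link(intercept, slope),
       prevalence = prev_link(intercept, slope))
}
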