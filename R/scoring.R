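#' Scoring configuration for the 8-item diabetes risk score
#'
#' The score sums points over eight items: age, BMI, waist circumference,
#' blood-pressure medication, history of elevated glucose, daily physical
#' activity, daily fruit/vegetable intake, and family history of diabetes.
#' Two published variants of the fruit/vegetable item exist: the original
#' instrument awards 1 point for \dQuote{no} (total range 0--26), a later
#' variant awards 2 (range 0--27). The default is 1, which is the only
#' variant consistent with a stated maximum of 26.
#'
#' @param fruit_veg_no_points Points for not eating fruit/vegetables daily;
#'   1 (original) or 2 (variant).
#' @param high_risk_cutoff Total score at or above which a user is classified
#'   high risk. Default 9, i.e. the cutoff written \dQuote{> 8} in
#'   cutoff tables.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(fruit_veg_no_points = 1L, high_risk_cutoff = 9L) {
  if (!fruit_veg_no_points %in% c(1L, 2L))
    stop_drs("fruit_veg_no_points must be 1 or 2", "drs_invalid_config")
  if (high_risk_cutoff < 0 || high_risk_cutoff > 27)
    stop_drs("high_risk_cutoff must lie in [0, 27]", "drs_invalid_config")
  structure(list(fruit_veg_no_points = as.integer(fruit_veg_no_points),
                 high_risk_cutoff = as.integer(high_risk_cutoff)),
            class = "scoring_config")
}

#' Body mass index from unit-tagged weight and height
#'
#' Converts pounds to kilograms (/2.20462) and inches to metres (*0.0254),
#' then computes weight / height^2. BMI is carried at full precision into
#' scoring; no intermediate rounding.
#'
#' @param weight Positive body weight.
#' @param height Positive body height.
#' @param weight_unit `"kg"` or `"lb"`.
#' @param height_unit `"m"` or `"inch"`.
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(70, 1.75)                       # 22.86
#' compute_bmi(154.324, 68.898, "lb", "inch")  # same body
#' @export
compute_bmi <- function(weight, height, weight_unit = c("kg", "lb"),
                        height_unit = c("m", "inch")) {
  weight_unit <- match.arg(weight_unit)
  height_unit <- match.arg(height_unit)
  if (any(is.na(weight)) || any(is.na(height)))
    stop_drs("weight and height must be non-missing", "drs_validation")
  if (any(weight <= 0))
    stop_drs("weight must be positive", "drs_validation")
  if (any(height <= 0))
    stop_drs("height must be positive", "drs_validation")
  w <- if (weight_unit == "lb") weight / 2.20462 else weight
  h <- if (height_unit == "inch") height * 0.0254 else height
  w / h^2
}

## Per-item banding. Category edges follow the printed instrument bands,
## read as closed intervals: BMI 25-30 scores 1 and exactly 30 stays 1;
## strictly above 30 scores 3. Same pattern for waist and age.

age_points <- function(age) {
  ifelse(age < 45, 0L, ifelse(age < 55, 2L, ifelse(age < 65, 3L, 4L)))
}

bmi_points <- function(bmi) {
  ifelse(bmi < 25, 0L, ifelse(bmi <= 30, 1L, 3L))
}

waist_points <- function(waist_cm, sex) {
  lo <- ifelse(sex == "male", 94, 80)
  hi <- ifelse(sex == "male", 102, 88)
  ifelse(waist_cm < lo, 0L, ifelse(waist_cm <= hi, 3L, 4L))
}

#' Score one risk profile
#'
#' Computes the eight item scores and their total for a single profile.
#' Flags follow the instrument's risk direction: `bp_medication`,
#' `told_high_glucose` and `family_diabetes` score when `TRUE`;
#' `daily_activity` and `daily_fruit_veg` score when `FALSE` (protective
#' behaviours absent).
#'
#' @param profile A list or one-row data frame with fields `age_years`, `sex`
#'   (`"male"`/`"female"`), either `bmi` or (`weight`, `height` with optional
#'   `weight_unit`, `height_unit`), `waist_cm`, and the five logical flags
#'   `bp_medication`, `told_high_glucose`, `daily_activity`,
#'   `daily_fruit_veg`, `family_diabetes`.
#' @param config A [scoring_config()].
#' @return A list of class `score_breakdown` with the eight item scores,
#'   `total`, and `risk_class`.
#' @examples
#' p <- list(age_years = 50, sex = "male", bmi = 26, waist_cm = 95,
#'           bp_medication = TRUE, told_high_glucose = FALSE,
#'           daily_activity = TRUE, daily_fruit_veg = TRUE,
#'           family_diabetes = FALSE)
#' score_profile(p)$total # 8
#' @export
score_profile <- function(profile, config = scoring_config()) {
  stopifnot(inherits(config, "scoring_config"))
  p <- as.list(profile)
  if (is.null(p$sex) || is.na(p$sex) || !p$sex %in% c("male", "female"))
    stop_drs("sex must be 'male' or 'female' (needed for the waist item)",
             "drs_validation")
  if (is.null(p$age_years) || is.na(p$age_years))
    stop_drs("age_years is missing", "drs_validation")
  if (p$age_years < 18)
    stop_drs("age_years must be >= 18 (adult instrument)", "drs_validation")
  if (is.null(p$waist_cm) || is.na(p$waist_cm) || p$waist_cm <= 0)
    stop_drs("waist_cm must be positive", "drs_validation")
  if (abs(p$waist_cm * 2 - round(p$waist_cm * 2)) > 1e-8)
    warning("waist_cm is finer than the instrument's 0.5 cm resolution",
            call. = FALSE)
  bmi <- p$bmi %||% compute_bmi(p$weight, p$height,
                                p$weight_unit %||% "kg",
                                p$height_unit %||% "m")
  flags <- c("bp_medication", "told_high_glucose", "daily_activity",
             "daily_fruit_veg", "family_diabetes")
  for (f in flags)
    if (is.null(p[[f]]) || is.na(p[[f]]))
      stop_drs(paste0(f, " is missing"), "drs_validation")
  items <- list(
    age = age_points(p$age_years),
    bmi = bmi_points(bmi),
    waist = waist_points(p$waist_cm, p$sex),
    bp = if (isTRUE(as.logical(p$bp_medication))) 2L else 0L,
    glucose_history = if (isTRUE(as.logical(p$told_high_glucose))) 5L else 0L,
    activity = if (isTRUE(as.logical(p$daily_activity))) 0L else 2L,
    fruit_veg = if (isTRUE(as.logical(p$daily_fruit_veg))) 0L
                else config$fruit_veg_no_points,
    family = if (isTRUE(as.logical(p$family_diabetes))) 5L else 0L
  )
  total <- sum(unlist(items))
  structure(c(items, list(total = total,
                          risk_class = classify_risk(total, config))),
            class = "score_breakdown")
}

#' Score a table of risk profiles
#'
#' Vectorised scoring of a profiles data frame (the `profiles.csv` schema:
#' `id`, `age`, `sex`, `weight`, `weight_unit`, `height`, `height_unit`,
#' `waist_cm`, `bp_med`, `high_glucose_hist`, `daily_activity`,
#' `daily_fruit_veg`, `family_diabetes`, flags coded 0/1). Columns named as
#' in [score_profile()] are also accepted.
#'
#' @param profiles Data frame of risk profiles.
#' @param config A [scoring_config()].
#' @return The input with the eight item-point columns, `total` and
#'   `risk_class` appended.
#' @export
score_profiles <- function(profiles, config = scoring_config()) {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0)
  get2 <- function(a, b) profiles[[a]] %||% profiles[[b]]
  age <- get2("age", "age_years")
  sex <- as.character(profiles$sex)
  waist <- profiles$waist_cm
  bmi <- profiles$bmi
  if (is.null(bmi)) {
    wu <- as.character(get2("weight_unit", "weight_unit") %||%
                         rep("kg", nrow(profiles)))
    hu <- as.character(get2("height_unit", "height_unit") %||%
                         rep("m", nrow(profiles)))
    w <- ifelse(wu == "lb", profiles$weight / 2.20462, profiles$weight)
    h <- ifelse(hu == "inch", profiles$height * 0.0254, profiles$height)
    if (any(is.na(w)) || any(is.na(h)) || any(w <= 0) || any(h <= 0))
      stop_drs("weight and height must be positive and non-missing",
               "drs_validation")
    bmi <- w / h^2
  }
  flag <- function(a, b) as.logical(as.integer(get2(a, b)))
  bp <- flag("bp_med", "bp_medication")
  gl <- flag("high_glucose_hist", "told_high_glucose")
  act <- flag("daily_activity", "daily_activity")
  fv <- flag("daily_fruit_veg", "daily_fruit_veg")
  fam <- flag("family_diabetes", "family_diabetes")
  out <- profiles
  out$pts_age <- age_points(age)
  out$pts_bmi <- bmi_points(bmi)
  out$pts_waist <- waist_points(waist, sex)
  out$pts_bp <- ifelse(bp, 2L, 0L)
  out$pts_glucose <- ifelse(gl, 5L, 0L)
  out$pts_activity <- ifelse(act, 0L, 2L)
  out$pts_fruit_veg <- ifelse(fv, 0L, config$fruit_veg_no_points)
  out$pts_family <- ifelse(fam, 5L, 0L)
  out$total <- out$pts_age + out$pts_bmi + out$pts_waist + out$pts_bp +
    out$pts_glucose + out$pts_activity + out$pts_fruit_veg + out$pts_family
  out$risk_class <- classify_risk(out$total, config)
  out
}

#' Classify a total score as low or high risk
#'
#' @param total Integer total score(s) in \[0, 27\].
#' @param config A [scoring_config()]; high risk when
#'   `total >= config$high_risk_cutoff`.
#' @return Character vector, `"low"` or `"high"`.
#' @examples
#' classify_risk(9)  # "high"
#' classify_risk(8)  # "low"
#' @export
classify_risk <- function(total, config = scoring_config()) {
  if (any(total < 0)) stop_drs("total score cannot be negative",
                               "drs_validation")
  if (any(total > 27)) stop_drs("total score cannot exceed 27",
                                "drs_validation")
  ifelse(total >= config$high_risk_cutoff, "high", "low")
}
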