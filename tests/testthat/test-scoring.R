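test_that("BMI is unit-converted correctly and validates its inputs", {
  expect_equal(compute_bmi(70, 1.75), 70 / 1.75^2, tolerance = 1e-12)
  # same physical body expressed in pounds and inches
  expect_equal(compute_bmi(154.324, 68.898, "lb", "inch"),
               compute_bmi(70, 1.75), tolerance = 1e-3)
  expect_error(compute_bmi(0, 1.75), class = "drs_validation")
  expect_error(compute_bmi(70, -1), class = "drs_validation")
  expect_error(compute_bmi(NA, 1.75), class = "drs_validation")
})

test_that("item points and totals match the instrument's point table", {
  expect_equal(score_profile(base_profile())$total, 0)
  worst <- base_profile(age_years = 70, bmi = 32, waist_cm = 105,
                        sex = "male", bp_medication = TRUE,
                        told_high_glucose = TRUE, daily_activity = FALSE,
                        daily_fruit_veg = FALSE, family_diabetes = TRUE)
  expect_equal(score_profile(worst)$total, 26)  # 4+3+4+2+5+2+1+5
  mid <- base_profile(age_years = 50, bmi = 26, waist_cm = 95,
                      sex = "male", bp_medication = TRUE)
  b <- score_profile(mid)
  expect_equal(unlist(b[c("age", "bmi", "waist", "bp")]),
               c(age = 2, bmi = 1, waist = 3, bp = 2))
  expect_equal(b$total, 8)
  # variant fruit/veg config raises the maximum to 27
  expect_equal(score_profile(worst, scoring_config(2))$total, 27)
})

test_that("category boundaries are closed as printed (no gaps, no overlap)", {
  # BMI exactly 25 and exactly 30 both score 1; just above 30 scores 3
  bmis <- c(24.999, 25, 30, 30.001)
  pts <- vapply(bmis, function(b)
    score_profile(base_profile(bmi = b))$bmi, 0L)
  expect_equal(pts, c(0L, 1L, 1L, 3L))
  # male waist edges 94 and 102; female edges 80 and 88
  wm <- vapply(c(93.5, 94, 102, 102.5), function(w)
    score_profile(base_profile(sex = "male", waist_cm = w))$waist, 0L)
  expect_equal(wm, c(0L, 3L, 3L, 4L))
  wf <- vapply(c(79.5, 80, 88, 88.5), function(w)
    score_profile(base_profile(waist_cm = w))$waist, 0L)
  expect_equal(wf, c(0L, 3L, 3L, 4L))
  # age edges 45, 55, 65
  ap <- vapply(c(44, 45, 54, 55, 64, 65), function(a)
    score_profile(base_profile(age_years = a))$age, 0L)
  expect_equal(ap, c(0L, 2L, 2L, 3L, 3L, 4L))
})

test_that("scoring is monotone in age, BMI and waist", {
  for (age in c(30, 50, 60, 70))
    for (bmi in c(22, 27, 32)) {
      totals <- vapply(c(70, 84, 95), function(w)
        score_profile(base_profile(age_years = age, bmi = bmi,
                                   waist_cm = w))$total, 0L)
      expect_true(all(diff(totals) >= 0))
    }
  totals_age <- vapply(c(30, 50, 60, 70), function(a)
    score_profile(base_profile(age_years = a))$total, 0L)
  expect_true(all(diff(totals_age) >= 0))
})

test_that("risk classification applies the >= cutoff rule", {
  expect_equal(classify_risk(9), "high")
  expect_equal(classify_risk(8), "low")
  expect_equal(classify_risk(0), "low")
  expect_equal(classify_risk(12, scoring_config(high_risk_cutoff = 13)),
               "low")
  expect_error(classify_risk(-1), class = "drs_validation")
})

test_that("scoring validates required fields", {
  expect_error(score_profile(base_profile(sex = NA)),
               class = "drs_validation")
  expect_error(score_profile(base_profile(age_years = 17)),
               class = "drs_validation")
  expect_error(score_profile(base_profile(bp_medication = NA)),
               class = "drs_validation")
  expect_warning(score_profile(base_profile(waist_cm = 70.25)),
                 "0.5 cm")
})

test_that("vectorised scoring agrees with per-profile scoring", {
  grid <- product_space_profiles()[seq(1, 2304, by = 37), ]
  df <- data.frame(
    id = seq_len(nrow(grid)), age = grid$age, sex = grid$sex,
    bmi = grid$bmi, waist_cm = waist_for(grid$sex, grid$waist_rank),
    bp_med = as.integer(grid$bp), high_glucose_hist = as.integer(grid$gluc),
    daily_activity = as.integer(grid$act),
    daily_fruit_veg = as.integer(grid$fv),
    family_diabetes = as.integer(grid$fam))
  scored <- score_profiles(df)
  singles <- vapply(seq_len(nrow(grid)), function(i)
    score_profile(list(age_years = grid$age[i], sex = grid$sex[i],
                       bmi = grid$bmi[i],
                       waist_cm = waist_for(grid$sex[i], grid$waist_rank[i]),
                       bp_medication = grid$bp[i],
                       told_high_glucose = grid$gluc[i],
                       daily_activity = grid$act[i],
                       daily_fruit_veg = grid$fv[i],
                       family_diabetes = grid$fam[i]))$total, 0L)
  expect_equal(scored$total, singles)
})
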