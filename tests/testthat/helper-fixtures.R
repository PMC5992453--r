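# Small fixtures built in code, shared across test files.

# A profile with every protective answer, overridable field by field.
base_profile <- function(...) {
  p <- list(age_years = 30, sex = "female", bmi = 22, waist_cm = 70,
            bp_medication = FALSE, told_high_glucose = FALSE,
            daily_activity = TRUE, daily_fruit_veg = TRUE,
            family_diabetes = FALSE)
  utils::modifyList(p, list(...))
}

# Full categorical product space of the instrument: one representative
# input per category of each item (2304 profiles).
product_space_profiles <- function() {
  expand.grid(
    age = c(30, 50, 60, 70),
    bmi = c(22, 27, 32),
    waist_rank = 1:3,
    sex = c("male", "female"),
    bp = c(FALSE, TRUE), gluc = c(FALSE, TRUE), act = c(TRUE, FALSE),
    fv = c(TRUE, FALSE), fam = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
}

waist_for <- function(sex, rank) {
  opts <- cbind(ifelse(sex == "male", 90, 75),
                ifelse(sex == "male", 98, 84),
                ifelse(sex == "male", 110, 95))
  opts[cbind(seq_along(rank), rank)]
}

# Brute-force AUC by pairwise enumeration.
auc_pairwise <- function(scores, statuses) {
  pos <- scores[as.logical(statuses)]
  neg <- scores[!as.logical(statuses)]
  wins <- outer(pos, neg, ">")
  ties <- outer(pos, neg, "==")
  (sum(wins) + 0.5 * sum(ties)) / (length(pos) * length(neg))
}

# Trapezoid area under the (fpr, tpr) polygon, anchored at (0,0) and (1,1).
auc_trapezoid <- function(points) {
  o <- order(points$fpr, points$tpr)
  x <- c(0, points$fpr[o], 1)
  y <- c(0, points$tpr[o], 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Exhaustive two-sided Fisher p over all tables with the observed margins.
fisher_enumerate <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Grid-search maximum-likelihood logistic fit (intercept + one binary
# predictor), successively refined; independent of any IRLS path.
grid_logistic <- function(y, x, span = 8, steps = 41, rounds = 6) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  c0 <- c1 <- 0; width <- span
  for (r in seq_len(rounds)) {
    g0 <- seq(c0 - width, c0 + width, length.out = steps)
    g1 <- seq(c1 - width, c1 + width, length.out = steps)
    vals <- outer(g0, g1, Vectorize(ll))
    idx <- arrayInd(which.max(vals), dim(vals))
    c0 <- g0[idx[1]]; c1 <- g1[idx[2]]
    width <- width * 2.5 / steps * 2
  }
  c(b0 = c0, b1 = c1)
}
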