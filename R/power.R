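#' Sample size for detecting an AUC above 0.5 (Hanley-McNeil)
#'
#' Solves z_(1-alpha/2) sqrt(V0) + z_(power) sqrt(V1) = A - 0.5 for a
#' continuous number of positives, with negatives fixed at `ratio` times the
#' positives. V(A) is the Hanley-McNeil variance
#' \[A(1-A) + (n_pos - 1)(Q1 - A^2) + (n_neg - 1)(Q2 - A^2)\] / (n_pos n_neg)
#' with Q1 = A/(2-A), Q2 = 2A^2/(1+A); V0 is evaluated at A = 0.5. The
#' continuous solution is rounded per `round` (nearest by default, as in
#' common ROC sample-size software; `"up"` gives the conservative ceiling),
#' and the total is n_pos * (1 + ratio).
#'
#' @param auc Alternative AUC, in (0.5, 1).
#' @param ratio Negatives per positive (kappa > 0).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param round `"nearest"` or `"up"` for the per-group rounding rule.
#' @return List with `n_pos`, `n_neg`, `total`, and the continuous solution
#'   `n_pos_continuous`.
#' @examples
#' auc_sample_size(0.70, ratio = 6) # 19 positives, 114 negatives, 133 total
#' @export
auc_sample_size <- function(auc, ratio = 1, alpha = 0.05, power = 0.80,
                            round = c("nearest", "up")) {
  round <- match.arg(round)
  if (auc <= 0.5 || auc >= 1)
    stop_drs("auc must lie strictly between 0.5 and 1", "drs_validation")
  if (ratio <= 0) stop_drs("ratio must be positive", "drs_validation")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop_drs("alpha and power must lie in (0, 1)", "drs_validation")
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  hm_var <- function(a, np, nn) {
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    (a * (1 - a) + (np - 1) * (q1 - a^2) + (nn - 1) * (q2 - a^2)) / (np * nn)
  }
  gap <- function(np) {
    za * sqrt(hm_var(0.5, np, ratio * np)) +
      zb * sqrt(hm_var(auc, np, ratio * np)) - (auc - 0.5)
  }
  n_cont <- stats::uniroot(gap, c(2, 1e7), tol = 1e-10)$root
  n_pos <- if (round == "nearest") as.integer(round_half_up(n_cont, 0))
           else as.integer(ceiling(n_cont))
  n_neg <- as.integer(round_half_up(ratio * n_pos, 0))
  list(n_pos = n_pos, n_neg = n_neg, total = n_pos + n_neg,
       n_pos_continuous = n_cont)
}

#' Achieved power of the AUC test at given group sizes
#'
#' Back-computes power from the Hanley-McNeil equation; companion check for
#' [auc_sample_size()].
#'
#' @inheritParams auc_sample_size
#' @param n_pos,n_neg Group sizes.
#' @return Achieved power.
#' @export
auc_power <- function(auc, n_pos, n_neg, alpha = 0.05) {
  za <- stats::qnorm(1 - alpha / 2)
  hm_var <- function(a, np, nn) {
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    (a * (1 - a) + (np - 1) * (q1 - a^2) + (nn - 1) * (q2 - a^2)) / (np * nn)
  }
  v0 <- hm_var(0.5, n_pos, n_neg)
  v1 <- hm_var(auc, n_pos, n_neg)
  stats::pnorm(((auc - 0.5) - za * sqrt(v0)) / sqrt(v1))
}

#' Sample size for a logistic-regression odds ratio (Demidenko z test)
#'
#' Wald z-test sample size for the slope beta1 = ln(OR) of a logistic model
#' with a single binomial(pi) exposure, following Demidenko's procedure as
#' implemented in G*Power's logistic-regression module. The variance of the
#' slope estimate under the alternative is
#' V1 = 1/((1-pi) p0 q0) + 1/(pi p1 q1); with the variance correction
#' (default) the null-hypothesis variance is evaluated at the mean-matched
#' null model, V0 = 1/(pbar qbar pi (1-pi)) with pbar = (1-pi) p0 + pi p1,
#' which inflates the requirement; without it V0 = V1. The returned n is
#' the ceiling of ((z_alpha sqrt(V0) + z_power sqrt(V1)) / ln OR)^2.
#'
#' Power analyses for a risk factor expected to increase risk are usually
#' specified directionally, so the default is a one-tailed alpha
#' (`tails = 1`), the convention under which the reference software
#' reproduces published calculations for this design; set `tails = 2` for a
#' non-directional test.
#'
#' @param or Alternative odds ratio (> 0, != 1).
#' @param p0 Event probability among the unexposed, in (0, 1).
#' @param pi Exposure prevalence, in (0, 1).
#' @param alpha Significance level.
#' @param power Target power.
#' @param corrected Apply the Demidenko variance correction (default TRUE).
#' @param tails 1 (default) or 2.
#' @return List with `n` (total sample size, rounded up) and `n_continuous`.
#' @examples
#' logistic_sample_size(4.5, p0 = 0.05, pi = 0.14)  # n = 292
#' @export
logistic_sample_size <- function(or, p0, pi, alpha = 0.05, power = 0.80,
                                 corrected = TRUE, tails = 1) {
  if (or <= 0 || or == 1)
    stop_drs("or must be positive and different from 1", "drs_validation")
  if (p0 <= 0 || p0 >= 1 || pi <= 0 || pi >= 1)
    stop_drs("p0 and pi must lie in (0, 1)", "drs_validation")
  if (!tails %in% c(1, 2)) stop_drs("tails must be 1 or 2", "drs_validation")
  b1 <- log(or)
  p1 <- stats::plogis(stats::qlogis(p0) + b1)
  v1 <- 1 / ((1 - pi) * p0 * (1 - p0)) + 1 / (pi * p1 * (1 - p1))
  v0 <- if (corrected) {
    pbar <- (1 - pi) * p0 + pi * p1
    1 / (pbar * (1 - pbar) * pi * (1 - pi))
  } else v1
  za <- if (tails == 1) stats::qnorm(1 - alpha) else stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n_cont <- ((za * sqrt(v0) + zb * sqrt(v1)) / abs(b1))^2
  list(n = as.integer(ceiling(n_cont - 1e-9)), n_continuous = n_cont)
}
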