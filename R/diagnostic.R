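#' Construct a confusion table
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @param cutoff Optional integer score cutoff the table was built at
#'   (positive call when score > cutoff).
#' @return Object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn, cutoff = NA_integer_) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop_drs("confusion cells must be non-negative integers",
             "drs_validation")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 cutoff = as.integer(cutoff)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("Confusion table",
      if (!is.na(x$cutoff)) sprintf("(positive call: score > %d)", x$cutoff),
      "\n")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, byrow = TRUE,
              dimnames = list(c("test+", "test-"), c("disease+", "disease-")))
  print(m)
  invisible(x)
}

#' Build a confusion table from scores and gold-standard statuses
#'
#' The positive screening call is `score > cutoff`, matching the
#' \dQuote{> c} convention of published cutoff tables (a narrative cutoff of
#' 9, \dQuote{score of 9 or higher}, is `cutoff = 8` here).
#'
#' @param scores Integer risk scores.
#' @param statuses Logical gold-standard positives (e.g. UDPD flags).
#' @param cutoff Integer cutoff.
#' @return A [confusion_table()].
#' @export
build_confusion <- function(scores, statuses, cutoff) {
  if (length(scores) == 0)
    stop_drs("empty input", "drs_validation")
  if (length(scores) != length(statuses))
    stop_drs("scores and statuses must have equal length", "drs_validation")
  statuses <- as.logical(statuses)
  call_pos <- scores > cutoff
  confusion_table(sum(call_pos & statuses), sum(call_pos & !statuses),
                  sum(!call_pos & statuses), sum(!call_pos & !statuses),
                  cutoff = cutoff)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Beta-quantile form of the exact interval: lower
#' `qbeta(alpha/2, x, n-x+1)` (0 when x = 0), upper
#' `qbeta(1-alpha/2, x+1, n-x)` (1 when x = n).
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  a <- (1 - conf_level) / 2
  c(lower = if (x == 0) 0 else stats::qbeta(a, x, n - x + 1),
    upper = if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x))
}

#' Diagnostic accuracy summary with exact confidence intervals
#'
#' Sensitivity, specificity, predictive values (each with Clopper-Pearson
#' 95% intervals), and both Youden conventions: `youden_j` = sensitivity +
#' specificity - 1 (the standard index) and `youden_plus` = sensitivity +
#' specificity (the un-shifted sum some reports print; the two differ by a
#' constant so cutoff selection is unaffected).
#'
#' @param table A [confusion_table()].
#' @param conf_level Confidence level for the exact intervals.
#' @return List of class `diagnostic_summary`; each proportion is a list
#'   with `est`, `lower`, `upper`. `ppv`/`npv` are `NA` (flagged via
#'   `undefined`) when their denominator is empty.
#' @export
diagnostic_summary <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "confusion_table"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  if (tp + fn == 0 || fp + tn == 0)
    stop_drs("need at least one gold-standard positive and one negative",
             "drs_validation")
  prop <- function(x, n) {
    if (n == 0)
      return(list(est = NA_real_, lower = NA_real_, upper = NA_real_))
    ci <- clopper_pearson(x, n, conf_level)
    list(est = x / n, lower = unname(ci[1]), upper = unname(ci[2]))
  }
  sens <- prop(tp, tp + fn)
  spec <- prop(tn, fp + tn)
  ppv <- prop(tp, tp + fp)
  npv <- prop(tn, tn + fn)
  structure(list(
    cutoff = table$cutoff,
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    youden_plus = sens$est + spec$est,
    youden_j = sens$est + spec$est - 1,
    kappa = cohen_kappa(table),
    undefined = c(ppv = tp + fp == 0, npv = tn + fn == 0)
  ), class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  f <- function(p) sprintf("%.2f (%.2f-%.2f)",
                           round_half_up(p$est, 2),
                           round_report(p$lower), round_report(p$upper))
  cat(sprintf(
    "cutoff >%s  sens %s  spec %s  ppv %s  npv %s  J %.2f  kappa %.3f\n",
    ifelse(is.na(x$cutoff), "?", x$cutoff), f(x$sensitivity),
    f(x$specificity), f(x$ppv), f(x$npv),
    x$youden_j, x$kappa))
  invisible(x)
}

#' Cohen's kappa for a 2x2 screening-vs-gold-standard table
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the marginals. Interpretive bands: <=0 none, 0.01-0.20
#' none to slight, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80
#' substantial, 0.81-1.00 almost perfect.
#'
#' @param table A [confusion_table()].
#' @return Kappa in \[-1, 1\]; `NA` with a warning when the marginals are
#'   degenerate (chance agreement 1).
#' @export
cohen_kappa <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  n <- table$tp + table$fp + table$fn + table$tn
  if (n == 0) stop_drs("empty table", "drs_validation")
  po <- (table$tp + table$tn) / n
  pe <- ((table$tp + table$fp) * (table$tp + table$fn) +
           (table$fn + table$tn) * (table$fp + table$tn)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warning("degenerate marginals: chance agreement is 1, kappa undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Interpretive band for a kappa value
#' @param kappa Numeric kappa.
#' @return Character label.
#' @export
kappa_band <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa <= 0) "no agreement"
  else if (kappa <= 0.20) "none to slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' ROC curve and AUC for an integer-valued score
#'
#' The AUC is the tie-corrected pairwise probability
#' P(score_pos > score_neg) + P(tie)/2, computed via the rank (Mann-Whitney)
#' statistic. Operating points are swept over every integer cutoff. The
#' confidence interval uses the Hanley-McNeil standard error with
#' Q1 = A/(2-A), Q2 = 2A^2/(1+A), truncated to \[0, 1\].
#'
#' @param scores Integer scores.
#' @param statuses Logical gold-standard positives.
#' @param conf_level Confidence level.
#' @return List of class `roc_result` with `auc`, `auc_ci`, `se`, and a
#'   data frame `points` of (cutoff, fpr, tpr).
#' @export
roc_auc <- function(scores, statuses, conf_level = 0.95) {
  statuses <- as.logical(statuses)
  n_pos <- sum(statuses); n_neg <- sum(!statuses)
  if (n_pos == 0 || n_neg == 0)
    stop_drs("need both a positive and a negative class", "drs_validation")
  r <- rank(scores)
  auc <- (sum(r[statuses]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  se <- hanley_mcneil_se(auc, n_pos, n_neg)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  cutoffs <- seq(min(scores) - 1L, max(scores))
  pts <- data.frame(
    cutoff = cutoffs,
    fpr = vapply(cutoffs, function(co) mean(scores[!statuses] > co), 0),
    tpr = vapply(cutoffs, function(co) mean(scores[statuses] > co), 0)
  )
  structure(list(auc = auc,
                 auc_ci = c(lower = max(0, auc - z * se),
                            upper = min(1, auc + z * se)),
                 se = se, n_pos = n_pos, n_neg = n_neg, points = pts),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.2f (95%% CI %.2f-%.2f), %d positives / %d negatives\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Diagnostic summaries over a grid of cutoffs, with optimal selection
#'
#' One [diagnostic_summary()] per cutoff; the selected cutoff maximises the
#' chosen criterion (Youden J or kappa). Ties break toward the lower cutoff,
#' which favours sensitivity -- the screening-appropriate direction.
#'
#' @param scores Integer scores.
#' @param statuses Logical gold-standard positives.
#' @param cutoffs Integer vector of cutoffs (positive call = score > cutoff).
#' @param criterion `"youden"` or `"kappa"`.
#' @return List of class `cutoff_grid` with `summaries` (one per cutoff),
#'   `selected` (the chosen cutoff) and `criterion`.
#' @export
cutoff_grid <- function(scores, statuses, cutoffs,
                        criterion = c("youden", "kappa")) {
  criterion <- match.arg(criterion)
  if (length(cutoffs) == 0) stop_drs("empty cutoff range", "drs_validation")
  tables <- lapply(cutoffs, function(co) build_confusion(scores, statuses, co))
  select_cutoff(tables, criterion)
}

#' Select the optimal cutoff from per-cutoff confusion tables
#'
#' The table-level companion of [cutoff_grid()], usable when only the
#' confusion tables (e.g. reconstructed from a published summary table) are
#' available rather than individual scores.
#'
#' When comparing against a published table, the criterion can be
#' evaluated at the table's reporting precision (`digits`): candidate
#' cutoffs whose rounded sensitivity + specificity tie are then separated
#' by the lower-cutoff rule. With `digits = NULL` (default) the exact
#' criterion is used.
#'
#' @param tables List of [confusion_table()]s, each with its `cutoff` set.
#' @param criterion `"youden"` or `"kappa"`.
#' @param digits Optional half-up rounding applied to the criterion before
#'   the argmax (reporting precision); `NULL` for exact.
#' @return As [cutoff_grid()].
#' @export
select_cutoff <- function(tables, criterion = c("youden", "kappa"),
                          digits = NULL) {
  criterion <- match.arg(criterion)
  summaries <- lapply(tables, diagnostic_summary)
  crit <- vapply(summaries, function(s)
    if (criterion == "youden") s$youden_j else s$kappa, 0)
  if (!is.null(digits)) crit <- round_half_up(crit, digits)
  if (all(is.na(crit)))
    stop_drs("criterion undefined at every cutoff", "drs_validation")
  cutoffs <- vapply(tables, function(t) t$cutoff, 0L)
  ord <- order(cutoffs)
  best <- ord[which.max(crit[ord])]  # which.max takes the first => lowest cutoff
  structure(list(summaries = summaries, criterion = criterion,
                 criterion_values = crit,
                 selected = unname(cutoffs[best])),
            class = "cutoff_grid")
}

#' @export
print.cutoff_grid <- function(x, ...) {
  for (s in x$summaries) print(s)
  cat(sprintf("selected cutoff: > %d (criterion: %s)\n",
              x$selected, x$criterion))
  invisible(x)
}
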