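#' Invert a rounded proportion to its integer numerator
#'
#' Published tables report proportions rounded (half-up) to a fixed number
#' of decimals. Given the reported value and the known denominator, the
#' underlying integer count is often unique and can be recovered exactly.
#' Ambiguity is never silently resolved: when zero or several integers are
#' consistent, an error of class `drs_not_unique` (carrying the candidate
#' set) is raised so the caller can bring additional constraints.
#'
#' @param p_reported Reported proportion.
#' @param n Denominator.
#' @param decimals Reported precision (default 2).
#' @return The unique integer count.
#' @examples
#' invert_rounded_count(0.70, 79)  # 55
#' @export
invert_rounded_count <- function(p_reported, n, decimals = 2) {
  if (n <= 0) stop_drs("n must be positive", "drs_validation")
  cand <- rounding_candidates(p_reported, n, decimals)
  if (length(cand) != 1)
    stop_drs(sprintf("no unique count: round(k/%d, %d) = %s for k in {%s}",
                     n, decimals, format(p_reported),
                     paste(cand, collapse = ", ")),
             "drs_not_unique", candidates = cand)
  cand
}

rounding_candidates <- function(p_reported, n, decimals = 2) {
  k <- 0:n
  tol <- 10^(-decimals) / 2 * 1e-6
  k[abs(round_half_up(k / n, decimals) - p_reported) < tol]
}

#' Rebuild a confusion table from four rounded accuracy metrics
#'
#' Joint constraint satisfaction over (tp, tn): candidate true-positive
#' counts come from the rounded sensitivity, candidate true-negative counts
#' from the rounded specificity, and the pair must also reproduce the
#' rounded PPV and NPV. Exactly one pair must survive.
#'
#' @param sens,spec,ppv,npv Reported proportions (half-up, `decimals` dp).
#' @param n_pos,n_neg Gold-standard positive and negative counts.
#' @param cutoff Optional cutoff tag for the returned table.
#' @param decimals Reported precision.
#' @return A [confusion_table()].
#' @examples
#' rebuild_confusion(0.70, 0.57, 0.54, 0.72, 79, 109) # (55, 47, 24, 62)
#' @export
rebuild_confusion <- function(sens, spec, ppv, npv, n_pos, n_neg,
                              cutoff = NA_integer_, decimals = 2) {
  if (n_pos <= 0 || n_neg <= 0)
    stop_drs("margins must be positive", "drs_validation")
  tp_cand <- rounding_candidates(sens, n_pos, decimals)
  tn_cand <- rounding_candidates(spec, n_neg, decimals)
  grid <- expand.grid(tp = tp_cand, tn = tn_cand)
  ok <- vapply(seq_len(nrow(grid)), function(i) {
    tp <- grid$tp[i]; tn <- grid$tn[i]
    fp <- n_neg - tn; fn <- n_pos - tp
    (tp + fp) > 0 && (tn + fn) > 0 &&
      round_half_up(tp / (tp + fp), decimals) == ppv &&
      round_half_up(tn / (tn + fn), decimals) == npv
  }, TRUE)
  grid <- grid[ok, , drop = FALSE]
  if (nrow(grid) == 0)
    stop_drs("no integer table is consistent with the four rounded metrics",
             "drs_infeasible")
  if (nrow(grid) > 1)
    stop_drs(sprintf("ambiguous reconstruction: %d candidate tables",
                     nrow(grid)), "drs_not_unique",
             candidates = grid)
  confusion_table(grid$tp, n_neg - grid$tn, n_pos - grid$tp, grid$tn,
                  cutoff = cutoff)
}

#' Published cutoff-table rows for the screening validation phase
#'
#' The six rows of the published FINDRISC cutoff characteristics table
#' (cutoffs >6 to >11 against UDPD status in 188 assessed users: 79
#' positives, 109 negatives): sensitivity, specificity, PPV and NPV, each
#' rounded to 2 decimals. These printed values are the *input* to the
#' reconstruction oracle.
#'
#' @return Data frame with columns `cutoff`, `sens`, `spec`, `ppv`, `npv`,
#'   `n_pos`, `n_neg`.
#' @export
table2_reported <- function() {
  data.frame(
    cutoff = 6:11,
    sens = c(0.78, 0.75, 0.70, 0.61, 0.52, 0.41),
    spec = c(0.39, 0.48, 0.57, 0.62, 0.75, 0.82),
    ppv  = c(0.48, 0.51, 0.54, 0.54, 0.60, 0.62),
    npv  = c(0.72, 0.72, 0.72, 0.69, 0.68, 0.65),
    n_pos = 79L, n_neg = 109L
  )
}

#' Reconstruct every confusion table of the published cutoff grid
#'
#' @param rows A data frame in the [table2_reported()] schema.
#' @return Named list of [confusion_table()]s, one per cutoff.
#' @export
reconstruct_table2 <- function(rows = table2_reported()) {
  out <- lapply(seq_len(nrow(rows)), function(i)
    rebuild_confusion(rows$sens[i], rows$spec[i], rows$ppv[i], rows$npv[i],
                      rows$n_pos[i], rows$n_neg[i], cutoff = rows$cutoff[i]))
  names(out) <- paste0(">", rows$cutoff)
  out
}

#' Split total incident cases across risk groups from rounded rates
#'
#' Person-time per group is approximated as group size times the mean
#' follow-up (months/12); the returned split minimises the summed absolute
#' deviation between the implied per-1000-person-year rates and the
#' reported ones. A tie between splits is an error listing both.
#'
#' @param total_cases Total incident cases.
#' @param group_sizes Numeric pair `c(n_high, n_low)`.
#' @param mean_followup_months Mean follow-up in months.
#' @param reported_rates Numeric pair: reported rates per 1000
#'   person-years, `c(high, low)`.
#' @return List with `cases_high`, `cases_low`, `implied_rates`, and
#'   `deviation`.
#' @examples
#' reconstruct_case_split(15, c(199, 127), 22.66, c(36.50, 8.59)) # 13 / 2
#' @export
reconstruct_case_split <- function(total_cases, group_sizes,
                                   mean_followup_months, reported_rates) {
  if (total_cases < 0) stop_drs("total_cases must be >= 0", "drs_validation")
  if (total_cases > min(group_sizes) + max(group_sizes))
    stop_drs("more cases than subjects", "drs_validation")
  py <- group_sizes * mean_followup_months / 12
  a <- 0:total_cases
  a <- a[a <= group_sizes[1] & (total_cases - a) <= group_sizes[2]]
  dev <- abs(1000 * a / py[1] - reported_rates[1]) +
    abs(1000 * (total_cases - a) / py[2] - reported_rates[2])
  best <- which(dev <= min(dev) + 1e-12)
  if (length(best) > 1)
    stop_drs(sprintf("tied splits: high-group cases in {%s}",
                     paste(a[best], collapse = ", ")),
             "drs_not_unique", candidates = a[best])
  list(cases_high = a[best], cases_low = total_cases - a[best],
       implied_rates = c(high = 1000 * a[best] / py[1],
                         low = 1000 * (total_cases - a[best]) / py[2]),
       deviation = dev[best])
}

#' Recover discordant-pair counts from a rounded paired t statistic
#'
#' For n paired binary observations with a known net change (gains minus
#' losses), searches all feasible (gains, losses) combinations for the one
#' whose paired t statistic (see [paired_binary_change()]) reproduces the
#' reported |t| at the stated precision. Requires uniqueness.
#'
#' @param n Number of pairs.
#' @param net_change Gains minus losses (follow-up ones minus baseline ones).
#' @param t_reported Reported |t|, rounded to `decimals`.
#' @param decimals Reported precision of t (default 2).
#' @return List with `gains` and `losses`.
#' @examples
#' solve_discordant_pairs(82, 14, 3.77) # 15 gains, 1 loss
#' @export
solve_discordant_pairs <- function(n, net_change, t_reported, decimals = 2) {
  if (abs(net_change) > n)
    stop_drs("net change cannot exceed the number of pairs",
             "drs_infeasible")
  g <- seq(max(0, net_change), n)
  l <- g - net_change
  feas <- l >= 0 & (g + l) <= n
  g <- g[feas]; l <- l[feas]
  t_abs <- vapply(seq_along(g), function(i) {
    d <- c(rep(-1, g[i]), rep(1, l[i]), rep(0, n - g[i] - l[i]))
    sd_d <- stats::sd(d)
    if (sd_d == 0) return(NA_real_)
    abs(mean(d) / (sd_d / sqrt(n)))
  }, 0)
  hit <- which(!is.na(t_abs) &
                 round_half_up(t_abs, decimals) == abs(t_reported))
  if (length(hit) == 0)
    stop_drs("no discordant-pair count reproduces the reported t",
             "drs_infeasible")
  if (length(hit) > 1)
    stop_drs(sprintf("ambiguous: gains in {%s}",
                     paste(g[hit], collapse = ", ")),
             "drs_not_unique", candidates = g[hit])
  list(gains = g[hit], losses = l[hit])
}

#' Reconstruct before/after indicator vectors for a behaviour flag
#'
#' Builds explicit paired 0/1 vectors with the given baseline prevalence
#' and transition counts, suitable for [paired_binary_change()].
#'
#' @param n Number of pairs.
#' @param baseline_ones Count of 1s at baseline.
#' @param gains Count of 0 to 1 transitions.
#' @param losses Count of 1 to 0 transitions.
#' @return List with `before` and `after` integer vectors.
#' @export
behavior_vectors <- function(n, baseline_ones, gains, losses) {
  stopifnot(baseline_ones <= n, gains <= n - baseline_ones,
            losses <= baseline_ones)
  before <- c(rep(1L, baseline_ones), rep(0L, n - baseline_ones))
  after <- before
  after[baseline_ones + seq_len(gains)] <- 1L
  after[seq_len(losses)] <- 0L
  list(before = before, after = after)
}

#' Reconstructed follow-up cohort as a 2x2 table and subject records
#'
#' Combines the published cohort margins (total cases, group sizes, mean
#' follow-up) with the reported group incidence rates via
#' [reconstruct_case_split()], returning both the 2x2 cell counts and
#' expanded subject-level records.
#'
#' @param total_cases,group_sizes,mean_followup_months,reported_rates As in
#'   [reconstruct_case_split()]; defaults are the published cohort values
#'   (15 cases; 199 high / 127 low; 22.66 months; rates 36.50 / 8.59).
#' @return List with `cells` (a, b, c, d), `records` (subject-level data
#'   frame), and the `split` detail.
#' @export
reconstruct_cohort <- function(total_cases = 15,
                               group_sizes = c(199, 127),
                               mean_followup_months = 22.66,
                               reported_rates = c(36.50, 8.59)) {
  split <- reconstruct_case_split(total_cases, group_sizes,
                                  mean_followup_months, reported_rates)
  a <- split$cases_high; b <- group_sizes[1] - a
  c <- split$cases_low; d <- group_sizes[2] - c
  list(cells = c(a = a, b = b, c = c, d = d),
       records = expand_two_by_two(a, b, c, d),
       split = split)
}
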