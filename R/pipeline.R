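#' Record-cleaning configuration
#'
#' Validity rules applied to raw app exports before analysis: minimum age,
#' a required phone country code (when a phone column is present), app
#' default-value sentinels for blood pressure, height and weight (a record
#' whose fields all equal the pre-filled defaults was never edited by the
#' user), and duplicate detection on a key column. Every rule can be
#' toggled off by setting it to `NULL` (or an empty sentinel list).
#'
#' @param min_age Minimum age in years (NULL disables).
#' @param country_code Required phone-number prefix (NULL disables).
#' @param sentinels Named list of default values, e.g.
#'   `list(height = 1.70, weight = 60)`; a record is excluded when every
#'   listed field equals its sentinel.
#' @param dedupe_key Column name used for duplicate detection
#'   (NULL disables).
#' @param required Columns that must be non-missing (NULL disables).
#' @return Object of class `cleaning_config`.
#' @export
cleaning_config <- function(min_age = 18, country_code = "852",
                            sentinels = list(), dedupe_key = "id",
                            required = c("age", "sex", "waist_cm")) {
  structure(list(min_age = min_age, country_code = country_code,
                 sentinels = sentinels, dedupe_key = dedupe_key,
                 required = required),
            class = "cleaning_config")
}

#' Clean raw records, logging each exclusion
#'
#' Applies the rules of a [cleaning_config()] in a fixed order (incomplete,
#' min_age, country_code, default_values, duplicate); each excluded record
#' is logged with the *first* rule it violated, so rule counts plus the
#' valid count always equal the raw count.
#'
#' @param raw Data frame of raw records.
#' @param config A [cleaning_config()].
#' @return List with `valid` (the retained rows), `exclusions` (data frame
#'   `row`, `id`, `rule`), and `counts` (exclusions per rule).
#' @export
clean_records <- function(raw, config = cleaning_config()) {
  stopifnot(is.data.frame(raw))
  n <- nrow(raw)
  rule <- rep(NA_character_, n)
  mark <- function(bad, label) {
    bad[is.na(bad)] <- FALSE
    rule[is.na(rule) & bad] <<- label
  }
  if (!is.null(config$required)) {
    have <- intersect(config$required, names(raw))
    if (length(have))
      mark(Reduce(`|`, lapply(raw[have], is.na)), "incomplete")
  }
  if (!is.null(config$min_age) && !is.null(raw$age))
    mark(raw$age < config$min_age, "min_age")
  if (!is.null(config$country_code) && !is.null(raw$phone))
    mark(!startsWith(gsub("^\\+", "", as.character(raw$phone)),
                     config$country_code), "country_code")
  if (length(config$sentinels)) {
    have <- intersect(names(config$sentinels), names(raw))
    if (length(have)) {
      all_default <- Reduce(`&`, lapply(have, function(f)
        raw[[f]] == config$sentinels[[f]]))
      mark(all_default, "default_values")
    }
  }
  if (!is.null(config$dedupe_key) && !is.null(raw[[config$dedupe_key]]))
    mark(duplicated(raw[[config$dedupe_key]]), "duplicate")
  keep <- is.na(rule)
  if (!any(keep)) warning("all records excluded", call. = FALSE)
  excl <- data.frame(row = which(!keep),
                     id = if (!is.null(raw$id)) raw$id[!keep] else
                       which(!keep),
                     rule = rule[!keep])
  list(valid = raw[keep, , drop = FALSE], exclusions = excl,
       counts = table(factor(excl$rule,
                             c("incomplete", "min_age", "country_code",
                               "default_values", "duplicate"))))
}

#' Run the full screening and follow-up pipeline
#'
#' Orchestrates the four study phases from input tables: descriptive
#' profile of scored users (phase 1a), cutoff validation against HbA1c
#' with the full diagnostic grid, AUC and kappa (phase 1b), cohort
#' incidence and unadjusted/adjusted logistic models with calibration
#' (phase 2a), and paired behaviour-change tests (phase 2b). The report is
#' a pure function of the inputs and configuration; analysis defaults are
#' echoed into it for provenance.
#'
#' @param config Either a path to a YAML file or a list with elements:
#'   `inputs` (paths or data frames `profiles`, `hba1c`, `followup`),
#'   `phases` (logical toggles `phase1a`, `phase1b`, `phase2a`, `phase2b`),
#'   and `params` (`cutoff`, `cutoffs` min/max, `criterion`,
#'   `fruit_veg_no_points`, `hl_groups`, `censor_at_diagnosis`,
#'   `zero_cell_policy`, `adjust` covariates).
#' @param out_json,out_tsv Optional output paths for the JSON report and
#'   the cutoff-grid TSV.
#' @return The report list (invisibly when written to file).
#' @export
run_pipeline <- function(config, out_json = NULL, out_tsv = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- utils::modifyList(list(
    cutoff = 9, cutoffs = c(6, 11), criterion = "youden",
    fruit_veg_no_points = 1, hl_groups = 10, censor_at_diagnosis = TRUE,
    zero_cell_policy = "haldane", adjust = c("sex", "education")),
    config$params %||% list())
  phases <- utils::modifyList(
    list(phase1a = TRUE, phase1b = TRUE, phase2a = TRUE, phase2b = TRUE),
    config$phases %||% list())
  load_tab <- function(x) if (is.character(x))
    utils::read.csv(x, stringsAsFactors = FALSE) else x
  need <- function(name, phase) {
    tab <- config$inputs[[name]]
    if (is.null(tab))
      stop_drs(sprintf("phase %s requires input '%s'", phase, name),
               "drs_missing_input")
    load_tab(tab)
  }
  scfg <- scoring_config(params$fruit_veg_no_points, params$cutoff)
  report <- list(params = params)

  profiles <- NULL
  if (phases$phase1a || phases$phase1b) {
    profiles <- score_profiles(need("profiles", "1a/1b"), scfg)
  }
  if (phases$phase1a) {
    report$phase1a <- list(
      n = nrow(profiles),
      score_mean = mean(profiles$total), score_sd = stats::sd(profiles$total),
      n_high = sum(profiles$risk_class == "high"),
      pct_high = 100 * mean(profiles$risk_class == "high"))
  }
  if (phases$phase1b) {
    hba1c <- need("hba1c", "1b")
    gl <- classify_glycemia(hba1c$hba1c_value,
                            unique(hba1c$hba1c_unit %||% "mmol/mol")[1])
    merged <- merge(profiles[, c("id", "total")],
                    cbind(id = hba1c$id, gl), by = "id")
    grid <- cutoff_grid(merged$total, merged$udpd_positive,
                        seq(params$cutoffs[1], params$cutoffs[2]),
                        params$criterion)
    roc <- roc_auc(merged$total, merged$udpd_positive)
    sel <- grid$summaries[[match(grid$selected,
                                 vapply(grid$summaries,
                                        function(s) s$cutoff, 0L))]]
    report$phase1b <- list(
      n = nrow(merged), n_pos = sum(merged$udpd_positive),
      prevalence = mean(merged$udpd_positive),
      grid = grid, auc = roc$auc, auc_ci = roc$auc_ci,
      selected_cutoff = grid$selected,
      kappa_at_selected = sel$kappa,
      kappa_band = kappa_band(sel$kappa))
    if (!is.null(out_tsv)) {
      tab <- do.call(rbind, lapply(grid$summaries, function(s) data.frame(
        cutoff = paste0(">", s$cutoff),
        sensitivity = round_half_up(s$sensitivity$est, 2),
        sens_ci = sprintf("%.2f-%.2f", round_report(s$sensitivity$lower),
                          round_report(s$sensitivity$upper)),
        specificity = round_half_up(s$specificity$est, 2),
        spec_ci = sprintf("%.2f-%.2f", round_report(s$specificity$lower),
                          round_report(s$specificity$upper)),
        ppv = round_half_up(s$ppv$est, 2), npv = round_half_up(s$npv$est, 2),
        youden_j = round_half_up(s$youden_j, 2),
        kappa = round_half_up(s$kappa, 3))))
      utils::write.table(tab, out_tsv, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    }
  }
  if (phases$phase2a) {
    fu <- cohort_factors(need("followup", "2a"))
    inc <- incidence_by_group(fu, params$censor_at_diagnosis)
    cells <- with(fu, c(
      a = sum(risk_group == "high" & incident_diabetes == 1),
      b = sum(risk_group == "high" & incident_diabetes == 0),
      c = sum(risk_group == "low" & incident_diabetes == 1),
      d = sum(risk_group == "low" & incident_diabetes == 0)))
    tbt <- two_by_two_analysis(cells["a"], cells["b"], cells["c"],
                               cells["d"], params$zero_cell_policy)
    adj <- intersect(params$adjust, names(fu))
    fit_u <- fit_logistic(fu, "incident_diabetes", "risk_group",
                          params$hl_groups)
    fit_a <- fit_logistic(fu, "incident_diabetes",
                          c("risk_group", adj), params$hl_groups)
    report$phase2a <- list(incidence = inc, two_by_two = tbt,
                           unadjusted = fit_u, adjusted = fit_a)
  }
  if (phases$phase2b) {
    fu <- need("followup", "2b")
    high <- fu[fu$risk_group == "high", , drop = FALSE]
    flags <- sub("_baseline$", "",
                 grep("_baseline$", names(high), value = TRUE))
    report$phase2b <- lapply(stats::setNames(flags, flags), function(f)
      paired_binary_change(high[[paste0(f, "_baseline")]],
                           high[[paste0(f, "_followup")]]))
  }
  if (!is.null(out_json)) {
    strip <- function(x) {
      if (inherits(x, "glm")) return(NULL)
      if (is.list(x)) {
        x <- lapply(x, strip)
        x[!vapply(x, is.null, TRUE)]
      } else x
    }
    jsonlite::write_json(strip(unclass(report)), out_json,
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}
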