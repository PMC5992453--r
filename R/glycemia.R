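#' Classify glycemic status from HbA1c
#'
#' Applies the American Diabetes Association thresholds: HbA1c >= 48
#' mmol/mol (6.5%) indicates diabetes; 39 <= HbA1c < 48 mmol/mol (5.7% to
#' <6.5%) indicates prediabetes; below 39 is normal. The gold-standard
#' positive class for screening (\dQuote{UDPD}: undiagnosed diabetes and
#' prediabetes) is any non-normal status. NGSP percent values are converted
#' to IFCC units via (percent - 2.15) * 10.929, rounded to the nearest
#' integer mmol/mol.
#'
#' @param value HbA1c value(s).
#' @param unit `"mmol/mol"` (IFCC) or `"percent"` (NGSP).
#' @return Data frame with `hba1c_mmol_per_mol`, `status`
#'   (`"normal"`/`"prediabetes"`/`"diabetes"`) and logical `udpd_positive`.
#' @examples
#' classify_glycemia(38)    # normal
#' classify_glycemia(39)    # prediabetes, UDPD positive
#' classify_glycemia(6.5, "percent") # 48 mmol/mol, diabetes
#' @export
classify_glycemia <- function(value, unit = c("mmol/mol", "percent")) {
  unit <- match.arg(unit)
  if (any(is.na(value)) || any(value <= 0))
    stop_drs("HbA1c values must be positive and non-missing",
             "drs_validation")
  mmol <- if (unit == "percent") round((value - 2.15) * 10.929) else value
  if (any(mmol > 200))
    warning("HbA1c above 200 mmol/mol is physiologically implausible",
            call. = FALSE)
  status <- ifelse(mmol >= 48, "diabetes",
                   ifelse(mmol >= 39, "prediabetes", "normal"))
  data.frame(hba1c_mmol_per_mol = mmol, status = status,
             udpd_positive = status != "normal")
}
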