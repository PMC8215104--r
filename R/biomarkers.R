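#' Friedewald LDL cholesterol
#'
#' `LDL = TC - HDL - TG/5` (all mg/dl). The formula is invalid at high
#' triglycerides; readings at or above `tg_limit` either raise an error or
#' return `NA` depending on `on_invalid`.
#'
#' @param tc Total cholesterol, mg/dl.
#' @param hdl HDL cholesterol, mg/dl.
#' @param tg Triglycerides, mg/dl.
#' @param tg_limit Validity bound for TG (default 400 mg/dl).
#' @param on_invalid `"error"` or `"missing"`.
#' @return LDL-C in mg/dl.
#' @export
friedewald_ldl <- function(tc, hdl, tg, tg_limit = 400,
                           on_invalid = c("error", "missing")) {
  on_invalid <- match.arg(on_invalid)
  if (any(c(tc, hdl, tg) < 0, na.rm = TRUE))
    stop("lipid inputs must be non-negative")
  bad <- !is.na(tg) & tg >= tg_limit
  if (any(bad)) {
    if (on_invalid == "error")
      stop("Friedewald formula invalid for TG >= ", tg_limit, " mg/dl")
    tg[bad] <- NA_real_
  }
  tc - hdl - tg / 5
}

#' Atherogenic index of plasma
#'
#' `AIP = log10(TG / HDL)`, both in mg/dl.
#'
#' @param tg Triglycerides, mg/dl; must be positive.
#' @param hdl HDL cholesterol, mg/dl; must be positive.
#' @export
aip <- function(tg, hdl) {
  if (any(c(tg, hdl) <= 0, na.rm = TRUE))
    stop("AIP requires positive TG and HDL")
  log10(tg / hdl)
}

#' HOMA-IR insulin resistance index
#'
#' `HOMA-IR = glucose * insulin / 405` with glucose in mg/dl and insulin
#' in uU/ml (mass-unit constant 405).
#'
#' @param glucose Fasting glucose, mg/dl.
#' @param insulin Fasting insulin, uU/ml.
#' @param constant Normalizing constant (default 405).
#' @export
homa_ir <- function(glucose, insulin, constant = 405) {
  if (any(c(glucose, insulin) < 0, na.rm = TRUE))
    stop("glucose and insulin must be non-negative")
  glucose * insulin / constant
}

#' QUICKI insulin sensitivity index
#'
#' `QUICKI = 1 / (log10(insulin) + log10(glucose))`, insulin in uU/ml and
#' glucose in mg/dl. Defined only where the log sum is positive.
#'
#' @param glucose Fasting glucose, mg/dl.
#' @param insulin Fasting insulin, uU/ml.
#' @export
quicki <- function(glucose, insulin) {
  s <- log10(insulin) + log10(glucose)
  if (any(!is.na(s) & s <= 0))
    stop("QUICKI undefined: log10(insulin) + log10(glucose) must be positive")
  1 / s
}

#' Average duplicate blood-pressure readings
#'
#' Arithmetic mean of the two readings per component; if one reading is
#' missing the available one is used with a warning.
#'
#' @param sbp_1,sbp_2 Systolic readings, mmHg.
#' @param dbp_1,dbp_2 Diastolic readings, mmHg.
#' @return Data frame with columns `sbp` and `dbp`.
#' @export
mean_bp <- function(sbp_1, sbp_2, dbp_1, dbp_2) {
  one_missing <- xor(is.na(sbp_1), is.na(sbp_2)) |
    xor(is.na(dbp_1), is.na(dbp_2))
  if (any(one_missing))
    warning(sum(one_missing),
            " subject(s) with a single BP reading; using it as the average",
            call. = FALSE)
  avg <- function(a, b) rowMeans(cbind(a, b), na.rm = TRUE)
  out <- data.frame(sbp = avg(sbp_1, sbp_2), dbp = avg(dbp_1, dbp_2))
  out$sbp[is.nan(out$sbp)] <- NA_real_
  out$dbp[is.nan(out$dbp)] <- NA_real_
  out
}

#' Mean visual-analogue appetite score
#'
#' @param vas Numeric matrix or data frame of 100-mm VAS items (one row
#'   per subject), or a numeric vector for a single subject.
#' @return Mean distance in mm per subject.
#' @export
appetite_score <- function(vas) {
  if (is.null(dim(vas))) vas <- matrix(vas, nrow = 1)
  vas <- as.matrix(vas)
  if (ncol(vas) == 0L) stop("no VAS items supplied")
  if (any(!is.na(vas) & (vas < 0 | vas > 100)))
    stop("VAS items must lie in [0, 100] mm")
  rowMeans(vas, na.rm = TRUE)
}

#' DASS-21 item-to-subscale assignment
#'
#' Standard mapping: depression items 3, 5, 10, 13, 16, 17, 21; anxiety
#' items 2, 4, 7, 9, 15, 19, 20; stress items 1, 6, 8, 11, 12, 14, 18.
#'
#' @return Named list of item indices.
#' @export
dass_item_map <- function() {
  list(depression = c(3, 5, 10, 13, 16, 17, 21),
       anxiety = c(2, 4, 7, 9, 15, 19, 20),
       stress = c(1, 6, 8, 11, 12, 14, 18))
}

#' DASS-21 severity cut-offs (Lovibond & Lovibond)
#'
#' Lower bounds of the mild, moderate, severe and extremely-severe bands
#' on the doubled (0-42) subscale score. Editable: pass a modified copy to
#' [score_dass()].
#'
#' @return Named list of numeric length-4 vectors.
#' @export
dass_severity_cuts <- function() {
  list(depression = c(10, 14, 21, 28),
       anxiety = c(8, 10, 15, 20),
       stress = c(15, 19, 26, 34))
}

#' Score the DASS-21 questionnaire
#'
#' Each subscale is twice the sum of its seven 0-3 items, giving an even
#' score in 0-42, banded into normal / mild / moderate / severe /
#' extremely severe.
#'
#' @param items Numeric matrix or data frame with 21 columns (items in
#'   questionnaire order), or a length-21 vector for one subject.
#' @param item_map Item-to-subscale assignment, see [dass_item_map()].
#' @param cuts Severity cut-offs, see [dass_severity_cuts()].
#' @return Data frame with `<subscale>` score and `<subscale>_severity`
#'   columns.
#' @export
score_dass <- function(items, item_map = dass_item_map(),
                       cuts = dass_severity_cuts()) {
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  items <- as.matrix(items)
  if (ncol(items) != 21L) stop("DASS-21 requires exactly 21 items")
  if (any(!is.na(items) & (items < 0 | items > 3 | items != round(items))))
    stop("DASS items must be integers in 0-3")
  bands <- c("normal", "mild", "moderate", "severe", "extremely_severe")
  out <- data.frame(row.names = seq_len(nrow(items)))
  for (sub in names(item_map)) {
    sc <- 2 * rowSums(items[, item_map[[sub]], drop = FALSE])
    out[[sub]] <- sc
    out[[paste0(sub, "_severity")]] <-
      bands[1L + findInterval(sc, cuts[[sub]])]
  }
  out
}

#' NCEP ATP III metabolic syndrome classification
#'
#' Counts the five criteria and flags MetS when three or more are met.
#' The default `"atp3"` ruleset: waist circumference > 102 cm (men) /
#' > 88 cm (women); blood pressure >= 130/85 mmHg (either component at
#' its bound); TG >= 150 mg/dl; HDL < 40 (men) / < 50 (women) mg/dl;
#' fasting glucose >= 100 mg/dl. The alternative `"atp3_wc88"` variant
#' uses waist > 88 cm and HDL < 50 mg/dl for everyone and glucose >= 110
#' mg/dl.
#'
#' @param wc Waist circumference, cm.
#' @param sex `"male"` or `"female"`.
#' @param sbp,dbp Averaged blood pressure, mmHg.
#' @param tg Triglycerides, mg/dl.
#' @param hdl HDL cholesterol, mg/dl.
#' @param glucose Fasting glucose, mg/dl.
#' @param ruleset `"atp3"` (default) or `"atp3_wc88"`.
#' @return Data frame with `criteria_count` (0-5) and logical `mets`;
#'   subjects with any missing input are unclassified (`NA`).
#' @export
classify_mets <- function(wc, sex, sbp, dbp, tg, hdl, glucose,
                          ruleset = c("atp3", "atp3_wc88")) {
  ruleset <- match.arg(ruleset)
  if (ruleset == "atp3") {
    wc_cut <- ifelse(sex == "male", 102, 88)
    glu_cut <- 100
    hdl_cut <- ifelse(sex == "male", 40, 50)
  } else {
    wc_cut <- rep(88, length(wc))
    glu_cut <- 110
    hdl_cut <- rep(50, length(wc))
  }
  crit <- cbind(wc > wc_cut,
                sbp >= 130 | dbp >= 85,
                tg >= 150,
                hdl < hdl_cut,
                glucose >= glu_cut)
  count <- as.integer(rowSums(crit))
  count[rowSums(is.na(crit)) > 0] <- NA_integer_
  data.frame(criteria_count = count, mets = count >= 3L)
}

#' Binary cardiometabolic risk flags
#'
#' Eight flags at the conventional cut-offs: high cholesterol (TC >= 220
#' mg/dl), high LDL-C (>= 160), low HDL-C (< 40 men / < 50 women), high
#' TG (>= 150), high blood pressure (SBP/DBP >= 130/85), hyperglycemia
#' (glucose >= 100), high HOMA-IR (> 2.6, strict), and low QUICKI (below
#' `quicki_cut`, default 0.33).
#'
#' @param tc,ldl,hdl,tg Lipids, mg/dl.
#' @param sbp,dbp Averaged blood pressure, mmHg.
#' @param glucose Fasting glucose, mg/dl.
#' @param homa HOMA-IR values.
#' @param quicki QUICKI values.
#' @param sex `"male"` or `"female"`.
#' @param quicki_cut Low-QUICKI threshold.
#' @return Data frame of eight logical columns; missing inputs give `NA`
#'   flags.
#' @export
classify_risk_flags <- function(tc, ldl, hdl, tg, sbp, dbp, glucose,
                                homa, quicki, sex, quicki_cut = 0.33) {
  data.frame(
    high_cholesterol = tc >= 220,
    high_ldl = ldl >= 160,
    low_hdl = hdl < ifelse(sex == "male", 40, 50),
    high_tg = tg >= 150,
    high_bp = sbp >= 130 | dbp >= 85,
    hyperglycemia = glucose >= 100,
    high_homa = homa > 2.6,
    low_quicki = quicki < quicki_cut
  )
}

#' Derived phenotype panel for a cohort
#'
#' Computes every derived quantity the analysis needs from the raw cohort
#' columns: averaged blood pressure, Friedewald LDL-C, AIP, HOMA-IR,
#' QUICKI, MetS status, the eight binary risk flags, DASS-21 subscales
#' (when items are present) and the VAS appetite score.
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @param quicki_cut Low-QUICKI flag threshold.
#' @param mets_ruleset Passed to [classify_mets()].
#' @return Data frame keyed by `subject_id`.
#' @export
phenotype_panel <- function(cohort, quicki_cut = 0.33,
                            mets_ruleset = "atp3") {
  bp <- mean_bp(cohort$sbp_1, cohort$sbp_2, cohort$dbp_1, cohort$dbp_2)
  out <- data.frame(subject_id = cohort$subject_id,
                    sbp = bp$sbp, dbp = bp$dbp,
                    stringsAsFactors = FALSE)
  out$ldl <- friedewald_ldl(cohort$tc, cohort$hdl, cohort$tg,
                            on_invalid = "missing")
  out$aip <- aip(cohort$tg, cohort$hdl)
  out$homa_ir <- homa_ir(cohort$glucose, cohort$insulin)
  out$quicki <- quicki(cohort$glucose, cohort$insulin)
  mets <- classify_mets(cohort$wc, cohort$sex, out$sbp, out$dbp,
                        cohort$tg, cohort$hdl, cohort$glucose,
                        ruleset = mets_ruleset)
  out$mets_count <- mets$criteria_count
  out$mets <- mets$mets
  out <- cbind(out, classify_risk_flags(
    cohort$tc, out$ldl, cohort$hdl, cohort$tg, out$sbp, out$dbp,
    cohort$glucose, out$homa_ir, out$quicki, cohort$sex,
    quicki_cut = quicki_cut))
  dass_cols <- paste0("dass_", 1:21)
  if (all(dass_cols %in% names(cohort)))
    out <- cbind(out, score_dass(cohort[, dass_cols]))
  vas_cols <- grep("^vas_", names(cohort), value = TRUE)
  if (length(vas_cols))
    out$appetite <- appetite_score(cohort[, vas_cols, drop = FALSE])
  out
}
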