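#' Canonical cohort column sets
#'
#' The package works on a plain data frame in a canonical layout: one row
#' per participant, named columns for anthropometrics, daily food-group and
#' nutrient intakes (g/day; sodium in mg/day), fasting biomarkers (mg/dl;
#' insulin in uU/ml), duplicate blood-pressure readings (mmHg), DASS-21
#' items, visual-analogue appetite items (mm), socio-economic indicator
#' items and a genotype label or RFLP fragment list.
#'
#' @return A list with character vectors `mandatory` and `optional`.
#' @export
cohort_columns <- function() {
  list(
    mandatory = c(
      "subject_id", "sex", "age", "weight", "height", "wc", "energy",
      "fruits", "vegetables", "whole_grains", "low_fat_dairy", "nuts",
      "legumes", "red_processed_meat", "sweetened_beverages", "cereals",
      "fish_seafood", "dairy_total", "meat_total", "sodium", "mufa", "sfa",
      "tc", "hdl", "tg", "glucose", "insulin",
      "sbp_1", "sbp_2", "dbp_1", "dbp_2", "physical_activity"
    ),
    optional = c(
      "fm", "ffm", "marital_status", "family_size",
      "ses_education", "ses_occupation", "ses_house",
      paste0("dass_", 1:21), paste0("vas_", 1:8),
      "genotype", "rflp_fragments"
    )
  )
}

.numeric_cohort_cols <- function() {
  cols <- cohort_columns()
  setdiff(
    c(cols$mandatory, cols$optional),
    c("subject_id", "sex", "physical_activity", "marital_status",
      "genotype", "rflp_fragments")
  )
}

#' Read a subject-level cohort table
#'
#' Reads a UTF-8 CSV with a header row into the canonical cohort layout.
#' An optional column mapping (a named character vector, or a YAML/JSON
#' file holding one) translates file column names to canonical names:
#' `c(wc = "waist_circ")` declares that the file column `waist_circ`
#' carries waist circumference. Cells that are empty, `"NA"`, or fail
#' numeric parsing become `NA` with a warning; row order is preserved.
#'
#' @param path Path to the CSV file.
#' @param mapping Named character vector (canonical name -> file column) or
#'   path to a YAML/JSON file containing one. `NULL` means columns already
#'   use canonical names.
#' @return A `data.frame`, one row per subject.
#' @export
read_cohort <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  if (nrow(raw) == 0L) stop("cohort file is empty: ", path)
  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping))
      mapping <- unlist(read_config_file(mapping))
    hit <- match(mapping, names(raw))
    if (anyNA(hit))
      stop("mapped columns absent from file: ",
           paste(mapping[is.na(hit)], collapse = ", "))
    names(raw)[hit] <- names(mapping)
  }
  cols <- cohort_columns()
  missing_cols <- setdiff(cols$mandatory, names(raw))
  if (length(missing_cols))
    stop("mandatory columns missing: ", paste(missing_cols, collapse = ", "))
  for (col in intersect(.numeric_cohort_cols(), names(raw))) {
    if (!is.numeric(raw[[col]])) {
      parsed <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- sum(is.na(parsed) & !is.na(raw[[col]]))
      if (bad > 0)
        warning(bad, " unparseable value(s) in column '", col,
                "' set to NA", call. = FALSE)
      raw[[col]] <- parsed
    }
  }
  raw$subject_id <- as.character(raw$subject_id)
  raw$sex <- validate_levels(raw$sex, c("male", "female"), "sex")
  raw$physical_activity <- validate_levels(
    raw$physical_activity, c("low", "moderate", "high"), "physical_activity")
  rownames(raw) <- NULL
  raw
}

#' Write a cohort table
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

validate_levels <- function(x, levels, what) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad))
    stop("invalid ", what, " value(s): ",
         paste(unique(x[bad]), collapse = ", "))
  x
}

#' Eligibility criteria
#'
#' Screening rules for an obese adult cohort: an age window, a minimum BMI
#' and a plausibility window on reported energy intake (implausibly low or
#' high totals are taken as mis-reporting). Both intervals are closed, so
#' a subject at an endpoint is retained.
#'
#' @param age_range Closed age interval in years.
#' @param bmi_min Minimum BMI in kg/m^2.
#' @param energy_range Closed energy interval in kcal/day.
#' @param exclusion_flags Character vector naming logical cohort columns;
#'   a `TRUE` in any of them excludes the subject.
#' @return An object of class `gx_eligibility_config`.
#' @export
eligibility_config <- function(age_range = c(20, 50), bmi_min = 30,
                               energy_range = c(800, 4200),
                               exclusion_flags = character(0)) {
  stopifnot(length(age_range) == 2L, age_range[1] <= age_range[2],
            length(energy_range) == 2L, energy_range[1] <= energy_range[2],
            bmi_min > 0)
  structure(list(age_range = age_range, bmi_min = bmi_min,
                 energy_range = energy_range,
                 exclusion_flags = exclusion_flags),
            class = "gx_eligibility_config")
}

#' Body mass index
#'
#' @param weight Weight in kg.
#' @param height Height in cm.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight, height) weight / (height / 100)^2

#' Apply eligibility screening
#'
#' Partitions the cohort into retained and excluded subjects. Rules are
#' checked in a fixed order and the first violated rule is logged per
#' subject: incomplete dietary/energy data, age outside the window, BMI
#' below the threshold, energy intake outside the plausibility window, and
#' finally any set exclusion flag. Screening problems are exclusions, not
#' errors, so the function always succeeds on a valid cohort.
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @param criteria An [eligibility_config()].
#' @return A list with `retained` (data frame), `log` (data frame with
#'   `subject_id` and `rule` for every excluded subject) and `counts`
#'   (exclusions per rule). `nrow(retained) + nrow(log)` always equals the
#'   input row count.
#' @export
apply_eligibility <- function(cohort, criteria = eligibility_config()) {
  stopifnot(inherits(criteria, "gx_eligibility_config"))
  diet_cols <- c("energy", "fruits", "vegetables", "whole_grains",
                 "low_fat_dairy", "nuts", "legumes", "red_processed_meat",
                 "sweetened_beverages", "cereals", "fish_seafood",
                 "dairy_total", "meat_total", "sodium", "mufa", "sfa")
  diet_cols <- intersect(diet_cols, names(cohort))
  incomplete <- rowSums(is.na(cohort[, diet_cols, drop = FALSE])) > 0
  b <- bmi(cohort$weight, cohort$height)
  age_bad <- is.na(cohort$age) | cohort$age < criteria$age_range[1] |
    cohort$age > criteria$age_range[2]
  bmi_bad <- is.na(b) | b < criteria$bmi_min
  energy_bad <- cohort$energy < criteria$energy_range[1] |
    cohort$energy > criteria$energy_range[2]
  energy_bad[is.na(energy_bad)] <- FALSE  # missing energy caught as incomplete
  rule <- rep(NA_character_, nrow(cohort))
  rule[energy_bad] <- "energy_out_of_range"
  rule[bmi_bad] <- "bmi_below_minimum"
  rule[age_bad] <- "age_out_of_range"
  rule[incomplete] <- "incomplete_dietary_data"
  for (flag in rev(criteria$exclusion_flags)) {
    if (!flag %in% names(cohort))
      stop("exclusion flag column not present: ", flag)
    hit <- !is.na(cohort[[flag]]) & cohort[[flag]]
    rule[hit & is.na(rule)] <- paste0("flag:", flag)
  }
  # re-impose first-rule precedence: incomplete > age > bmi > energy > flags
  excluded <- !is.na(rule)
  list(
    retained = cohort[!excluded, , drop = FALSE],
    log = data.frame(subject_id = cohort$subject_id[excluded],
                     rule = rule[excluded], stringsAsFactors = FALSE),
    counts = if (any(excluded)) table(rule[excluded]) else
      table(factor(character(0)))
  )
}

#' Socio-economic status category
#'
#' Sums three ordinal indicator scales (education, occupation, house
#' ownership) and maps the total to a low/middle/high category. By default
#' the cut points are the empirical tertiles of the summed score within the
#' cohort; explicit cut points may be supplied instead.
#'
#' @param items Data frame with columns `education`, `occupation`, `house`
#'   (ordinal codes).
#' @param cut_points Optional numeric length-2 vector `c(c1, c2)`:
#'   total <= c1 is low, total <= c2 middle, otherwise high.
#' @param scale_range Allowed closed range for each item code.
#' @return Character vector in `{"low","middle","high"}`.
#' @export
score_ses <- function(items, cut_points = NULL, scale_range = c(1, 5)) {
  need <- c("education", "occupation", "house")
  if (!all(need %in% names(items)))
    stop("items must contain columns: ", paste(need, collapse = ", "))
  m <- as.matrix(items[, need])
  if (any(!is.na(m) & (m < scale_range[1] | m > scale_range[2])))
    stop("SES item outside the configured scale [", scale_range[1], ", ",
         scale_range[2], "]")
  total <- rowSums(m)
  labels <- c("low", "middle", "high")
  if (is.null(cut_points)) {
    grp <- quantile_ranks(total, k = 3)
  } else {
    stopifnot(length(cut_points) == 2L, cut_points[1] < cut_points[2])
    grp <- 1L + (total > cut_points[1]) + (total > cut_points[2])
  }
  labels[grp]
}

#' Sample skewness
#'
#' Third standardized moment, `m3 / m2^(3/2)`. A constant sample has
#' undefined moments; by convention 0 is returned so that constants route
#' to the mean/SD report.
#'
#' @param x Numeric vector; `NA`s dropped.
#' @export
skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Descriptive cohort summary with normality-based routing
#'
#' Continuous variables are reported as mean (SD) when approximately
#' symmetric and as median (25th, 75th percentile) when the absolute
#' sample skewness exceeds the routing threshold. Categorical variables
#' are reported as percentage tables.
#'
#' @param cohort Cohort data frame.
#' @param variables Continuous column names (defaults to all numeric
#'   columns).
#' @param categorical Categorical column names.
#' @param skew_threshold Absolute-skewness routing threshold.
#' @return A data frame with one row per continuous variable (or per
#'   category level), columns `variable`, `level`, `routing`, `summary`
#'   plus the underlying statistics.
#' @export
summarize_cohort <- function(cohort, variables = NULL, categorical = NULL,
                             skew_threshold = 1) {
  if (is.null(variables))
    variables <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  rows <- list()
  for (v in variables) {
    x <- cohort[[v]]
    ok <- sum(!is.na(x))
    if (ok == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA, routing = "missing", summary = "all missing",
        mean = NA_real_, sd = NA_real_, median = NA_real_, q25 = NA_real_,
        q75 = NA_real_, skewness = NA_real_, pct = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    sk <- skewness(x)
    qq <- stats::quantile(x, c(.25, .5, .75), na.rm = TRUE, names = FALSE)
    routed <- if (!is.na(sk) && abs(sk) > skew_threshold) "median_iqr"
              else "mean_sd"
    txt <- if (routed == "mean_sd")
      sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE))
    else sprintf("%.2f (%.2f, %.2f)", qq[2], qq[1], qq[3])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = NA, routing = routed, summary = txt,
      mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
      median = qq[2], q25 = qq[1], q75 = qq[3], skewness = sk,
      pct = NA_real_, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    tab <- table(cohort[[v]])
    pct <- 100 * tab / sum(tab)
    for (lv in names(tab)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lv, routing = "percentage",
        summary = sprintf("%.1f%%", pct[[lv]]),
        mean = NA_real_, sd = NA_real_, median = NA_real_, q25 = NA_real_,
        q75 = NA_real_, skewness = NA_real_, pct = as.numeric(pct[[lv]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Read a YAML or JSON configuration file
#'
#' @param path File path; format inferred from the extension.
#' @return The parsed list.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.(json)$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Map IPAQ MET-minutes/week to an activity category
#'
#' Helper for cohorts carrying raw activity volume instead of a category:
#' below 600 MET-min/week is low, 600 to below 3000 moderate, at or above
#' 3000 high.
#'
#' @param met_min MET-minutes per week.
#' @export
ipaq_category <- function(met_min) {
  out <- rep(NA_character_, length(met_min))
  out[!is.na(met_min) & met_min < 600] <- "low"
  out[!is.na(met_min) & met_min >= 600 & met_min < 3000] <- "moderate"
  out[!is.na(met_min) & met_min >= 3000] <- "high"
  out
}
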