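#' Equal-frequency quantile group ranks
#'
#' Assigns each value to one of `k` equal-frequency groups within its
#' stratum (typically sex), the machinery behind sex-specific quintiles,
#' medians and tertiles. Ranking is by `ceiling(k * rank / n)` with
#' minimum ranks for ties, so tied values share the lowest qualifying
#' group; with all values identical every subject lands in group 1.
#'
#' @param x Numeric values; `NA` propagates to an `NA` rank.
#' @param strata Optional stratum labels (e.g. sex); ranks are computed
#'   independently within each stratum.
#' @param k Number of groups (5 for quintiles, 3 for tertiles, 2 for a
#'   median split).
#' @return Integer vector of group ranks in `1..k`.
#' @export
quantile_ranks <- function(x, strata = NULL, k) {
  stopifnot(k >= 1)
  if (is.null(strata)) strata <- rep("all", length(x))
  stopifnot(length(strata) == length(x))
  out <- rep(NA_integer_, length(x))
  for (s in unique(strata[!is.na(strata)])) {
    idx <- which(strata == s & !is.na(x))
    n <- length(idx)
    if (n < k)
      stop("stratum '", s, "' has ", n, " non-missing values; need >= ", k)
    r <- rank(x[idx], ties.method = "min")
    out[idx] <- as.integer(ceiling(k * r / n))
  }
  out
}

#' DASH score component mapping
#'
#' The Fung construction uses eight components: five emphasized food
#' groups (fruits, vegetables, whole grains, low-fat dairy, and nuts plus
#' legumes merged into one component) scored by sex-specific quintile
#' rank, and three discouraged components (sodium, red and processed meat,
#' sweetened beverages) reverse-scored. Each maps to one or more cohort
#' columns that are summed in g/day (sodium in mg/day).
#'
#' @return List with `emphasized` and `discouraged` component-to-column
#'   mappings.
#' @export
dash_components <- function() {
  list(
    emphasized = list(
      fruits = "fruits", vegetables = "vegetables",
      whole_grains = "whole_grains", low_fat_dairy = "low_fat_dairy",
      nuts_legumes = c("nuts", "legumes")
    ),
    discouraged = list(
      sodium = "sodium", red_processed_meat = "red_processed_meat",
      sweetened_beverages = "sweetened_beverages"
    )
  )
}

.component_amount <- function(cohort, cols) {
  m <- as.matrix(cohort[, cols, drop = FALSE])
  rowSums(m)
}

#' Fung DASH diet-quality score
#'
#' Sex-specific quintile ranks of each component intake are computed
#' within the cohort. Emphasized components score their quintile rank
#' (1 to 5, highest intake scores 5); discouraged components are
#' reverse-scored (6 minus rank, so the lowest intake scores 5). The
#' total is the sum over the eight components and ranges 8 to 40; a
#' subject missing any component amount is left unscored (`NA`).
#'
#' @param cohort Cohort data frame with intake columns and `sex`.
#' @param components Component mapping, see [dash_components()].
#' @return Data frame with `subject_id`, one `dash_<component>` column per
#'   component and `dash_total`.
#' @export
score_dash <- function(cohort, components = dash_components()) {
  out <- data.frame(subject_id = cohort$subject_id,
                    stringsAsFactors = FALSE)
  for (comp in names(components$emphasized)) {
    amt <- .component_amount(cohort, components$emphasized[[comp]])
    out[[paste0("dash_", comp)]] <-
      quantile_ranks(amt, strata = cohort$sex, k = 5)
  }
  for (comp in names(components$discouraged)) {
    amt <- .component_amount(cohort, components$discouraged[[comp]])
    out[[paste0("dash_", comp)]] <-
      6L - quantile_ranks(amt, strata = cohort$sex, k = 5)
  }
  score_cols <- setdiff(names(out), "subject_id")
  out$dash_total <- rowSums(out[, score_cols])
  out
}

#' MDS component mapping
#'
#' The alcohol-free Trichopoulou Mediterranean Diet Score uses six
#' protective components (vegetables, legumes, fruits and nuts, cereals,
#' fish and seafood, and the MUFA:SFA ratio) and two non-protective
#' components (meat, dairy).
#'
#' @return List with `protective` and `nonprotective` mappings; the
#'   special entry `"mufa_sfa_ratio"` denotes the fat-quality ratio.
#' @export
mds_components <- function() {
  list(
    protective = list(
      vegetables = "vegetables", legumes = "legumes",
      fruits_nuts = c("fruits", "nuts"), cereals = "cereals",
      fish_seafood = "fish_seafood", mufa_sfa = "mufa_sfa_ratio"
    ),
    nonprotective = list(meat = "meat_total", dairy = "dairy_total")
  )
}

#' MUFA to SFA ratio
#'
#' @param mufa Monounsaturated fat intake, g/day.
#' @param sfa Saturated fat intake, g/day.
#' @param strict If `TRUE` (default) a non-positive SFA raises an error;
#'   otherwise the ratio is `NA` for those subjects.
#' @return `mufa / sfa`.
#' @export
mufa_sfa_ratio <- function(mufa, sfa, strict = TRUE) {
  bad <- !is.na(sfa) & sfa <= 0
  if (any(bad)) {
    if (strict) stop("MUFA:SFA ratio undefined for sfa <= 0")
    sfa[bad] <- NA_real_
  }
  mufa / sfa
}

#' Trichopoulou Mediterranean Diet Score (alcohol-free, 0-8)
#'
#' Each protective component scores 1 for an intake at or above the
#' sex-specific median (0 otherwise); each non-protective component
#' scores 1 for an intake strictly below the median. The total is the sum
#' of the eight indicators. A subject with an undefined component (e.g.
#' zero SFA) is unscored for that component and gets an `NA` total.
#'
#' @param cohort Cohort data frame with intake columns, `mufa`, `sfa`,
#'   `sex`.
#' @param components Component mapping, see [mds_components()].
#' @return Data frame with `subject_id`, `mds_<component>` indicator
#'   columns and `mds_total`.
#' @export
score_mds <- function(cohort, components = mds_components()) {
  out <- data.frame(subject_id = cohort$subject_id,
                    stringsAsFactors = FALSE)
  amount_of <- function(cols) {
    if (identical(cols, "mufa_sfa_ratio"))
      mufa_sfa_ratio(cohort$mufa, cohort$sfa, strict = FALSE)
    else .component_amount(cohort, cols)
  }
  sex_median <- function(amt) {
    med <- rep(NA_real_, length(amt))
    for (s in unique(cohort$sex)) {
      idx <- cohort$sex == s
      med[idx] <- stats::median(amt[idx], na.rm = TRUE)
    }
    med
  }
  for (comp in names(components$protective)) {
    amt <- amount_of(components$protective[[comp]])
    out[[paste0("mds_", comp)]] <- as.integer(amt >= sex_median(amt))
  }
  for (comp in names(components$nonprotective)) {
    amt <- amount_of(components$nonprotective[[comp]])
    out[[paste0("mds_", comp)]] <- as.integer(amt < sex_median(amt))
  }
  ind_cols <- setdiff(names(out), "subject_id")
  out$mds_total <- rowSums(out[, ind_cols])
  out
}

#' Assign score tertiles
#'
#' Splits scores into three equal-frequency groups (T1 lowest), optionally
#' within strata such as sex. Ties share the lower tertile. The 33.3rd and
#' 66.7th empirical percentiles per stratum are attached as reporting cut
#' points.
#'
#' @param scores Numeric scores.
#' @param strata Optional stratum labels for within-stratum tertiles.
#' @return Factor with levels `T1`, `T2`, `T3` and attribute `cut_points`
#'   (a per-stratum matrix).
#' @export
assign_tertiles <- function(scores, strata = NULL) {
  grp <- quantile_ranks(scores, strata = strata, k = 3)
  out <- factor(paste0("T", grp), levels = c("T1", "T2", "T3"))
  out[is.na(grp)] <- NA
  if (is.null(strata)) strata <- rep("all", length(scores))
  cp <- t(vapply(unique(strata[!is.na(strata)]), function(s)
    stats::quantile(scores[strata == s], c(1 / 3, 2 / 3), na.rm = TRUE,
                    names = FALSE), numeric(2)))
  colnames(cp) <- c("p33.3", "p66.7")
  attr(out, "cut_points") <- cp
  out
}
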