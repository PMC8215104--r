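#' Nested covariate adjustment sets
#'
#' The three adjustment sets used throughout the inferential layer:
#' `crude` (no covariates), `model1` (age, physical activity, SES) and
#' `model2` (model1 plus waist circumference). Physical activity and SES
#' enter as unordered categorical covariates.
#'
#' @param name One of `"crude"`, `"model1"`, `"model2"`.
#' @return Object of class `gx_model_spec` with `name` and `covariates`.
#' @export
model_spec <- function(name = c("crude", "model1", "model2")) {
  name <- match.arg(name)
  covariates <- switch(name,
    crude = character(0),
    model1 = c("age", "physical_activity", "ses"),
    model2 = c("age", "physical_activity", "ses", "wc"))
  structure(list(name = name, covariates = covariates),
            class = "gx_model_spec")
}

.covariate_terms <- function(spec, data) {
  miss <- setdiff(spec$covariates, names(data))
  if (length(miss))
    stop("covariates absent from data: ", paste(miss, collapse = ", "))
  spec$covariates
}

.as_factor_cols <- function(data, cols) {
  for (col in intersect(cols, names(data)))
    if (!is.numeric(data[[col]])) data[[col]] <- factor(data[[col]])
  data
}

#' Tertile comparison tables
#'
#' Sex-stratified descriptive comparison across diet-score tertiles:
#' one-way ANOVA p-values for continuous variables and chi-square
#' p-values on the tertile-by-category contingency table for categorical
#' variables, alongside per-tertile summaries.
#'
#' @param data Data frame for one stratum, holding a tertile column.
#' @param tertile_col Name of the tertile factor column.
#' @param continuous Continuous variable names.
#' @param categorical Categorical variable names.
#' @return Data frame with columns `variable`, `type`, per-tertile
#'   summaries `T1`/`T2`/`T3`, `statistic`, `p_value` and a `warning`
#'   marker for degenerate chi-square tables.
#' @export
tables_by_tertile <- function(data, tertile_col = "tertile",
                              continuous = character(0),
                              categorical = character(0)) {
  tert <- factor(data[[tertile_col]])
  if (nlevels(droplevels(tert[!is.na(tert)])) < 2)
    stop("need at least 2 non-empty tertiles")
  rows <- list()
  cell <- function(x) sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE),
                              stats::sd(x, na.rm = TRUE))
  pick <- function(sm, lv) if (lv %in% names(sm)) sm[[lv]] else NA_character_
  for (v in continuous) {
    y <- data[[v]]
    fit <- stats::lm(y ~ tert)
    a <- stats::anova(fit)
    sm <- tapply(y, tert, cell)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "continuous",
      T1 = pick(sm, "T1"), T2 = pick(sm, "T2"), T3 = pick(sm, "T3"),
      statistic = a[1, "F value"], p_value = a[1, "Pr(>F)"],
      warning = "", stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    tab <- table(data[[v]], tert)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    warn <- ""
    test <- withCallingHandlers(
      stats::chisq.test(tab, correct = FALSE),
      warning = function(w) {
        warn <<- "low expected counts"
        invokeRestart("muffleWarning")
      })
    pr <- prop.table(tab, 1) * 100
    sm <- apply(pr, 2, function(col)
      paste(sprintf("%s %.1f%%", rownames(pr), col), collapse = "; "))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "categorical",
      T1 = pick(sm, "T1"), T2 = pick(sm, "T2"), T3 = pick(sm, "T3"),
      statistic = unname(test$statistic), p_value = test$p.value,
      warning = warn, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.wald_or_rows <- function(est, se, labels, model_name, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(contrast = labels, or = exp(est),
             ci_low = exp(est - z * se), ci_high = exp(est + z * se),
             p_value = 2 * stats::pnorm(-abs(est / se)),
             model = model_name, stringsAsFactors = FALSE)
}

#' Genotype-to-outcome odds ratios
#'
#' Binary logistic regression of a risk flag on genotype (CC reference),
#' optionally adjusted per a [model_spec()]. Returns exponentiated
#' coefficients with Wald 95% confidence intervals for CT vs CC and TT vs
#' CC. Quasi-separation (non-convergence or an exploding coefficient) is
#' flagged rather than silently reported.
#'
#' @param data Data frame with `genotype` and the outcome and covariate
#'   columns.
#' @param outcome Name of the logical/binary outcome column.
#' @param spec A [model_spec()].
#' @param genotype_col Genotype column name.
#' @return Data frame of ORs with a `flag` column (empty when clean).
#' @export
fit_genotype_outcome_or <- function(data, outcome,
                                    spec = model_spec("crude"),
                                    genotype_col = "genotype") {
  data <- .as_factor_cols(data, c("physical_activity", "ses"))
  data[[genotype_col]] <- factor(data[[genotype_col]],
                                 levels = c("CC", "CT", "TT"))
  covs <- .covariate_terms(spec, data)
  rhs <- paste(c(genotype_col, covs), collapse = " + ")
  fml <- stats::as.formula(paste0("`", outcome, "` ~ ", rhs))
  fit <- stats::glm(fml, data = data, family = stats::binomial())
  cf <- summary(fit)$coefficients
  idx <- paste0(genotype_col, c("CT", "TT"))
  idx <- idx[idx %in% rownames(cf)]
  out <- .wald_or_rows(cf[idx, "Estimate"], cf[idx, "Std. Error"],
                       sub(genotype_col, "", idx, fixed = TRUE),
                       spec$name)
  out$contrast <- paste0(out$contrast, " vs CC")
  out$flag <- ""
  if (!fit$converged || any(abs(cf[idx, "Estimate"]) > 10))
    out$flag <- "possible quasi-separation"
  out
}

#' Diet-score-to-genotype multinomial odds ratios
#'
#' Multinomial logistic regression of the 3-level genotype (CC reference)
#' on a continuous diet-quality score, per adjustment set. The reported
#' OR is per unit of score for membership in CT (or TT) versus CC.
#'
#' @param data Data frame with `genotype`, the score and covariates.
#' @param score Name of the continuous score column.
#' @param spec A [model_spec()].
#' @param genotype_col Genotype column name.
#' @return Data frame of per-unit-score ORs with Wald 95% CIs; genotype
#'   levels empty in the stratum are dropped with a warning and flagged.
#' @export
fit_diet_genotype_multinomial <- function(data, score,
                                          spec = model_spec("crude"),
                                          genotype_col = "genotype") {
  data <- .as_factor_cols(data, c("physical_activity", "ses"))
  g <- factor(data[[genotype_col]], levels = c("CC", "CT", "TT"))
  present <- levels(droplevels(g[!is.na(g)]))
  dropped <- setdiff(c("CC", "CT", "TT"), present)
  if (length(dropped))
    warning("empty genotype level(s) dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  data[[genotype_col]] <- droplevels(g)
  covs <- .covariate_terms(spec, data)
  rhs <- paste(c(paste0("`", score, "`"), covs), collapse = " + ")
  fml <- stats::as.formula(paste0(genotype_col, " ~ ", rhs))
  fit <- nnet::multinom(fml, data = data, trace = FALSE)
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(present[-1], names(cf)))
  term <- paste0("`", score, "`")
  term <- if (term %in% colnames(cf)) term else score
  rows <- lapply(rownames(cf), function(lev) {
    est <- cf[lev, term]
    # with only two genotype levels multinom reduces to a binary logit and
    # vcov names lose the level prefix
    vc_name <- if (paste0(lev, ":", term) %in% rownames(vc))
      paste0(lev, ":", term) else term
    se <- sqrt(vc[vc_name, vc_name])
    r <- .wald_or_rows(est, se, paste(lev, "vs CC"), spec$name)
    r$flag <- if (length(dropped))
      paste("dropped:", paste(dropped, collapse = ",")) else ""
    r
  })
  do.call(rbind, rows)
}

#' Genotype-by-diet-tertile ANCOVA interaction
#'
#' Fits the general linear model
#' `response ~ genotype + tertile + genotype:tertile + covariates` within
#' one stratum (the study runs it separately per sex) and tests the
#' interaction block with the partial F-test against the main-effects
#' model. Adjusted (least-squares) cell means and their standard errors
#' are evaluated at the covariate means via \pkg{emmeans}, exactly the
#' estimated marginal means a GLM procedure reports.
#'
#' @param data Data frame for one stratum.
#' @param response Name of the continuous response column.
#' @param covariates Covariate names (default the full adjustment set:
#'   age, physical activity, SES, waist circumference).
#' @param genotype_col,tertile_col Factor column names.
#' @return Object of class `gx_interaction`: `p_interaction`,
#'   `f_statistic`, `df`, `cell_means` (genotype x tertile grid with
#'   `emmean`, `se`, `n`; empty cells flagged), the fitted `model` and an
#'   `emmeans` grid for post-hoc contrasts.
#' @export
ancova_interaction <- function(data, response,
                               covariates = c("age", "physical_activity",
                                              "ses", "wc"),
                               genotype_col = "genotype",
                               tertile_col = "tertile") {
  data <- .as_factor_cols(data, c("physical_activity", "ses"))
  data[[genotype_col]] <- factor(data[[genotype_col]])
  data[[tertile_col]] <- factor(data[[tertile_col]])
  covariates <- intersect(covariates, names(data))
  keep <- stats::complete.cases(
    data[, c(response, genotype_col, tertile_col, covariates)])
  data <- data[keep, , drop = FALSE]
  rhs_full <- paste(c(covariates,
                      paste(genotype_col, tertile_col, sep = " * ")),
                    collapse = " + ")
  rhs_main <- paste(c(covariates, genotype_col, tertile_col),
                    collapse = " + ")
  f_full <- stats::as.formula(paste0("`", response, "` ~ ", rhs_full))
  f_main <- stats::as.formula(paste0("`", response, "` ~ ", rhs_main))
  fit_full <- stats::lm(f_full, data = data)
  fit_main <- stats::lm(f_main, data = data)
  # partial F on the interaction block, computed from the deviances so a
  # numerically zero sum of squares yields F = 0 rather than a blank
  df_int <- stats::df.residual(fit_main) - stats::df.residual(fit_full)
  df_res <- stats::df.residual(fit_full)
  rss_full <- stats::deviance(fit_full)
  rss_main <- stats::deviance(fit_main)
  estimable <- df_int > 0 && df_res > 0 && rss_full > 0
  cmp <- list(f = NA_real_, p = NA_real_)
  if (estimable) {
    cmp$f <- max(0, (rss_main - rss_full) / df_int) / (rss_full / df_res)
    cmp$p <- stats::pf(cmp$f, df_int, df_res, lower.tail = FALSE)
  }
  emm <- emmeans::emmeans(fit_full,
                          stats::as.formula(paste0("~ ", genotype_col,
                                                   " * ", tertile_col)))
  cm <- as.data.frame(emm)
  names(cm)[names(cm) == "emmean"] <- "emmean"
  names(cm)[names(cm) == "SE"] <- "se"
  counts <- as.data.frame(table(data[[genotype_col]], data[[tertile_col]]))
  names(counts) <- c(genotype_col, tertile_col, "n")
  cm <- merge(cm, counts, by = c(genotype_col, tertile_col), sort = TRUE)
  cm$empty <- cm$n == 0
  structure(list(
    response = response,
    covariates = covariates,
    p_interaction = cmp$p,
    f_statistic = cmp$f,
    df = c(df_int, df_res),
    estimable = estimable,
    cell_means = cm,
    model = fit_full,
    emmeans = emm,
    n = nrow(data)
  ), class = "gx_interaction")
}

#' @export
print.gx_interaction <- function(x, ...) {
  cat("Genotype x tertile ANCOVA on", x$response,
      sprintf("(n = %d)\n", x$n))
  if (x$estimable)
    cat(sprintf("Interaction F(%d, %d) = %.3f, p = %.4f\n",
                x$df[1], x$df[2], x$f_statistic, x$p_interaction))
  else cat("Interaction block inestimable (empty cells)\n")
  cat("Adjusted cell means:\n")
  print(x$cell_means[, c(1, 2, 3, 4, ncol(x$cell_means) - 1)],
        row.names = FALSE)
  invisible(x)
}

#' Post-hoc comparisons of adjusted means
#'
#' Pairwise contrasts of the adjusted cell means across tertiles within
#' each genotype, from the fitted interaction model. The default is
#' unadjusted LSD contrasts; Bonferroni correction is available.
#'
#' @param x A fitted `gx_interaction`.
#' @param method `"lsd"` (unadjusted) or `"bonferroni"`.
#' @return Data frame of contrasts with estimate, SE, t and p-value.
#' @export
posthoc_cell_comparisons <- function(x, method = c("lsd", "bonferroni")) {
  stopifnot(inherits(x, "gx_interaction"))
  method <- match.arg(method)
  adjust <- if (method == "lsd") "none" else "bonferroni"
  fac <- names(x$cell_means)[1:2]
  ctr <- emmeans::contrast(x$emmeans, method = "pairwise",
                           by = fac[1], adjust = adjust)
  out <- as.data.frame(ctr)
  out$flag <- ifelse(is.na(out$estimate), "inestimable", "")
  out
}
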