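#' Validate and normalize a run configuration
#'
#' A run configuration is a list (or YAML/JSON file) with either an
#' `input` CSV path or a `simulate` block (arguments for
#' [cohort_config()]), plus optional `eligibility`, `mets_ruleset`,
#' `quicki_cut`, `posthoc`, `seed`, `out` and `log_level` entries.
#' Defaults are filled, cross-field constraints checked, and the
#' normalized configuration returned; normalizing twice is a fixed point.
#'
#' @param x List, or path to a YAML/JSON file. An empty file or `NULL`
#'   yields the all-defaults configuration (simulate mode).
#' @return Object of class `gx_run_config`.
#' @export
validate_config <- function(x = NULL) {
  if (is.character(x) && length(x) == 1L) x <- read_config_file(x)
  if (is.null(x)) x <- list()
  if (inherits(x, "gx_run_config")) x <- unclass(x)
  known <- c("input", "mapping", "simulate", "eligibility", "mets_ruleset",
             "quicki_cut", "posthoc", "seed", "out", "log_level")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(x$input) && !is.null(x$simulate))
    stop("config must set exactly one of 'input' and 'simulate'")
  defaults <- list(
    input = NULL, mapping = NULL, simulate = list(), eligibility = list(),
    mets_ruleset = "atp3", quicki_cut = 0.33, posthoc = "lsd",
    seed = 1L, out = NULL, log_level = "info")
  for (k in names(defaults))
    if (is.null(x[[k]])) x[[k]] <- defaults[[k]]
  x$mets_ruleset <- match.arg(x$mets_ruleset, c("atp3", "atp3_wc88"))
  x$posthoc <- match.arg(x$posthoc, c("lsd", "bonferroni"))
  x$seed <- as.integer(x$seed)
  x <- x[intersect(known, names(x))]
  structure(x, class = "gx_run_config")
}

.write_table <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  rounded <- df
  for (col in names(rounded))
    if (is.numeric(rounded[[col]]))
      rounded[[col]] <- round(rounded[[col]], 4)
  utils::write.csv(rounded, path, row.names = FALSE, na = "")
  raw_path <- file.path(dir, paste0(name, "_raw.csv"))
  utils::write.csv(df, raw_path, row.names = FALSE, na = "")
  path
}

.interaction_rows <- function(fits, sex, score) {
  do.call(rbind, lapply(names(fits), function(resp) {
    f <- fits[[resp]]
    data.frame(sex = sex, score = score, response = resp,
               f_statistic = f$f_statistic, df1 = f$df[1], df2 = f$df[2],
               p_interaction = f$p_interaction, n = f$n,
               stringsAsFactors = FALSE)
  }))
}

#' Run the full gene-diet interaction pipeline
#'
#' Executes every stage in order: cohort input (or simulation),
#' eligibility screening, diet-quality scoring and tertile assignment,
#' phenotype derivation, genotype statistics, and the inferential layer
#' (tertile comparison tables per sex, diet-to-genotype multinomial ORs,
#' genotype-to-risk-flag ORs under the three adjustment sets, and
#' sex-stratified genotype-by-tertile ANCOVA interactions with adjusted
#' cell means and post-hoc contrasts). When `out` is set, every table is
#' written as CSV (presentation copy rounded to 4 decimals plus a
#' full-precision `_raw` copy) together with a machine-readable run
#' manifest (seed, config hash, package version).
#'
#' @param config A [validate_config()] result, a config list, or a path.
#' @return Invisibly, a list with all intermediate and final results.
#' @export
run_pipeline <- function(config = NULL) {
  config <- validate_config(config)
  set.seed(config$seed)
  # --- cohort acquisition -------------------------------------------------
  if (!is.null(config$input)) {
    cohort <- read_cohort(config$input, mapping = config$mapping)
    truth <- NULL
  } else {
    sim_args <- config$simulate
    sim_args$seed <- NULL
    cc <- do.call(cohort_config, sim_args)
    sim <- simulate_cohort(cc, seed = config$seed)
    cohort <- sim$cohort
    truth <- sim$truth
  }
  elig <- do.call(eligibility_config, config$eligibility)
  screened <- apply_eligibility(cohort, elig)
  cohort <- screened$retained
  if (nrow(cohort) == 0L) stop("screening stage: no subjects retained")
  # --- scoring + phenotypes ----------------------------------------------
  dash <- score_dash(cohort)
  mds <- score_mds(cohort)
  cohort$dash_total <- dash$dash_total
  cohort$mds_total <- mds$mds_total
  cohort$dash_tertile <- assign_tertiles(cohort$dash_total,
                                         strata = cohort$sex)
  cohort$mds_tertile <- assign_tertiles(cohort$mds_total,
                                        strata = cohort$sex)
  panel <- phenotype_panel(cohort, quicki_cut = config$quicki_cut,
                           mets_ruleset = config$mets_ruleset)
  analysis <- cbind(cohort,
                    panel[match(cohort$subject_id, panel$subject_id),
                          setdiff(names(panel), "subject_id")])
  ses_cols <- c("ses_education", "ses_occupation", "ses_house")
  if (all(ses_cols %in% names(analysis))) {
    ses_items <- data.frame(education = analysis$ses_education,
                            occupation = analysis$ses_occupation,
                            house = analysis$ses_house)
    analysis$ses <- score_ses(ses_items)
  }
  # --- genotype statistics ------------------------------------------------
  if (!"genotype" %in% names(analysis) &&
      "rflp_fragments" %in% names(analysis))
    analysis$genotype <- call_genotypes(analysis$rflp_fragments)
  allele_stats <- genotype_frequencies(analysis$genotype)
  hwe <- hwe_exact_test(allele_stats$counts)
  # --- descriptives -------------------------------------------------------
  cont_vars <- c("age", "weight", "fm", "ffm", "wc", "energy", "tc", "hdl",
                 "tg", "glucose", "insulin", "dash_total", "mds_total")
  cont_vars <- intersect(cont_vars, names(analysis))
  descriptives <- summarize_cohort(
    analysis, variables = cont_vars,
    categorical = intersect(c("sex", "physical_activity", "marital_status",
                              "ses", "genotype"), names(analysis)))
  intake_vars <- intersect(
    c("fruits", "vegetables", "whole_grains", "low_fat_dairy", "nuts",
      "legumes", "red_processed_meat", "sweetened_beverages", "cereals",
      "fish_seafood", "dairy_total", "meat_total", "sodium", "mufa", "sfa"),
    names(analysis))
  intake_summary <- summarize_cohort(analysis, variables = intake_vars)
  # --- sex-stratified tertile tables --------------------------------------
  tert_tables <- list()
  tert_cont <- intersect(c("age", "weight", "fm", "ffm", "wc", "appetite",
                           "ldl", "hdl", "tc", "tg", "aip", "glucose",
                           "insulin", "homa_ir", "quicki", "sbp", "dbp"),
                         names(analysis))
  tert_cat <- intersect(c("physical_activity", "marital_status", "ses",
                          "mets", "genotype"), names(analysis))
  for (s in c("male", "female")) for (sc in c("dash", "mds")) {
    dat <- analysis[analysis$sex == s, , drop = FALSE]
    dat$tertile <- dat[[paste0(sc, "_tertile")]]
    tert_tables[[paste(s, sc, sep = "_")]] <-
      tables_by_tertile(dat, continuous = tert_cont, categorical = tert_cat)
  }
  # --- odds-ratio models --------------------------------------------------
  specs <- lapply(c("crude", "model1", "model2"), model_spec)
  diet_or <- list()
  for (s in c("male", "female")) for (sc in c("dash", "mds")) {
    dat <- analysis[analysis$sex == s, , drop = FALSE]
    rows <- lapply(specs, function(sp)
      fit_diet_genotype_multinomial(dat, paste0(sc, "_total"), sp))
    tab <- do.call(rbind, rows)
    tab$sex <- s
    tab$score <- sc
    diet_or[[paste(s, sc, sep = "_")]] <- tab
  }
  diet_or <- do.call(rbind, diet_or)
  flags <- c("mets", "high_cholesterol", "high_ldl", "low_hdl", "high_tg",
             "high_bp", "hyperglycemia", "high_homa", "low_quicki")
  flags <- intersect(flags, names(analysis))
  risk_or <- do.call(rbind, lapply(flags, function(fl) {
    tab <- do.call(rbind, lapply(specs, function(sp)
      fit_genotype_outcome_or(analysis, fl, sp)))
    tab$outcome <- fl
    tab
  }))
  # --- interaction models -------------------------------------------------
  responses <- intersect(c("tg", "glucose", "sbp", "dbp", "tc", "hdl",
                           "ldl"), names(analysis))
  interactions <- list()
  cell_means <- list()
  posthoc <- list()
  for (s in c("male", "female")) for (sc in c("dash", "mds")) {
    dat <- analysis[analysis$sex == s, , drop = FALSE]
    dat$tertile <- dat[[paste0(sc, "_tertile")]]
    fits <- lapply(stats::setNames(responses, responses), function(r)
      ancova_interaction(dat, r))
    interactions[[paste(s, sc, sep = "_")]] <-
      .interaction_rows(fits, s, sc)
    cm <- do.call(rbind, lapply(names(fits), function(r) {
      d <- fits[[r]]$cell_means
      d$response <- r; d$sex <- s; d$score <- sc
      d
    }))
    cell_means[[paste(s, sc, sep = "_")]] <- cm
    ph <- do.call(rbind, lapply(names(fits), function(r) {
      d <- posthoc_cell_comparisons(fits[[r]], method = config$posthoc)
      d$response <- r; d$sex <- s; d$score <- sc
      d
    }))
    posthoc[[paste(s, sc, sep = "_")]] <- ph
  }
  interactions <- do.call(rbind, interactions)
  rownames(interactions) <- NULL
  cell_means <- do.call(rbind, cell_means)
  posthoc <- do.call(rbind, posthoc)
  significant <- interactions[!is.na(interactions$p_interaction) &
                                interactions$p_interaction < 0.05, ,
                              drop = FALSE]
  results <- list(
    config = config, cohort = analysis, exclusions = screened$log,
    dash = dash, mds = mds, panel = panel,
    allele_stats = allele_stats, hwe = hwe,
    descriptives = descriptives, intake_summary = intake_summary,
    tertile_tables = tert_tables, diet_genotype_or = diet_or,
    genotype_risk_or = risk_or, interactions = interactions,
    significant_interactions = significant,
    interaction_cell_means = cell_means, posthoc = posthoc,
    truth = truth)
  # --- outputs ------------------------------------------------------------
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    write_cohort(analysis, file.path(config$out, "cohort.csv"))
    .write_table(screened$log, config$out, "exclusions")
    .write_table(descriptives, config$out, "descriptives")
    .write_table(intake_summary, config$out, "intake_summary")
    for (nm in names(tert_tables))
      .write_table(tert_tables[[nm]], config$out,
                   paste0("tertile_table_", nm))
    .write_table(diet_or, config$out, "diet_genotype_or")
    .write_table(risk_or, config$out, "genotype_risk_or")
    .write_table(interactions, config$out, "interactions")
    .write_table(significant, config$out, "significant_interactions")
    .write_table(cell_means, config$out, "interaction_cell_means")
    .write_table(posthoc, config$out, "posthoc_contrasts")
    cfg_json <- file.path(config$out, "config.json")
    jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                         null = "null", pretty = TRUE, force = TRUE)
    manifest <- list(
      seed = config$seed,
      config_hash = unname(tools::md5sum(cfg_json)),
      package_version = as.character(utils::packageVersion("gxdiet")),
      n_input = nrow(analysis) + nrow(screened$log),
      n_retained = nrow(analysis),
      n_excluded = nrow(screened$log))
    jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(results)
}
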