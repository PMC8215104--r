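#' Planted effect configuration
#'
#' Effects the generator can plant, all expressed on interpretable
#' scales. Continuous effects are in units of the response's marginal SD:
#' `genotype_shift` gives per-genotype mean shifts and `interaction` a
#' 3 x 3 genotype-by-tertile matrix of cell shifts (rows CC/CT/TT,
#' columns T1/T2/T3) indexed by the tertiles of `interaction_score`.
#' Binary outcomes are drawn from logistic models: each entry of `binary`
#' names a flag column and gives the baseline prevalence `p0` (the CC
#' probability) and per-genotype log odds ratios. The default plants no
#' continuous effects and a TT-vs-CC odds ratio of 3.58 on a planted
#' high-triglyceride flag, the anchor effect size for recovery studies.
#'
#' @param genotype_shift Named list: response -> c(CC=, CT=, TT=) in SD
#'   units.
#' @param interaction Named list: response -> 3x3 matrix in SD units.
#' @param interaction_score `"dash"` or `"mds"`: whose tertiles index the
#'   interaction matrix.
#' @param binary Named list of `list(p0=, log_or=c(CC=, CT=, TT=))`.
#' @return Object of class `gx_effects`.
#' @export
effect_config <- function(genotype_shift = list(),
                          interaction = list(),
                          interaction_score = c("dash", "mds"),
                          binary = list(
                            high_tg_planted = list(
                              p0 = 0.30,
                              log_or = c(CC = 0, CT = 0, TT = log(3.58))))) {
  interaction_score <- match.arg(interaction_score)
  for (m in interaction)
    stopifnot(is.matrix(m), all(dim(m) == c(3, 3)))
  structure(list(genotype_shift = genotype_shift,
                 interaction = interaction,
                 interaction_score = interaction_score,
                 binary = binary),
            class = "gx_effects")
}

#' Null effect configuration
#'
#' All planted effects zero: genotype has no influence on any response or
#' flag. Used for type-I-error and coverage calibration.
#'
#' @export
null_effects <- function() {
  effect_config(binary = list(
    high_tg_planted = list(p0 = 0.30, log_or = c(CC = 0, CT = 0, TT = 0))))
}

#' Synthetic cohort configuration
#'
#' Defaults describe an obese adult cohort of the kind the analysis
#' expects: 347 subjects, 58.2% male, genotype mix CC/CT/TT =
#' 37.8/51.9/10.3%, log-normal food-group intakes and Gaussian biomarkers
#' anchored to realistic marginals (TG mean 119.97 SD 58.46 mg/dl, TC
#' 188.43 SD 33.73, fruits median 444 g/day, ...). Energy intake is a
#' partial-attribution function of the simulated intakes plus noise,
#' truncated to the 800-4200 kcal/day eligibility window so the default
#' cohort screens with zero exclusions. Age and waist circumference carry
#' a configurable share of each response's variance (mild confounding);
#' genotypes are randomized against everything else, as in nature.
#'
#' @param n Cohort size.
#' @param sex_ratio Proportion male.
#' @param genotype_probs Named CC/CT/TT probabilities (ignored when
#'   `hwe_maf` is given).
#' @param hwe_maf Optional minor (T) allele frequency; genotype
#'   probabilities then follow Hardy-Weinberg proportions.
#' @param covariate_r2 Named vector: share of marginal response variance
#'   carried by standardized age and waist circumference.
#' @param effects An [effect_config()].
#' @param intakes,biomarkers,energy Optional overrides of the default
#'   parameter lists (partial lists are merged over the defaults).
#' @param seed Default seed used by [simulate_cohort()].
#' @return Object of class `gx_cohort_config`.
#' @export
cohort_config <- function(n = 347, sex_ratio = 0.582,
                          genotype_probs = c(CC = 0.378, CT = 0.519,
                                             TT = 0.103),
                          hwe_maf = NULL,
                          covariate_r2 = c(age = 0.10, wc = 0.10),
                          effects = effect_config(),
                          intakes = list(), biomarkers = list(),
                          energy = list(), seed = NULL) {
  stopifnot(n >= 1, sex_ratio >= 0, sex_ratio <= 1)
  if (!is.null(hwe_maf)) {
    stopifnot(hwe_maf >= 0, hwe_maf <= 0.5)
  } else if (abs(sum(genotype_probs) - 1) > 1e-6) {
    stop("genotype_probs must sum to 1")
  }
  stopifnot(inherits(effects, "gx_effects"))
  intake_defaults <- list(
    # median g/day and log-scale SD per component; sodium mg/day, sfa g/day
    fruits = c(444.03, 0.71), vegetables = c(320.53, 0.59),
    whole_grains = c(150, 0.60), low_fat_dairy = c(120, 0.80),
    nuts = c(10.98, 1.15), legumes = c(49.13, 0.70),
    red_processed_meat = c(49.05, 0.78), sweetened_beverages = c(100, 0.90),
    cereals = c(523.44, 0.50), fish_seafood = c(6.37, 1.46),
    dairy_total = c(260.62, 0.84), extra_meat = c(25, 0.80),
    sodium = c(3500, 0.30), sfa = c(28, 0.25))
  biomarker_defaults <- list(
    tc = c(mean = 188.43, sd = 33.73),
    hdl_male = c(mean = 42.5, sd = 8.0),
    hdl_female = c(mean = 48.4, sd = 8.0),
    tg = c(mean = 119.97, sd = 58.46),
    glucose = c(mean = 91.5, sd = 10.0),
    insulin_meanlog = log(13.1), insulin_sdlog = 0.70,
    sbp = c(mean = 115.64, sd = 16.44),
    dbp = c(mean = 76.33, sd = 12.32),
    bp_reading_sd = 4,
    mufa_sfa_ratio = c(mean = 1.21, sd = 0.31),
    tg_floor = 10)
  energy_defaults <- list(
    base = 1945, noise_sd = 250,
    kcal_per_g = c(fruits = 0.275, vegetables = 0.125, whole_grains = 0.60,
                   nuts = 3.0, legumes = 0.60, sweetened_beverages = 0.20,
                   cereals = 0.70, fish_seafood = 0.75, dairy_total = 0.30,
                   meat_total = 1.25),
    clamp = c(810, 4190))
  merge_over <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  structure(list(
    n = n, sex_ratio = sex_ratio, genotype_probs = genotype_probs,
    hwe_maf = hwe_maf, covariate_r2 = covariate_r2, effects = effects,
    intakes = merge_over(intake_defaults, intakes),
    biomarkers = merge_over(biomarker_defaults, biomarkers),
    energy = merge_over(energy_defaults, energy),
    age = c(mean = 38.08, sd = 7.49, lo = 20, hi = 50),
    height = list(male = c(175, 6), female = c(162, 6)),
    wc = list(male = c(113.3, 7.5), female = c(104.5, 10.0)),
    activity_probs = c(low = 0.478, moderate = 0.277, high = 0.245),
    marital_probs = c(married = 0.86, single = 0.14),
    sex_intake_factor = c(male = 1.08, female = 0.90),
    seed = seed
  ), class = "gx_cohort_config")
}

.rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Simulate genotype labels
#'
#' I.i.d. categorical draws from the configured genotype mix, or from
#' Hardy-Weinberg proportions for a given minor allele frequency.
#'
#' @param n Number of subjects.
#' @param probs Named CC/CT/TT probabilities.
#' @param maf Optional T-allele frequency (HWE mode overrides `probs`).
#' @param seed Optional seed.
#' @return Character vector of `CC`/`CT`/`TT`.
#' @export
simulate_genotypes <- function(n, probs = c(CC = 0.378, CT = 0.519,
                                            TT = 0.103),
                               maf = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(maf))
    probs <- c(CC = (1 - maf)^2, CT = 2 * maf * (1 - maf), TT = maf^2)
  if (abs(sum(probs) - 1) > 1e-6) stop("genotype probabilities must sum to 1")
  sample(c("CC", "CT", "TT"), n, replace = TRUE, prob = probs[c("CC", "CT",
                                                                "TT")])
}

#' Simulate food-group and nutrient intakes
#'
#' Independent log-normal draws per component, with sex-specific location
#' (men's medians scaled up, women's down). MUFA is derived from SFA via
#' a truncated-normal MUFA:SFA ratio so the fat-quality component has the
#' configured spread. All values are strictly positive.
#'
#' @param n Number of subjects.
#' @param sex Character vector of `"male"`/`"female"`.
#' @param config A [cohort_config()] (its `intakes`, `biomarkers` and
#'   `sex_intake_factor` entries are used).
#' @param seed Optional seed.
#' @return Data frame of intake columns including `meat_total`, `mufa`,
#'   `sfa`.
#' @export
simulate_intakes <- function(n, sex, config = cohort_config(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fac <- config$sex_intake_factor[sex]
  out <- data.frame(row.names = seq_len(n))
  for (comp in names(config$intakes)) {
    p <- config$intakes[[comp]]
    out[[comp]] <- stats::rlnorm(n, log(p[1] * fac), p[2])
  }
  out$meat_total <- out$red_processed_meat + out$extra_meat
  out$extra_meat <- NULL
  ratio <- .rtruncnorm(n, config$biomarkers$mufa_sfa_ratio["mean"],
                       config$biomarkers$mufa_sfa_ratio["sd"], lo = 0.3)
  out$mufa <- ratio * out$sfa
  out
}

.simulate_energy <- function(intakes, config) {
  e <- config$energy
  contrib <- rep(0, nrow(intakes))
  for (comp in names(e$kcal_per_g))
    contrib <- contrib + e$kcal_per_g[[comp]] * intakes[[comp]]
  raw <- e$base + contrib + stats::rnorm(nrow(intakes), 0, e$noise_sd)
  pmin(pmax(raw, e$clamp[1]), e$clamp[2])
}

.response_mean <- function(resp, sex, bm) {
  switch(resp,
    hdl = ifelse(sex == "male", bm$hdl_male["mean"], bm$hdl_female["mean"]),
    rep(bm[[resp]]["mean"], length(sex)))
}

.response_sd <- function(resp, bm) {
  if (resp == "hdl") unname(bm$hdl_male["sd"]) else unname(bm[[resp]]["sd"])
}

#' Simulate biomarker columns with planted effects
#'
#' Each continuous response is `mean + SD * (covariate part + genotype
#' shift + interaction cell shift + noise)`, where the covariate part
#' loads on standardized age and waist circumference with the configured
#' variance shares and the noise absorbs the remainder, so the marginal
#' SD stays at its configured value under the null. Insulin is
#' log-normal; blood pressure is generated as a latent value plus two
#' noisy readings. Planted binary flags are Bernoulli draws from the
#' configured logistic models.
#'
#' @param frame Data frame with `sex`, `age`, `wc`, `genotype` and the
#'   tertile column named by the effect configuration
#'   (`dash_tertile`/`mds_tertile`).
#' @param config A [cohort_config()].
#' @param seed Optional seed.
#' @return Data frame of biomarker columns.
#' @export
simulate_biomarkers <- function(frame, config = cohort_config(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(frame)
  bm <- config$biomarkers
  eff <- config$effects
  r2 <- config$covariate_r2
  # covariates standardized empirically (age is truncated-normal, WC is
  # sex-specific) so the configured variance shares are exact
  std <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  z_age <- std(frame$age)
  z_wc <- rep(0, n)
  for (s in unique(frame$sex))
    z_wc[frame$sex == s] <- std(frame$wc[frame$sex == s])
  tert_col <- paste0(eff$interaction_score, "_tertile")
  tert <- frame[[tert_col]]
  struct_part <- function(resp) {
    shift <- rep(0, n)
    gs <- eff$genotype_shift[[resp]]
    if (!is.null(gs)) shift <- shift + unname(gs[frame$genotype])
    gm <- eff$interaction[[resp]]
    if (!is.null(gm)) {
      gi <- match(frame$genotype, c("CC", "CT", "TT"))
      ti <- match(as.character(tert), c("T1", "T2", "T3"))
      shift <- shift + gm[cbind(gi, ti)]
    }
    shift
  }
  noise_frac <- sqrt(max(0, 1 - sum(r2)))
  draw <- function(resp) {
    mu <- .response_mean(resp, frame$sex, bm)
    s <- .response_sd(resp, bm)
    std <- sqrt(r2["age"]) * z_age + sqrt(r2["wc"]) * z_wc +
      struct_part(resp) + noise_frac * stats::rnorm(n)
    mu + s * std
  }
  out <- data.frame(row.names = seq_len(n))
  out$tc <- draw("tc")
  out$hdl <- pmax(draw("hdl"), 20)
  out$tg <- pmax(draw("tg"), bm$tg_floor)
  out$glucose <- pmax(draw("glucose"), 60)
  out$insulin <- stats::rlnorm(n, bm$insulin_meanlog, bm$insulin_sdlog)
  sbp_latent <- pmax(draw("sbp"), 85)
  dbp_latent <- pmax(draw("dbp"), 50)
  out$sbp_1 <- sbp_latent + stats::rnorm(n, 0, bm$bp_reading_sd)
  out$sbp_2 <- sbp_latent + stats::rnorm(n, 0, bm$bp_reading_sd)
  out$dbp_1 <- dbp_latent + stats::rnorm(n, 0, bm$bp_reading_sd)
  out$dbp_2 <- dbp_latent + stats::rnorm(n, 0, bm$bp_reading_sd)
  for (flag in names(eff$binary)) {
    spec <- eff$binary[[flag]]
    eta <- stats::qlogis(spec$p0) + unname(spec$log_or[frame$genotype])
    out[[flag]] <- stats::rbinom(n, 1, stats::plogis(eta))
  }
  out
}

#' Simulate a complete cohort with ground truth
#'
#' End-to-end generation: sex, age, anthropometrics, genotypes (with RFLP
#' fragment serializations), intakes and energy, diet-quality scores and
#' sex-specific tertiles (computed with the package's own scoring, so
#' planted interaction effects are indexed by the tertiles the analysis
#' will actually use), biomarkers with planted effects, and questionnaire
#' blocks (DASS-21 items, VAS appetite items, SES indicators). The same
#' seed always reproduces the same cohort.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (falls back to `config$seed`, then 1).
#' @return Object of class `gx_simulated_cohort`: a list with `cohort`
#'   (the subject table) and `truth` (tertile memberships, planted
#'   effects, generator parameters).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "gx_cohort_config"))
  if (is.null(seed)) seed <- if (is.null(config$seed)) 1L else config$seed
  set.seed(seed)
  n <- config$n
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
  age <- .rtruncnorm(n, config$age["mean"], config$age["sd"],
                     config$age["lo"], config$age["hi"])
  height <- ifelse(sex == "male",
                   stats::rnorm(n, config$height$male[1],
                                config$height$male[2]),
                   stats::rnorm(n, config$height$female[1],
                                config$height$female[2]))
  bmi_val <- 30 + stats::rgamma(n, shape = 2, scale = 1.6)
  weight <- bmi_val * (height / 100)^2
  ffm_frac <- ifelse(sex == "male", 0.72, 0.57) + stats::rnorm(n, 0, 0.02)
  ffm <- ffm_frac * weight
  fm <- weight - ffm
  wc <- ifelse(sex == "male",
               .rtruncnorm(n, config$wc$male[1], config$wc$male[2], lo = 90),
               .rtruncnorm(n, config$wc$female[1], config$wc$female[2],
                           lo = 80))
  genotype <- simulate_genotypes(n, probs = config$genotype_probs,
                                 maf = config$hwe_maf)
  frag_for <- function(g) switch(g, CC = "192;380", TT = "572",
                                 CT = "192;380;572")
  intakes <- simulate_intakes(n, sex, config)
  energy <- .simulate_energy(intakes, config)
  cohort <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)), sex = sex, age = age,
    weight = weight, height = height, wc = wc, fm = fm, ffm = ffm,
    energy = energy, stringsAsFactors = FALSE)
  cohort <- cbind(cohort, intakes)
  cohort$genotype <- genotype
  cohort$rflp_fragments <- vapply(genotype, frag_for, character(1))
  cohort$physical_activity <- sample(names(config$activity_probs), n,
                                     TRUE, config$activity_probs)
  cohort$marital_status <- sample(names(config$marital_probs), n,
                                  TRUE, config$marital_probs)
  for (item in c("ses_education", "ses_occupation", "ses_house"))
    cohort[[item]] <- sample(1:5, n, TRUE,
                             prob = c(0.05, 0.20, 0.35, 0.25, 0.15))
  cohort$family_size <- sample(1:7, n, TRUE,
                               prob = c(.08, .22, .25, .25, .12, .05, .03))
  for (i in 1:21)
    cohort[[paste0("dass_", i)]] <- sample(0:3, n, TRUE,
                                           prob = c(.55, .20, .15, .10))
  for (i in 1:8)
    cohort[[paste0("vas_", i)]] <- .rtruncnorm(n, 33.58, 12, 0, 100)
  dash <- score_dash(cohort)
  mds <- score_mds(cohort)
  cohort$dash_total <- dash$dash_total
  cohort$mds_total <- mds$mds_total
  dash_tert <- assign_tertiles(cohort$dash_total, strata = sex)
  mds_tert <- assign_tertiles(cohort$mds_total, strata = sex)
  frame <- data.frame(sex = sex, age = age, wc = wc, genotype = genotype,
                      dash_tertile = dash_tert, mds_tertile = mds_tert,
                      stringsAsFactors = FALSE)
  cohort <- cbind(cohort, simulate_biomarkers(frame, config))
  truth <- list(
    seed = seed, config = config,
    tertiles = data.frame(subject_id = cohort$subject_id,
                          dash_tertile = dash_tert, mds_tertile = mds_tert,
                          stringsAsFactors = FALSE),
    effects = config$effects)
  structure(list(cohort = cohort, truth = truth),
            class = "gx_simulated_cohort")
}

#' @export
print.gx_simulated_cohort <- function(x, ...) {
  gf <- genotype_frequencies(x$cohort$genotype)
  cat("Simulated cohort: n =", nrow(x$cohort),
      sprintf("(%.1f%% male), seed %d\n",
              100 * mean(x$cohort$sex == "male"), x$truth$seed))
  cat(sprintf("Genotypes CC/CT/TT: %.1f/%.1f/%.1f%%, f(T) = %.3f\n",
              100 * gf$proportions["CC"], 100 * gf$proportions["CT"],
              100 * gf$proportions["TT"], gf$f_T))
  invisible(x)
}
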