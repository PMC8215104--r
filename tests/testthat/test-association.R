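make_or_data <- function(counts) {
  # counts: named list genotype -> c(cases, controls)
  rows <- lapply(names(counts), function(g) {
    data.frame(genotype = g,
               outcome = rep(c(1, 0), counts[[g]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("crude logistic OR equals the 2x2 cross-product ratio", {
  dat <- make_or_data(list(CC = c(10, 90), TT = c(20, 80)))
  got <- fit_genotype_outcome_or(dat, "outcome")
  tt <- got[got$contrast == "TT vs CC", ]
  expect_equal(tt$or, (20 * 90) / (80 * 10), tolerance = 1e-6)
  expect_true(tt$ci_low <= tt$or && tt$or <= tt$ci_high)
  expect_equal(tt$flag, "")
  # three-level case: each contrast is its own cross-product ratio
  dat3 <- make_or_data(list(CC = c(15, 85), CT = c(25, 75), TT = c(30, 70)))
  got3 <- fit_genotype_outcome_or(dat3, "outcome")
  expect_equal(got3$or[got3$contrast == "CT vs CC"],
               (25 * 85) / (75 * 15), tolerance = 1e-6)
  expect_equal(got3$or[got3$contrast == "TT vs CC"],
               (30 * 85) / (70 * 15), tolerance = 1e-6)
})

test_that("null simulation: outcome independent of genotype gives OR near 1", {
  set.seed(31)
  n <- 10000
  dat <- data.frame(
    genotype = sample(c("CC", "CT", "TT"), n, TRUE, c(.378, .519, .103)),
    outcome = rbinom(n, 1, 0.3))
  got <- fit_genotype_outcome_or(dat, "outcome")
  expect_true(all(got$or > 0.9 & got$or < 1.1))
  expect_true(all(got$ci_low <= got$or & got$or <= got$ci_high))
})

test_that("adjusted logistic models accept the nested covariate sets", {
  set.seed(32)
  n <- 600
  dat <- data.frame(
    genotype = sample(c("CC", "CT", "TT"), n, TRUE),
    age = runif(n, 20, 50),
    wc = rnorm(n, 108, 10),
    physical_activity = sample(c("low", "moderate", "high"), n, TRUE),
    ses = sample(c("low", "middle", "high"), n, TRUE))
  dat$outcome <- rbinom(n, 1, plogis(-1 + 0.02 * (dat$age - 35)))
  expect_equal(model_spec("crude")$covariates, character(0))
  expect_equal(model_spec("model1")$covariates,
               c("age", "physical_activity", "ses"))
  expect_equal(model_spec("model2")$covariates,
               c("age", "physical_activity", "ses", "wc"))
  for (nm in c("crude", "model1", "model2")) {
    got <- fit_genotype_outcome_or(dat, "outcome", model_spec(nm))
    expect_equal(nrow(got), 2)
    expect_equal(unique(got$model), nm)
    expect_true(all(got$ci_low <= got$or & got$or <= got$ci_high))
  }
  expect_error(
    fit_genotype_outcome_or(dat[, c("genotype", "outcome")], "outcome",
                            model_spec("model1")), "covariates absent")
})

test_that("multinomial diet-genotype model matches stratified 2x2 oracles", {
  # binary score: the per-unit OR for level L vs CC is the cross-product
  # of the L/CC by score table
  counts <- list(CC = c(40, 60), CT = c(55, 45), TT = c(20, 30))
  rows <- lapply(names(counts), function(g)
    data.frame(genotype = g, score = rep(c(1, 0), counts[[g]])))
  dat <- do.call(rbind, rows)
  got <- fit_diet_genotype_multinomial(dat, "score")
  or_ct <- (55 * 60) / (45 * 40)
  or_tt <- (20 * 60) / (30 * 40)
  expect_equal(got$or[got$contrast == "CT vs CC"], or_ct, tolerance = 1e-4)
  expect_equal(got$or[got$contrast == "TT vs CC"], or_tt, tolerance = 1e-4)
})

test_that("multinomial recovery of a planted per-score log-odds slope", {
  set.seed(33)
  n <- 5000
  score <- rnorm(n, 24, 4.3)
  # genotype sampled with TT log-odds slope 0.2 per score unit vs CC
  eta_ct <- 0.3 + 0 * score
  eta_tt <- -1 + 0.2 * (score - 24)
  p <- cbind(1, exp(eta_ct), exp(eta_tt))
  p <- p / rowSums(p)
  g <- apply(p, 1, function(pr) sample(c("CC", "CT", "TT"), 1, prob = pr))
  dat <- data.frame(genotype = g, score = score - 24)
  got <- fit_diet_genotype_multinomial(dat, "score")
  expect_equal(got$or[got$contrast == "TT vs CC"], exp(0.2),
               tolerance = 0.1)
  expect_equal(got$or[got$contrast == "CT vs CC"], 1, tolerance = 0.1)
  # null: score independent of genotype
  dat0 <- data.frame(genotype = sample(c("CC", "CT", "TT"), n, TRUE),
                     score = rnorm(n))
  got0 <- fit_diet_genotype_multinomial(dat0, "score")
  expect_true(all(abs(log(got0$or)) < 0.1))
  # empty level dropped with warning and flag
  expect_warning(
    few <- fit_diet_genotype_multinomial(
      data.frame(genotype = sample(c("CC", "CT"), 200, TRUE),
                 score = rnorm(200)), "score"), "TT")
  expect_match(few$flag[1], "TT")
})

make_cell_data <- function(n_cell, means = matrix(0, 3, 3), sd = 1,
                           seed = 1) {
  set.seed(seed)
  g <- rep(c("CC", "CT", "TT"), each = 3 * n_cell)
  t <- rep(rep(c("T1", "T2", "T3"), each = n_cell), 3)
  gi <- match(g, c("CC", "CT", "TT"))
  ti <- match(t, c("T1", "T2", "T3"))
  data.frame(genotype = g, tertile = t,
             y = rnorm(length(g), means[cbind(gi, ti)], sd))
}

test_that("ANCOVA without covariates reproduces two-way ANOVA exactly", {
  dat <- make_cell_data(8, seed = 34)
  fit <- ancova_interaction(dat, "y", covariates = character(0))
  ref <- anova(lm(y ~ genotype * tertile, dat))
  expect_equal(fit$f_statistic, ref["genotype:tertile", "F value"])
  expect_equal(fit$p_interaction, ref["genotype:tertile", "Pr(>F)"])
  expect_equal(fit$df, c(4, ref["Residuals", "Df"]))
  # adjusted means equal raw cell means in the balanced zero-covariate case
  raw <- aggregate(y ~ genotype + tertile, dat, mean)
  merged <- merge(fit$cell_means, raw, by = c("genotype", "tertile"))
  expect_equal(merged$emmean, merged$y)
})

test_that("adjusted means are invariant to affine covariate recoding", {
  set.seed(35)
  dat <- make_cell_data(10, seed = 35)
  dat$age <- runif(nrow(dat), 20, 50)
  dat$y <- dat$y + 0.05 * dat$age
  f1 <- ancova_interaction(dat, "y", covariates = "age")
  dat2 <- dat
  dat2$age <- 2 * dat$age + 5
  f2 <- ancova_interaction(dat2, "y", covariates = "age")
  expect_equal(f1$cell_means$emmean, f2$cell_means$emmean)
  expect_equal(f1$p_interaction, f2$p_interaction)
})

test_that("partial F-test and contrasts agree with direct algebra", {
  dat <- make_cell_data(6, seed = 36)
  fit <- ancova_interaction(dat, "y", covariates = character(0))
  # t-contrast oracle: difference of cell means over sigma*sqrt(2/n)
  lmfit <- lm(y ~ genotype * tertile, dat)
  sigma <- summary(lmfit)$sigma
  cm <- aggregate(y ~ genotype + tertile, dat, mean)
  ph <- posthoc_cell_comparisons(fit, "lsd")
  m_t1 <- cm$y[cm$genotype == "CC" & cm$tertile == "T1"]
  m_t2 <- cm$y[cm$genotype == "CC" & cm$tertile == "T2"]
  row <- ph[ph$genotype == "CC" & ph$contrast == "T1 - T2", ]
  expect_equal(row$estimate, m_t1 - m_t2)
  expect_equal(row$SE, sigma * sqrt(2 / 6))
  expect_equal(row$p.value,
               2 * pt(-abs((m_t1 - m_t2) / (sigma * sqrt(2 / 6))),
                      df.residual(lmfit)))
  # Bonferroni never reports smaller p than LSD
  phb <- posthoc_cell_comparisons(fit, "bonferroni")
  expect_true(all(phb$p.value >= ph$p.value - 1e-12))
})

test_that("identical cell patterns give zero contrasts with p = 1", {
  cell <- c(1, 2, 3, 4)
  dat <- data.frame(
    genotype = rep(c("CC", "CT", "TT"), each = 12),
    tertile = rep(rep(c("T1", "T2", "T3"), each = 4), 3),
    y = rep(cell, 9))
  fit <- ancova_interaction(dat, "y", covariates = character(0))
  ph <- posthoc_cell_comparisons(fit, "lsd")
  expect_equal(ph$estimate, rep(0, nrow(ph)))
  expect_equal(ph$p.value, rep(1, nrow(ph)))
  expect_equal(fit$f_statistic, 0)
})

test_that("planted cell shift is detected and localizes to its contrast", {
  means <- matrix(0, 3, 3, dimnames = list(c("CC", "CT", "TT"),
                                           c("T1", "T2", "T3")))
  means["CT", "T2"] <- -1.2
  dat <- make_cell_data(40, means = means, seed = 37)
  fit <- ancova_interaction(dat, "y", covariates = character(0))
  expect_lt(fit$p_interaction, 0.01)
  ph <- posthoc_cell_comparisons(fit, "lsd")
  expect_lt(ph$p.value[ph$genotype == "CT" & ph$contrast == "T1 - T2"],
            0.01)
})

test_that("empty cells are flagged in the adjusted-mean grid", {
  dat <- make_cell_data(5, seed = 38)
  dat <- dat[!(dat$genotype == "TT" & dat$tertile == "T3"), ]
  fit <- ancova_interaction(dat, "y", covariates = character(0))
  empty <- fit$cell_means[fit$cell_means$genotype == "TT" &
                            fit$cell_means$tertile == "T3", ]
  expect_true(empty$empty)
  expect_true(is.na(empty$emmean))
})

test_that("tertile tables run ANOVA and chi-square with the right p-values", {
  set.seed(39)
  n <- 120
  dat <- data.frame(
    tertile = factor(rep(c("T1", "T2", "T3"), each = n / 3)),
    y = rnorm(n), g = sample(c("a", "b"), n, TRUE))
  out <- tables_by_tertile(dat, continuous = "y", categorical = "g")
  ref <- anova(lm(y ~ tertile, dat))[1, "Pr(>F)"]
  expect_equal(out$p_value[out$variable == "y"], ref)
  # identical category distribution across tertiles: statistic 0, p 1
  bal <- data.frame(tertile = factor(rep(c("T1", "T2", "T3"), each = 20)),
                    g = rep(rep(c("a", "b"), each = 10), 3))
  outb <- tables_by_tertile(bal, categorical = "g")
  expect_equal(outb$statistic, 0)
  expect_equal(outb$p_value, 1)
  # hand-computed 2x2 chi-square oracle on counts (20,80 / 10,90)
  tab <- matrix(c(20, 10, 80, 90), 2)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - exp_counts)^2 / exp_counts)
  d22 <- data.frame(
    tertile = factor(rep(c("T1", "T2"), times = c(100, 100))),
    g = c(rep(c("yes", "no"), c(20, 80)), rep(c("yes", "no"), c(10, 90))))
  # two tertile levels suffice for the chi-square branch
  out22 <- tables_by_tertile(d22, categorical = "g")
  expect_equal(out22$statistic, stat, tolerance = 1e-10)
  expect_equal(out22$p_value, pchisq(stat, 1, lower.tail = FALSE))
})
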