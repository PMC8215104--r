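test_that("Friedewald LDL: arithmetic, identity, validity bound", {
  expect_equal(friedewald_ldl(188.43, 44.97, 119.97), 119.466)
  expect_equal(friedewald_ldl(50, 50, 0), 0)
  # conservation against an independent spreadsheet-style oracle
  set.seed(20)
  tc <- runif(50, 120, 280); hdl <- runif(50, 30, 80)
  tg <- runif(50, 40, 390)
  ldl <- friedewald_ldl(tc, hdl, tg)
  expect_equal(ldl, tc - hdl - tg / 5)
  expect_equal(tc, ldl + hdl + tg / 5)
  expect_error(friedewald_ldl(200, 50, 450), "400")
  expect_true(is.na(friedewald_ldl(200, 50, 450, on_invalid = "missing")))
})

test_that("AIP is the log ratio, antisymmetric, and guarded", {
  expect_equal(aip(50, 50), 0)
  expect_equal(aip(119.97, 44.97), 0.426, tolerance = 5e-4)
  set.seed(21)
  a <- runif(20, 10, 300); b <- runif(20, 10, 300)
  expect_equal(aip(a, b), -aip(b, a))
  expect_error(aip(0, 50), "positive")
})

test_that("HOMA-IR and QUICKI formulas and their monotone relationship", {
  expect_equal(homa_ir(405, 1), 1)
  expect_equal(homa_ir(91, 13.1), 2.943, tolerance = 5e-4)
  expect_equal(homa_ir(100, 0), 0)
  expect_equal(quicki(10, 10), 0.5)
  expect_equal(quicki(91, 13.1), 0.325, tolerance = 5e-4)
  expect_error(quicki(1, 1), "positive")
  # both are monotone transforms of the glucose x insulin product
  set.seed(22)
  g <- runif(200, 70, 200); ins <- runif(200, 2, 40)
  expect_equal(cor(quicki(g, ins), homa_ir(g, ins), method = "spearman"), -1)
  prod1 <- 90 * 10; prod2 <- 95 * 12
  expect_lt(homa_ir(90, 10), homa_ir(95, 12))
  expect_gt(quicki(90, 10), quicki(95, 12))
})

test_that("MetS classification counts criteria with sex-specific cuts", {
  # rule-by-rule: male with WC 110, BP 135/80, TG 160, HDL 45, glucose 95
  got <- classify_mets(110, "male", 135, 80, 160, 45, 95)
  expect_equal(got$criteria_count, 3L)
  expect_true(got$mets)
  # all healthy
  none <- classify_mets(90, "male", 118, 75, 100, 55, 90)
  expect_equal(none$criteria_count, 0L)
  expect_false(none$mets)
  # female HDL 49 meets the sex-specific low-HDL cut
  f <- classify_mets(80, "female", 118, 75, 100, 49, 90)
  expect_equal(f$criteria_count, 1L)
  # boundary: BP exactly 130/85 counts; count never exceeds 5
  all5 <- classify_mets(120, "female", 130, 85, 200, 30, 120)
  expect_equal(all5$criteria_count, 5L)
  # missing input leaves the subject unclassified
  expect_true(is.na(classify_mets(NA, "male", 120, 80, 100, 50, 90)$mets))
  # alternative ruleset: WC > 88 for everyone, glucose cut 110
  alt <- classify_mets(95, "male", 120, 80, 100, 55, 105,
                       ruleset = "atp3_wc88")
  expect_equal(alt$criteria_count, 1L)  # only the WC criterion
})

test_that("risk flags honor inclusive/strict boundaries", {
  fl <- classify_risk_flags(tc = 220, ldl = 160, hdl = 39, tg = 150,
                            sbp = 130, dbp = 70, glucose = 100,
                            homa = 2.6, quicki = 0.33, sex = "male")
  expect_true(fl$high_cholesterol)   # inclusive >=
  expect_true(fl$high_ldl)
  expect_true(fl$high_tg)
  expect_true(fl$high_bp)
  expect_true(fl$hyperglycemia)
  expect_false(fl$high_homa)         # strict >
  expect_false(fl$low_quicki)        # strict <
  healthy <- classify_risk_flags(180, 100, 55, 100, 115, 75, 90, 1.5,
                                 0.36, "male")
  expect_false(any(unlist(healthy)))
  # sex-specific HDL cut
  f <- classify_risk_flags(180, 100, 49, 100, 115, 75, 90, 1.5, 0.36,
                           "female")
  expect_true(f$low_hdl)
})

test_that("DASS-21 subscales double the item sums and band severities", {
  expect_equal(unlist(score_dass(rep(0, 21))[, c("depression", "anxiety",
                                                 "stress")],
                      use.names = FALSE), c(0, 0, 0))
  hi <- score_dass(rep(3, 21))
  expect_equal(unlist(hi[, c("depression", "anxiety", "stress")],
                      use.names = FALSE), c(42, 42, 42))
  expect_equal(hi$depression_severity, "extremely_severe")
  # all depression items at 1 -> score 14 -> moderate under Lovibond cuts
  items <- rep(0, 21)
  items[dass_item_map()$depression] <- 1
  one <- score_dass(items)
  expect_equal(one$depression, 14)
  expect_equal(one$depression_severity, "moderate")
  expect_equal(one$anxiety, 0)
  expect_error(score_dass(rep(4, 21)), "0-3")
  expect_error(score_dass(rep(1, 20)), "21")
  # parity property: subscales are always even
  set.seed(23)
  m <- matrix(sample(0:3, 21 * 40, TRUE), ncol = 21)
  sc <- score_dass(m)
  expect_true(all(sc$depression %% 2 == 0))
  expect_true(all(sc$anxiety %% 2 == 0))
  expect_true(all(sc$stress %% 2 == 0))
})

test_that("BP averaging and appetite score are plain means with guards", {
  expect_equal(mean_bp(120, 120, 80, 80)$sbp, 120)
  got <- mean_bp(110, 130, 70, 90)
  expect_equal(got$sbp, 120)
  expect_equal(got$dbp, 80)
  expect_warning(one <- mean_bp(c(110, NA), c(130, 120), c(70, 70),
                                c(90, 80)), "single")
  expect_equal(one$sbp[2], 120)
  expect_equal(appetite_score(40), 40)
  expect_equal(appetite_score(c(20, 40, 60)), 40)
  set.seed(24)
  m <- matrix(runif(5 * 30, 0, 100), ncol = 5)
  expect_equal(appetite_score(m), rowMeans(m))
  expect_error(appetite_score(150), "100")
  expect_error(appetite_score(numeric(0)), "items")
})

test_that("phenotype panel assembles derived columns consistently", {
  cohort <- make_toy_cohort(40, seed = 25)
  panel <- phenotype_panel(cohort)
  expect_equal(nrow(panel), 40)
  expect_equal(panel$ldl, cohort$tc - cohort$hdl - cohort$tg / 5)
  expect_equal(panel$mets, panel$mets_count >= 3)
  expect_true(all(panel$mets_count <= 5, na.rm = TRUE))
  expect_equal(panel$sbp, (cohort$sbp_1 + cohort$sbp_2) / 2)
})
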