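# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (explicit sort-and-walk loops, direct factorial
# formulas) so they share no code path with the package implementation.

# Sort-and-bucket quantile group oracle: walk the sorted values assigning
# equal-frequency buckets; tied values inherit the bucket of their first
# occurrence (the lowest qualifying group).
oracle_quantile_groups <- function(x, k) {
  n <- length(x)
  ord <- order(x)
  grp <- integer(n)
  # bucket of sorted position p: smallest j with p <= n*j/k
  bucket_of_pos <- vapply(seq_len(n), function(p)
    min(which(p <= n * seq_len(k) / k)), integer(1))
  for (i in seq_len(n)) {
    first_pos <- min(which(x[ord] == x[i]))  # ties take the first occurrence
    grp[i] <- bucket_of_pos[first_pos]
  }
  grp
}

# DASH oracle: quintile-bucket per sex per component, reverse the
# discouraged ones, sum.
oracle_dash_total <- function(cohort) {
  emph <- list(fruits = "fruits", vegetables = "vegetables",
               whole_grains = "whole_grains", low_fat_dairy = "low_fat_dairy",
               nuts_legumes = c("nuts", "legumes"))
  disc <- list(sodium = "sodium", red_processed_meat = "red_processed_meat",
               sweetened_beverages = "sweetened_beverages")
  total <- numeric(nrow(cohort))
  by_sex_groups <- function(amount) {
    g <- integer(length(amount))
    for (s in unique(cohort$sex)) {
      idx <- cohort$sex == s
      g[idx] <- oracle_quantile_groups(amount[idx], 5)
    }
    g
  }
  for (cols in emph)
    total <- total + by_sex_groups(rowSums(cohort[, cols, drop = FALSE]))
  for (cols in disc)
    total <- total + 6 - by_sex_groups(rowSums(cohort[, cols, drop = FALSE]))
  total
}

# MDS oracle: direct median comparisons per sex.
oracle_mds_total <- function(cohort) {
  total <- numeric(nrow(cohort))
  med_by_sex <- function(amount) {
    m <- numeric(length(amount))
    for (s in unique(cohort$sex))
      m[cohort$sex == s] <- median(amount[cohort$sex == s])
    m
  }
  prot <- list("vegetables", "legumes", c("fruits", "nuts"), "cereals",
               "fish_seafood")
  for (cols in prot) {
    amt <- rowSums(cohort[, cols, drop = FALSE])
    total <- total + (amt >= med_by_sex(amt))
  }
  ratio <- cohort$mufa / cohort$sfa
  total <- total + (ratio >= med_by_sex(ratio))
  for (col in c("meat_total", "dairy_total")) {
    amt <- cohort[[col]]
    total <- total + (amt < med_by_sex(amt))
  }
  total
}

# Direct factorial HWE enumeration (log-scale), independent of the
# recurrence used by the implementation.
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  log_prob <- function(h) {
    a <- (na - h) / 2
    b <- n - a - h
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
      h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
      lfactorial(2 * n)
  }
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  lp <- vapply(hets, log_prob, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- p[hets == n_ab]
  sum(p[p <= obs * (1 + 1e-9)])
}

# Minimal random cohort in canonical layout (no effects, independent
# columns) for scoring and I/O tests.
make_toy_cohort <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  intake <- function(med, sdlog) rlnorm(n, log(med), sdlog)
  data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    sex = sample(c("male", "female"), n, TRUE),
    age = runif(n, 20, 50),
    weight = runif(n, 80, 130), height = runif(n, 150, 190),
    wc = runif(n, 90, 130), energy = runif(n, 1500, 3800),
    fruits = intake(444, 0.7), vegetables = intake(320, 0.6),
    whole_grains = intake(150, 0.6), low_fat_dairy = intake(120, 0.8),
    nuts = intake(11, 1.1), legumes = intake(49, 0.7),
    red_processed_meat = intake(49, 0.8),
    sweetened_beverages = intake(100, 0.9),
    cereals = intake(523, 0.5), fish_seafood = intake(6.4, 1.4),
    dairy_total = intake(260, 0.8), meat_total = intake(75, 0.6),
    sodium = intake(3500, 0.3), mufa = intake(34, 0.3),
    sfa = intake(28, 0.25),
    tc = rnorm(n, 188, 34), hdl = runif(n, 30, 70),
    tg = runif(n, 50, 350), glucose = runif(n, 75, 130),
    insulin = rlnorm(n, log(13), 0.7),
    sbp_1 = rnorm(n, 116, 16), sbp_2 = rnorm(n, 116, 16),
    dbp_1 = rnorm(n, 76, 12), dbp_2 = rnorm(n, 76, 12),
    physical_activity = sample(c("low", "moderate", "high"), n, TRUE),
    stringsAsFactors = FALSE)
}

# Screening fixture: n_complete eligible records plus planted violations.
make_screening_fixture <- function(n_total = 352, n_incomplete = 2,
                                   n_energy_bad = 3, seed = 7) {
  cohort <- make_toy_cohort(n_total, seed = seed)
  cohort$weight <- pmax(cohort$weight,
                        31 * (cohort$height / 100)^2)  # everyone obese
  idx_inc <- seq_len(n_incomplete)
  idx_energy <- n_incomplete + seq_len(n_energy_bad)
  cohort$fruits[idx_inc] <- NA
  cohort$energy[idx_energy] <- c(750, 4500, 600)[seq_len(n_energy_bad)]
  cohort
}
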