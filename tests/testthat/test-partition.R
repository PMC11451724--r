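test_that("Cox-Snell R2 formula and contracts", {
  expect_equal(cox_snell_r2(-100, -100, 50), 0)
  expect_equal(cox_snell_r2(-100, -90, 50), 1 - exp(-0.4), tolerance = 1e-12)
  # monotone in the model log likelihood
  r <- vapply(c(-95, -92, -90, -85), function(l) cox_snell_r2(-100, l, 50),
              numeric(1))
  expect_true(all(diff(r) > 0))
  expect_error(cox_snell_r2(-90, -100, 50), "loglik")
  expect_error(cox_snell_r2(-100, -90, 0), "n")
})

test_that("contribution normalizes likelihood drops", {
  expect_equal(unname(contribution(c(a = 5))), 1)
  expect_equal(contribution(c(A = 2, B = 2)), c(A = 0.5, B = 0.5))
  drops <- c(genotype = 68, cohort = 16.4, sex = 14.6, lab = 3.3, diet = 0.76)
  ct <- contribution(drops)
  expect_equal(sum(ct), 1, tolerance = 1e-12)
  expect_equal(unname(ct), unname(drops / sum(drops)), tolerance = 1e-12)
  expect_equal(unname(round(ct, 4)),
               c(0.6598, 0.1591, 0.1417, 0.0320, 0.0074))
  expect_error(contribution(c(a = 0, b = 0)), "no covariate")
  expect_error(contribution(c(a = -1, b = 2)), ">= 0")
  # invariant to adding a constant to every log likelihood
  ll_full <- -500
  ll_red <- c(a = -520, b = -504)
  shift <- 123.4
  expect_equal(contribution(ll_full - ll_red),
               contribution((ll_full + shift) - (ll_red + shift)),
               tolerance = 1e-12)
})

test_that("pipeline output satisfies its invariants and is deterministic", {
  rec <- simulate_lifespans(sim_params(flies_per_cell = 8L, seed = 44L))
  vp <- partition_pipeline(rec)
  expect_true(all(vp$drops >= 0))
  expect_equal(sum(vp$contributions), 1, tolerance = 1e-10)
  expect_true(all(vp$contributions >= 0 & vp$contributions <= 1))
  expect_true(all(vp$r2_full >= vp$r2_reduced))
  expect_s3_class(vp$ph, "ph_test")
  vp2 <- partition_pipeline(rec)
  vp$fit_full <- vp2$fit_full <- vp$ph <- vp2$ph <- NULL
  expect_identical(vp, vp2)
})

test_that("null covariate drops shrink with n (consistency)", {
  drop_null <- function(n_per_cell, seed) {
    rec <- simulate_lifespans(sim_params(
      flies_per_cell = n_per_cell, seed = seed,
      beta = list(genotype = c("w1118" = 0, "Oregon-R" = -0.4,
                               "wDahomey" = 0.4, "Canton-S" = 0.15)),
      cohort_frailty_sd = 0
    ))
    vp <- partition_pipeline(rec, ph_diagnostic = FALSE)
    vp$drops[["diet"]]     # diet carries no effect here
  }
  small <- mean(vapply(1:5, function(s) drop_null(16L, s), numeric(1)))
  big <- mean(vapply(1:5, function(s) drop_null(125L, 100 + s), numeric(1)))
  # a null drop is ~chi2(1)/2 regardless of n: its *contribution* vanishes
  expect_lt(big, 5)
  contrib_small <- mean(vapply(1:5, function(s) {
    rec <- simulate_lifespans(sim_params(flies_per_cell = 16L, seed = s,
                                         cohort_frailty_sd = 0))
    partition_pipeline(rec, ph_diagnostic = FALSE)$contributions[["diet"]]
  }, numeric(1)))
  expect_lt(contrib_small, 0.2)
})

test_that("pure genotype effect is attributed almost entirely to genotype", {
  meds <- t(vapply(1:20, function(s) {
    rec <- simulate_lifespans(sim_params(
      flies_per_cell = 63L, seed = 500 + s,
      beta = list(genotype = c("w1118" = 0, "Oregon-R" = -0.4,
                               "wDahomey" = 0.4, "Canton-S" = 0.15)),
      cohort_frailty_sd = 0
    ))
    partition_pipeline(rec, ph_diagnostic = FALSE)$contributions
  }, numeric(5)))
  expect_gt(median(meds[, "genotype"]), 0.9)
  for (cv in c("lab", "sex", "cohort", "diet")) {
    expect_lt(median(meds[, cv]), 0.05)
  }
})

test_that("permuting diet labels destroys the diet contribution", {
  rec <- simulate_lifespans(sim_params(flies_per_cell = 31L, seed = 64L))
  base <- partition_pipeline(rec, ph_diagnostic = FALSE)$drops[["diet"]]
  set.seed(99)
  worse <- vapply(1:25, function(i) {
    perm <- rec
    perm$diet <- sample(perm$diet)
    partition_pipeline(perm, ph_diagnostic = FALSE)$drops[["diet"]]
  }, numeric(1))
  expect_gt(mean(worse < base), 0.95)
})
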