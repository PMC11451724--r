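test_that("mirror-symmetric binary covariate forces beta = 0", {
  # two identical event-time sets, labels swapped: partial likelihood is
  # symmetric in beta, so the maximum sits at 0
  rec <- data.frame(
    time_days = c(1, 2, 3, 4, 1, 2, 3, 4),
    event = 1,
    grp = rep(c("a", "b"), each = 4)
  )
  fit <- cox_fit(rec, "grp")
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), 0, tolerance = 1e-8)
  expect_equal(fit$loglik, fit$loglik_null)
})

test_that("6-subject fit matches grid-search maximization of the oracle PL", {
  time <- c(2, 4, 5, 7, 9, 12)
  event <- rep(1L, 6)
  x <- c(1, 0, 1, 0, 1, 0)
  rec <- data.frame(time_days = time, event = event, grp = c("b", "a")[2 - x])
  fit <- cox_fit(rec, "grp")
  # closed-form oracle PL for a tie-free binary covariate, on a fine grid
  grid <- seq(-3, 3, by = 1e-5)
  n1_risk <- vapply(time, function(t) sum(x[time >= t]), numeric(1))
  n_risk <- vapply(time, function(t) sum(time >= t), numeric(1))
  llg <- sum(x) * grid
  for (j in seq_along(time)) {
    llg <- llg - log((n_risk[j] - n1_risk[j]) + n1_risk[j] * exp(grid))
  }
  beta_grid <- grid[which.max(llg)]
  expect_lt(abs(unname(fit$beta) - beta_grid), 1e-4)
  # and the maximized value agrees with the naive loop oracle
  expect_equal(fit$loglik,
               oracle_cox_loglik(time, event, matrix(x), unname(fit$beta)),
               tolerance = 1e-10)
})

test_that("loglik, score and information match the loop oracle with ties", {
  set.seed(19)
  rec <- simulate_lifespans(small_design(flies_per_cell = 15L, seed = 4L))
  rec$time_days <- round(rec$time_days)          # force heavy ties
  rec <- rec[rec$time_days > 0, ]
  X <- cbind(gB = as.numeric(rec$genotype == "gB"),
             M = as.numeric(rec$sex == "M"))
  beta <- c(0.3, -0.2)
  for (ties in c("efron", "breslow")) {
    mine <- cox_loglik(rec, c("genotype", "sex"), beta = beta, ties = ties)
    expect_equal(mine$loglik,
                 oracle_cox_loglik(rec$time_days, rec$event, X, beta, ties),
                 tolerance = 1e-9)
  }
})

test_that("fit agrees with survival::coxph under both tie methods", {
  skip_if_not_installed("survival")
  rec <- simulate_lifespans(sim_params(flies_per_cell = 6L, seed = 27L))
  rec$time_days <- round(rec$time_days)          # many ties
  rec <- rec[rec$time_days > 0, ]
  terms <- c("lab", "sex", "cohort", "genotype", "diet")
  for (ties in c("efron", "breslow")) {
    fit <- cox_fit(rec, terms, ties = ties)
    ref <- survival::coxph(
      survival::Surv(time_days, event) ~ lab + sex + cohort + genotype + diet,
      data = rec, ties = ties
    )
    expect_true(fit$converged)
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$loglik, logLik(ref)[1], tolerance = 1e-8)
    expect_equal(fit$loglik_null, ref$loglik[1], tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(sqrt(diag(ref$var))),
                 tolerance = 1e-5)
  }
})

test_that("Efron and Breslow coincide exactly on tie-free data", {
  rec <- simulate_lifespans(small_design(flies_per_cell = 20L, seed = 8L))
  stopifnot(!anyDuplicated(rec$time_days[rec$event == 1]))
  fe <- cox_fit(rec, c("genotype", "sex"), ties = "efron")
  fb <- cox_fit(rec, c("genotype", "sex"), ties = "breslow")
  expect_equal(fe$beta, fb$beta, tolerance = 1e-10)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-10)
})

test_that("score test at beta = 0 equals the log-rank statistic (tie-free)", {
  for (seed in c(2L, 14L)) {
    rec <- simulate_lifespans(small_design(flies_per_cell = 20L, seed = seed,
                                           censor_rate = 0.1))
    sc <- cox_loglik(rec, "diet", ties = "breslow")
    score_stat <- drop(sc$grad^2 / sc$info)
    lr <- logrank_test(rec[rec$diet == "AL", ], rec[rec$diet == "DR", ])
    expect_equal(score_stat, lr$statistic, tolerance = 1e-8)
  }
})

test_that("loglik >= loglik_null and concavity along a line through the MLE", {
  rec <- simulate_lifespans(small_design(flies_per_cell = 25L, seed = 6L))
  fit <- cox_fit(rec, c("genotype", "sex"))
  expect_gte(fit$loglik, fit$loglik_null)
  dir <- c(1, -0.5)
  ll <- vapply(seq(-1, 1, length.out = 9), function(s) {
    cox_loglik(rec, c("genotype", "sex"), beta = fit$beta + s * dir)$loglik
  }, numeric(1))
  expect_true(all(diff(ll[1:5]) > 0))
  expect_true(all(diff(ll[5:9]) < 0))
  expect_true(all(diff(ll, differences = 2) < 0))  # concave along the line
})

test_that("reference-level choice changes coding, not the maximum", {
  rec <- simulate_lifespans(small_design(flies_per_cell = 20L, seed = 12L))
  f1 <- cox_fit(rec, c("genotype", "sex"))
  f2 <- cox_fit(rec, c("genotype", "sex"),
                reference = list(genotype = "gB", sex = "M"))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(unname(f1$beta["genotype=gB"]),
               -unname(f2$beta["genotype=gA"]), tolerance = 1e-6)
})

test_that("separation is flagged and collinearity raises a named error", {
  # group a always dies before group b: monotone likelihood
  rec <- data.frame(
    time_days = c(1, 2, 3, 10, 11, 12), event = 1,
    grp = rep(c("a", "b"), each = 3)
  )
  fit <- cox_fit(rec, "grp")
  expect_false(fit$converged)
  expect_match(fit$message, "separation|diverging")

  rec2 <- simulate_lifespans(small_design(flies_per_cell = 10L, seed = 5L))
  rec2$dup <- rec2$genotype
  expect_error(cox_fit(rec2, c("genotype", "dup")), "collinear")
  expect_error(cox_fit(rec2[rec2$genotype == "gA", ], "genotype"),
               "fewer than 2")
})
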