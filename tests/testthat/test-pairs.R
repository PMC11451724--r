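test_that("Bonferroni threshold arithmetic and contracts", {
  expect_equal(bonferroni_threshold(0.05, 64), 0.00078125)
  expect_equal(signif(bonferroni_threshold(0.05, 64), 2), 0.00078)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  # monotone decreasing in m
  ms <- c(1, 2, 8, 64, 640)
  expect_true(all(diff(vapply(ms, function(m) bonferroni_threshold(0.05, m),
                              numeric(1))) < 0))
  expect_error(bonferroni_threshold(0.05, 0), "count")
  expect_error(bonferroni_threshold(1.2, 4), "alpha")
})

test_that("pair grid covers the design and identical arms give p = 1", {
  rec <- simulate_lifespans(sim_params(flies_per_cell = 6L, seed = 71L))
  pg <- pair_grid(rec)
  expect_equal(nrow(pg), 64)
  expect_true(all(pg$n_dr > 0 & pg$n_al > 0))

  # a stratum whose DR and AL arms are identical copies
  one <- rec[rec$lab == "Hoffman" & rec$cohort == "1" &
               rec$genotype == "w1118" & rec$sex == "F", ]
  dup <- one[one$diet == "DR", ]
  dup$diet <- "AL"
  pg1 <- pair_grid(rbind(one[one$diet == "DR", ], dup))
  expect_equal(pg1$p_value, 1, tolerance = 1e-12)
  expect_identical(pg1$direction, "none")
  expect_equal(pg1$delta_l, 0)
})

test_that("strata missing an arm are skipped with a warning", {
  rec <- simulate_lifespans(sim_params(flies_per_cell = 5L, seed = 72L))
  drop_one <- rec[!(rec$lab == "Lyu" & rec$cohort == "4" &
                      rec$genotype == "w1118" & rec$sex == "M" &
                      rec$diet == "AL"), ]
  expect_warning(pg <- pair_grid(drop_one), "skipped")
  expect_equal(nrow(pg), 63)
})

test_that("direction calls are antisymmetric under diet relabeling", {
  rec <- simulate_lifespans(sim_params(flies_per_cell = 12L, seed = 73L))
  pg <- pair_grid(rec)
  swapped <- rec
  swapped$diet <- ifelse(rec$diet == "DR", "AL", "DR")
  pg2 <- pair_grid(swapped)
  expect_equal(pg$p_value, pg2$p_value, tolerance = 1e-12)
  expect_equal(pg$delta_l, -pg2$delta_l)
  flip <- c(DR = "AL", AL = "DR", none = "none")
  expect_identical(unname(flip[pg$direction]), pg2$direction)
})

test_that("delta_l sign agrees with direction", {
  rec <- simulate_lifespans(sim_params(flies_per_cell = 12L, seed = 74L))
  pg <- pair_grid(rec)
  has_dir <- pg$direction != "none" & pg$delta_l != 0
  expect_true(all(pg$delta_l[pg$direction == "DR" & has_dir] >= 0))
  expect_true(all(pg$delta_l[pg$direction == "AL" & has_dir] <= 0))
})

test_that("summary counting is a pure function of (p, direction)", {
  fx <- table3_fixture()
  s <- summarize_pairs(fx)
  expect_equal(s$n_pairs, 64)
  expect_equal(s$bonferroni_threshold, 0.05 / 64)
  # rollups sum to the global counts
  for (r in s$rollups) {
    expect_equal(sum(r$dr), s$n_significant_dr)
    expect_equal(sum(r$al), s$n_significant_al)
  }
  expect_lte(s$n_significant_dr + s$n_significant_al, s$n_pairs)
  s2 <- summarize_pairs(fx)
  expect_identical(s, s2)
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  expect_equal(cross_lab_correlation(1:10, 1:10)$rho, 1)
  expect_equal(cross_lab_correlation(1:10, 10:1)$rho, -1)
  expect_equal(cross_lab_correlation(1:10, 1:10)$p_value, 0)
  # 10-pair fixture with two ties
  x <- c(53.1, 55.0, 48.2, 48.2, 60.1, 44.9, 51.3, 51.3, 58.8, 49.5)
  y <- c(52.0, 56.3, 47.1, 50.0, 58.4, 46.2, 50.9, 53.3, 57.0, 47.1)
  cr <- cross_lab_correlation(x, y)
  expect_equal(cr$rho, oracle_spearman(x, y), tolerance = 1e-12)
  expect_equal(cr$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(cr$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_error(cross_lab_correlation(rep(1, 5), 1:5), "constant")
  expect_error(cross_lab_correlation(1:2, 2:1), "3 matched")
})

test_that("delta correlation: duplicates give rho 1, shared effects agree", {
  rec <- simulate_lifespans(sim_params(flies_per_cell = 12L, seed = 75L))
  pg <- pair_grid(rec)
  a <- pg[pg$lab == "Hoffman", ]
  b <- a
  expect_equal(delta_correlation(a, b)$rho, 1)
  # unmatched strata dropped with warning
  expect_warning(dc <- delta_correlation(a[-1, ], a), "unmatched")
  expect_equal(dc$n, 31)
})

test_that("null diet effect is not spuriously shared across labs", {
  # independent per-lab noise: delta-L correlation centred at 0
  rhos <- vapply(1:40, function(s) {
    rec <- simulate_lifespans(sim_params(
      flies_per_cell = 12L, seed = 900 + s,
      beta = list(), cohort_frailty_sd = 0.2
    ))
    pg <- pair_grid(rec)
    delta_correlation(pg[pg$lab == "Hoffman", ],
                      pg[pg$lab == "Lyu", ])$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.12)
})
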