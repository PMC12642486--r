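# organismal-assay statistics against hand-worked and textbook oracles

test_that("climbing index arithmetic and invariances", {
  one <- climbing_index(data.frame(n_flies = 20, n_crossed = 15))
  expect_equal(one$summary$mean_pct, 75)

  two <- climbing_index(data.frame(n_flies = c(20, 20), n_crossed = c(20, 0)))
  expect_equal(two$summary$mean_pct, 50)
  expect_equal(two$summary$sd_pct, sd(c(100, 0)))   # ~70.71

  all_cross <- climbing_index(data.frame(n_flies = c(10, 10),
                                         n_crossed = c(10, 10)))
  expect_equal(all_cross$summary$mean_pct, 100)
  expect_equal(all_cross$summary$sd_pct, 0)

  expect_error(climbing_index(data.frame(n_flies = numeric(0),
                                         n_crossed = numeric(0))), "empty")
  expect_error(climbing_index(data.frame(n_flies = 10, n_crossed = 11)),
               "n_crossed")

  # permutation invariance over vials and [0, 100] bounds
  set.seed(8)
  df <- data.frame(n_flies = rep(20, 6), n_crossed = sample(0:20, 6))
  a <- climbing_index(df)$summary
  b <- climbing_index(df[sample(6), , drop = FALSE])$summary
  expect_equal(a$mean_pct, b$mean_pct)
  expect_equal(a$sd_pct, b$sd_pct)
  expect_true(all(climbing_index(df)$per_vial$pct >= 0 &
                  climbing_index(df)$per_vial$pct <= 100))
})

test_that("Welch test: worked example, invariances, oracle agreement", {
  r <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.0213, tolerance = 1e-2)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  shifted <- welch_t_test(c(1, 2, 3) + 100, c(4, 5, 6) + 100)
  expect_equal(shifted$statistic, r$statistic)

  expect_error(welch_t_test(1, c(1, 2)), "n >= 2")

  set.seed(9)
  for (i in 1:50) {
    a <- rnorm(sample(3:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1))
    got <- welch_t_test(a, b)
    ref <- oracle_welch(a, b)
    expect_equal(got$statistic, ref$t, tolerance = 1e-10)
    expect_equal(got$df, ref$df, tolerance = 1e-10)
    expect_equal(got$p_value, ref$p, tolerance = 1e-10)
  }
})

test_that("Kaplan-Meier equals the empirical survivor function (no censoring)", {
  km <- kaplan_meier(data.frame(time_days = 1:4, event = 1))
  expect_equal(km_survival_at(km, 2), 0.5)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))

  set.seed(10)
  t_i <- sample(1:40, 60, replace = TRUE)
  km2 <- kaplan_meier(data.frame(time_days = t_i, event = 1))
  for (d in unique(t_i))
    expect_equal(km_survival_at(km2, d), mean(t_i > d))
})

test_that("Kaplan-Meier matches the hand product-limit under censoring", {
  rec <- data.frame(time_days = c(1, 2, 3), event = c(1, 0, 1))
  km <- kaplan_meier(rec)
  # S(1) = 2/3; censoring at 2; S(3) = 2/3 * (1 - 1/1) = 0
  expect_equal(km_survival_at(km, c(1, 2, 2.5, 3)), c(2/3, 2/3, 2/3, 0))

  set.seed(11)
  t_i <- sample(1:30, 80, replace = TRUE)
  e_i <- rbinom(80, 1, 0.8)
  km2 <- kaplan_meier(data.frame(time_days = t_i, event = e_i))
  ref <- oracle_km(t_i, e_i)
  expect_equal(km_survival_at(km2, ref$time), ref$surv, tolerance = 1e-12)
})

test_that("log-rank: symmetry, hand-worked table, label invariance", {
  a <- data.frame(time_days = c(3, 5, 8, 10), event = 1)
  expect_equal(logrank_test(a, a)$statistic, 0, tolerance = 1e-12)
  expect_equal(logrank_test(a, a)$p_value, 1, tolerance = 1e-12)

  b <- data.frame(time_days = c(1, 2), event = 1)
  c2 <- data.frame(time_days = c(3, 4), event = 1)
  got <- logrank_test(b, c2)
  ref <- oracle_logrank(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(got$statistic, ref$chisq, tolerance = 1e-10)
  expect_equal(got$p_value, ref$p, tolerance = 1e-10)
  expect_equal(logrank_test(c2, b)$statistic, got$statistic,
               tolerance = 1e-12)

  set.seed(12)
  g1 <- data.frame(time_days = sample(1:30, 40, TRUE),
                   event = rbinom(40, 1, 0.9))
  g2 <- data.frame(time_days = sample(1:40, 35, TRUE),
                   event = rbinom(35, 1, 0.9))
  got2 <- logrank_test(g1, g2)
  ref2 <- oracle_logrank(g1$time_days, g1$event, g2$time_days, g2$event)
  expect_equal(got2$statistic, ref2$chisq, tolerance = 1e-8)

  nothing <- data.frame(time_days = c(2, 3), event = 0)
  expect_error(logrank_test(nothing, nothing), "no events")
})

test_that("significance stars follow the conventional thresholds", {
  expect_identical(signif_stars(c(0.02, 5e-4, 0.2, 5e-3, 5e-5)),
                   c("*", "***", "ns", "**", "****"))
})

test_that("cohort simulation is seeded, structured, and effect-faithful", {
  cfg <- cohort_config(list(wt = list(n = 40), mut = list(n = 40,
                                                          lifespan_scale = 0.8,
                                                          eda_um2 = 5.5e3)),
                       seed = 21)
  coh1 <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh1, coh2)
  expect_equal(nrow(coh1$survival), 80)
  expect_true(all(coh1$survival$time_days > 0))
  expect_true(all(coh1$climbing$n_crossed <= coh1$climbing$n_flies))
  expect_true(all(coh1$cardiac$esa_um2 <= coh1$cardiac$eda_um2))
  expect_true(all(coh1$cardiac$fs_percent >= 0 &
                  coh1$cardiac$fs_percent < 100))
  expect_error(cohort_config(list(wt = list(nonsense = 1))), "unknown")
})

test_that("group summary: SD of identical values, stars, and detection power", {
  same <- data.frame(group = "g", eda_um2 = rep(5000, 4))
  gs <- group_summary(same, params = "eda_um2")
  expect_equal(gs$summary$sd, 0)
  expect_null(gs$tests)

  # a 25% EDA deficit at n = 30/group is detected in most replicates
  hits <- 0
  for (seed in 1:20) {
    cfg <- cohort_config(list(wt = list(n = 30),
                              mut = list(n = 30, eda_um2 = 0.75 * 7.7e3)),
                         seed = seed)
    card <- simulate_cohort(cfg)$cardiac
    gs <- group_summary(card, params = "eda_um2")
    row <- gs$tests[gs$tests$parameter == "eda_um2", ]
    mut_lower <- gs$summary$mean[gs$summary$group == "mut"] <
      gs$summary$mean[gs$summary$group == "wt"]
    if (row$p_value < 0.05 && mut_lower) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.8)
})

test_that("assay CSV readers validate their schemas", {
  sp <- tempfile(fileext = ".csv")
  write.csv(data.frame(fly_id = "a1", group = "wt", time_days = 10,
                       event = "died"), sp, row.names = FALSE)
  df <- read_survival_csv(sp)
  expect_identical(df$event, 1L)
  write.csv(data.frame(x = 1), sp, row.names = FALSE)
  expect_error(read_survival_csv(sp), "columns")

  cp <- tempfile(fileext = ".csv")
  write.csv(data.frame(vial_id = "v1", group = "wt", n_flies = 20,
                       n_crossed = 12), cp, row.names = FALSE)
  expect_equal(read_climbing_csv(cp)$n_crossed, 12)
  write.csv(data.frame(x = 1), cp, row.names = FALSE)
  expect_error(read_climbing_csv(cp), "columns")
})
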