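# Monte Carlo mapped power and the traditional two-group power calculation.

test_that("two-sample power equals alpha at zero effect and is consistent", {
  expect_equal(ttest_power(0, mean = 27, sd = 8, n_per_group = 15), 0.05,
               tolerance = 1e-10)
  # minimum detectable effect shrinks with n
  e15 <- ttest_power_min_effect(27, 8, 15)
  e100 <- ttest_power_min_effect(27, 8, 100)
  e1e5 <- ttest_power_min_effect(27, 8, 1e5)
  expect_gt(e15, e100)
  expect_gt(e100, e1e5)
  expect_lt(e1e5, 0.01)
  expect_equal(ttest_power(e15, 27, 8, 15), 0.8, tolerance = 1e-6)
  expect_error(ttest_power_min_effect(27, 8, 15, power = 0.04), "power")
})

test_that("analytic power matches a Monte Carlo t-test oracle", {
  mean0 <- 27; sd0 <- 8; n <- 15; eff <- 0.5
  set.seed(77)
  B <- 1e5
  x <- matrix(rnorm(B * n, mean0, sd0), B)
  y <- matrix(rnorm(B * n, mean0 * (1 + eff), sd0 * (1 + eff)), B)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, var) / n; vy <- apply(y, 1, var) / n
  tt <- (my - mx) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (n - 1) + vy^2 / (n - 1))
  rej <- abs(tt) > qt(0.975, df)
  expect_equal(ttest_power(eff, mean0, sd0, n), mean(rej), tolerance = 0.01)
})

test_that("mapped power: additivity, group dominance and calibration", {
  m <- mcmp_power(pq_model(), effect_sizes = 0.35, include_null = TRUE,
                  n_per_effect = 40, group_size = 15, n_boot = 2000,
                  seed = 5, control = fast_control(iter_max = 40))
  cv <- m$curve
  # per-patient contributions sum exactly to the full-data LRT
  expect_equal(cv$sum_diofv, cv$lrt_full_data, tolerance = 1e-6)
  # informative (fed) patients carry the covariate signal
  di <- m$diofv[m$diofv$effect == 0.35, ]
  expect_gt(mean(di$diofv[di$food == 1]), mean(di$diofv[di$food == 0]))
  # the estimated food effect tracks the simulated one
  expect_equal(cv$theta_hat[cv$effect == 0.35], 0.35, tolerance = 0.5)
  # fasting patients are untouched by profiling the food effect
  expect_lt(max(abs(di$diofv[di$food == 0])), 1e-4)
  # the covariate signal raises power above the null cohort's
  expect_gte(cv$power_05[cv$effect == 0.35], cv$power_05[cv$effect == 0])
  expect_true(all(cv$power_01 <= cv$power_05))
})

test_that("bootstrap at full cohort size approaches the full-data LRT", {
  m <- mcmp_power(pq_model(), effect_sizes = 0.4, include_null = FALSE,
                  n_per_effect = 40, group_size = 20, n_boot = 500,
                  seed = 6, control = fast_control(iter_max = 40))
  # resampling the whole cohort: power concentrates on the indicator of
  # the full-data likelihood-ratio statistic
  lrt <- m$curve$lrt_full_data
  p <- m$curve$power_05
  if (lrt > 3.84 * 2) expect_gt(p, 0.8) else expect_lt(p, 0.9)
})

test_that("effect sizes outside (0, 1) are rejected", {
  expect_error(mcmp_power(pq_model(), effect_sizes = c(0.5, 1.2)), "effect")
  expect_error(mcmp_power(pq_model(), effect_sizes = 0.3,
                          n_per_effect = 41), "even")
})
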