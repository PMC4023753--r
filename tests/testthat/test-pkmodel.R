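# Structural model: transit kinetics, covariate construction, profile
# solution and derived quantities.

test_that("transit rate follows MTT = (n + 1)/ktr and validates input", {
  expect_equal(transit_rate(2.04, 3), 4 / 2.04, tolerance = 1e-12)
  expect_equal(transit_rate(1, 0), 1)
  expect_error(transit_rate(0, 3), "positive")
  expect_error(transit_rate(2, -1), "integer")
})

test_that("mean arrival time through the transit chain equals MTT", {
  # Monte Carlo: sum of (n + 1) exponential waits at rate ktr
  set.seed(1)
  ktr <- transit_rate(2.04, 3)
  waits <- matrix(rexp(4 * 1e6, rate = ktr), ncol = 4)
  expect_equal(mean(rowSums(waits)), 2.04, tolerance = 0.005)
})

test_that("CV transform and its inverse round-trip", {
  expect_equal(cv_percent(0), 0)
  expect_equal(omega2_from_cv(48.8), log(1 + 0.488^2), tolerance = 1e-12)
  x <- c(0.5, 5, 30.7, 48.8, 120, 200)
  expect_equal(cv_percent(omega2_from_cv(x)), x, tolerance = 1e-10)
  expect_error(cv_percent(-0.1), "non-negative")
})

test_that("individual parameters reduce to typical values at reference", {
  typ <- pq_params()
  cm <- pq_covmodel()
  ip <- individual_params(typ, cm, list(weight = 52, age = 33, food = 0),
                          occasion = 1)
  expect_equal(unclass(ip)[1:7], unclass(typ)[1:7], tolerance = 1e-12)
  expect_equal(ip$F, 1)
})

test_that("dose-occasion and age effects apply linearly", {
  typ <- pq_params()
  cm <- pq_covmodel(theta_dose_F = 0.253, theta_age_Vp1 = 0.0410)
  ip3 <- individual_params(typ, cm, list(weight = 52, age = 33, food = 0),
                           occasion = 3)
  expect_equal(ip3$F, 1 + 0.253 * 2, tolerance = 1e-12)
  ip_age <- individual_params(typ, cm, list(weight = 52, age = 43, food = 0),
                              occasion = 1)
  expect_equal(ip_age$Vp1 / typ$Vp1, 1.41, tolerance = 1e-12)
  # allometry: clearances with exponent 3/4, volumes with 1
  ip_wt <- individual_params(typ, cm, list(weight = 65, age = 33, food = 0),
                             occasion = 1)
  expect_equal(ip_wt$CL / typ$CL, (65 / 52)^0.75)
  expect_equal(ip_wt$Vc / typ$Vc, 65 / 52)
  expect_error(individual_params(typ, pq_covmodel(theta_age_Vp1 = -0.2),
                                 list(weight = 52, age = 60, food = 0)),
               "non-positive")
})

test_that("profile is zero without dose mass and linear in dose", {
  p <- pq_params()
  tt <- c(1, 6, 24, 100, 500)
  d0 <- data.frame(time = c(0, 24, 48), amt = 0)
  expect_equal(solve_profile(p, d0, tt), rep(0, 5))
  d1 <- data.frame(time = c(0, 24, 48), amt = 554)
  d2 <- data.frame(time = c(0, 24, 48), amt = 1108)
  expect_equal(solve_profile(p, d2, tt), 2 * solve_profile(p, d1, tt),
               tolerance = 1e-12)
  expect_error(solve_profile(p, d1, c(5, 1)), "sorted")
  expect_error(solve_profile(p, data.frame(time = 0, amt = -1), tt),
               "non-negative")
})

test_that("analytic solution matches the stiff ODE oracle on the regimen", {
  p <- pq_params()
  d <- data.frame(time = c(0, 24, 48), amt = 960 * 0.577)
  tt <- c(0.5, 1, 2, 3, 4, 7, 24, 25, 31, 49, 52, 60, 96, 168, 672, 3024)
  ca <- solve_profile(p, d, tt)
  expect_equal(ca, ode_profile(p, d, tt), tolerance = 1e-6)
  # and the matrix-exponential path agrees with the analytic path
  expect_equal(solve_profile(p, d, tt, method = "matexp"), ca,
               tolerance = 1e-9)
})

test_that("profile solution agrees with the ODE oracle on random models", {
  set.seed(99)
  for (r in 1:25) {
    p <- random_params()
    d <- data.frame(time = c(0, 24, 48), amt = runif(3, 100, 1000))
    tt <- sort(runif(12, 0.1, 1500))
    expect_equal(solve_profile(p, d, tt), ode_profile(p, d, tt),
                 tolerance = 1e-6)
  }
})

test_that("mass is conserved and concentrations vanish at long times", {
  set.seed(5)
  p <- pq_params()
  d <- data.frame(time = c(0, 24, 48), amt = c(500, 600, 700))
  tt <- c(1, 23, 47, 100, 1000, 5000)
  st <- solve_amounts(p, d, tt)
  given <- vapply(tt, function(t) sum(d$amt[d$time < t]), 0)
  expect_equal(rowSums(st), given, tolerance = 1e-8)
  expect_true(all(st >= -1e-10))
  conc <- solve_profile(p, d, c(10, 5e4))
  expect_true(all(conc >= 0))
  expect_lt(conc[2] / conc[1], 1e-6)
})

test_that("terminal half-life matches the reported value and its limits", {
  p <- pq_params()
  t12 <- terminal_halflife(p)
  expect_equal(t12, 19.5, tolerance = 0.02)
  # smallest-magnitude eigenvalue near the characteristic-polynomial root
  expect_equal(log(2) / (t12 * 24), 0.001475, tolerance = 1e-3)
  # one-compartment limit
  p1 <- pq_params(Q1 = 0, Q2 = 0)
  expect_equal(terminal_halflife(p1), log(2) * p1$Vc / p1$CL / 24,
               tolerance = 1e-8)
  # invariance under F rescaling: apparent parameterization scales all
  # clearances and volumes together
  sc <- 1.7
  p2 <- pq_params(CL = p$CL * sc, Vc = p$Vc * sc, Q1 = p$Q1 * sc,
                  Vp1 = p$Vp1 * sc, Q2 = p$Q2 * sc, Vp2 = p$Vp2 * sc)
  expect_equal(terminal_halflife(p2), t12, tolerance = 1e-10)
})

test_that("log-linear regression on the terminal tail recovers lambda_z", {
  p <- pq_params()
  d <- data.frame(time = c(0, 24, 48), amt = 554)
  tt <- seq(60 * 24, 138 * 24, by = 24)
  conc <- solve_profile(p, d, tt)
  slope <- -coef(lm(log(conc) ~ tt))[[2]]
  lz <- log(2) / (terminal_halflife(p) * 24)
  expect_equal(slope, lz, tolerance = 0.01)
})
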