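# FOCE-I engine: closed forms, quadrature oracles, censored records and
# noise-free recovery.

test_that("without random effects the OFV is the closed-form normal -2LL", {
  times <- c(1, 4, 24, 72, 168)
  set.seed(2)
  sigma <- 0.2
  f <- toy_pred_log(0, times)
  dv <- exp(f + rnorm(5, 0, sigma))
  dat <- toy_dataset(times, dv)
  spec <- toy_spec(omega2 = c(CL = 0), sigma = sigma)
  got <- focei_ofv(dat, spec)
  expect_equal(got$ofv,
               sum(log(2 * pi * sigma^2) + (log(dv) - f)^2 / sigma^2),
               tolerance = 1e-8)
})

test_that("FOCE-I matches adaptive quadrature on a one-eta subject", {
  times <- c(1, 4, 24, 72, 168)
  omega2 <- 0.09
  sigma <- 0.15
  set.seed(3)
  eta_true <- rnorm(1, 0, sqrt(omega2))
  dv <- exp(toy_pred_log(eta_true, times) + rnorm(5, 0, sigma))
  dat <- toy_dataset(times, dv)
  got <- focei_ofv(dat, toy_spec(omega2 = c(CL = omega2), sigma = sigma))
  lik <- function(etas) vapply(etas, function(e) {
    f <- toy_pred_log(e, times)
    prod(dnorm(log(dv), f, sigma)) * dnorm(e, 0, sqrt(omega2))
  }, 0)
  oracle <- -2 * log(integrate(lik, -2, 2, rel.tol = 1e-10)$value)
  expect_equal(got$ofv, oracle, tolerance = 0.1 / abs(oracle))
})

test_that("a subject without observations contributes nothing", {
  times <- c(1, 4, 24)
  set.seed(4)
  dv <- exp(toy_pred_log(0, times) + rnorm(3, 0, 0.15))
  dat <- toy_dataset(times, dv)
  spec <- toy_spec()
  base <- focei_ofv(dat, spec)
  empty <- dat[dat$EVID == 1L, ]
  empty$ID <- 2L
  dat2 <- rbind(dat, empty)
  class(dat2) <- class(dat)
  got <- focei_ofv(dat2, spec)
  expect_equal(got$ofv, base$ofv, tolerance = 1e-10)
  expect_equal(unname(got$iofv["2"]), 0, tolerance = 1e-10)
})

test_that("censored-record contribution has the stated closed forms", {
  expect_equal(m3_contribution(log(1.2), 0.3, 1.2), -2 * log(0.5),
               tolerance = 1e-12)
  expect_lt(m3_contribution(log(1.2) - 8, 0.3, 1.2), 1e-6)
  expect_error(m3_contribution(0, -1, 1.2), "positive")
  expect_error(m3_contribution(0, 0.3, 0), "positive")
})

test_that("M3 likelihood matches quadrature on a censored one-eta subject", {
  times <- c(1, 4, 24, 72, 168, 1680, 2352, 3024)
  omega2 <- 0.09
  sigma <- 0.3
  lloq <- 1.2
  set.seed(5)
  eta_true <- rnorm(1, 0, sqrt(omega2))
  dv <- exp(toy_pred_log(eta_true, times) + rnorm(length(times), 0, sigma))
  blq <- as.integer(dv < lloq)
  expect_gt(sum(blq), 0)  # late samples censor under these parameters
  dv[blq == 1] <- NA
  dat <- toy_dataset(times, dv, blq)
  got <- focei_ofv(dat, toy_spec(omega2 = c(CL = omega2), sigma = sigma,
                                 blq = "m3"))
  lik <- function(etas) vapply(etas, function(e) {
    f <- toy_pred_log(e, times)
    dens <- ifelse(blq == 1, pnorm((log(lloq) - f) / sigma),
                   dnorm(log(dv), f, sigma))
    prod(dens) * dnorm(e, 0, sqrt(omega2))
  }, 0)
  oracle <- -2 * log(integrate(lik, -2, 2, rel.tol = 1e-10)$value)
  expect_equal(got$ofv, oracle, tolerance = 0.1 / abs(oracle))
  # omitting instead of integrating censored rows changes the OFV
  got_omit <- focei_ofv(dat, toy_spec(omega2 = c(CL = omega2),
                                      sigma = sigma, blq = "omit"))
  expect_false(isTRUE(all.equal(got$ofv, got_omit$ofv)))
})

test_that("OFV is additive over subjects and inner modes converge", {
  st <- sim_study(n_fed = 4, n_fasting = 4, seed = 21)
  r <- focei_ofv(st$dat, pq_model())
  expect_equal(r$ofv, sum(r$iofv), tolerance = 1e-6)
  expect_true(all(r$converged))
})

test_that("noise-free data return the generating typical values", {
  des <- pq_design(n_fed = 3, n_fasting = 3)
  pop <- sample_population(des, seed = 31)
  gen <- pq_model(omega2 = c(CL = 0), sigma = 1e-3, estim_sigma = FALSE)
  dat <- simulate_dataset(pop, gen, seed = 31, design = des)
  inits <- list(theta = gen$theta[1:7] * exp(c(0.1, -0.1, 0.08, -0.08,
                                               0.1, -0.1, 0.05)),
                dose_slope = 0.2)
  ft <- pq_fit(dat, gen, inits = inits,
               control = pq_control(rel_tol = 1e-9, iter_max = 400,
                                    eval_max = 2000))
  est <- coef(ft)
  for (nm in c("CL", "Vc", "Q1", "Vp1", "Q2", "Vp2", "MTT"))
    expect_equal(est[[nm]], gen$theta[[nm]], tolerance = 1e-3)
  expect_equal(est[["dose_slope"]], 0.253, tolerance = 5e-3)
})

test_that("adding a parameter never worsens the minimised OFV", {
  st <- sim_study(n_fed = 4, n_fasting = 4, seed = 22)
  spec0 <- pq_model()
  f0 <- pq_fit(st$dat, spec0, control = fast_control(iter_max = 60))
  spec1 <- pq_add_relation(f0$spec, "F", "FOOD", "linear", ref = 0)
  f1 <- pq_fit(st$dat, spec1, control = fast_control(iter_max = 60))
  expect_lte(f1$ofv, f0$ofv + 0.01)
})
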