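# Study-design emulation: demographics, dosing, schedule, censoring and
# the exchange CSV dialect.

test_that("population sampling is reproducible and respects the design", {
  p1 <- sample_population(pq_design(), seed = 3)
  p2 <- sample_population(pq_design(), seed = 3)
  expect_identical(p1, p2)
  expect_error(sample_population(pq_design(n_fed = 0, n_fasting = 0)),
               "empty")
  # enlarging the cohort never perturbs existing subjects
  big <- sample_population(pq_design(n_fed = 20, n_fasting = 20), seed = 3)
  expect_equal(p1$wt[p1$food == 1], big$wt[big$food == 1][1:15])
})

test_that("covariates stay in the published ranges and dose matches", {
  pop <- sample_population(pq_design(n_fed = 5000, n_fasting = 5000),
                           seed = 10)
  expect_true(all(pop$wt >= 39 & pop$wt <= 73))
  expect_true(all(pop$age >= 18 & pop$age <= 55))
  dose_kg <- pop$dose_mg / pop$wt
  expect_gt(median(dose_kg), 17.0)
  expect_lt(median(dose_kg), 18.0)
  expect_true(all(dose_kg > 15.5 & dose_kg < 19.5))
})

test_that("a 53.33 kg subject receives exactly three tablets daily", {
  des <- pq_design()
  tabs <- floor(53.33 * 3 * des$target_dose / des$tablet_mg + 0.25) / 3
  expect_equal(tabs, 3)
  expect_equal(tabs * des$tablet_mg / 53.33, 18.0, tolerance = 1e-3)
})

test_that("the schedule has 22 dosing-phase and 13 follow-up samples", {
  tt <- pq_schedule(pq_design())
  expect_equal(length(tt), 35)
  expect_equal(sum(tt <= 60), 22)
  expect_equal(sum(tt > 60), 13)
  expect_false(is.unsorted(tt, strictly = TRUE))
})

test_that("zero variability reproduces the deterministic profile", {
  des <- pq_design(n_fed = 1, n_fasting = 1)
  pop <- sample_population(des, seed = 4)
  spec <- pq_model(omega2 = c(CL = 0), sigma = 1e-12)
  dat <- simulate_dataset(pop, spec, seed = 4, design = des)
  s <- pop[1, ]
  obs <- dat[dat$ID == s$id & dat$EVID == 0 & dat$TIME > 0, ]
  p <- pq_params(F = 1 + spec$dose_slope * (0:2))
  p$MTT <- rep(p$MTT, 3)
  ip <- individual_params(pq_params(), pq_covmodel(theta_dose_F = 0),
                          list(weight = s$wt, age = s$age, food = s$food))
  ref <- pq_params(CL = ip$CL, Vc = ip$Vc, Q1 = ip$Q1, Vp1 = ip$Vp1,
                   Q2 = ip$Q2, Vp2 = ip$Vp2, MTT = rep(ip$MTT, 3),
                   F = ip$F * (1 + spec$dose_slope * (0:2)))
  doses <- data.frame(time = c(0, 24, 48), amt = s$dose_mg * 0.577,
                      occasion = 1:3)
  conc <- solve_profile(ref, doses, obs$TIME)
  got <- ifelse(obs$BLQ == 1, NA, obs$DV)
  keep <- !is.na(got)
  expect_equal(got[keep], conc[keep], tolerance = 1e-6)
})

test_that("residual noise alone reproduces the stated CV", {
  # many replicates of a single time point, all etas zero
  des <- pq_design(n_fed = 400, n_fasting = 0)
  des$sampling_offsets <- list(c(4), numeric(0), numeric(0))
  des$followup_days <- numeric(0)
  cd <- pq_covdist(weight = list(fed = c(51.99, 52, 52.01),
                                 fasting = c(51.99, 52, 52.01)),
                   age = list(fed = c(32.9, 33, 33.1),
                              fasting = c(32.9, 33, 33.1)))
  pop <- sample_population(des, cd, seed = 6)
  spec <- pq_model(omega2 = c(CL = 0))  # all random effects off
  dat <- simulate_dataset(pop, spec, seed = 6, design = des)
  conc <- dat$DV[dat$EVID == 0 & dat$TIME == 4]
  expect_equal(100 * sd(conc) / mean(conc), 30.7, tolerance = 0.12)
})

test_that("BLQ records concentrate in the late terminal phase", {
  st <- sim_study(n_fed = 15, n_fasting = 15, seed = 8)
  obs <- st$dat[st$dat$EVID == 0 & st$dat$TIME > 0, ]
  frac_blq <- mean(obs$BLQ)
  expect_gt(frac_blq, 0.03)
  expect_lt(frac_blq, 0.2)
  late <- obs$TIME[obs$BLQ == 1] > 70 * 24
  expect_gt(mean(late), 0.5)
  # BLQ only when the (withheld) concentration fell below the limit
  expect_true(all(is.na(obs$DV[obs$BLQ == 1])))
  expect_true(all(obs$DV[obs$BLQ == 0] >= st$design$lloq))
})

test_that("dataset invariants hold and the CSV dialect round-trips", {
  st <- sim_study(n_fed = 3, n_fasting = 3, seed = 9)
  dat <- st$dat
  obs <- dat[dat$EVID == 0, ]
  expect_true(all(xor(is.na(obs$DV), obs$BLQ == 0)))
  # dose rows precede the observations they affect
  for (id in unique(dat$ID)) {
    d <- dat[dat$ID == id, ]
    first_obs_after <- which(d$EVID == 0 & d$TIME > 0)[1]
    expect_true(any(d$EVID[seq_len(first_obs_after)] == 1))
  }
  # occasions consistent with dose times
  expect_true(all(obs$OCC == pmax(1, findInterval(obs$TIME, c(0, 24, 48),
                                                  left.open = TRUE))))
  path <- tempfile(fileext = ".csv")
  write_pkdata(dat, path)
  back <- read_pkdata(path)
  expect_equal(back$DV, dat$DV, tolerance = 1e-5)
  expect_identical(back$BLQ, dat$BLQ)
  expect_identical(back$ID, dat$ID)
  expect_equal(back$TIME, dat$TIME, tolerance = 1e-9)
})

test_that("fed and fasting arms are exchangeable without food effects", {
  # same demographics in both arms, no food terms in the model: flipping
  # the food flag must not change a subject's simulated data
  des <- pq_design(n_fed = 4, n_fasting = 0)
  cd <- pq_covdist(weight = list(fed = c(45, 52, 60),
                                 fasting = c(45, 52, 60)),
                   age = list(fed = c(20, 33, 50),
                              fasting = c(20, 33, 50)))
  pop <- sample_population(des, cd, seed = 12)
  d1 <- simulate_dataset(pop, pq_model(), seed = 12)
  pop$food <- 0L
  d2 <- simulate_dataset(pop, pq_model(), seed = 12)
  expect_equal(d1$DV, d2$DV)
})
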