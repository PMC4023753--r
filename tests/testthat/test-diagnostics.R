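# Model evaluation: VPC, bootstrap and post hoc secondary parameters.

test_that("VPC is deterministic given a seed and its bands are ordered", {
  st <- sim_study(n_fed = 4, n_fasting = 4, seed = 41)
  v1 <- vpc(st$spec, st$dat, n_sim = 60, seed = 2)
  v2 <- vpc(st$spec, st$dat, n_sim = 60, seed = 2)
  expect_identical(v1$bins, v2$bins)
  b <- v1$bins
  expect_true(all(b$p5_lo <= b$p5_hi + 1e-12, na.rm = TRUE))
  expect_true(all(b$p5_med <= b$p50_med + 1e-9, na.rm = TRUE))
  expect_true(all(b$p50_med <= b$p95_med + 1e-9, na.rm = TRUE))
  expect_true(all(v1$coverage$observed >= 0 & v1$coverage$observed <= 100))
})

test_that("VPC self-calibrates on data simulated from the same model", {
  st <- sim_study(n_fed = 15, n_fasting = 15, seed = 43)
  v <- vpc(st$spec, st$dat, n_sim = 300, seed = 3)
  # about 5% of observations on each side of the 90% PI; wide a priori
  # bounds reflect between-subject correlation of the outside counts
  expect_gt(v$coverage$observed[1], 1)
  expect_lt(v$coverage$observed[1], 10)
  expect_gt(v$coverage$observed[2], 1)
  expect_lt(v$coverage$observed[2], 10)
})

test_that("stratified bootstrap keeps arm sizes and reports intervals", {
  st <- sim_study(n_fed = 4, n_fasting = 4, seed = 44)
  # fixed model: replicates differ only through resampling
  spec <- st$spec
  spec$estim_theta[] <- FALSE
  spec$estim_dose_slope <- FALSE
  spec$estim_omega2[] <- FALSE
  spec$estim_sigma <- FALSE
  spec$relations$estim <- FALSE
  spec$estim_theta[c("CL", "Vc")] <- TRUE
  b <- bootstrap_fit(st$dat, spec, n = 8, seed = 1,
                     control = fast_control(iter_max = 30))
  expect_equal(b$n_ok, 8)
  expect_true(all(b$ci[1, ] <= b$ci[2, ] + 1e-12))
  expect_true(all(is.finite(b$rse)))
  lone <- st$dat[st$dat$ID %in% c(unique(st$dat$ID[st$dat$FOOD == 1]),
                                  unique(st$dat$ID[st$dat$FOOD == 0])[1]), ]
  class(lone) <- class(st$dat)
  expect_error(bootstrap_fit(lone, spec, n = 2), "stratum")
})

test_that("resampling identical subjects yields zero-width intervals", {
  st <- sim_study(n_fed = 2, n_fasting = 2, seed = 45)
  # all four subjects byte-identical clones of subject 1
  base <- st$dat[st$dat$ID == 1, ]
  clones <- do.call(rbind, lapply(1:4, function(i) {
    d <- base; d$ID <- i; d$FOOD <- as.integer(i <= 2); d
  }))
  class(clones) <- class(st$dat)
  spec <- st$spec
  spec$estim_theta[] <- FALSE
  spec$estim_dose_slope <- FALSE
  spec$estim_omega2[] <- FALSE
  spec$estim_sigma <- FALSE
  spec$relations$estim <- FALSE
  spec$estim_theta["CL"] <- TRUE
  b <- bootstrap_fit(clones, spec, n = 5, seed = 2,
                     control = fast_control(iter_max = 30))
  expect_lt(diff(range(b$estimates[, "CL"])) / mean(b$estimates[, "CL"]),
            1e-4)
})

test_that("secondary parameters match their oracles", {
  st <- sim_study(n_fed = 8, n_fasting = 8, seed = 46)
  ft <- list(spec = .resolve_refs(st$spec, st$dat), dataset = st$dat,
             ebes = matrix(0, 16, 11,
                           dimnames = list(1:16, NULL)))
  class(ft) <- "pqfit"
  s <- secondary_params(ft, grid_step = 0.02)
  p <- s$params
  expect_true(all(p$cl_f_kg > 0 & p$v_f_kg > 0 & p$t_half_days > 0))
  expect_true(all(p$tmax > 0 & p$tmax < 24))
  # AUC against a fine trapezoid oracle for a typical subject
  i <- which.min(abs(p$wt - median(p$wt)))
  d <- st$dat[st$dat$ID == p$id[i] & st$dat$EVID == 1, ]
  ip <- piperaq:::.indiv_generic(ft$spec, d$WT[1], d$AGE[1], d$SEX[1],
                                 d$FOOD[1], numeric(11))
  pp <- pq_params(CL = ip$CL, Vc = ip$Vc, Q1 = ip$Q1, Vp1 = ip$Vp1,
                  Q2 = ip$Q2, Vp2 = ip$Vp2, MTT = ip$MTT, F = ip$F)
  doses <- data.frame(time = c(0, 24, 48), amt = d$AMT[1] * 0.577,
                      occasion = 1:3)
  tt <- seq(0, 138 * 24, by = 0.5)
  conc <- solve_profile(pp, doses, tt)  # ng/ml
  auc_trap <- sum((conc[-1] + conc[-length(conc)]) / 2 * diff(tt)) / 1000
  expect_equal(p$auc_d138[i], auc_trap, tolerance = 0.1)
  expect_true(all(is.finite(s$tests)))
})

test_that("day-7 level and AUC rank with 1/CL when only CL varies", {
  st <- sim_study(n_fed = 1, n_fasting = 1, seed = 48)
  base <- st$dat[st$dat$ID == 1, ]
  n <- 12
  clones <- do.call(rbind, lapply(seq_len(n), function(i) {
    d <- base; d$ID <- i; d$FOOD <- as.integer(i %% 2); d
  }))
  class(clones) <- class(st$dat)
  eb <- matrix(0, n, 11, dimnames = list(seq_len(n), NULL))
  eb[, 1] <- seq(-0.6, 0.6, length.out = n)  # eta on CL only
  ft <- list(spec = .resolve_refs(st$spec, clones), dataset = clones,
             ebes = eb)
  class(ft) <- "pqfit"
  s <- secondary_params(ft, grid_step = 0.05)
  inv_cl <- 1 / s$params$cl_f_kg
  expect_equal(cor(rank(s$params$auc_d138), rank(inv_cl)), 1)
  expect_equal(cor(rank(s$params$day7), rank(inv_cl)), 1)
})

test_that("typical-cohort Tmax sits in the observed range", {
  st <- sim_study(n_fed = 10, n_fasting = 10, seed = 47)
  ft <- list(spec = .resolve_refs(st$spec, st$dat), dataset = st$dat,
             ebes = matrix(0, 20, 11, dimnames = list(1:20, NULL)))
  class(ft) <- "pqfit"
  s <- secondary_params(ft, grid_step = 0.02)
  expect_gt(median(s$params$tmax), 2.8)
  expect_lt(median(s$params$tmax), 4.4)
})
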