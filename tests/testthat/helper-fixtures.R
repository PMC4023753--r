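# Shared fixtures, built in code at test time.

# small simulated study (default design truncated to n subjects)
sim_study <- function(n_fed = 5, n_fasting = 5, seed = 7, spec = pq_model(),
                      design = pq_design(n_fed = n_fed,
                                         n_fasting = n_fasting)) {
  pop <- sample_population(design, pq_covdist(), seed = seed)
  list(pop = pop,
       dat = simulate_dataset(pop, spec, seed = seed, design = design),
       design = design, spec = spec)
}

# deterministic perturbation of the generating values for refit starts
perturbed_inits <- function(spec, seed = 42, sd_theta = 0.15,
                            sd_omega = 0.3) {
  set.seed(seed)
  list(theta = spec$theta[1:7] * exp(rnorm(7, 0, sd_theta)),
       dose_slope = spec$dose_slope * 1.3,
       omega2 = spec$omega2[spec$omega2 > 0] * exp(rnorm(7, 0, sd_omega)),
       sigma = spec$sigma * 1.15)
}

# deSolve reference solution of the full compartment system (stiff solver)
ode_profile <- function(params, doses, times, ktr_per_dose = NULL) {
  m <- params$n_transit + 1
  Focc <- if (length(params$F) > 1) params$F[doses$occasion] else
    rep(params$F, nrow(doses))
  ktr <- if (!is.null(ktr_per_dose)) ktr_per_dose else
    rep(transit_rate(if (length(params$MTT) > 1) params$MTT[1] else
      params$MTT, params$n_transit), nrow(doses))
  k10 <- params$CL / params$Vc; k12 <- params$Q1 / params$Vc
  k21 <- params$Q1 / params$Vp1; k13 <- params$Q2 / params$Vc
  k31 <- params$Q2 / params$Vp2
  kt <- ktr[1]  # equal-rate chains only
  rhs <- function(t, y, p) {
    dy <- numeric(m + 3)
    dy[1] <- -kt * y[1]
    if (m > 1) for (i in 2:m) dy[i] <- kt * (y[i - 1] - y[i])
    dy[m + 1] <- kt * y[m] - (k10 + k12 + k13) * y[m + 1] +
      k21 * y[m + 2] + k31 * y[m + 3]
    dy[m + 2] <- k12 * y[m + 1] - k21 * y[m + 2]
    dy[m + 3] <- k13 * y[m + 1] - k31 * y[m + 3]
    list(dy)
  }
  y0 <- stats::setNames(numeric(m + 3), paste0("y", seq_len(m + 3)))
  ev <- data.frame(var = "y1", time = doses$time, value = doses$amt * Focc,
                   method = "add")
  tt <- sort(unique(c(0, times, doses$time)))
  out <- deSolve::lsoda(y0, times = tt, func = rhs, parms = NULL,
                        events = list(data = ev), rtol = 1e-11, atol = 1e-12)
  out[match(times, out[, 1]), m + 2] / params$Vc * 1000
}

# random positive parameter set in a physiological neighbourhood
random_params <- function() {
  pq_params(CL = exp(runif(1, log(20), log(200))),
            Vc = exp(runif(1, log(800), log(9000))),
            Q1 = exp(runif(1, log(100), log(1200))),
            Vp1 = exp(runif(1, log(2000), log(20000))),
            Q2 = exp(runif(1, log(30), log(400))),
            Vp2 = exp(runif(1, log(8000), log(70000))),
            MTT = exp(runif(1, log(0.5), log(6))),
            n_transit = sample(0:5, 1))
}

fast_control <- function(...) pq_control(rel_tol = 1e-6, ...)

# a hand-built single-subject dataset on a simplified model (no covariate
# slopes, no dose-occasion effect) so the R-side model mirror is trivial
toy_spec <- function(omega2 = c(CL = 0.09), sigma = 0.15, blq = "omit") {
  pq_model(relations = NULL, dose_slope = 0, estim_dose_slope = FALSE,
           omega2 = omega2, sigma = sigma, blq = blq)
}

toy_dataset <- function(times, dv, blq = rep(0L, length(dv)), wt = 52,
                        age = 33) {
  dose <- data.frame(ID = 1L, TIME = c(0, 24, 48), EVID = 1L, AMT = 960,
                     DV = NA_real_, BLQ = 0L, OCC = 1:3, WT = wt, AGE = age,
                     SEX = 1L, FOOD = 0L)
  obs <- data.frame(ID = 1L, TIME = times, EVID = 0L, AMT = NA_real_,
                    DV = dv, BLQ = blq, OCC = pmax(1, findInterval(
                      times, c(0, 24, 48), left.open = TRUE)),
                    WT = wt, AGE = age, SEX = 1L, FOOD = 0L)
  out <- rbind(dose, obs)
  out <- out[order(out$TIME, -out$EVID), ]
  class(out) <- c("pq_dataset", "data.frame")
  out
}

# deterministic log-prediction under the toy model for a CL deviation,
# through the public profile interface (mirror of the engine's kernel)
toy_pred_log <- function(eta_cl, times, wt = 52) {
  typ <- pq_params()
  ip <- individual_params(typ, pq_covmodel(theta_dose_F = 0,
                                           theta_age_Vp1 = 0),
                          list(weight = wt, age = 33, food = 0),
                          effects = list(eta_bsv = c(CL = eta_cl)))
  doses <- data.frame(time = c(0, 24, 48), amt = 960 * 0.577, occasion = 1:3)
  log(solve_profile(ip, doses, times))
}

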