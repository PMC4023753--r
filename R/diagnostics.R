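# Model evaluation: visual predictive check, stratified nonparametric
# bootstrap, and post hoc secondary parameters with group comparison.

#' Visual predictive check
#'
#' Simulates `n_sim` replicate studies at the original design (same
#' subjects, doses and nominal times), computes the 95% confidence band of
#' the simulated 5th, 50th and 95th percentiles per nominal time bin, and
#' the fractions of observations below/above the simulated 90% prediction
#' interval with percentile confidence intervals.  Binning is by nominal
#' scheduled time (the design is fixed); no smoothing is applied.
#'
#' @param fit a `pqfit`, or a [pq_model()] whose current values are used.
#' @param dataset the observed `pq_dataset` (default: the fitted data).
#' @param n_sim number of simulated replicate studies.
#' @param seed integer seed.
#' @param blq_in_coverage include BLQ records in the coverage counts
#'   (counted at LLOQ/2, simulated values floored likewise)?  Default FALSE.
#' @return Object of class `pq_vpc` with elements `bins` (per-time observed
#'   and simulated percentiles), `coverage` (fractions outside the 90% PI
#'   with 95% CIs) and the call settings.
#' @export
vpc <- function(fit, dataset = NULL, n_sim = 2000, seed = 1,
                blq_in_coverage = FALSE) {
  spec <- if (inherits(fit, "pqfit")) fit$spec else fit
  dataset <- dataset %||% (if (inherits(fit, "pqfit")) fit$dataset else NULL)
  if (is.null(dataset)) stop("a dataset is required")
  obs <- dataset[dataset$EVID == 0L & dataset$TIME > 0, ]
  if (!nrow(obs)) stop("empty dataset")
  lloq <- spec$lloq
  times <- sort(unique(obs$TIME))
  val <- function(dv, blq) {
    v <- ifelse(blq == 1L, lloq / 2, dv)
    if (!blq_in_coverage) v[blq == 1L] <- NA_real_
    v
  }
  yobs <- val(obs$DV, obs$BLQ)
  bin <- match(obs$TIME, times)
  # simulate replicates; store concentrations per replicate
  nsub <- length(unique(dataset$ID))
  sims <- matrix(NA_real_, nrow(obs), n_sim)
  for (r in seq_len(n_sim)) {
    simdat <- .simulate_from_design(dataset, spec, seed + 7919L * r)
    so <- simdat[simdat$EVID == 0L & simdat$TIME > 0, ]
    sims[, r] <- val(so$DV, so$BLQ)
  }
  probs <- c(0.05, 0.5, 0.95)
  obs_pct <- t(vapply(seq_along(times), function(b)
    quantile(yobs[bin == b], probs, na.rm = TRUE, names = FALSE),
    numeric(3)))
  # per-replicate percentiles per bin -> 95% CI of each percentile
  sim_pct <- array(NA_real_, c(length(times), 3, n_sim))
  for (r in seq_len(n_sim))
    sim_pct[, , r] <- t(vapply(seq_along(times), function(b)
      quantile(sims[bin == b, r], probs, na.rm = TRUE, names = FALSE),
      numeric(3)))
  ci <- apply(sim_pct, c(1, 2), quantile, probs = c(0.025, 0.5, 0.975),
              na.rm = TRUE)
  bins <- data.frame(time = times,
                     obs_p5 = obs_pct[, 1], obs_p50 = obs_pct[, 2],
                     obs_p95 = obs_pct[, 3],
                     p5_lo = ci[1, , 1], p5_med = ci[2, , 1], p5_hi = ci[3, , 1],
                     p50_lo = ci[1, , 2], p50_med = ci[2, , 2], p50_hi = ci[3, , 2],
                     p95_lo = ci[1, , 3], p95_med = ci[2, , 3], p95_hi = ci[3, , 3])
  # 90% prediction interval from the pooled simulations per bin
  pi_lo <- vapply(seq_along(times), function(b)
    quantile(sims[bin == b, ], 0.05, na.rm = TRUE, names = FALSE), 0)
  pi_hi <- vapply(seq_along(times), function(b)
    quantile(sims[bin == b, ], 0.95, na.rm = TRUE, names = FALSE), 0)
  frac_out <- function(v) {
    below <- mean(v < pi_lo[bin], na.rm = TRUE)
    above <- mean(v > pi_hi[bin], na.rm = TRUE)
    c(below = below, above = above)
  }
  obs_frac <- frac_out(yobs)
  rep_frac <- vapply(seq_len(n_sim), function(r) frac_out(sims[, r]),
                     numeric(2))
  cov_ci <- apply(rep_frac, 1, quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE)
  coverage <- data.frame(side = c("below", "above"),
                         observed = 100 * as.numeric(obs_frac),
                         ci_lo = 100 * cov_ci[1, ],
                         ci_hi = 100 * cov_ci[2, ])
  structure(list(bins = bins, coverage = coverage, n_sim = n_sim,
                 seed = seed, lloq = lloq, n_subjects = nsub,
                 blq_in_coverage = blq_in_coverage),
            class = "pq_vpc")
}

#' @export
#' @method print pq_vpc
print.pq_vpc <- function(x, ...) {
  cat(sprintf("Visual predictive check (%d simulated studies)\n", x$n_sim))
  cat(sprintf("Observed data below simulated 90%% PI: %.2f%% (95%% CI %.2f-%.2f)\n",
              x$coverage$observed[1], x$coverage$ci_lo[1], x$coverage$ci_hi[1]))
  cat(sprintf("Observed data above simulated 90%% PI: %.2f%% (95%% CI %.2f-%.2f)\n",
              x$coverage$observed[2], x$coverage$ci_lo[2], x$coverage$ci_hi[2]))
  invisible(x)
}

#' @export
#' @method plot pq_vpc
plot.pq_vpc <- function(x, log = "y", ...) {
  b <- x$bins
  shade <- function(lo, hi, col)
    polygon(c(b$time, rev(b$time)), c(lo, rev(hi)), col = col, border = NA)
  ylim <- range(c(b$obs_p5, b$obs_p95, b$p5_lo, b$p95_hi, x$lloq),
                na.rm = TRUE)
  plot(b$time, b$obs_p50, type = "n", log = log, ylim = ylim,
       xlab = "Time (h)", ylab = "Piperaquine (ng/ml)", ...)
  shade(pmax(b$p5_lo, 1e-3), pmax(b$p5_hi, 1e-3), grDevices::adjustcolor("steelblue", 0.3))
  shade(pmax(b$p50_lo, 1e-3), pmax(b$p50_hi, 1e-3), grDevices::adjustcolor("grey40", 0.3))
  shade(pmax(b$p95_lo, 1e-3), pmax(b$p95_hi, 1e-3), grDevices::adjustcolor("steelblue", 0.3))
  lines(b$time, b$obs_p50, lwd = 2)
  lines(b$time, b$obs_p5, lty = 2)
  lines(b$time, b$obs_p95, lty = 2)
  abline(h = x$lloq, lty = 3)
  invisible(x)
}

#' Stratified nonparametric bootstrap of a model fit
#'
#' Resamples subjects with replacement within strata (food group by
#' default), refits the model to each replicate, and reports 2.5-97.5
#' percentile confidence intervals and relative standard errors
#' (`100 * SE / mean`) for every estimated parameter.
#'
#' @param dataset a `pq_dataset`.
#' @param spec [pq_model()] with initial estimates (typically the final
#'   estimates of a fit).
#' @param n number of bootstrap replicates.
#' @param strata column name used for stratified resampling.
#' @param seed integer seed.
#' @param control [pq_control()] for the replicate fits.
#' @return Object of class `pq_boot` with the replicate estimates,
#'   percentile CIs and RSEs.
#' @export
bootstrap_fit <- function(dataset, spec = pq_model(), n = 1000,
                          strata = "FOOD", seed = 1,
                          control = pq_control(iter_max = 60)) {
  one <- dataset[!duplicated(dataset$ID), ]
  groups <- split(one$ID, one[[strata]])
  if (any(vapply(groups, length, 0L) < 2))
    stop("each stratum needs at least 2 subjects")
  est <- vector("list", n)
  for (r in seq_len(n)) {
    set.seed(.subject_seed(seed + 300000L, r))
    ids <- unlist(lapply(groups, function(g)
      sample(g, length(g), replace = TRUE)))
    bd <- .reindex_dataset(dataset, ids)
    ftr <- tryCatch(pq_fit(bd, spec, control = control),
                    error = function(e) NULL)
    est[[r]] <- if (is.null(ftr)) NULL else coef(ftr)
  }
  keep <- !vapply(est, is.null, TRUE)
  em <- do.call(rbind, est[keep])
  ci <- apply(em, 2, quantile, probs = c(0.025, 0.975))
  rse <- 100 * apply(em, 2, sd) / colMeans(em)
  structure(list(estimates = em, ci = ci, rse = rse, n = n,
                 n_ok = sum(keep), strata = strata),
            class = "pq_boot")
}

#' @export
#' @method print pq_boot
print.pq_boot <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap, %d/%d successful replicates (stratified by %s)\n",
              x$n_ok, x$n, x$strata))
  out <- data.frame(mean = colMeans(x$estimates),
                    ci2.5 = x$ci[1, ], ci97.5 = x$ci[2, ],
                    rse_pct = x$rse)
  print(signif(out, 4))
  invisible(x)
}

# rebuild a dataset with (possibly duplicated) subjects renumbered 1..n
.reindex_dataset <- function(dataset, ids) {
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    d <- dataset[dataset$ID == ids[k], ]
    d$ID <- k
    out[[k]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- class(dataset)
  res
}

#' Post hoc secondary parameters and group comparison
#'
#' Derives per-subject secondary parameters from the empirical Bayes
#' estimates of a fitted model: CL/F and total V/F (Vc + Vp1 + Vp2) per kg,
#' terminal half-life, AUC from time 0 to day 138 computed as
#' `sum(dose_base * F_occ) / CL` (linear system), predicted Cmax and Tmax by
#' dense-grid evaluation over the dosing interval, and the day 7 (168 h)
#' concentration.  Fed and fasting groups are compared per parameter with a
#' nonparametric Mann-Whitney test (exact for eight or fewer subjects per
#' group, normal approximation with continuity and tie correction
#' otherwise).
#'
#' @param fit a `pqfit`.
#' @param dataset optional `pq_dataset` (default: the fitted data).
#' @param grid_step time resolution (h) of the Cmax/Tmax search grid.
#' @return Object of class `pq_secondary`: `params` (one row per subject)
#'   and `tests` (Mann-Whitney p-values fed vs fasting).
#' @export
secondary_params <- function(fit, dataset = NULL, grid_step = 0.01) {
  stopifnot(inherits(fit, "pqfit"))
  if (is.null(fit$ebes)) stop("empirical Bayes estimates unavailable")
  dataset <- dataset %||% fit$dataset
  spec <- fit$spec
  ml <- .model_list(spec)
  ids <- unique(dataset$ID)
  grid <- seq(0, 72, by = grid_step)
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    d <- dataset[dataset$ID == ids[k], ]
    dose <- d[d$EVID == 1L, ]
    eta <- numeric(5 + 2 * spec$n_occ)
    if (as.character(ids[k]) %in% rownames(fit$ebes))
      eta <- fit$ebes[as.character(ids[k]), ]
    ip <- .indiv_generic(spec, dose$WT[1], dose$AGE[1], dose$SEX[1],
                         dose$FOOD[1], eta)
    amt_base <- dose$AMT * spec$salt_factor
    Focc <- ip$F[dose$OCC]
    auc <- sum(amt_base * Focc) / ip$CL  # h*ug/ml (mg / (L/h) = mg h/L)
    subj <- list(tobs = grid, y = numeric(length(grid)),
                 blq = integer(length(grid)), dose_time = dose$TIME,
                 dose_amt = amt_base, dose_occ = as.integer(dose$OCC),
                 wt = dose$WT[1],
                 covs = .subject_covs(spec, dose$WT[1], dose$AGE[1],
                                      dose$SEX[1], dose$FOOD[1]))
    cgrid <- exp(cpp_pred_subject(subj, ml, as.numeric(eta)))
    day7 <- exp(cpp_pred_subject(modifyList(subj, list(
      tobs = 168, y = 0, blq = 0L)), ml, as.numeric(eta)))
    pp <- pq_params(CL = ip$CL, Vc = ip$Vc, Q1 = ip$Q1, Vp1 = ip$Vp1,
                    Q2 = ip$Q2, Vp2 = ip$Vp2, MTT = spec$theta[["MTT"]],
                    n_transit = spec$n_transit)
    rows[[k]] <- data.frame(
      id = ids[k], food = dose$FOOD[1], wt = dose$WT[1],
      cl_f_kg = ip$CL / dose$WT[1],
      v_f_kg = (ip$Vc + ip$Vp1 + ip$Vp2) / dose$WT[1],
      t_half_days = terminal_halflife(pp),
      auc_d138 = auc,
      cmax = max(cgrid), tmax = grid[which.max(cgrid)] - max(dose$TIME),
      day7 = day7)
  }
  params <- do.call(rbind, rows)
  vars <- c("cl_f_kg", "v_f_kg", "t_half_days", "auc_d138", "cmax", "tmax",
            "day7")
  tests <- vapply(vars, function(v) {
    a <- params[[v]][params$food == 1]
    b <- params[[v]][params$food == 0]
    if (!length(a) || !length(b)) return(NA_real_)
    suppressWarnings(wilcox.test(a, b,
                                 exact = min(length(a), length(b)) <= 8,
                                 correct = TRUE)$p.value)
  }, 0)
  structure(list(params = params, tests = tests), class = "pq_secondary")
}

#' @export
#' @method print pq_secondary
print.pq_secondary <- function(x, ...) {
  p <- x$params
  vars <- c("cl_f_kg", "v_f_kg", "t_half_days", "auc_d138", "cmax", "tmax",
            "day7")
  med <- vapply(vars, function(v) median(p[[v]]), 0)
  q1 <- vapply(vars, function(v) quantile(p[[v]], 0.25, names = FALSE), 0)
  q3 <- vapply(vars, function(v) quantile(p[[v]], 0.75, names = FALSE), 0)
  out <- data.frame(median = med, IQR_lo = q1, IQR_hi = q3,
                    p_fed_vs_fasting = x$tests[vars])
  rownames(out) <- c("CL/F (L/h/kg)", "V/F (L/kg)", "t1/2 (days)",
                     "AUC day 0-138 (h*ug/ml)", "Cmax (ng/ml)", "Tmax (h)",
                     "Day 7 conc (ng/ml)")
  print(signif(out, 3))
  invisible(x)
}

# R mirror of the C++ individual-parameter construction (generic relations)
.indiv_generic <- function(spec, wt, age, sex, food, eta) {
  covs <- .subject_covs(spec, wt, age, sex, food)
  th <- spec$theta
  relm <- function(param) {
    r <- spec$relations
    m <- 1
    if (nrow(r)) for (i in seq_len(nrow(r))) {
      if (r$param[i] != param) next
      x <- covs[[r$cov[i]]]
      f <- switch(r$form[i],
                  linear = 1 + r$th1[i] * (x - r$ref[i]),
                  power = (x / r$ref[i])^r$th1[i],
                  exponential = exp(r$th1[i] * (x - r$ref[i])),
                  piecewise = if (x < r$ref[i]) 1 + r$th1[i] * (x - r$ref[i])
                              else 1 + r$th2[i] * (x - r$ref[i]))
      if (f <= 0) stop("covariate effect produced a non-positive parameter")
      m <- m * f
    }
    m
  }
  wtr <- wt / spec$ref_wt
  acl <- wtr^spec$allo_cl
  av <- wtr^spec$allo_v
  occ <- seq_len(spec$n_occ)
  list(CL = th[["CL"]] * acl * relm("CL") * exp(eta[1]),
       Vc = th[["Vc"]] * av * relm("Vc") * exp(eta[2]),
       Q1 = th[["Q1"]] * acl * relm("Q1"),
       Vp1 = th[["Vp1"]] * av * relm("Vp1") * exp(eta[3]),
       Q2 = th[["Q2"]] * acl * relm("Q2") * exp(eta[4]),
       Vp2 = th[["Vp2"]] * av * relm("Vp2"),
       MTT = th[["MTT"]] * relm("MTT") * exp(eta[5] + eta[5 + spec$n_occ + occ]),
       F = th[["F"]] * (1 + spec$dose_slope * (occ - 1)) * relm("F") *
         exp(eta[5 + occ]))
}
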