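# Monte Carlo mapped power: map covariate effect size to the power of
# detecting it at the original study size, via per-patient likelihood-ratio
# contributions from a large simulated cohort.

#' Monte Carlo mapped power for a categorical food effect on F
#'
#' For each effect size e, a cohort of `n_per_effect` virtual patients (half
#' fed, half fasting) is simulated under the final model with relative
#' bioavailability multiplied by (1 + e) in the fed half.  The full model
#' (food effect on F estimated) and the reduced model (no food effect) are
#' then evaluated on that cohort, and the per-patient difference in
#' individual objective-function contributions, dOFV_i = iOFV_reduced -
#' iOFV_full, is tabulated.  `n_boot` bootstrap draws of `group_size`
#' patients from each group map the signal back to the original study size:
#' power is the fraction of draws whose summed dOFV exceeds the 1-df
#' likelihood-ratio critical values 3.84 (alpha 0.05) and 6.63 (alpha 0.01).
#' A null (effect 0) cohort is included by default as a type-I calibration.
#'
#' By default the full-model re-estimation profiles only the food effect,
#' holding the remaining parameters at the final model
#' (`reestimate = "food"`); `"food_variance"` additionally re-estimates
#' variance components and `"full"` everything.
#'
#' @param spec final-model [pq_model()].
#' @param design [pq_design()] (its arm sizes are replaced by
#'   `n_per_effect / 2` per arm for the simulated cohorts).
#' @param cov_dist [pq_covdist()].
#' @param effect_sizes fractional food effects on F.
#' @param include_null prepend the effect-0 calibration cohort?
#' @param n_per_effect simulated patients per effect size (even).
#' @param group_size patients per group resampled per bootstrap draw.
#' @param n_boot bootstrap draws per effect size.
#' @param seed integer seed.
#' @param reestimate `"food"`, `"food_variance"` or `"full"`.
#' @param control [pq_control()] for the full-model fits.
#' @return Object of class `pq_mcmp`: `curve` (effect size, power at both
#'   alphas), `min_effect_80` (smallest effect with power >= 0.8 at alpha
#'   0.05 on the monotone-read curve), and the per-patient `diofv` tables.
#' @export
mcmp_power <- function(spec = pq_model(), design = pq_design(),
                       cov_dist = pq_covdist(),
                       effect_sizes = seq(0.05, 0.5, by = 0.05),
                       include_null = TRUE, n_per_effect = 200,
                       group_size = 15, n_boot = 10000, seed = 1,
                       reestimate = c("food", "food_variance", "full"),
                       control = pq_control(iter_max = 60)) {
  reestimate <- match.arg(reestimate)
  if (any(effect_sizes <= 0 | effect_sizes >= 1))
    stop("effect sizes must be in (0, 1)")
  if (n_per_effect %% 2 != 0) stop("'n_per_effect' must be even")
  grid <- c(if (include_null) 0, effect_sizes)
  des <- design
  des$n_fed <- des$n_fasting <- n_per_effect / 2
  # reduced model: final spec, nothing estimated
  sp_red <- spec
  sp_red$estim_theta[] <- FALSE
  sp_red$estim_dose_slope <- FALSE
  sp_red$estim_omega2[] <- FALSE
  sp_red$estim_sigma <- FALSE
  if (nrow(sp_red$relations)) sp_red$relations$estim <- FALSE
  # full model: + food on F
  sp_full <- pq_add_relation(sp_red, "F", "FOOD", "linear", ref = 0,
                             th1 = 0, estim = TRUE)
  if (reestimate %in% c("food_variance", "full")) {
    sp_full$estim_omega2 <- spec$estim_omega2
    sp_full$estim_sigma <- spec$estim_sigma
  }
  if (reestimate == "full") {
    sp_full$estim_theta <- spec$estim_theta
    sp_full$estim_dose_slope <- spec$estim_dose_slope
    rel_n <- nrow(sp_full$relations)
    sp_full$relations$estim <- c(spec$relations$estim, TRUE)[seq_len(rel_n)]
  }
  rows <- vector("list", length(grid))
  diofv_tables <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    e <- grid[g]
    seed_g <- (seed + 7919L * g) %% 2147483000L
    pop <- sample_population(des, cov_dist, seed = seed_g)
    sp_gen <- if (e > 0)
      pq_add_relation(spec, "F", "FOOD", "linear", ref = 0, th1 = e,
                      estim = FALSE)
    else spec
    dat <- simulate_dataset(pop, sp_gen, seed = seed_g, design = des)
    red <- focei_ofv(dat, sp_red)
    full_fit <- pq_fit(dat, sp_full, control = control)
    di <- red$iofv - full_fit$iofv[names(red$iofv)]
    food_of <- pop$food[match(as.integer(names(di)), pop$id)]
    diofv_tables[[g]] <- data.frame(id = as.integer(names(di)),
                                    food = food_of, effect = e, diofv = di)
    fed <- di[food_of == 1]
    fas <- di[food_of == 0]
    set.seed(seed_g + 17L)
    sums <- vapply(seq_len(n_boot), function(b)
      sum(sample(fed, group_size, replace = TRUE)) +
        sum(sample(fas, group_size, replace = TRUE)), 0)
    rows[[g]] <- data.frame(effect = e,
                            power_05 = mean(sums > 3.84),
                            power_01 = mean(sums > 6.63),
                            theta_hat = .food_theta(full_fit),
                            sum_diofv = sum(di),
                            lrt_full_data = red$ofv - full_fit$ofv)
  }
  curve <- do.call(rbind, rows)
  # monotone read of the power curve (isotonic by cumulative max over
  # positive effects)
  pos <- curve$effect > 0
  mono05 <- cummax(curve$power_05[pos])
  eff <- curve$effect[pos]
  min80 <- if (any(mono05 >= 0.8)) eff[which(mono05 >= 0.8)[1]] else NA_real_
  structure(list(curve = curve, min_effect_80 = min80,
                 diofv = do.call(rbind, diofv_tables),
                 group_size = group_size, n_boot = n_boot,
                 n_per_effect = n_per_effect, reestimate = reestimate),
            class = "pq_mcmp")
}

.food_theta <- function(fit) {
  r <- fit$spec$relations
  i <- which(r$param == "F" & r$cov == "FOOD")
  if (length(i)) r$th1[max(i)] else NA_real_
}

#' @export
#' @method print pq_mcmp
print.pq_mcmp <- function(x, ...) {
  cat(sprintf("Monte Carlo mapped power (%d patients/effect, groups of %d, %d bootstrap draws)\n",
              x$n_per_effect, x$group_size, x$n_boot))
  print(signif(x$curve[, c("effect", "power_05", "power_01")], 3),
        row.names = FALSE)
  if (is.na(x$min_effect_80))
    cat("80% power (alpha 0.05) not reached on the evaluated grid\n")
  else
    cat(sprintf("Smallest effect with >= 80%% power (alpha 0.05): %.0f%%\n",
                100 * x$min_effect_80))
  invisible(x)
}

#' @export
#' @method plot pq_mcmp
plot.pq_mcmp <- function(x, ...) {
  cv <- x$curve
  plot(100 * cv$effect, cv$power_05, type = "b", pch = 16, ylim = c(0, 1),
       xlab = "Food effect on relative bioavailability (%)",
       ylab = "Power", ...)
  lines(100 * cv$effect, cv$power_01, type = "b", pch = 1, lty = 2)
  abline(h = 0.8, lty = 3)
  legend("bottomright", c("alpha = 0.05", "alpha = 0.01"),
         pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Two-sample power calculation for total exposure (NCA comparison)
#'
#' The traditional groupwise comparison the mapped-power approach is set
#' against: total-exposure means are compared between a fasting group with
#' mean `mean` and SD `sd` and a fed group whose mean is `mean * (1 +
#' effect)`, with the SD assumed proportional to the mean.  Power uses the
#' two-sided Welch t test (noncentral t with Welch-Satterthwaite degrees of
#' freedom).  `ttest_power_min_effect()` inverts the calculation for the
#' smallest detectable fractional difference.
#'
#' @param effect fractional difference in means (> -1).
#' @param mean,sd fasting-group mean and SD (same units; `sd > 0`).
#' @param n_per_group subjects per group (>= 2).
#' @param alpha two-sided significance level.
#' @param power target power for the inversion.
#' @return `ttest_power()`: the power; `ttest_power_min_effect()`: the
#'   minimum detectable fractional difference.
#' @export
ttest_power <- function(effect, mean, sd, n_per_group, alpha = 0.05) {
  if (sd <= 0) stop("'sd' must be positive")
  if (n_per_group < 2) stop("'n_per_group' must be >= 2")
  s1 <- sd
  s2 <- sd * (1 + effect)
  se <- sqrt(s1^2 / n_per_group + s2^2 / n_per_group)
  v1 <- s1^2 / n_per_group
  v2 <- s2^2 / n_per_group
  df <- (v1 + v2)^2 / (v1^2 / (n_per_group - 1) + v2^2 / (n_per_group - 1))
  ncp <- mean * effect / se
  tcrit <- qt(1 - alpha / 2, df)
  pt(-tcrit, df, ncp) + pt(tcrit, df, ncp, lower.tail = FALSE)
}

#' @rdname ttest_power
#' @export
ttest_power_min_effect <- function(mean, sd, n_per_group, power = 0.8,
                                   alpha = 0.05) {
  if (power <= alpha || power >= 1) stop("infeasible power target")
  f <- function(e) ttest_power(e, mean, sd, n_per_group, alpha) - power
  if (f(20) < 0) stop("infeasible power target for this design")
  uniroot(f, c(1e-8, 20), tol = 1e-10)$root
}
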