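# S3 methods for fitted models.

#' @export
#' @method print pqfit
print.pqfit <- function(x, ...) {
  cat("Population PK model (FOCE-I)\n")
  cat(sprintf("  %d subjects, %d observations, OFV = %.3f\n",
              x$n_subjects, x$n_obs, x$ofv))
  cat(sprintf("  outer: %d iterations, %d evaluations, convergence %d\n",
              x$opt$iterations, x$opt$evaluations, x$opt$convergence))
  cat("Estimates:\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.pqfit <- function(object, ...) object$coefficients

#' @export
logLik.pqfit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$par), class = "logLik")
}

#' Summarise a fitted population PK model
#'
#' Reports typical values, covariate slopes, and variance components
#' converted to percent CV (`100 * sqrt(exp(omega2) - 1)`), the reporting
#' convention for log-normal effects.
#'
#' @param object a `pqfit`.
#' @param ... unused.
#' @export
#' @method summary pqfit
summary.pqfit <- function(object, ...) {
  sp <- object$spec
  om <- sp$omega2[sp$omega2 > 0]
  out <- list(theta = sp$theta, dose_slope = sp$dose_slope,
              relations = sp$relations,
              cv = stats::setNames(cv_percent(om), names(om)),
              sigma_cv = cv_percent(sp$sigma^2),
              ofv = object$ofv, n_subjects = object$n_subjects,
              n_obs = object$n_obs, opt = object$opt)
  class(out) <- "summary.pqfit"
  out
}

#' @export
#' @method print summary.pqfit
print.summary.pqfit <- function(x, ...) {
  cat("Typical values:\n"); print(signif(x$theta, 4))
  cat(sprintf("Dose-occasion slope on F: %.3f per occasion\n", x$dose_slope))
  if (nrow(x$relations)) {
    cat("Covariate relationships:\n")
    print(x$relations[, c("param", "cov", "form", "ref", "th1", "th2")])
  }
  cat("Variability (% CV):\n"); print(signif(x$cv, 3))
  cat(sprintf("Residual error: %.1f %%CV\n", x$sigma_cv))
  cat(sprintf("OFV %.3f  (%d subjects, %d observations)\n",
              x$ofv, x$n_subjects, x$n_obs))
  invisible(x)
}

#' Predicted concentrations from a fitted model
#'
#' Population predictions use zero random effects; individual predictions
#' use the empirical Bayes estimates.  Predictions are made at the
#' observation rows of `newdata` (default: the fitted dataset).
#'
#' @param object a `pqfit`.
#' @param newdata optional `pq_dataset`.
#' @param type `"individual"` or `"population"`.
#' @param ... unused.
#' @return Numeric vector of predicted concentrations (ng/ml), one per
#'   observation row (EVID == 0) of the data, in row order.
#' @export
predict.pqfit <- function(object, newdata = NULL,
                          type = c("individual", "population"), ...) {
  type <- match.arg(type)
  data <- newdata %||% object$dataset
  spec <- object$spec
  ml <- .model_list(spec)
  q <- 5 + 2 * spec$n_occ
  ids <- unique(data$ID)
  out <- numeric(0)
  for (id in ids) {
    d <- data[data$ID == id, ]
    dose <- d[d$EVID == 1L, ]
    obs <- d[d$EVID == 0L, ]
    if (!nrow(obs)) next
    eta <- numeric(q)
    if (type == "individual" && as.character(id) %in% rownames(object$ebes))
      eta <- object$ebes[as.character(id), ]
    subj <- list(tobs = obs$TIME, y = numeric(nrow(obs)),
                 blq = integer(nrow(obs)), dose_time = dose$TIME,
                 dose_amt = dose$AMT * spec$salt_factor,
                 dose_occ = as.integer(dose$OCC), wt = dose$WT[1],
                 covs = .subject_covs(spec, dose$WT[1], dose$AGE[1],
                                      dose$SEX[1], dose$FOOD[1]))
    out <- c(out, exp(cpp_pred_subject(subj, ml, as.numeric(eta))))
  }
  out
}

#' Individual weighted residuals
#'
#' `(log(DV) - log(IPRED)) / sigma` at the empirical Bayes estimates;
#' BLQ rows yield NA.
#'
#' @param object a `pqfit`.
#' @param ... unused.
#' @export
residuals.pqfit <- function(object, ...) {
  data <- object$dataset
  obs <- data[data$EVID == 0L, ]
  ipred <- predict(object, type = "individual")
  res <- (log(obs$DV) - log(ipred)) / object$spec$sigma
  res[obs$BLQ == 1L] <- NA_real_
  res
}

#' Simulate replicate datasets from a fitted model
#'
#' Re-simulates the fitted study design (same subjects, doses and nominal
#' times) with new random effects and residual errors drawn from the
#' estimated model.
#'
#' @param object a `pqfit`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `pq_dataset` objects (length `nsim`).
#' @export
simulate.pqfit <- function(object, nsim = 1, seed = 1, ...) {
  lapply(seq_len(nsim), function(r)
    .simulate_from_design(object$dataset, object$spec, seed + r - 1L))
}

# simulate at the design embedded in an existing dataset
.simulate_from_design <- function(dataset, spec, seed) {
  ml <- .model_list(spec)
  q <- 5 + 2 * spec$n_occ
  out <- dataset
  for (id in unique(dataset$ID)) {
    sel <- dataset$ID == id
    d <- dataset[sel, ]
    dose <- d[d$EVID == 1L, ]
    obs_i <- which(sel & dataset$EVID == 0L)
    if (!length(obs_i)) next
    set.seed(.subject_seed(seed + 900000L, as.integer(id)))
    eta <- numeric(q)
    eta[1:5] <- rnorm(5) * sqrt(ml$omega2[1:5])
    eta[5 + seq_len(spec$n_occ)] <- rnorm(spec$n_occ) * sqrt(ml$omega2[6])
    eta[5 + spec$n_occ + seq_len(spec$n_occ)] <-
      rnorm(spec$n_occ) * sqrt(ml$omega2[7])
    tt <- dataset$TIME[obs_i]
    subj <- list(tobs = tt, y = numeric(length(tt)),
                 blq = integer(length(tt)), dose_time = dose$TIME,
                 dose_amt = dose$AMT * spec$salt_factor,
                 dose_occ = as.integer(dose$OCC), wt = dose$WT[1],
                 covs = .subject_covs(spec, dose$WT[1], dose$AGE[1],
                                      dose$SEX[1], dose$FOOD[1]))
    dv <- exp(cpp_pred_subject(subj, ml, eta) +
                rnorm(length(tt)) * spec$sigma)
    blq <- as.integer(dv < spec$lloq)
    dv[blq == 1L] <- NA_real_
    out$DV[obs_i] <- dv
    out$BLQ[obs_i] <- blq
  }
  out
}

#' Goodness-of-fit plot
#'
#' Observed versus population and individual predictions on the log10
#' scale, with the line of identity and the quantification limit.
#'
#' @param x a `pqfit`.
#' @param ... passed to `plot`.
#' @export
plot.pqfit <- function(x, ...) {
  obs <- x$dataset[x$dataset$EVID == 0L, ]
  keep <- obs$BLQ == 0L & is.finite(obs$DV)
  ipred <- predict(x, type = "individual")[keep]
  ppred <- predict(x, type = "population")[keep]
  dv <- obs$DV[keep]
  oldpar <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(oldpar))
  for (p in list(list(v = ppred, lab = "Population prediction"),
                 list(v = ipred, lab = "Individual prediction"))) {
    plot(log10(p$v), log10(dv), xlab = paste0("log10 ", p$lab),
         ylab = "log10 observed (ng/ml)", pch = 1, col = "grey30", ...)
    abline(0, 1)
    abline(h = log10(x$spec$lloq), lty = 2)
  }
  invisible(x)
}
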