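# FOCE-I estimation: objective-function evaluation and maximum-likelihood
# fitting of the mixed-effects model.

#' Optimisation control for [pq_fit()]
#'
#' The outer problem minimises the FOCE-I objective over transformed
#' parameters (log for positive quantities, raw for covariate slopes) with
#' `nlminb`; the inner (per-subject) posterior-mode search is a damped
#' Gauss-Newton iteration warm-started across outer evaluations.
#'
#' @param iter_max maximum outer iterations.
#' @param eval_max maximum outer objective evaluations.
#' @param rel_tol relative convergence tolerance on the objective.
#' @param trace print outer progress every `trace` iterations (0 = silent).
#' @return List of class `pq_control`.
#' @export
pq_control <- function(iter_max = 150, eval_max = 800, rel_tol = 1e-7,
                       trace = 0) {
  structure(list(iter_max = iter_max, eval_max = eval_max,
                 rel_tol = rel_tol, trace = trace), class = "pq_control")
}

#' FOCE-I objective function value and per-subject contributions
#'
#' For each subject the conditional (posterior-mode) random effects are
#' located and the Laplace-type approximation to minus twice the marginal
#' log-likelihood is evaluated; the total OFV is the sum of the per-subject
#' contributions (iOFV).  Records below the LLOQ enter as censored-normal
#' terms under the M3 policy or are omitted.
#'
#' @param dataset a `pq_dataset` data.frame.
#' @param spec [pq_model()]; its current parameter values are used.
#' @param params optional named list overriding elements of `spec`
#'   (`theta`, `dose_slope`, `omega2`, `sigma`).
#' @return List with `ofv`, named `iofv`, `ebes` (posterior-mode etas,
#'   subjects x effects) and `converged` flags.
#' @export
focei_ofv <- function(dataset, spec = pq_model(), params = NULL) {
  spec <- .apply_params(spec, params)
  spec <- .resolve_refs(spec, dataset)
  subjects <- .build_subjects(dataset, spec)
  q <- 5 + 2 * spec$n_occ
  warm <- matrix(0, length(subjects), q)
  res <- cpp_focei(subjects, .model_list(spec), warm)
  .focei_result(res, names(subjects), spec)
}

.apply_params <- function(spec, params) {
  if (is.null(params)) return(spec)
  if (!is.null(params$theta)) spec$theta[names(params$theta)] <- params$theta
  if (!is.null(params$dose_slope)) spec$dose_slope <- params$dose_slope
  if (!is.null(params$omega2)) spec$omega2[names(params$omega2)] <- params$omega2
  if (!is.null(params$sigma)) spec$sigma <- params$sigma
  spec
}

.eta_names <- function(spec) {
  c("CL", "Vc", "Vp1", "Q2", "MTT",
    paste0("F_occ", seq_len(spec$n_occ)),
    paste0("MTT_occ", seq_len(spec$n_occ)))
}

.focei_result <- function(res, ids, spec) {
  iofv <- stats::setNames(res$iofv, ids)
  ebes <- res$eta
  dimnames(ebes) <- list(ids, .eta_names(spec))
  list(ofv = res$ofv, iofv = iofv, ebes = ebes,
       converged = stats::setNames(res$converged, ids))
}

#' Censored-record likelihood contribution (M3)
#'
#' Minus twice the log-probability that a log-normal observation with
#' predicted log-concentration `pred_log` and log-scale SD `sigma` falls
#' below the quantification limit: `-2 * log(Phi((log(lloq) - pred_log) /
#' sigma))`.
#'
#' @param pred_log predicted natural-log concentration.
#' @param sigma residual SD on the log scale (> 0).
#' @param lloq lower limit of quantification, ng/ml (> 0).
#' @return The -2 log-likelihood term (vectorised over `pred_log`).
#' @export
#' @examples
#' m3_contribution(log(1.2), 0.3, 1.2)  # -2 log(1/2)
m3_contribution <- function(pred_log, sigma, lloq) {
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  if (any(lloq <= 0)) stop("'lloq' must be positive")
  -2 * pnorm((log(lloq) - pred_log) / sigma, log.p = TRUE)
}

#' Fit the population pharmacokinetic model by FOCE-I
#'
#' Minimises the FOCE-I objective (minus twice the approximate marginal
#' log-likelihood) over the model's free parameters.  Positive parameters
#' are optimised on the log scale, covariate slopes on the natural scale
#' bounded so every individual multiplier stays positive over the observed
#' covariate range.  The fit is deterministic given the data and initial
#' estimates.
#'
#' @param dataset a `pq_dataset` data.frame (long format; dose amounts in mg
#'   piperaquine phosphate).
#' @param spec [pq_model()] defining structure, initial estimates and which
#'   parameters are estimated.
#' @param inits optional named list of initial-value overrides (`theta`,
#'   `dose_slope`, `omega2`, `sigma`).
#' @param control [pq_control()].
#' @return Object of class `pqfit`: components `coefficients` (typical
#'   values, slopes, variances, sigma on their natural scales), `ofv`,
#'   `iofv`, `ebes`, `spec` (the specification updated to the estimates),
#'   `opt` (optimiser diagnostics) and `dataset`.
#' @seealso [focei_ofv()], [vpc()], [bootstrap_fit()], [secondary_params()]
#' @export
pq_fit <- function(dataset, spec = pq_model(), inits = NULL,
                   control = pq_control()) {
  spec <- .apply_params(spec, inits)
  spec <- .resolve_refs(spec, dataset)
  subjects <- .build_subjects(dataset, spec)
  n_obs <- sum(vapply(subjects, function(s) length(s$tobs), 0L))
  if (!n_obs) stop("no usable observations")
  pk <- .pq_pack(spec, .covstats(dataset, spec))
  q <- 5 + 2 * spec$n_occ
  env <- new.env(parent = emptyenv())
  env$warm <- matrix(0, length(subjects), q)
  env$evals <- 0L
  obj <- function(par) {
    sp <- .pq_unpack(spec, stats::setNames(par, names(pk$par)))
    res <- tryCatch(cpp_focei(subjects, .model_list(sp), env$warm),
                    error = function(e) NULL)
    env$evals <- env$evals + 1L
    if (is.null(res) || !all(res$ok) || !is.finite(res$ofv)) return(1e10)
    env$warm <- res$eta
    env$last_par <- par
    env$last_val <- res$ofv
    if (isTRUE(control$trace > 0) && env$evals %% control$trace == 0)
      message(sprintf("eval %d  OFV %.4f", env$evals, res$ofv))
    res$ofv
  }
  # forward-difference gradient with a step well above the noise floor of
  # the inner optimisation (nlminb's internal step is too small for that)
  grad <- function(par) {
    f0 <- if (!is.null(env$last_par) && identical(par, env$last_par))
      env$last_val else obj(par)
    h <- 1e-4
    vapply(seq_along(par), function(k) {
      p2 <- par
      p2[k] <- par[k] + h
      (obj(p2) - f0) / h
    }, 0)
  }
  opt <- if (length(pk$par)) {
    nlminb(pk$par, obj, gradient = grad, lower = pk$lower, upper = pk$upper,
           control = list(iter.max = control$iter_max,
                          eval.max = control$eval_max,
                          rel.tol = control$rel_tol))
  } else {
    list(par = numeric(0), convergence = 0L, iterations = 0L,
         message = "no free parameters")
  }
  spec_hat <- .pq_unpack(spec, stats::setNames(opt$par, names(pk$par)))
  final <- cpp_focei(subjects, .model_list(spec_hat), env$warm)
  fr <- .focei_result(final, names(subjects), spec_hat)
  est <- stats::setNames(opt$par, names(pk$par))
  structure(list(coefficients = .natural_coefs(spec_hat),
                 par = est, ofv = final$ofv, iofv = fr$iofv,
                 ebes = fr$ebes, inner_converged = fr$converged,
                 spec = spec_hat, spec_init = spec,
                 opt = list(convergence = opt$convergence,
                            message = opt$message,
                            iterations = opt$iterations,
                            evaluations = env$evals),
                 n_obs = n_obs, n_subjects = length(subjects),
                 dataset = dataset, control = control,
                 call = match.call()),
            class = "pqfit")
}

.natural_coefs <- function(spec) {
  r <- spec$relations
  rel <- if (nrow(r))
    stats::setNames(r$th1, paste0(r$param, "~", r$cov, ".", r$form))
  else numeric(0)
  rel2 <- if (nrow(r) && any(r$form == "piecewise")) {
    i <- which(r$form == "piecewise")
    stats::setNames(r$th2[i], paste0(r$param[i], "~", r$cov[i], ".hi"))
  } else numeric(0)
  onm <- names(spec$omega2)[spec$omega2 > 0]
  c(spec$theta[names(spec$theta) != "F"],
    dose_slope = spec$dose_slope, rel, rel2,
    stats::setNames(as.numeric(spec$omega2[spec$omega2 > 0]),
                    paste0("omega2.", onm, recycle0 = TRUE)),
    sigma = spec$sigma)
}
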