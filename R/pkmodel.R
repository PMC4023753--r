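# Structural and stochastic model layer: typical parameters, covariate
# functions, individual-parameter construction and concentration prediction.

#' Typical structural parameters of the final piperaquine model
#'
#' Apparent (dose-relative, F-scaled) disposition and absorption parameters.
#' Defaults are the final-model population estimates: elimination clearance
#' CL/F 67.6 L/h, central volume Vc/F 3030 L, inter-compartment clearances
#' Q1/F 408 and Q2/F 109 L/h, peripheral volumes Vp1/F 6240 and
#' Vp2/F 24400 L, mean absorption transit time 2.04 h through three transit
#' compartments, and population relative bioavailability fixed at 1.
#'
#' @param CL,Vc,Q1,Vp1,Q2,Vp2 disposition parameters (L/h and L).
#' @param MTT mean absorption transit time (h).
#' @param n_transit number of transit compartments (non-negative integer).
#' @param F relative bioavailability (fraction; population value fixed at 1).
#' @return A named list of class `pq_params`.
#' @export
#' @examples
#' p <- pq_params()
#' terminal_halflife(p)
pq_params <- function(CL = 67.6, Vc = 3030, Q1 = 408, Vp1 = 6240, Q2 = 109,
                      Vp2 = 24400, MTT = 2.04, n_transit = 3, F = 1) {
  p <- list(CL = CL, Vc = Vc, Q1 = Q1, Vp1 = Vp1, Q2 = Q2, Vp2 = Vp2,
            MTT = MTT, n_transit = as.integer(n_transit), F = F)
  for (nm in c("CL", "Vc", "Vp1", "Vp2", "MTT"))
    if (any(p[[nm]] <= 0)) stop("'", nm, "' must be strictly positive")
  if (any(p$Q1 < 0) || any(p$Q2 < 0)) stop("'Q1'/'Q2' must be non-negative")
  if (p$n_transit < 0) stop("'n_transit' must be >= 0")
  if (any(p$F <= 0)) stop("'F' must be strictly positive")
  class(p) <- "pq_params"
  p
}

#' Variance components of the final model
#'
#' Between-subject (BSV) and between-occasion (IOV) variances of the
#' log-normal random effects, plus the additive residual SD on the natural-log
#' concentration scale.  Defaults are supplied as percent CV (the reporting
#' convention) and converted with [omega2_from_cv()].
#'
#' @param cv_bsv named vector of BSV percent CVs (parameters CL, Vc, Vp1, Q2,
#'   MTT); parameters absent have zero variability.
#' @param cv_iov named vector of IOV percent CVs (parameters F, MTT).
#' @param cv_sigma residual error magnitude, percent CV.
#' @return List with `omega2_bsv`, `omega2_iov` (variances) and `sigma` (SD).
#' @export
pq_variances <- function(cv_bsv = c(CL = 24.4, Vc = 51.6, Vp1 = 45.6,
                                    Q2 = 25.8, MTT = 24.1),
                         cv_iov = c(F = 48.8, MTT = 39.4),
                         cv_sigma = 30.7) {
  if (any(cv_bsv < 0) || any(cv_iov < 0)) stop("CVs must be non-negative")
  if (cv_sigma <= 0) stop("residual CV must be positive")
  list(omega2_bsv = vapply(cv_bsv, omega2_from_cv, 0),
       omega2_iov = vapply(cv_iov, omega2_from_cv, 0),
       sigma = sqrt(omega2_from_cv(cv_sigma)))
}

#' Covariate model of the final analysis
#'
#' Fixed allometric body-weight scaling (exponent 3/4 on clearance
#' parameters, 1 on volumes), a linear dose-occasion effect on relative
#' bioavailability, a linear age effect on the first peripheral volume, and
#' optional categorical food effects on MTT and F.  References default to
#' the pooled study medians (52 kg, 33 years).
#'
#' @param allo_exp_clearance,allo_exp_volume fixed allometric exponents.
#' @param ref_weight,ref_age centering references (kg, years).
#' @param theta_dose_F linear increase in F per dose occasion (fraction).
#' @param theta_age_Vp1 linear fractional change in Vp1 per year of age.
#' @param theta_food_MTT,theta_food_F categorical food effects (fraction).
#' @return Named list of class `pq_covmodel`.
#' @export
pq_covmodel <- function(allo_exp_clearance = 0.75, allo_exp_volume = 1,
                        ref_weight = 52, ref_age = 33,
                        theta_dose_F = 0.253, theta_age_Vp1 = 0.0410,
                        theta_food_MTT = 0, theta_food_F = 0) {
  cm <- list(allo_exp_clearance = allo_exp_clearance,
             allo_exp_volume = allo_exp_volume,
             ref_weight = ref_weight, ref_age = ref_age,
             theta_dose_F = theta_dose_F, theta_age_Vp1 = theta_age_Vp1,
             theta_food_MTT = theta_food_MTT, theta_food_F = theta_food_F)
  class(cm) <- "pq_covmodel"
  cm
}

#' Transit absorption rate constant
#'
#' The transit chain delays absorption so that the mean transit time is
#' `MTT = (n_transit + 1) / ktr`; the absorption rate out of the last stage
#' equals the inter-transit rate constant.
#'
#' @param MTT mean absorption transit time (h), strictly positive.
#' @param n_transit number of transit compartments (integer >= 0).
#' @return ktr in 1/h.
#' @export
#' @examples
#' transit_rate(2.04, 3)  # 1.9608 /h
transit_rate <- function(MTT, n_transit) {
  if (any(!is.finite(MTT)) || any(MTT <= 0))
    stop("'MTT' must be strictly positive")
  if (any(n_transit < 0) || any(n_transit != round(n_transit)))
    stop("'n_transit' must be a non-negative integer")
  (n_transit + 1) / MTT
}

#' Convert a log-scale variance to percent CV and back
#'
#' For a log-normally distributed quantity with log-scale variance
#' `omega2`, the coefficient of variation is
#' `CV% = 100 * sqrt(exp(omega2) - 1)`.  `omega2_from_cv()` is the inverse.
#'
#' @param omega2 variance of the log-scale effect (>= 0).
#' @param cv coefficient of variation in percent (> 0 for the inverse).
#' @return `cv_percent`: CV in percent; `omega2_from_cv`: the variance.
#' @export
cv_percent <- function(omega2) {
  if (any(omega2 < 0)) stop("'omega2' must be non-negative")
  100 * sqrt(exp(omega2) - 1)
}

#' @rdname cv_percent
#' @export
omega2_from_cv <- function(cv) {
  if (any(cv < 0)) stop("'cv' must be non-negative")
  log(1 + (cv / 100)^2)
}

#' Individual parameters for one subject and occasion
#'
#' Applies the covariate model and the realized random effects to the typical
#' parameters: clearances scale with `(weight/ref)^(3/4)`, volumes with
#' `(weight/ref)`, Vp1 carries the linear age effect, F the linear
#' dose-occasion effect, the categorical food effect and its occasion-level
#' random effect, and MTT the food effect plus subject- and occasion-level
#' random effects.
#'
#' @param typical [pq_params()] typical values.
#' @param cov_model [pq_covmodel()].
#' @param covariates list with `weight` (kg), `age` (years), `food` (0/1).
#' @param effects list with `eta_bsv` (named vector over CL, Vc, Vp1, Q2,
#'   MTT; missing names mean 0) and `eta_iov` (list with `F` and `MTT`,
#'   vectors indexed by occasion; missing mean 0).
#' @param occasion dose occasion index (1-based).
#' @return `pq_params` with the individual values for that occasion.
#' @export
individual_params <- function(typical, cov_model = pq_covmodel(),
                              covariates, effects = list(), occasion = 1L) {
  stopifnot(inherits(typical, "pq_params"))
  if (occasion < 1) stop("'occasion' must be >= 1")
  eb <- effects$eta_bsv %||% numeric(0)
  ei <- effects$eta_iov %||% list()
  e <- function(nm) if (nm %in% names(eb)) eb[[nm]] else 0
  ko <- function(nm) {
    v <- ei[[nm]]
    if (is.null(v) || length(v) < occasion) 0 else v[[occasion]]
  }
  wtr <- covariates$weight / cov_model$ref_weight
  if (!is.finite(wtr) || wtr <= 0) stop("invalid weight")
  acl <- wtr^cov_model$allo_exp_clearance
  av <- wtr^cov_model$allo_exp_volume
  age_mult <- 1 + cov_model$theta_age_Vp1 * (covariates$age - cov_model$ref_age)
  food <- covariates$food %||% 0
  fmtt <- 1 + cov_model$theta_food_MTT * food
  ff <- 1 + cov_model$theta_food_F * food
  occ_mult <- 1 + cov_model$theta_dose_F * (occasion - 1)
  if (age_mult <= 0 || fmtt <= 0 || ff <= 0 || occ_mult <= 0)
    stop("covariate effect produced a non-positive parameter")
  pq_params(CL = typical$CL * acl * exp(e("CL")),
            Vc = typical$Vc * av * exp(e("Vc")),
            Q1 = typical$Q1 * acl,
            Vp1 = typical$Vp1 * av * age_mult * exp(e("Vp1")),
            Q2 = typical$Q2 * acl * exp(e("Q2")),
            Vp2 = typical$Vp2 * av,
            MTT = typical$MTT * fmtt * exp(e("MTT") + ko("MTT")),
            n_transit = typical$n_transit,
            F = typical$F * occ_mult * ff * exp(ko("F")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.check_doses <- function(doses) {
  stopifnot(is.data.frame(doses), all(c("time", "amt") %in% names(doses)))
  if (any(doses$amt < 0)) stop("dose amounts must be non-negative")
  if (is.null(doses$occasion)) doses$occasion <- seq_len(nrow(doses))
  doses
}

.occ_value <- function(x, occ) if (length(x) == 1L) rep(x, length(occ)) else x[occ]

#' Concentration-time profile of the linear compartment system
#'
#' Solves the linear system dose -> transit chain -> central with two
#' peripheral compartments and first-order elimination.  The default path
#' uses the closed-form eigendecomposition of the disposition matrix
#' convolved with the Erlang transit input; `method = "matexp"` propagates
#' the full compartment state with matrix exponentials over the
#' piecewise-constant intervals between dose events (identical solution,
#' used for mass-balance accounting).  `F` and `MTT` in `params` may be
#' vectors indexed by dose occasion, carrying occasion-level variability.
#'
#' @param params [pq_params()]; `F` and `MTT` scalar or per-occasion vectors.
#' @param doses data.frame with columns `time` (h), `amt` (mg piperaquine
#'   base) and optionally `occasion` (default: dose index).
#' @param times sorted, non-negative prediction times (h).
#' @param method `"analytic"` (default) or `"matexp"`.
#' @return Central-compartment concentrations in ng/ml at `times`.
#' @export
#' @examples
#' p <- pq_params()
#' d <- data.frame(time = c(0, 24, 48), amt = 960 * 0.577)
#' solve_profile(p, d, times = c(1, 4, 24, 72, 168))
solve_profile <- function(params, doses, times,
                          method = c("analytic", "matexp")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "pq_params"))
  if (is.unsorted(times)) stop("'times' must be sorted")
  if (any(times < 0)) stop("'times' must be non-negative")
  doses <- .check_doses(doses)
  Focc <- .occ_value(params$F, doses$occasion)
  MTTocc <- .occ_value(params$MTT, doses$occasion)
  ktr <- transit_rate(MTTocc, params$n_transit)
  if (method == "analytic") {
    cpp_profile_conc(as.numeric(times), as.numeric(doses$time),
                     as.numeric(doses$amt * Focc), as.numeric(ktr),
                     params$n_transit, params$CL, params$Vc, params$Q1,
                     params$Vp1, params$Q2, params$Vp2)
  } else {
    st <- solve_amounts(params, doses, times)
    st[, "central"] / params$Vc * 1000
  }
}

#' Compartment amounts by matrix-exponential propagation
#'
#' Full state (transit stages, central, both peripherals, cumulative
#' eliminated amount) of the dosing system, advanced with
#' `Matrix::expm` over piecewise-constant intervals.  The transit rate of the
#' currently active occasion applies between dose events.
#'
#' @inheritParams solve_profile
#' @return Matrix (length(times) x (n_transit + 5)) of amounts in mg.
#' @export
solve_amounts <- function(params, doses, times) {
  stopifnot(inherits(params, "pq_params"))
  doses <- .check_doses(doses)
  if (is.unsorted(times)) stop("'times' must be sorted")
  m <- params$n_transit + 1L
  nstate <- m + 4L
  Focc <- .occ_value(params$F, doses$occasion)
  MTTocc <- .occ_value(params$MTT, doses$occasion)
  ktrocc <- transit_rate(MTTocc, params$n_transit)
  k10 <- params$CL / params$Vc
  k12 <- params$Q1 / params$Vc
  k21 <- params$Q1 / params$Vp1
  k13 <- params$Q2 / params$Vc
  k31 <- params$Q2 / params$Vp2
  amat <- function(ktr) {
    A <- matrix(0, nstate, nstate)
    for (i in seq_len(m)) A[i, i] <- -ktr
    if (m > 1) for (i in seq_len(m - 1)) A[i + 1, i] <- ktr
    ic <- m + 1L
    A[ic, m] <- ktr
    A[ic, ic] <- -(k10 + k12 + k13)
    A[ic, ic + 1L] <- k21
    A[ic, ic + 2L] <- k31
    A[ic + 1L, ic] <- k12
    A[ic + 1L, ic + 1L] <- -k21
    A[ic + 2L, ic] <- k13
    A[ic + 2L, ic + 2L] <- -k31
    A[ic + 3L, ic] <- k10
    A
  }
  ord <- order(doses$time)
  dtimes <- doses$time[ord]
  damt <- (doses$amt * Focc)[ord]
  dktr <- ktrocc[ord]
  state <- numeric(nstate)
  cur_t <- 0
  cur_ktr <- dktr[1]
  out <- matrix(0, length(times), nstate)
  events <- sort(unique(c(dtimes, times)))
  for (ev in events) {
    dt <- ev - cur_t
    if (dt > 0)
      state <- as.numeric(Matrix::expm(amat(cur_ktr) * dt) %*% state)
    cur_t <- ev
    # observations at a dose time are taken before the dose
    hit <- which(abs(times - ev) < 1e-12)
    if (length(hit)) out[hit, ] <- rep(state, each = length(hit))
    dj <- which(abs(dtimes - ev) < 1e-12)
    if (length(dj)) {
      state[1] <- state[1] + sum(damt[dj])
      cur_ktr <- dktr[max(dj)]
    }
  }
  colnames(out) <- c(paste0("transit", seq_len(m)), "central", "periph1",
                     "periph2", "eliminated")
  out
}

#' Terminal elimination half-life
#'
#' `ln(2) / lambda_z` where `lambda_z` is the smallest-magnitude non-zero
#' eigenvalue of the 3x3 disposition rate matrix built from
#' k10 = CL/Vc, k12 = Q1/Vc, k21 = Q1/Vp1, k13 = Q2/Vc, k31 = Q2/Vp2.
#' Compartments decoupled by a zero inter-compartment clearance contribute
#' zero eigenvalues and are ignored, so the one-compartment limit
#' `ln(2) * Vc / CL` is recovered when Q1 = Q2 = 0.  The value is invariant
#' under rescaling of F (apparent parameterization).
#'
#' @param params [pq_params()].
#' @return Half-life in days.
#' @export
#' @examples
#' terminal_halflife(pq_params())  # about 19.6 days
terminal_halflife <- function(params) {
  stopifnot(inherits(params, "pq_params"))
  if (params$Vc <= 0 || params$Vp1 <= 0 || params$Vp2 <= 0)
    stop("degenerate volumes")
  eg <- cpp_disp_eigen(params$CL, params$Vc, params$Q1, params$Vp1,
                       params$Q2, params$Vp2)
  lam <- eg$lambda[eg$lambda > 1e-12]
  if (!length(lam)) stop("no elimination pathway")
  log(2) / min(lam) / 24
}
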