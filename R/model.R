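# Model specification: which parameters are estimated, covariate
# relationships, BLQ policy, and the packing of free parameters for the
# outer optimisation.

.PARAM_CODES <- c(CL = 1L, Vc = 2L, Q1 = 3L, Vp1 = 4L, Q2 = 5L, Vp2 = 6L,
                  MTT = 7L, F = 8L)
.FORM_CODES <- c(linear = 1L, power = 2L, exponential = 3L, piecewise = 4L)

#' Mixed-effects model specification
#'
#' Describes the estimable model: typical-value initial estimates, which
#' parameters carry between-subject (BSV) and between-occasion (IOV)
#' variability, covariate relationships (functional forms: linear, power,
#' exponential, piecewise-linear for continuous covariates; linear for
#' categorical), the BLQ policy, and the fixed components (population F = 1,
#' three transit compartments, allometric exponents 3/4 and 1, reference
#' weight 52 kg).  Defaults reproduce the final model: a linear dose-occasion
#' effect on F and a linear age effect on Vp1 centered at 33 years.
#'
#' @param theta named initial typical values (CL, Vc, Q1, Vp1, Q2, Vp2, MTT,
#'   F); F is fixed.
#' @param estim_theta named logical: which typical values are estimated.
#' @param dose_slope linear increase in F per dose occasion (fraction).
#' @param estim_dose_slope estimate the dose-occasion slope?
#' @param relations data.frame of covariate relationships with columns
#'   `param`, `cov`, `form`, `ref` (NA = dataset median, resolved at fit
#'   time), `th1`, `th2` (piecewise upper slope), `estim`.
#' @param omega2 named variances: BSV on CL, Vc, Vp1, Q2, MTT and IOV as
#'   `F_IOV`, `MTT_IOV`; zero variance removes the random effect.
#' @param estim_omega2 named logical over the same names.
#' @param sigma additive residual SD on natural-log concentrations.
#' @param estim_sigma estimate sigma?
#' @param blq `"omit"` (drop BLQ records) or `"m3"` (censored-normal
#'   likelihood).
#' @param n_transit fixed number of transit compartments.
#' @param n_occ number of dose occasions.
#' @param ref_wt allometric reference body weight (kg).
#' @param allo_cl,allo_v fixed allometric exponents.
#' @param lloq lower limit of quantification (ng/ml).
#' @param salt_factor mg piperaquine base per mg phosphate salt; dose
#'   amounts in datasets are phosphate and are converted on entry.
#' @return List of class `pq_model`.
#' @export
#' @examples
#' spec <- pq_model()
#' coef_names <- names(.pq_pack(spec)$par)
pq_model <- function(theta = c(CL = 67.6, Vc = 3030, Q1 = 408, Vp1 = 6240,
                               Q2 = 109, Vp2 = 24400, MTT = 2.04, F = 1),
                     estim_theta = c(CL = TRUE, Vc = TRUE, Q1 = TRUE,
                                     Vp1 = TRUE, Q2 = TRUE, Vp2 = TRUE,
                                     MTT = TRUE, F = FALSE),
                     dose_slope = 0.253, estim_dose_slope = TRUE,
                     relations = data.frame(param = "Vp1", cov = "AGE",
                                            form = "linear", ref = 33,
                                            th1 = 0.0410, th2 = 0,
                                            estim = TRUE,
                                            stringsAsFactors = FALSE),
                     omega2 = NULL, estim_omega2 = NULL,
                     sigma = NULL, estim_sigma = TRUE,
                     blq = c("omit", "m3"),
                     n_transit = 3L, n_occ = 3L, ref_wt = 52,
                     allo_cl = 0.75, allo_v = 1,
                     lloq = 1.2, salt_factor = 0.577) {
  v <- pq_variances()
  if (is.null(omega2))
    omega2 <- c(v$omega2_bsv[c("CL", "Vc", "Vp1", "Q2", "MTT")],
                F_IOV = unname(v$omega2_iov["F"]),
                MTT_IOV = unname(v$omega2_iov["MTT"]))
  om <- c(CL = 0, Vc = 0, Vp1 = 0, Q2 = 0, MTT = 0, F_IOV = 0, MTT_IOV = 0)
  om[names(omega2)] <- unname(omega2)
  if (is.null(estim_omega2)) estim_omega2 <- om > 0
  eo <- om > 0 & FALSE
  eo[names(estim_omega2)] <- unname(estim_omega2)
  eo <- eo & om > 0
  if (is.null(sigma)) sigma <- v$sigma
  if (!is.null(relations) && nrow(relations)) {
    stopifnot(all(relations$param %in% names(.PARAM_CODES)),
              all(relations$form %in% names(.FORM_CODES)))
    if (is.null(relations$th2)) relations$th2 <- 0
    if (is.null(relations$estim)) relations$estim <- TRUE
  } else {
    relations <- data.frame(param = character(), cov = character(),
                            form = character(), ref = numeric(),
                            th1 = numeric(), th2 = numeric(),
                            estim = logical(), stringsAsFactors = FALSE)
  }
  m <- list(theta = theta, estim_theta = estim_theta,
            dose_slope = dose_slope, estim_dose_slope = estim_dose_slope,
            relations = relations, omega2 = om, estim_omega2 = eo,
            sigma = sigma, estim_sigma = estim_sigma,
            blq = match.arg(blq), n_transit = as.integer(n_transit),
            n_occ = as.integer(n_occ), ref_wt = ref_wt,
            allo_cl = allo_cl, allo_v = allo_v, lloq = lloq,
            salt_factor = salt_factor,
            cov_names = c("WT", "AGE", "SEX", "FOOD"))
  class(m) <- "pq_model"
  m
}

#' Add a covariate relationship to a model specification
#'
#' @param spec [pq_model()].
#' @param param structural parameter name (e.g. `"F"`, `"MTT"`, `"Vp1"`).
#' @param cov covariate column name (`"WT"`, `"AGE"`, `"SEX"`, `"FOOD"`).
#' @param form functional form: `"linear"`, `"power"`, `"exponential"` or
#'   `"piecewise"`.
#' @param ref centering reference (NA: dataset median, resolved at fit time).
#' @param th1,th2 initial slopes (`th2` only for piecewise).
#' @param estim estimate the slope(s)?
#' @return The augmented `pq_model`.
#' @export
pq_add_relation <- function(spec, param, cov, form = "linear", ref = NA,
                            th1 = 0, th2 = 0, estim = TRUE) {
  stopifnot(inherits(spec, "pq_model"),
            param %in% names(.PARAM_CODES),
            form %in% names(.FORM_CODES),
            cov %in% spec$cov_names)
  spec$relations <- rbind(spec$relations,
                          data.frame(param = param, cov = cov, form = form,
                                     ref = ref, th1 = th1, th2 = th2,
                                     estim = estim, stringsAsFactors = FALSE))
  spec
}

.subject_covs <- function(spec, wt, age, sex, food) {
  stats::setNames(c(wt, age, sex, food), spec$cov_names)
}

# spec -> flat list consumed by the C++ kernels
.model_list <- function(spec) {
  r <- spec$relations
  list(theta = as.numeric(spec$theta[c("CL", "Vc", "Q1", "Vp1", "Q2", "Vp2",
                                       "MTT", "F")]),
       dose_slope = spec$dose_slope,
       rel_param = unname(.PARAM_CODES[r$param]),
       rel_cov = match(r$cov, spec$cov_names) - 1L,
       rel_form = unname(.FORM_CODES[r$form]),
       rel_ref = as.numeric(r$ref),
       rel_th1 = as.numeric(r$th1),
       rel_th2 = as.numeric(r$th2),
       omega2 = as.numeric(spec$omega2[c("CL", "Vc", "Vp1", "Q2", "MTT",
                                         "F_IOV", "MTT_IOV")]),
       sigma = spec$sigma,
       ref_wt = spec$ref_wt, allo_cl = spec$allo_cl, allo_v = spec$allo_v,
       n_transit = spec$n_transit, n_occ = spec$n_occ, lloq = spec$lloq)
}

# dataset -> list of per-subject records for the C++ engine.
# Drops the predose baseline (no drug on board) and, under the "omit"
# policy, all BLQ records.
.build_subjects <- function(dataset, spec) {
  stopifnot(is.data.frame(dataset))
  need <- c("ID", "TIME", "EVID", "AMT", "DV", "BLQ", "OCC", "WT", "AGE",
            "SEX", "FOOD")
  if (!all(need %in% names(dataset)))
    stop("dataset lacks columns: ",
         paste(setdiff(need, names(dataset)), collapse = ", "))
  ids <- unique(dataset$ID)
  subjects <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    d <- dataset[dataset$ID == ids[k], ]
    dose <- d[d$EVID == 1L, ]
    obs <- d[d$EVID == 0L, ]
    if (!nrow(dose)) stop("subject ", ids[k], " has no dose records")
    obs <- obs[obs$TIME > min(dose$TIME), , drop = FALSE]
    if (spec$blq == "omit") obs <- obs[obs$BLQ == 0L, , drop = FALSE]
    y <- ifelse(obs$BLQ == 1L, 0, log(pmax(obs$DV, 1e-12)))
    subjects[[k]] <- list(tobs = obs$TIME, y = y,
                          blq = as.integer(obs$BLQ),
                          dose_time = dose$TIME,
                          dose_amt = dose$AMT * spec$salt_factor,
                          dose_occ = as.integer(dose$OCC),
                          wt = dose$WT[1],
                          covs = .subject_covs(spec, dose$WT[1], dose$AGE[1],
                                               dose$SEX[1], dose$FOOD[1]))
  }
  names(subjects) <- ids
  subjects
}

# resolve NA covariate references to dataset medians
.resolve_refs <- function(spec, dataset) {
  r <- spec$relations
  if (nrow(r)) {
    for (i in seq_len(nrow(r))) {
      if (is.na(r$ref[i])) {
        obs1 <- dataset[!duplicated(dataset$ID), ]
        r$ref[i] <- median(obs1[[r$cov[i]]])
      }
    }
  }
  spec$relations <- r
  spec
}

# ---------------------------------------------------------------------------
# Free-parameter packing: log scale for positives, raw for covariate slopes.
# ---------------------------------------------------------------------------

#' @keywords internal
.pq_pack <- function(spec, covstats = NULL) {
  par <- numeric(0); lower <- numeric(0); upper <- numeric(0)
  nm <- character(0)
  add <- function(name, value, lo, hi) {
    par <<- c(par, value); lower <<- c(lower, lo); upper <<- c(upper, hi)
    nm <<- c(nm, name)
  }
  for (p in names(spec$theta))
    if (isTRUE(spec$estim_theta[[p]]))
      add(paste0("lt_", p), log(spec$theta[[p]]),
          log(spec$theta[[p]]) - 5, log(spec$theta[[p]]) + 5)
  if (isTRUE(spec$estim_dose_slope))
    add("dose_slope", spec$dose_slope,
        -0.999 / max(spec$n_occ - 1, 1), 10)
  r <- spec$relations
  if (nrow(r)) for (i in seq_len(nrow(r))) {
    if (!isTRUE(r$estim[i])) next
    bounds <- .slope_bounds(r$form[i], r$ref[i], covstats[[r$cov[i]]])
    add(paste0("rel1_", r$param[i], "_", r$cov[i], "_", i),
        r$th1[i], bounds[1], bounds[2])
    if (r$form[i] == "piecewise")
      add(paste0("rel2_", r$param[i], "_", r$cov[i], "_", i),
          r$th2[i], bounds[1], bounds[2])
  }
  for (p in names(spec$omega2))
    if (isTRUE(spec$estim_omega2[[p]]))
      add(paste0("lo_", p), log(spec$omega2[[p]]), log(1e-5), log(5))
  if (isTRUE(spec$estim_sigma))
    add("lsig", log(spec$sigma), log(5e-3), log(2))
  names(par) <- nm
  list(par = par, lower = lower, upper = upper)
}

# slope bounds keeping 1 + th * (x - ref) positive over the covariate range
.slope_bounds <- function(form, ref, range) {
  if (form %in% c("power")) return(c(-20, 20))
  if (form %in% c("exponential")) return(c(-5, 5))
  if (is.null(range) || is.na(ref)) return(c(-10, 10))
  lo <- if (range[2] > ref) -0.999 / (range[2] - ref) else -10
  hi <- if (range[1] < ref) 0.999 / (ref - range[1]) else 10
  c(lo, hi)
}

#' @keywords internal
.pq_unpack <- function(spec, par) {
  nm <- names(par)
  for (p in names(spec$theta)) {
    key <- paste0("lt_", p)
    if (key %in% nm) spec$theta[[p]] <- exp(par[[key]])
  }
  if ("dose_slope" %in% nm) spec$dose_slope <- par[["dose_slope"]]
  r <- spec$relations
  if (nrow(r)) for (i in seq_len(nrow(r))) {
    k1 <- paste0("rel1_", r$param[i], "_", r$cov[i], "_", i)
    k2 <- paste0("rel2_", r$param[i], "_", r$cov[i], "_", i)
    if (k1 %in% nm) r$th1[i] <- par[[k1]]
    if (k2 %in% nm) r$th2[i] <- par[[k2]]
  }
  spec$relations <- r
  for (p in names(spec$omega2)) {
    key <- paste0("lo_", p)
    if (key %in% nm) spec$omega2[[p]] <- exp(par[[key]])
  }
  if ("lsig" %in% nm) spec$sigma <- exp(par[["lsig"]])
  spec
}

.covstats <- function(dataset, spec) {
  one <- dataset[!duplicated(dataset$ID), ]
  out <- lapply(spec$cov_names, function(cn) range(one[[cn]]))
  names(out) <- spec$cov_names
  out
}
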