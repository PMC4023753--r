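# Study-design emulation: dosing regimen, rich sampling schedule,
# demographic sampling and dataset simulation.

#' Study design of the food-effect trial
#'
#' Fifteen fed and fifteen fasting adults, weight-based once-daily dosing for
#' three days targeting 18 mg piperaquine phosphate/kg/day with 320-mg
#' tablets, rich sampling after each dose (predose and 0.5, 1, 2, 3, 4, 7,
#' 24 h after dose 1; 1, 3, 4, 5, 7, 24 h after dose 2; 1, 2, 3, 4, 5, 6, 8,
#' 12 h after dose 3) plus follow-up on days 4, 5, 7, 14, 21, 28, 42, 56,
#' 70, 84, 98, 112 and 126, and a lower limit of quantification of
#' 1.2 ng/ml.
#'
#' @param n_fed,n_fasting subject counts per arm.
#' @param dose_times dose times (h).
#' @param lloq lower limit of quantification (ng/ml).
#' @param target_dose daily target dose, mg piperaquine phosphate per kg.
#' @param tablet_mg tablet strength, mg phosphate.
#' @param sampling_offsets list of within-occasion sampling offsets (h after
#'   each dose); first occasion includes the predose 0 h sample.
#' @param followup_days follow-up sampling days after the first dose.
#' @return List of class `pq_design`.
#' @export
pq_design <- function(n_fed = 15, n_fasting = 15,
                      dose_times = c(0, 24, 48),
                      lloq = 1.2, target_dose = 18, tablet_mg = 320,
                      sampling_offsets = list(c(0, 0.5, 1, 2, 3, 4, 7, 24),
                                              c(1, 3, 4, 5, 7, 24),
                                              c(1, 2, 3, 4, 5, 6, 8, 12)),
                      followup_days = c(4, 5, 7, 14, 21, 28, 42, 56, 70, 84,
                                        98, 112, 126)) {
  if (n_fed + n_fasting <= 0) stop("empty design")
  if (lloq <= 0) stop("'lloq' must be positive")
  if (length(sampling_offsets) != length(dose_times))
    stop("one offset set per dose occasion required")
  d <- list(n_fed = n_fed, n_fasting = n_fasting, dose_times = dose_times,
            lloq = lloq, target_dose = target_dose, tablet_mg = tablet_mg,
            sampling_offsets = sampling_offsets,
            followup_days = followup_days)
  class(d) <- "pq_design"
  d
}

#' Nominal sampling times of a design
#'
#' @param design [pq_design()].
#' @return Sorted vector of nominal sampling times (h after first dose).
#' @export
pq_schedule <- function(design) {
  tt <- unlist(lapply(seq_along(design$dose_times), function(i)
    design$dose_times[i] + design$sampling_offsets[[i]]))
  sort(unique(c(tt, design$followup_days * 24)))
}

#' Demographic covariate distributions
#'
#' Weight and age are drawn from scaled Beta distributions matched per arm to
#' the published medians and ranges (the only published shape information);
#' weight and age are sampled independently.  Sex is 13 males to 2 females
#' per arm.
#'
#' @param weight,age per-arm list(`fasting = c(lo, med, hi)`, `fed = ...`).
#' @param p_male probability of male sex.
#' @return List of class `pq_covdist`.
#' @export
pq_covdist <- function(weight = list(fasting = c(39, 50, 62),
                                     fed = c(45, 53, 73)),
                       age = list(fasting = c(18, 38, 55),
                                  fed = c(19, 28, 45)),
                       p_male = 13 / 15) {
  cd <- list(weight = weight, age = age, p_male = p_male)
  class(cd) <- "pq_covdist"
  cd
}

# Beta(a, b) scaled to [lo, hi] with median at med (a fixed at 2,
# b from the (a - 1/3)/(a + b - 2/3) median approximation)
.rbeta_med <- function(n, lo, med, hi, a = 2) {
  p <- (med - lo) / (hi - lo)
  b <- max((a - 1 / 3) / p - a + 2 / 3, 0.2)
  lo + (hi - lo) * rbeta(n, a, b)
}

.subject_seed <- function(seed, id) {
  (((seed %% 1000003) + 1) * 7919 + id * 104729) %% 2147483629L + 1L
}

#' Sample a virtual study population
#'
#' Draws demographics per subject from the covariate distributions and
#' assigns the weight-based dose: the three-day course is rounded to whole
#' 320-mg tablets, conservatively (rounded down unless within a quarter
#' tablet of the next count, `floor(weight * 54 / 320 + 0.25)`), and split
#' evenly over the three doses.  This reproduces the administered dose
#' spread of the study (median close to 17.5 mg phosphate/kg/day, range
#' about 16 to 18.8).  Each subject has an independent random substream
#' derived from `seed`, so enlarging the population never perturbs existing
#' subjects.
#'
#' @param design [pq_design()].
#' @param cov_dist [pq_covdist()].
#' @param seed integer seed (>= 0).
#' @return data.frame with id, food (0/1), wt, age, sex (1 = male), tablets
#'   and dose_mg (daily dose, mg phosphate).
#' @export
sample_population <- function(design = pq_design(), cov_dist = pq_covdist(),
                              seed = 1) {
  if (design$n_fed + design$n_fasting <= 0) stop("empty design")
  if (seed < 0) stop("'seed' must be non-negative")
  n <- design$n_fed + design$n_fasting
  food <- c(rep(1L, design$n_fed), rep(0L, design$n_fasting))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    arm <- if (food[i] == 1L) "fed" else "fasting"
    w <- cov_dist$weight[[arm]]
    a <- cov_dist$age[[arm]]
    set.seed(.subject_seed(seed, i))
    wt <- .rbeta_med(1, w[1], w[2], w[3])
    age <- .rbeta_med(1, a[1], a[2], a[3])
    sex <- rbinom(1, 1, cov_dist$p_male)
    course_tablets <- floor(wt * 3 * design$target_dose / design$tablet_mg +
                              0.25)
    out[[i]] <- data.frame(id = i, food = food[i], wt = wt, age = age,
                           sex = sex, tablets = course_tablets / 3,
                           dose_mg = course_tablets * design$tablet_mg / 3)
  }
  do.call(rbind, out)
}

# occasion of an observation: doses strictly before it (trough samples at a
# dose time belong to the previous occasion); clamped to 1
.obs_occasion <- function(time, dose_times) {
  pmax(1L, vapply(time, function(t) sum(dose_times < t), 0L))
}

#' Simulate a study dataset under the mixed-effects model
#'
#' Draws subject-level (BSV) and occasion-level (IOV) random effects,
#' computes each subject's concentration profile at the design's nominal
#' times through the same prediction kernel used by the estimation engine,
#' adds additive residual noise on the log scale, and censors observations
#' below the LLOQ (value withheld, BLQ flag set).  The predose 0 h sample of
#' drug-naive patients is a true zero and is flagged BLQ.  Per-subject
#' random substreams keep subjects independent of cohort size.
#'
#' @param subjects data.frame from [sample_population()].
#' @param model [pq_model()] carrying structural, covariate and variance
#'   parameters.
#' @param variances optional [pq_variances()] overriding the model's
#'   `omega2`/`sigma`.
#' @param seed integer seed (>= 0).
#' @param design [pq_design()].
#' @return A `pq_dataset` data.frame in the exchange dialect (columns ID,
#'   TIME, EVID, AMT, DV, BLQ, OCC, WT, AGE, SEX, FOOD).
#' @export
simulate_dataset <- function(subjects, model = pq_model(), variances = NULL,
                             seed = 1, design = pq_design()) {
  if (seed < 0) stop("'seed' must be non-negative")
  if (!is.null(variances)) {
    model$omega2 <- c(CL = 0, Vc = 0, Vp1 = 0, Q2 = 0, MTT = 0,
                      F_IOV = 0, MTT_IOV = 0)
    model$omega2[names(variances$omega2_bsv)] <-
      unname(variances$omega2_bsv)
    model$omega2[paste0(names(variances$omega2_iov), "_IOV")] <-
      unname(variances$omega2_iov)
    model$sigma <- variances$sigma
  }
  ml <- .model_list(model)
  times <- pq_schedule(design)
  n_occ <- model$n_occ
  rows <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    set.seed(.subject_seed(seed + 500000L, s$id))
    eta <- numeric(5 + 2 * n_occ)
    eta[1:5] <- rnorm(5) * sqrt(ml$omega2[1:5])
    eta[5 + seq_len(n_occ)] <- rnorm(n_occ) * sqrt(ml$omega2[6])
    eta[5 + n_occ + seq_len(n_occ)] <- rnorm(n_occ) * sqrt(ml$omega2[7])
    eps <- rnorm(length(times)) * ml$sigma
    subj <- list(tobs = times, y = numeric(length(times)),
                 blq = integer(length(times)),
                 dose_time = design$dose_times,
                 dose_amt = rep(s$dose_mg * model$salt_factor, n_occ),
                 dose_occ = seq_len(n_occ), wt = s$wt,
                 covs = .subject_covs(model, s$wt, s$age, s$sex, s$food))
    logc <- cpp_pred_subject(subj, ml, eta)
    dv <- exp(logc + eps)
    blq <- as.integer(dv < design$lloq)
    dv[blq == 1L] <- NA_real_
    dose_rows <- data.frame(ID = s$id, TIME = design$dose_times, EVID = 1L,
                            AMT = s$dose_mg, DV = NA_real_, BLQ = 0L,
                            OCC = seq_len(n_occ), WT = s$wt, AGE = s$age,
                            SEX = s$sex, FOOD = s$food)
    obs_rows <- data.frame(ID = s$id, TIME = times, EVID = 0L,
                           AMT = NA_real_, DV = dv, BLQ = blq,
                           OCC = .obs_occasion(times, design$dose_times),
                           WT = s$wt, AGE = s$age, SEX = s$sex,
                           FOOD = s$food)
    r <- rbind(dose_rows, obs_rows)
    # dose rows precede the observations they affect; trough samples at a
    # dose time are drawn before that dose
    r <- r[order(r$TIME, -r$EVID), ]
    rows[[i]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pq_dataset", "data.frame")
  attr(out, "lloq") <- design$lloq
  out
}

#' Read and write the long-format exchange CSV dialect
#'
#' Header row, comma-separated, columns ID, TIME, EVID, AMT, DV, BLQ, OCC,
#' WT, AGE, SEX, FOOD; DV empty on dose rows and `"."` when withheld (BLQ);
#' times written with three decimals.
#'
#' @param x a `pq_dataset` data.frame.
#' @param path file path.
#' @return `read_pkdata()` returns a `pq_dataset`; `write_pkdata()` returns
#'   `path` invisibly.
#' @export
write_pkdata <- function(x, path) {
  out <- x
  out$TIME <- sprintf("%.3f", out$TIME)
  out$DV <- ifelse(is.na(x$DV), ".", sprintf("%.6g", x$DV))
  out$AMT <- ifelse(is.na(x$AMT), ".", sprintf("%.6g", x$AMT))
  out$WT <- sprintf("%.4g", x$WT)
  out$AGE <- sprintf("%.4g", x$AGE)
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pkdata
#' @export
read_pkdata <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("TIME", "AMT", "DV", "WT", "AGE")) {
    v <- x[[nm]]
    v[v == "."] <- NA
    x[[nm]] <- as.numeric(v)
  }
  for (nm in c("ID", "EVID", "BLQ", "OCC", "SEX", "FOOD"))
    x[[nm]] <- as.integer(x[[nm]])
  class(x) <- c("pq_dataset", "data.frame")
  x
}
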