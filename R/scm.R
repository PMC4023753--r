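# Covariate model building: stepwise search and the full covariate approach
# for the food effect.

#' Stepwise covariate model search
#'
#' Forward addition followed by backward deletion on a candidate set of
#' (parameter, covariate, functional form) triples.  At each forward step
#' every remaining candidate is added to the current model and refitted; the
#' candidate with the largest OFV drop is kept if the drop exceeds
#' `forward_dofv` (3.84, p < 0.05 at 1 df).  Backward deletion then removes,
#' one at a time, any retained candidate whose removal raises the OFV by
#' less than `backward_dofv` (6.63, p < 0.01 at 1 df).  Ties are broken
#' toward fewer added parameters, then lexicographically.
#'
#' @param dataset a `pq_dataset`.
#' @param spec_base base [pq_model()]; its own relations are permanent and
#'   not subject to deletion.
#' @param candidates data.frame with columns `param`, `cov`, `form`.
#' @param forward_dofv,backward_dofv likelihood-ratio thresholds (1 df).
#' @param control [pq_control()] for the candidate fits.
#' @return List of class `pq_scm`: `spec` (selected model), `log`
#'   (data.frame trail of every tested step with OFV changes) and
#'   `included` (retained candidate rows).
#' @export
scm_search <- function(dataset, spec_base = pq_model(), candidates,
                       forward_dofv = 3.84, backward_dofv = 6.63,
                       control = pq_control(iter_max = 80)) {
  stopifnot(is.data.frame(candidates))
  if (!nrow(candidates)) {
    return(structure(list(spec = spec_base,
                          log = data.frame(), included = candidates),
                     class = "pq_scm"))
  }
  candidates <- candidates[order(candidates$param, candidates$cov,
                                 candidates$form), , drop = FALSE]
  n_base_rel <- nrow(spec_base$relations)
  fit_spec <- function(sp) pq_fit(dataset, sp, control = control)
  base_fit <- fit_spec(spec_base)
  log_rows <- list()
  note <- function(phase, cand, dofv, kept) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      phase = phase, param = cand$param, cov = cand$cov, form = cand$form,
      dofv = dofv, kept = kept, stringsAsFactors = FALSE)
  }
  npar_of <- function(form) if (form == "piecewise") 2L else 1L
  included <- integer(0)  # row indices into candidates
  cur_spec <- spec_base
  cur_ofv <- base_fit$ofv
  remaining <- seq_len(nrow(candidates))
  # forward addition
  repeat {
    if (!length(remaining)) break
    trial <- lapply(remaining, function(i) {
      ci <- candidates[i, ]
      sp <- pq_add_relation(cur_spec, ci$param, ci$cov, ci$form)
      ft <- tryCatch(fit_spec(sp), error = function(e) NULL)
      if (is.null(ft)) return(list(dofv = -Inf, spec = NULL, ofv = NA))
      list(dofv = cur_ofv - ft$ofv, spec = ft$spec, ofv = ft$ofv)
    })
    dofv <- vapply(trial, function(t) t$dofv, 0)
    for (k in seq_along(remaining))
      note("forward", candidates[remaining[k], ], dofv[k], FALSE)
    ok <- which(dofv > forward_dofv)
    if (!length(ok)) break
    npar <- vapply(remaining[ok], function(i) npar_of(candidates$form[i]), 0L)
    best <- ok[order(-dofv[ok], npar)][1]
    i <- remaining[best]
    log_rows[[length(log_rows)]]$kept <- FALSE  # rewritten below
    note("forward-keep", candidates[i, ], dofv[best], TRUE)
    included <- c(included, i)
    cur_spec <- trial[[best]]$spec
    cur_ofv <- trial[[best]]$ofv
    remaining <- setdiff(remaining, i)
  }
  # backward deletion (only SCM-added relations are candidates for removal)
  repeat {
    if (!length(included)) break
    drops <- vapply(seq_along(included), function(k) {
      sp <- cur_spec
      sp$relations <- sp$relations[-(n_base_rel + k), , drop = FALSE]
      ft <- tryCatch(fit_spec(sp), error = function(e) NULL)
      if (is.null(ft)) return(Inf)
      ft$ofv - cur_ofv  # OFV rise on removal
    }, 0)
    weakest <- which.min(drops)
    if (drops[weakest] >= backward_dofv) break
    i <- included[weakest]
    note("backward-drop", candidates[i, ], drops[weakest], FALSE)
    sp <- cur_spec
    sp$relations <- sp$relations[-(n_base_rel + weakest), , drop = FALSE]
    ft <- fit_spec(sp)
    cur_spec <- ft$spec
    cur_ofv <- ft$ofv
    included <- included[-weakest]
  }
  structure(list(spec = cur_spec,
                 log = do.call(rbind, log_rows),
                 included = candidates[included, , drop = FALSE],
                 ofv = cur_ofv, base_ofv = base_fit$ofv),
            class = "pq_scm")
}

#' @export
#' @method print pq_scm
print.pq_scm <- function(x, ...) {
  cat("Stepwise covariate model search\n")
  if (nrow(x$included)) {
    cat("Retained relationships:\n")
    print(x$included, row.names = FALSE)
  } else cat("No covariate relationships retained.\n")
  if (!is.null(x$log) && nrow(x$log)) {
    cat("Search trail:\n")
    print(x$log, row.names = FALSE)
  }
  invisible(x)
}

#' Full covariate approach for the food effect
#'
#' Adds the categorical food effect simultaneously to the mean absorption
#' transit time and to relative bioavailability, fits both effects, and
#' bootstraps subjects stratified by food group to obtain percentile
#' distributions of the two effects (the clinical-relevance display).  By
#' default each bootstrap replicate re-estimates only the two food thetas
#' with the remaining parameters held at their point estimates
#' (`refit = "full"` re-estimates everything).
#'
#' @param dataset a `pq_dataset` containing both food groups.
#' @param spec_final final-model [pq_model()] (typically `fit$spec`).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param refit `"food"` (default) or `"full"`.
#' @param control [pq_control()] for the refits.
#' @return Object of class `pq_food`: point estimates, bootstrap draws and
#'   2.5-97.5 percentile intervals of `theta_food_MTT` and `theta_food_F`.
#' @export
full_covariate_food <- function(dataset, spec_final = pq_model(),
                                n_boot = 500, seed = 1,
                                refit = c("food", "full"),
                                control = pq_control(iter_max = 60)) {
  refit <- match.arg(refit)
  one <- dataset[!duplicated(dataset$ID), ]
  if (length(unique(one$FOOD)) < 2)
    stop("both food groups are required")
  sp <- pq_add_relation(spec_final, "MTT", "FOOD", "linear", ref = 0)
  sp <- pq_add_relation(sp, "F", "FOOD", "linear", ref = 0)
  if (refit == "food") sp <- .fix_all_but_relations(sp, tail_n = 2)
  point <- pq_fit(dataset, sp, control = control)
  nr <- nrow(point$spec$relations)
  get_food <- function(ft)
    c(MTT = ft$spec$relations$th1[nr - 1], F = ft$spec$relations$th1[nr])
  groups <- split(one$ID, one$FOOD)
  draws <- matrix(NA_real_, n_boot, 2,
                  dimnames = list(NULL, c("theta_food_MTT", "theta_food_F")))
  sp_b <- point$spec
  for (r in seq_len(n_boot)) {
    set.seed(.subject_seed(seed + 600000L, r))
    ids <- unlist(lapply(groups, function(g)
      sample(g, length(g), replace = TRUE)))
    bd <- .reindex_dataset(dataset, ids)
    ft <- tryCatch(pq_fit(bd, sp_b, control = control),
                   error = function(e) NULL)
    if (!is.null(ft)) draws[r, ] <- get_food(ft)
  }
  ok <- stats::complete.cases(draws)
  ci <- apply(draws[ok, , drop = FALSE], 2, quantile,
              probs = c(0.025, 0.975))
  structure(list(point = get_food(point), draws = draws[ok, , drop = FALSE],
                 ci = ci, n_boot = n_boot, n_ok = sum(ok), refit = refit),
            class = "pq_food")
}

# switch off every estimation flag except the last `tail_n` relations
.fix_all_but_relations <- function(spec, tail_n) {
  spec$estim_theta[] <- FALSE
  spec$estim_dose_slope <- FALSE
  spec$estim_omega2[] <- FALSE
  spec$estim_sigma <- FALSE
  n <- nrow(spec$relations)
  spec$relations$estim <- seq_len(n) > n - tail_n
  spec
}

#' @export
#' @method print pq_food
print.pq_food <- function(x, ...) {
  cat(sprintf("Full covariate approach: food on MTT and F (%d/%d bootstrap replicates)\n",
              x$n_ok, x$n_boot))
  out <- data.frame(estimate = x$point,
                    ci2.5 = x$ci[1, ], ci97.5 = x$ci[2, ])
  rownames(out) <- c("food on MTT", "food on F")
  print(signif(out, 3))
  invisible(x)
}

#' @export
#' @method plot pq_food
plot.pq_food <- function(x, ...) {
  boxplot(x$draws, names = c("MTT", "F"),
          ylab = "Estimated food effect (fraction)", ...)
  abline(h = c(-0.25, 0, 0.25), lty = c(2, 1, 2), col = "grey50")
  invisible(x)
}
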