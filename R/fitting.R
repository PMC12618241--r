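# Maximum-likelihood fitting and information criteria.

#' Information criteria from a fitted likelihood
#'
#' `AIC = 2*nll + 2k` and `BIC = 2*nll + k*log(n)`, where `nll` is the
#' minimised negative log-likelihood, `k` the number of free parameters and
#' `n` the number of likelihood-contributing trials.
#'
#' @param nll negative log-likelihood at the optimum.
#' @param k number of free parameters.
#' @param n number of trials entering the likelihood (n >= 1).
#' @return list with elements `aic` and `bic`.
#' @export
information_criteria <- function(nll, k, n) {
  stopifnot(is_count(n), k >= 0)
  list(aic = 2 * nll + 2 * k, bic = 2 * nll + k * log(n))
}

#' Fit a model to one participant's choices
#'
#' Minimises the negative log-likelihood over the model's bounded
#' parameter space with differential evolution ([de_optim()], default 500
#' generations), then polishes the best point with bounded L-BFGS-B.
#' `phase = "pre"` truncates the session at the phase boundary to
#' reproduce pre-changepoint-only fits; post-only fitting is rejected
#' because the value history preceding the changepoint would be missing.
#' `qasymm2` requires a dataset with a changepoint (its post rates are
#' inert otherwise) and is flagged degenerate on `"none"`/pre-only data.
#'
#' @param model model name (see [ti_models()]).
#' @param data a `ti_data` with recorded choices.
#' @param phase `"all"` (default) or `"pre"`.
#' @param likelihood `"all"` or `"feedback"` (see
#'   [negative_log_likelihood()]).
#' @param maxiter,popsize,tol differential-evolution settings.
#' @param seed optimiser seed; refits with the same seed are identical.
#' @param init optional warm-start points (rows of parameter vectors).
#' @param polish run a bounded quasi-Newton refinement after DE.
#' @return object of class `ti_fit`: `model`, `par` (named), `nll`, `aic`,
#'   `bic`, `k`, `n_trials`, `phase`, `likelihood`, `seed`, `converged`,
#'   `iterations`, `n_evaluations`.
#' @export
fit_model <- function(model, data, phase = c("all", "pre"),
                      likelihood = c("all", "feedback"), maxiter = 500,
                      popsize = NULL, tol = 1e-7, seed = 1L, init = NULL,
                      polish = TRUE) {
  phase <- match.arg(phase)
  likelihood <- match.arg(likelihood)
  spec <- model_spec(model)
  stopifnot(inherits(data, "ti_data"))
  if (phase == "pre") data <- truncate_pre(data)
  if (spec$name == "qasymm2" && !any(data$session$trials$phase == "post"))
    stop("degenerate fit: qasymm2 needs post-changepoint trials ",
         "(its post rates are otherwise inert)", call. = FALSE)
  tr <- data$session$trials
  chosen <- data$responses$chosen_item
  use <- !data$responses$missed & !is.na(chosen)
  if (likelihood == "feedback") use <- use & tr$feedback
  if (!any(use)) stop("empty dataset: nothing to fit", call. = FALSE)
  chose_hi <- chosen == tr$correct_item
  left <- as.integer(tr$left_item)
  right <- as.integer(tr$right_item)
  corr <- as.integer(tr$correct_item)
  fb <- tr$feedback
  post <- tr$phase == "post"
  n_items <- data$session$n_items
  code <- spec$code
  obj <- function(par) {
    p_hi <- ti_probs_cpp(code, par, left, right, corr, fb, post, n_items)
    pr <- ifelse(chose_hi, p_hi, 1 - p_hi)
    -sum(log(pmax(pr[use], 1e-12)))
  }
  de <- de_optim(obj, spec$lower, spec$upper, maxiter = maxiter,
                 popsize = popsize, tol = tol, seed = seed, init = init)
  par <- de$par
  val <- de$value
  if (polish) {
    pol <- tryCatch(
      optim(par, obj, method = "L-BFGS-B", lower = spec$lower,
            upper = spec$upper),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value) && pol$value < val) {
      par <- pmin(pmax(pol$par, spec$lower), spec$upper)
      val <- pol$value
    }
  }
  names(par) <- spec$par_names
  n_used <- sum(use)
  ic <- information_criteria(val, spec$k, n_used)
  structure(
    list(model = spec$name, par = par, nll = val, aic = ic$aic,
         bic = ic$bic, k = spec$k, n_trials = n_used, phase = phase,
         likelihood = likelihood, seed = seed, converged = de$converged,
         iterations = de$iterations, n_evaluations = de$n_evaluations),
    class = "ti_fit")
}

#' @export
print.ti_fit <- function(x, ...) {
  cat("<ti_fit> ", x$model, " (", x$phase, " trials): nll=",
      round(x$nll, 3), ", AIC=", round(x$aic, 2), ", BIC=",
      round(x$bic, 2), "\n  ", sep = "")
  cat(paste(names(x$par), signif(x$par, 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Warm-start expansions along the nesting chain qsymm -> qasymm -> qasymm2.
nested_starts <- function(model, fits) {
  starts <- NULL
  if (model == "qasymm" && !is.null(fits$qsymm)) {
    p <- fits$qsymm$par
    starts <- rbind(starts, c(p[["alpha"]], p[["alpha"]], p[["eta"]],
                              p[["tau"]]))
  }
  if (model == "qasymm2") {
    if (!is.null(fits$qasymm)) {
      p <- fits$qasymm$par
      starts <- rbind(starts,
                      c(p[["alpha_plus"]], p[["alpha_minus"]],
                        p[["alpha_plus"]], p[["alpha_minus"]],
                        p[["eta"]], p[["tau"]]))
    }
    if (!is.null(fits$qsymm)) {
      p <- fits$qsymm$par
      starts <- rbind(starts, c(rep(p[["alpha"]], 4L), p[["eta"]],
                                p[["tau"]]))
    }
  }
  if (model == "qadapt" && !is.null(fits$qasymm)) {
    # omega = 0 collapses qadapt onto qasymm with alpha_minus = 0; seed the
    # matching one-sided start in the direction of the fitted bias
    p <- fits$qasymm$par
    a0 <- if (p[["alpha_plus"]] >= p[["alpha_minus"]])
      min(0.5, p[["alpha_plus"]]) else max(-0.5, -p[["alpha_minus"]])
    starts <- rbind(starts, c(a0, 0, p[["eta"]], p[["tau"]]))
  }
  starts
}

#' Fit several models to one participant
#'
#' Fits each requested model in nesting order, warm-starting richer models
#' from the optimum of the models they nest (qsymm inside qasymm inside
#' qasymm2; qadapt from the one-sided qasymm collapse), which keeps the
#' analytic ordering `nll(qasymm) <= nll(qsymm)` intact at reduced
#' iteration budgets.
#'
#' @param data a `ti_data`.
#' @param models model names (default all four).
#' @param ... passed to [fit_model()].
#' @return named list of `ti_fit`.
#' @export
fit_models <- function(data, models = ti_models(), ...) {
  order_pref <- intersect(ti_models(), models)
  fits <- list()
  for (m in order_pref)
    fits[[m]] <- fit_model(m, data, init = nested_starts(m, fits), ...)
  fits
}

#' Tidy table of fits
#'
#' @param fits a named list of `ti_fit` (one participant) or a list of
#'   such lists (a cohort); for a cohort, names or `participant_ids` label
#'   the rows.
#' @param participant_ids optional ids for the cohort case.
#' @return data.frame with one row per (participant, model).
#' @export
fit_table <- function(fits, participant_ids = NULL) {
  if (inherits(fits[[1L]], "ti_fit")) fits <- list(fits)
  ids <- participant_ids %||% names(fits) %||%
    sprintf("p%02d", seq_along(fits))
  rbind_fill(lapply(seq_along(fits), function(i) {
    rbind_fill(lapply(fits[[i]], function(f) {
      row <- data.frame(participant_id = ids[i], model = f$model,
                        nll = f$nll, aic = f$aic, bic = f$bic, k = f$k,
                        n_trials = f$n_trials, seed = f$seed,
                        converged = f$converged)
      for (nm in names(f$par)) row[[nm]] <- f$par[[nm]]
      row
    }))
  }))
}

#' Per-participant AIC (or BIC) matrix from cohort fits
#'
#' @param cohort_fits list (participants) of named lists of `ti_fit`.
#' @param criterion `"aic"` or `"bic"`.
#' @return numeric matrix, participants x models.
#' @export
criterion_matrix <- function(cohort_fits, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  models <- names(cohort_fits[[1L]])
  out <- t(vapply(cohort_fits,
                  function(fs) vapply(fs, function(f) f[[criterion]],
                                      numeric(1))[models],
                  numeric(length(models))))
  colnames(out) <- models
  out
}
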