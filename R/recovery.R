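# Model- and parameter-recovery suites, plus generative model validation.

# Recovery sampling regimes: one preset per generating model, chosen so
# each model sits where it is identifiable from its competitors (see the
# methods vignette).  In particular, qasymm draws its loser rate away from
# 0: at alpha_minus = 0 the model coincides with qadapt at omega = 0 and
# the generating model would be undecidable in principle.
recovery_sampler <- function(model) {
  eta <- c(1, 2.5)
  tau <- c(0.1, 0.3)
  switch(model,
    qsymm = list(alpha = c(0.1, 0.3), eta = eta, tau = tau),
    qasymm = list(alpha_plus = c(0.25, 0.45), alpha_minus = c(0.08, 0.2),
                  eta = eta, tau = tau),
    qasymm2 = param_preset("winner", "qasymm2"),  # pre/post bias reversal
    qadapt = list(alpha0 = c(0.25, 0.45), omega = c(0.7, 1), eta = eta,
                  tau = tau))
}

#' Model recovery: confusion of generating vs best-fitting model
#'
#' For each generating model, simulates `n_agents` synthetic participants
#' (parameters from that model's recovery preset, fresh session designs,
#' Bernoulli choices), fits all candidate models to each, and tallies the
#' winner under the chosen criterion.  Ties within 1e-6 go to the model
#' with fewer parameters.
#'
#' @param models candidate (and generating) model names.
#' @param n_agents simulated participants per generating model.
#' @param seed master seed; the whole suite is reproducible from it.
#' @param criterion `"aic"` (default) or `"bic"`.
#' @param maxiter,popsize optimiser budget per fit (reduced defaults for
#'   desk-scale runs).
#' @param conditions changepoint directions cycled over agents.
#' @return list of class `ti_recovery`: `confusion` (generating x
#'   best-fitting counts), `details` (per-agent table), `criterion`.
#' @export
model_recovery <- function(models = ti_models(), n_agents = 5, seed = 1L,
                           criterion = c("aic", "bic"), maxiter = 60,
                           popsize = 16, conditions = c("up", "down")) {
  criterion <- match.arg(criterion)
  if (length(models) < 2L) stop("need at least two models", call. = FALSE)
  confusion <- matrix(0L, length(models), length(models),
                      dimnames = list(generating = models, best = models))
  details <- list()
  withr::with_seed(seed, {
    for (gm in models) {
      spec <- model_spec(gm)
      sampler <- recovery_sampler(gm)
      for (a in seq_len(n_agents)) {
        sseed <- draw_seeds(1L)
        params <- sample_params(spec, sampler)
        cond <- conditions[(a - 1L) %% length(conditions) + 1L]
        session <- generate_session(cond, seed = sseed)
        dat <- sample_choices(probability_dataset(gm, params, session),
                              seed = sseed %% 1000003L + 1L)
        fits <- fit_models(dat, models, maxiter = maxiter,
                           popsize = popsize, seed = sseed %% 99991L + 1L)
        crit <- vapply(fits, function(f) f[[criterion]], numeric(1))
        ks <- vapply(fits, function(f) f$k, numeric(1))
        best <- names(crit)[order(crit + 1e-6 * ks)][1L]
        # ties within 1e-6 resolved towards the simpler model
        near <- crit - min(crit) <= 1e-6
        if (sum(near) > 1L) best <- names(crit)[near][which.min(ks[near])]
        confusion[gm, best] <- confusion[gm, best] + 1L
        details[[length(details) + 1L]] <-
          data.frame(generating = gm, agent = a, condition = cond,
                     best = best, t(crit))
      }
    }
  })
  structure(list(confusion = confusion, details = do.call(rbind, details),
                 criterion = criterion),
            class = "ti_recovery")
}

#' @export
print.ti_recovery <- function(x, ...) {
  cat("<ti_recovery> criterion=", x$criterion, "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Parameter recovery for one model
#'
#' Simulates agents from the given model (parameters from `sampler`),
#' refits the same model, and reports generating vs recovered values with
#' Spearman rank correlations per parameter; for `qasymm` the asymmetry
#' index A is included.
#'
#' @param model model name.
#' @param n_agents number of simulated participants.
#' @param seed master seed.
#' @param sampler named list of `c(lo, hi)` ranges (defaults to the
#'   uniform preset spanning the bounds interior).
#' @param maxiter,popsize optimiser budget per fit.
#' @param conditions changepoint directions cycled over agents.
#' @return list of class `ti_param_recovery`: `pairs` (data.frame of
#'   generating and recovered values), `spearman` (named vector).
#' @export
parameter_recovery <- function(model, n_agents = 20, seed = 1L,
                               sampler = param_preset("uniform", model),
                               maxiter = 60, popsize = 16,
                               conditions = c("up", "down")) {
  spec <- model_spec(model)
  rows <- list()
  withr::with_seed(seed, {
    for (a in seq_len(n_agents)) {
      sseed <- draw_seeds(1L)
      params <- sample_params(spec, sampler)
      cond <- conditions[(a - 1L) %% length(conditions) + 1L]
      session <- generate_session(cond, seed = sseed)
      dat <- sample_choices(probability_dataset(model, params, session),
                            seed = sseed %% 1000003L + 1L)
      fit <- fit_model(model, dat, maxiter = maxiter, popsize = popsize,
                       seed = sseed %% 99991L + 1L)
      row <- data.frame(agent = a, condition = cond)
      for (nm in spec$par_names) {
        row[[paste0("gen_", nm)]] <- params[[nm]]
        row[[paste0("rec_", nm)]] <- fit$par[[nm]]
      }
      if (model == "qasymm") {
        row$gen_A <- asymmetry_index(params[["alpha_plus"]],
                                     params[["alpha_minus"]])
        row$rec_A <- if (sum(fit$par[c("alpha_plus", "alpha_minus")]) > 0)
          asymmetry_index(fit$par[["alpha_plus"]], fit$par[["alpha_minus"]])
        else NA_real_
      }
      rows[[a]] <- row
    }
  })
  pairs <- do.call(rbind, rows)
  vars <- c(spec$par_names, if (model == "qasymm") "A")
  rho <- vapply(vars, function(nm) {
    g <- pairs[[paste0("gen_", nm)]]
    r <- pairs[[paste0("rec_", nm)]]
    ok <- is.finite(g) & is.finite(r)
    if (sum(ok) < 3L) return(NA_real_)
    stats::cor(g[ok], r[ok], method = "spearman")
  }, numeric(1))
  structure(list(model = model, pairs = pairs, spearman = rho),
            class = "ti_param_recovery")
}

#' @export
print.ti_param_recovery <- function(x, ...) {
  cat("<ti_param_recovery> ", x$model, ", ", nrow(x$pairs), " agents\n",
      sep = "")
  print(round(x$spearman, 3))
  invisible(x)
}

#' Generative check: behavioural metrics of models simulated from fits
#'
#' Simulates each participant's fitted model on that participant's session
#' (probability-level, no sampling error) and computes the headline
#' behavioural metrics: pre-changepoint asymmetry slope and pre/post
#' non-anchor TI accuracy, supporting the changepoint-by-direction
#' contrast on simulated behaviour.
#'
#' @param fits list of `ti_fit`, one per participant.
#' @param sessions list of `ti_session`, matching `fits`.
#' @return data.frame with one row per participant: `model`, `condition`,
#'   `slope`, `acc_pre`, `acc_post`.
#' @export
generative_check <- function(fits, sessions) {
  stopifnot(length(fits) == length(sessions))
  do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    s <- sessions[[i]]
    pd <- probability_dataset(f$model, f$par, s,
                              sprintf("genchk%02d", i))
    slope <- asymmetry_slope(pd, phase = "pre")$slope
    acc <- vapply(c("pre", "post"), function(ph) {
      tt <- ti_trial_table(pd)
      n <- s$n_items
      keep <- tt$phase == ph & !tt$feedback &
        tt$left_rank_pre %in% 2:(n - 1) & tt$right_rank_pre %in% 2:(n - 1)
      mean(tt$accuracy[keep])
    }, numeric(1))
    data.frame(model = f$model, condition = s$condition, slope = slope,
               acc_pre = acc[["pre"]], acc_post = acc[["post"]])
  }))
}
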