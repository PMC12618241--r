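# Synthetic cohort generation: model-predicted choice probabilities,
# Bernoulli choice sampling, and cohorts standing in for the human groups.

#' Model-predicted choice probabilities over a session
#'
#' Runs the compiled stepping engine and returns, per trial, the
#' probability of choosing the ground-truth-higher item under the
#' hierarchy in force.  Deterministic given (model, params, session);
#' fitting and probability-level analyses use these values directly, which
#' avoids binomial sampling error from drawing discrete choices.
#'
#' @param model model name (see [ti_models()]).
#' @param params named parameter vector within the fitting bounds.
#' @param session a `ti_session`.
#' @param engine `"cpp"` (default, compiled) or `"r"` (reference
#'   implementation, identical results).
#' @return numeric vector, one probability per trial.
#' @export
simulate_probabilities <- function(model, params, session,
                                   engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  spec <- model_spec(model)
  par <- check_params(spec, params)
  if (engine == "r") return(simulate_agent(model, par, session)$trace$p_correct)
  tr <- session$trials
  ti_probs_cpp(spec$code, unname(par),
               as.integer(tr$left_item), as.integer(tr$right_item),
               as.integer(tr$correct_item), tr$feedback,
               tr$phase == "post", session$n_items)
}

# Construct a ti_data container.
new_ti_data <- function(session, participant_id, provenance, p_correct = NULL,
                        chosen_item = NULL, missed = NULL, params = NULL,
                        model = NULL) {
  nt <- nrow(session$trials)
  resp <- data.frame(trial = session$trials$trial)
  resp$p_correct <- if (is.null(p_correct)) NA_real_ else p_correct
  resp$chosen_item <- if (is.null(chosen_item)) NA_integer_ else
    as.integer(chosen_item)
  resp$missed <- if (is.null(missed)) rep(FALSE, nt) else missed
  resp$correct <- !resp$missed &
    resp$chosen_item == session$trials$correct_item
  resp$correct[resp$missed | is.na(resp$chosen_item)] <- NA
  structure(
    list(session = session, participant_id = participant_id,
         provenance = provenance, responses = resp,
         generating_model = model, generating_params = params),
    class = "ti_data")
}

#' @export
print.ti_data <- function(x, ...) {
  cat("<ti_data> participant=", x$participant_id, ", condition=",
      x$session$condition, ", ", nrow(x$responses), " trials, provenance=",
      x$provenance, "\n", sep = "")
  invisible(x)
}

#' Probability-level dataset for one simulated agent
#'
#' Wraps [simulate_probabilities()] output as a dataset whose "responses"
#' are the model's choice probabilities (provenance
#' `"simulated_probabilities"`); behavioural metrics treat the per-trial
#' probability of the correct choice as the accuracy value.
#'
#' @param model,params,session as in [simulate_probabilities()].
#' @param participant_id identifier stored with the dataset.
#' @return a `ti_data` object.
#' @export
probability_dataset <- function(model, params, session,
                                participant_id = "sim01") {
  p <- simulate_probabilities(model, params, session)
  new_ti_data(session, participant_id, "simulated_probabilities",
              p_correct = p, params = check_params(model_spec(model), params),
              model = model)
}

#' Sample binary choices from a probability-level dataset
#'
#' Each trial's choice is an independent Bernoulli draw of the
#' ground-truth-higher item with the model-predicted probability; missed
#' responses are injected independently at `miss_rate` and carry no choice.
#'
#' @param prob_data a `ti_data` with provenance
#'   `"simulated_probabilities"`.
#' @param seed integer seed.
#' @param miss_rate probability of a missed response per trial.
#' @return a `ti_data` with provenance `"simulated_choices"`.
#' @export
sample_choices <- function(prob_data, seed = 1L, miss_rate = 0) {
  stopifnot(inherits(prob_data, "ti_data"))
  p <- prob_data$responses$p_correct
  if (any(is.na(p) | p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  stopifnot(miss_rate >= 0, miss_rate <= 1)
  tr <- prob_data$session$trials
  other <- ifelse(tr$correct_item == tr$left_item, tr$right_item,
                  tr$left_item)
  withr::with_seed(seed, {
    pick_hi <- rbinom(length(p), 1L, p) == 1L
    missed <- rbinom(length(p), 1L, miss_rate) == 1L
  })
  chosen <- ifelse(pick_hi, tr$correct_item, other)
  chosen[missed] <- NA_integer_
  new_ti_data(prob_data$session, prob_data$participant_id,
              "simulated_choices", p_correct = p, chosen_item = chosen,
              missed = missed, params = prob_data$generating_params,
              model = prob_data$generating_model)
}

#' Parameter-sampling presets
#'
#' Uniform sampling boxes (one `c(lo, hi)` per parameter) used to generate
#' synthetic participants.  `"winner"` reflects the winner-biased regime
#' reported for human TI learners (`alpha_plus ~ U(0.15, 0.4)`,
#' `alpha_minus ~ U(0, 0.1)`), `"loser"` is its mirror, and `"uniform"`
#' spans the interior of the fitting bounds.  Presets for `qasymm2` and
#' `qadapt` place the models in regimes where their signature behaviour
#' (rate reset / preference-driven modulation) is expressed.
#'
#' @param preset `"winner"`, `"loser"` or `"uniform"`.
#' @param model model name.
#' @return named list of `c(lo, hi)` ranges.
#' @export
param_preset <- function(preset = c("winner", "loser", "uniform"),
                         model = "qasymm") {
  preset <- match.arg(preset)
  spec <- model_spec(model)
  # eta capped so the update gain alpha * eta stays <= 1: the winner update
  # then cannot overshoot its fixed point and value estimates remain on the
  # model's bounded (+-1) scale, as in fitted human participants
  eta <- c(1, 2.5)
  tau <- c(0.1, 0.3)
  win <- c(0.15, 0.4)
  los <- c(0, 0.1)
  out <- switch(spec$name,
    qsymm = list(alpha = c(0.05, 0.35), eta = eta, tau = tau),
    qasymm = switch(preset,
      winner = list(alpha_plus = win, alpha_minus = los, eta = eta, tau = tau),
      loser = list(alpha_plus = los, alpha_minus = win, eta = eta, tau = tau),
      uniform = list(alpha_plus = c(0.05, 0.45), alpha_minus = c(0.05, 0.45),
                     eta = c(0.5, 4), tau = c(0.05, 0.4))),
    qasymm2 = switch(preset,
      winner = list(alpha_plus_pre = win, alpha_minus_pre = los,
                    alpha_plus_post = los, alpha_minus_post = win,
                    eta = eta, tau = tau),
      loser = list(alpha_plus_pre = los, alpha_minus_pre = win,
                   alpha_plus_post = win, alpha_minus_post = los,
                   eta = eta, tau = tau),
      uniform = list(alpha_plus_pre = c(0.05, 0.45),
                     alpha_minus_pre = c(0.05, 0.45),
                     alpha_plus_post = c(0.05, 0.45),
                     alpha_minus_post = c(0.05, 0.45),
                     eta = c(0.5, 4), tau = c(0.05, 0.4))),
    qadapt = switch(preset,
      winner = list(alpha0 = c(0.2, 0.45), omega = c(0.6, 1), eta = eta,
                    tau = tau),
      loser = list(alpha0 = c(-0.45, -0.2), omega = c(0.6, 1), eta = eta,
                   tau = tau),
      uniform = list(alpha0 = c(-0.45, 0.45), omega = c(0, 1),
                     eta = c(0.5, 4), tau = c(0.05, 0.4))))
  # samplers must respect the model's fitting bounds
  for (nm in names(out)) {
    i <- match(nm, spec$par_names)
    if (out[[nm]][1] < spec$lower[i] || out[[nm]][2] > spec$upper[i])
      stop("sampler range for ", nm, " escapes the fitting bounds",
           call. = FALSE)
  }
  out
}

# Draw one parameter vector from a sampler (uses current RNG stream).
sample_params <- function(spec, sampler) {
  if (!identical(names(sampler), spec$par_names))
    stop("config error: sampler must name exactly the parameters ",
         paste(spec$par_names, collapse = ", "), call. = FALSE)
  vapply(sampler, function(r) {
    if (length(r) != 2L || r[2] < r[1])
      stop("config error: sampler ranges must be c(lo, hi)", call. = FALSE)
    runif(1L, r[1], r[2])
  }, numeric(1))
}

#' Cohort configuration
#'
#' @param n_up,n_down numbers of synthetic participants in the 'up' and
#'   'down' conditions.
#' @param model generating model name.
#' @param sampler named list of `c(lo, hi)` uniform ranges per parameter
#'   (see [param_preset()]); ranges must respect the fitting bounds.
#' @param seed master seed; each participant receives a derived sub-seed
#'   for their session design, parameters and choices.
#' @param miss_rate per-trial missed-response probability.
#' @param binary if `TRUE` sample Bernoulli choices, otherwise keep
#'   probability-level datasets.
#' @return a list of class `ti_cohort_config`.
#' @export
cohort_config <- function(n_up = 5, n_down = 5, model = "qasymm",
                          sampler = param_preset("winner", model),
                          seed = 1L, miss_rate = 0, binary = TRUE) {
  stopifnot(n_up >= 0, n_down >= 0, n_up + n_down >= 1)
  spec <- model_spec(model)
  if (!identical(names(sampler), spec$par_names))
    stop("config error: sampler parameters must match ",
         paste(spec$par_names, collapse = ", "), call. = FALSE)
  structure(list(n_up = n_up, n_down = n_down, model = model,
                 sampler = sampler, seed = seed, miss_rate = miss_rate,
                 binary = binary),
            class = "ti_cohort_config")
}

#' Generate a synthetic cohort
#'
#' Each synthetic participant receives a fresh randomised session design
#' (own item-to-rank allocation and trial order), parameters drawn from the
#' configured sampler, and either probability-level or sampled binary
#' responses.  Generating parameters are stored on each dataset.
#' Reproducible from the master seed.
#'
#' @param cfg a [cohort_config()].
#' @return list of `ti_data`, length `n_up + n_down`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_up = 2, n_down = 2, seed = 7))
#' sapply(cohort, function(d) d$session$condition)
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "ti_cohort_config"))
  spec <- model_spec(cfg$model)
  conds <- c(rep("up", cfg$n_up), rep("down", cfg$n_down))
  withr::with_seed(cfg$seed, {
    seeds <- draw_seeds(2L * length(conds))
    lapply(seq_along(conds), function(i) {
      pid <- sprintf("%s%02d", conds[i], sum(conds[seq_len(i)] == conds[i]))
      params <- with_seed_if(seeds[2L * i - 1L],
                             sample_params(spec, cfg$sampler))
      session <- generate_session(conds[i], seed = seeds[2L * i])
      pd <- probability_dataset(cfg$model, params, session, pid)
      if (cfg$binary)
        sample_choices(pd, seed = seeds[2L * i - 1L] %% 1000003L + 1L,
                       miss_rate = cfg$miss_rate)
      else pd
    })
  })
}

#' Cohort manifest table
#'
#' One row per participant: id, condition, generating model and
#' parameters.
#'
#' @param cohort list of `ti_data` from [generate_cohort()].
#' @return data.frame.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(d) {
    ps <- as.list(d$generating_params %||% numeric())
    cbind(data.frame(participant_id = d$participant_id,
                     condition = d$session$condition,
                     model = d$generating_model %||% NA_character_,
                     seed = d$session$seed),
          if (length(ps)) as.data.frame(ps) else NULL)
  }))
}
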