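# Candidate value-learning models and the pure-R stepping engine.
#
# All four agents share the same skeleton: on every trial the probability
# of choosing the ground-truth-higher item is a logistic function of the
# value difference; on feedback trials the winner (the higher-ranked item)
# and loser are updated with a difference-weighted Rescorla-Wagner rule
# whose winner/loser learning rates define the model family.

#' Names of the candidate models
#'
#' * `qsymm`: one shared learning rate (`alpha`) for winners and losers.
#' * `qasymm`: free winner (`alpha_plus`) and loser (`alpha_minus`) rates.
#' * `qasymm2`: like `qasymm` but with separate rate pairs before and after
#'   the changepoint (switching at the first moved-anchor feedback trial).
#' * `qadapt`: a signed base rate `alpha0` split across winner and loser on
#'   each feedback trial by the preference-dependent modulator
#'   [lambda_modulator()] with sensitivity `omega`.
#'
#' All models also carry the difference-scaling factor `eta` and the choice
#' temperature `tau`.
#'
#' @return character vector of model names.
#' @export
ti_models <- function() c("qsymm", "qasymm", "qasymm2", "qadapt")

#' Model specification: parameters, bounds, dimensionality
#'
#' Fitting bounds are the study defaults: learning rates in (0, 0.5), the
#' signed base rate in (-0.5, 0.5), `eta` in (0, 10), `tau` in (0, 1]
#' (floored at 1e-9 to exclude the deterministic-choice degenerate limit).
#'
#' @param name one of [ti_models()].
#' @return a list with `name`, `par_names`, `lower`, `upper` and `k` (the
#'   number of free parameters entering the AIC/BIC penalty).
#' @export
model_spec <- function(name = ti_models()) {
  name <- match.arg(name)
  tau_lo <- 1e-9
  spec <- switch(name,
    qsymm = list(
      par_names = c("alpha", "eta", "tau"),
      lower = c(0, 0, tau_lo), upper = c(0.5, 10, 1)),
    qasymm = list(
      par_names = c("alpha_plus", "alpha_minus", "eta", "tau"),
      lower = c(0, 0, 0, tau_lo), upper = c(0.5, 0.5, 10, 1)),
    qasymm2 = list(
      par_names = c("alpha_plus_pre", "alpha_minus_pre", "alpha_plus_post",
                    "alpha_minus_post", "eta", "tau"),
      lower = c(0, 0, 0, 0, 0, tau_lo), upper = c(0.5, 0.5, 0.5, 0.5, 10, 1)),
    qadapt = list(
      par_names = c("alpha0", "omega", "eta", "tau"),
      lower = c(-0.5, 0, 0, tau_lo), upper = c(0.5, 1, 10, 1)))
  spec$name <- name
  spec$k <- length(spec$par_names)
  spec$code <- match(name, ti_models())
  class(spec) <- "ti_model_spec"
  spec
}

# Validate and order a parameter vector against a spec.
check_params <- function(spec, params) {
  if (is.list(params)) params <- unlist(params)
  if (!is.null(names(params)) && all(spec$par_names %in% names(params)))
    params <- params[spec$par_names]
  if (length(params) != spec$k)
    stop("expected ", spec$k, " parameters (", paste(spec$par_names,
         collapse = ", "), ") for model ", spec$name, call. = FALSE)
  params <- as.numeric(params)
  if (any(params < spec$lower - 1e-12) || any(params > spec$upper + 1e-12))
    stop("parameters outside fitting bounds for model ", spec$name,
         call. = FALSE)
  names(params) <- spec$par_names
  params
}

#' Difference-weighted prediction term
#'
#' The relative difference `d = eta * (q_x - q_y)` that scales value
#' updates: an expected outcome (large positive difference) induces a small
#' update, a surprising one a large update.
#'
#' @param q_x,q_y current value estimates of winner and loser.
#' @param eta non-negative scaling factor.
#' @return numeric.
#' @export
relative_difference <- function(q_x, q_y, eta) {
  if (any(eta < 0)) stop("eta must be non-negative", call. = FALSE)
  eta * (q_x - q_y)
}

#' Logistic choice rule
#'
#' Probability of choosing item x over item y given their value estimates:
#' `1 / (1 + exp(-(q_x - q_y) / tau))`.
#'
#' @param q_x,q_y value estimates.
#' @param tau positive choice temperature.
#' @return probability in `[0, 1]`; complements sum to one.
#' @export
choice_prob <- function(q_x, q_y, tau) {
  if (any(tau <= 0)) stop("tau must be positive", call. = FALSE)
  1 / (1 + exp(-(q_x - q_y) / tau))
}

#' Preference-dependent asymmetry modulator
#'
#' `lambda = -4*omega*p^2 + 4*omega*p + 1 - omega`, a downward parabola in
#' the choice probability p, maximal (fully asymmetric updating, lambda =
#' 1) when the agent has no preference (p = 0.5) and minimal (lambda =
#' 1 - omega) when the preference is strong (p near 0 or 1).  With omega =
#' 0 the modulator is identically 1.
#'
#' @param p choice probability in `[0, 1]`.
#' @param omega sensitivity in `[0, 1]`.
#' @return lambda in `[1 - omega, 1]`.
#' @export
lambda_modulator <- function(p, omega) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (any(omega < 0 | omega > 1)) stop("omega must lie in [0, 1]", call. = FALSE)
  -4 * omega * p^2 + 4 * omega * p + 1 - omega
}

#' Split a signed base learning rate into winner and loser rates
#'
#' `alpha_plus = alpha0*(1+lambda)/2 - min(alpha0, 0)` and
#' `alpha_minus = alpha0*(1-lambda)/2 - min(alpha0, 0)`.  Both returned
#' rates are non-negative, they always sum to `|alpha0|`, and the sign of
#' `alpha0` fixes which rate dominates: the split can soften but never
#' reverse the agent's bias.
#'
#' @param alpha0 signed base rate in `[-0.5, 0.5]`.
#' @param lam modulator in `[0, 1]` (see [lambda_modulator()]).
#' @return named numeric `c(alpha_plus, alpha_minus)`.
#' @export
adapt_rates <- function(alpha0, lam) {
  shift <- ifelse(alpha0 < 0, alpha0, 0)
  c(alpha_plus = alpha0 * (1 + lam) / 2 - shift,
    alpha_minus = alpha0 * (1 - lam) / 2 - shift)
}

#' Learning-rate asymmetry index
#'
#' `A = (alpha_plus - alpha_minus) / |alpha_plus + alpha_minus|`: +1 is
#' full winner bias, -1 full loser bias, 0 symmetry.
#'
#' @param alpha_plus,alpha_minus non-negative learning rates, not both 0.
#' @return numeric in `[-1, 1]`.
#' @export
asymmetry_index <- function(alpha_plus, alpha_minus) {
  s <- alpha_plus + alpha_minus
  if (any(s == 0))
    stop("asymmetry index undefined when both learning rates are 0",
         call. = FALSE)
  (alpha_plus - alpha_minus) / abs(s)
}

#' Initialise an agent state
#'
#' Item values start at 0 (the symmetric mid-point of the bounded value
#' scale).
#'
#' @param n_items number of items.
#' @return list with element `q`, the value vector.
#' @export
init_agent <- function(n_items) list(q = rep(0, n_items))

#' Advance an agent by one trial
#'
#' Computes the probability of choosing the ground-truth-higher item, then
#' (feedback trials only) applies the difference-weighted, rectified
#' winner/loser updates with rates chosen by the model: static
#' (`qsymm`/`qasymm`), phase-dependent (`qasymm2`), or modulated by the
#' pre-update winner probability (`qadapt`).  Updates are keyed to the
#' feedback outcome, not to the choice; no-feedback trials leave values
#' untouched.
#'
#' @param model model name (see [ti_models()]).
#' @param params named parameter vector for the model.
#' @param state agent state from [init_agent()] or a previous step.
#' @param left,right item ids shown.
#' @param correct the ground-truth-higher item under the hierarchy in
#'   force.
#' @param feedback logical: is this an adjacent (feedback) trial?
#' @param post logical: is the trial in the post-changepoint phase
#'   (selects the `qasymm2` rate pair)?
#' @return list with `p` (probability of choosing `correct`), the new
#'   `state`, and the per-trial quantities `d`, `lambda`, `alpha_plus_t`,
#'   `alpha_minus_t` (NA on no-feedback trials).
#' @export
step_agent <- function(model, params, state, left, right, correct,
                       feedback, post = FALSE) {
  spec <- model_spec(model)
  par <- check_params(spec, params)
  q <- state$q
  hi <- correct
  lo <- if (left == hi) right else left
  if (hi == lo) stop("invalid context: winner and loser coincide",
                     call. = FALSE)
  tau <- par[["tau"]]
  eta <- par[["eta"]]
  p <- choice_prob(q[hi], q[lo], tau)
  lam <- NA_real_
  ap <- NA_real_
  am <- NA_real_
  d <- NA_real_
  if (feedback) {
    rates <- switch(spec$name,
      qsymm = c(par[["alpha"]], par[["alpha"]]),
      qasymm = c(par[["alpha_plus"]], par[["alpha_minus"]]),
      qasymm2 = if (post)
        c(par[["alpha_plus_post"]], par[["alpha_minus_post"]])
      else
        c(par[["alpha_plus_pre"]], par[["alpha_minus_pre"]]),
      qadapt = {
        lam <- lambda_modulator(p, par[["omega"]])
        adapt_rates(par[["alpha0"]], lam)
      })
    ap <- rates[[1L]]
    am <- rates[[2L]]
    d <- relative_difference(q[hi], q[lo], eta)
    up_w <- max(0, ap * (1 - d - q[hi]))
    up_l <- min(0, am * (-1 + d - q[lo]))
    q[hi] <- q[hi] + up_w
    q[lo] <- q[lo] + up_l
  }
  state$q <- q
  list(p = p, state = state, d = d, lambda = lam,
       alpha_plus_t = ap, alpha_minus_t = am)
}

#' Simulate an agent over a session (reference engine)
#'
#' Pure-R trial-by-trial simulation producing the full latent trace.  The
#' compiled engine used for fitting ([simulate_probabilities()]) computes
#' the same probabilities; the two implementations are held equal by the
#' test suite.
#'
#' @param model model name.
#' @param params named parameter vector.
#' @param session a `ti_session`.
#' @return list with `trace`, a data.frame (`trial`, `p_correct`, `d`,
#'   `lambda`, `alpha_plus_t`, `alpha_minus_t`), and `q`, the n_trials x
#'   n_items matrix of post-update value estimates.
#' @export
simulate_agent <- function(model, params, session) {
  spec <- model_spec(model)
  par <- check_params(spec, params)
  tr <- session$trials
  nt <- nrow(tr)
  q <- rep(0, session$n_items)
  qmat <- matrix(NA_real_, nt, session$n_items)
  p <- d <- lam <- apv <- amv <- rep(NA_real_, nt)
  post <- tr$phase == "post"
  hi_v <- tr$correct_item
  lo_v <- ifelse(tr$left_item == hi_v, tr$right_item, tr$left_item)
  tau <- par[["tau"]]
  eta <- par[["eta"]]
  for (t in seq_len(nt)) {
    hi <- hi_v[t]
    lo <- lo_v[t]
    pt <- 1 / (1 + exp(-(q[hi] - q[lo]) / tau))
    p[t] <- pt
    if (tr$feedback[t]) {
      rates <- switch(spec$name,
        qsymm = c(par[["alpha"]], par[["alpha"]]),
        qasymm = c(par[["alpha_plus"]], par[["alpha_minus"]]),
        qasymm2 = if (post[t])
          c(par[["alpha_plus_post"]], par[["alpha_minus_post"]])
        else
          c(par[["alpha_plus_pre"]], par[["alpha_minus_pre"]]),
        qadapt = {
          lam[t] <- lambda_modulator(pt, par[["omega"]])
          adapt_rates(par[["alpha0"]], lam[t])
        })
      apv[t] <- rates[[1L]]
      amv[t] <- rates[[2L]]
      d[t] <- eta * (q[hi] - q[lo])
      q[hi] <- q[hi] + max(0, apv[t] * (1 - d[t] - q[hi]))
      q[lo] <- q[lo] + min(0, amv[t] * (-1 + d[t] - q[lo]))
    }
    qmat[t, ] <- q
  }
  list(trace = data.frame(trial = tr$trial, p_correct = p, d = d,
                          lambda = lam, alpha_plus_t = apv,
                          alpha_minus_t = amv),
       q = qmat)
}

#' Post-changepoint discriminability of the unmoved (non-anchor) items
#'
#' Simulates one agent on matched 'up' and 'down' sessions (same seed, so
#' the same item-to-rank allocation) and returns, for each condition, the
#' mean over post-changepoint trials of the mean pairwise absolute value
#' difference among the five non-anchor items i2..i6.  Winner-biased
#' asymmetric agents compress the value space more after a 'down' than an
#' 'up' changepoint, so their 'down' discriminability is the lower one.
#'
#' @param model model name.
#' @param params named parameter vector.
#' @param seed session seed shared by the two conditions.
#' @return named numeric `c(up = , down = )`.
#' @export
discriminability_contrast <- function(model, params, seed = 1L) {
  one <- function(condition) {
    s <- generate_session(condition, seed = seed)
    sim <- simulate_agent(model, params, s)
    non_anchor <- which(s$hierarchy_pre$rank %in% 2:(s$n_items - 1))
    rows <- which(s$trials$phase == "post")
    qs <- sim$q[rows, non_anchor, drop = FALSE]
    mean(apply(qs, 1L, function(v) mean(abs(c(dist(v))))))
  }
  c(up = one("up"), down = one("down"))
}
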