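# Choice likelihood of a dataset under a model.

# Per-trial probability of the response actually made (NA where missed or
# no choice recorded).  Probabilities come from the stepping engine and do
# not depend on the choices, because updates are keyed to feedback.
response_probs <- function(model, params, data, engine = "cpp") {
  p_hi <- simulate_probabilities(model, params, data$session, engine)
  tr <- data$session$trials
  chosen <- data$responses$chosen_item
  out <- ifelse(chosen == tr$correct_item, p_hi, 1 - p_hi)
  out[data$responses$missed | is.na(chosen)] <- NA_real_
  out
}

#' Negative log-likelihood of a dataset under a model
#'
#' Sum over non-missed trials of minus the log probability the model
#' assigns to the response actually made.  By default both feedback and
#' no-feedback (TI) trials contribute to the likelihood, while only
#' feedback trials drive value updates; `likelihood = "feedback"` restricts
#' the sum to feedback trials for sensitivity analyses.  Probabilities are
#' floored at 1e-12 before the log to guard the deterministic-choice
#' limit.
#'
#' @param model model name (see [ti_models()]).
#' @param params named parameter vector within bounds.
#' @param data a `ti_data` with recorded choices.
#' @param likelihood `"all"` (default) or `"feedback"`.
#' @param engine `"cpp"` or `"r"` (see [simulate_probabilities()]).
#' @return the negative log-likelihood in nats.
#' @export
negative_log_likelihood <- function(model, params, data,
                                    likelihood = c("all", "feedback"),
                                    engine = "cpp") {
  likelihood <- match.arg(likelihood)
  stopifnot(inherits(data, "ti_data"))
  pr <- response_probs(model, params, data, engine)
  use <- !is.na(pr)
  if (likelihood == "feedback") use <- use & data$session$trials$feedback
  if (!any(use))
    stop("empty dataset: no scoreable trials contribute to the likelihood",
         call. = FALSE)
  -sum(log(pmax(pr[use], 1e-12)))
}

# Truncate a dataset to its pre-changepoint prefix (phase == "pre").
# Used for the pre-changepoint-only fits.
truncate_pre <- function(data) {
  s <- data$session
  keep <- s$trials$phase == "pre"
  if (!any(keep)) stop("no pre-changepoint trials", call. = FALSE)
  s$trials <- s$trials[keep, , drop = FALSE]
  data$session <- s
  data$responses <- data$responses[keep, , drop = FALSE]
  data
}
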