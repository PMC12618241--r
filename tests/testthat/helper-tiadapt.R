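# Shared fixtures: everything is generated in code at test time.

# Reduced optimiser budget for desk-scale fits; fits remain seeded and
# deterministic.
quick <- list(maxiter = 40, popsize = 14)

# A winner-biased asymmetric parameter set used across tests.
winner_par <- c(alpha_plus = 0.3, alpha_minus = 0.05, eta = 2, tau = 0.2)

# One cached session per condition (cheap, but avoid regenerating
# everywhere).
session_up <- generate_session("up", seed = 101)
session_down <- generate_session("down", seed = 101)

# Binary dataset from a winner-biased agent.
make_binary_data <- function(session, par = winner_par, model = "qasymm",
                             seed = 11, miss_rate = 0) {
  sample_choices(probability_dataset(model, par, session),
                 seed = seed, miss_rate = miss_rate)
}

# A deterministic "perfect responder" who always picks the item that is
# higher under the hierarchy in force.
make_perfect_data <- function(session) {
  pd <- probability_dataset("qasymm",
                            c(alpha_plus = 0, alpha_minus = 0, eta = 0,
                              tau = 1), session)
  tr <- session$trials
  d <- sample_choices(pd, seed = 1)
  d$responses$chosen_item <- tr$correct_item
  d$responses$missed <- rep(FALSE, nrow(tr))
  d$responses$correct <- rep(TRUE, nrow(tr))
  d$provenance <- "simulated_choices"
  d
}
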