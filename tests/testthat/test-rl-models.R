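test_that("choice rule is a normalised logistic in the value difference", {
  expect_equal(choice_prob(0.3, 0.3, 0.5), 0.5)
  expect_equal(choice_prob(0.2, 0, 0.2), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(choice_prob(50, -50, 0.1), 1)
  expect_error(choice_prob(0, 0, 0), "positive")
  for (i in 1:50) {
    qx <- runif(1, -1, 1); qy <- runif(1, -1, 1); tau <- runif(1, 0.01, 1)
    expect_equal(choice_prob(qx, qy, tau) + choice_prob(qy, qx, tau), 1)
  }
})

test_that("relative difference scales the value gap", {
  expect_equal(relative_difference(0.4, 0.4, 3), 0)
  expect_equal(relative_difference(0.9, 0.1, 0), 0)
  expect_equal(relative_difference(0.5, -0.5, 2), 2)
  expect_error(relative_difference(0, 0, -1), "non-negative")
})

test_that("asymmetry modulator is a bounded parabola in preference", {
  p <- seq(0, 1, 0.05)
  expect_equal(lambda_modulator(p, 0), rep(1, length(p)))
  expect_equal(lambda_modulator(0.5, 0.8), 1)
  expect_equal(lambda_modulator(1, 0.5), 0.5)
  expect_equal(lambda_modulator(0, 0.5), 0.5)
  for (om in seq(0, 1, 0.1)) {
    lam <- lambda_modulator(p, om)
    expect_true(all(lam >= 1 - om - 1e-12 & lam <= 1 + 1e-12))
  }
  expect_error(lambda_modulator(1.2, 0.5), "0, 1")
})

test_that("base-rate split conserves |alpha0| and never reverses bias", {
  expect_equal(adapt_rates(0.4, 1),
               c(alpha_plus = 0.4, alpha_minus = 0))
  expect_equal(adapt_rates(0.4, 0),
               c(alpha_plus = 0.2, alpha_minus = 0.2))
  expect_equal(adapt_rates(-0.4, 1),
               c(alpha_plus = 0, alpha_minus = 0.4))
  for (a0 in seq(-0.5, 0.5, 0.1)) {
    for (lam in seq(0, 1, 0.1)) {
      r <- adapt_rates(a0, lam)
      expect_equal(unname(sum(r)), abs(a0))
      expect_true(all(r >= -1e-12))
      if (a0 > 0) expect_gte(r[["alpha_plus"]], r[["alpha_minus"]])
      if (a0 < 0) expect_lte(r[["alpha_plus"]], r[["alpha_minus"]])
    }
  }
})

test_that("asymmetry index hits its endpoints and midpoints", {
  expect_equal(asymmetry_index(0.2, 0.2), 0)
  expect_equal(asymmetry_index(0.3, 0), 1)
  expect_equal(asymmetry_index(0, 0.3), -1)
  expect_equal(asymmetry_index(0.1, 0.3), -0.5)
  expect_error(asymmetry_index(0, 0), "undefined")
})

test_that("single-trial updates follow the rectified difference-weighted rule", {
  par <- c(alpha_plus = 0.2, alpha_minus = 0.1, eta = 0, tau = 0.5)
  st <- init_agent(3)
  out <- step_agent("qasymm", par, st, left = 1, right = 2, correct = 1,
                    feedback = TRUE)
  expect_equal(out$state$q, c(0.2, -0.1, 0))   # winner +0.2, loser -0.1
  expect_equal(out$p, 0.5)

  # d large enough to make the winner bracket negative: clipped at 0
  par2 <- c(alpha_plus = 0.2, alpha_minus = 0.1, eta = 2, tau = 0.5)
  st2 <- init_agent(3)
  st2$q <- c(0.5, 0.1, 0)                      # d = 2*(0.5-0.1) = 0.8
  out2 <- step_agent("qasymm", par2, st2, left = 1, right = 2, correct = 1,
                     feedback = TRUE)
  expect_equal(out2$state$q[1], 0.5)           # 1 - 0.8 - 0.5 < 0 -> no move
  expect_equal(out2$state$q[2], 0.1 + 0.1 * (-1 + 0.8 - 0.1))
  expect_equal(out2$d, 0.8)

  # no-feedback trials record a probability but change no values
  out3 <- step_agent("qasymm", par, init_agent(3), 1, 3, 1, feedback = FALSE)
  expect_equal(out3$state$q, c(0, 0, 0))
  expect_equal(out3$p, 0.5)
  expect_error(step_agent("qasymm", par, init_agent(3), 1, 1, 1, TRUE),
               "winner and loser")
})

test_that("winner values never fall and loser values never rise on update", {
  set.seed(42)
  for (i in 1:100) {
    par <- c(alpha_plus = runif(1, 0, 0.5), alpha_minus = runif(1, 0, 0.5),
             eta = runif(1, 0, 10), tau = runif(1, 0.05, 1))
    st <- init_agent(4)
    st$q <- runif(4, -1, 1)
    pair <- sample(4, 2)
    out <- step_agent("qasymm", par, st, pair[1], pair[2], pair[1],
                      feedback = TRUE)
    expect_gte(out$state$q[pair[1]], st$q[pair[1]])
    expect_lte(out$state$q[pair[2]], st$q[pair[2]])
  }
})

test_that("model family collapses: shared rates and omega = 0", {
  s <- session_down
  p_symm <- simulate_probabilities("qsymm", c(alpha = 0.2, eta = 2, tau = 0.3), s)
  p_asym <- simulate_probabilities("qasymm",
    c(alpha_plus = 0.2, alpha_minus = 0.2, eta = 2, tau = 0.3), s)
  expect_identical(p_symm, p_asym)

  p_adapt <- simulate_probabilities("qadapt",
    c(alpha0 = 0.3, omega = 0, eta = 2, tau = 0.2), s)
  p_onesided <- simulate_probabilities("qasymm",
    c(alpha_plus = 0.3, alpha_minus = 0, eta = 2, tau = 0.2), s)
  expect_identical(p_adapt, p_onesided)

  # qasymm2 with equal pre/post rate pairs is qasymm
  p_a2 <- simulate_probabilities("qasymm2",
    c(alpha_plus_pre = 0.3, alpha_minus_pre = 0.05, alpha_plus_post = 0.3,
      alpha_minus_post = 0.05, eta = 2, tau = 0.2), s)
  p_a1 <- simulate_probabilities("qasymm", winner_par, s)
  expect_identical(p_a2, p_a1)
})

test_that("compiled and reference engines agree on every model", {
  set.seed(7)
  for (m in ti_models()) {
    spec <- model_spec(m)
    for (i in 1:5) {
      par <- setNames(runif(spec$k, spec$lower,
                            pmin(spec$upper, c(rep(0.5, spec$k - 2), 5, 1))),
                      spec$par_names)
      par[["tau"]] <- max(par[["tau"]], 0.05)
      for (s in list(session_up, session_down)) {
        expect_equal(simulate_probabilities(m, par, s, engine = "cpp"),
                     simulate_probabilities(m, par, s, engine = "r"),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("winner-biased learning compresses the upper value range", {
  for (seed in c(3, 11, 27)) {
    s <- generate_session("up", seed = seed)
    sim <- simulate_agent("qasymm", winner_par, s)
    q <- sim$q[max(which(s$trials$phase == "pre")), ]
    spacing <- diff(q[hierarchy_order(s$hierarchy_pre)])
    # spacing between successive ranks shrinks as rank grows
    expect_lt(unname(coef(lm(spacing ~ seq_along(spacing)))[2]), 0)
    expect_gt(spacing[1], spacing[5])
  }
})

test_that("post-changepoint non-anchor values are less discriminable after 'down'", {
  dc <- discriminability_contrast("qasymm", winner_par, seed = 5)
  expect_lt(dc[["down"]], dc[["up"]])
  # a symmetric agent shows no such direction asymmetry (near-equal)
  dc_s <- discriminability_contrast("qsymm", c(alpha = 0.15, eta = 2,
                                               tau = 0.2), seed = 5)
  asym_gap <- (dc[["up"]] - dc[["down"]]) / mean(dc)
  symm_gap <- abs(dc_s[["up"]] - dc_s[["down"]]) / mean(dc_s)
  expect_gt(asym_gap, symm_gap)
})
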