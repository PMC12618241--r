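test_that("the chance threshold matches an exact binomial tail oracle", {
  for (n in c(50, 162, 169)) {
    k <- binomial_threshold(n, 0.01)
    tail_at <- function(k) sum(dbinom(k:n, n, 0.5))  # independent oracle
    expect_lt(tail_at(k), 0.01)
    expect_gte(tail_at(k - 1), 0.01)
  }
})

test_that("the inclusion filter rejects chance and high-miss participants", {
  s <- session_up
  # chance performer: flat probabilities, sampled choices
  pd <- probability_dataset("qasymm",
    c(alpha_plus = 0, alpha_minus = 0, eta = 0, tau = 1), s)
  chance <- sample_choices(pd, seed = 2)
  f <- inclusion_filter(chance)
  expect_false(f$accuracy_pass)
  expect_false(f$include)

  # competent performer passes
  good <- make_binary_data(s, seed = 3)
  expect_true(inclusion_filter(good)$include)

  # a miss proportion above the cutoff excludes regardless of accuracy
  perfect <- make_perfect_data(s)
  idx <- seq_len(ceiling(0.61 * nrow(s$trials)))
  perfect$responses$missed[idx] <- TRUE
  perfect$responses$chosen_item[idx] <- NA
  perfect$responses$correct[idx] <- NA
  f2 <- inclusion_filter(perfect)
  expect_gt(f2$miss_prop, 0.6)
  expect_false(f2$miss_pass)
  expect_false(f2$include)
  # the miss denominator is the observed trial count, not a constant
  expect_identical(f2$n_trials, nrow(s$trials))
})

test_that("sliding TI accuracy handles flat, degenerate and alternating input", {
  s <- session_up
  perfect <- make_perfect_data(s)
  sw <- sliding_ti_accuracy(perfect, window = 70)
  expect_true(all(sw$accuracy == 1))
  expect_setequal(unique(sw$category), c("low", "mid", "high"))
  # window spanning everything ends at the overall category mean
  d <- make_binary_data(s, seed = 5)
  sw_all <- sliding_ti_accuracy(d, window = nrow(s$trials))
  tt <- ti_trial_table(d)
  key <- paste(pmin(tt$left_rank_pre, tt$right_rank_pre),
               pmax(tt$left_rank_pre, tt$right_rank_pre))
  low_rows <- key %in% c("2 4", "2 5") & !tt$feedback
  last_low <- tail(sw_all$accuracy[sw_all$category == "low"], 1)
  expect_equal(last_low, mean(tt$accuracy[low_rows]))

  # alternating correctness with window 2 averages to 0.5
  alt <- perfect
  for (cat in list(c("2 4", "2 5"), c("2 6", "3 5"), c("3 6", "4 6"))) {
    rows <- which(key %in% cat & !tt$feedback)
    wrong <- rows[seq(1, length(rows), by = 2)]
    tr <- s$trials
    other <- ifelse(tr$correct_item == tr$left_item, tr$right_item,
                    tr$left_item)
    alt$responses$chosen_item[wrong] <- other[wrong]
    alt$responses$correct[wrong] <- FALSE
  }
  sw2 <- sliding_ti_accuracy(alt, window = 2)
  by_cat <- split(sw2$accuracy, sw2$category)
  for (acc in by_cat) expect_true(all(acc[-1] == 0.5))
})

test_that("choice matrices are antisymmetric with design-matched counts", {
  s <- session_down
  perfect <- make_perfect_data(s)
  cm <- choice_matrix(perfect, phase = "pre")
  n <- s$n_items
  for (i in 1:n) for (j in 1:n) {
    if (i == j) {
      expect_true(is.na(cm$p[i, j]))
    } else {
      expect_equal(cm$p[i, j] + cm$p[j, i], 1)
      expect_equal(cm$p[i, j], as.numeric(i > j))  # ground-truth responder
    }
  }
  # counts mirror the design: adjacent pairs 4 per block, others 2
  pre_blocks <- sum(s$trials$phase == "pre" & s$trials$block == 1) / 54 * 3
  expect_equal(cm$counts[1, 2] >= 2, TRUE)
  expect_true(all(cm$counts == t(cm$counts)))

  # random responder converges to 0.5 everywhere
  many <- lapply(1:8, function(i) {
    pd <- probability_dataset("qasymm",
      c(alpha_plus = 0, alpha_minus = 0, eta = 0, tau = 1),
      generate_session("down", seed = i))
    sample_choices(pd, seed = i + 100)
  })
  cm2 <- choice_matrix(many, phase = "all")
  off <- cm2$p[upper.tri(cm2$p)]
  expect_lt(max(abs(off - 0.5)), 0.2)
  expect_lt(abs(mean(off) - 0.5), 0.05)
})

test_that("compression and distance slopes behave on canonical responders", {
  s <- session_up
  perfect <- make_perfect_data(s)
  expect_equal(asymmetry_slope(perfect, "pre")$slope, 0)
  expect_equal(distance_effect(perfect, "pre")$slope, 0)

  # winner-biased simulated agent: negative compression, positive distance
  pd <- probability_dataset("qasymm", winner_par, s)
  expect_lt(asymmetry_slope(pd, "pre")$slope, 0)
  expect_gt(distance_effect(pd, "pre")$slope, 0)
  # loser-biased mirror flips the compression sign
  mirror <- c(alpha_plus = 0.05, alpha_minus = 0.3, eta = 2, tau = 0.2)
  expect_gt(asymmetry_slope(probability_dataset("qasymm", mirror, s),
                            "pre")$slope, 0)
})

test_that("anchor preference filters the design as specified", {
  s <- session_up
  anchors <- c(match(1L, s$hierarchy_pre$rank),
               match(7L, s$hierarchy_pre$rank))
  perfect <- make_perfect_data(s)
  # a ground-truth responder never prefers the bottom anchor pre-change
  ap <- anchor_preference(perfect, "bottom", "pre")
  expect_equal(ap$p_choose, 0)
  expect_equal(anchor_preference(perfect, "top", "pre")$p_choose, 1)

  # count reconciliation against set arithmetic on the session design
  tr <- s$trials
  contains <- tr$left_item %in% anchors[1] | tr$right_item %in% anchors[1]
  both <- (tr$left_item %in% anchors) & (tr$right_item %in% anchors)
  expected_n <- sum(contains & !both & !tr$feedback & tr$phase == "pre")
  expect_identical(ap$n_trials, expected_n)
  expect_error(anchor_preference(perfect, 99), "extreme")

  # the winner-biased 'up' agent raises its moved-anchor preference
  pd <- probability_dataset("qasymm", winner_par, s)
  expect_gt(anchor_preference(pd, "bottom", "post")$p_choose,
            anchor_preference(pd, "bottom", "pre")$p_choose)
})

test_that("nonparametric effect sizes follow r = z/sqrt(N)", {
  expect_equal(effect_size_r(5.22, 44), 5.22 / sqrt(44), tolerance = 1e-12)
  expect_equal(round(effect_size_r(5.22, 44), 2), 0.79)
  expect_equal(effect_size_r(0, 30), 0)
  expect_equal(effect_size_r(-2, 25), -effect_size_r(2, 25))

  set.seed(8)
  x <- rnorm(40, mean = 1)
  es <- effect_size_nonparametric(x, resamples = 500, seed = 3)
  expect_equal(es$r, es$z / sqrt(es$n))
  expect_true(es$ci[1] <= es$r && es$r <= es$ci[2])
  es2 <- effect_size_nonparametric(x, resamples = 500, seed = 3)
  expect_identical(es$ci, es2$ci)
})
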