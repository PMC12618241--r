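# Behavioural metrics: inclusion filter, sliding TI accuracy, choice
# matrices, value-compression (asymmetry) slope, symbolic distance effect,
# anchor preferences and nonparametric effect sizes.

#' Merged per-trial table for analysis
#'
#' Joins trials and responses and adds the pre-changepoint ranks of both
#' items, the combined pair value (sum of pre-changepoint ranks), the
#' ordinal distance, and an `accuracy` column: the 0/1 correctness of the
#' recorded choice, or the model-predicted probability of the correct
#' choice for probability-level datasets.
#'
#' @param data a `ti_data`.
#' @return data.frame.
#' @export
ti_trial_table <- function(data) {
  stopifnot(inherits(data, "ti_data"))
  s <- data$session
  tt <- cbind(s$trials, data$responses[setdiff(names(data$responses),
                                               "trial")])
  rp <- s$hierarchy_pre$rank
  tt$left_rank_pre <- rp[tt$left_item]
  tt$right_rank_pre <- rp[tt$right_item]
  tt$pair_value <- tt$left_rank_pre + tt$right_rank_pre
  tt$distance <- abs(tt$left_rank_pre - tt$right_rank_pre)
  tt$accuracy <- if (data$provenance == "simulated_probabilities")
    tt$p_correct else as.numeric(tt$correct)
  tt
}

# Probability of choosing a specific item on each trial (NA if the item
# was not shown or the trial is unscoreable).
prob_choose_item <- function(data, item) {
  tt <- ti_trial_table(data)
  shown <- tt$left_item == item | tt$right_item == item
  if (data$provenance == "simulated_probabilities") {
    p <- ifelse(tt$correct_item == item, tt$p_correct, 1 - tt$p_correct)
  } else {
    p <- as.numeric(tt$chosen_item == item)
    p[tt$missed | is.na(tt$chosen_item)] <- NA
  }
  p[!shown] <- NA
  p
}

#' Performance-based inclusion filter
#'
#' A participant is retained iff (a) their number of correct
#' pre-changepoint responses reaches the smallest count k whose exact
#' binomial tail probability `P(X >= k | n, 0.5)` falls below `alpha`
#' (n = scoreable pre-changepoint trials), i.e. chance-level
#' pre-changepoint performance is rejected, and (b) their missed-response
#' proportion over all recorded trials does not exceed `miss_cutoff`.
#'
#' @param data a `ti_data` with recorded choices and labelled phases.
#' @param alpha binomial-test significance level (default 0.01).
#' @param miss_cutoff maximal tolerated miss proportion (default 0.6).
#' @return list: `include` (logical), `accuracy_pass`, `miss_pass`,
#'   `n_pre`, `n_correct_pre`, `threshold`, `miss_prop`, `n_trials`.
#' @export
inclusion_filter <- function(data, alpha = 0.01, miss_cutoff = 0.6) {
  stopifnot(inherits(data, "ti_data"))
  if (data$provenance == "simulated_probabilities")
    stop("inclusion filter needs recorded (binary) responses", call. = FALSE)
  tt <- ti_trial_table(data)
  pre <- tt[tt$phase == "pre", , drop = FALSE]
  if (!nrow(pre)) stop("no pre-changepoint trials", call. = FALSE)
  scoreable <- !pre$missed & !is.na(pre$chosen_item)
  n <- sum(scoreable)
  k_correct <- sum(pre$correct[scoreable])
  # with no scoreable pre trials, above-chance performance cannot be
  # demonstrated: fail the accuracy criterion rather than error
  threshold <- if (n > 0L) binomial_threshold(n, alpha) else NA_integer_
  miss_prop <- mean(tt$missed)
  acc_pass <- n > 0L && k_correct >= threshold
  miss_pass <- miss_prop <= miss_cutoff
  list(include = acc_pass && miss_pass, accuracy_pass = acc_pass,
       miss_pass = miss_pass, n_pre = n, n_correct_pre = k_correct,
       threshold = threshold, miss_prop = miss_prop, n_trials = nrow(tt))
}

#' Above-chance correct-count threshold
#'
#' Smallest k with exact binomial tail `P(X >= k | n, 0.5) < alpha`.
#'
#' @param n number of trials.
#' @param alpha significance level.
#' @return integer threshold.
#' @export
binomial_threshold <- function(n, alpha = 0.01) {
  ks <- 0:n
  tail <- pbinom(ks - 1, n, 0.5, lower.tail = FALSE)
  ks[min(which(tail < alpha))]
}

# Default low/mid/high categories of non-anchor TI pairs, as
# pre-changepoint rank pairs (tertiles of combined rank).
default_ti_categories <- function() {
  list(low = list(c(2, 4), c(2, 5)),
       mid = list(c(2, 6), c(3, 5)),
       high = list(c(3, 6), c(4, 6)))
}

#' Sliding-window TI accuracy by pair category
#'
#' For each category of (non-anchor) TI pairs, computes the trailing mean
#' accuracy over that category's trials using a window of `window` trials
#' (shorter at the start), indexed relative to the first post-changepoint
#' trial.  Categories are named lists of pre-changepoint rank pairs; the
#' default splits the six non-anchor TI pairs into low/mid/high combined
#' value.
#'
#' @param data a `ti_data`.
#' @param window window length in category trials (default 70).
#' @param categories named list of lists of rank pairs.
#' @return data.frame with `category`, `trial`, `trial_rel`, `accuracy`.
#' @export
sliding_ti_accuracy <- function(data, window = 70,
                                categories = default_ti_categories()) {
  stopifnot(window >= 1)
  tt <- ti_trial_table(data)
  first_post <- if (any(tt$phase == "post")) min(tt$trial[tt$phase == "post"])
    else NA_integer_
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pair_key <- key(tt$left_rank_pre, tt$right_rank_pre)
  out <- lapply(names(categories), function(nm) {
    keys <- vapply(categories[[nm]], function(p) key(p[1], p[2]),
                   character(1))
    rows <- tt[pair_key %in% keys & !tt$feedback & !is.na(tt$accuracy), ,
               drop = FALSE]
    if (!nrow(rows)) {
      warning("category '", nm, "' has no scoreable trials; omitted",
              call. = FALSE)
      return(NULL)
    }
    acc <- vapply(seq_len(nrow(rows)), function(i) {
      mean(rows$accuracy[max(1L, i - window + 1L):i])
    }, numeric(1))
    data.frame(category = nm, trial = rows$trial,
               trial_rel = rows$trial - first_post, accuracy = acc)
  })
  do.call(rbind, out)
}

#' Pairwise choice matrix
#'
#' Cell `[i, j]` holds the mean probability of choosing the item holding
#' pre-changepoint rank i over the item holding pre-changepoint rank j
#' (cellwise mean of participant means).  Antisymmetry
#' `p[i,j] = 1 - p[j,i]` holds by construction; the diagonal is undefined.
#'
#' @param data a `ti_data` or list of them.
#' @param phase `"pre"`, `"post"` or `"all"`.
#' @return list of class `ti_choice_matrix` with `p` (n x n matrix),
#'   `counts` (summed scoreable trials per cell) and `phase`.
#' @export
choice_matrix <- function(data, phase = c("pre", "post", "all")) {
  phase <- match.arg(phase)
  if (inherits(data, "ti_data")) data <- list(data)
  n <- data[[1L]]$session$n_items
  acc <- matrix(0, n, n)
  cnt_p <- matrix(0, n, n)
  counts <- matrix(0L, n, n)
  for (d in data) {
    tt <- ti_trial_table(d)
    if (phase != "all") tt <- tt[tt$phase == phase, , drop = FALSE]
    p_left <- if (d$provenance == "simulated_probabilities")
      ifelse(tt$correct_item == tt$left_item, tt$p_correct,
             1 - tt$p_correct)
    else {
      v <- as.numeric(tt$chosen_item == tt$left_item)
      v[tt$missed | is.na(tt$chosen_item)] <- NA
      v
    }
    ok <- !is.na(p_left)
    m_num <- matrix(0, n, n)
    m_den <- matrix(0L, n, n)
    for (r in which(ok)) {
      i <- tt$left_rank_pre[r]
      j <- tt$right_rank_pre[r]
      m_num[i, j] <- m_num[i, j] + p_left[r]
      m_num[j, i] <- m_num[j, i] + (1 - p_left[r])
      m_den[i, j] <- m_den[i, j] + 1L
      m_den[j, i] <- m_den[j, i] + 1L
    }
    has <- m_den > 0L
    acc[has] <- acc[has] + m_num[has] / m_den[has]
    cnt_p[has] <- cnt_p[has] + 1
    counts <- counts + m_den
  }
  p <- acc / cnt_p
  p[cnt_p == 0] <- NA
  diag(p) <- NA
  dimnames(p) <- dimnames(counts) <-
    list(chosen_rank = seq_len(n), over_rank = seq_len(n))
  structure(list(p = p, counts = counts, phase = phase),
            class = "ti_choice_matrix")
}

#' Value-compression (asymmetry) slope
#'
#' Ordinary least squares of per-pair TI accuracy on combined pair value
#' (sum of the two items' pre-changepoint ground-truth ranks).  A negative
#' slope - higher-valued pairs judged less accurately - is the behavioural
#' signature of winner-biased learning; a positive slope marks loser bias.
#'
#' @param data a `ti_data`.
#' @param phase `"pre"` (default), `"post"` or `"all"`.
#' @param pairs `"ti"` (default: all no-feedback pairs) or `"nonanchor"`
#'   (restrict to pairs among pre-changepoint ranks 2..6).
#' @return list of class `ti_compression`: `slope`, `intercept`, `points`
#'   (per-pair value/accuracy table), `n_trials`.
#' @export
asymmetry_slope <- function(data, phase = c("pre", "post", "all"),
                            pairs = c("ti", "nonanchor")) {
  phase <- match.arg(phase)
  pairs <- match.arg(pairs)
  tt <- ti_trial_table(data)
  if (phase != "all") tt <- tt[tt$phase == phase, , drop = FALSE]
  tt <- tt[!tt$feedback & !is.na(tt$accuracy), , drop = FALSE]
  if (pairs == "nonanchor") {
    n <- data$session$n_items
    keep <- tt$left_rank_pre %in% 2:(n - 1) &
      tt$right_rank_pre %in% 2:(n - 1)
    tt <- tt[keep, , drop = FALSE]
  }
  if (!nrow(tt)) stop("no scoreable TI trials in this phase", call. = FALSE)
  agg <- stats::aggregate(accuracy ~ pair_value + left_rank_pre +
                            right_rank_pre, data = tt, FUN = mean)
  if (length(unique(agg$pair_value)) < 2L)
    stop("need at least two distinct combined pair values", call. = FALSE)
  fit <- lm(accuracy ~ pair_value, data = agg)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]), points = agg,
                 n_trials = nrow(tt)),
            class = "ti_compression")
}

#' Symbolic distance effect
#'
#' OLS slope of per-pair TI accuracy on the ordinal distance between the
#' compared items (pre-changepoint ranks); positive slopes mark the
#' classic distance effect.
#'
#' @param data a `ti_data`.
#' @param phase `"pre"` (default), `"post"` or `"all"`.
#' @return list with `slope` and `points`.
#' @export
distance_effect <- function(data, phase = c("pre", "post", "all")) {
  phase <- match.arg(phase)
  tt <- ti_trial_table(data)
  if (phase != "all") tt <- tt[tt$phase == phase, , drop = FALSE]
  tt <- tt[!tt$feedback & !is.na(tt$accuracy), , drop = FALSE]
  if (!nrow(tt)) stop("no scoreable TI trials in this phase", call. = FALSE)
  agg <- stats::aggregate(accuracy ~ distance + left_rank_pre +
                            right_rank_pre, data = tt, FUN = mean)
  fit <- lm(accuracy ~ distance, data = agg)
  list(slope = unname(coef(fit)[2L]), points = agg)
}

#' Preference for an anchor item
#'
#' Proportion (or model probability) of choosing the requested former
#' anchor on eligible trials of a phase: no-feedback trials containing the
#' anchor, excluding the anchor-vs-anchor pair \{i1, i7\}, so the measure
#' reflects preference against non-neighbouring non-anchor items only.
#'
#' @param data a `ti_data`.
#' @param anchor `"bottom"` (former rank 1, i1), `"top"` (former rank n,
#'   i7), or the item id of one of them.
#' @param phase `"pre"`, `"post"` or `"all"`.
#' @return list: `p_choose` (mean preference), `n_trials`.
#' @export
anchor_preference <- function(data, anchor = c("bottom", "top"),
                              phase = c("pre", "post", "all")) {
  phase <- match.arg(phase)
  s <- data$session
  anchors <- anchor_items(s)
  if (is.character(anchor)) {
    anchor <- match.arg(anchor)
    item <- anchors[[anchor]]
  } else {
    item <- as.integer(anchor)
    if (!item %in% anchors)
      stop("anchor must be one of the extreme-ranked items", call. = FALSE)
  }
  tt <- ti_trial_table(data)
  p_anchor <- prob_choose_item(data, item)
  both_anchors <- (tt$left_item %in% anchors) & (tt$right_item %in% anchors)
  keep <- !tt$feedback & !both_anchors & !is.na(p_anchor)
  if (phase != "all") keep <- keep & tt$phase == phase
  if (!any(keep)) stop("no eligible anchor trials in this phase",
                       call. = FALSE)
  list(p_choose = mean(p_anchor[keep]), n_trials = sum(keep))
}

#' Nonparametric effect size r = z / sqrt(N)
#'
#' @param z standardised test statistic of a Wilcoxon / Mann-Whitney test.
#' @param n sample size N.
#' @return numeric effect size.
#' @export
effect_size_r <- function(z, n) {
  stopifnot(is_count(n))
  z / sqrt(n)
}

# z statistic (normal approximation) of a signed-rank / rank-sum test.
rank_test_z <- function(x, y = NULL, paired = TRUE) {
  if (paired) {
    d <- if (is.null(y)) x else x - y
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L) return(0)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    (W - mu) / sig
  } else {
    n1 <- length(x)
    n2 <- length(y)
    U <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sig <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    (U - mu) / sig
  }
}

#' Nonparametric effect size with bootstrap confidence interval
#'
#' Computes the z statistic of a Wilcoxon signed-rank (paired /
#' one-sample) or Mann-Whitney (unpaired) test by normal approximation,
#' the effect size `r = z / sqrt(N)` (N = total observations), and a
#' percentile confidence interval from a seeded bootstrap of the
#' underlying values.
#'
#' @param x numeric values (differences or first sample).
#' @param y optional second sample.
#' @param paired paired/one-sample (default) or two-sample.
#' @param resamples bootstrap resamples (default 10000).
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return list of class `ti_effect_size`: `z`, `n`, `r`, `ci`.
#' @export
effect_size_nonparametric <- function(x, y = NULL, paired = TRUE,
                                      resamples = 10000, seed = 1L,
                                      conf = 0.95) {
  if (paired && !is.null(y)) {
    stopifnot(length(x) == length(y))
    x <- x - y
    y <- NULL
  }
  n <- length(x) + length(y %||% numeric())
  if (n < 1L) stop("need at least one observation", call. = FALSE)
  z <- rank_test_z(x, y, paired)
  r <- z / sqrt(n)
  rs <- withr::with_seed(seed, vapply(seq_len(resamples), function(i) {
    xb <- sample(x, replace = TRUE)
    yb <- if (is.null(y)) NULL else sample(y, replace = TRUE)
    rank_test_z(xb, yb, paired) / sqrt(n)
  }, numeric(1)))
  a <- (1 - conf) / 2
  structure(list(z = z, n = n, r = r,
                 ci = unname(quantile(rs, c(a, 1 - a)))),
            class = "ti_effect_size")
}
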