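# Session construction: blocks, sub-blocks, feedback assignment and the
# pre/post phase labelling around the changepoint.

# One block of trials under hierarchy `h` (uses the current RNG stream).
# A block holds every unordered pair once per sub-block plus one extra
# presentation of each adjacent pair per sub-block; sub-block 2 re-presents
# the sub-block-1 trials with left/right mirrored, in an independent order.
make_block <- function(h) {
  n <- h$n_items
  pairs <- t(combn(seq_len(n), 2L))
  adj <- pairs[abs(h$rank[pairs[, 1L]] - h$rank[pairs[, 2L]]) == 1L, ,
               drop = FALSE]
  base <- rbind(pairs, adj)
  m <- nrow(base)
  flip <- sample(c(TRUE, FALSE), m, replace = TRUE)
  left1 <- ifelse(flip, base[, 2L], base[, 1L])
  right1 <- ifelse(flip, base[, 1L], base[, 2L])
  o1 <- sample.int(m)
  o2 <- sample.int(m)
  df <- data.frame(
    sub_block = rep(1:2, each = m),
    left_item = c(left1[o1], right1[o2]),
    right_item = c(right1[o1], left1[o2]))
  df$feedback <- abs(h$rank[df$left_item] - h$rank[df$right_item]) == 1L
  df$correct_item <- ifelse(h$rank[df$left_item] > h$rank[df$right_item],
                            df$left_item, df$right_item)
  df
}

#' Generate one block of trials
#'
#' For the default 7-item hierarchy this yields 54 trials (24 with
#' feedback, 30 without): two shuffled sub-blocks, each containing all 21
#' unordered pairs plus one repeat of each of the 6 adjacent pairs, with
#' left/right placement mirrored between sub-blocks.
#'
#' @param h the `ti_hierarchy` in force.
#' @param seed optional integer seed for the shuffles and left/right
#'   assignment.
#' @return a data.frame with columns `sub_block`, `left_item`,
#'   `right_item`, `feedback`, `correct_item`.
#' @export
generate_block <- function(h, seed = NULL) {
  with_seed_if(seed, make_block(h))
}

#' Generate a full task session
#'
#' Six blocks of 54 trials by default.  Blocks before `changepoint_block`
#' use the original hierarchy; from `changepoint_block` onwards the
#' restructured hierarchy is in force, which silently re-routes feedback:
#' both conditions gain feedback on the former top vs former bottom pair,
#' while the 'up' condition loses feedback on the old bottom pair (i1,i2)
#' and the 'down' condition on the old top pair (i6,i7).  Trials are
#' labelled `phase = "pre"` strictly before the first changepoint-block
#' presentation of the moved-anchor pair \{i1, i7\} and `"post"` from that
#' trial on (see [label_phases()]).
#'
#' @param condition `"up"`, `"down"`, or `"none"` (a no-changepoint control
#'   session in which all trials are `"pre"`).
#' @param seed integer seed; the whole design is reproducible from it.
#' @param n_items,n_blocks,changepoint_block design dimensions (defaults
#'   7 items, 6 blocks, change at block 4).
#' @return an object of class `ti_session`: list with `trials` (data.frame
#'   with columns `block`, `sub_block`, `trial`, `left_item`, `right_item`,
#'   `feedback`, `correct_item`, `phase`), `condition`, `n_items`,
#'   `changepoint_block`, `hierarchy_pre`, `hierarchy_post`, `seed`.
#' @export
#' @examples
#' s <- generate_session("down", seed = 1)
#' nrow(s$trials)                # 324
#' table(s$trials$feedback)      # 144 feedback, 180 no-feedback
generate_session <- function(condition = c("up", "down", "none"), seed = 1L,
                             n_items = 7, n_blocks = 6,
                             changepoint_block = 4) {
  condition <- match.arg(condition)
  stopifnot(is_count(n_blocks), is_count(changepoint_block),
            changepoint_block > 1, changepoint_block <= n_blocks)
  withr::with_seed(seed, {
    h_pre <- build_hierarchy(n_items)
    h_post <- apply_changepoint(h_pre, condition)
    blocks <- lapply(seq_len(n_blocks), function(b) {
      h <- if (condition != "none" && b >= changepoint_block) h_post else h_pre
      cbind(block = b, make_block(h))
    })
    trials <- do.call(rbind, blocks)
    trials$trial <- seq_len(nrow(trials))
    trials <- trials[, c("block", "sub_block", "trial", "left_item",
                         "right_item", "feedback", "correct_item")]
    s <- structure(
      list(trials = trials, condition = condition, n_items = as.integer(n_items),
           changepoint_block = as.integer(changepoint_block),
           hierarchy_pre = h_pre, hierarchy_post = h_post, seed = seed),
      class = "ti_session")
    label_phases(s)
  })
}

#' @export
print.ti_session <- function(x, ...) {
  cat("<ti_session> condition=", x$condition, ", ", nrow(x$trials),
      " trials over ", max(x$trials$block), " blocks (changepoint block ",
      x$changepoint_block, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Label trials as pre- or post-changepoint
#'
#' The boundary is the first changepoint-block trial presenting the pair of
#' former anchors (pre-changepoint ranks 1 and n), regardless of the
#' response made on it: that trial and all later trials are `"post"`.  A
#' `"none"` session is labelled all-`"pre"`.
#'
#' @param s a `ti_session`.
#' @return `s` with a `phase` column on `s$trials`.
#' @export
label_phases <- function(s) {
  tr <- s$trials
  if (s$condition == "none") {
    tr$phase <- "pre"
  } else {
    a <- match(1L, s$hierarchy_pre$rank)          # former bottom, i1
    b <- match(s$n_items, s$hierarchy_pre$rank)   # former top, i_n
    hit <- tr$block == s$changepoint_block &
      ((tr$left_item == a & tr$right_item == b) |
         (tr$left_item == b & tr$right_item == a))
    if (!any(hit))
      stop("design error: moved-anchor pair never presented in the ",
           "changepoint block", call. = FALSE)
    first <- min(tr$trial[hit])
    tr$phase <- ifelse(tr$trial >= first, "post", "pre")
  }
  s$trials <- tr
  s
}

# Former-anchor item ids of a session (pre-changepoint ranks 1 and n).
anchor_items <- function(s) {
  c(bottom = match(1L, s$hierarchy_pre$rank),
    top = match(s$n_items, s$hierarchy_pre$rank))
}
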