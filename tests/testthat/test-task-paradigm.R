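test_that("hierarchies are seeded rank permutations", {
  h <- build_hierarchy(7, seed = 1)
  expect_setequal(h$rank, 1:7)
  expect_identical(h, build_hierarchy(7, seed = 1))
  expect_error(build_hierarchy(2), "at least 3")

  # n = 3: every draw is one of the 6 permutations, reproducibly
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (s in 1:20) {
    r <- build_hierarchy(3, seed = s)$rank
    expect_true(any(vapply(perms, function(p) all(p == r), logical(1))))
    expect_identical(r, build_hierarchy(3, seed = s)$rank)
  }
})

test_that("the changepoint moves exactly one anchor and preserves the rest", {
  h <- new_hierarchy_identity(7)
  expect_identical(hierarchy_order(apply_changepoint(h, "down")),
                   c(7L, 1L, 2L, 3L, 4L, 5L, 6L))
  expect_identical(hierarchy_order(apply_changepoint(h, "up")),
                   c(2L, 3L, 4L, 5L, 6L, 7L, 1L))
  expect_identical(apply_changepoint(h, "none"), h)
  expect_error(apply_changepoint(apply_changepoint(h, "up"), "up"),
               "already applied")

  for (s in 1:10) {
    h0 <- build_hierarchy(7, seed = s)
    for (cond in c("up", "down")) {
      h1 <- apply_changepoint(h0, cond)
      # exactly one item jumps to the opposite extreme ...
      jump <- which(abs(h1$rank - h0$rank) == 6L)
      expect_length(jump, 1L)
      expect_identical(h0$rank[jump], if (cond == "down") 7L else 1L)
      # ... and pairwise order among all other items is untouched
      keep <- setdiff(1:7, jump)
      expect_identical(order(h0$rank[keep]), order(h1$rank[keep]))
    }
  }
})

test_that("feedback is delivered exactly on rank-neighbour pairs", {
  h <- new_hierarchy_identity(7)
  expect_true(feedback_rule(3, 4, h))
  expect_false(feedback_rule(3, 5, h))
  expect_error(feedback_rule(3, 3, h), "invalid pair")
  # after a 'down' changepoint the former anchors become neighbours
  expect_true(feedback_rule(7, 1, apply_changepoint(h, "down")))
  expect_true(feedback_rule(7, 1, apply_changepoint(h, "up")))
})

test_that("blocks contain 54 trials with the required pair multiset", {
  h <- build_hierarchy(7, seed = 5)
  for (s in 1:200) {
    b <- generate_block(h, seed = s)
    expect_identical(nrow(b), 54L)
    expect_identical(sum(b$feedback), 24L)
    expect_identical(sum(!b$feedback), 30L)
  }
  b <- generate_block(h, seed = 1)
  key <- paste(pmin(b$left_item, b$right_item),
               pmax(b$left_item, b$right_item))
  tab <- table(key)
  expect_identical(length(tab), 21L)
  adj <- abs(h$rank[b$left_item] - h$rank[b$right_item]) == 1L
  expect_identical(sort(unique(key[adj])), names(tab)[tab == 4L])
  expect_true(all(tab[!names(tab) %in% key[adj]] == 2L))
  # every pair seen once per orientation per sub-block appearance
  orient <- table(paste(b$left_item, b$right_item))
  expect_true(all(orient <= 2L))
  for (k in unique(key[!adj])) {
    items <- strsplit(k, " ")[[1L]]
    expect_identical(unname(orient[paste(items[1L], items[2L])]),
                     unname(orient[paste(items[2L], items[1L])]))
  }
  # different seeds permute, never alter, the (pair, orientation) multiset
  b2 <- generate_block(h, seed = 2)
  expect_setequal(paste(b$left_item, b$right_item, b$feedback),
                  paste(b2$left_item, b2$right_item, b2$feedback))
  expect_false(identical(b$left_item, b2$left_item))
})

test_that("sessions re-route feedback at the changepoint as designed", {
  for (s in c(1, 7)) {
    for (cond in c("up", "down")) {
      sess <- generate_session(cond, seed = s)
      tr <- sess$trials
      expect_identical(nrow(tr), 324L)
      i1 <- match(1L, sess$hierarchy_pre$rank)
      i2 <- match(2L, sess$hierarchy_pre$rank)
      i6 <- match(6L, sess$hierarchy_pre$rank)
      i7 <- match(7L, sess$hierarchy_pre$rank)
      pk <- function(a, b) paste(pmin(a, b), pmax(a, b))
      pair <- pk(tr$left_item, tr$right_item)
      fb_pre <- unique(pair[tr$block < 4 & tr$feedback])
      fb_post <- unique(pair[tr$block >= 4 & tr$feedback])
      # both groups gain feedback on the former-anchor pair {i1, i7}
      expect_identical(setdiff(fb_post, fb_pre), pk(i1, i7))
      # 'up' loses (i1,i2); 'down' loses (i6,i7)
      lost <- if (cond == "up") pk(i1, i2) else pk(i6, i7)
      expect_identical(setdiff(fb_pre, fb_post), lost)
      # and feedback on {i1,i7} informs that i7 < i1 from block 4 on
      anchor_rows <- tr$block >= 4 & pair == pk(i1, i7)
      expect_true(all(tr$feedback[anchor_rows]))
      expect_true(all(tr$correct_item[anchor_rows] == i1))
    }
  }
})

test_that("phase labels split at the first moved-anchor trial of block 4", {
  sess <- generate_session("down", seed = 2)
  tr <- sess$trials
  i1 <- match(1L, sess$hierarchy_pre$rank)
  i7 <- match(7L, sess$hierarchy_pre$rank)
  hit <- tr$block == 4 &
    ((tr$left_item == i1 & tr$right_item == i7) |
       (tr$left_item == i7 & tr$right_item == i1))
  first <- min(tr$trial[hit])
  expect_true(all(tr$phase[tr$trial < first] == "pre"))
  expect_true(all(tr$phase[tr$trial >= first] == "post"))
  expect_true(all(tr$phase[tr$block <= 3] == "pre"))
  # block-4 trials before the boundary stay pre
  expect_identical(sum(tr$block == 4 & tr$phase == "pre"),
                   sum(tr$block == 4 & tr$trial < first))

  # no-changepoint control session is all pre
  none <- generate_session("none", seed = 2)
  expect_true(all(none$trials$phase == "pre"))
})
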