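#' Build a randomly ranked item hierarchy
#'
#' Assigns each of `n_items` items a distinct ground-truth rank (1 =
#' lowest), emulating the random allocation of stimuli to ranks at the
#' start of a session.  Item identities are the integers `1..n_items`;
#' throughout the package, "i_r" denotes the item holding *pre-changepoint*
#' rank r.
#'
#' @param n_items number of items in the hierarchy (default 7; minimum 3).
#' @param seed optional integer seed; the same seed always yields the same
#'   hierarchy.  `NULL` draws from the current RNG stream.
#' @return an object of class `ti_hierarchy`: a list with elements `rank`
#'   (integer vector, `rank[i]` is the rank of item i), `n_items`,
#'   `condition` (`"none"`, `"up"` or `"down"`) and `changed` (logical).
#' @seealso [apply_changepoint()], [feedback_rule()], [generate_session()]
#' @export
#' @examples
#' h <- build_hierarchy(7, seed = 1)
#' sort(h$rank)          # a permutation of 1..7
#' hierarchy_order(h)    # item ids from lowest to highest rank
build_hierarchy <- function(n_items = 7, seed = NULL) {
  if (!is_count(n_items) || n_items < 3)
    stop("invalid design: a hierarchy needs at least 3 items", call. = FALSE)
  n_items <- as.integer(n_items)
  ranks <- with_seed_if(seed, sample.int(n_items))
  new_hierarchy(ranks, condition = "none", changed = FALSE)
}

new_hierarchy <- function(ranks, condition, changed) {
  structure(
    list(rank = as.integer(ranks), n_items = length(ranks),
         condition = condition, changed = changed),
    class = "ti_hierarchy")
}

#' @export
print.ti_hierarchy <- function(x, ...) {
  cat("<ti_hierarchy> ", x$n_items, " items, condition=", x$condition,
      if (x$changed) " (changepoint applied)" else "", "\n", sep = "")
  cat("  items lowest to highest: ",
      paste(hierarchy_order(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Item ids ordered from lowest to highest rank
#'
#' With items initially ranked in id order, the post-changepoint orderings
#' read `7123456` ('down') and `2345671` ('up').
#'
#' @param h a `ti_hierarchy`.
#' @return integer vector of item ids, position r holding the rank-r item.
#' @export
hierarchy_order <- function(h) order(h$rank)

#' Rank lookup
#'
#' @param h a `ti_hierarchy`.
#' @param items item ids.
#' @return integer ranks of `items` under `h`.
#' @export
rank_of <- function(h, items) h$rank[items]

#' Apply the mid-session changepoint to a hierarchy
#'
#' In the 'down' condition the top-ranked item moves to the bottom (all
#' other items shift up one rank); in the 'up' condition the bottom-ranked
#' item moves to the top (all others shift down one).  The relative order
#' of all non-moved items is preserved.  `"none"` is the identity.
#'
#' @param h a `ti_hierarchy` that has not yet been changed.
#' @param condition `"up"`, `"down"` or `"none"`.
#' @return the restructured `ti_hierarchy` with `changed = TRUE` (unless
#'   `condition = "none"`).
#' @export
#' @examples
#' h <- new_hierarchy_identity(7)
#' hierarchy_order(apply_changepoint(h, "down"))  # 7 1 2 3 4 5 6
#' hierarchy_order(apply_changepoint(h, "up"))    # 2 3 4 5 6 7 1
apply_changepoint <- function(h, condition = c("up", "down", "none")) {
  condition <- match.arg(condition)
  if (condition == "none") return(h)
  if (isTRUE(h$changed))
    stop("changepoint already applied to this hierarchy", call. = FALSE)
  n <- h$n_items
  r <- h$rank
  if (condition == "down") {
    moved <- r == n
    r[!moved] <- r[!moved] + 1L
    r[moved] <- 1L
  } else {
    moved <- r == 1L
    r[!moved] <- r[!moved] - 1L
    r[moved] <- n
  }
  new_hierarchy(r, condition, changed = TRUE)
}

#' Identity-ranked hierarchy
#'
#' Convenience constructor in which item i holds rank i; useful for reading
#' changepoint orderings directly.
#'
#' @param n_items number of items.
#' @return a `ti_hierarchy`.
#' @export
new_hierarchy_identity <- function(n_items = 7) {
  new_hierarchy(seq_len(n_items), condition = "none", changed = FALSE)
}

#' Feedback rule: do two items trigger feedback?
#'
#' Feedback is delivered exactly when the compared items are neighbours in
#' rank under the hierarchy in force ('adjacent trials'); non-neighbouring
#' ('TI') comparisons are silent.
#'
#' @param x,y distinct item ids.
#' @param h the `ti_hierarchy` in force on the trial.
#' @return logical.
#' @export
feedback_rule <- function(x, y, h) {
  if (any(x == y)) stop("invalid pair: items must differ", call. = FALSE)
  abs(h$rank[x] - h$rank[y]) == 1L
}
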