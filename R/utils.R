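# Internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream;
# seed = NULL runs in the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# x*log(x) with the 0*log(0) = 0 convention
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

# Draw sub-seeds for per-participant / per-stage reproducibility; kept
# below 2^31 so they are valid R integer seeds.
draw_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

# rbind data.frames with differing columns, padding with NA.
rbind_fill <- function(dfs) {
  dfs <- dfs[!vapply(dfs, is.null, logical(1))]
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (nm in setdiff(cols, names(d))) d[[nm]] <- NA
    d[cols]
  }))
}
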