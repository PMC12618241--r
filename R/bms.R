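# Random-effects Bayesian model selection over per-participant model
# evidences (variational Dirichlet-multinomial scheme), with exceedance
# probabilities, Bayes omnibus risk and protected exceedance
# probabilities.

#' Log model evidence from AIC values
#'
#' Approximates each participant-model log evidence as `-AIC/2`.
#'
#' @param aic_matrix numeric matrix or data.frame, participants x models
#'   (at least two model columns), finite entries.
#' @return log-evidence matrix of the same shape.
#' @export
evidence_from_aic <- function(aic_matrix) {
  m <- as.matrix(aic_matrix)
  if (ncol(m) < 2L)
    stop("model selection needs at least two models", call. = FALSE)
  if (any(!is.finite(m)))
    stop("AIC matrix contains non-finite entries", call. = FALSE)
  -m / 2
}

#' Random-effects Bayesian model selection
#'
#' Treats the model generating each participant's data as a draw from an
#' unknown population frequency vector `r` with a Dirichlet prior, and
#' estimates the posterior over `r` by variational Bayes (iterating
#' responsibilities and Dirichlet concentrations to convergence).  Reports
#' per-model expected frequencies, exceedance probabilities (`xp`: the
#' probability that a model is the most frequent), the Bayes omnibus risk
#' (`bor`: posterior probability of the equal-frequency null, from the
#' variational free energies of the random-effects and null models), and
#' protected exceedance probabilities
#' `pxp = xp * (1 - bor) + bor / M`.
#'
#' Exceedance probabilities use the exact Beta integral for two models and
#' seeded Dirichlet Monte-Carlo otherwise.
#'
#' @param log_evidence participants x models matrix (e.g. from
#'   [evidence_from_aic()]).
#' @param prior_alpha prior Dirichlet concentration per model (default 1,
#'   uniform).
#' @param tol convergence tolerance on the concentrations.
#' @param maxit iteration cap; non-convergence is flagged, not fatal.
#' @param nsamp Monte-Carlo sample count for `xp` when M > 2.
#' @param seed seed for the Monte-Carlo draw.
#' @return object of class `ti_bms`: `models`, `alpha` (posterior
#'   concentrations), `expected_freq`, `xp`, `bor`, `pxp`, `free_energy`,
#'   `null_free_energy`, `converged`, `iterations`.
#' @export
rfx_bms <- function(log_evidence, prior_alpha = 1, tol = 1e-6, maxit = 1e4,
                    nsamp = 1e6, seed = 1L) {
  l <- as.matrix(log_evidence)
  M <- ncol(l)
  N <- nrow(l)
  if (M < 2L) stop("need at least two models", call. = FALSE)
  if (N < 1L) stop("need at least one participant", call. = FALSE)
  if (any(!is.finite(l)))
    stop("log-evidence matrix contains non-finite entries", call. = FALSE)
  models <- colnames(l) %||% paste0("m", seq_len(M))
  alpha0 <- rep(prior_alpha, M)
  alpha <- alpha0
  u <- matrix(1 / M, N, M)
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    elnr <- digamma(alpha) - digamma(sum(alpha))
    lu <- sweep(l, 2L, elnr, "+")
    lu <- lu - apply(lu, 1L, max)
    u <- exp(lu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  expected_freq <- alpha / sum(alpha)

  xp <- exceedance_prob(alpha, nsamp = nsamp, seed = seed)

  # variational free energy of the random-effects model ...
  elnr <- digamma(alpha) - digamma(sum(alpha))
  lnC <- function(a) lgamma(sum(a)) - sum(lgamma(a))
  F1 <- sum(u * l) - sum(xlogx(u)) + lnC(alpha0) - lnC(alpha) +
    sum((colSums(u) + alpha0 - alpha) * elnr)
  # ... versus the null model with frequencies fixed equal (1/M each)
  F0 <- sum(apply(l, 1L, function(row) logsumexp(row - log(M))))
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- xp * (1 - bor) + bor / M

  structure(
    list(models = models, alpha = setNames(alpha, models),
         expected_freq = setNames(expected_freq, models),
         xp = setNames(xp, models), bor = bor,
         pxp = setNames(pxp, models), free_energy = F1,
         null_free_energy = F0, converged = converged, iterations = it),
    class = "ti_bms")
}

#' @export
print.ti_bms <- function(x, ...) {
  cat("<ti_bms> ", length(x$models), " models, BOR=", signif(x$bor, 3),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(round(rbind(expected_freq = x$expected_freq, xp = x$xp,
                    pxp = x$pxp), 4))
  invisible(x)
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' Probability, per model, that its population frequency exceeds all
#' others under `Dirichlet(alpha)`.  Exact via the Beta distribution for
#' two models; seeded Monte-Carlo otherwise.
#'
#' @param alpha Dirichlet concentration vector (length >= 2).
#' @param nsamp number of Monte-Carlo draws when `length(alpha) > 2`.
#' @param seed RNG seed for the Monte-Carlo draw.
#' @return numeric vector summing to 1.
#' @export
exceedance_prob <- function(alpha, nsamp = 1e6, seed = 1L) {
  M <- length(alpha)
  stopifnot(M >= 2L)
  if (M == 2L) {
    xp1 <- 1 - pbeta(0.5, alpha[1L], alpha[2L])
    return(c(xp1, 1 - xp1))
  }
  withr::with_seed(seed, {
    g <- matrix(rgamma(nsamp * M, shape = rep(alpha, each = nsamp)),
                nsamp, M)
    tabulate(max.col(g), M) / nsamp
  })
}

#' Expected model frequencies from a BMS result
#'
#' @param result a `ti_bms`.
#' @return named numeric vector `alpha / sum(alpha)`, summing to 1.
#' @export
model_frequency_estimates <- function(result) {
  stopifnot(inherits(result, "ti_bms"))
  result$alpha / sum(result$alpha)
}
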