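#' Hypothesis model for an nAFC task
#'
#' Bundles the `n` Gaussian evidence distributions: isotropic normals in
#' (n-1)-dimensional evidence space whose means sit at the vertices of a
#' regular simplex with edge `delta_mu` and common standard deviation
#' `sigma`. Equidistant means give equal discriminability between every pair
#' of choices, so the task is symmetric whatever the true hypothesis.
#'
#' @param n Number of choices (>= 2).
#' @param delta_mu Pairwise separation of the means (> 0). Default 1
#'   (unit-edge simplex).
#' @param sigma Evidence standard deviation per coordinate (> 0). Default 1.
#' @return An object of class `hypothesis_model` with elements `n`, `means`
#'   (`n x (n-1)` matrix), `sigma`, `delta_mu`.
#' @examples
#' m <- hypothesis_model(3)
#' dist(m$means)   # all pairwise distances 1
#' @export
hypothesis_model <- function(n, delta_mu = 1, sigma = 1) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  means <- simplex_vertices(n, delta_mu)   # validates n, delta_mu
  structure(
    list(n = as.integer(n), means = means, sigma = sigma,
         delta_mu = delta_mu),
    class = "hypothesis_model")
}

#' @export
print.hypothesis_model <- function(x, ...) {
  cat(sprintf("nAFC hypothesis model: n = %d, delta_mu = %g, sigma = %g\n",
              x$n, x$delta_mu, x$sigma))
  invisible(x)
}

#' Draw one evidence sample
#'
#' One observation from the true hypothesis: an isotropic Gaussian draw with
#' mean `means[true_index + 1, ]` and per-coordinate standard deviation
#' `sigma`. Uses R's RNG, so `set.seed()` controls reproducibility.
#'
#' @param model A [hypothesis_model()].
#' @param true_index Zero-based index of the true hypothesis.
#' @return Numeric vector of length `n - 1`.
#' @export
sample_evidence <- function(model, true_index) {
  stopifnot(inherits(model, "hypothesis_model"))
  if (length(true_index) != 1L || !is.finite(true_index) ||
      true_index < 0 || true_index >= model$n || true_index != round(true_index))
    stop("`true_index` must be an integer in [0, n)", call. = FALSE)
  mu <- model$means[true_index + 1L, ]
  mu + stats::rnorm(length(mu), sd = model$sigma)
}

#' Log-likelihoods of an evidence sample under all hypotheses
#'
#' `log P(x | H_i)` for each of the `n` isotropic Gaussian hypotheses.
#' Differences satisfy
#' `log L_i - log L_j = (||x - mu_j||^2 - ||x - mu_i||^2) / (2 sigma^2)`;
#' the common additive constant is irrelevant to the posterior but retained
#' so the values are genuine log-densities.
#'
#' @param model A [hypothesis_model()].
#' @param x Evidence vector of length `n - 1`.
#' @return Numeric vector of `n` log-densities.
#' @export
log_likelihoods <- function(model, x) {
  stopifnot(inherits(model, "hypothesis_model"))
  if (!is.numeric(x) || length(x) != model$n - 1L || any(!is.finite(x)))
    stop("`x` must be a finite numeric vector of length n - 1", call. = FALSE)
  d <- ncol(model$means)
  sq <- rowSums(sweep(model$means, 2L, x)^2)
  -sq / (2 * model$sigma^2) - d * log(model$sigma * sqrt(2 * pi))
}

#' Sequential Bayesian belief update (log domain)
#'
#' One step of Bayesian updating with the previous posterior as prior:
#' `log P_i(t+1) = log P_i(t) + log L_i(t) - log M(t)` where the log-marginal
#' `log M(t)` is computed by log-sum-exp. Working in the log domain keeps
#' long trajectories stable; the result is renormalized exactly.
#'
#' @param log_state Numeric vector of `n` log-probabilities (log-sum-exp 0).
#' @param logL Numeric vector of `n` log-likelihoods.
#' @return Updated vector of `n` normalized log-probabilities.
#' @export
bayes_update <- function(log_state, logL) {
  if (!is.numeric(log_state) || !is.numeric(logL) ||
      length(log_state) != length(logL))
    stop("`log_state` and `logL` must be numeric vectors of equal length",
         call. = FALSE)
  if (any(is.na(log_state)) || any(is.na(logL)) || any(logL == Inf) ||
      any(log_state == Inf))
    stop("inputs must be finite (or -Inf for zero probability)",
         call. = FALSE)
  u <- log_state + logL
  u - logsumexp(u)
}

#' SPRT log probability-ratio update
#'
#' The two-choice sequential probability ratio test accumulates the log
#' likelihood ratio additively: `log PR(t+1) = log PR(t) + log LR(t)`. With a
#' uniform prior this equals the log-odds of the Bayesian posterior at every
#' step, which is the package's cross-check between the two formulations.
#'
#' @param log_pr Current log probability ratio (finite).
#' @param log_lr Log likelihood ratio of the new sample (finite).
#' @return `log_pr + log_lr`.
#' @export
sprt_log_pr_update <- function(log_pr, log_lr) {
  if (!is.numeric(log_pr) || !is.numeric(log_lr) ||
      any(!is.finite(log_pr)) || any(!is.finite(log_lr)))
    stop("inputs must be finite numerics", call. = FALSE)
  log_pr + log_lr
}

#' Uniform prior in the log domain
#'
#' @param n Number of choices.
#' @return `rep(-log(n), n)`.
#' @export
uniform_log_prior <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
    stop("`n` must be a single integer >= 2", call. = FALSE)
  rep(-log(n), as.integer(n))
}

# numerically stable log(sum(exp(u)))
logsumexp <- function(u) {
  m <- max(u)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(u - m)))
}
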