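#' Cost specification for the speed/accuracy reward
#'
#' A decision earns `r = -W e - c T`: an error cost `W` paid on incorrect
#' choices (`e = 1`) plus a time cost `c` per evidence sample. Only the
#' ratio `c/W` matters for the optimal boundary; with the default `W = 1`
#' the per-step cost `c` equals the cost ratio.
#'
#' @param W Error cost (> 0), identical for every error type.
#' @param c Cost per time step (>= 0).
#' @return Object of class `cost_spec`.
#' @export
cost_spec <- function(c, W = 1) {
  if (length(W) != 1L || !is.finite(W) || W <= 0)
    stop("`W` must be a single positive number", call. = FALSE)
  if (length(c) != 1L || !is.finite(c) || c < 0)
    stop("`c` must be a single nonnegative number", call. = FALSE)
  structure(list(W = W, c = c), class = "cost_spec")
}

#' @export
print.cost_spec <- function(x, ...) {
  cat(sprintf("costs: W = %g, c = %g (c/W = %g)\n", x$W, x$c, x$c / x$W))
  invisible(x)
}

family_code <- function(family) {
  match(family, c("flat", "curve", "power", "oscil")) - 1L
}

#' Run a batch of decision trials
#'
#' Simulates independent decision episodes: belief starts at the uniform
#' prior, one evidence sample and one Bayesian update per step, stopping at
#' the first step whose post-update belief strictly crosses the boundary.
#' Trials that never cross within `max_steps` are flagged
#' (`terminated = FALSE`) with no reward assigned.
#'
#' All randomness comes from deterministic counter-based substreams derived
#' from `seed` (and `stream`, which distinguishes independent batches under
#' one master seed); R's RNG state is untouched.
#'
#' @param model A [hypothesis_model()].
#' @param spec A [boundary_spec()].
#' @param costs A [cost_spec()].
#' @param n_trials Number of trials.
#' @param seed Master seed (integer).
#' @param true_index Zero-based true hypothesis, or `NULL` (default) to draw
#'   it uniformly per trial (the symmetric task).
#' @param max_steps Step cap per trial (default 10000).
#' @param stream Substream index (default 0); batches with different streams
#'   under the same seed are independent.
#' @return A data.frame with one row per trial: `trial_id`, `true_index`,
#'   `chosen`, `error`, `T`, `reward`, `crossing_belief`, `terminated`.
#' @examples
#' m <- hypothesis_model(3)
#' b <- boundary_spec("flat", theta = 0.8)
#' head(run_trials(m, b, cost_spec(0.04), n_trials = 10, seed = 1))
#' @export
run_trials <- function(model, spec, costs, n_trials, seed,
                       true_index = NULL, max_steps = 10000L, stream = 0L) {
  stopifnot(inherits(model, "hypothesis_model"),
            inherits(spec, "boundary_spec"),
            inherits(costs, "cost_spec"))
  if (length(n_trials) != 1L || !is.finite(n_trials) || n_trials < 1)
    stop("`n_trials` must be >= 1", call. = FALSE)
  if (length(max_steps) != 1L || !is.finite(max_steps) || max_steps < 1)
    stop("`max_steps` must be >= 1", call. = FALSE)
  ti <- -1L
  if (!is.null(true_index)) {
    if (length(true_index) != 1L || !is.finite(true_index) ||
        true_index < 0 || true_index >= model$n ||
        true_index != round(true_index))
      stop("`true_index` must be an integer in [0, n)", call. = FALSE)
    ti <- as.integer(true_index)
  }
  cpp_run_trials(model$means, model$sigma, family_code(spec$family),
                 spec$theta, spec$alpha, spec$beta,
                 costs$W, costs$c, as.integer(n_trials),
                 as.integer(max_steps), as.numeric(seed),
                 as.integer(stream), ti)
}

#' Run a single decision trial
#'
#' Convenience wrapper around [run_trials()] for one episode with a fixed
#' true hypothesis.
#'
#' @inheritParams run_trials
#' @param true_index Zero-based true hypothesis (required).
#' @return A list of class `trial_outcome` with fields `chosen`,
#'   `true_index`, `error`, `T`, `reward`, `crossing_belief`, `terminated`.
#' @export
run_trial <- function(model, spec, costs, true_index, seed,
                      max_steps = 10000L, stream = 0L) {
  if (is.null(true_index))
    stop("`true_index` is required for a single trial", call. = FALSE)
  df <- run_trials(model, spec, costs, n_trials = 1L, seed = seed,
                   true_index = true_index, max_steps = max_steps,
                   stream = stream)
  out <- as.list(df[1L, c("chosen", "true_index", "error", "T", "reward",
                          "crossing_belief", "terminated")])
  structure(out, class = "trial_outcome")
}

#' @export
print.trial_outcome <- function(x, ...) {
  if (x$terminated)
    cat(sprintf("trial: chose %d (true %d, error %d) at T = %d, reward %g\n",
                x$chosen, x$true_index, x$error, x$T, x$reward))
  else
    cat(sprintf("trial: unterminated (true %d)\n", x$true_index))
  invisible(x)
}

#' Monte-Carlo reward estimate for one boundary
#'
#' Runs `n_trials` episodes (true hypothesis uniform per trial) and
#' aggregates them. Means are taken over terminated trials only;
#' unterminated trials are counted and reported. By construction the
#' aggregate satisfies the reward decomposition
#' `mean_reward = -W * mean_error - c * mean_T` exactly, which is why a
#' single mean reward admits many (error, time) trade-offs.
#'
#' @inheritParams run_trials
#' @param keep_outcomes Attach the per-trial data.frame as attribute
#'   `"outcomes"`? Default `FALSE`.
#' @return Object of class `reward_estimate`: `mean_reward`, `reward_std`
#'   (per-trial spread of rewards), `mean_error`, `mean_T`, `n_trials`,
#'   `n_unterminated`.
#' @export
estimate_reward <- function(model, spec, costs, n_trials, seed,
                            max_steps = 10000L, stream = 0L,
                            keep_outcomes = FALSE) {
  df <- run_trials(model, spec, costs, n_trials = n_trials, seed = seed,
                   true_index = NULL, max_steps = max_steps, stream = stream)
  est <- summarize_outcomes(df, costs)
  if (keep_outcomes) attr(est, "outcomes") <- df
  est
}

#' Aggregate a batch of trial outcomes
#'
#' @param outcomes Data.frame from [run_trials()].
#' @param costs The [cost_spec()] used (recorded for the identity check).
#' @return A `reward_estimate`.
#' @export
summarize_outcomes <- function(outcomes, costs) {
  stopifnot(is.data.frame(outcomes), inherits(costs, "cost_spec"))
  term <- outcomes[outcomes$terminated, , drop = FALSE]
  n_un <- sum(!outcomes$terminated)
  if (nrow(term) == 0L) {
    warning("all trials unterminated; estimate is empty", call. = FALSE)
    est <- list(mean_reward = NA_real_, reward_std = NA_real_,
                mean_error = NA_real_, mean_T = NA_real_,
                n_trials = nrow(outcomes), n_unterminated = n_un,
                W = costs$W, c = costs$c)
  } else {
    est <- list(
      mean_reward = mean(term$reward),
      reward_std = stats::sd(term$reward),
      mean_error = mean(term$error),
      mean_T = mean(term$T),
      n_trials = nrow(outcomes),
      n_unterminated = n_un,
      W = costs$W, c = costs$c)
  }
  structure(est, class = "reward_estimate")
}

#' @export
print.reward_estimate <- function(x, ...) {
  cat(sprintf(
    "reward estimate (%d trials, %d unterminated):\n  mean reward %.5f (sd %.4f), mean error %.4f, mean T %.2f\n",
    x$n_trials, x$n_unterminated, x$mean_reward, x$reward_std,
    x$mean_error, x$mean_T))
  invisible(x)
}
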