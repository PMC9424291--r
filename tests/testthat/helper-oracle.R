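# Independent oracles, deliberately written as literal/naive code paths so
# they share nothing with the package implementations they check.

# Literal transcription of the general boundary parameterization:
# F = theta * [1 + alpha/C * sum_j f(dmax_j; beta) * prod_{i in j} P_i]
naive_boundary_value <- function(p, family, theta, alpha, beta) {
  n <- length(p)
  if (n < 3) return(theta)
  combs <- utils::combn(n, 3)
  C3n <- ncol(combs)
  total <- 0
  for (col in seq_len(C3n)) {
    idx <- combs[, col]
    p3 <- p[idx]
    dmax <- max(abs(c(p3[1] - p3[2], p3[1] - p3[3], p3[2] - p3[3])))
    f <- if (family == "flat") 0
         else if (family == "curve") 1
         else if (family == "power") p3_pow(dmax, beta)
         else if (family == "oscil") cos(2 * pi * beta * dmax)
         else stop("bad family")
    prodp <- p3[1] * p3[2] * p3[3]
    total <- total + f * prodp
  }
  theta * (1 + (alpha / C3n) * total)
}
p3_pow <- function(d, b) if (d == 0 && b == 0) 1 else d^b

# random belief vectors, uniform on the simplex
random_beliefs <- function(m, n) {
  g <- matrix(stats::rexp(m * n), m, n)
  g / rowSums(g)
}

# Linear-domain Bayes rule (the textbook form), used to check the
# log-domain update.
linear_bayes <- function(prior, lik) {
  u <- prior * lik
  u / sum(u)
}

# Pure-R two-choice simulator: runs the posterior rule and the SPRT rule on
# the SAME evidence stream (drawn from R's RNG) and returns both outcomes.
# Likelihoods via dnorm products, stopping at posterior > Theta vs
# |log PR| > log-odds(Theta).
r_sim_2afc <- function(delta_mu, sigma, Theta, truth, max_steps = 10000) {
  mu <- c(+delta_mu / 2, -delta_mu / 2)
  prior <- c(0.5, 0.5)
  log_pr <- 0
  post_T <- NA_integer_; post_choice <- NA_integer_
  sprt_T <- NA_integer_; sprt_choice <- NA_integer_
  theta_lo <- log(Theta / (1 - Theta))
  for (t in seq_len(max_steps)) {
    x <- stats::rnorm(1, mean = mu[truth + 1], sd = sigma)
    lik <- stats::dnorm(x, mean = mu, sd = sigma)
    prior <- linear_bayes(prior, lik)
    log_pr <- log_pr + log(lik[1] / lik[2])
    if (is.na(post_T) && max(prior) > Theta) {
      post_T <- t; post_choice <- which.max(prior) - 1L
    }
    if (is.na(sprt_T) && abs(log_pr) > theta_lo) {
      sprt_T <- t; sprt_choice <- if (log_pr > 0) 0L else 1L
    }
    if (!is.na(post_T) && !is.na(sprt_T)) break
  }
  list(post = list(T = post_T, choice = post_choice),
       sprt = list(T = sprt_T, choice = sprt_choice))
}

# all 24 permutations of 1:4
combinat_perms4 <- function() {
  out <- list()
  for (i in 1:4) for (j in setdiff(1:4, i)) for (k in setdiff(1:4, c(i, j)))
    out[[length(out) + 1L]] <- c(i, j, k, setdiff(1:4, c(i, j, k)))
  out
}

# Synthetic landscape-like table for acceptance-region tests.
synthetic_grid <- function(mean_reward, reward_std, n_trials = 1000L) {
  k <- length(mean_reward)
  structure(
    data.frame(family = "curve", theta = seq_len(k) / (k + 1), alpha = 0,
               beta = 0, cost_ratio = 0.04, mean_reward = mean_reward,
               reward_std = reward_std, mean_error = 0.1, mean_T = 10,
               n_trials = n_trials, n_unterminated = 0L),
    class = c("landscape_grid", "data.frame"))
}
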