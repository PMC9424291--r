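m3 <- hypothesis_model(3)

test_that("trial outcomes satisfy the reward and crossing contracts", {
  spec <- boundary_spec("flat", 0.8)
  costs <- cost_spec(c = 0.04, W = 1)
  out <- run_trials(m3, spec, costs, n_trials = 2000, seed = 4)
  term <- out[out$terminated, ]
  expect_gt(nrow(term), 0)
  # reward = -W e - c T exactly, per trial
  expect_equal(term$reward, -costs$W * term$error - costs$c * term$T,
               tolerance = 1e-12)
  # error = 0 iff chosen = true
  expect_identical(term$error == 0L, term$chosen == term$true_index)
  # crossing belief strictly exceeds the flat boundary level
  expect_true(all(term$crossing_belief > spec$theta))
  expect_true(all(term$T >= 1L))
})

test_that("noiseless evidence gives deterministic correct decisions", {
  m0 <- hypothesis_model(3, delta_mu = 1, sigma = 1e-6)
  out <- run_trials(m0, boundary_spec("flat", 0.9), cost_spec(0.04),
                    n_trials = 200, seed = 2, true_index = 1)
  expect_true(all(out$terminated))
  expect_true(all(out$error == 0L))
  expect_equal(length(unique(out$T)), 1L)
})

test_that("batches are deterministic per (seed, stream) and independent across streams", {
  spec <- boundary_spec("curve", 0.7, 5)
  costs <- cost_spec(0.02)
  a <- run_trials(m3, spec, costs, 500, seed = 10, stream = 3)
  b <- run_trials(m3, spec, costs, 500, seed = 10, stream = 3)
  expect_identical(a, b)
  c_ <- run_trials(m3, spec, costs, 500, seed = 10, stream = 4)
  expect_false(identical(a$reward, c_$reward))
  d <- run_trials(m3, spec, costs, 500, seed = 11, stream = 3)
  expect_false(identical(a$reward, d$reward))
})

test_that("unterminated trials are flagged, not rewarded", {
  # a boundary pushed above 1 in the interior with a tight step cap
  spec <- boundary_spec("flat", 0.999999)
  out <- run_trials(m3, spec, cost_spec(0.04), 50, seed = 6, max_steps = 2)
  expect_true(any(!out$terminated))
  un <- out[!out$terminated, ]
  expect_true(all(is.na(un$reward)))
  expect_true(all(is.na(un$chosen)))
  est <- suppressWarnings(summarize_outcomes(out, cost_spec(0.04)))
  expect_equal(est$n_unterminated, sum(!out$terminated))
})

test_that("estimate_reward satisfies the mean-reward decomposition exactly", {
  for (cw in c(0.01, 0.1)) {
    costs <- cost_spec(c = cw * 2, W = 2)
    est <- estimate_reward(m3, boundary_spec("flat", 0.75), costs,
                           n_trials = 3000, seed = 12)
    expect_equal(est$mean_reward,
                 -costs$W * est$mean_error - costs$c * est$mean_T,
                 tolerance = 1e-10)
  }
})

test_that("posterior-threshold calibration: accuracy matches the threshold", {
  # n = 2, flat Theta = 0.9: overshoot makes empirical accuracy >= 0.9
  est <- estimate_reward(hypothesis_model(2), boundary_spec("flat", 0.9),
                         cost_spec(0.04), n_trials = 10000, seed = 13)
  acc <- 1 - est$mean_error
  se <- sqrt(est$mean_error * (1 - est$mean_error) / est$n_trials)
  expect_gte(acc, 0.9 - 3 * se)
})

test_that("statistics are invariant to relabeling the true hypothesis", {
  spec <- boundary_spec("flat", 0.8)
  costs <- cost_spec(0.04)
  n_tr <- 4000
  ests <- lapply(0:2, function(k)
    summarize_outcomes(run_trials(m3, spec, costs, n_tr, seed = 14,
                                  true_index = k, stream = k), costs))
  Ts <- vapply(ests, `[[`, numeric(1), "mean_T")
  es <- vapply(ests, `[[`, numeric(1), "mean_error")
  # agree within ~4 Monte-Carlo standard errors
  se_err <- sqrt(max(es) * (1 - max(es)) / n_tr)
  expect_lt(max(es) - min(es), 4 * se_err * sqrt(2))
  expect_lt(max(Ts) - min(Ts), 0.1 * mean(Ts) + 4 * 0.1)
})

test_that("flat boundary: higher theta is slower and more accurate", {
  costs <- cost_spec(0.04)
  ests <- lapply(seq_along(c(0.5, 0.7, 0.9)), function(i) {
    th <- c(0.5, 0.7, 0.9)[i]
    estimate_reward(m3, boundary_spec("flat", th), costs, 4000,
                    seed = 15, stream = i)
  })
  Ts <- vapply(ests, `[[`, numeric(1), "mean_T")
  es <- vapply(ests, `[[`, numeric(1), "mean_error")
  expect_true(all(diff(Ts) > 0))
  expect_true(all(diff(es) < 0))
})

test_that("n = 2 engine statistics match an independent SPRT oracle", {
  # (i) rule equivalence, trial by trial on one shared evidence stream
  set.seed(16)
  for (i in 1:30) {
    sim <- r_sim_2afc(delta_mu = 1, sigma = 1, Theta = 0.8,
                      truth = i %% 2)
    expect_identical(sim$post$T, sim$sprt$T)
    expect_identical(sim$post$choice, sim$sprt$choice)
  }
  # (ii) engine batch statistics agree with the pure-R posterior simulator
  # within Monte-Carlo error (independent streams)
  m2 <- hypothesis_model(2)
  est <- estimate_reward(m2, boundary_spec("flat", 0.8), cost_spec(0.04),
                         n_trials = 4000, seed = 17)
  set.seed(18)
  res <- t(replicate(1500, {
    tr <- sample(0:1, 1)
    s <- r_sim_2afc(1, 1, 0.8, truth = tr)
    c(T = s$post$T, err = as.integer(s$post$choice != tr))
  }))
  se_T <- stats::sd(res[, "T"]) / sqrt(nrow(res))
  se_e <- sqrt(mean(res[, "err"]) * (1 - mean(res[, "err"])) / nrow(res))
  expect_lt(abs(est$mean_T - mean(res[, "T"])), 4 * se_T + 0.05)
  expect_lt(abs(est$mean_error - mean(res[, "err"])), 4 * se_e + 0.005)
})
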