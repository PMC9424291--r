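test_that("SAT points extract accepted cells with their labels", {
  g <- synthetic_grid(c(-0.3, -0.1, -0.32), 0.2)
  g$mean_error <- c(0.2, 0.1, 0.05)
  g$mean_T <- c(5, 8, 12)
  acc <- acceptance_region(g, delta = 0)
  pts <- sat_points(acc)
  expect_equal(nrow(pts), 1L)
  expect_equal(pts$mean_error, 0.1)
  expect_equal(pts$mean_T, 8)

  # two cells with equal reward but different (error, T): two SAT points
  g2 <- synthetic_grid(c(-0.5, -0.5), 0.2)
  g2$mean_error <- c(0.1, 0.3); g2$mean_T <- c(10, 5)
  pts2 <- sat_points(acceptance_region(g2, 0))
  expect_equal(nrow(pts2), 2L)
  expect_equal(sort(pts2$mean_T), c(5, 10))

  # empty set: flagged empty output
  ge <- g[0, ]
  class(ge) <- c("acceptance_set", "data.frame")
  ge$delta <- numeric()
  expect_warning(p0 <- sat_points(list(ge)), "empty")
  expect_equal(nrow(p0), 0L)
})

test_that("mean SAT curve averages family-balanced in cost-ratio order", {
  pts <- data.frame(
    cost_ratio = c(0.1, 0.1, 0.1, 0.01, 0.01),
    family = c("curve", "curve", "oscil", "curve", "oscil"),
    theta = 0.6, alpha = 0, beta = 0,
    mean_error = c(0.2, 0.4, 0.1, 0.05, 0.15),
    mean_T = c(4, 6, 8, 20, 30),
    mean_reward = -1)
  cv <- mean_sat_curve(pts)
  expect_equal(cv$cost_ratio, c(0.01, 0.1))
  # family means first: curve (0.3, 5), oscil (0.1, 8) -> (0.2, 6.5)
  expect_equal(cv$mean_error[2], 0.2)
  expect_equal(cv$mean_T[2], 6.5)
  expect_equal(cv$mean_T[1], 25)
  # duplicating one family's rows leaves the balanced mean unchanged
  cv2 <- mean_sat_curve(rbind(pts, pts[pts$family == "curve", ]))
  expect_equal(cv2$mean_T, cv$mean_T)
  expect_warning(mean_sat_curve(pts[pts$cost_ratio == 0.1, ]), "single")
})

test_that("implicit threshold series groups, filters, and transforms", {
  # constant crossing beliefs -> constant series, static
  out <- data.frame(T = rep(c(2, 3, 4, 5), each = 10),
                    crossing_belief = 0.8, terminated = TRUE)
  its <- implicit_threshold(out, min_count = 5)
  expect_equal(its$series$mean_crossing_belief, rep(0.8, 4))
  expect_equal(its$series$transformed_threshold, rep(log_odds(0.8), 4))
  expect_identical(its$category, "static")

  # beliefs decreasing in T -> collapsing
  tt <- rep(2:8, each = 8)
  out2 <- data.frame(T = tt, crossing_belief = 0.95 - 0.05 * tt,
                     terminated = TRUE)
  expect_identical(implicit_threshold(out2)$category, "collapsing")
  # and increasing in T -> increasing
  out3 <- data.frame(T = tt, crossing_belief = 0.4 + 0.05 * tt,
                     terminated = TRUE)
  expect_identical(implicit_threshold(out3)$category, "increasing")

  # sparse times dropped; averages within groups verified by hand
  out4 <- data.frame(T = c(rep(2, 6), rep(3, 6), rep(9, 2), rep(4, 6)),
                     crossing_belief = c(rep(0.7, 6), rep(0.8, 6),
                                         rep(0.99, 2), rep(0.75, 6)),
                     terminated = TRUE)
  s4 <- implicit_threshold(out4, min_count = 5)$series
  expect_equal(s4$times, c(2, 3, 4))
  expect_equal(s4$mean_crossing_belief, c(0.7, 0.8, 0.75))

  expect_warning(
    e <- implicit_threshold(data.frame(T = 1, crossing_belief = 0.5,
                                       terminated = FALSE)),
    "no terminated")
  expect_identical(e$category, NA_character_)
})

test_that("dynamics classifier has the stated operating characteristics", {
  base <- data.frame(times = 1:20, n = 50)
  base$transformed_threshold <- 1.5
  expect_identical(classify_dynamics(base), "static")
  base$transformed_threshold <- 0.1 * base$times
  expect_identical(classify_dynamics(base), "increasing")
  base$transformed_threshold <- -0.1 * base$times
  expect_identical(classify_dynamics(base), "collapsing")
  expect_error(classify_dynamics(base[1:2, ]), "3 time points")

  # noisy zero-slope series: static at >= 90% of 100 replicates
  set.seed(31)
  hits <- 0
  for (i in 1:100) {
    ser <- data.frame(times = 1:15, n = 30,
                      transformed_threshold = 1 + rnorm(15, sd = 0.05))
    hits <- hits + (classify_dynamics(ser) == "static")
  }
  expect_gte(hits, 90)
})

test_that("Hick's law fit recovers exact and degenerate inputs", {
  d <- data.frame(n = c(2, 4, 8, 16), mean_T = 5 + 2 * log(c(2, 4, 8, 16)))
  fit <- hicks_law_fit(d)
  expect_equal(fit$a, 5, tolerance = 1e-10)
  expect_equal(fit$b, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  flatd <- data.frame(n = c(2, 3, 4), mean_T = 7)
  expect_equal(hicks_law_fit(flatd)$b, 0, tolerance = 1e-12)

  # named-vector interface
  fit2 <- hicks_law_fit(c("2" = 5 + 2 * log(2), "4" = 5 + 2 * log(4),
                          "8" = 5 + 2 * log(8)))
  expect_equal(fit2$b, 2, tolerance = 1e-10)
  expect_error(hicks_law_fit(data.frame(n = c(2, 3), mean_T = c(1, 2))),
               "3 distinct")
})

test_that("normalization identities match closed forms", {
  expect_equal(renormalize_added_option(0.6, 0.4, 0),
               c(0.6, 0.4, 0))
  rn <- renormalize_added_option(0.6, 0.4, 0.5)
  expect_equal(rn, c(0.4, 0.8 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(rn, c(0.4, 0.26667, 0.33333), tolerance = 1e-4)
  set.seed(32)
  for (i in 1:20) {
    p0 <- runif(1); p2 <- runif(1)
    expect_equal(sum(renormalize_added_option(p0, 1 - p0, p2)), 1,
                 tolerance = 1e-12)
  }
  expect_error(renormalize_added_option(0.7, 0.4, 0.1), "P0 \\+ P1")
  expect_error(renormalize_added_option(0.6, 0.4, 1.5), "\\[0, 1\\]")

  expect_equal(belief_gap(0.6, 0.4, 0), 0.2, tolerance = 1e-12)
  expect_equal(belief_gap(0.6, 0.4, 0.5), 0.2 / 1.5, tolerance = 1e-12)
  expect_equal(belief_gap(0.6, 0.4, 0.5), 0.13333, tolerance = 1e-4)
  p2s <- seq(0, 1, by = 0.1)
  expect_true(all(diff(belief_gap(0.6, 0.4, p2s)) < 0))

  d0 <- iia_distances(0.5, 0, 0.8)
  expect_equal(d0$d_T, 0.8 - 0.5)
  expect_equal(iia_distances(1 / 3, 0, 0.8)$d, 0, tolerance = 1e-12)
  # d_T increases and d decreases in P2 (finite differences, 100 points)
  set.seed(33)
  for (i in 1:100) {
    pi_ <- runif(1, 0.05, 0.95); p2 <- runif(1, 0, 0.9); h <- 1e-6
    a <- iia_distances(pi_, p2, 0.8); b <- iia_distances(pi_, p2 + h, 0.8)
    expect_gt(b$d_T, a$d_T)
    expect_lt(b$d, a$d)
  }
})
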