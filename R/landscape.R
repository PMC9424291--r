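#' Default boundary-parameter grids
#'
#' The default search axes per family: `theta` spans `(1/n + 0.01, 0.99)`;
#' `alpha` spans `[-20, 20]` (covering the full range of boundary shapes the
#' curve sections explore); `beta` spans `[0, 5]` for `power` and `[0, 3]`
#' for `oscil`.
#'
#' @param n Number of choices.
#' @param family Boundary family.
#' @param n_theta,n_alpha,n_beta Grid sizes (defaults 15, 9, 5).
#' @return Named list of numeric axes `theta`, `alpha`, `beta`.
#' @export
default_axes <- function(n, family = c("flat", "curve", "power", "oscil"),
                         n_theta = 15L, n_alpha = 9L, n_beta = 5L) {
  family <- match.arg(family)
  theta <- seq(1 / n + 0.01, 0.99, length.out = n_theta)
  alpha <- if (family == "flat") 0 else seq(-20, 20, length.out = n_alpha)
  beta <- switch(family,
    flat = 0, curve = 0,
    power = seq(0, 5, length.out = n_beta),
    oscil = seq(0, 3, length.out = n_beta))
  list(theta = theta, alpha = alpha, beta = beta)
}

#' Monte-Carlo reward landscape over boundary parameters
#'
#' Grid search: one [estimate_reward()] per parameter cell, each cell from
#' its own deterministic substream of `seed`, so the whole table is
#' bit-reproducible and cells are mutually independent.
#'
#' @param model A [hypothesis_model()].
#' @param family Boundary family.
#' @param cost_ratio Cost ratio `c/W` (with `W` fixed at `W`, so
#'   `c = cost_ratio * W`).
#' @param axes Named list with numeric `theta`, and (for nonlinear families)
#'   `alpha`, `beta`; defaults from [default_axes()].
#' @param n_trials Trials per grid cell (default 5000; raise toward 1e5
#'   for tighter landscapes at proportional cost).
#' @param seed Master seed.
#' @param W Error cost (default 1).
#' @param max_steps Per-trial step cap.
#' @param stream_offset Added to each cell's substream id; lets several
#'   landscapes under one seed stay independent.
#' @return A data.frame of class `landscape_grid` with one row per cell:
#'   `family`, `theta`, `alpha`, `beta`, `cost_ratio`, `mean_reward`,
#'   `reward_std`, `mean_error`, `mean_T`, `n_trials`, `n_unterminated`.
#'   Attributes record the axes, model, seed and costs.
#' @export
sweep_landscape <- function(model, family, cost_ratio, axes = NULL,
                            n_trials = 5000L, seed = 1L, W = 1,
                            max_steps = 10000L, stream_offset = 0L) {
  stopifnot(inherits(model, "hypothesis_model"))
  family <- match.arg(family, c("flat", "curve", "power", "oscil"))
  if (is.null(axes)) axes <- default_axes(model$n, family)
  if (family == "flat") { axes$alpha <- 0; axes$beta <- 0 }
  if (family == "curve") axes$beta <- 0
  for (ax in c("theta", "alpha", "beta")) {
    if (is.null(axes[[ax]]) || length(axes[[ax]]) == 0L ||
        any(!is.finite(axes[[ax]])))
      stop("axis `", ax, "` must be a non-empty finite numeric vector",
           call. = FALSE)
    axes[[ax]] <- sort(unique(as.numeric(axes[[ax]])))
  }
  costs <- cost_spec(c = cost_ratio * W, W = W)
  grid <- expand.grid(theta = axes$theta, alpha = axes$alpha,
                      beta = axes$beta, KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- boundary_spec(family, theta = grid$theta[i],
                          alpha = grid$alpha[i], beta = grid$beta[i])
    est <- estimate_reward(model, spec, costs, n_trials = n_trials,
                           seed = seed, max_steps = max_steps,
                           stream = stream_offset + i)
    res[[i]] <- data.frame(
      family = family, theta = grid$theta[i], alpha = grid$alpha[i],
      beta = grid$beta[i], cost_ratio = cost_ratio,
      mean_reward = est$mean_reward, reward_std = est$reward_std,
      mean_error = est$mean_error, mean_T = est$mean_T,
      n_trials = est$n_trials, n_unterminated = est$n_unterminated,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out,
            class = c("landscape_grid", "data.frame"),
            axes = axes, family = family, cost_ratio = cost_ratio,
            n_trials_per_cell = n_trials, seed = seed, W = W,
            model = list(n = model$n, delta_mu = model$delta_mu,
                         sigma = model$sigma))
}

#' Near-optimal (degenerate) acceptance set
#'
#' Extracts every grid cell whose mean reward lies within `delta` standard
#' deviations of the landscape maximum:
#' `mean_reward >= r_max - delta * sigma_x`. With `delta = 0` this is the
#' argmax cell set (ties included). The default `delta = 0.02` is the width
#' below which the accepted region's extent stops changing while membership
#' merely thins.
#'
#' @param grid A `landscape_grid`.
#' @param delta Acceptance width (>= 0), default 0.02.
#' @param sigma_mode `"per_trial"` (default): `sigma_x` is the per-trial
#'   reward standard deviation of each cell; `"sem"`: its standard error of
#'   the mean.
#' @return The accepted subset of `grid` rows, class `acceptance_set`, with
#'   an added `delta` column and attributes `r_max`, `delta`, `sigma_mode`.
#' @export
acceptance_region <- function(grid, delta = 0.02,
                              sigma_mode = c("per_trial", "sem")) {
  stopifnot(inherits(grid, "landscape_grid") || is.data.frame(grid))
  sigma_mode <- match.arg(sigma_mode)
  if (length(delta) != 1L || !is.finite(delta) || delta < 0)
    stop("`delta` must be a single number >= 0", call. = FALSE)
  need <- c("mean_reward", "reward_std", "n_trials", "n_unterminated")
  if (!all(need %in% names(grid)))
    stop("grid is missing columns: ",
         paste(setdiff(need, names(grid)), collapse = ", "), call. = FALSE)
  ok <- is.finite(grid$mean_reward)
  if (!any(ok)) stop("no terminated cells in grid", call. = FALSE)
  r_max <- max(grid$mean_reward[ok])
  sig <- grid$reward_std
  if (sigma_mode == "sem")
    sig <- sig / sqrt(pmax(grid$n_trials - grid$n_unterminated, 1L))
  keep <- ok & grid$mean_reward >= r_max - delta * sig
  out <- grid[keep, , drop = FALSE]
  out$delta <- delta
  rownames(out) <- NULL
  structure(as.data.frame(out),
            class = c("acceptance_set", "data.frame"),
            r_max = r_max, delta = delta, sigma_mode = sigma_mode,
            family = attr(grid, "family"),
            cost_ratio = attr(grid, "cost_ratio"))
}

#' Smoothed sections through a reward landscape
#'
#' For each requested `alpha`, takes the slice of the (theta x alpha) grid,
#' smooths mean reward as a function of `theta`, and reports a 95%
#' confidence band. The peak-overlap summary checks whether the bands of all
#' sections intersect at their respective peaks — the construct used to
#' argue that the sections are statistically indistinguishable at their
#' maxima.
#'
#' The default smoother is a penalized regression spline
#' (`mgcv::gam`, `bs = "tp"`), whose penalty null space contains straight
#' lines, so a noiseless linear section is recovered exactly; `bs = "gp"`
#' selects a Gaussian-process smooth instead.
#'
#' @param grid A `landscape_grid` with a single `beta` value.
#' @param alpha_values Alphas to section at; must be grid values.
#' @param bs `mgcv` smooth basis (default `"tp"`).
#' @param k Basis dimension (`-1` = mgcv default).
#' @param level Band coverage (default 0.95).
#' @return List of class `landscape_sections`: `sections` (named list of
#'   data.frames with `theta`, `raw_mean`, `smooth`, `lower`, `upper`),
#'   `peaks` (per-section peak location and band), and `peak_overlap`
#'   (logical: do all peak bands share a common value?).
#' @export
landscape_sections <- function(grid, alpha_values, bs = "tp", k = -1,
                               level = 0.95) {
  stopifnot(is.data.frame(grid))
  if (length(unique(grid$beta)) > 1L)
    stop("sections require a single `beta` value; subset the grid first",
         call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  secs <- list()
  peaks <- data.frame(alpha = numeric(), theta_peak = numeric(),
                      peak = numeric(), lower = numeric(), upper = numeric())
  for (a in alpha_values) {
    sl <- grid[abs(grid$alpha - a) < 1e-12, , drop = FALSE]
    if (nrow(sl) == 0L)
      stop("alpha = ", a, " is not on the grid", call. = FALSE)
    sl <- sl[order(sl$theta), , drop = FALSE]
    lf <- stats::lm(mean_reward ~ theta, data = sl)
    lin_r2 <- suppressWarnings(summary(lf))$r.squared
    if (nrow(sl) >= 4L && is.finite(lin_r2) && lin_r2 < 1 - 1e-10) {
      kk <- if (k > 0) min(k, nrow(sl)) else min(10L, nrow(sl) - 1L)
      fit <- tryCatch(
        suppressWarnings(mgcv::gam(mean_reward ~ s(theta, k = kk, bs = bs),
                                   data = sl, method = "REML")),
        error = function(e) lf)  # degenerate section: linear fallback
      pr <- stats::predict(fit, newdata = sl, se.fit = TRUE)
      sm <- as.numeric(pr$fit); se <- as.numeric(pr$se.fit)
    } else {
      # exactly linear (noiseless) or too few points: linear/identity fit
      pr <- stats::predict(lf, newdata = sl, se.fit = TRUE)
      sm <- as.numeric(pr$fit); se <- as.numeric(pr$se.fit)
      if (nrow(sl) < 4L) { sm <- sl$mean_reward; se <- rep(0, nrow(sl)) }
    }
    sec <- data.frame(theta = sl$theta, raw_mean = sl$mean_reward,
                      smooth = sm, lower = sm - z * se, upper = sm + z * se)
    secs[[as.character(a)]] <- sec
    ip <- which.max(sm)
    peaks <- rbind(peaks, data.frame(
      alpha = a, theta_peak = sl$theta[ip], peak = sm[ip],
      lower = sec$lower[ip], upper = sec$upper[ip]))
  }
  overlap <- max(peaks$lower) <= min(peaks$upper)
  structure(list(sections = secs, peaks = peaks, peak_overlap = overlap),
            class = "landscape_sections")
}

#' @export
print.landscape_sections <- function(x, ...) {
  cat(sprintf("landscape sections at %d alpha value(s); peak bands %s\n",
              nrow(x$peaks),
              if (x$peak_overlap) "overlap" else "do not overlap"))
  print(x$peaks)
  invisible(x)
}
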