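#' Speed-accuracy trade-off points from acceptance sets
#'
#' One SAT point per accepted boundary: its mean error against its mean
#' decision time, labeled by cost ratio and family. Because the mean reward
#' `-W e - c T` has two degrees of freedom, cells with indistinguishable
#' rewards can carry distinct (error, time) pairs — the SAT spread of the
#' degenerate set.
#'
#' @param acceptance_sets A single `acceptance_set` or a list of them (e.g.
#'   one per cost ratio / family).
#' @return Data.frame with columns `cost_ratio`, `family`, `theta`, `alpha`,
#'   `beta`, `mean_error`, `mean_T`, `mean_reward`. Empty sets contribute no
#'   rows (with a warning).
#' @export
sat_points <- function(acceptance_sets) {
  if (inherits(acceptance_sets, "acceptance_set"))
    acceptance_sets <- list(acceptance_sets)
  stopifnot(is.list(acceptance_sets))
  cols <- c("cost_ratio", "family", "theta", "alpha", "beta",
            "mean_error", "mean_T", "mean_reward")
  out <- lapply(acceptance_sets, function(s) {
    if (NROW(s) == 0L) {
      warning("empty acceptance set skipped", call. = FALSE)
      return(NULL)
    }
    as.data.frame(s)[, cols]
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- stats::setNames(
    as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  rownames(out) <- NULL
  out
}

#' Mean speed-accuracy trade-off curve
#'
#' The piecewise-linear curve through the per-cost-ratio mean decision time
#' and mean error, averaged family-balanced: each family's points are first
#' averaged, then the family means are averaged, so no family dominates by
#' having a larger acceptance set.
#'
#' @param points SAT points data.frame from [sat_points()].
#' @return Data.frame of curve vertices (`cost_ratio`, `mean_T`,
#'   `mean_error`) in increasing cost-ratio order. A single cost ratio
#'   yields a degenerate one-vertex curve, with a warning.
#' @export
mean_sat_curve <- function(points) {
  stopifnot(is.data.frame(points), nrow(points) > 0L)
  fam_means <- stats::aggregate(
    points[, c("mean_T", "mean_error")],
    by = list(cost_ratio = points$cost_ratio, family = points$family),
    FUN = mean)
  cr_means <- stats::aggregate(
    fam_means[, c("mean_T", "mean_error")],
    by = list(cost_ratio = fam_means$cost_ratio), FUN = mean)
  cr_means <- cr_means[order(cr_means$cost_ratio), , drop = FALSE]
  rownames(cr_means) <- NULL
  if (nrow(cr_means) < 2L)
    warning("single cost ratio: degenerate one-vertex SAT curve",
            call. = FALSE)
  cr_means
}

#' Implicit threshold dynamics from crossing beliefs
#'
#' Sorts boundary-crossing beliefs by decision time, averaging beliefs with
#' identical decision times, and maps the averages to the log-odds scale.
#' A static nonlinear boundary thereby acquires an apparent time course:
#' trajectories that stop late tend to stop in different regions of the
#' boundary than trajectories that stop early.
#'
#' @param outcomes Trial data.frame from [run_trials()] (terminated rows are
#'   used; others ignored).
#' @param min_count Decision times observed fewer than this many times are
#'   dropped (default 5): tail times are too sparsely sampled for a stable
#'   mean.
#' @param classifier_z Slope z-band used by [classify_dynamics()].
#' @param drift_tol Practical-equivalence floor passed to
#'   [classify_dynamics()].
#' @return List of class `implicit_threshold_series`: `series` (data.frame
#'   `times`, `mean_crossing_belief`, `n`, `transformed_threshold`) and
#'   `category` (`"increasing"`, `"collapsing"`, `"static"`, or `NA` if
#'   fewer than 3 time points survive).
#' @export
implicit_threshold <- function(outcomes, min_count = 5L, classifier_z = 2,
                               drift_tol = 0.08) {
  stopifnot(is.data.frame(outcomes))
  term <- outcomes[outcomes$terminated & is.finite(outcomes$crossing_belief), ,
                   drop = FALSE]
  if (nrow(term) == 0L) {
    warning("no terminated outcomes; empty series", call. = FALSE)
    ser <- data.frame(times = integer(), mean_crossing_belief = numeric(),
                      n = integer(), transformed_threshold = numeric())
    return(structure(list(series = ser, category = NA_character_),
                     class = "implicit_threshold_series"))
  }
  agg <- stats::aggregate(term$crossing_belief, by = list(times = term$T),
                          FUN = mean)
  cnt <- stats::aggregate(term$crossing_belief, by = list(times = term$T),
                          FUN = length)
  ser <- data.frame(times = agg$times, mean_crossing_belief = agg$x,
                    n = cnt$x)
  ser <- ser[ser$n >= min_count, , drop = FALSE]
  ser <- ser[order(ser$times), , drop = FALSE]
  rownames(ser) <- NULL
  ser$transformed_threshold <- if (nrow(ser)) log_odds(ser$mean_crossing_belief)
                               else numeric()
  res <- structure(list(series = ser, category = NA_character_),
                   class = "implicit_threshold_series")
  if (nrow(ser) >= 3L)
    res$category <- classify_dynamics(res, z = classifier_z,
                                      drift_tol = drift_tol)
  res
}

#' @export
print.implicit_threshold_series <- function(x, ...) {
  cat(sprintf("implicit threshold series: %d time points, category %s\n",
              nrow(x$series), x$category))
  invisible(x)
}

#' Classify implicit threshold dynamics
#'
#' Fits a weighted least-squares line (weights = trials per time point) to
#' the log-odds-transformed threshold against decision time. The series is
#' `"static"` unless the slope is both statistically distinguishable from
#' zero (outside `z` standard errors) and practically meaningful: the fitted
#' drift over the observed time span must exceed `drift_tol` log-odds units.
#' Otherwise the slope's sign gives `"increasing"` or `"collapsing"`.
#'
#' The practical-equivalence floor exists because with many trials the
#' fitted slope of an essentially flat series becomes statistically
#' significant: discrete-time overshoot at the shortest decision times
#' induces a real but immaterial drift (of order 0.02-0.03 log-odds) even
#' for a strictly constant threshold. The default `drift_tol = 0.08`
#' corresponds to a posterior threshold moving from 0.80 to about 0.815
#' over the whole trial-duration range -- behaviorally negligible, yet well
#' below the 0.1-0.7 log-odds drifts produced by genuinely curved
#' boundaries.
#'
#' @param series An `implicit_threshold_series`, or a data.frame with
#'   columns `times`, `transformed_threshold` and optionally `n`.
#' @param z Half-width of the slope acceptance band in standard errors
#'   (default 2).
#' @param drift_tol Practical-equivalence floor on the absolute fitted
#'   drift (slope times time span), in log-odds units (default 0.08).
#' @return `"increasing"`, `"collapsing"` or `"static"`.
#' @export
classify_dynamics <- function(series, z = 2, drift_tol = 0.08) {
  if (inherits(series, "implicit_threshold_series")) series <- series$series
  stopifnot(is.data.frame(series))
  if (nrow(series) < 3L)
    stop("need at least 3 time points to classify dynamics", call. = FALSE)
  w <- if ("n" %in% names(series)) series$n else rep(1, nrow(series))
  fit <- stats::lm(transformed_threshold ~ times, data = series, weights = w)
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- co["times", "Estimate"]
  se <- co["times", "Std. Error"]
  drift <- abs(slope) * (max(series$times) - min(series$times))
  if (!is.finite(se) || abs(slope) <= z * se || drift <= drift_tol)
    return("static")
  if (slope > 0) "increasing" else "collapsing"
}

#' Hick's law fit
#'
#' Ordinary least squares of mean decision time on the natural log of the
#' number of alternatives: `mean_T = a + b log(n)`. Units: `a` in steps,
#' `b` in steps per log-unit of choice count.
#'
#' @param mean_T_by_n Data.frame with columns `n` and `mean_T`, or a named
#'   numeric vector (names = choice counts).
#' @return List of class `hick_fit`: `a` (intercept), `b` (slope),
#'   `r_squared`.
#' @export
hicks_law_fit <- function(mean_T_by_n) {
  if (is.numeric(mean_T_by_n) && !is.null(names(mean_T_by_n)))
    mean_T_by_n <- data.frame(n = as.numeric(names(mean_T_by_n)),
                              mean_T = as.numeric(mean_T_by_n))
  stopifnot(is.data.frame(mean_T_by_n),
            all(c("n", "mean_T") %in% names(mean_T_by_n)))
  d <- unique(mean_T_by_n[, c("n", "mean_T")])
  if (length(unique(d$n)) < 3L)
    stop("need at least 3 distinct choice counts", call. = FALSE)
  fit <- stats::lm(mean_T ~ log(n), data = d)
  structure(list(a = unname(stats::coef(fit)[1L]),
                 b = unname(stats::coef(fit)[2L]),
                 r_squared = suppressWarnings(summary(fit))$r.squared),
            class = "hick_fit")
}

#' @export
print.hick_fit <- function(x, ...) {
  cat(sprintf("Hick's law: mean_T = %.3f + %.3f log(n)  (R^2 = %.4f)\n",
              x$a, x$b, x$r_squared))
  invisible(x)
}

#' Renormalized beliefs after adding a third option
#'
#' Given two-option beliefs `P0 + P1 = 1` and a new option with belief
#' `P2`, the normalized three-option beliefs are each original value divided
#' by `1 + P2`. The shrinkage of existing beliefs is the normalization
#' account of IIA and regularity violations.
#'
#' @param P0,P1 Existing beliefs, summing to 1 (tol 1e-9).
#' @param P2 Belief in the added option, in `[0, 1]`.
#' @return Numeric vector `(P0, P1, P2) / (1 + P2)`, summing to 1.
#' @export
renormalize_added_option <- function(P0, P1, P2) {
  vals <- c(P0, P1, P2)
  if (length(vals) != 3L || any(!is.finite(vals)) ||
      any(vals < 0) || any(vals > 1))
    stop("P0, P1, P2 must each be single values in [0, 1]", call. = FALSE)
  if (abs(P0 + P1 - 1) > 1e-9)
    stop("P0 + P1 must equal 1 (tol 1e-9)", call. = FALSE)
  c(P0, P1, P2) / (1 + P2)
}

#' Belief gap between two options after adding a third
#'
#' `Delta_{i,j} = |P_i - P_j| / (1 + P_2)`: adding an option shrinks the
#' belief difference supporting either of the originals, so more evidence
#' is needed to separate them.
#'
#' @param Pi,Pj Beliefs of the two original options, in `[0, 1]`.
#' @param P2 Belief of the added option, in `[0, 1]`.
#' @return The renormalized absolute gap.
#' @export
belief_gap <- function(Pi, Pj, P2) {
  vals <- c(Pi, Pj, P2)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("inputs must lie in [0, 1]", call. = FALSE)
  abs(Pi - Pj) / (1 + P2)
}

#' Distances to boundary and to the flat prior after adding an option
#'
#' `d_T = T - P_i / (1 + P_2)` (distance from a renormalized belief up to a
#' flat boundary level `T`, which grows with `P_2`) and
#' `d = P_i / (1 + P_2) - 1/3` (distance down to the three-option flat
#' prior, which shrinks with `P_2`).
#'
#' @param Pi Belief of an existing option, in `[0, 1]`.
#' @param P2 Belief of the added option, in `[0, 1]`.
#' @param T_level Flat boundary level, in (0, 1).
#' @return Named list with `d_T` and `d`.
#' @export
iia_distances <- function(Pi, P2, T_level) {
  if (any(!is.finite(c(Pi, P2, T_level))) || Pi < 0 || Pi > 1 ||
      P2 < 0 || P2 > 1 || T_level <= 0 || T_level >= 1)
    stop("Pi, P2 in [0,1]; T_level in (0,1)", call. = FALSE)
  tilde <- Pi / (1 + P2)
  list(d_T = T_level - tilde, d = tilde - 1 / 3)
}
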