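#' Vertices of a regular (n-1)-simplex
#'
#' Returns the `n` hypothesis means used by the evidence model: the vertices
#' of a regular simplex in (n-1)-dimensional space, centered at the origin,
#' with all pairwise distances equal to `delta_mu`. Only pairwise distances
#' and the centroid are pinned down; the particular orientation is a
#' deterministic recursive construction (any orthogonal transform would do,
#' since every downstream quantity depends on distances alone).
#'
#' @param n Number of choices (integer, >= 2).
#' @param delta_mu Common pairwise distance between means (> 0). Controls
#'   task difficulty relative to the evidence noise.
#' @return A numeric matrix with `n` rows and `n - 1` columns; row `i` is the
#'   mean vector of hypothesis `i`.
#' @examples
#' simplex_vertices(3, 1)   # equilateral triangle, unit edge
#' @export
simplex_vertices <- function(n, delta_mu = 1) {
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
    stop("`n` must be a single integer >= 2", call. = FALSE)
  if (length(delta_mu) != 1L || !is.finite(delta_mu) || delta_mu <= 0)
    stop("`delta_mu` must be a single positive number", call. = FALSE)
  n <- as.integer(n)

  # Recursive construction of a unit-edge regular simplex:
  # start from {+1/2, -1/2} in 1-D, then lift: scale the k-vertex simplex to
  # edge 1 in (k-1) dims, append a new vertex on the new axis, recenter.
  v <- matrix(c(0.5, -0.5), ncol = 1L)
  if (n > 2L) {
    for (k in 3:n) {
      d <- k - 1L                      # target dimension
      prev <- cbind(v, 0)              # embed previous k-1 vertices
      # distance from centroid (origin) to each previous vertex:
      r2 <- sum(prev[1L, ]^2)
      # new vertex at height h on last axis with |new - old|^2 = r2 + h^2 = 1
      h <- sqrt(1 - r2)
      newv <- c(rep(0, d - 1L), h)
      v <- rbind(prev, newv)
      v <- sweep(v, 2L, colMeans(v))   # recenter on the origin
      # recentering shrinks edges? No: translation preserves distances, but
      # the previous simplex was centered, so only the last axis shifts.
      # Rescale to restore unit edge exactly (guards accumulated rounding).
      edge <- sqrt(sum((v[1L, ] - v[2L, ])^2))
      v <- v / edge
    }
  }
  dimnames(v) <- NULL
  v * delta_mu
}

#' Log-odds transform and its inverse
#'
#' Maps a posterior probability threshold on a simplex edge to the equivalent
#' SPRT log-odds threshold: `log(theta / (1 - theta))`.
#'
#' @param theta_post Probability strictly inside (0, 1).
#' @return Log-odds (real).
#' @export
log_odds <- function(theta_post) {
  if (!is.numeric(theta_post) || any(!is.finite(theta_post)) ||
      any(theta_post <= 0) || any(theta_post >= 1))
    stop("`theta_post` must lie strictly inside (0, 1)", call. = FALSE)
  log(theta_post / (1 - theta_post))
}

#' @rdname log_odds
#' @param x Log-odds value(s).
#' @export
inverse_log_odds <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("`x` must be finite", call. = FALSE)
  1 / (1 + exp(-x))
}

#' Triplet subspaces of the belief simplex
#'
#' All unordered combinations of three distinct choices out of `n`. These
#' index the outer 3-choice faces of the belief simplex over which the
#' nonlinear boundary parameterization is summed; there are
#' `choose(n, 3)` of them (1, 4, 10 for n = 3, 4, 5).
#'
#' @param n Number of choices (integer, >= 3).
#' @return An integer matrix with `choose(n, 3)` rows and 3 columns; each row
#'   is strictly increasing, zero-based (choice indices `0 .. n-1`).
#' @export
triplet_subspaces <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 3 || n != round(n))
    stop("`n` must be a single integer >= 3", call. = FALSE)
  t(utils::combn(as.integer(n), 3L)) - 1L
}

#' Maximum pairwise spread of a 3-component belief
#'
#' The maximum absolute difference between the components of a triplet belief
#' vector; the argument of the boundary shape functions. Zero at the face
#' center (all equal), one at a vertex.
#'
#' @param p3 Numeric vector of exactly 3 probabilities in `[0, 1]`.
#' @return A number in `[0, 1]`.
#' @export
delta_max <- function(p3) {
  if (length(p3) != 3L || !is.numeric(p3))
    stop("`p3` must be a numeric vector of length 3", call. = FALSE)
  if (any(!is.finite(p3)) || any(p3 < 0) || any(p3 > 1))
    stop("components of `p3` must lie in [0, 1]", call. = FALSE)
  max(p3) - min(p3)
}

#' Validate a belief vector
#'
#' Checks that `p` is a probability vector on the simplex: components in
#' `[0, 1]` summing to 1 within `tol`.
#'
#' @param p Numeric vector.
#' @param tol Sum tolerance (default 1e-9).
#' @return `p`, invisibly, after validation.
#' @keywords internal
#' @export
check_belief <- function(p, tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 2L || any(!is.finite(p)))
    stop("belief must be a finite numeric vector, length >= 2", call. = FALSE)
  if (any(p < -tol) || any(p > 1 + tol))
    stop("belief components must lie in [0, 1]", call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop("belief components must sum to 1 (tol ", format(tol), ")",
         call. = FALSE)
  invisible(p)
}

#' Prior-offset decrease when adding an alternative
#'
#' The drop in the uniform prior belief per choice when moving from `n` to
#' `n + 1` alternatives: `1/n - 1/(n+1) = 1/(n(n+1))`. This is the
#' normalization account of the decreasing pre-stimulus offset observed in
#' accumulation-related neural activity as set size grows.
#'
#' @param n Number of choices before the addition (integer >= 2).
#' @return The offset decrease, `1 / (n (n + 1))`.
#' @export
offset_decrease <- function(n) {
  if (any(!is.finite(n)) || any(n < 2) || any(n != round(n)))
    stop("`n` must be integer(s) >= 2", call. = FALSE)
  1 / (n * (n + 1))
}
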