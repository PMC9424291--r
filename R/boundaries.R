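#' Decision boundary specification
#'
#' One member of the permutation-symmetric family of time-independent
#' decision boundaries. The boundary is evaluated on the belief vector `P`
#' as
#' \deqn{F(P) = \theta \Big[1 + \frac{\alpha}{C^n_3} \sum_{j \in C^n_3}
#'   f(\Delta_{max} P_j;\, \beta) \prod_{i \in j} P_i\Big]}
#' where the sum runs over all triplet subspaces (3-choice faces), the
#' product of the three face beliefs collapses the modulation whenever fewer
#' than three components are nonzero, and `f` is the family shape function:
#' `flat` (f = 0), `curve` (f = 1), `power` (f = dmax^beta) and `oscil`
#' (f = cos(2 pi beta dmax)).
#'
#' `theta` is the edge-intersection parameter: on any edge (at most two
#' nonzero beliefs) the boundary reduces to the flat threshold `theta`.
#' `alpha` is the modulation amplitude (`alpha = 0` recovers `flat`);
#' `beta` is a shape/frequency parameter (`beta = 0` recovers `curve` for
#' both `power` and `oscil`, with `0^0 := 1`).
#'
#' @param family One of `"flat"`, `"curve"`, `"power"`, `"oscil"`.
#' @param theta Edge-intersection threshold, in (0, 1).
#' @param alpha Amplitude (finite; ignored by `flat`).
#' @param beta Shape parameter (finite; ignored by `flat` and `curve`).
#' @return An object of class `boundary_spec`.
#' @examples
#' boundary_spec("curve", theta = 0.6, alpha = 10)
#' @export
boundary_spec <- function(family = c("flat", "curve", "power", "oscil"),
                          theta, alpha = 0, beta = 0) {
  family <- match.arg(family)
  if (length(theta) != 1L || !is.finite(theta) || theta <= 0 || theta >= 1)
    stop("`theta` must be a single number in (0, 1)", call. = FALSE)
  if (length(alpha) != 1L || !is.finite(alpha))
    stop("`alpha` must be a single finite number", call. = FALSE)
  if (length(beta) != 1L || !is.finite(beta))
    stop("`beta` must be a single finite number", call. = FALSE)
  if (family == "flat") { alpha <- 0; beta <- 0 }
  if (family == "curve") beta <- 0
  structure(list(family = family, theta = theta, alpha = alpha, beta = beta),
            class = "boundary_spec")
}

#' @export
print.boundary_spec <- function(x, ...) {
  cat(sprintf("boundary %s(theta = %g, alpha = %g, beta = %g)\n",
              x$family, x$theta, x$alpha, x$beta))
  invisible(x)
}

#' @export
format.boundary_spec <- function(x, ...) {
  sprintf("%s(%g, %g, %g)", x$family, x$theta, x$alpha, x$beta)
}

#' @export
as.data.frame.boundary_spec <- function(x, ...) {
  data.frame(family = x$family, theta = x$theta, alpha = x$alpha,
             beta = x$beta, stringsAsFactors = FALSE)
}

#' Boundary shape function
#'
#' The per-triplet modulation `f(dmax; beta)` of each family, applied to the
#' maximum pairwise spread of a triplet belief (see [delta_max()]).
#'
#' @param family Family name.
#' @param dmax Spread value(s) in `[0, 1]`.
#' @param beta Shape parameter.
#' @return `f(dmax; beta)`, vectorized over `dmax`.
#' @export
shape_fn <- function(family, dmax, beta = 0) {
  if (!is.character(family) || length(family) != 1L ||
      !family %in% c("flat", "curve", "power", "oscil"))
    stop("unknown boundary family: ", paste(family, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(dmax)) || any(dmax < 0) || any(dmax > 1))
    stop("`dmax` must lie in [0, 1]", call. = FALSE)
  switch(family,
    flat  = rep(0, length(dmax)),
    curve = rep(1, length(dmax)),
    # 0^0 := 1 so beta = 0 reduces power to curve everywhere
    power = ifelse(dmax == 0 & beta == 0, 1, dmax^beta),
    oscil = cos(2 * pi * beta * dmax))
}

#' Evaluate a decision boundary at a belief state
#'
#' @param p Belief vector (length `n`, on the simplex).
#' @param spec A [boundary_spec()].
#' @return The threshold level `F(p)` that any single belief component must
#'   strictly exceed to trigger a decision. Not clipped: values above 1
#'   (unreachable boundary) or below `1/n` are legal.
#' @export
boundary_value <- function(p, spec) {
  stopifnot(inherits(spec, "boundary_spec"))
  check_belief(p)
  n <- length(p)
  if (spec$family == "flat" || spec$alpha == 0 || n < 3L)
    return(spec$theta)
  trip <- triplet_subspaces(n)
  s <- 0
  for (r in seq_len(nrow(trip))) {
    p3 <- p[trip[r, ] + 1L]
    s <- s + shape_fn(spec$family, delta_max(p3), spec$beta) * prod(p3)
  }
  spec$theta * (1 + spec$alpha * s / nrow(trip))
}

#' Boundary crossing rule
#'
#' Tests the decision rule `P_i > F(P)` (strict). If at least one component
#' crosses, the winner is the component with the largest belief (any crosser
#' is dominated by the maximum, which necessarily also crosses); exact ties
#' on the maximum are broken uniformly at random from R's RNG stream.
#'
#' @param p Belief vector.
#' @param spec A [boundary_spec()].
#' @return Zero-based index of the chosen hypothesis, or `NA_integer_` if no
#'   component crosses.
#' @export
crossing <- function(p, spec) {
  f <- boundary_value(p, spec)
  if (max(p) <= f) return(NA_integer_)
  win <- which(p == max(p))
  if (length(win) > 1L) win <- sample(win, 1L)
  as.integer(win - 1L)
}
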