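# Heuristic Gaussian transition density in angular space: the variance is
# slaved to the local slope lambda(Theta(t)) of the (regularized) effective
# force, evaluated at the current deterministic mean.

core_mean_var <- function(x0, t, N, s, mu1, mu2) {
  r <- recycle_num(x0 = x0, t = t, N = N, s = s, mu1 = mu1, mu2 = mu2)
  m <- core_mean_freq(r$x0, r$t, r$N, r$s, r$mu1, r$mu2)
  Theta <- acos(pmin(pmax(1 - 2 * m$X, -1), 1))
  lam <- core_slope(Theta, r$N, r$s, r$mu1, r$mu2)
  arg <- 2 * lam * r$t
  v <- numeric(length(arg))
  small <- abs(arg) < 1e-8
  if (any(small))
    v[small] <- (r$t / r$N * (1 + lam * r$t))[small]
  if (any(!small))
    v[!small] <- (expm1(arg) / (2 * r$N * lam))[!small]
  list(Theta = Theta, v = v, clamped = m$clamped)
}

#' Time-varying variance of the angular Gaussian density
#'
#' \eqn{\langle\langle\theta^2\rangle\rangle(t) = (e^{2\lambda t} - 1)/(2N\lambda)}
#' with \eqn{\lambda = \lambda(\Theta(t))} the boundary-regularized slope of the
#' effective force ([force_slope()]) evaluated at the current deterministic
#' mean.  At \eqn{\lambda = 0} (e.g. `4Nmu = 1`, where drift and mutation
#' balance exactly) the variance reduces continuously to the Brownian value
#' `t/N`; the branch is switched by series expansion when `|lambda t|` is
#' below 1e-8.
#'
#' @param theta0 Initial angle in `[0, pi]`.
#' @param params A [wf_params()] object.
#' @param t Elapsed generations (>= 0, vectorised).
#' @return Variance in radians^2.
#' @export
variance_angle <- function(theta0, params, t) {
  params <- as_wf_params(params)
  if (any(!is.finite(t) | t < 0)) stop("'t' must be >= 0")
  x0 <- angle_to_freq(theta0)
  core_mean_var(x0, t, params$N, params$s, params$mu1, params$mu2)$v
}

# theta*_weak: a fifth of the distance from theta0 to the nearest boundary,
# so the weight is ~1 over the bulk of the short-time density (h(theta0) =
# tanh(5) to leading order) while still enforcing h ~ theta at the boundary.
theta_star_weak_frac <- 0.2

core_theta_star <- function(x0, N, s) {
  r <- recycle_num(x0 = x0, N = N, s = s)
  th0 <- acos(1 - 2 * r$x0)
  thw <- theta_star_weak_frac * pmin(th0, pi - th0)
  u <- ifelse(r$s > 0, r$x0, 1 - r$x0)
  w <- ifelse(r$s == 0, 0, 0.5 * (1 + tanh(log(4 * r$N * abs(r$s) * u) / 0.5)))
  (1 - w) * thw + w * 0.1
}

#' Boundary scale of the absorbing-boundary weighting function
#'
#' Chooses the angular scale `theta*` over which the weighting function
#' [boundary_weight()] bends the Gaussian solution down to satisfy the
#' effective absorbing boundary conditions (`q ~ theta` near loss,
#' `q ~ pi - theta` near fixation) of the zero-mutation case.
#'
#' When selection on the initial variant is strong (`4 N |s| u >> 1`, with
#' `u = x0` for `s > 0` and `u = 1 - x0` for `s < 0`) density builds up at the
#' boundary quickly and a fixed `theta* = 0.1` is used; when it is weak the
#' scale is tied to the initial angle, `theta* = min(theta0, pi - theta0)/5`,
#' keeping the weight essentially 1 over the bulk of the short-time density.
#' Intermediate strengths interpolate through a tanh switch of width 0.5 in
#' `log(4 N |s| u)`; at `s = 0` the weak-selection scale is used exactly.
#'
#' @param params A [wf_params()] object.
#' @param x0 Initial frequency, strictly inside `(0, 1)`.
#' @return The angular scale `theta*` (radians).
#' @export
boundary_theta_star <- function(params, x0) {
  params <- as_wf_params(params)
  if (any(x0 <= 0 | x0 >= 1))
    stop("'x0' must lie strictly inside (0, 1); regularize boundary ",
         "observations first (see regularize_boundary_obs())")
  core_theta_star(x0, params$N, params$s)
}

#' Absorbing-boundary weighting function
#'
#' \eqn{h(\theta) = \tanh(\theta/\theta^*)\,\tanh((\pi-\theta)/\theta^*)}:
#' linear in `theta` within `theta*` of loss, linear in `pi - theta` within
#' `theta*` of fixation, and ~1 elsewhere.  Multiplying the angular Gaussian
#' by `h` imposes the effective absorbing boundary behaviour of the
#' zero-mutation Wright-Fisher process; the resulting mass deficit represents
#' probability absorbed at the fixation/loss boundaries and is deliberately
#' not renormalized away.
#'
#' @param theta Angles in `[0, pi]` (vectorised).
#' @param theta_star Positive angular scale, typically from
#'   [boundary_theta_star()].
#' @return Weights in `[0, 1]`.
#' @export
boundary_weight <- function(theta, theta_star) {
  if (any(theta_star <= 0)) stop("'theta_star' must be > 0")
  if (any(theta < 0 | theta > pi)) stop("'theta' outside [0, pi]")
  tanh(theta / theta_star) * tanh((pi - theta) / theta_star)
}

#' Regularize exact-boundary observations
#'
#' With non-zero mutation the boundary conditions are zero-flux and the
#' density diverges for transitions landing exactly on `x = 0` or `x = 1`;
#' observed boundary frequencies are therefore moved half an individual into
#' the interior: `0 -> 1/(2N)`, `1 -> 1 - 1/(2N)`.  Interior values pass
#' through unchanged.
#'
#' @param x Frequencies in `[0, 1]` (vectorised).
#' @param params A [wf_params()] object (supplies `N`).
#' @return Regularized frequencies.
#' @export
regularize_boundary_obs <- function(x, params) {
  params <- as_wf_params(params)
  eps <- 1 / (2 * params$N)
  ifelse(x <= 0, eps, ifelse(x >= 1, 1 - eps, x))
}

# Log-density kernel on interior points; weighting applied when mu1 = mu2 = 0.
core_logdens_angular <- function(x, x0, t, N, s, mu1, mu2) {
  r <- recycle_num(x = x, x0 = x0, t = t, N = N, s = s, mu1 = mu1, mu2 = mu2)
  mv <- core_mean_var(r$x0, r$t, r$N, r$s, r$mu1, r$mu2)
  th <- acos(1 - 2 * r$x)
  ld <- dnorm(th, mv$Theta, sqrt(mv$v), log = TRUE) - 0.5 * log(r$x * (1 - r$x))
  absorbing <- r$mu1 + r$mu2 == 0
  if (any(absorbing)) {
    ts <- core_theta_star(r$x0[absorbing], r$N[absorbing], r$s[absorbing])
    ld[absorbing] <- ld[absorbing] +
      log(tanh(th[absorbing] / ts) * tanh((pi - th[absorbing]) / ts))
  }
  ld
}

# Log-mass absorbed past a boundary: Gaussian tail of the angular density
# beyond theta = 0 (loss) or theta = pi (fixation).
core_logtail_angular <- function(boundary, x0, t, N, s, mu1, mu2) {
  r <- recycle_num(b = boundary, x0 = x0, t = t, N = N, s = s,
                   mu1 = mu1, mu2 = mu2)
  mv <- core_mean_var(r$x0, r$t, r$N, r$s, r$mu1, r$mu2)
  sd <- sqrt(mv$v)
  out <- numeric(length(r$b))
  lo <- r$b == 0
  out[lo] <- pnorm(0, mv$Theta[lo], sd[lo], log.p = TRUE)
  out[!lo] <- pnorm(pi, mv$Theta[!lo], sd[!lo], lower.tail = FALSE, log.p = TRUE)
  out
}

#' Heuristic Gaussian transition probability density
#'
#' The short-time closed-form approximation to the Wright-Fisher transition
#' density: a Gaussian in Fisher's angular coordinate with mean
#' \eqn{\Theta(t)} (the deterministic path, [deterministic_mean_angle()]) and
#' variance \eqn{\langle\langle\theta^2\rangle\rangle(t)}
#' ([variance_angle()]), mapped back to frequency space with the Jacobian
#' \eqn{d\theta/dx = 1/\sqrt{x(1-x)}}:
#' \deqn{p(x, x_0; t) = \frac{h(\theta(x))}{\sqrt{x(1-x)}}\,
#'   \mathcal{N}\!\left(\theta(x);\, \Theta(t),\,
#'   \langle\langle\theta^2\rangle\rangle(t)\right),
#'   \qquad \cos\theta_0 = 1 - 2x_0.}
#' The weighting function `h` ([boundary_weight()]) is applied only in the
#' absorbing case `mu1 = mu2 = 0`; with mutation the boundaries are zero-flux,
#' `h` is dropped, and exact-boundary arguments are regularized via
#' [regularize_boundary_obs()].  The approximation is accurate for times short
#' compared with the fixation timescale ([fixation_timescale()]).
#'
#' @param x Frequencies at which to evaluate the density (vectorised).
#' @param x0 Initial frequency; must be inside `(0, 1)` when `mu1 = mu2 = 0`.
#' @param t Elapsed generations (> 0).
#' @param params A [wf_params()] object.
#' @return Density values, per unit frequency.
#' @examples
#' p <- wf_params(N = 1e3)
#' xs <- seq(0.01, 0.99, by = 0.01)
#' d <- transition_density(xs, x0 = 0.5, t = 50, params = p)
#' sum(d) * 0.01  # close to 1 at short times
#' @export
transition_density <- function(x, x0, t, params) {
  params <- as_wf_params(params)
  if (length(t) != 1L || !is.finite(t) || t <= 0)
    stop("'t' must be a single value > 0, got: ", deparse(t))
  if (any(!is.finite(x) | x < 0 | x > 1)) stop("'x' outside [0, 1]")
  if (length(x0) != 1L || !is.finite(x0) || x0 < 0 || x0 > 1)
    stop("'x0' must be a single frequency in [0, 1]")
  absorbing <- params$mu1 == 0 && params$mu2 == 0
  if (absorbing && (x0 <= 0 || x0 >= 1))
    stop("'x0' at an absorbing boundary (x0 = ", x0, ") has no dynamics when ",
         "mu1 = mu2 = 0")
  x0 <- regularize_boundary_obs(x0, params)
  p <- numeric(length(x))
  if (absorbing) {
    interior <- x > 0 & x < 1
    p[interior] <- exp(core_logdens_angular(x[interior], x0, t, params$N,
                                            params$s, params$mu1, params$mu2))
    # density -> 0 at the exact boundaries through the weight
  } else {
    xr <- regularize_boundary_obs(x, params)
    p <- exp(core_logdens_angular(xr, x0, t, params$N, params$s,
                                  params$mu1, params$mu2))
  }
  p
}
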