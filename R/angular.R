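#' Fisher's angular transformation
#'
#' Maps a variant frequency `x` in `[0, 1]` to the angular coordinate
#' \eqn{\theta = \arccos(1 - 2x)} (equivalently \eqn{x = \sin^2(\theta/2)}).
#' In this coordinate the Wright-Fisher diffusion has a constant diffusion
#' coefficient `1/2N`: equal angular distances are traversed in equal mean
#' square times, at the cost of an effective convective force
#' (see [effective_force()]).
#'
#' @param x Frequencies in `[0, 1]` (vectorised).
#' @return Angles in radians, in `[0, pi]`.
#' @seealso [angle_to_freq()] for the inverse map.
#' @examples
#' freq_to_angle(c(0, 0.5, 1))   # 0, pi/2, pi
#' @export
freq_to_angle <- function(x) {
  bad <- !is.finite(x) | x < 0 | x > 1
  if (any(bad))
    stop("frequency outside [0, 1]: ", paste(utils::head(x[bad], 3L), collapse = ", "))
  # equivalent to acos(1 - 2x) but well conditioned at both boundaries
  2 * atan2(sqrt(x), sqrt(1 - x))
}

#' Inverse of Fisher's angular transformation
#'
#' @param theta Angles in radians, in `[0, pi]` (vectorised).
#' @return Frequencies `x = (1 - cos(theta)) / 2`.
#' @export
angle_to_freq <- function(theta) {
  bad <- !is.finite(theta) | theta < 0 | theta > pi
  if (any(bad))
    stop("angle outside [0, pi]: ", paste(utils::head(theta[bad], 3L), collapse = ", "))
  sin(theta / 2)^2  # = (1 - cos(theta))/2, accurate near theta = 0
}

#' Effective convective force in angular space
#'
#' The drift term of the Wright-Fisher diffusion after Fisher's angular
#' transformation:
#' \deqn{2N f(\theta) = (2N(\mu_1+\mu_2) - 1)\cot\theta +
#'       2N(\mu_1-\mu_2)/\sin\theta + Ns \sin\theta.}
#' The cot term combines genetic drift (which pushes probability flux towards
#' the boundaries) with the symmetric part of mutation (which opposes it); the
#' `1/sin` term is proportional to the difference in mutation rates; the `sin`
#' term carries selection and vanishes at the boundaries, where drift always
#' dominates.  For `4Nmu < 1` (with `mu1 = mu2`) the force is unstable about
#' `theta = pi/2` (monomorphic regime); for `4Nmu > 1` it is stable
#' (polymorphic regime).
#'
#' The force diverges at `theta = 0` and `theta = pi`; those inputs raise an
#' error rather than returning a fabricated finite value.  Use
#' [force_slope()] where boundary-safe derivatives are needed.
#'
#' @param theta Angles strictly inside `(0, pi)` (vectorised).
#' @param params A [wf_params()] object.
#' @return Force in radians per generation.
#' @examples
#' p <- wf_params(N = 1e4, s = 1e-3)
#' 2 * p$N * effective_force(pi / 2, p)  # = Ns = 10
#' @export
effective_force <- function(theta, params) {
  params <- as_wf_params(params)
  bad <- !is.finite(theta) | theta < 0 | theta > pi
  if (any(bad))
    stop("angle outside [0, pi]: ", paste(utils::head(theta[bad], 3L), collapse = ", "))
  if (any(theta == 0 | theta == pi))
    stop("effective force diverges at theta = 0 or pi; use force_slope() for ",
         "boundary-regularized behaviour")
  with(params, {
    (1 / (2 * N)) * ((2 * N * (mu1 + mu2) - 1) * cos(theta) / sin(theta) +
                       2 * N * (mu1 - mu2) / sin(theta) +
                       N * s * sin(theta))
  })
}

# Regularized force: cot(theta) and 1/sin(theta) replaced by their third-order
# expansions about theta = pi/2 (u = theta - pi/2: cot -> -u - u^3/3,
# 1/sin -> 1 + u^2/2); the selection term keeps exact trigonometry.  Total on
# [0, pi]; this is the force whose derivative enters the variance.
regularized_force <- function(theta, N, s, mu1, mu2) {
  u <- theta - pi / 2
  (1 / (2 * N)) * ((2 * N * (mu1 + mu2) - 1) * (-u - u^3 / 3) +
                     2 * N * (mu1 - mu2) * (1 + u^2 / 2)) +
    (s / 2) * sin(theta)
}

core_slope <- function(theta, N, s, mu1, mu2) {
  u <- theta - pi / 2
  (1 / (2 * N)) * (-(2 * N * (mu1 + mu2) - 1) * (1 + u^2) +
                     2 * N * (mu1 - mu2) * u) +
    (s / 2) * cos(theta)
}

#' Boundary-regularized slope of the effective force
#'
#' Derivative \eqn{\lambda(\theta) = f'(\theta)} of the effective convective
#' force in which the terms that diverge at the boundaries (`cot` and `1/sin`)
#' are replaced by third-order Taylor expansions about `theta = pi/2`, keeping
#' the selection term exact:
#' \deqn{\lambda(\theta) = \frac{1}{2N}\left[-(2N(\mu_1+\mu_2)-1)(1+u^2) +
#'   2N(\mu_1-\mu_2)\,u\right] + \frac{s}{2}\cos\theta, \quad u = \theta - \pi/2.}
#' This makes \eqn{\lambda} finite and well behaved on all of `[0, pi]`, which
#' is what the time-varying variance of the heuristic Gaussian density needs as
#' the deterministic mean approaches fixation or loss.
#'
#' @inheritParams effective_force
#' @param theta Angles in `[0, pi]` (vectorised; total function).
#' @return Slope in 1/generations.
#' @examples
#' force_slope(pi / 2, wf_params(N = 1e3))          # 1/(2N): unstable drift
#' force_slope(pi / 2, wf_params(N = 1e3, mu1 = 2.5e-3, mu2 = 2.5e-3)) # stable
#' @export
force_slope <- function(theta, params) {
  params <- as_wf_params(params)
  bad <- !is.finite(theta) | theta < 0 | theta > pi
  if (any(bad))
    stop("angle outside [0, pi]: ", paste(utils::head(theta[bad], 3L), collapse = ", "))
  core_slope(theta, params$N, params$s, params$mu1, params$mu2)
}
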