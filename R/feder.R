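# Frequency-space Gaussian baseline density (Feder-style): deterministic
# logistic mean (no drift correction, no mutation, no boundary handling) and a
# variance accumulated along that path,
#   Var(t) = int_0^t X(u)(1-X(u))/N du = (X(t) - x0)/(gamma N)   (s != 0).
# The calculation is Moran-model based; comparisons against Wright-Fisher
# data keep times in WF generations and instead fold the Moran -> WF
# conversion ("Moran times scaled by one half") into the sweep rate,
# gamma = s/2, while the variance integrand keeps the WF diffusion rate
# x(1-x)/N (so the neutral variance is exactly x0(1-x0) t / N).

core_feder_mean_var <- function(x0, t, N, s) {
  r <- recycle_num(x0 = x0, t = t, N = N, s = s)
  g <- r$s / 2  # Moran-convention sweep rate
  Xf <- r$x0 / (r$x0 + (1 - r$x0) * exp(-g * r$t))
  V <- numeric(length(Xf))
  small <- abs(g * r$t) < 1e-8
  if (any(small))
    V[small] <- (r$x0 * (1 - r$x0) * r$t / r$N)[small]
  if (any(!small))
    V[!small] <- ((Xf - r$x0) / (g * r$N))[!small]
  list(mean = Xf, v = V)
}

core_logdens_feder <- function(x, x0, t, N, s) {
  mv <- core_feder_mean_var(x0, t, N, s)
  dnorm(x, mv$mean, sqrt(mv$v), log = TRUE)
}

core_logtail_feder <- function(boundary, x0, t, N, s) {
  r <- recycle_num(b = boundary, x0 = x0, t = t, N = N, s = s)
  mv <- core_feder_mean_var(r$x0, r$t, r$N, r$s)
  sd <- sqrt(mv$v)
  out <- numeric(length(r$b))
  lo <- r$b == 0
  out[lo] <- pnorm(0, mv$mean[lo], sd[lo], log.p = TRUE)
  out[!lo] <- pnorm(1, mv$mean[!lo], sd[!lo], lower.tail = FALSE, log.p = TRUE)
  out
}

#' Gaussian baseline transition density (boundary-blind)
#'
#' The comparison density used for benchmarking: a Gaussian in frequency
#' space whose mean follows the plain logistic sweep
#' \eqn{dX/dt = sX(1-X)} and whose variance integrates the diffusion rate
#' along that path, \eqn{Var(t) = \int_0^t X(1-X)/N\,du}.  It ignores both the
#' drift correction to the mean and the boundaries at `x = 0, 1` (mass can
#' spill outside `[0, 1]`), and ignores mutation; that boundary blindness is
#' exactly what the angular density improves on for initial frequencies near
#' the boundaries.
#'
#' @inheritParams transition_density
#' @return Density values, per unit frequency.
#' @examples
#' feder_transition_density(0.5, x0 = 0.5, t = 100, params = wf_params(1e3))
#' @export
feder_transition_density <- function(x, x0, t, params) {
  params <- as_wf_params(params)
  if (length(t) != 1L || !is.finite(t) || t <= 0)
    stop("'t' must be a single value > 0")
  if (length(x0) != 1L || x0 <= 0 || x0 >= 1)
    stop("'x0' must lie strictly inside (0, 1)")
  exp(core_logdens_feder(x, x0, t, params$N, params$s))
}
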