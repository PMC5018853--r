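# Deterministic mean path of the heuristic Gaussian density.
#
# The mean in frequency space solves
#   dX/dt = s X(1-X) + mu1 (1-X) - mu2 X - (1-2X)/(4N)
# i.e. selection + mutation + an effective "deterministic" drift force; the
# last term is what makes the mean decrease towards loss when the frequency is
# below the critical value ~ 1/(4Ns) where drift dominates selection.
# Written as dX/dt = a X^2 + b X + c with
#   a = -s,  b = s - (mu1+mu2) + 1/(2N),  c = mu1 - 1/(4N)
# this is a Riccati equation with constant coefficients and closes in terms of
# tanh (two real roots), tan (complex roots), a rational function (double
# root), or an exponential / linear form when s ~ 0.  Paths that exit [0, 1]
# are clamped there: deterministic loss (X = 0, theta = 0) or fixation
# (X = 1, theta = pi).

core_mean_freq <- function(x0, t, N, s, mu1, mu2) {
  r <- recycle_num(x0 = x0, t = t, N = N, s = s, mu1 = mu1, mu2 = mu2)
  n <- length(r$x0)
  b <- r$s - (r$mu1 + r$mu2) + 1 / (2 * r$N)
  cc <- r$mu1 - 1 / (4 * r$N)
  X <- numeric(n)

  lin <- abs(r$s) < 1e-12 / (2 * r$N)
  if (any(lin)) {
    i <- which(lin)
    bi <- b[i]; ci <- cc[i]; x0i <- r$x0[i]; ti <- r$t[i]
    Xi <- numeric(length(i))
    cst <- abs(bi) < 1e-15
    Xi[cst] <- x0i[cst] + ci[cst] * ti[cst]
    if (any(!cst)) {
      k <- !cst
      Xi[k] <- (x0i[k] + ci[k] / bi[k]) * exp(bi[k] * ti[k]) - ci[k] / bi[k]
    }
    X[i] <- Xi
  }

  if (any(!lin)) {
    j <- which(!lin)
    a <- -r$s[j]; bj <- b[j]; cj <- cc[j]
    x0j <- r$x0[j]; tj <- r$t[j]; sj <- r$s[j]
    disc <- bj^2 - 4 * a * cj
    Cj <- -bj / (2 * a)
    Y0 <- x0j - Cj
    Xj <- numeric(length(j))

    pos <- disc > 0
    if (any(pos)) {
      A <- sqrt(disc[pos]) / (2 * abs(a[pos]))
      z <- Y0[pos] / A
      tau <- tanh(sj[pos] * A * tj[pos])
      den <- 1 + z * tau
      Xp <- Cj[pos] + A * (tau + z) / den
      # pole of the |z| > 1 branch: the path diverged (hit a boundary) earlier
      blew <- !is.finite(Xp) | den <= 0
      if (any(blew)) Xp[blew] <- ifelse(z[blew] > 0, 1, 0)
      Xj[pos] <- Xp
    }
    dz <- disc == 0
    if (any(dz)) {
      den <- 1 - a[dz] * Y0[dz] * tj[dz]
      Xd <- Cj[dz] + Y0[dz] / den
      blew <- !is.finite(Xd) | den <= 0
      if (any(blew)) Xd[blew] <- ifelse(Y0[dz][blew] > 0, 1, 0)
      Xj[dz] <- Xd
    }
    neg <- disc < 0
    if (any(neg)) {
      B <- sqrt(-disc[neg]) / (2 * abs(a[neg]))
      phi <- a[neg] * B * tj[neg] + atan(Y0[neg] / B)
      ok <- abs(phi) < pi / 2
      Xn <- ifelse(ok, Cj[neg] + B * tan(phi), ifelse(a[neg] > 0, 1, 0))
      Xj[neg] <- Xn
    }
    X[j] <- Xj
  }

  clamped <- !is.finite(X) | X <= 0 | X >= 1
  X[!is.finite(X)] <- ifelse(r$x0[!is.finite(X)] > 0.5, 1, 0)
  list(X = pmin(pmax(X, 0), 1), clamped = clamped)
}

#' Deterministic mean frequency of the Wright-Fisher process
#'
#' Closed-form solution of the effective deterministic dynamics
#' \eqn{dX/dt = sX(1-X) + \mu_1(1-X) - \mu_2 X - (1-2X)/4N}, the mean of the
#' heuristic Gaussian transition density.  For `s != 0` this is a tanh
#' (logistic-type) path between the roots of the quadratic right-hand side;
#' for `s = 0` the equation is linear with an exponential solution.  Values
#' are clamped to `[0, 1]`: a path that exits the interval corresponds to
#' deterministic loss or fixation.
#'
#' @param x0 Initial frequency in `[0, 1]`.
#' @param params A [wf_params()] object.
#' @param t Elapsed time in generations (>= 0; vectorised together with `x0`).
#' @return Numeric vector of mean frequencies.
#' @examples
#' p <- wf_params(N = 1e4, s = 1e-3)
#' deterministic_mean_freq(0.1, p, c(0, 500, 2000))
#' @export
deterministic_mean_freq <- function(x0, params, t) {
  params <- as_wf_params(params)
  if (any(!is.finite(t) | t < 0))
    stop("'t' must be >= 0, got: ", paste(utils::head(t[t < 0 | !is.finite(t)], 3L), collapse = ", "))
  if (any(!is.finite(x0) | x0 < 0 | x0 > 1))
    stop("'x0' outside [0, 1]")
  core_mean_freq(x0, t, params$N, params$s, params$mu1, params$mu2)$X
}

#' Deterministic mean path in angular coordinates
#'
#' [deterministic_mean_freq()] pushed through Fisher's angular transformation,
#' with a flag marking deterministic fixation (`theta = pi`) or loss
#' (`theta = 0`).
#'
#' @param theta0 Initial angle in `[0, pi]`.
#' @inheritParams deterministic_mean_freq
#' @return A list with components `theta` (radians, same length as `t`) and
#'   `clamped` (logical).
#' @export
deterministic_mean_angle <- function(theta0, params, t) {
  params <- as_wf_params(params)
  if (any(!is.finite(t) | t < 0)) stop("'t' must be >= 0")
  x0 <- angle_to_freq(theta0)
  m <- core_mean_freq(x0, t, params$N, params$s, params$mu1, params$mu2)
  list(theta = acos(1 - 2 * m$X), clamped = m$clamped)
}
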