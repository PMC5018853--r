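# Maximum-likelihood fitting: a coarse log-grid scan (the (N, s) surface is
# banana-shaped with flat directions, so derivative-free global search comes
# first) followed by a Nelder-Mead polish from the best grid point.

#' Default search bounds for maximum-likelihood fitting
#'
#' @param N Range of effective population sizes (log-scanned).
#' @param s_mag Range of |s| values scanned on a signed log grid (plus s = 0).
#' @param mu Range of mutation rates scanned when fitting mutation.
#' @return A list of bounds understood by [fit_ml()].
#' @export
default_bounds <- function(N = c(1e2, 1e6), s_mag = c(1e-5, 1e-1),
                           mu = c(1e-7, 1e-3)) {
  list(N = sort(N), s_mag = sort(s_mag), mu = sort(mu))
}

log_grid <- function(lo, hi, n) {
  if (lo == hi) return(lo)
  10^seq(log10(lo), log10(hi), length.out = n)
}

signed_s_grid <- function(s_mag, n_per_sign = 21L) {
  g <- log_grid(s_mag[1], s_mag[2], n_per_sign)
  sort(unique(c(-g, 0, g)))
}

polish_fit <- function(trans, start, bounds, mu_fixed, fit_mutation, density) {
  lo <- c(log10(bounds$N[1]), -bounds$s_mag[2])
  hi <- c(log10(bounds$N[2]), bounds$s_mag[2])
  if (fit_mutation) {
    lo <- c(lo, log10(bounds$mu[1])); hi <- c(hi, log10(bounds$mu[2]))
  }
  obj <- function(par) {
    if (any(par < lo) || any(par > hi)) return(1e10)
    mu <- if (fit_mutation) 10^par[3] else mu_fixed
    -ll_grid(trans, 10^par[1], par[2], mu[1], mu[length(mu)], density)
  }
  p0 <- c(log10(start$N), start$s)
  if (fit_mutation) p0 <- c(p0, log10(start$mu))
  scale <- c(0.2, max(abs(start$s), 1e-5))
  if (fit_mutation) scale <- c(scale, 0.25)
  fit <- optim(p0, obj, method = "Nelder-Mead",
               control = list(maxit = 300, parscale = scale))
  list(par = fit$par, value = -fit$value)
}

#' Maximum-likelihood estimation from a frequency time series
#'
#' Maximizes the time-series likelihood over the effective population size and
#' selection coefficient (and optionally a shared mutation rate
#' `mu1 = mu2 = mu`): a coarse scan over a log-spaced `N` grid (41 points) and
#' a signed log `s` grid including 0 (43 points), optionally crossed with a
#' log `mu` grid (17 points), followed by a derivative-free Nelder-Mead polish
#' from the best grid point.  The neutral profile (`s = 0`) is fitted
#' alongside, giving the likelihood-ratio statistic
#' `lrt = 2 (logLik_max - logLik_{s=0})`.
#'
#' @param series A [wf_series()].
#' @param bounds Search box from [default_bounds()].
#' @param fit_mutation If `TRUE`, also fit a shared mutation rate
#'   (`"angular"` density only; the baseline ignores mutation).
#' @param density `"angular"` or `"feder"`.
#' @param mu Fixed mutation rate(s) used when `fit_mutation = FALSE`; either a
#'   single shared rate or `c(mu1, mu2)`.
#' @return A `"wf_fit"` list: `N_hat`, `s_hat`, `mu1_hat`, `mu2_hat`,
#'   `loglik`, `loglik_null`, `lrt`, `density`.
#' @examples
#' \donttest{
#' tr <- wf_discrete_trajectory(wf_params(1e4, s = 1e-3), 0.1, T = 1e4, seed = 1)
#' fit <- fit_ml(sample_series(tr, 100))
#' fit$N_hat; fit$s_hat
#' }
#' @export
fit_ml <- function(series, bounds = default_bounds(), fit_mutation = FALSE,
                   density = c("angular", "feder"), mu = 0) {
  density <- match.arg(density)
  if (density == "feder" && fit_mutation) {
    warning("the baseline density ignores mutation; fit_mutation dropped")
    fit_mutation <- FALSE
  }
  if (log10(bounds$N[2] / bounds$N[1]) < 2 && bounds$N[1] != bounds$N[2])
    stop("'bounds$N' must span at least two decades (or be a single point)")
  trans <- series_transitions(series)
  mu_fixed <- rep_len(mu, 2L)

  N_grid <- log_grid(bounds$N[1], bounds$N[2], 41L)
  s_grid <- signed_s_grid(bounds$s_mag)
  mu_grid <- if (fit_mutation) log_grid(bounds$mu[1], bounds$mu[2], 17L) else NA
  nN <- length(N_grid); nS <- length(s_grid)
  Nv <- rep(N_grid, times = nS)
  sv <- rep(s_grid, each = nN)

  best <- list(ll = -Inf)
  best_null <- list(ll = -Inf)
  for (mg in mu_grid) {
    m1 <- if (fit_mutation) rep(mg, nN * nS) else rep(mu_fixed[1], nN * nS)
    m2 <- if (fit_mutation) m1 else rep(mu_fixed[2], nN * nS)
    ll <- ll_grid(trans, Nv, sv, m1, m2, density)
    k <- which.max(ll)
    if (length(k) && ll[k] > best$ll)
      best <- list(ll = ll[k], N = Nv[k], s = sv[k],
                   mu = if (fit_mutation) mg else mu_fixed)
    null_idx <- which(sv == 0)
    kn <- null_idx[which.max(ll[null_idx])]
    if (length(kn) && ll[kn] > best_null$ll)
      best_null <- list(ll = ll[kn], N = Nv[kn],
                        mu = if (fit_mutation) mg else mu_fixed)
  }
  if (!is.finite(best$ll))
    stop("fit failure: likelihood is non-finite over the whole search grid ",
         "(series '", series$site_id, "')")

  point_bounds <- bounds$N[1] == bounds$N[2] && bounds$s_mag[1] == bounds$s_mag[2]
  if (!point_bounds) {
    pol <- polish_fit(trans, list(N = best$N, s = best$s, mu = best$mu[1]),
                      bounds, mu_fixed, fit_mutation, density)
    if (is.finite(pol$value) && pol$value > best$ll) {
      best$ll <- pol$value
      best$N <- 10^pol$par[1]
      best$s <- pol$par[2]
      if (fit_mutation) best$mu <- rep(10^pol$par[3], 2L)
    }
    null_obj <- function(lN) {
      mu <- if (fit_mutation) best_null$mu[1] else mu_fixed
      -ll_grid(trans, 10^lN, 0, mu[1], mu[length(mu)], density)
    }
    if (bounds$N[1] < bounds$N[2]) {
      opt <- optimize(null_obj, log10(bounds$N), tol = 1e-4)
      if (is.finite(opt$objective) && -opt$objective > best_null$ll) {
        best_null$ll <- -opt$objective
        best_null$N <- 10^opt$minimum
      }
    }
  }

  ll_max <- max(best$ll, best_null$ll)  # the null is nested in the alternative
  null_wins <- best_null$ll > best$ll
  mu_hat <- rep_len(if (fit_mutation) best$mu else mu_fixed, 2L)
  structure(list(N_hat = if (null_wins) best_null$N else best$N,
                 s_hat = if (null_wins) 0 else best$s,
                 mu1_hat = mu_hat[1], mu2_hat = mu_hat[2],
                 loglik = ll_max, loglik_null = best_null$ll,
                 lrt = max(0, 2 * (ll_max - best_null$ll)),
                 density = density),
            class = "wf_fit")
}

#' @export
print.wf_fit <- function(x, ...) {
  cat(sprintf("ML fit (%s density)\n", x$density))
  cat(sprintf("  N_hat = %.4g, s_hat = %.4g, mu_hat = (%.3g, %.3g)\n",
              x$N_hat, x$s_hat, x$mu1_hat, x$mu2_hat))
  cat(sprintf("  logLik = %.3f (null %.3f), LRT = %.3f\n",
              x$loglik, x$loglik_null, x$lrt))
  invisible(x)
}

#' Dense log-likelihood surface over parameter grids
#'
#' Evaluates the time-series log-likelihood on the full Cartesian grid of the
#' supplied parameter values, for contour plots and profile diagnostics (e.g.
#' the near-invariance of the likelihood in the mutation rate when sampling is
#' sparse).  The `loglik_rel` component is scaled so its maximum is 0.
#'
#' @inheritParams fit_ml
#' @param N_grid,s_grid Parameter grids (required).
#' @param mu_grid Optional grid of shared mutation rates `mu1 = mu2`.
#' @param mu Fixed mutation rates when `mu_grid` is `NULL`.
#' @return A `"wf_surface"`: grids, `loglik` array (`N x s [x mu]`),
#'   `loglik_rel`, and the `argmax` grid coordinates.
#' @export
likelihood_surface <- function(series, N_grid, s_grid, mu_grid = NULL,
                               density = c("angular", "feder"), mu = 0) {
  density <- match.arg(density)
  trans <- series_transitions(series)
  stopifnot(all(is.finite(N_grid)), all(is.finite(s_grid)))
  mu_fixed <- rep_len(mu, 2L)
  nN <- length(N_grid); nS <- length(s_grid)
  Nv <- rep(N_grid, times = nS)
  sv <- rep(s_grid, each = nN)
  if (is.null(mu_grid)) {
    ll <- ll_grid(trans, Nv, sv, rep(mu_fixed[1], nN * nS),
                  rep(mu_fixed[2], nN * nS), density)
    dim(ll) <- c(nN, nS)
  } else {
    ll <- array(NA_real_, c(nN, nS, length(mu_grid)))
    for (k in seq_along(mu_grid)) {
      mk <- rep(mu_grid[k], nN * nS)
      ll[, , k] <- ll_grid(trans, Nv, sv, mk, mk, density)
    }
  }
  am <- which(ll == max(ll), arr.ind = TRUE)
  am <- am[1, , drop = TRUE]
  structure(list(N = N_grid, s = s_grid, mu = mu_grid,
                 loglik = ll, loglik_rel = ll - max(ll),
                 argmax = am,
                 argmax_values = c(N = N_grid[am[1]], s = s_grid[am[2]],
                                   mu = if (!is.null(mu_grid)) mu_grid[am[3]] else NA)),
            class = "wf_surface")
}

#' Profile log-likelihood over the mutation-rate axis
#'
#' @param surface A `"wf_surface"` computed with a `mu_grid`.
#' @return A data frame with columns `mu` and `loglik` (maximized over N, s).
#' @export
profile_mu <- function(surface) {
  if (is.null(surface$mu)) stop("surface was computed without a mu grid")
  data.frame(mu = surface$mu,
             loglik = apply(surface$loglik, 3, max))
}

#' Likelihood-ratio statistic for selection
#'
#' `2 (max logLik over (N, s) - max logLik over N with s = 0)`.  The statistic
#' is used only to rank sites (it is known to be biased as a calibrated test),
#' so no p-value is attached.
#'
#' @inheritParams fit_ml
#' @return Non-negative scalar.
#' @export
lrt_selection <- function(series, bounds = default_bounds(),
                          density = c("angular", "feder"), mu = 0) {
  fit_ml(series, bounds = bounds, density = match.arg(density), mu = mu)$lrt
}
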