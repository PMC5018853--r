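# Wright-Fisher simulators: the discrete binomial model (exact oracle) and an
# Euler-Maruyama integrator of the frequency-space SDE
#   dx = M(x) dt + sqrt(x(1-x)/N) dW
# which is the diffusion the angular density approximates.

wf_step_mean <- function(x, s, mu1, mu2) {
  pmin(pmax(x + s * x * (1 - x) + mu1 * (1 - x) - mu2 * x, 0), 1)
}

new_wf_trajectory <- function(times, freqs, seed, params) {
  structure(list(times = times, freqs = freqs, seed = seed, params = params),
            class = "wf_trajectory")
}

#' @export
print.wf_trajectory <- function(x, ...) {
  cat(sprintf("Wright-Fisher trajectory: %d points over %g generations (seed %d)\n",
              length(x$times), max(x$times), x$seed))
  cat(sprintf("  x0 = %g, final x = %g\n", x$freqs[1], x$freqs[length(x$freqs)]))
  invisible(x)
}

#' Discrete-generation binomial Wright-Fisher trajectory
#'
#' The reference stochastic model: each generation the frequency is pushed by
#' selection and mutation to `x' = x + s x(1-x) + mu1 (1-x) - mu2 x` (clipped
#' to `[0,1]`), then resampled as `Binomial(N, x')/N`.  The one-generation
#' variance is `x(1-x)/N`, twice the diffusion coefficient `D(x)`.  With
#' `mu1 = mu2 = 0` the boundaries are absorbing: once lost or fixed the
#' trajectory stays there.
#'
#' @param params A [wf_params()] object; `N` must be a whole number >= 2 for
#'   this operation.
#' @param x0 Initial frequency in `[0, 1]`.
#' @param T Number of generations to simulate (>= 1).
#' @param seed Integer RNG seed; fixed seed gives an identical trajectory.
#' @return A `"wf_trajectory"`: list with `times` (0..T), `freqs`, `seed`,
#'   `params`.
#' @examples
#' tr <- wf_discrete_trajectory(wf_params(1000, s = 0.01), 0.1, T = 200, seed = 1)
#' tail(tr$freqs, 3)
#' @export
wf_discrete_trajectory <- function(params, x0, T, seed) {
  params <- as_wf_params(params)
  if (params$N != round(params$N) || params$N < 2)
    stop("discrete simulation needs an integer N >= 2, got N = ", params$N)
  if (T < 1) stop("'T' must be >= 1")
  if (!is.finite(x0) || x0 < 0 || x0 > 1) stop("'x0' outside [0, 1]: ", x0)
  N <- as.integer(params$N)
  set.seed(seed)
  x <- numeric(T + 1)
  x[1] <- x0
  absorbing <- params$mu1 == 0 && params$mu2 == 0
  for (g in seq_len(T)) {
    xp <- wf_step_mean(x[g], params$s, params$mu1, params$mu2)
    x[g + 1] <- rbinom(1L, N, xp) / N
    if (absorbing && (x[g + 1] <= 0 || x[g + 1] >= 1)) {
      if (g < T) x[(g + 2):(T + 1)] <- x[g + 1]
      break
    }
  }
  new_wf_trajectory(0:T, x, as.integer(seed), params)
}

#' Euler-Maruyama trajectory of the Wright-Fisher SDE
#'
#' Integrates `dx = M(x) dt + sqrt(x(1-x) dt / N) Z` with standard-normal
#' `Z`, clipping to `[0, 1]`; with `mu1 = mu2 = 0` the boundaries are
#' absorbing (the noise amplitude vanishes there).  Equivalent in law, as
#' `dt -> 0`, to the angular-space SDE with force `f(theta)` and noise
#' variance `1/N`.  `N` need not be an integer here.
#'
#' @inheritParams wf_discrete_trajectory
#' @param dt Time step in generations (`0 < dt <= 1`; default 0.1, stable for
#'   `N >= 100` and `|s| <= 0.01`).
#' @return A `"wf_trajectory"` with times `0, dt, 2dt, ..., T`.
#' @export
wf_sde_trajectory <- function(params, x0, T, dt = 0.1, seed) {
  params <- as_wf_params(params)
  if (!is.finite(dt) || dt <= 0 || dt > 1) stop("'dt' must be in (0, 1]")
  if (!is.finite(x0) || x0 < 0 || x0 > 1) stop("'x0' outside [0, 1]: ", x0)
  nstep <- round(T / dt)
  set.seed(seed)
  x <- numeric(nstep + 1)
  x[1] <- x0
  z <- rnorm(nstep)
  for (k in seq_len(nstep)) {
    xc <- x[k]
    drift <- params$s * xc * (1 - xc) + params$mu1 * (1 - xc) - params$mu2 * xc
    x[k + 1] <- min(max(xc + drift * dt +
                          sqrt(xc * (1 - xc) * dt / params$N) * z[k], 0), 1)
  }
  new_wf_trajectory(seq(0, by = dt, length.out = nstep + 1), x,
                    as.integer(seed), params)
}

#' Endpoint ensembles of the two simulators
#'
#' Vectorised Monte-Carlo runs used as distributional oracles: `n_rep`
#' independent replicates propagated to time `t`, returning only the final
#' frequencies.
#'
#' @inheritParams wf_discrete_trajectory
#' @param t Final time in generations.
#' @param n_rep Number of replicates.
#' @return Numeric vector of `n_rep` endpoint frequencies.
#' @export
wf_discrete_endpoints <- function(params, x0, t, n_rep, seed) {
  params <- as_wf_params(params)
  if (params$N != round(params$N) || params$N < 2)
    stop("discrete simulation needs an integer N >= 2")
  N <- as.integer(params$N)
  set.seed(seed)
  x <- rep(x0, n_rep)
  for (g in seq_len(round(t))) {
    xp <- wf_step_mean(x, params$s, params$mu1, params$mu2)
    x <- rbinom(n_rep, N, xp) / N
  }
  x
}

#' @rdname wf_discrete_endpoints
#' @param dt SDE time step in generations.
#' @export
wf_sde_endpoints <- function(params, x0, t, dt = 0.1, n_rep, seed) {
  params <- as_wf_params(params)
  set.seed(seed)
  x <- rep(x0, n_rep)
  for (k in seq_len(round(t / dt))) {
    drift <- params$s * x * (1 - x) + params$mu1 * (1 - x) - params$mu2 * x
    x <- pmin(pmax(x + drift * dt +
                     sqrt(x * (1 - x) * dt / params$N) * rnorm(n_rep), 0), 1)
  }
  x
}

#' Construct a frequency time series
#'
#' @param times Strictly increasing times in generations (length >= 2).
#' @param freqs Frequencies in `[0, 1]`, same length as `times`.
#' @param site_id Site identifier.
#' @return A `"wf_series"` object.
#' @export
wf_series <- function(times, freqs, site_id = "site1") {
  if (length(times) != length(freqs) || length(times) < 2L)
    stop("'times' and 'freqs' must have equal length >= 2")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(!is.finite(freqs) | freqs < 0 | freqs > 1))
    stop("'freqs' outside [0, 1]")
  structure(list(site_id = as.character(site_id), times = as.numeric(times),
                 freqs = as.numeric(freqs)),
            class = "wf_series")
}

#' @export
print.wf_series <- function(x, ...) {
  cat(sprintf("Frequency time series '%s': %d points, t in [%g, %g]\n",
              x$site_id, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Subsample a trajectory into an observed time series
#'
#' Keeps the trajectory values at times `0, delta_t, 2 delta_t, ...` (plus the
#' final time), emulating periodic sampling of an underlying trajectory.
#'
#' @param traj A `"wf_trajectory"`.
#' @param delta_t Sampling interval in generations (>= 1, <= span).
#' @param site_id Identifier for the resulting series.
#' @return A `"wf_series"`.
#' @export
sample_series <- function(traj, delta_t, site_id = "site1") {
  if (!inherits(traj, "wf_trajectory")) stop("'traj' must be a wf_trajectory")
  span <- max(traj$times)
  if (delta_t < 1) stop("'delta_t' must be >= 1 generation")
  if (delta_t > span)
    stop("degenerate series: delta_t = ", delta_t, " exceeds the span ", span)
  want <- unique(c(seq(0, span, by = delta_t), span))
  keep <- !is.na(match(round(traj$times, 6), round(want, 6)))
  wf_series(traj$times[keep], traj$freqs[keep], site_id)
}

#' Simulate a labeled collection of sites for selection-scan studies
#'
#' `floor(frac_selected * n_sites)` sites evolve under `params_sel`, the rest
#' under `params_null`; every site gets its own trajectory and reproducible
#' seed spawned from the master seed by a counter scheme
#' (`site_seed_i = (seed * 48271 + i) mod (2^31 - 1)`), so the set is
#' identical for a given master seed regardless of evaluation order.
#'
#' @param n_sites Number of sites (>= 1).
#' @param frac_selected Proportion of sites under selection, in `[0, 1]`.
#' @param params_sel,params_null [wf_params()] for selected / neutral sites.
#' @param x0 Initial frequency shared by all sites.
#' @param T Total span in generations.
#' @param delta_t Sampling interval in generations.
#' @param seed Master integer seed.
#' @return A `"wf_site_set"`: list with `series` (list of `"wf_series"`) and
#'   `labels` (`"selected"` / `"neutral"`).
#' @export
simulate_site_set <- function(n_sites, frac_selected, params_sel, params_null,
                              x0, T, delta_t, seed) {
  if (n_sites < 1) stop("'n_sites' must be >= 1")
  if (frac_selected < 0 || frac_selected > 1)
    stop("'frac_selected' must be in [0, 1]")
  n_sel <- floor(frac_selected * n_sites)
  labels <- rep(c("selected", "neutral"), c(n_sel, n_sites - n_sel))
  series <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    p <- if (i <= n_sel) params_sel else params_null
    site_seed <- (seed * 48271 + i) %% 2147483647
    traj <- wf_discrete_trajectory(p, x0, T, seed = site_seed)
    series[[i]] <- sample_series(traj, delta_t, site_id = sprintf("site%05d", i))
  }
  structure(list(series = series, labels = labels), class = "wf_site_set")
}

#' @export
print.wf_site_set <- function(x, ...) {
  cat(sprintf("Site set: %d series (%d selected, %d neutral)\n",
              length(x$series), sum(x$labels == "selected"),
              sum(x$labels == "neutral")))
  invisible(x)
}
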