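# Time-series likelihood: the Markov product of transition densities,
#   log L = sum_i log p(x_{i+1}, x_i; t_{i+1} - t_i).
#
# Boundary protocol for absorbing data (mu1 = mu2 = 0):
#   interior -> interior : log density (weighted angular Gaussian / baseline)
#   interior -> boundary : log of the absorbed Gaussian mass beyond the
#                          boundary (theta < 0 for loss, theta > pi for
#                          fixation; x < 0 / x > 1 for the baseline)
#   boundary -> same     : 0  (absorbed state persists with probability 1)
#   boundary -> other    : -Inf (departure from an absorbing state)
# With mutation all exact-boundary observations are first regularized to
# 1/(2N) from the boundary and every transition is scored by the density.

series_transitions <- function(series) {
  if (!inherits(series, "wf_series")) stop("'series' must be a wf_series")
  if (any(diff(series$times) <= 0))
    stop("series '", series$site_id, "': times must be strictly increasing")
  m <- length(series$times) - 1L
  list(xf = series$freqs[seq_len(m)],
       xt = series$freqs[seq_len(m) + 1L],
       dt = diff(series$times))
}

# Log-likelihood of one series over a vector of parameter points (all of
# N, s, mu1, mu2 length G); returns a length-G vector.  The heavy path for
# grid scans: transitions x grid evaluated in one vectorised sweep.
ll_grid <- function(trans, N, s, mu1, mu2, density = "angular") {
  m <- length(trans$xf)
  G <- length(N)
  xf <- rep(trans$xf, times = G)
  xt <- rep(trans$xt, times = G)
  dt <- rep(trans$dt, times = G)
  Ne <- rep(N, each = m)
  se <- rep(s, each = m)
  m1 <- rep(mu1, each = m)
  m2 <- rep(mu2, each = m)
  ll <- numeric(m * G)

  mutating <- density == "angular" && any(mu1 + mu2 > 0)
  if (mutating) {
    eps <- 1 / (2 * Ne)
    xf_r <- ifelse(xf <= 0, eps, ifelse(xf >= 1, 1 - eps, xf))
    xt_r <- ifelse(xt <= 0, eps, ifelse(xt >= 1, 1 - eps, xt))
    ll <- core_logdens_angular(xt_r, xf_r, dt, Ne, se, m1, m2)
  } else {
    bf <- xf <= 0 | xf >= 1
    bt <- xt <= 0 | xt >= 1
    ii <- !bf & !bt
    ib <- !bf & bt
    bstay <- bf & xt == xf
    bdep <- bf & xt != xf
    if (any(ii)) {
      ll[ii] <- if (density == "angular")
        core_logdens_angular(xt[ii], xf[ii], dt[ii], Ne[ii], se[ii], m1[ii], m2[ii])
      else
        core_logdens_feder(xt[ii], xf[ii], dt[ii], Ne[ii], se[ii])
    }
    if (any(ib)) {
      bnd <- ifelse(xt[ib] >= 1, 1, 0)
      ll[ib] <- if (density == "angular")
        core_logtail_angular(bnd, xf[ib], dt[ib], Ne[ib], se[ib], m1[ib], m2[ib])
      else
        core_logtail_feder(bnd, xf[ib], dt[ib], Ne[ib], se[ib])
    }
    ll[bstay] <- 0
    ll[bdep] <- -Inf
  }
  dim(ll) <- c(m, G)
  colSums(ll)
}

#' Log-likelihood of a frequency time series
#'
#' Sums the log transition density over consecutive observations
#' (the process is Markov, so the likelihood factorises over transitions).
#' Exact-boundary observations follow the absorbing / zero-flux protocol
#' described for [transition_density()]: with `mu1 = mu2 = 0` the transition
#' into a boundary is scored by the absorbed Gaussian tail mass, staying at
#' the boundary contributes zero, and leaving it is impossible (`-Inf`); with
#' mutation, boundary observations are regularized half an individual inward.
#'
#' @param series A [wf_series()] (or an object from [sample_series()]).
#' @param params A [wf_params()] object.
#' @param density `"angular"` for the heuristic angular-Gaussian density,
#'   `"feder"` for the frequency-space Gaussian baseline.
#' @return The log-likelihood (scalar; may be `-Inf`).
#' @examples
#' tr <- wf_discrete_trajectory(wf_params(1e3, s = 1e-3), 0.3, T = 1000, seed = 2)
#' sr <- sample_series(tr, 100)
#' log_likelihood(sr, wf_params(1e3, s = 1e-3))
#' @export
log_likelihood <- function(series, params, density = c("angular", "feder")) {
  params <- as_wf_params(params)
  density <- match.arg(density)
  trans <- series_transitions(series)
  if (all(trans$xf <= 0 | trans$xf >= 1) && all(trans$xt <= 0 | trans$xt >= 1))
    warning("series '", series$site_id, "' consists entirely of boundary ",
            "observations; likelihood is degenerate")
  ll <- ll_grid(trans, params$N, params$s, params$mu1, params$mu2, density)
  as.numeric(ll)
}
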