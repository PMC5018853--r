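# Independent oracles shared across tests.

# Runge-Kutta solve of the deterministic mean ODE (selection + mutation +
# the drift force), the ground truth for the closed-form mean path.
ode_mean_oracle <- function(x0, params, t) {
  f <- function(t, X, parms) {
    list(params$s * X * (1 - X) + params$mu1 * (1 - X) - params$mu2 * X -
           (1 - 2 * X) / (4 * params$N))
  }
  out <- deSolve::ode(y = c(X = x0), times = c(0, t), func = f, parms = NULL,
                      rtol = 1e-12, atol = 1e-12)
  unname(out[-1, "X"])
}

# Numerical integral of a density over (0, 1) on a uniform theta grid
# (dx = sqrt(x(1-x)) dtheta keeps the integrand bounded near the boundaries).
integrate_density <- function(params, x0, t, n = 4001L,
                              fn = transition_density) {
  th <- seq(1e-8, pi - 1e-8, length.out = n)
  xs <- angle_to_freq(th)
  d <- fn(xs, x0, t, params)
  sum(d * sqrt(xs * (1 - xs))) * (th[2] - th[1])
}

density_moment <- function(params, x0, t, pow = 1, n = 4001L,
                           fn = transition_density) {
  th <- seq(1e-8, pi - 1e-8, length.out = n)
  xs <- angle_to_freq(th)
  d <- fn(xs, x0, t, params)
  sum(xs^pow * d * sqrt(xs * (1 - xs))) * (th[2] - th[1])
}

make_series <- function(times, freqs, id = "s1") wf_series(times, freqs, id)

# Small simulated series for inference tests.
sim_series <- function(params, x0, T, delta_t, seed, id = "s1") {
  sample_series(wf_discrete_trajectory(params, x0, T, seed), delta_t, id)
}
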