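# Method evaluation: ROC over likelihood-ratio statistics, replicate
# parameter-recovery studies, and the total-variation comparison between the
# analytic density and the discrete Wright-Fisher simulator.

#' ROC curve of a likelihood-ratio selection scan
#'
#' Sites are ranked by how strongly the likelihood-ratio statistic rejects
#' neutrality (largest first, ties broken by stable site order) and the true
#' positive rate is traced against the false positive rate; the area under the
#' curve is computed by the trapezoid rule.
#'
#' @param site_set A `"wf_site_set"` from [simulate_site_set()] (needs both
#'   labels present).
#' @param density Density backend used to compute the per-site statistics.
#' @param stats Optional pre-computed vector of per-site statistics (skips the
#'   per-site fits).
#' @param bounds Search bounds passed to [lrt_selection()].
#' @return A `"wf_roc"`: list with `points` (data frame `fpr`, `tpr`), `auc`
#'   and the per-site `stats`.
#' @export
roc_curve <- function(site_set, density = c("angular", "feder"), stats = NULL,
                      bounds = default_bounds()) {
  if (!inherits(site_set, "wf_site_set")) stop("'site_set' must be a wf_site_set")
  density <- match.arg(density)
  labels <- site_set$labels
  if (length(unique(labels)) < 2L)
    stop("undefined AUC: site set contains a single class (", unique(labels), ")")
  if (is.null(stats))
    stats <- vapply(site_set$series, lrt_selection, numeric(1),
                    bounds = bounds, density = density)
  ord <- order(-stats, seq_along(stats))  # stable in site order on ties
  pos <- labels[ord] == "selected"
  tpr <- c(0, cumsum(pos) / sum(pos))
  fpr <- c(0, cumsum(!pos) / sum(!pos))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc,
                 stats = stats, density = density),
            class = "wf_roc")
}

#' @export
print.wf_roc <- function(x, ...) {
  cat(sprintf("ROC (%s density): %d sites, AUC = %.4f\n",
              x$density, length(x$stats), x$auc))
  invisible(x)
}

#' Replicate parameter-recovery study
#'
#' Simulates `n_reps` discrete Wright-Fisher trajectories under known
#' parameters, samples each every `delta_t` generations, refits `(N, s)` by
#' maximum likelihood, and summarizes the relative errors
#' `|est - true| / true` by their median and interquartile range.  Replicates
#' whose fit fails are dropped (an error is raised if more than 10% fail).
#'
#' @param true_params [wf_params()] used to generate the data.
#' @param x0 Initial frequency.
#' @param T Trajectory span in generations.
#' @param delta_t Sampling interval in generations.
#' @param n_reps Number of replicates (>= 30).
#' @param seed Master seed; replicate `i` uses `rep_seeds[i]`.
#' @param density `"angular"` or `"feder"`.
#' @param rep_seeds Optional explicit per-replicate seeds (defaults to
#'   `seed + 0:(n_reps-1)`).
#' @param bounds Search bounds for [fit_ml()].
#' @return A `"wf_recovery"`: per-replicate `errors` data frame plus
#'   `median_rel_err` and `iqr_rel_err` (each with components `N` and `s`) and
#'   the failure count `n_fail`.
#' @export
recovery_study <- function(true_params, x0, T, delta_t, n_reps, seed,
                           density = c("angular", "feder"), rep_seeds = NULL,
                           bounds = default_bounds()) {
  true_params <- as_wf_params(true_params)
  density <- match.arg(density)
  if (n_reps < 30) stop("'n_reps' must be >= 30 for stable medians")
  if (is.null(rep_seeds)) rep_seeds <- seed + seq_len(n_reps) - 1
  rows <- vector("list", n_reps)
  n_fail <- 0L
  for (i in seq_len(n_reps)) {
    res <- tryCatch({
      traj <- wf_discrete_trajectory(true_params, x0, T, seed = rep_seeds[i])
      sr <- sample_series(traj, delta_t, site_id = sprintf("rep%04d", i))
      fit <- fit_ml(sr, bounds = bounds, density = density)
      data.frame(rep = i, N_hat = fit$N_hat, s_hat = fit$s_hat,
                 rel_N = abs(fit$N_hat - true_params$N) / true_params$N,
                 rel_s = abs(fit$s_hat - true_params$s) / abs(true_params$s))
    }, error = function(e) NULL)
    if (is.null(res)) n_fail <- n_fail + 1L else rows[[i]] <- res
  }
  if (n_fail > 0.1 * n_reps)
    stop("recovery study failed: ", n_fail, "/", n_reps, " fits errored")
  if (n_fail > 0) message(n_fail, " replicate fit(s) dropped")
  errors <- do.call(rbind, rows)
  structure(list(errors = errors,
                 median_rel_err = c(N = median(errors$rel_N),
                                    s = median(errors$rel_s)),
                 iqr_rel_err = c(N = unname(diff(quantile(errors$rel_N, c(0.25, 0.75)))),
                                 s = unname(diff(quantile(errors$rel_s, c(0.25, 0.75))))),
                 n_fail = n_fail, density = density,
                 true_params = true_params),
            class = "wf_recovery")
}

#' @export
print.wf_recovery <- function(x, ...) {
  cat(sprintf("Recovery study (%s density, %d replicates, %d dropped)\n",
              x$density, nrow(x$errors) + x$n_fail, x$n_fail))
  cat(sprintf("  median rel. error: N %.1f%%, s %.1f%%\n",
              100 * x$median_rel_err["N"], 100 * x$median_rel_err["s"]))
  invisible(x)
}

# Bin masses of the analytic density over a partition of [0, 1], including
# boundary atoms: Gaussian tail mass beyond theta = 0 / pi plus (absorbing
# case) the mass removed by the weighting function, split by side.
density_bin_masses <- function(params, x0, t, breaks, n_theta = 4000L) {
  th_gr <- seq(0, pi, length.out = n_theta + 1L)
  th_mid <- (th_gr[-1] + th_gr[-length(th_gr)]) / 2
  dth <- diff(th_gr)
  mv <- core_mean_var(regularize_boundary_obs(x0, params), t,
                      params$N, params$s, params$mu1, params$mu2)
  g <- dnorm(th_mid, mv$Theta, sqrt(mv$v))
  absorbing <- params$mu1 == 0 && params$mu2 == 0
  if (absorbing) {
    ts <- core_theta_star(x0, params$N, params$s)
    h <- tanh(th_mid / ts) * tanh((pi - th_mid) / ts)
  } else h <- rep(1, length(th_mid))
  w <- g * h * dth
  xs <- (1 - cos(th_mid)) / 2
  bin <- pmin(pmax(findInterval(xs, breaks, rightmost.closed = TRUE), 1L),
              length(breaks) - 1L)
  mass <- as.numeric(rowsum(w, bin, reorder = TRUE))
  out <- numeric(length(breaks) - 1L)
  out[sort(unique(bin))] <- mass
  # absorbed / escaped mass -> boundary bins
  tail_lo <- pnorm(0, mv$Theta, sqrt(mv$v))
  tail_hi <- pnorm(pi, mv$Theta, sqrt(mv$v), lower.tail = FALSE)
  def <- g * (1 - h) * dth
  out[1] <- out[1] + tail_lo + sum(def[th_mid < pi / 2])
  out[length(out)] <- out[length(out)] + tail_hi + sum(def[th_mid >= pi / 2])
  out
}

#' Total-variation distance between the analytic density and simulation
#'
#' Propagates `n_rep` discrete Wright-Fisher replicates to time `t`, bins the
#' endpoints into `bins` equal-width frequency classes, and compares with the
#' analytic transition density integrated over the same classes (absorbed
#' probability is assigned to the boundary classes on both sides).  Small
#' values mean the closed-form density reproduces the simulated
#' Green's function.
#'
#' @inheritParams transition_density
#' @param n_rep Number of simulation replicates.
#' @param seed RNG seed for the simulation.
#' @param bins Number of frequency classes.
#' @return The total-variation distance in `[0, 1]`.
#' @export
density_sim_tv <- function(params, x0, t, n_rep = 1e5, seed = 1, bins = 50L) {
  params <- as_wf_params(params)
  xs <- wf_discrete_endpoints(params, x0, t, n_rep, seed)
  breaks <- seq(0, 1, length.out = bins + 1L)
  sim <- tabulate(pmin(pmax(findInterval(xs, breaks, rightmost.closed = TRUE),
                            1L), bins), nbins = bins) / n_rep
  model <- density_bin_masses(params, x0, t, breaks)
  0.5 * sum(abs(sim - model / sum(model)))
}
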