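#' Population-genetic parameters of the two-variant Wright-Fisher model
#'
#' Bundles the four parameters of the diffusion approximation of the 2-allele
#' Wright-Fisher model: the mean per-generation change in variant frequency is
#' \eqn{M(x) = s x(1-x) + \mu_1(1-x) - \mu_2 x} and half the between-generation
#' variance is \eqn{D(x) = x(1-x)/2N}.
#'
#' `N` is real-valued because it is an inference target; operations that need
#' an integer census size (the discrete binomial simulator) check this
#' themselves.  The population-scaled combinations `Ns`, `2N(mu1+mu2)` and
#' `2N(mu1-mu2)` drive all of the angular-space formulas.
#'
#' @param N Effective population size (> 0; real-valued).
#' @param s Selection coefficient per generation; `s > 0` favours variant 1.
#' @param mu1 Mutation rate variant 0 -> 1, per generation (>= 0).
#' @param mu2 Mutation rate variant 1 -> 0, per generation (>= 0).
#'
#' @return An object of class `"wf_params"`: a list with elements
#'   `N`, `s`, `mu1`, `mu2`.
#' @examples
#' p <- wf_params(N = 1e4, s = 1e-3)
#' p
#' @export
wf_params <- function(N, s = 0, mu1 = 0, mu2 = 0) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N <= 0)
    stop("'N' must be a single finite value > 0, got: ", deparse(N))
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s))
    stop("'s' must be a single finite value, got: ", deparse(s))
  if (!is.numeric(mu1) || length(mu1) != 1L || !is.finite(mu1) || mu1 < 0)
    stop("'mu1' must be a single finite value >= 0, got: ", deparse(mu1))
  if (!is.numeric(mu2) || length(mu2) != 1L || !is.finite(mu2) || mu2 < 0)
    stop("'mu2' must be a single finite value >= 0, got: ", deparse(mu2))
  structure(list(N = as.numeric(N), s = as.numeric(s),
                 mu1 = as.numeric(mu1), mu2 = as.numeric(mu2)),
            class = "wf_params")
}

#' @export
print.wf_params <- function(x, ...) {
  cat("Wright-Fisher parameters\n")
  cat(sprintf("  N   = %g\n  s   = %g   (Ns = %g)\n", x$N, x$s, x$N * x$s))
  cat(sprintf("  mu1 = %g, mu2 = %g   (4N mu_tot/2 = %g)\n",
              x$mu1, x$mu2, 2 * x$N * (x$mu1 + x$mu2)))
  invisible(x)
}

as_wf_params <- function(params) {
  if (!inherits(params, "wf_params"))
    stop("'params' must be a 'wf_params' object (see wf_params())")
  params
}

#' Characteristic fixation timescale
#'
#' The validity horizon of the short-time density: roughly the expected time
#' for a variant that survives drift to reach fixation.  For pure drift this is
#' of order `N` generations; under selection it is `2 log(2N) / |s|`.
#'
#' @param params A [wf_params()] object.
#' @return Timescale in generations.
#' @export
fixation_timescale <- function(params) {
  params <- as_wf_params(params)
  if (params$s == 0) params$N else 2 * log(2 * params$N) / abs(params$s)
}
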