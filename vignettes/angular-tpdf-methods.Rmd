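---
title: "Wright-Fisher transition densities in Fisher's angular coordinates: model and methods"
author: "wfangular"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wright-Fisher transition densities in Fisher's angular coordinates: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(wfangular)
```

## The problem

Given a time series of variant (allele) frequencies $\{x_i\}$ observed at
generations $\{t_i\}$ in a population of two reproducing variants, how likely
is it that the observed changes were produced by genetic drift alone, and if
selection or mutation acted, how strong were they?  Answering this by
likelihood requires the transition probability density function (TPDF)
$p(x, x_0; t)$ of the Wright-Fisher (WF) diffusion

$$\partial_t p = -\partial_x\!\left[M(x)\,p\right] + \partial_x^2\!\left[D(x)\,p\right],
\qquad
M(x) = s x(1-x) + \mu_1(1-x) - \mu_2 x,
\qquad
D(x) = \frac{x(1-x)}{2N},$$

where $N$ is the effective population size, $s$ the selection coefficient per
generation ($s > 0$ favours variant 1), and $\mu_1, \mu_2$ the mutation rates
between the two variants.  Exact spectral solutions converge usefully only in
the long-time limit; the practically important regime — longitudinal sampling
of evolving populations such as intra-host virus data — is the *short-time*
limit, where intermediate frequency changes are observed.  This package
implements a closed-form short-time approximation and the inference stack on
top of it.

## Fisher's angular transformation

The coordinate $\theta = \arccos(1 - 2x)$ (equivalently $x = \sin^2\theta/2$)
makes the diffusion coefficient constant: $\langle d\theta^2\rangle = dt/2N$
regardless of position.  The price is an effective convective force

$$2N f(\theta) = \left(2N(\mu_1+\mu_2) - 1\right)\cot\theta
 + \frac{2N(\mu_1-\mu_2)}{\sin\theta} + Ns\,\sin\theta,$$

implemented in `effective_force()`.  The $\cot\theta$ term encodes the
probability *flux* towards fixation and loss that a frequency-dependent
diffusion coefficient creates (no individual trajectory is convected — the
neutral process remains a martingale in $x$); the $1/\sin\theta$ term carries
any asymmetry between the mutation rates; the $\sin\theta$ term carries
selection and vanishes at the boundaries, which is why drift always dominates
at frequencies below roughly $(4Ns)^{-1}$.  For $\mu_1 = \mu_2 = \mu$ the
force switches from unstable ($4N\mu < 1$, monomorphic regime) to stable
($4N\mu > 1$, polymorphic regime) at the classical threshold $4N\mu = 1$,
where drift and mutation cancel exactly.

## The heuristic Gaussian density

Because the noise in $\theta$-space is additive, a Gaussian ansatz is natural:

$$p(x, x_0; t) = \frac{h(\theta)}{\sqrt{x(1-x)}}\;
\mathcal{N}\!\left(\theta(x);\, \Theta(t),\, \sigma^2(t)\right),$$

with three ingredients.

**Mean.**  $\Theta(t)$ solves the deterministic limit of the $\theta$-space
dynamics; transformed to frequency space this is
$\dot X = sX(1-X) + \mu_1(1-X) - \mu_2 X - (1-2X)/4N$ — note the last term, an
effective deterministic force contributed by drift, without which the mean of
a rare beneficial variant would incorrectly always sweep upward.  The right
side is a constant-coefficient quadratic (Riccati) form
$\dot X = aX^2 + bX + c$ with $a = -s$, $b = s - (\mu_1{+}\mu_2) + 1/2N$,
$c = \mu_1 - 1/4N$, and closes in elementary functions
(`deterministic_mean_freq()`):

* two real roots — the tanh (logistic-type) path
  $X = C + A\tanh(sAt + \mathrm{artanh}\,\frac{x_0 - C}{A})$, evaluated in an
  algebraically equivalent form that is valid on both sides of the roots;
* complex roots (possible when one mutation rate is large and selection
  opposes it) — the corresponding tan path;
* a double root — the rational path; and
* $s \to 0$ — the linear equation's exponential solution, with the switch at
  $|s| < 10^{-12}/2N$ where the tanh parametrization degenerates.

Paths that exit $[0,1]$ are clamped there and flagged: deterministic loss
($\Theta = 0$) or fixation ($\Theta = \pi$).  Monotonicity of every branch
makes pointwise clamping equivalent to clamping at the first exit.  The
package's correctness reference for all branches is a Runge-Kutta integration
of the same ODE (tests agree to $10^{-8}$).

**Variance.**  If the force had constant slope $\lambda$ the exact variance
would be the Ornstein-Uhlenbeck law $\sigma^2(t) = (e^{2\lambda t}-1)/2N\lambda$.
The heuristic replaces $\lambda$ by the local slope evaluated at the current
mean, $\lambda(\Theta(t))$ — a deliberate, simple choice (not a path
integral of the slope), which is the form `variance_angle()` implements.  The
slope itself (`force_slope()`) uses a regularized force in which the divergent
$\cot\theta$ and $1/\sin\theta$ are replaced by third-order expansions about
$\theta = \pi/2$ ($\cot\theta \to -u - u^3/3$, $1/\sin\theta \to 1 + u^2/2$,
$u = \theta - \pi/2$), keeping $\sin\theta$ exact.  The expansion point
$\pi/2$ is the only one that renders both terms polynomial and bounded on all
of $[0, \pi]$, so the variance stays finite as the mean approaches a
boundary.  At $\lambda = 0$ the variance is continuously $t/N$; the branch is
switched by series expansion when $|\lambda t| < 10^{-8}$.

**Boundaries.**  With $\mu_1 = \mu_2 = 0$ the boundaries absorb, which in
angular space demands $q \sim \theta$ near loss and $q \sim \pi - \theta$
near fixation.  The Gaussian is therefore multiplied by the weight
$h(\theta) = \tanh(\theta/\theta^*)\tanh((\pi-\theta)/\theta^*)$, which has
exactly those limits and is $\approx 1$ elsewhere; any function with the
three limits is admissible and the tanh product was chosen for smoothness and
symmetry.  The resulting mass deficit *is* the absorbed probability; the
density is deliberately not renormalized.  The scale $\theta^*$
(`boundary_theta_star()`) is $0.1$ when selection on the initial variant is
strong ($4N|s|u \gg 1$, $u = x_0$ or $1 - x_0$), because selection piles
density onto a boundary quickly; when selection is weak it is tied to the
initial angle as $\theta^*_{\rm weak} = \min(\theta_0, \pi - \theta_0)/5$, and
the two regimes are blended by a tanh switch of width $0.5$ in
$\ln(4N|s|u)$.  The $1/5$ factor makes $h(\theta_0) = \tanh 5 \approx 0.9999$,
i.e. the weight is inert over the bulk of the short-time density; with a
factor as large as $1/2$ the weight visibly eats interior mass
($h(\theta_0) \approx 0.96$ at the centre and far less one standard deviation
towards the boundary), which measurably degrades the density-vs-simulation
agreement this package tests for.  With mutation the boundaries are zero-flux
instead: the weight is dropped, and since the Jacobian then makes the density
divergent exactly at $x \in \{0, 1\}$, observed boundary frequencies are
moved half an individual inward, $x_\epsilon = 1/2N$
(`regularize_boundary_obs()`) — the natural sub-individual scale, which also
keeps likelihoods finite and $N$-consistent.

The approximation is accurate to times of order the fixation timescale $\tau$
(`fixation_timescale()`: $\sim N$ under drift, $\sim 2\ln(2N)/|s|$ under
selection).  Long-time accuracy is explicitly out of scope; with strong
mutation *and* selection the density stays accurate even at $t \sim \tau$
because mutation-selection balance keeps probability away from the
boundaries.

```{r density-example}
p <- wf_params(N = 1e3, s = 0.01)        # Ns = 10
t <- round(0.25 * fixation_timescale(p))
xs <- seq(0.005, 0.995, by = 0.005)
plot(xs, transition_density(xs, x0 = 0.1, t = t, params = p), type = "l",
     xlab = "variant frequency x", ylab = "p(x | x0 = 0.1)",
     main = sprintf("Ns = 10, t = %d generations", t))
lines(xs, feder_transition_density(xs, 0.1, t, p), lty = 2)
legend("topright", c("angular Gaussian", "boundary-blind baseline"),
       lty = 1:2, bty = "n")
```

## Likelihood and boundary protocol

The process is Markov, so
$\log L(N, s, \mu_1, \mu_2) = \sum_i \log p(x_{i+1}, x_i;\, t_{i+1} - t_i)$
(`log_likelihood()`).  Two degenerate situations need explicit conventions:

* **Absorbing data** ($\mu = 0$): a transition from the interior to an exact
  boundary is scored by the *absorbed mass* — the Gaussian tail beyond
  $\theta = 0$ or $\theta = \pi$ — rather than by a density (the weighted
  density limit at the boundary is not a probability of fixation, and
  discarding fixation events would throw away the most selection-informative
  part of a sweep).  Staying at the boundary afterwards has probability one
  (contributes 0), and leaving it is impossible ($-\infty$).
* **Mutating data**: every exact-boundary observation is regularized to
  $x_\epsilon$ and all transitions are density-scored.

## Fitting, scan and evaluation

The $(N, s)$ surface is banana-shaped with genuinely flat directions (the
mutation axis at sparse sampling), so `fit_ml()` scans a coarse grid first —
$N$ log-spaced over $10^2$–$10^6$ (41 points), $s$ on a signed log grid
$\pm[10^{-5}, 10^{-1}]$ plus 0 (43 points), optionally $\mu$ log-spaced over
$10^{-7}$–$10^{-3}$ (17 points) — then polishes the best point with
Nelder-Mead.  The neutral profile ($s = 0$) is fitted alongside and
$\mathrm{LRT} = 2(\log L_{\max} - \log L_{s=0})$ ranks sites in the selection
scan; no p-value is attached because the statistic is biased as a calibrated
test.  `roc_curve()` sweeps the ranked list into TPR/FPR points (stable
order on ties) with a trapezoid AUC, and `recovery_study()` runs the full
simulate-sample-refit loop, summarizing $|\hat\vartheta - \vartheta|/\vartheta$
by median and interquartile range.

## The baseline density

`feder_transition_density()` is the comparison method: a Gaussian *in
frequency space* whose mean follows the plain logistic sweep (no drift
correction, no mutation) and whose variance accumulates the diffusion rate
along that path, $\mathrm{Var}(t) = \int_0^t X(1-X)/N\,du$.  It ignores the
boundaries — under a strong sweep an appreciable part of its mass sits
outside $[0,1]$ — which is precisely the failure mode the angular density
fixes.  The calculation it reproduces is Moran-model based; the Moran-to-WF
time convention ("Moran times scaled by one half") is folded into the sweep
rate, $\gamma = s/2$, while the variance integrand keeps the WF diffusion
rate so that the neutral variance is exactly $x_0(1-x_0)t/N$.  The original
calculation's boundary handling and exact variance recursion are not
documented; this module's fidelity contract is reproducing the documented
comparison outcomes (a roughly factor-two selection-coefficient bias, hence
$\sim$100% median relative error, and a worse selection-scan ROC), not
bit-compatibility.

## Simulators and what the synthetic data do (not) show

`wf_discrete_trajectory()` is the primary oracle: per generation the
deterministic update $x' = x + sx(1-x) + \mu_1(1-x) - \mu_2 x$ (mutation
applied deterministically, valid for $N\mu \ll 1$) followed by binomial
resampling $\mathrm{Bin}(N, x')/N$ — exact, no discretization error, but
requiring integer $N$.  `wf_sde_trajectory()` integrates the frequency-space
SDE by Euler-Maruyama (default $dt = 0.1$, stable for $N \ge 100$,
$|s| \le 0.01$); frequency-space stepping with clipping was chosen over
$\theta$-space stepping because the angular force diverges at the boundaries.
The two simulators agree in distribution at short times (two-sample KS check
in the test suite), which is the adopted correctness criterion since no step
size is canonical.

The generators emulate the study conditions used throughout: trajectories of
$T = 10^4$ generations sampled every $\Delta t \in \{100, 1000, 2500\}$
generations, $N = 10^4$, $s = 10^{-3}$ ($Ns = 10$), initial frequencies
$x_0 \in \{0.1, 0.5\}$, and site sets with 10% selected sites.  They produce
*exact* frequencies: real data are finite-depth samples of the population,
and the additional binomial sampling noise (normally handled by a hidden
Markov layer) is deliberately not modelled, so passing tests demonstrate
correctness of the density and inference machinery, not robustness to
sequencing noise.  Linkage, recombination, demographic change and more than
two variants are likewise out of scope.

## Numerical choices and problem sizes

* Density-vs-simulation agreement is measured as total variation distance over
  50 frequency bins against $10^5$ discrete-WF replicates
  (`density_sim_tv()`), with absorbed probability assigned to the boundary
  bins on both sides; the package checks all 12 combinations of
  $x_0 \in \{0.1, 0.5, 0.9\}$, $Ns \in \{0, 10\}$, $4N\mu \in \{0, 10\}$ at
  $t = 0.05\,\tau$ (the earliest display-style time fraction) and finds
  TV $\le 0.04$ everywhere, plus $t \sim \tau$ under strong mutation.
* Recovery studies run 100 replicates per condition and the selection scan
  1000 sites; these sizes give stable medians and a stable AUC ordering while
  keeping the full suite comfortably fast on one CPU.
* The integer census sizes, seeds and per-site counter scheme
  (`site_seed = 48271 * seed + i mod 2^31-1`) make every stochastic result
  bit-reproducible.

## Known limitations

* Validity is $O(\tau)$; do not trust the density (or likelihoods built on
  transitions longer than $\sim \min(N, 1/|s|)$ generations).
* The variance heuristic evaluates $\lambda$ at the current mean only; under
  strong selection with $x_0$ near a boundary the width can be mildly
  misestimated mid-sweep.
* The likelihood treats observed frequencies as exact (no sampling-depth
  model).
* The LRT is a ranking statistic here, not a calibrated test.
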