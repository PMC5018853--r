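# wfangular

Likelihood-based inference of evolutionary parameters — effective population
size *N*, selection coefficient *s* and mutation rates *μ₁*, *μ₂* — from
variant- or allele-frequency time series, built on a closed-form short-time
approximation of the two-allele Wright-Fisher transition probability density
(TPDF).  It is aimed at anyone analysing longitudinal polymorphism data
(evolve-and-resequence experiments, intra-host virus sampling, language or
ecological variant dynamics) who needs fast, direct likelihood evaluation
instead of numerically solving the Wright-Fisher dynamics per candidate
parameter value.

## The model

The Wright-Fisher diffusion for a variant at frequency *x* has drift
*M(x) = sx(1−x) + μ₁(1−x) − μ₂x* and diffusion coefficient
*D(x) = x(1−x)/2N*.  In Fisher's angular coordinate θ = arccos(1 − 2x) the
noise becomes coordinate-independent (variance 1/*N* per generation) at the
cost of an effective convective force

> 2*N f*(θ) = (2*N*(μ₁+μ₂) − 1)·cot θ + 2*N*(μ₁−μ₂)/sin θ + *Ns*·sin θ.

The package's core approximation is a Gaussian in θ:

> *p*(*x*, *x₀*; *t*) = *h*(θ)/√(*x*(1−*x*)) · 𝒩(θ(*x*); Θ(*t*), ⟨⟨θ²⟩⟩(*t*)),

where Θ(*t*) is the closed-form (tanh-type) solution of the deterministic
dynamics including an effective drift force −(1−2*X*)/4*N*, the variance
⟨⟨θ²⟩⟩ = (e^{2λt} − 1)/2*N*λ is slaved to the local force slope λ(Θ(*t*)),
and *h* is a boundary weight enforcing absorbing behaviour when mutation is
absent.  The time-series likelihood is the Markov product of these densities;
maximum likelihood, likelihood-ratio selection scans with ROC evaluation, a
boundary-blind Gaussian baseline density for benchmarking, and
discrete-binomial / Euler-Maruyama Wright-Fisher simulators complete the
stack.  The methods vignette (`vignettes/angular-tpdf-methods.Rmd`) derives
and motivates every piece.

## Worked example

Simulate a selective sweep (N = 10⁴, s = 10⁻³, so Ns = 10) from frequency
0.1, sample it every 100 generations for 10⁴ generations, and refit the
parameters from the sampled series alone:

```r
library(wfangular)
p      <- wf_params(N = 1e4, s = 1e-3)
traj   <- wf_discrete_trajectory(p, x0 = 0.1, T = 1e4, seed = 1)
series <- sample_series(traj, delta_t = 100)
fit_ml(series)
#> ML fit (angular density)
#>   N_hat = 9800, s_hat = 0.0008754, mu_hat = (0, 0)
#>   logLik = 159.835 (null 156.837), LRT = 5.995
```

Both parameters are recovered within ~2% and ~13% of truth for this
trajectory; `LRT = 5.995` is the evidence against neutrality
(2·(logLik − logLik at s = 0)) used to rank sites in a scan.  The density
itself can be checked directly against simulation:

```r
density_sim_tv(wf_params(1e3, s = 0.01), x0 = 0.1, t = 76, n_rep = 1e5, seed = 1)
#> [1] 0.02166846   # total-variation distance to 1e5 Wright-Fisher replicates
```

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "wfangular", package = "wfangular")` with subcommands
`simulate`, `density`, `fit`, `scan`, `roc` and `recovery`.

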