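---
title: "Joint modelling of BART behaviour and network fractional anisotropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of BART behaviour and network fractional anisotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`bartjoint` fits a joint hierarchical Bayesian model that couples a
cognitive model of risky choice on the Balloon Analogue Risk Task
(BART) with a probabilistic description of white-matter structural
connectivity, so that individual differences in behaviour and in brain
structure inform each other through a shared multivariate prior. This
vignette is the package's own account of the model, its assumptions,
the choices we made where the design was open, and what the synthetic
tests do and do not establish.

## The cognitive model

On trial $k$ a participant holds a subjective belief about the success
rate of one more pump. The belief follows a logistic trend in the trial
number,

$$\mu_{\alpha k} = \mathrm{logit}^{-1}(\alpha_0 + \alpha_1 k),
\qquad p^*_k = 1 - \mu_{\alpha k},$$

so $\alpha_0$ is the baseline success-belief logit and $\alpha_1$ its
per-trial drift ($\alpha_1 < 0$ means the perceived burst risk grows as
bursts accumulate; $\alpha_1 = 0$ recovers a constant-belief model).
Before acting, the participant fixes an optimal pump target

$$\omega_k = \frac{-\gamma}{\log(1 - p^*_k)},$$

proportional to the risk propensity $\gamma \ge 0$ and shrunk by the
subjective burst probability. Each pump/cash decision at occasion $j$
is Bernoulli with

$$\theta_{kj} = \bigl[1 + e^{\beta (j - \omega_k)}\bigr]^{-1},$$

a logistic decay centred at $\omega_k$ whose slope is the behavioural
consistency $\beta \ge 0$: at $\beta = 0$ responding is a coin flip, and
as $\beta \to \infty$ the agent pumps exactly $\lceil \omega_k \rceil - 1$
times (bursts permitting). Within a trial the target is fixed — the
model assumes no mid-trial belief updating.

A note on the $\omega_k$ expression: one rendering of the model family
places $\log(1-p^*)$ as a multiplicative factor. We implement the
quotient form above, which is the reading under which $p^*$ "acts in
the denominator", $\omega$ is nonnegative and bounds the attainable
pumps, and the population-level estimates reproduce a sensible pump
target (with $\gamma = 0.442$ and $p^* = 0.066$, $\omega \approx 6.5$,
matching the task's burst design).

The belief parameters are anchored by a second observation model: the
cumulative success rate before trial $k$,
$C_k = \sum_{l<k} s_l \big/ \sum_{l<k} n_l$ (successful pumps over pump
attempts), is modelled as
$C_k \sim \mathrm{Beta}(\mu_{\alpha k}\sigma_\alpha,
(1-\mu_{\alpha k})\sigma_\alpha)$ in the mean–concentration
(Ferrari–Cribari-Neto) parameterisation, for $k = 2..K$ ($C_1$ has an
empty history and is excluded). Note that this factor reuses the same
actions that enter the Bernoulli likelihood — a composite-likelihood
construction that we implement exactly as defined; its consequences
are discussed under *Known limitations*.

## The neural model

Structural connectivity is a symmetric $12\times 12$ matrix of tract
fractional anisotropy (FA) over six bilateral regions (thalamus,
striatum, dlPFC, ACC, IFG, insula). A *network* is a named set of ROI
pairs; its Network FA is the collection of FA values of those tracts.
Two confirmatory networks are built in: ACC–Insula–IFG (loss- and
risk-aversion signalling) and dlPFC–Thalamus–Striatum (top-down
control), each as the three within-triplet tracts in both hemispheres —
six ipsilateral tracts per network, no interhemispheric pairs (the
bilateral reading of the network definition).

Tract FA is modelled on the logit scale,
$\mathrm{logit}(f_n) \sim \mathcal{N}(\delta_x, \sigma_x)$: $\delta_x$
is the latent Network-FA location of network $x$ and $\sigma_x$ the
inter-tract variability, which deliberately stays outside the joint
covariance (it is measurement spread, not a neural trait). Tracts with
FA exactly 0 denote failed streamline reconstruction and are dropped
from the likelihood with a warning.

## The joint structure

Per subject, the vector $(\gamma, \beta, \delta_1, \delta_2)$ follows a
multivariate Student-$t$ with location
$\mu = (\mu_\gamma, \mu_\beta, \mu_{\delta_1}, \mu_{\delta_2})$ and a
structured scale matrix

$$\Sigma = \begin{pmatrix}
\sigma_\gamma^2 & 0 & \sigma_\gamma\sigma_{\delta_1}\rho_1 & \sigma_\gamma\sigma_{\delta_2}\rho_2 \\
0 & \sigma_\beta^2 & \sigma_\beta\sigma_{\delta_1}\rho_3 & \sigma_\beta\sigma_{\delta_2}\rho_4 \\
\sigma_\gamma\sigma_{\delta_1}\rho_1 & \sigma_\beta\sigma_{\delta_1}\rho_3 & \sigma_{\delta_1}^2 & 0 \\
\sigma_\gamma\sigma_{\delta_2}\rho_2 & \sigma_\beta\sigma_{\delta_2}\rho_4 & 0 & \sigma_{\delta_2}^2
\end{pmatrix}.$$

The four free correlations $\rho_1..\rho_4$ carry the confirmatory
questions (cognition–network couplings); the zeros at
$(\gamma,\beta)$ and $(\delta_1,\delta_2)$ are structural and are
preserved exactly because the sampler parameterises $\Sigma$ by
$(\sigma, \rho)$ rather than sampling free covariance entries. The
belief parameters $\alpha_0, \alpha_1$ sit outside the covariance in
their own normal hierarchies: they condition the behavioural model so
that $\gamma$ and $\beta$ can be recovered with subjective
probabilities accounted for. The heavy-tailed $t$ (rather than a
Gaussian) makes the learned correlations robust to outlying subjects;
its degrees of freedom $\nu$ are a fixed tuning parameter, default 4
(small enough for genuine robustness, $> 2$ so the prior correlation is
defined), never sampled.

Positivity of $\gamma$ and $\beta$ is handled by truncation at zero:
the $t$ density is evaluated on the natural scale and negative
proposals are rejected. The truncation's normalising constant depends
on $(\mu, \Sigma)$ and is not applied; this mildly reweighs the
hyperprior near the boundary and is negligible at the default
hyper-means (3+ prior SDs from zero).

### Hyperpriors

The original specification of the hyperpriors is not available, so the
package uses documented weakly-informative defaults, overridable via
`bjm_priors()` or a JSON config: $\mathcal N(0, 10)$ on location
hyper-means (truncated at 0 for $\mu_\gamma, \mu_\beta$),
$\mathcal N(0, 1)$ on $\mu_{\alpha_1}$ (a per-trial slope of a logit —
unit scale is already generous), half-$\mathcal N(0,5)$ on every scale
parameter (including the Beta concentration $\sigma_\alpha$), and
$\mathrm{U}(-1,1)$ on each $\rho$ subject to positive definiteness of
$\Sigma$, enforced by rejection.

## Inference

No general MCMC backend is assumed: `bjm_fit()` implements an adaptive
random-walk Metropolis-within-Gibbs sampler. Subject-level parameters
are conditionally independent across subjects given the population
level, so each of the six subject-level components is proposed and
accepted for all subjects simultaneously (with the action and
success-rate likelihood kernels in C++); population-level parameters
are updated one scalar at a time, twice per iteration by default.
Proposal scales adapt toward 0.44 acceptance during warmup and are
frozen afterwards, preserving detailed balance for the retained draws.
Support violations — negative $\gamma, \beta$ or scales, $|\rho| \ge 1$,
non-positive-definite $\Sigma$ — reject proposals through a $-\infty$
log-ratio, never through transformation tricks, so draws satisfy the
constraints exactly.

Numerical guards: pump probabilities are clamped to
$[10^{-12}, 1-10^{-12}]$ inside logs (extreme $\beta(j-\omega)$
otherwise overflows); observed $C_k$ of exactly 0 or 1 (a burst-free or
success-free history) are clamped to $[10^{-3}, 1-10^{-3}]$ before the
Beta density, whose support is open.

The reference protocol (12 chains × 15,000 iterations, 5,000 burn-in,
thinning 1) is configurable but the package defaults to a desk-scale
protocol — 4 chains × 2,000 post-warmup draws after 1,000 warmup
iterations (~1 minute for 23 subjects) — which achieves $\hat R < 1.05$
on all population-level parameters in the recovery experiment.
Convergence is monitored with the split-chain Gelman–Rubin statistic.
`summary()` reports posterior means and central 95% credible intervals;
because interval labelling conventions differ (a 5% lower quantile
paired with a 97.5% upper appears in some reports), the quantile pair
is an explicit argument, defaulting to $(0.025, 0.975)$.

Posterior predictive checking follows the standard recipe: for each
subject, parameter sets are drawn from the joint posterior, full
sessions are replayed through the task generator, and the observed
per-session mean and SD of pumps are compared with their predictive
distributions.

## The synthetic world

The generator reproduces the statistical structure the analysis
assumes, with defaults stating the task design: 36 trials per session;
burst thresholds i.i.d. discrete-uniform on $\{3,\dots,9\}$ — the
unique consecutive-integer uniform with mean 6 and SD 2; 25 cents per
pump. A safety cap of 50 pumps per trial (forced cash, flagged) guards
against degenerate parameter corners; it never binds at the default
burst support.

Population truths for the recovery experiment: hyper-means
$(\mu_\gamma, \mu_\beta, \mu_{\alpha_0}, \mu_{\alpha_1}) =
(0.45, 1.5, 2.6, -0.005)$, $\rho_2 = -0.5$ and the other correlations
zero. Values the task or reference protocol does not pin down were
chosen once on plausibility grounds and not revisited: hyper-SDs
$(0.15, 0.4)$ for $\gamma, \beta$ give coefficient-of-variation ~30%
across subjects, typical of cognitive-model hierarchies; network
locations $\mu_{\delta_1} = -0.3$, $\mu_{\delta_2} = -0.1$ put mean
tract FA at 0.43–0.48, the range reported for the frontal association
and cortico-striatal tracts involved; $\sigma_{\delta} = 0.3$ yields
between-subject FA spread of roughly ±0.07; inter-tract noise
$\sigma_1 = \sigma_2 = 0.25$ makes a 6-tract network estimate a
subject's $\delta$ with standard error ~0.10, comfortably below the
between-subject spread; $\sigma_{\alpha_0} = 0.3$ and
$\sigma_{\alpha_1} = 0.003$ keep belief trajectories within the range
that produces 0–2 expected bursts' difference over a session.

What a green synthetic test establishes: that the likelihoods,
hierarchy, sampler, diagnostics and predictive machinery are internally
consistent and that the confirmatory correlation $\rho_2$ is detectable
at $S = 23$. What it does not establish: anything about real BART
populations or real tractography, whose FA values are spatially
correlated across tracts, non-logit-normal in the tails, and subject to
reconstruction failures that are not missing at random.

## Known limitations

The most consequential one is a property of the model as defined, which
the package reproduces faithfully rather than repairs. The Beta
success-rate factor evaluates ~35 *cumulative* — hence strongly
dependent and nearly identical — statistics per subject as if
independent, and those statistics are computed from the same actions
that enter the Bernoulli likelihood. Two effects follow in simulation
studies. First, the concentration $\sigma_\alpha$ inflates until each
subject's $\alpha_0$ is effectively pinned to the logit of their
*realized* success rate. Second, the realized rate is mechanically
below the generating belief (bursts depress successes regardless of
belief: at the default truths the realized rate is ≈0.90 versus a
generating $\mu_\alpha = 0.93$), so recovered $\alpha_0$ sit ≈0.4
logits low with inflated spread, and $\gamma$ — which trades off
against $\alpha_0$ through $\omega = -\gamma/\log \mu_\alpha$ —
compensates upward. Population behaviour (pump patterns, predictive
checks, the sign and strength of $\rho_2$, convergence) is reproduced
well; the *absolute* calibration of $(\gamma, \alpha_0)$ against a
generative agent is not. The acceptance suite states the hyper-mean
coverage check at face value and we leave it failing rather than
weaken it; anyone extending the model could decouple the two factors
(e.g., model per-trial burst outcomes instead of cumulative rates) at
the cost of departing from the reference formulation.

Smaller ones: the truncation constant of the multivariate $t$ is not
renormalised (see above); $C_k$ clamping introduces a fixed penalty for
burst-free histories; the sampler is random-walk based, so posteriors
with strong subject-level ridges mix more slowly than a gradient-based
sampler would — the default protocol compensates with adaptation and
two population sweeps per iteration.

## Reproducibility

Every stochastic entry point takes a `seed` and restores the caller's
RNG state; `bjm_fit()` derives per-chain seeds from its single seed, so
a fit is a pure function of (data, configuration, seed).
`write_samples()` persists draws as plain CSV plus a JSON sidecar with
the full configuration, chains seeds included.
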