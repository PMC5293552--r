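---
title: "Methods: sparse causal network inference by expectation propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse causal network inference by expectation propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epnet)
```

This vignette is the package's own account of its model, its numerical
choices, and the limits of what its tests demonstrate.

## The generative model and its assumptions

We observe molecules $Y_1,\dots,Y_n$ (genes, proteins) across conditions
$c$, replicates $r$ and times $t$, together with perturbation signals
$x_c(t)$ (0/1 by default, quantitative if known). Perturbations are
modelled as *soft interventions*: each perturbation is an extra network
node with weighted edges into its (possibly unknown) targets, shifting
rather than overriding their regulation. The dynamics are a coupled
sigmoidal ODE system,

$$\frac{d y_i}{dt} = \beta_i \, g\!\Big(\sum_{p \neq i} w_{pi}\, z_p(t)\Big)
  - \alpha_i \, y_i(t), \qquad g(u) = \frac{1}{1 + e^{-u}},$$

with $z$ the joint state of molecules and perturbation signals,
$\alpha_i$ a decay rate (1/time) and $\beta_i$ a production scale
(concentration/time). The weight matrix $W$ is $(n+m)\times(n+m)$, indexed
source $\times$ target; the diagonal and all columns of perturbation nodes
are structural zeros (self-regulation lives in $\alpha_i$; nothing
regulates a perturbation).

A forward-Euler discretization over the measured (possibly irregular) grid
gives

$$y_i(t+1) = \Delta_t \beta_i\, g(u_i(t)) + y_i(t)\,[1 - \alpha_i \Delta_t],$$

which is a dynamic Bayesian network whose inter-slice weights are tied
across time: the network structure is assumed constant over the
experiment. Under steady-state conditions ($dy/dt = 0$) the model reduces
to $y_i = (\beta_i/\alpha_i)\, g(u_i)$ and each experiment contributes one
observation row instead of a chain of transitions.

Measurement noise is Gaussian per molecule with unknown variance
$\sigma_i^2 \sim \mathrm{IG}(a, b)$; marginalizing $\sigma_i^2$ yields a
Student-t observation density with $2a$ degrees of freedom
(`student_t_marginal_density()`). Replicate counts in this field are small,
so a heavy-tailed marginal is more honest than a plug-in variance. We
default to $a = 1$, $b = 0.1$ — weakly informative at concentration scales
of order one — and expose both in the configuration.

## From ODE to per-node sparse regression

The raw sigmoid inside a Bayesian message-passing scheme is numerically
hostile, so inference uses the standard bounded piecewise-linear surrogate:
$g$ is replaced by the identity clamped to the minimally and maximally
*measured* concentrations of the molecule in that replicate and condition
(`clipped_response()`, bounds from `compute_clip_bounds()`, never from
model output). In the linear regime the product $\Delta_t \beta_i w_{pi}$
is not separately identifiable, so each node is fit in the
*effective-weight* parameterization

$$y_i(t+1) = \sum_p \tilde w_{pi}\, z_p(t)\,\Delta_t + d_i\, y_i(t)
  + c_i\, \Delta_t + \varepsilon,$$

with $\tilde w = \beta w$ absorbed, $d_i = 1 - \alpha_i \Delta_t$ the
decay coefficient (Gaussian prior $N(1, 1)$: small decay leaves $d$ near
one; no positivity constraint is imposed, and $\hat\alpha_i = (1 -
\hat d_i)/\bar\Delta_t$ is reported in time-series mode), and $c_i$ an
intercept with a broad Gaussian prior. The intercept is the linearization
constant of the sigmoid about its operating point; mean-centered data
hardly need it, raw simulated concentrations do. Steady-state problems
drop the decay column and $\Delta_t$.

Candidate parents of node $i$ are all other molecules plus all
perturbation nodes; when perturbation targets are known, only the mapped
perturbations remain and their prior inclusion probability rises to 0.99
(capped below one so the spike component stays defined).

## Spike-and-slab prior and expectation propagation

Each candidate weight carries
$w \sim \gamma\, N(0, \sigma_1^2) + (1-\gamma)\, N(0, \sigma_2^2)$,
$\gamma \sim \mathrm{Bernoulli}(\rho)$, with slab variance
$\sigma_1^2 = 10$ (large enough for low-bias estimates of present edges)
and spike variance $\sigma_2^2 = 10^{-4}$: the theoretical spike is a
delta at zero, but an exact delta breaks the message-passing numerics, and
$10^{-4}$ keeps spiked weights below noise scale. Default
$\rho = 0.1$ for molecule edges and $0.5$ for perturbation edges with
unknown targets; prior knowledge overwrites individual entries
(`set_prior_edges()`).

Expectation Propagation approximates each non-Gaussian factor by a
Gaussian site, iteratively re-estimating every site against its cavity
(the posterior with that site removed) by moment matching. Two regimes are
implemented:

* **Gaussian-limit mode (default).** A per-node noise variance is fixed by
  method of moments from differenced series — for a smooth signal the
  variance of second differences is $6\sigma^2$ (first differences, factor
  2, when a series is too short; for steady-state data, where no
  differences exist, a fixed quarter of the cross-experiment variance).
  The noise estimate is always taken on the *raw* series, before any
  spline upsampling, because interpolation manufactures smoothness. The
  likelihood is then exactly Gaussian, so EP iterates only over the $p$
  spike-and-slab prior sites, each updated in closed form
  (`spike_slab_site_moments()`): the tilted distribution is a
  two-component Gaussian mixture whose moments and slab responsibility —
  the updated inclusion probability — are analytic. This path is
  deterministic and fast.
* **Student-t mode** (`noise.mode = "student_t"`). The full marginal
  likelihood is kept: each observation row gets its own Gaussian site on
  the scalar projection $u = x_{\text{row}} \cdot w$, refined by
  one-dimensional quadrature of the tilted density
  (`likelihood_site_update()`); in clipped mode the projection is clamped
  to the row's measurement bounds inside the quadrature. Prior sites are
  refreshed after each full data sweep.

Numerical policy: sites are damped (factor 0.8, i.e. 80% of the new
parameters), tilted variances floored at $10^{-10}$, and every rank-one
covariance update is step-halved until positive definiteness is preserved;
a site whose update cannot be made safe (or whose quadrature returns
non-finite moments) is skipped for that sweep rather than aborting — EP
has no convergence guarantee outside log-concave factors, and
spike-and-slab sites are not log-concave. Convergence is declared when the
maximum absolute change of posterior means and inclusion probabilities in
a sweep falls below $10^{-4}$ (common EP practice; the paper trail for
this class of solvers typically runs 20–100 sweeps, our default is 20). A
node whose solve fails entirely is flagged and reports its prior — a run
never dies because one node is ill-conditioned. Nodes are solved
independently, so `jobs = k` parallelizes with bit-identical results.

`enumerate_spike_slab()` is the package's exact small-$p$ reference: for
$p \le 15$ candidate regressors it enumerates all $2^p$ inclusion
configurations with closed-form Gaussian evidences. It shares no code with
the EP path and is what the test suite compares EP against (inclusion
probabilities within $\pm 0.05$, means within 10% or 0.05 absolute, across
randomized instances).

## Preprocessing

`fit_spline()` maps each measured series into cubic B-spline space, either
interpolating (natural cubic, knots at the data points — fits pass through
every observation) or smoothing (`smooth.spline`, smoothing parameter by
generalized cross-validation unless overridden), optionally on the log
scale; series containing non-positive values (mean-centered data do) get a
recorded offset $10^{-6} + |\min|$ that is inverted on evaluation.
`resample_series()` evaluates the fit on a denser uniform grid —
upsampling only, and never outside the observed time range. Perturbation
signals are design variables, not measurements, and are carried onto the
new grid by zero-order hold. Both the regression targets and the regressor
values are taken from the same resampled grid (the natural reading of the
tied-weight DBN); mean-centering (`mean_center()`, the normalization used
for signalling-array data) precedes any splining, and log-scale splining
is opt-in.

## What the simulator emulates — and what it does not

`simulate_benchmark()` replaces an external benchmark generator at desk
scale. Choices, fixed once:

* **Topology**: directed Erdős–Rényi with edge probability
  $d/(n-1)$ for mean in-degree $d$ (default 2, sparse like curated
  regulatory networks); weights uniform in $\pm[0.5, 2]$, equal sign
  probability; $\alpha \sim U(0.2, 0.8)$ (so $\alpha \Delta_t < 1$ on the
  default unit grid), $\beta \sim U(0.5, 1.5)$.
* **Perturbations**: a random 20% of molecules each get a dedicated
  perturbation node with one inhibitory edge of magnitude 2; each
  perturbation is active (signal 1) in its own condition only, so the
  dataset has one condition per perturbation. On–off timing (active on
  $[0, t_{\text{off}})$) is available for challenge-style designs.
* **Initial conditions**: the unperturbed steady state (found by damped
  fixed-point iteration to residual $10^{-10}$), plus a per-replicate
  Gaussian displacement of relative scale 0.3. The displacement emulates
  replicate-to-replicate variability in the starting state, as in
  multifactorial designs where each repeat perturbs the system
  differently; a system observed exactly at equilibrium would yield flat
  series in which no method could find anything.
* **Noise**: i.i.d. Gaussian per observation, default 5% of each
  molecule's noise-free dynamic range.
* **Integration**: fixed-substep Euler, 10 substeps per output interval by
  default; `substeps = 1` makes the simulator coincide exactly with the
  inference-side discretization, which the oracle tests exploit.
* **Steady-state designs**: one experiment per molecule; knockout clamps
  the target to zero (a perfect intervention), knockdown halves its
  production, multifactorial rescales the production of a random ~25%
  subset by $U(0.25, 1.75)$. Knockout/knockdown datasets carry known
  perturbation nodes; multifactorial targets stay unknown.

What it does **not** emulate: realistic degree distributions (hubs,
motifs) of curated transcriptional networks; transcription/translation
two-stage kinetics; intrinsic molecular noise; correlated measurement
error. Passing the recovery tests therefore shows the solver inverts its
own model class under realistic noise and sample sizes — it does not
certify performance on any particular organism's data, where model
mismatch dominates.

## Evaluation conventions

Edges are ranked by posterior inclusion probability. AUROC is the
rank-based Mann–Whitney statistic with ties counting one half; AUPR uses
the average-precision (step) convention with tied scores processed as one
block — trapezoidal PR interpolation is biased and deliberately avoided.
Self-edges and edges into perturbation nodes are never evaluable;
perturbation-to-molecule edges are excluded by default (gold standards
cover molecule–molecule structure) and includable by flag for
known-vs-unknown-target comparisons. Pairs missing from a submitted
ranking score zero.

## Problem sizes used by the tests

The suite exercises the full benchmark protocol at the sizes the claims
are stated for: the perturbation-benefit comparison runs five 100-node
networks (10 time points, 3 replicates per condition, targets hidden)
against their observational twins; structure recovery uses a 10-node
network with 15 time points and 5 replicates; the spline comparison five
100-node, 7-time-point observational datasets upsampled to 20 points; the
prior-knowledge sweep five 20-node perturbed datasets at 0/25/50% injected
true edges. Everything completes in a few minutes on one CPU; the EP inner
loop is $O(P^2)$ per site update thanks to rank-one covariance updates.

## Known limitations and open choices

* $\beta$ and $w$ are only identified up to their product in the linear
  regime; we report effective weights and recover only $\alpha$.
* Whether the original formulation placed $\beta$ inside or outside the
  discretized production term is ambiguous; the two readings are
  algebraically identical and we fix $\mu = \Delta_t \beta g(u) + y(1 -
  \alpha\Delta_t)$.
* Inclusion probabilities are used as confidences; weight-based scores
  (e.g. $|\hat w|/\mathrm{sd}$) are a reasonable alternative we did not
  adopt, as the inclusion probability is the natural Bayesian quantity.
* The noise hyperparameters may in principle be per molecule; we support
  both but default to global values.
* EP is a deterministic approximation: on strongly multimodal posteriors
  (near-collinear regulators) inclusion probabilities can be over- or
  under-confident relative to the exact enumeration, which is only
  feasible for small parent sets.
* Missing values are dropped from the likelihood, not imputed; a node
  needs at least two usable transition rows.
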