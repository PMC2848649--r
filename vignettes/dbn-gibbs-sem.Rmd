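---
title: "Dynamic Bayesian networks with Gibbs sampling and stochastic EM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic Bayesian networks with Gibbs sampling and stochastic EM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gibbsdbn)
```

## The model class

A dynamic Bayesian network (DBN) describes a sequence of positions, each
carrying the same set of random variables (a *slice*).  The slice is an
ordinary Bayesian network; *intra-slice* edges connect variables within a
position, *inter-slice* edges connect a variable at position $t$ to one at
$t+1$.  Parameters are tied across positions, so a model specified on one
slice scores and generates sequences of any length.  The hidden Markov
model is the smallest example: a hidden discrete chain with one observed
child per slice.

`gibbsdbn` supports discrete (categorical), multinomial, Poisson,
univariate and multivariate Gaussian, univariate and bivariate von Mises,
and Kent (FB5) nodes.  Every parent must be discrete; the parent states
select which parameter component of the child applies, so a discrete
parent over a continuous child yields a mixture, and a hidden discrete
chain over angular children yields the kind of model used for protein and
RNA backbone geometry, where torsion-angle pairs live on the torus and
unit vectors on the sphere.

Two modelling conventions are worth stating explicitly:

* **Hidden values are discrete.**  Only discrete nodes may be flagged
  hidden.  The Gibbs conditional of a hidden entry is then a finite
  enumeration over its states, which keeps inference exact per site.  The
  models this package targets all have discrete latent chains.
* **Initial slices get their own parameter set.**  A node with inter
  parents cannot use the tied conditional at position 1 (its inter parent
  does not exist there).  Each such node owns a second parameter set over
  its intra parents only — for an HMM hidden chain this is simply the
  initial state distribution — estimated jointly with everything else
  during EM.  This is the simplest parameterization that makes the
  unrolled network well defined.

Angles are radians in $[0, 2\pi)$ throughout; observed unit vectors are
renormalized when within $10^{-6}$ of unit norm and rejected otherwise.
Conditional probability tables (CPTs) are stored in run-time-dimensioned
arrays (`mdarray`) in row-major order with the node's own states on the
last axis: a node of size 2 with parents of sizes 3 and 4 has a
$3 \times 4 \times 2$ CPT.

## Directional node families

The **Kent (FB5) distribution** on the unit sphere has density

$$f(\mathbf x) = \frac{1}{C(\kappa, \beta)}
  \exp\{\kappa\,\boldsymbol\gamma_1\!\cdot\!\mathbf x +
        \beta[(\boldsymbol\gamma_2\!\cdot\!\mathbf x)^2 -
              (\boldsymbol\gamma_3\!\cdot\!\mathbf x)^2]\},$$

with concentration $\kappa > 0$, ellipticity $0 \le 2\beta < \kappa$
(unimodal regime) and orthonormal axes $\gamma_1$ (mean direction),
$\gamma_2, \gamma_3$ (major/minor contour axes).  At $\beta = 0$ it is the
von Mises–Fisher distribution.  The normalizer is computed two ways: an
exact series $C = 2\pi\sum_j \frac{\Gamma(j+\frac12)}{\Gamma(j+1)}
\beta^{2j} (\kappa/2)^{-2j-\frac12} I_{2j+\frac12}(\kappa)$ (the default),
and the large-$\kappa$ closed form $2\pi e^\kappa[(\kappa-2\beta)
(\kappa+2\beta)]^{-1/2}$, which agrees with the series to about 1% on the
log scale for $\kappa \ge 50$ and is available where speed matters.

The **bivariate von Mises (cosine variant)** on the torus has density

$$f(\phi, \psi) \propto \exp\{\kappa_1\cos(\phi-\mu) +
  \kappa_2\cos(\psi-\nu) - \kappa_3\cos(\phi-\mu-\psi+\nu)\},$$

where $\kappa_3$ couples the two angles; with the minus-sign convention
used here a positive $\kappa_3$ induces *negative* circular correlation
(the convention matches the reference samples this package reproduces:
$\kappa_1=\kappa_2=100, \kappa_3=49$ yields strongly negatively correlated
angle pairs).  Unimodality requires $\kappa_1 > |\kappa_3|$ and
$\kappa_2 > |\kappa_3|$.  The normalizer again has two routes: the exact
one-dimensional reduction $C = \int_0^{2\pi} e^{\kappa_2\cos\alpha}\,
2\pi I_0\!\big(\sqrt{\kappa_1^2+\kappa_3^2-2\kappa_1\kappa_3\cos\alpha}
\big)\,d\alpha$ evaluated by the periodic trapezoid rule (spectrally
accurate; the default and the authority), and a Bessel-product series.
The alternating series cancels catastrophically at strong coupling (for
example $\kappa_1=\kappa_2=100, \kappa_3=49$ it loses all significant
digits); this is detected from the ratio of the signed sum to the sum of
magnitudes, and the quadrature value is returned with a warning.

### Numerical choices for the directional samplers and estimators

* **Kent sampling** uses the exact marginal–conditional decomposition in
  the frame of the axes: the colatitude variable $u = 1-\cos\theta$ has
  marginal $\propto e^{-\kappa u} I_0(\beta u(2-u))$, inverted on a
  4096-point grid placed at the quantiles of an exponential with rate
  $\kappa - 2\beta$ — the *actual* small-$u$ scale, since
  $I_0(x) \sim e^x$; a grid placed by $\kappa$ alone collapses at strong
  ellipticity and visibly biases samples (this failure mode is covered by
  a moment-matching test against quadrature).  Given the colatitude, the
  longitude density $\propto e^{\beta\sin^2\theta\cos 2\phi}$ is a von
  Mises in $2\phi$, drawn exactly by envelope rejection plus a random
  half-turn.  The same grid-inversion pattern samples the bivariate von
  Mises: $\psi$ from its exact 1-D marginal on a 4096-point grid, then
  $\phi$ from the exact von Mises conditional with
  $\kappa_c = \sqrt{a^2+b^2}$, $a = \kappa_1-\kappa_3\cos(\psi-\nu)$,
  $b = -\kappa_3\sin(\psi-\nu)$.  Grid inversion was preferred over
  rejection for the joint samplers because it is deterministic for a
  given RNG stream, vectorizes, and its only error (linear interpolation
  of a smooth CDF on 4096 points) is far below the statistical noise of
  any downstream use.
* **Kent estimation** starts from the classical moment estimators — mean
  direction, tangent-plane scatter eigenstructure, and
  $\hat\kappa = (2-2\bar R-r_2)^{-1} + (2-2\bar R+r_2)^{-1}$,
  $\hat\beta = \frac12[(2-2\bar R-r_2)^{-1} - (2-2\bar R+r_2)^{-1}]$ —
  and then refines $(\kappa, \beta)$ by maximizing the exact
  log-likelihood with the axes fixed.  The refinement matters: at
  $(\kappa, \beta) = (1000, 499)$ the moment estimators are roughly 10%
  biased, while the refined estimates recover the truth to a few percent
  at $n = 5000$.  Constraints are kept by smooth reparameterization,
  $\beta = 0.4995\,\kappa\,(1+\tanh t)/2$; the clip sits at 0.999 of the
  unimodality bound because reference parameter sets of practical
  interest lie as close as $\beta/\kappa = 0.499$.
* **Bivariate von Mises estimation** takes $\hat\mu, \hat\nu$ from the
  circular means and maximizes the exact likelihood in
  $(\kappa_1, \kappa_2, \kappa_3)$ — the model is a 3-parameter
  exponential family given the means, so only three aligned trig moments
  enter — from an `A1inv` moment start, with
  $\kappa_3 = 0.95\min(\kappa_1,\kappa_2)\tanh t$ keeping the unimodal
  regime.
* **von Mises** concentration uses the standard three-regime rational
  inverse of the mean resultant length; $\bar R \ge 1-10^{-12}$ caps
  $\hat\kappa$ at $10^4$ with a warning.

## Inference

Hidden entries are resampled by **systematic-scan Gibbs sampling**:
slices in order, nodes in slice order, each hidden entry drawn from
$p(h \mid \text{blanket}) \propto p(h \mid \text{parents})
\prod_c p(x_c \mid \text{parents}_c)$ normalized over the node's states in
log space.  Work per entry is proportional to the state count, so one
sweep costs $O(l \times s)$ resample operations per hidden chain ($l$
total slices, $s$ states); the operation count is exposed as an attribute
and tested, not timed.  Two implementation choices:

* At each (slice, node) site the resampling is vectorized across
  sequences.  Sequences are independent chains, so this is just a
  particular valid ordering of the same systematic scan, and it makes the
  sweep a handful of matrix-indexing operations per site instead of a
  per-entry loop.  All randomness flows through R's global RNG; the
  per-iteration draw pattern is a deterministic function of the seed, and
  the RNG state is captured in the training state for exact resumption.
* Non-discrete children cannot change within a sweep (they are always
  observed), so their log-densities under every parent configuration are
  precomputed once per sweep and the inner loop only gathers.

The chain is initialized by ancestral sampling from the current model
(each hidden entry from $p(h \mid \text{parents})$ in scan order), which
starts the sampler in a feasible region; a uniform initialization would
also be valid but mixes from a worse region.

Two likelihood monitors are provided.  The **completed-data
log-likelihood** $\log P(D \mid H, \theta)$ scores the data jointly with
the current hidden assignment — defined for every topology.  The
**forward log-likelihood** $\log P(D \mid \theta)$ sums over all hidden
paths by the scaled forward recursion and is exact, but only defined for
HMM-shaped models (one hidden discrete chain with a self inter edge and
observed intra-slice children); any other topology is refused.  A
forward–backward smoother exists only inside the test suite, as the
oracle the Gibbs marginals are checked against (total variation below
0.02 at $5\times10^4$ sweeps on the 2-state reference model).

## Learning

Both EM flavours share one mechanism: a completed dataset is reduced to
per-node, per-parameter-set sufficient statistics (CPT counts, Gaussian
moment sums, circular resultants, the bivariate von Mises trig moments,
Kent mean vector and scatter), and the M-step re-estimates every family
from statistics alone.

* **S-EM**: one Gibbs sweep per iteration completes the data; `burn_in`
  extra sweeps (default 10) precede the first iteration only.
* **MC-EM**: `mcem_samples` sweeps per iteration; the statistics of the
  $m$ completions are averaged before the M-step.  With a large $m$ this
  approaches deterministic EM, which the tests verify against an exact
  expected-counts implementation on a small HMM.

M-step defaults: CPT/multinomial pseudocount 0.05 per cell (zero entries
would make hidden states permanently unreachable for the Gibbs chain);
Gaussian covariance ridge $10^{-6}$, with a pooled-covariance fallback for
parent configurations holding fewer than $d+1$ points; configurations
with no observations keep their previous parameters.

S-EM produces a parameter *sequence* that fluctuates around the plateau
rather than converging pointwise.  The reported estimate is therefore,
by default, a re-estimate from the sufficient statistics averaged over
the last `avg_window` (20) iterations — averaging statistics rather than
parameters keeps every family's constraints intact by construction — with
the last iterate available as an alternative.  Early stopping compares
the mean completed log-likelihood of the last `window` (10) iterations
against the previous window at a relative tolerance of 0.01; setting the
tolerance to 0 runs the full schedule.

**Restarts.**  The likelihood surface of a hidden-chain model is
multimodal (state merge/split optima), and no EM variant escapes a wrong
basin reliably — this was cross-checked against an independent
Baum–Welch implementation, which strands in local optima on the same
data.  `n_starts` runs the full schedule from several random
initializations and keeps the run with the best final-window completed
log-likelihood; the basins are typically separated by hundreds of
log-units, so selection is unambiguous.

## Synthetic benchmarks and what they do (not) show

`generate_benchmark()` builds three reference architectures, each 200
sequences of 50 slices by default:

* `discrete_hmm` — 5-state hidden chain, 5-symbol discrete output;
* `gaussian_hmm` — 10-state hidden chain, 4-dimensional Gaussian output;
* `complex` — two hidden chains H (5 states) and I (3 states), H
  parenting a 4-dimensional Gaussian node G and I a bivariate von Mises
  node V.

True parameters are drawn diffusely: CPT rows from a flat Dirichlet,
Gaussian means standard normal with random-rotation covariances
(eigenvalues uniform on $[0.25, 1]$), von Mises means uniform with
$\kappa_{1,2} \sim U(5, 50)$ and $\kappa_3$ uniform within half the
unimodality bound, Kent axes from random rotations with
$\kappa \sim U(20, 200)$ and $\beta$ up to $0.4\,\kappa/2$.  Sequences
are sampled ancestrally and every hidden-node entry is masked.

A flat-Dirichlet truth is the right stress test for *numerical* behaviour
(the training invariants: finite likelihoods, parameters staying in their
legal domains, a non-decreasing smoothed likelihood trend) but is often
nearly unidentifiable: different parameter configurations fit such data
almost equally well, so no estimator — exact EM included — can promise
entry-wise CPT recovery on it.  Parameter-recovery claims therefore use
`reference_hmm()`, a designed, strongly identified 5-state model (cyclic
transitions 0.7/0.2, 0.95-diagonal emissions) on which the
maximum-likelihood error per CPT entry at 10,000 slices is comfortably
below the 0.05 acceptance band.  The same logic applies to real data:
passing these tests shows the machinery is correct, not that any
particular real dataset is informative enough to pin down its
parameters.

The S-EM completed-likelihood trace rises steeply and then fluctuates
around a stationary plateau.  "Non-decreasing after smoothing" is
operationalized as: the window-10 smoothed trace shows no net decrease
over the run and no statistically significant downward slope — strict
monotonicity is not a property S-EM possesses, since plateau noise on a
weakly identified benchmark can exceed the net rise.

Problem sizes throughout the test suite (sequence counts, sweep counts,
Monte Carlo sizes) are chosen so each tolerance sits several standard
errors from its threshold at the stated seed — e.g. $10^5$ draws for
0.01-level frequency checks, $5\times10^4$ sweeps for total-variation
0.02, $n = 5000$–$10^4$ for the 10–15% directional recovery bands.

## Serialization and the command line

Training states (parameters, hidden assignment, statistics window,
likelihood trace, RNG state, config) serialize to a versioned JSON text
file.  Doubles are written as `%.17g` strings because JSON numbers
round-trip through the JSON library with only 15 significant digits —
with exact doubles and the saved RNG state, `load_state()` +
`train(resume =)` reproduces an uninterrupted run bit for bit, which the
tests assert.  Sequence data and DBN specifications use small
tab-separated text formats with `?` marking hidden entries and 0-based
node indices in edge lines; both round-trip exactly.

The `exec/gibbsdbn` script exposes `benchmark`, `train`, `sample` and
`loglik` subcommands over these files; it is a thin wrapper over
`cli_main()`, which returns exit status 2 for usage errors and 1 for
runtime failures.

## Known limitations

* Hidden nodes must be discrete; continuous latent variables are out of
  scope.
* Inter edges connect adjacent slices only; no longer-range temporal
  edges.
* Parents must be discrete — there is no conditional linear Gaussian
  regression on continuous parents.
* The bivariate von Mises is the cosine variant only; the Fisher–Bingham
  family beyond FB5 and the sine variant are not implemented.
* The forward algorithm (and hence the exact likelihood monitor) applies
  only to HMM-shaped topologies; for everything else the completed-data
  likelihood is the monitor.
* Multinomial trial counts are per observation, not a parameter; the
  ancestral sampler uses a caller-supplied count.
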