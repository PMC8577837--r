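---
title: "Conditional mixtures of spike counts: models, fitting, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional mixtures of spike counts: models, fitting, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condmix)
```

## The model family

`condmix` models a population of $d_N$ neurons' spike counts
$\mathbf n = (n_1, \dots, n_{d_N})$ in response to a stimulus $x$ as a
finite mixture with a latent component index $k \in \{1, \dots, d_K\}$,
written in exponential-family natural coordinates:

$$
p(\mathbf n, k \mid x) \propto \exp\!\big(
\theta_N(x) \cdot \mathbf n + \theta_N^* \cdot \mathrm{lf}(\mathbf n)
+ \theta_K \cdot \delta(k) + \mathbf n \cdot \Theta_{NK} \cdot \delta(k)
\big),
$$

with $\mathrm{lf}(\mathbf n)$ the vector of log-factorials and $\delta(k)$
the indicator of components $2..d_K$. Every component is a product of
independent Conway–Maxwell (CoM) Poisson distributions; with
$\theta_N^* = -1$ each component is an independent-Poisson (IP) product and
the whole model is an IP mixture. The parameters play distinct roles:

* $\theta_N(x)$ — baseline log-rate parameters; the only
  stimulus-dependent block in *minimal* models.
* $\Theta_{NK}$ ($d_N \times (d_K - 1)$, components indexed by columns;
  component $k > 1$ adds column $k-1$) — per-component log-gains on the
  baseline. Mixing gain-modulated copies of one tuned population is what
  produces stimulus-dependent noise correlations.
* $\theta_K$ — biases on the component probabilities.
* $\theta_N^*$ (CB family only, shared by all components) — dispersion
  parameters. A single CoM-Poisson neuron is under-dispersed when its entry
  is $< -1$ and over-dispersed when in $(-1, 0)$; the family constraint is
  $\theta_N^* < 0$, which makes the (truncated) series normalizer converge.

Although components are independent products, a $d_K$-component mixture
with uniform weights reproduces *any* sample covariance of its component
rate vectors, so the family is not restricted to weak or positive
correlations. IP mixtures couple means and variances (Fano factors are
always $\ge 1$); the CB dispersion block breaks that coupling.

### Stimulus maps

* **von Mises**: $\theta_N(x) = \theta_{N0} + \Theta_{NX}\,(\cos 2x, \sin
  2x)$. Orientations are degrees with a 180° period at every interface;
  angles are doubled and converted to radians internally.
* **discrete**: $\theta_N(x) = \theta_{N0} + \Theta_{NX}\,\delta(x)$ over
  an ordered set of condition labels; the first level is the baseline.
  Levels are ordered numerically for numeric labels and lexically
  otherwise, so condition indexing is reproducible across runs.
* **maximal**: an independent full mixture per condition, fit separately
  per condition.

Minimal models (the first two) share $\theta_K$, $\Theta_{NK}$,
$\theta_N^*$ across stimuli. That restriction is a feature, not a
convenience: it makes the log-likelihood gradient in $x$ depend on the data
only through $\mathbf n$ itself, giving the closed-form Fisher information

$$
I(x) = \partial_x \theta_N(x) \cdot \Sigma(x) \cdot \partial_x \theta_N(x)
     = \partial_x \mu(x) \cdot \Sigma(x)^{-1} \cdot \partial_x \mu(x),
$$

(the second form is the linear Fisher information, used in the test suite
as an independent cross-check rather than as the implementation), and it
puts $p(\mathbf n \mid x)$ in the exponential family with linear sufficient
statistics: $\log p(\mathbf n \mid x) - \theta_N(x)\cdot\mathbf n$ plus the
log-partition is constant in $x$ for fixed $\mathbf n$, which is the
encoding-model form assumed by linear probabilistic population codes. Both
identities are verified as properties in the test suite.

## Numerical choices

**Series truncation.** CoM-Poisson normalizers, moments, and expected
log-factorials have no closed form and are evaluated by truncating their
series. The default cutoff is $\max(128, \lceil 10 \cdot \lambda \rceil)$
with $\lambda = \exp(\theta_n / {-\theta^*})$ the CoM location parameter —
ten times the location bounds the neglected tail mass below about
$10^{-12}$ in the count regimes the models operate in. During a fit the
cutoff is fixed at $\max(128, 10 \times \text{largest observed count})$
(capped at 1024) so that the optimized objective is a single, consistent
function; because the truncated mean parameters are the exact derivatives
of the truncated log-partition, the M-step gradients match finite
differences of the truncated objective to machine precision — a property
the suite checks at $10^{-5}$ relative for every parameter block, variant,
and family.

**Log-space accumulation.** All series and mixture sums go through
log-sum-exp; densities are returned as log-probabilities.

**Degenerate inputs.** Empirical rates of silent neurons are floored at
$0.1 / d_T$ before logs are taken, since natural parameters require
strictly positive rates. Held-out log-posteriors are floored at
$\log 10^{-12}$ before averaging, so a decoder that assigns numerically
zero probability to the truth stays finite but visibly catastrophic.

## Fitting

`fit_cm()` runs approximate expectation-maximization:

* **E-step** (exact): responsibilities are
  $\mathrm{softmax}(0,\ \theta_K + \mathbf n \cdot \Theta_{NK})$ — the
  stimulus-dependent and dispersion terms are shared across components and
  cancel.
* **M-step** (approximate): the complete log-likelihood is convex in the
  natural parameters; it is ascended for `ascent_steps` (default 100) Adam
  steps (momenta 0.9/0.999, state reset every EM iteration, full-batch
  gradients). The learning rate at EM iteration $t$ of $d_I$ interpolates
  log-linearly from 0.002 down to 0.0005.

Defaults are $d_I = 500$ EM iterations with 100 ascent steps. CB fits first
train the IP model for $0.8\,d_I$ iterations, then set $\theta_N^* = -1$ —
which leaves the density exactly unchanged — and continue with the
dispersion block free for the remaining $0.2\,d_I$; this avoids spending
truncated-series evaluations on the early, rapidly-moving phase of
training. Because the M-step is truncated at a fixed step count, EM's
monotonicity guarantee holds only approximately; the suite checks the data
log-likelihood trace never decreases by more than $10^{-6}$ per trial
across 20 seeded runs.

A single-component IP fit is an independent Poisson regression — a convex
problem solved exactly (per neuron, against the von Mises design
$(1, \cos 2x, \sin 2x)$, or in closed form for discrete maps as
per-condition mean rates). `fit_cm(dK = 1)` therefore returns that exact
solution directly rather than iterating EM on a model with no latent
structure; this also makes the information gain of the baseline
specification against itself exactly zero, as it should be.

**Initialization.** Baseline from the independent fit; component weights
from Dirichlet(2); modulations uniform in $[-10^{-4}, 10^{-4}]$ for
discrete/maximal maps. For von Mises maps the modulation columns are
initialized as $0.2 \sin(2\rho_i + 2\pi k / d_K)$ in each neuron's
preferred orientation $\rho_i = \tfrac12\mathrm{atan2}(b_i, a_i)$ (with
$(a_i, b_i)$ the neuron's tuning row — the baseline offset moves the gain,
not the peak). The per-component phase shift gives every modulation a
distinct peak over preferred orientations, which separates the components
early in training. Everything is a deterministic function of the seed.

## Decoding and model comparison

Bayesian decoding is brute-force normalization of
$p(\mathbf n \mid x)\,p(x)$ over the discrete conditions, with the prior
estimated as presentation frequencies. Model comparison uses 10-fold
cross-validation, stratified by condition (the stratification is this
package's choice; it guarantees every condition appears in every training
fold) with two metrics: the **information gain** — held-out per-trial
log-likelihood minus that of the von Mises independent-Poisson baseline
refit on the same training fold — and the **mean log-posterior** of the
true condition. Reference decoders (a multiclass linear map and a
two-hidden-layer sigmoid MLP, both emitting the $d_X - 1$ natural
parameters of a categorical distribution) train by minibatch Adam
(learning rate $3\times10^{-4}$, minibatches of 500, 80/10/10
train/test/validation split, early stopping when test performance declines
epoch-to-epoch).

## The synthetic generators

The generators are the package's data supply and define its study
conditions.

**Randomized ground-truth models** (`random_ground_truth_cm`): preferred
(doubled) angles tiled as $\rho_i = i/d_N \cdot 360°$; concentrations
$\log \kappa_i \sim N(-0.1, 0.2)$; gains $\log \gamma_i \sim N(0.2, 0.1)$;
tuning rows $(\kappa_i \cos\rho_i, \kappa_i \sin\rho_i)$ with offsets
$\log\gamma_i - \log I_0(\kappa_i)$, so baseline tuning curves are von
Mises bumps peaking at rate $\gamma_i e^{\kappa_i}/I_0(\kappa_i)$ (a few
spikes per trial — typical of short cortical count windows); modulations
$\sim N(0.2, 0.1)$; dispersion $\theta_{N,i}^* \sim U(-1.5, -0.8)$. Two
optional extras for decoding-oriented models: re-centering $\theta_K$ so
every component's peak index score shares a common ceiling over a dense
361-point grid (keeps several components active at every stimulus in large
populations), and conversion of the von Mises map to a discrete lookup
over a condition grid.

**Information-limited populations** (`info_limited_recipe`): a source
population of $d_N = 200$ (by default) conditionally independent Poisson
neurons with homogeneous von Mises tuning — identical gain and
concentration, tiled preferred orientations, the only homogeneity
consistent with exactly linear Fisher-information growth — responds to a
latent orientation $s$ drawn from a von Mises distribution centred on the
true stimulus $x$. Marginalizing over $s$ correlates the neurons and caps
the information about $x$ at the noise channel's Fisher information,
computed here by quadrature. The source gain (5) and tuning concentration
(1), and the noise scale (circular standard deviation 10°), are this
package's choices of a physiologically plausible regime: peak rates of a
few spikes and information saturating near
$1/\mathrm{var} \approx 33\ \mathrm{rad}^{-2}$.

## Problem sizes used in the checks

The test suite and acceptance script run the full pipelines at sizes a
workstation handles in minutes, chosen once as the package's standard
demonstration conditions:

* Ground-truth recovery: $d_N = 20$, $d_K = 5$ CB model, 200 trials at
  each of 10 orientations (2000 total), refit with $d_I = 100$ EM
  iterations. This reduced schedule already recovers the generating tuning
  curves with $r^2 \approx 0.996$ (the full $d_I = 500$ schedule gives
  marginally higher values); correlation matrices and Fano factors at probe
  orientations match the truth to well within 0.1.
* Information limiting: $d_N = 100$ source neurons, 10{,}000 responses
  over 10 orientations, $d_K = 20$ IP fit. The learned model's Fisher
  information saturates near the noise-channel bound (within 20% of it,
  and an order of magnitude below the source population's unbounded linear
  growth) — the saturation hovers around the bound rather than strictly
  under it, as expected of an estimate of a quantity that the bound caps
  only in the infinite-data limit.
* Properties (normalization, dual-parameterization round trips,
  CB-at-$-1$ equivalence, gradient checks, Fisher-information identities)
  run on 2–3 neuron models where exhaustive enumeration is exact.

What passing these checks shows — and what it does not: the generators
emulate stimulus-locked count statistics of the kind seen in primary
visual cortex (tuned rates, gain-type co-modulation, mild over/under
dispersion, noise correlations of order 0.01–0.3). They do not emulate
temporal dynamics within trials, non-stationarity across a session,
electrode artefacts, or neuron-specific dispersion structure beyond the
shared-$\theta_N^*$ family, so performance on real recordings must be
validated on real recordings.

## Known limitations and open choices

* The M-step is truncated gradient ascent, so likelihood traces can
  plateau slightly below the exact EM path; increasing `ascent_steps`
  trades time for tightness.
* Full-batch M-step gradients are used (no minibatching); for datasets far
  beyond $10^5$ trials a stochastic variant would be preferable.
* CB covariance matrices can be near-singular for strongly under-dispersed
  populations; the linear-Fisher-information cross-check then warns and
  the covariance form should be used.
* Component labels are not identifiable — fits match ground truth up to a
  permutation of components, which affects no downstream quantity.
* Maximal models are fit per condition and cannot share statistical
  strength across stimuli; they are the right choice only when every
  condition is data-rich.
* Dataset I/O is CSV (and JSON for models); counts above what CSV handles
  comfortably (millions of trials) are out of scope.

```{r example, eval = FALSE}
# the end-to-end recovery experiment at the sizes above
truth <- random_ground_truth_cm(random_cm_recipe(dN = 20, dK = 5,
                                                 family = "CB"), seed = 11)
dat <- simulate_cm_dataset(truth, seq(0, 162, by = 18), reps = 200, seed = 12)
fit <- fit_cm(dat$counts, stimulus = dat$stimulus, family = "CB", dK = 5,
              schedule = cm_schedule(em_iters = 100, trace_stride = 10),
              seed = 13)
plot(fit)
```
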