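---
title: "A joint phylogenetic–psychophysical model of quantity discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A joint phylogenetic–psychophysical model of quantity discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloweber)
```

## The problem

Comparative studies of the approximate number system summarize a species'
quantity-discrimination precision by its Weber fraction $w$: the
proportional difference between two quantities needed for reliable
discrimination. An animal with $w = 0.2$ can tell 10 from 12; one with
$w = 0.5$ only 10 from 15. The published record, however, consists of
binary trial outcomes — an individual animal, in one study, under one task
paradigm, judged one pair of quantities correctly or not. Species-level
$w$ is never observed directly, species differ in how many subjects and
trials they contribute, and species are not independent data points: they
are related by a phylogeny.

`phyloweber` treats all of this in one hierarchical Bayesian model. The
latent per-trial log Weber fraction is linked to binary accuracy through a
psychophysical model, species-level effects carry phylogenetic correlation
controlled by Pagel's $\lambda$, and study, subject and task effects absorb
the heterogeneity of a multi-study compilation. One species-level predictor
at a time (brain size, neuron counts or densities, socioecology, cognitive
test scores) can be regressed on the latent trait.

## The psychophysical link

Under the linear-scale scalar-variability model a quantity $n$ is
represented as a Gaussian with mean $n$ and standard deviation $wn$. Two
independent representations of $n_1$ and $n_2$ are correctly ordered with
probability

$$
P(\text{correct}) \;=\;
\Phi\!\left(\frac{|n_1-n_2|}{w\sqrt{n_1^2+n_2^2}}\right),
$$

implemented in `predict_accuracy()`. The model class fixes the structure
(linear scaling of noise with magnitude); the probit form is the closed
form of the Gaussian ordering probability, which we adopt as the link. Two
properties matter downstream: accuracy is bounded below by $1/2$ (a
two-alternative structure is assumed for all three paradigms), and it
depends on the pair only through its ratio, which is Weber's law itself.
We include no lapse/guessing parameter; paradigm-level accuracy shifts are
absorbed by the task effects.

`discrimination_bound()` gives the complementary threshold reading: the
smallest integer $m >$ reference with $(m-\mathrm{ref})/\mathrm{ref} \ge w$.

## The hierarchical model

For trial $t$ by subject $s(t)$ of species $i(t)$ in study $j(t)$ under
paradigm $k(t)$:

$$
\log w_t = \beta_0 + \beta_1 x_{i(t)} + \sigma_{sp}\,u_{i(t)}
 + \sigma_{study}\,v_{j(t)} + \sigma_{subj}\,z_{s(t)} + \sigma_{task}\,q_{k(t)},
$$

$$
\text{correct}_t \sim \mathrm{Bernoulli}\!\left(\Phi\!\left(
\frac{|n_{1t}-n_{2t}|}{w_t\sqrt{n_{1t}^2+n_{2t}^2}}\right)\right).
$$

The species effects $u$ are multivariate normal with correlation
$M = \lambda V + (1-\lambda) I$, where $V$ is the phylogenetic correlation
matrix derived from the time tree and $\lambda \in [0,1]$ is sampled
jointly with everything else; only $V$ is fixed. At $\lambda = 0$ species
are independent; at $\lambda = 1$ their correlation is fully determined by
shared ancestry. Study, subject and task effects are independent standard
normals scaled by their $\sigma$; subjects are nested in species by the
labelling convention `species/subject`. Equal-quantity trials are retained
and contribute a constant $\log \tfrac12$.

$V$ is normalized to unit diagonal — a correlation, not a covariance. For
an ultrametric tree the entry for species $i,j$ is the shared root-to-MRCA
path length divided by total depth, so tree depth divides out and
$\sigma_{sp}$ carries all the scale. Whether to mix on the correlation or
the raw time-covariance scale is a genuinely open choice; the correlation
convention makes $M$'s diagonal exactly 1 for every $\lambda$ and keeps
$\sigma_{sp}$ interpretable, so we adopt it.

### Priors

The priors are weakly informative, centred on the plausible animal range
($w$ of order 0.1–1):

| parameter | prior | rationale |
|---|---|---|
| $\beta_0$ | Normal($\log 0.5$, 1) | grand $w$ within a factor ~e² of 0.5 |
| $\beta_1$ | Normal(0, 1) | on z-scored predictors; effects comparable across runs |
| $\sigma_{sp}, \sigma_{study}, \sigma_{subj}, \sigma_{task}$ | half-Normal(1) | scales of order ≤ 1 on log w |
| $\lambda$ | Uniform(0, 1) | no prior pull toward or away from phylogenetic signal |

Predictors are z-standardized (after the log transforms described below)
inside `fit()`, so $\beta_1$ values from different predictor runs share a
scale. Each predictor is fitted in its own run; species missing that
predictor are dropped for that run only. We deliberately do not fit a
joint multi-predictor regression: with ragged missingness across species,
single-predictor runs under identical controls are the comparable unit.

### Parameterization and sampling

All random-effect blocks are non-centered. For the species block we use
the eigendecomposition $V = Q\,\mathrm{diag}(d)\,Q^\top$, so that
$M(\lambda) = Q\,\mathrm{diag}(\lambda d + 1 - \lambda)\,Q^\top$ and

$$
u = Q\,\mathrm{diag}\!\left(\sqrt{\lambda d_i + 1 - \lambda}\right) z,
\qquad z \sim \mathcal N(0, I).
$$

This gives analytic gradients in $\lambda$ (through the square roots)
without re-factorizing a matrix at every step, and keeps the geometry
funnel-free for the sampler. $\lambda$ is sampled on the logit scale and
the $\sigma$ on the log scale, with the usual Jacobians.

Sampling is by the no-U-turn sampler (multinomial variant) over an
analytic log-posterior gradient written in C++: per iteration the
trajectory doubles until the generalized U-turn criterion fires, states
are selected with multinomial weights, dual averaging adapts the step size
to a target acceptance of 0.85, and a diagonal metric is estimated in
expanding warmup windows flanked by step-size-only buffers. Iterations
whose Hamiltonian error exceeds 1000 count as divergent; `fit()` warns if
more than 10% of post-warmup transitions diverge. A single integer seed
deterministically derives every chain's seed, so identical settings give
bit-identical draws. Convergence is assessed with split-chain
rank-normalized Rhat (`rhat()`), with the conventional threshold of 1.05;
constant parameters return 1 by convention.

### Numerical choices

* Likelihood terms for trials sharing a (species, study, subject, task,
  pair, outcome) cell are collapsed to weighted rows; this is exact.
* The standardized difference $c/w$ is capped at $10^6$ inside the
  gradient: beyond that the trial probability is numerically 0/1, and the
  uncapped ratio overflows during extreme warmup excursions (such points
  are rejected as divergent anyway).
* Eigenvalues of $M$ are floored at $10^{-12}$ before the square root.
* Ultrametricity is checked at relative tolerance $10^{-6}$ on root-to-tip
  depths; published supertrees carry rounding slack, so violations warn
  (and depths are mean-normalized in $V$) rather than error.
* Ties in rank normalization use average ranks; Rhat on fewer than 2
  chains or 10 draws per chain is an error, not a number.

## Trees, PGLS and predictors

Trees are handled with `ape`: `load_tree()` parses and validates,
`graft_split()` adds calibrated sister splits (used for the robin and
dog/wolf divergences whose ages are known from calibration sources rather
than the base supertree), and `tree_to_correlation()` builds $V$.
`example_timetree()` assembles a synthetic 33-species bird/mammal tree
entirely by such grafts; it is a structural stand-in, not a published
phylogeny.

Residual brain volume is computed by phylogenetic GLS
(`pgls_residuals()`): log endocranial volume regressed on log body mass
with correlation $V$ at $\lambda = 1$. Since RBV is a pre-computed
predictor rather than part of the joint model, the standard Brownian
default is used rather than estimating a separate $\lambda$ for the
regression. Endocranial volume missing from the record is converted from
brain mass with tissue density 1.036 g cm⁻³; cortical and cerebellar
neuron numbers for primates lacking measurements come from the published
power-law scaling rules (coefficients 37,813,551.018 × mass^0.891 and
69,640,042.656 × mass^0.936). Neuron *densities* are never imputed —
density and number are decoupled in primates, so no scaling rule is
defensible and `impute_neuron_counts()` refuses. Size-like predictors
(ECV, group size, home range, day journey, neuron numbers and densities)
are natural-log transformed; percent fruit and the two cognitive scores
are not. Natural rather than base-10 log is an interpretability choice;
the base only rescales $\beta_1$. Published general-cognition scores coded
"high = poor" are negated so high means good. The cerebellar outlier
species (the elephant) is retained by default; excluding it is a data
choice the user makes on the predictor table, not a package switch.

## The synthetic-data generator

`simulate_dataset()` generates data with exactly the generative structure
the model assumes — the same additive log-$w$ composition, the same MVN
species effects under $M(\lambda)$, the same Bernoulli link — so full-loop
parameter recovery is a meaningful test of the implementation. Defaults
describe a desk-scale study: 8 species, 6 studies, 5 subjects per species,
50 trials per subject (≈2000 trials), grand $w = 0.4$, $\lambda = 0.8$,
$\sigma_{sp} = 0.4$, $\sigma_{study} = 0.2$, $\sigma_{subj} = 0.2$,
$\sigma_{task} = 0.15$, and a quantity-pair pool of 15 classic comparisons
with ratios 1.1–3, chosen so $w \in [0.1, 1]$ is identifiable from
accuracy. The `"paper33"` preset reproduces the structural footprint of a
large literature compilation — 33 species, 49 studies, 672 subjects — for
full-scale smoke tests.

What the generator does *not* emulate: species-specific procedural quirks
of individual studies, stimulus-level covariates (area, density,
presentation time), drop-out, unbalanced pair selection tied to a
species' ability, or real predictor distributions (the predictor is
standard normal by construction). Passing recovery tests therefore show
that the implementation correctly inverts its own generative model at
realistic scale — not that the model is well-specified for any particular
empirical compilation.

## Test and experiment scales

The test suite runs recovery at desk scale (8 species, ≈2000 trials) with
short chains (2 × 400 draws) and smoke-level replicate counts (3), and
simulation-based calibration at tiny scale (8 species, 192 trials, 20
replicates, coarse 4-bin rank check at α = 0.01). These sizes are chosen
as the smallest at which each property is informative; the
`analysis/04_recovery.R` driver runs the full 20-replicate version of the
recovery experiment, and the model-convergence check uses the full 4 × 1000
sampler settings.

## Known limitations

* A single $w$ per species per trial context: task-specific Weber
  fractions (e.g. a sequential-task-specific link to self-control) are
  outside this model by construction.
* $\lambda$ is weakly identified at 8 species; with few species its
  posterior moves modestly from the uniform prior, which the recovery
  tests reflect (ordering, not point recovery, is the contract).
* The probit link's tail behaviour means nearly-perfect accuracy carries
  little gradient information about $w$; pair pools concentrated at easy
  ratios will leave small $w$ poorly resolved.
* Subject effects are nested in species but not additionally in study; a
  subject tested in two studies is treated as one subject with one effect.
* Polytomies and non-binary trees must be resolved before use.
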