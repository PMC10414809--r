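---
title: "Inferring constructive plant networks: model, nulls, and dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring constructive plant networks: model, nulls, and dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(constnet)
```

## The problem

Plants shape the conditions other plants experience. A nurse shrub casts
shade, accumulates litter and moisture, and creates a microhabitat in which
subordinate species establish; other species do better in the open. The same
survey data — which species occur at which sites, across microhabitats —
therefore mix two signals: species responding to the environment (including
environments other plants construct) and species associating with or
avoiding each other once the environment is accounted for. `constnet`
separates the two with a probabilistic graphical model, screens the
resulting associations against permutation nulls, and assembles what
survives into a two-layer signed network in which microhabitats and species
are both nodes.

Everything downstream of the data is correlational: a significant negative
association between two subordinates is a *hypothesis* about competition, to
be confirmed with removal or replacement experiments, not a demonstrated
interaction. The package is explicit about this in its vocabulary ("links"
are putative) and in its design (the screening stage exists to prune, not to
prove).

## The occurrence model

Let $y_s \in \{0,1\}^S$ be the occupancy configuration of site $s$ and $x_s
\in \mathbb{R}^K$ its environmental covariates (one-hot microhabitat
indicators and/or continuous factors). The model is a pairwise Markov
network,

$$
p(y \mid x) \;\propto\; \exp\!\Big( \sum_{i}(\alpha_i \cdot x)\, y_i
  \;+\; \sum_{i<j} \beta_{ij}\, y_i y_j \Big),
$$

with $\alpha_i \in \mathbb{R}^K$ the direct effect of each factor on species
$i$ and $\beta_{ij}$ the conditional association between species $i$ and
$j$ given everything else. $\alpha_i > 0$ means the species is associated
with (thrives in) a microhabitat or responds positively to a factor;
$\alpha_i < 0$ means avoidance. $\beta_{ij} > 0$ ($< 0$) means the pair
co-occurs more (less) than their environmental responses and the remaining
species explain.

Three conventions matter for interpreting magnitudes:

* The pairwise sum runs over **unordered pairs** $i<j$ — one term and one
  link per species pair, no factor of two, no self-terms. $\beta$ is stored
  as a symmetric matrix with zero diagonal, and its entries are exactly the
  conditional log-odds contributions of one neighbour's presence.
* There is **no implicit intercept**. If you want one, include an all-ones
  covariate column (the package does this for you when `covars = NULL`).
  This keeps $\alpha$ strictly "effects of environmental factors"; with
  one-hot microhabitat columns and no intercept the per-habitat baselines
  are directly readable off $\alpha$.
* Intraspecific terms $\beta_{ii}$ do not exist in the occurrence model —
  with binary $y_i$, $y_i^2 = y_i$ and a diagonal term is not separately
  identifiable from $\alpha$. Self-regulation is a dynamics-level concept
  (the diagonal of $B$ below).

## Estimation

`mrf_fit()` exposes four estimators behind one interface.

**Exact maximum likelihood** (`method = "exact"`) enumerates all $2^S$
configurations (refused above $S = 20$; configurations are indexed with
species 1 as the least-significant bit, giving a deterministic order). The
objective is the mean per-site log-likelihood with an optional ridge penalty
on $\beta$ (default $10^{-3}$ on that per-site scale; $\alpha$ is not
penalized). Because the model is a regular exponential family, the gradient
is "observed minus expected sufficient statistics" and the Hessian is the
feature covariance under the model, both available from the same
enumeration; the fitter runs damped Newton–Raphson and declares convergence
when the penalized gradient norm falls below `tol` ($10^{-6}$). At a
converged unpenalized optimum the familiar moment-matching identities hold:
model-expected prevalences and pairwise co-occurrence frequencies equal
their empirical counterparts (this is tested, and is the sharpest
correctness check the method admits). Sites sharing a covariate row share
one partition-function evaluation, so categorical designs cost little.

**Pseudolikelihood** (`method = "pseudolikelihood"`) drops the partition
function: each species is regressed logistically on the covariates plus all
other species' occupancies, via an in-package ridge-penalized Newton solver
(neighbour coefficients penalized, covariate coefficients not). The two
directed coefficients of each pair are averaged into the symmetric
$\hat\beta_{ij}$ — averaging, not max or min, because the model's $\beta$ is
symmetric by definition and the two node-wise estimates are equally valid
estimators of it. Near-separation (a non-converged node model or a
coefficient beyond $\pm 15$) triggers a refit with ridge on all coefficients
and a warning. Pseudolikelihood is consistent, and on data within the exact
method's reach the two agree closely (tested: $r > 0.9$ at 2000 sites, gap
shrinking with $n$).

**Count models** (`method = "poisson"` / `"negbin"`) handle abundance
matrices by node-conditional log-link regressions of each species' counts on
covariates plus the *raw* counts of the other species, symmetrized the same
way; `negbin` estimates one dispersion per species. A joint Poisson MRF with
positive interaction terms is not normalizable, so these fits are reported
as conditional-association estimates, and any positive $\hat\beta$ under
`poisson` carries a warning saying exactly that. Whether a joint rather than
node-conditional treatment of abundance is preferable is left open; the
node-conditional route is the standard tractable choice.

Species observed at every site or at none carry no information about their
associations: the node-conditional methods exclude them and mark their rows
`NA` (they stay in the output), while the exact fitter keeps them under a
full ridge penalty with a warning.

## Ground-truth data: the Gibbs sampler and the nurse scenario

`gibbs_sample()` draws independent sites from the model: each site runs a
single-site Gibbs chain with conditional log-odds $\alpha_i \cdot x +
\sum_{j \ne i} \beta_{ij} y_j$, species updated in a per-site random
permutation drawn once from the seed (fixed scan order can introduce
artifacts; per-site randomization avoids them reproducibly). Defaults of 250
sweeps with a 200-sweep mixing allowance are validated by a total-variation
check: at $S = 3$ and 20 000 sites the empirical configuration distribution
sits within TV $< 0.02$ of the exact one (observed $\approx 0.006$). All
sites update in lockstep internally, so the sampler is vectorized without
changing the per-site chain.

`make_nurse_scenario()` encodes the canonical two-microhabitat system as
ground truth: covariates are one-hot `nurse` / `open` columns; `Sub1` and
`Sub2` have $\alpha_{\text{nurse}} - \alpha_{\text{open}} = +1.5$, `Sub3`
$-1.5$; and $\beta(\text{Sub1},\text{Sub2}) = -1$ (putative competition
between the two facilitated subordinates). No canonical effect magnitudes
exist for this system, so these are modelling choices, fixed at values where
recovery succeeds from roughly 500 sites (the default 250 + 250); they are
arguments, not constants. Default problem sizes throughout the package's
tests — 500–2000 sites for recovery checks, 20 000 for distributional
checks, 20 replicates for calibration rates — are chosen as the smallest
sizes at which the corresponding statistical property is comfortably
resolved.

## Null-model screening

Inferred $\beta$ values are compared to a fixed-margin permutation null
(`screen_beta()`): curveball trades (via **vegan**) preserve every site's
richness and every species' prevalence exactly, the model is refitted on
each permuted matrix, and each pair gets $z = (\hat\beta -
\text{null mean})/\text{null sd}$, a two-sided permutation p-value with the
$(b+1)/(m+1)$ correction (its floor is $1/(m+1)$), and Benjamini–Hochberg
q-values across the $S(S-1)/2$ pairs. Defaults: 199 permutations, FDR 0.05,
$5\times$ fill trades between draws.

One refinement proved necessary. With heterogeneous microhabitats, a
*global* fixed-margin null scrambles each species across habitats, so the
null's $\hat\beta$ distribution absorbs habitat-preference structure that
belongs to $\alpha$: pairs with shared or opposed habitat preferences showed
inflated false-positive rates in scenario data. When the covariates are
categorical (at most `max_strata` distinct covariate rows), permutations are
therefore **stratified**: trades stay within a microhabitat, preserving each
species' per-habitat prevalence (and still all global margins). That is what
"separating environmental structure from association" requires of the null.
With effectively continuous covariates the global null is used and q-values
for environmentally structured pairs should be read cautiously — only the
fixed-fixed margin family is implemented, a documented assumption.

Two further properties of fixed-margin nulls are worth keeping in mind when
reading screen output. First, the ensemble is negatively biased: fixing
each site's richness makes species compete for slots, so the null mean of
$\hat\beta$ sits below zero, and a near-zero pair can be "significant"
because its estimate lies *above* that negative mean. `build_network()`
therefore admits a screened link only when the sign of its weight matches
the sign of its permutation z-score — a negative link must be negative both
in its raw weight and in its departure from the null, the usual
segregation/aggregation direction logic of co-occurrence null models.
Second, when a strong true association is present, the fixed row sums carry
part of its signature into every pair's null distribution, so weak links
adjacent to strong ones deserve extra skepticism (one more reason links are
hypotheses for experiments, not conclusions).

$\alpha$ effects cannot be screened by matrix permutation (it leaves
covariates untouched); `screen_alpha()` instead permutes the covariate rows
across sites and refits, which breaks the species–environment pairing while
preserving both marginal structures.

Under a homogeneous null ($\beta = 0$, intercept-only, $S = 5$, 500 sites)
the realized false-positive pair rate at nominal FDR 0.05 is well below 0.05
— permutation-plus-BH is conservative here, which for a hypothesis-pruning
tool is the right side to err on. Power at the scenario's default effect
size ($\beta = -1$, 500 sites) is about 0.8, so single-dataset absence of a
link is weak evidence of absence.

## The constructive network

`build_network()` collates screened parameters into one multilayer object:
species and environment factors are nodes (a single graph with a node-type
attribute, which keeps cross-layer queries and export trivial), $\alpha$
links connect factors to species, $\beta$ links connect species pairs
(canonically ordered, at most one per pair). A link must pass every filter
supplied — q-value below the FDR *and* $|{\text{weight}}| \ge$
`min_weight` — because statistical significance and effect size are
different questions. Weights are the raw parameter values; signs are the
weights' signs; zero-weight links are never stored, so raising `min_weight`
can only remove links. In exports ($\texttt{GraphML}$, TSV edge list) the
$\alpha$ links are rendered factor $\to$ species: the microhabitat acts on
the plant. Where a nurse's canopy is itself the habitat, the nurse appears
as an environment node — the model's $\alpha$ is a species–environment
effect, and "under the nurse" versus "open" are the two environments.

`network_summary()` reports per-layer link counts by sign, connectance
(realized over possible links: $SK$ and $S(S-1)/2$), positive fractions and
per-species degree. Structural analyses beyond that (modularity, nestedness,
motifs) are out of scope.

## Coupled dynamics

To explore consequences of an inferred structure, the fitted parameters can
be rescaled into a generalized Lotka–Volterra system with environment
feedback:

$$
\frac{dN_i}{dt} = N_i\Big(r_i + \sum_j B_{ij} N_j\Big) + f(A_i, k)\, N_i,
\qquad
\frac{dE_k}{dt} = f(K) + f(\gamma_{ki})\, N_i .
$$

The coupling functions are left unspecified in this general form; the
package's defaults are the minimal linear choices — $f(A_i,k) = \sum_k
A_{ik} E_k$, $f(K) = K_k$ constant, $f(\gamma_{ki}) N_i = \sum_i \gamma_{ki}
N_i$ — recorded in the `dynamics_spec` so saturating alternatives (plausible
for facilitation, which often peaks at intermediate stress) can be added
without touching the integrator; they are deliberately not guessed at here.
`rescale_from_mrf()` sets $B_{ij} = c_\beta \beta_{ij}$ off-diagonal,
$B_{ii} = -s$ (self-regulation), $A = c_\alpha \alpha$. The scales
$c_\beta, c_\alpha$ and $s$ are free parameters (defaults 0.1, 0.1, 1.0):
an occurrence model carries no abundance units, so any mapping to dynamical
rates is an assumption and is documented as such. Only the signs transfer
with any authority.

Integration is fixed-step classical RK4 (`dt = 0.01` default), chosen over
adaptive solvers for bit-for-bit reproducibility; correctness is checked
against closed forms (exponential, logistic, linear environment drift, all
within $10^{-6}$ relative at `dt = 0.01`), by step-halving (endpoint shifts
$< 10^{-5}$ relative), and against an independent adaptive solver
(**deSolve**) on a coupled system. After each step, species below an
extinction threshold ($10^{-9}$) are clamped to zero — preventing the
negative-abundance excursions polynomial ODEs otherwise allow — and the
environment can be clipped to per-factor bounds (for quantities like
moisture fractions). Non-finite states truncate the trajectory and set a
`diverged` flag rather than erroring: blow-up is a legitimate, reportable
outcome of positive feedback. `equilibria()` solves the interior equilibrium
at fixed environment ($r + AE + BN^\ast = 0$) and reports feasibility and
local stability from the community Jacobian $J_{ij} = N_i^\ast B_{ij}$.

## Reproducibility and the pipeline

Every stochastic routine takes an explicit seed and restores the caller's
RNG state, so no call mutates global state. `run_pipeline()` chains fit →
screen → network → (optional) dynamics from a YAML/list configuration,
writing CSV/TSV/GraphML artifacts and a JSON manifest with seeds, per-stage
status and timings, and md5 hashes; identical configuration and seed yield
byte-identical CSV/TSV artifacts, and `resume = TRUE` skips stages whose
outputs exist. The CSV dialect is fixed (comma, UTF-8, `.` decimal,
leading `site_id` column) to avoid locale drift.

## What the synthetic tests do and do not show

All validation data come from the package's own Gibbs sampler — the model
recovering parameters from its own draws, at independent sites. Real
vegetation data violate that in known ways: spatial autocorrelation among
plots (effective sample size smaller than plot count), detection error,
abundance measured as cover classes, environmental gradients not reduced to
clean categories, and true interaction structure that is neither pairwise
nor constant across sites. Passing the recovery and calibration suites
therefore shows the machinery is correct, not that half a thousand field
plots identify a competition coefficient. The screening stage, the
conservative calibration, and the insistence that links are hypotheses are
the package's hedges against exactly that gap; independent experimental
confirmation remains the final arbiter of any link.

Known limitations, restated compactly: occurrence mode assumes binary
detection without error; the abundance variants are conditional-association
estimates, not a normalized joint model; only the fixed-fixed permutation
family is implemented; exact likelihood is capped at $S = 20$ species;
sites are exchangeable (no space, no time series); and the dynamics
rescaling is an assumption-laden bridge intended for qualitative
exploration, not forecasting.
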