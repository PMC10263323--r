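---
title: "Methods: Bayesian diet mixing and food-web topology in isoweb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian diet mixing and food-web topology in isoweb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoweb)
```

isoweb implements the quantitative core of a two-tracer stable-isotope
food-web analysis: trophic discrimination factors (TDFs), a hierarchical
Bayesian mixing model for diet proportions, mixing-polygon validation,
two-baseline trophic positions, and binary food-web topology. This
vignette records the models, the numerical choices, and the design
decisions that were genuinely open, in the order a full analysis runs.

## Trophic discrimination factors

A TDF (Δ, in ‰ per trophic step) is the systematic enrichment between a
consumer's tissue and its diet. `calc_tdf()` estimates it as the mean and
sample SD (n − 1 denominator) of the per-source differences
(consumer mean − source mean), one difference per candidate source,
equally weighted regardless of the source's sample size. This
mean-difference reading is the only one available when raw per-individual
data are not at hand; it is exact for the zone-wise contrasts we ship as
worked examples. Two consequences worth noting:

* the candidate-source set is an explicit argument, never inferred — with
  group means only, different plausible source sets give materially
  different TDFs, so the choice must be visible in the call;
* negative carbon TDFs are allowed and do occur (littoral grazers can sit
  above the consumer in δ¹³C).

`tdf_source_regression()` fits per-source TDF on source isotope value by
OLS (`lm()`). Because the difference consumer − source is an affine
function of the source value when the consumer mean is fixed, a slope near
−1 with r² ≈ 1 means the regression is recovering that identity rather
than a biological signal; the function documents this rather than hiding
it.

## The mixing model

For consumer $j$ and tracer $k \in \{\delta^{13}C, \delta^{15}N\}$:

$$y_{jk} \sim \mathrm{N}(\mu_{jk},\, s_{jk}), \qquad
\mu_{jk} = \sum_i p_{ji}\,(\mu_{S,ik} + \mu_{TDF,k}), \qquad
s_{jk}^2 = \xi_k \sum_i p_{ji}^2\,(\sigma_{S,ik}^2 + \sigma_{TDF,k}^2).$$

Global proportions follow $p \sim \mathrm{Dirichlet}(\alpha)$; consumer
proportions $p_j$ add $\mathrm{N}(0, \sigma_{re})$ deviations to the
isometric log-ratio (ILR) coordinates of $p$ and back-transform. The
multiplicative scale $\xi_k$ absorbs sampling bias and predation-process
variance beyond what propagates from source and TDF uncertainty
(`error_model = "process_only"` pins $\xi_k = 1$). There are deliberately
no covariates or grouping factors beyond the consumer random effect: the
target application is a population of adults sampled without known
structure.

**Priors.** The uniform ("generalist") prior uses $\alpha_i = 1$, so
$\sum\alpha = n$ and every source has prior mean $1/n$. The
biomass-informed prior sets $\alpha_i = b_i\,n/\sum b$ from standing
biomasses $b_i$ (mg C m⁻²): it shifts prior means toward abundant sources
while keeping the same total concentration $\sum\alpha = n$ — informative
in location, not in strength. A source with no biomass estimate can
receive the arithmetic mean of the known biomasses (`neutral_fill`), a
neutral α that avoids biasing its contribution either way. The phrasing
"α = 1 divided by the number of sources" admits a second reading,
$\alpha_i = 1/n$; that variant is selectable (`total = "one"`) but is not
the default, because $\alpha_i = 1$ is the conventional uninformative
mixing prior and is the only reading under which both prior kinds share
the same total concentration. Error-scale and random-effect priors are
wide and documented: $\xi_k \sim \mathrm{U}(0, 20)$,
$\sigma_{re} \sim \text{Half-N}(1)$.

**Sampler.** The posterior is explored by independent adaptive
random-walk Metropolis chains on unconstrained coordinates: the ILR of
$p$ ($d-1$ dims, updated jointly), each consumer's ILR deviation vector,
$\log\xi_k$, and $\log\sigma_{re}$. A Gibbs scheme or an external sampler
would also work; the RW choice keeps the package self-contained and is
simple to verify. Densities on ILR coordinates include the inverse-ILR
Jacobian $\log|J| = \sum_i \log p_i + \tfrac12\log d$ (checked against
numerical differentiation in the test suite). Proposal scales adapt
toward acceptance 0.3 (inside the 0.23–0.44 band appropriate for low- to
moderate-dimension RW) by Robbins–Monro with gain $t^{-0.6}$, and are
frozen after burn-in so the post-burn chain is a valid Markov chain.
Defaults are 3 chains, 30 000 iterations, 15 000 burn-in, thinning 10;
the seed has no default — every run must state it. Degenerate input with
a single source returns the forced posterior $p = 1$ without sampling.

**Diagnostics.** `gelman_rubin()` computes split-chain R̂ (each chain
halved, so within-chain drift also inflates the statistic); convergence
is declared below 1.1. `geweke()` compares the mean of the first 10%
window against the last 50% window, scaled by AR-fit spectral-density
variance estimates; |z| < 1.96 passes. Both are implemented in the
package and calibrated in the test suite (iid chains give R̂ < 1.05 and a
Geweke pass rate at the nominal level; separated or drifting chains are
flagged).

**Model comparison.** `compare_models()` ranks fits by PSIS-LOO (default)
or WAIC on the deviance scale, from the pointwise per-consumer
log-likelihoods stored with every fit. The PSIS smoothing fits a
generalized Pareto distribution (Zhang–Stephens empirical Bayes) to the
upper 20% tail of the importance ratios and replaces tail weights by
expected order statistics, truncated at the raw maximum; the Pareto shape
k is reported per model as a reliability diagnostic. Weights are the
Akaike-type pseudo-weights $w_m \propto \exp(-d_m/2)$ on criterion
differences — a single-column summary matching how applied comparisons
are usually tabulated. They are not stacking weights and should be read
as relative support, not posterior model probabilities.

## Mixing-polygon validation

A mixing model is only feasible for consumers inside the convex hull of
the TDF-corrected sources. `polygon_test()` draws, per iterate, each
source vertex from
$\mathrm{N}(\mu_S + \mu_{TDF},\ \sqrt{\sigma_S^2 + \sigma_{TDF}^2})$
per tracer (TDF uncertainty in quadrature; a zone-keyed TDF table is
looked up per source zone), forms the convex hull (`chull()`), and counts
consumer membership with an exact point-in-hull test (boundary counts as
inside; collinear hulls fall back to a point-on-segment test). The
"95% mixing region" criterion is operationalized as inclusion
probability ≥ 0.05 — the published convention for this test, which the
source literature applies without defining numerically. Default 1500
iterates; the Monte-Carlo standard error is ≤ 0.5/√iterates. Models
failing the test are flagged in the grid output, never dropped, since a
failed assumption is itself a result worth tabulating.

## Trophic position and food-chain length

The two-baseline formulation estimates reliance on baseline 1 from
carbon alone, $\alpha = (\delta^{13}C_{cons} - \delta^{13}C_{b2}) /
(\delta^{13}C_{b1} - \delta^{13}C_{b2})$ clipped to [0, 1], then
$TP = \lambda + (\delta^{15}N_{cons} - [\alpha\,\delta^{15}N_{b1} +
(1-\alpha)\,\delta^{15}N_{b2}])/\Delta_n$. Clipping means a consumer
isotopically outside the baseline span reduces exactly to the
single-baseline formula — the identity is tested. $\Delta_n$ is a
required argument with two natural presets (3.4 ‰, the literature
default; or a locally calculated nitrogen TDF): published food-chain
lengths in this system are not recoverable under any single stated
$\Delta_n$, so the package refuses to hide the choice behind a default.
Food-chain length is the maximum TP over the supplied top consumers.

## Topology

`compute_metrics()` works on a 0/1 adjacency matrix with predators as
columns and prey as rows. Directed connectance uses $C = L/N^2$ (not
$L/(N(N-1))$), matching the printed-table convention of the comparison
literature; cannibalistic self-links count toward L and make a node
non-basal. Species richness S is carried as node metadata and summed,
because topology nodes aggregate species. Node categories are inferred
from integer trophic levels (basal = 1, consumer = 1 + max prey level):
herbivores eat only basal nodes, omnivores eat ≥ 2 distinct prey levels
(the standard "feeds on more than one trophic level" rule, adopted
because no sharper definition is in general use), predators eat only
animal prey at one level. Cycles among non-basal nodes (where the
longest-path level is undefined) fall back to shortest-path-to-basal + 1
with a warning. Sub-network links are classified by endpoint zones:
littoral–littoral, pelagic–pelagic, or coupling.

## Synthetic data: what it emulates and what it does not

`gen_mixing_dataset()` draws consumers from exactly the generative
process the model assumes — ILR-space random effects, then Normal tracer
values with variance $\xi_k \sum_i p_{ji}^2(\sigma_S^2+\sigma_{TDF}^2)$ —
so parameter-recovery tests probe the estimator, not model mismatch.
Passing recovery therefore shows correctness of the implementation under
its own assumptions; it does not show robustness to non-Normal tissue
distributions, isotopic routing, or concentration dependence, none of
which the model represents. `gen_foodweb()` builds webs whose generating
categories are recoverable by construction (herbivores on basal prey,
omnivores spanning levels, predators on herbivores) and hits a target
connectance within the admissible link range. `gen_biomass()` draws
log-uniform biomasses over two orders of magnitude, mimicking the skew of
real benthic/zooplankton biomass spectra; the shipped
`synthetic_biomass_elsol.csv` is likewise synthetic (field biomasses for
the worked example were never published) and is labelled as such. The
packaged isotope table carries a nominal n = 3 per group because the
original group sample sizes were not published; nothing downstream uses
n.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run deliberately scaled-down
problems chosen to make Monte-Carlo error small relative to the
assertions: recovery uses 20 replicates of 30 consumers × 3 sources with
2 × 4000-iteration chains (posterior means land within ±0.04 of truth,
against a ±0.1 assertion); the 5 × 2 model grid uses 9 simulated
consumers and 2 × 1500–3000-iteration chains; polygon checks use
300–1500 iterates. Proposal scales start at 0.2; acceptance targets NaN
(zero-variance degenerate likelihoods) as rejection. Stored draws keep
the global proportions, error scales, random-effect scale and
per-consumer proportions; every stored simplex vector sums to 1 within
1e-9 by construction of the inverse ILR.

Stochastic ordering checks (e.g. that the fixture-based trout fits rank
littoral macroinvertebrates above zooplankton) are evaluated over three
fixed simulation seeds and are required to hold in a majority (≥ 2 of 3)
of them — a deliberate criterion for a property that is qualitative and
subject to Monte-Carlo variation, fixed before the checks were first run.

## Known limitations

* Two tracers only; no simplex-volume generalization of the polygon test.
* No concentration weighting, lipid normalization, or C:N-based TDF
  correction.
* The RW sampler mixes slowly for the random-effect scale at short chain
  lengths; R̂ for σ_re can exceed 1.1 when chains are cut aggressively,
  while diet proportions converge much faster. The defaults are sized so
  all parameters pass.
* Comparison weights are pseudo-weights, not stacking; with many
  near-identical models they spread support rather than concentrate it.
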