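# isoweb

Stable-isotope food-web analysis for lakes: empirical trophic discrimination
factors, Bayesian diet mixing models with uniform and biomass-informed
Dirichlet priors, mixing-polygon validation, trophic position /
food-chain-length computation, and binary food-web topology metrics — with
seeded synthetic-data generators so every stage is testable end to end.

## Who this is for

Trophic ecologists working with two-tracer stable-isotope data
(δ¹³C in ‰ vs VPDB, δ¹⁵N in ‰ vs AIR) who want a single, reproducible
pipeline from per-sample measurements to (a) the proportional contribution
of candidate diet sources to a consumer, (b) consumer trophic positions and
food-chain length, and (c) topology descriptors of the surrounding binary
food web. The worked example throughout the package is an introduced
top predator (rainbow trout, *Oncorhynchus mykiss*) feeding across the
littoral and pelagic zones of a high-mountain lake, with six candidate
sources (three oligochaetes, a gastropod, two zooplankton species).

## The model

For consumer *j* and tracer *k*, the mixing model is

    y_jk ~ Normal(mu_jk, s_jk)
    mu_jk  = sum_i p_ji (mu_S,ik + mu_TDF,k)
    s_jk^2 = xi_k * sum_i p_ji^2 (sigma_S,ik^2 + sigma_TDF,k^2)

where `p_ji` are consumer-level diet proportions obtained by perturbing the
isometric log-ratio (ILR) coordinates of the global proportions `p` with
Normal(0, σ_re) consumer random effects, `mu_TDF` / `sigma_TDF` are the
trophic discrimination factor (TDF) per tracer, and `xi_k` is a
multiplicative error scale. The prior on `p` is Dirichlet(α), either
uniform (αᵢ = 1) or biomass-informed (αᵢ = bᵢ·n/Σb, preserving the total
concentration Σα = n). The posterior is sampled by adaptive random-walk
Metropolis chains on unconstrained coordinates; convergence is checked by
split R-hat and Geweke z, and models are compared with PSIS-LOO or WAIC and
Akaike-type pseudo-weights. Model feasibility is screened by the
Monte-Carlo mixing-polygon test (consumers must fall inside the convex hull
of TDF-corrected sources with probability ≥ 0.05).

Trophic positions use the two-baseline formulation

    alpha = (δ13C_cons − δ13C_base2) / (δ13C_base1 − δ13C_base2)   (clipped to [0,1])
    TP    = λ + (δ15N_cons − [alpha·δ15N_base1 + (1−alpha)·δ15N_base2]) / Δn

and food-chain length is the maximum TP over top consumers. Topology
metrics on the 0/1 link matrix (predator columns, prey rows) include link
count L, linkage densities L/S and L/N, directed connectance C = L/N², node
categories (basal / herbivore / omnivore / predator by prey trophic
levels), and the littoral/pelagic/coupling decomposition of links.

## Worked example

```r
library(isoweb)

src  <- trout_diet_sources()                 # six-source summary table
tab  <- table1_fixture()
trout <- tab[tab$lake == "El Sol" & tab$name == "Oncorhynchus mykiss", ]

# TDF contrast between trout tissue and its pelagic sources
pel <- tab[tab$lake == "El Sol" &
           tab$name %in% c("Daphnia ambigua", "Leptodiaptomus cuauhtemoci"), ]
calc_tdf(c(d13C = -15.3, d15N = 6.63), pel)
#> # A tibble: 1 × 6
#>   name       mean_dC sd_dC mean_dN sd_dN provenance
#> 1 calculated    7.22  2.09    2.55 0.877 calculated

# fit the mixing model with the study's calculated TDF and a uniform prior
cons <- simulate_consumers(trout, n = 9, seed = 101)
fit  <- fit_mixing_model(
  mixing_model_spec(src, tdf_presets()[1, ], uniform_prior(src$name)),
  cons, chains = 2, iterations = 4000, burn = 2000, thin = 5, seed = 201)
round(diet_proportions(fit), 3)
#> Lumbriculus variegatus  Tubifex tubifex  Limnodrilus hoffmeisteri
#>                  0.309            0.144                     0.076
#> Physa sp.  Daphnia ambigua  Leptodiaptomus cuauhtemoci
#>     0.308            0.090                       0.073
```

The posterior puts roughly 80% of the diet on littoral benthic
macroinvertebrates (the oligochaetes and the gastropod) and ~20% on
pelagic zooplankton, with *L. variegatus* and *Physa* sp. as the leading
sources and *D. ambigua* ahead of *L. cuauhtemoci* among the zooplankton.
Topology metrics come straight from the link matrix or from printed
counts:

```r
web_metrics_from_counts(S = 261, N = 42, L = 99)
#> # A tibble: 1 × 7
#>       S     N     L    D1    D2    Lp      C
#> 1   261    42    99 0.379  2.36  1764 0.0561
```

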