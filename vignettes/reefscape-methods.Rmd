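---
title: "Methods: comparing genetic and species beta-diversity across seascapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing genetic and species beta-diversity across seascapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefscape)
```

## The scientific problem

Dispersal links habitat patches. In the sea, the strength of that link
depends on how the seascape is configured: where reefs sit, how far apart
they are, and what lies between them. When dispersal is limiting,
compositional dissimilarity between sites increases with distance — called
isolation by distance (IBD) for allele frequencies within a species, and
distance decay for species composition within a community. If the same
neutral process (dispersal) structures both levels, pairwise genetic
dissimilarity and pairwise species dissimilarity should covary across the
same site pairs: a positive beta species–genetic diversity correlation
(beta-SGDC).

`reefscape` implements the full comparative workflow needed to test these
predictions in two ocean basins with contrasting configurations: per-species
genetic beta-diversity from SNP genotypes, per-family species
beta-diversity from incidence tables, least-cost in-water distances, and
mixed-model regressions on stacked pairwise data. A synthetic two-basin
generator produces data with the same statistical structure, so every stage
— and the headline basin contrast itself — is testable without any
download.

## Genetic beta-diversity: the G-statistics hierarchy

For each species, diploid biallelic SNP genotypes are coded as alt-allele
dosages 0/1/2 with missing calls `NA`. Per locus, with $k$ populations,
per-population allele frequencies $p_i$ and genotyped sample sizes $n_i$,
the package uses the Nei–Chesser small-sample (unbiased) estimators with
the harmonic mean sample size $\tilde n = k / \sum_i n_i^{-1}$:

$$\hat H_S = \frac{2\tilde n}{2\tilde n - 1}\,
  \overline{2 p_i (1 - p_i)}, \qquad
  \hat H_T = 2 \bar p (1 - \bar p) + \frac{\hat H_S}{2 \tilde n k},$$

where $\bar p$ is the unweighted mean of the $p_i$. Multi-locus statistics
form ratios of across-locus *averages* of $\hat H_S$ and $\hat H_T$ (a
ratio of averages, not an average of per-locus ratios, which is the
convention of the standard population-genetics implementations this mirrors
and is much better behaved at weakly polymorphic loci):

$$G_{ST} = \frac{H_T - H_S}{H_T}, \qquad
  G'_{ST} = \frac{G_{ST}(k - 1 + H_S)}{(k-1)(1 - H_S)}, \qquad
  G''_{ST} = \frac{k (H_T - H_S)}{(k H_T - H_S)(1 - H_S)}.$$

$G'_{ST}$ is Hedrick's standardization by the maximum attainable value;
$G''_{ST}$ (Meirmans–Hedrick) adds the small-$k$ bias correction and is the
pairwise and overall metric used throughout. Three numerical conventions
matter:

* **Negative estimates are kept.** Unbiased estimators legitimately go
  slightly negative for samples from one panmictic population; clamping at
  zero would bias every downstream regression. The pipeline preserves them.
* **Monomorphic data are flagged, not zeroed.** If $H_T = 0$ over all loci
  the statistic is undefined and reported as such.
* **Pair-local locus sets.** For pairwise values, loci with all calls
  missing in either member of the pair are dropped for that pair only, so
  different pairs may rest on slightly different locus subsets within one
  resampling iteration.

### Filtering and resampling

The filter chain runs in a fixed, documented order with denominators
recomputed after each step: (1) individuals with more than 50 % missing
calls are removed; (2) SNPs with more than 20 % missing data within any
sampling site are removed; (3) SNPs with more than 5 % missing data overall
are removed; (4) one SNP per RAD locus tag is kept (the lowest position,
ties broken by record order). The source workflows this mirrors list the
rules without an order; individuals-first is the conventional choice and is
frozen here so results are reproducible. Filtering is idempotent, and a
species is eligible for a basin only with at least 3 genotyped individuals
at every site.

Because species differ in locus counts and sampling effort, derived metrics
are computed on repeated random subsamples: each iteration draws a fixed
number of loci (the minimum across species; 2852 in the motivating
two-ocean dataset) without replacement and caps each site at 10 individuals,
then the pairwise matrices are averaged across iterations (999 by
convention), with cellwise standard deviations retained as a stability
diagnostic. Seeding is two-level: one master seed, with iteration $i$
running on a derived stream seed, so any single iteration can be reproduced
in isolation. Whether "overall" statistics are averaged per iteration and
then across iterations, or computed once on aggregated matrices, is not
fixed by convention; the pipeline aggregates per iteration and then takes
the mean, and both orders are available through the API.

## Species beta-diversity: the Baselga partition of Jaccard dissimilarity

Per family, with $a$ species shared by two sites and $b$, $c$ exclusive to
each:

$$\beta_{jac} = \frac{b+c}{a+b+c}, \qquad
  \beta_{jtu} = \frac{2\min(b,c)}{a + 2\min(b,c)}, \qquad
  \beta_{jne} = \beta_{jac} - \beta_{jtu}.$$

Turnover ($\beta_{jtu}$) captures replacement independent of richness
differences; the nestedness-resultant component ($\beta_{jne}$) is the
remainder. The multiple-site generalization follows Baselga's Jaccard
family, with $\Sigma\min$ and $\Sigma\max$ the sums over site pairs of the
smaller and larger exclusive counts, $\Sigma S_i$ total richness over
sites and $S_T$ pooled richness:

$$\beta_{JTU} = \frac{2\Sigma\min}{\Sigma S_i - S_T + 2\Sigma\min}, \qquad
  \beta_{JAC} = \frac{\Sigma\min + \Sigma\max}
                     {\Sigma S_i - S_T + \Sigma\min + \Sigma\max}.$$

Additivity $\beta_{jac} = \beta_{jtu} + \beta_{jne}$ holds to machine
precision for every computed pair and multi-site triple, and the test suite
enforces it at $10^{-12}$. (On a *printed* three-decimal table the
components can misalign by one final-digit unit after rounding — the
bundled reference table contains two such rows — so data checks against
printed values use printed precision, never the machine bound.)

Two semantics choices are deliberate. Sites with no member of a family are
retained when the family is analysed: against a non-empty site they yield
$b$ or $c$ equal to the partner's full richness (dissimilarity 1, all
turnover 0 by the $0/0$ convention — one-sided absence is a richness
difference, so it loads on nestedness); a pair of two family-empty sites is
undefined and is excluded from regression tables rather than recorded as 0.
A species absent everywhere is inert.

Dispersal capacity enters through pelagic larval duration (PLD, days):
species-level values where recorded, otherwise the median over congeners
with data, otherwise missing and excluded from trait comparisons.

## Least-cost in-water distance

Geographic distance between sites is the shortest path through sea,
avoiding land, over a gridded land/sea mask (any single-band elevation or
mask raster in ESRI ASCII form; cells at or above a threshold, default 0 m,
are land — depth is otherwise ignored). Sea cells become graph nodes; edges
connect neighbours with haversine great-circle weights (Earth radius
6371 km). The default neighbourhood is 16 (rook + bishop + knight moves)
because the worst-case lattice anisotropy of a 16-neighbour metric is
$1/\cos(13.3^\circ) - 1 \approx 2.7\%$ at bearings about 13° off-axis and
below 1.4 % elsewhere, against up to 8 % for the 8-neighbour lattice.
Corner-cutting through land is forbidden: a diagonal step is blocked when
both flanking orthogonal cells are land, and a knight step requires its
two-cell corridor to be sea. Sites snap to the nearest sea cell within a
configurable radius (default 2 cells) and pairs in disconnected components
are flagged infinite rather than dropped silently. Dijkstra's algorithm
(via `igraph`) does the rest; outputs are symmetric, satisfy the triangle
inequality, and can never undercut the great-circle distance between the
snapped cells.

## The MLPE regression

All hypotheses reduce to a regression of stacked pairwise values: responses
are pairwise $G''_{ST}$ (genetic IBD), pairwise $\beta_{jtu}$ or
$\beta_{jac}$ (species IBD), or family dissimilarity paired with each
species' genetic dissimilarity (beta-SGDC); the predictor is in-water
distance or genetic dissimilarity; the grouping unit is the species or
family contributing each matrix. Pairwise observations are not independent:
two pairs sharing a site share that site's idiosyncrasies. The
maximum-likelihood population-effects (MLPE) model of Clarke et al. handles
this with a residual correlation $\rho$ between same-group pairs sharing
exactly one site, plus a random intercept per group:

$$y_{g,ij} = \alpha + \beta x_{g,ij} + u_g + \varepsilon_{g,ij},
  \quad u_g \sim N(0, \sigma^2_u).$$

The fit profiles $\beta$ and $\sigma^2_\varepsilon$ out analytically and
optimizes the restricted likelihood over $(\rho, \lambda =
\sigma^2_u/\sigma^2_\varepsilon)$, with $\rho$ constrained to $[0, 0.5)$ —
the range on which the sharing-structure correlation matrix is positive
definite for these designs — via a logistic transform, and $\lambda$ via a
log transform (Nelder–Mead from three starts). The covariance is assembled
densely; the designs here are tiny (tens to hundreds of rows). REML is the
default; ML is available, and the ML log-likelihood at the optimum equals a
direct multivariate-normal density evaluation with the explicitly assembled
covariance (enforced at $10^{-8}$ in the tests). With $\rho$ fixed at 0 and
no random intercept the estimator collapses exactly to ordinary least
squares.

Inference on the slope is a Wald $t$-test with
$df = n_{pairs} - n_{groups} - 1$; the convention is recorded in every fit
because no single convention is canonical for distance-matrix designs.
With only 4 sites (6 pairs per group) variance components are weakly
identified; fits flag $\hat\sigma^2_u$ at the zero boundary instead of
hiding it. Calibration under the null (no slope, $\rho = 0.3$, species
random intercepts, 8 sites × 6 groups) keeps the empirical size of the
5 %-level test within [0.025, 0.10], and the slope estimator is unbiased in
parameter-recovery simulations (both run in `test-acceptance.R`).

Variance explained follows Nakagawa–Schielzeth:
$R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_u + \sigma^2_\varepsilon)$ and
$R^2_c = (\sigma^2_f + \sigma^2_u) / (\sigma^2_f + \sigma^2_u +
\sigma^2_\varepsilon)$, with $\sigma^2_f$ the population variance of the
fixed-effect predictor over the data.

Between-basin contrasts of per-unit metrics (per-species $G''_{ST}$,
per-family turnover, PLD) are one-way fixed-effects ANOVAs; the PLD
comparison is the same `ocean_anova()` applied to the trait vector, with no
extra machinery. The significance threshold is 0.05 throughout and no
multiple-testing correction is applied; output tables report p-values and
never significance labels.

## The synthetic two-basin generator

The generator emulates the *statistical structure* the analysis assumes,
not the biology that produces it:

* **Seascape.** Per basin, a regular 0.5° grid with ~5 % island cover and
  4 sites on an east–west arc: a compact basin (spacing 650 km, realized
  in-water distances ≈ 650–2000 km) and a spread basin (spacing 1300 km,
  ≈ 1300–3900 km), matching the contrast between a dense and a sparse reef
  network.
* **Genotypes.** Per locus, an ancestral frequency $p_0 \sim U(0.1, 0.9)$;
  site logit-frequencies add a Gaussian field with covariance
  $\sigma^2 e^{-d_{ij}/\kappa}$ plus independent site noise $\tau^2$;
  genotypes are $\mathrm{Binomial}(2, p_{site})$ with 2 % of calls
  missing. Defaults $\sigma = 0.35$, $\tau = 0.15$, 3000 loci and 12
  individuals per site were chosen once so that pairwise $G''_{ST}$ lands
  in the empirically typical reef-fish range (~0.005–0.07) and then
  frozen. The decay range is the basin's connectivity dial:
  $\kappa = 1500$ km in the spread basin (comparable to the spacing, so a
  clear IBD signal) and $\kappa = 10^6$ km in the compact basin — far
  beyond any inter-site distance, so the residual distance trend
  (~$3.5\times10^{-8}$ per km) is far below detectability and the
  genetic-IBD test should reject at about its nominal rate. An earlier
  draft used $\kappa = 5\times10^4$ km, which quietly left a *detectable*
  trend and made the "no genetic IBD" half of the contrast ambiguous; the
  present value implements the intended scenario.
* **Communities.** Each species receives a range centre at one site and
  occupancy probability $0.95\, e^{-d/\lambda}$ times a site richness
  gradient (a 35 % drop across the basin, inducing nestedness), with
  independent Bernoulli occupancy; 3 families × 25 species per basin.
  $\lambda$ (700 km compact, 1400 km spread) is moderate relative to
  spacing in both basins, so species IBD is expected in both — the
  decoupling is genetic-only, as in the motivating contrast.

A Gaussian-field generator was chosen over coalescent simulation
deliberately: it gives direct, cheap, tunable control of the IBD signal.
The cost is realism — no drift–mutation balance, no linkage, no shared
genealogy across loci, no co-occurrence dependence between species, and
site noise that is exchangeable rather than historically structured. A
passing end-to-end run therefore demonstrates that the pipeline recovers
the patterns it assumes, under its own assumptions; it does not validate
those assumptions against real reef systems.

All generators are seed-deterministic (byte-identical VCF output under a
fixed seed) and emit files every reader in the package accepts.

## Validation problem sizes

The package's own study-scale validation (`run_synth_experiment()`, also
the heart of `scripts/acceptance.R`) runs 20 independent replicates of the
full two-basin design at the default configuration — 7 + 12 species, 3000
loci, 4 sites and 12 individuals per site per basin — and measures three
rates: significant positive genetic IBD in the spread basin (expected in
≥ 90 % of replicates), and non-significant genetic IBD alongside
significant species IBD in the compact basin (expected jointly in ≥ 70 %).
Species IBD is scored on total dissimilarity $\beta_{jac}$, the more
powerful of the two responses at 3 families × 6 pairs. MLPE calibration
uses 200 replicates of an 8-site × 6-group design; oracle-equivalence
checks use 100 random small genotype datasets and 50 random incidence
tables. These sizes were picked so the whole validation runs in a few
minutes on one core while leaving the binomial bands around each rate
decisive.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_config(seed = 1)
sc <- simulate_seascape(cfg)
st <- site_table(sc$sites[sc$sites$basin == "spread", ])
sg <- build_sea_graph(sc$grids$spread)
d <- least_cost_distance(sg, st)
gts <- simulate_genotypes(cfg, d, "spread")
com <- simulate_communities(cfg, d, "spread")
bs <- run_basin(gts, com, st, d)
bs$fits
summary(bs$fit_objects$genetic_ibd)
```

## Known limitations

* Ocean currents are absent: distance is purely geometric, so asymmetric
  or current-mediated connectivity cannot be represented.
* The MLPE Wald test's degrees of freedom are a convention, not a derived
  quantity; with 4-site designs, p-values near the threshold deserve
  caution and the boundary flag should be checked.
* The 16-neighbour lattice overestimates open-water distance by up to
  ~2.7 % in the worst direction; refine the grid or accept the bias.
* Per-family beta-diversity with very small families (a handful of
  species) is coarse: one species' occupancy flips move the metric in
  steps.
* The generator's independence assumptions (loci, species) understate the
  variance real data would show at the same nominal sizes.
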