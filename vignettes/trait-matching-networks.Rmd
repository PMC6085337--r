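---
title: "Trait matching, functional diversity and niche structure in mutualistic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait matching, functional diversity and niche structure in mutualistic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutualinet)
```

## The scientific problem

Plant–animal mutualisms (seed dispersal by frugivorous birds, pollination by
nectarivorous birds and by flower-visiting insects) assemble under two joint
constraints. At the level of species pairs, morphological *trait matching*
decides which interactions are possible and profitable: fruit diameter
against bill width, corolla depth against bill or proboscis length. At the
level of whole communities, the *functional diversity* available on each
trophic side constrains the interaction niches of the other side: a plant
community spanning a wide range of fruit sizes offers frugivores more ways
to partition resources (bottom-up control), and vice versa a functionally
diverse animal community widens and partitions the plants' pollination or
dispersal niches (top-down control). Climate and land use enter upstream,
by shaping the functional diversity of both sides along environmental
gradients.

`mutualinet` implements this full chain of reasoning as a tested pipeline:
trait-table and interaction-record handling, degree-weighted RLQ ordination
with fourth-corner permutation inference, functional-dispersion and
interaction-niche metrics per site network, and a Bayesian hierarchical
structural equation model (SEM) that links climate, land use, functional
diversity and niche structure across mutualisms. Because field datasets of
this kind are typically access-restricted, the package also contains a
synthetic-data generator that reproduces the statistical structure such
studies assume, with known ground truth; all validation in the test suite
runs against it.

## Data model

Each mutualism carries a plant and an animal trait table with exactly three
quantitative traits, one per functional role: a **matching** trait (size
constraint), an **energy** trait (provisioning or requirement) and a
**foraging** trait (stratum or mobility). Ratio traits (Kipp's index,
forewing index) are computed from their components before any transform.
All traits are square-root transformed before analysis, uniformly — the
transform applies to ratio traits like any other, a deliberate choice where
practice varies. Missing values are a distinguished marker (`NA`), never
zero, and can be filled by genus→family→order means
(`impute_trait_taxonomic()`, provenance recorded per cell) or by log–log
allometries (`impute_trait_allometric()`), e.g. bee body length from
intertegular distance with intercept 1.89 and slope 0.518.

Interaction records are long-format rows (site, mutualism, plant, animal,
count). Two derived objects matter: the binary **metaweb** `L` (was the pair
ever observed, across all sites of a mutualism) and the per-site weighted
networks. Species orderings are lexicographic everywhere so that every
derived matrix is bit-for-bit reproducible. Site covariates are mean annual
temperature (MAT, °C), mean annual precipitation (MAP, mm·yr⁻¹) and binary
land use (LU; 0 near-natural, 1 anthropogenic); missing MAT/MAP are imputed
by OLS on a cubic polynomial of elevation plus additive habitat indicators
(`impute_climate()`), with the fit R² reported.

## RLQ ordination and fourth-corner inference

With `P = L / sum(L)`, the row and column margins `r`, `c` are proportional
to species degree. Trait columns are centred and scaled to unit variance
*under these weights*, and the cross-covariance matrix

$$\Omega = \tilde R^\top (P - r c^\top) \tilde Q$$

is decomposed by SVD; $\lambda_k$ is the squared $k$-th singular value,
and the species scores $x_k = \tilde R u_k$, $y_k = \tilde Q v_k$ attain
$(x_k^\top P y_k)^2 = \lambda_k$ under orthonormal coefficient vectors.
Degree-weighting conventions for this three-table ordination are described
loosely in the applied literature (species weighted by their number of
links, without fixing the standardisation), so we commit to the standard
correspondence-analysis convention above (relative-degree weights, trait
standardisation under those weights) and verify the defining maximisation
property directly: the test suite checks, on random small
instances, that $\lambda_1$ equals a brute-force grid maximisation of the
squared cross-covariance over unit coefficient vectors to 1e-3, and that
$\sum_k \lambda_k = \lVert\Omega\rVert_F^2$ to 1e-10. Axis signs are fixed
by making the largest-magnitude coefficient positive per axis. Axis
retention uses cumulative percent cross-covariance (default coverage 0.99)
with a floor of two axes for the planar trait-space summaries.

Significance uses the sequential fourth-corner permutation scheme: model 2
permutes plant identities, model 4 animal identities, model 6 runs both and
reports the **maximum** of the two p-values — the only combination that is
type-I-error safe for the fourth-corner problem. P-values use the add-one
formula with ties counted as extreme (conservative). The global statistic
is $\sum\lambda$ (upper tail, and computable without an SVD since it equals
the squared Frobenius norm of $\Omega$ — this makes 999-permutation tests
cheap); axis correlations hold the observed scores fixed as variables;
trait–axis correlations recompute the ordination per permutation and use
$|r|$ since the axis orientation is arbitrary. The default permutation
number is 9999 for final inference; simulation studies in the tests use 999.
Degenerate permutations (zero weighted variance) are redrawn and counted.
Evidence across several tests (e.g. matching-trait correlations across
mutualisms) is pooled by Moran's exact Bernoulli probability
$P = \binom{N}{K}\alpha^K(1-\alpha)^{N-K}$, computed in log space; this is
the point probability as conventionally reported, not a tail sum.

## Functional diversity and interaction niches

Gower distances standardise each trait by its range, so distances live in
[0, 1] and two species at opposite extremes of every trait are exactly 1
apart. Ranges are computed **per site community** by default: functional
dispersion is a community property, and this keeps the metric internally
referenced; a global-range mode is available (`global_ranges = TRUE`) since
usage varies and the choice is not settled. Zero-range traits are excluded
from the mean with a warning; missing values use pairwise deletion.

Species are embedded by classical PCoA (`stats::cmdscale`); axes with
eigenvalues below 1e-8 of the maximum, including all negative-eigenvalue
axes, are dropped. No Cailliez/Lingoes correction is applied by default:
range-standardised quantitative Gower on three traits is near-Euclidean, so
the correction would mostly add noise axes; it is available via
`correction = "cailliez"`. Functional dispersion is then the
abundance-weighted mean distance to the abundance-weighted centroid, with
**marginal interaction totals** as abundances. It is invariant to abundance
rescaling and to splitting a species in two, and is zero for communities of
one species. Multivariate FD (all three traits) and univariate FD per trait
type are both reported; no algebraic relation between them is assumed.

Niche breadth is the mean effective number of partners
$e^{H_i}$, $H_i = -\sum_j p_{ij}\ln p_{ij}$; niche partitioning is the mean
standardised Kullback–Leibler specialisation
$d'_i = (d_i - d_{\min})/(d_{\max} - d_{\min})$ with
$d_i = \sum_j p'_{ij}\ln(p'_{ij}/q_j)$ against partner availability $q$.
The integer bounds are computed per species: $d_{\min}$ from
largest-remainder rounding of the proportional allocation followed by
single-unit descent, and $d_{\max}$ by exploiting that the KL divergence is
convex in the allocation, so its maximum sits at an extreme point of the
capacity-capped simplex — the search tries, for every partner, filling it
first and the rest by ascending availability, then refines by single-unit
ascent. On all 2×2 and 2×3 integer matrices with totals ≤ 6 these bounds
bracket the observed divergence exhaustively (the test suite enumerates
every marginal-preserving matrix); for larger networks they are a documented
heuristic. Degenerate bounds ($d_{\max}=d_{\min}$, e.g. a species with a
single interaction) give $d' = 0$. Network-level values are unweighted
arithmetic means across species — the convention when "mean" is stated
without weights — with an abundance-weighted option (`weighted = TRUE`).

`niche_pipeline()` joins FD, niche metrics and covariates into one row per
site × mutualism; `scale_metrics()` log-transforms the $e^H$ columns and
z-scales every modelling column across the pooled table. Pooled (rather than
per-mutualism) z-scaling is deliberate: the SEM pools mutualisms and absorbs
level differences in a random factor, so scaling within mutualisms would
remove exactly the variation the random factor is meant to model.

## The hierarchical structural equation model

On z-scaled data, two bivariate-Gaussian blocks:

- $(FD_p, FD_a) \sim \mathrm{MAT} + \mathrm{MAP} + \mathrm{LU}$,
- $(\mathrm{niche}_p, \mathrm{niche}_a) \sim \mathrm{MAT} + \mathrm{MAP} +
  \mathrm{LU} + FD_p + FD_a$,

each with a residual correlation within the pair (always estimated, never
under selection — the covariance terms represent correlated errors from
unmeasured common causes and reciprocal effects, not optional paths) and
with equation-specific random intercepts for study site and mutualism type
(crossed grouping; the shared-versus-equation-specific choice is not settled
in the literature we follow, and equation-specific intercepts with a common
grouping are the less restrictive option). Since all endogenous variables
are observed, the recursive system factorises into these two conditional
blocks — no latent integration is needed.

Each of the 16 directed paths carries a selection indicator
$\gamma_k \sim \mathrm{Bernoulli}(1/2)$ with effective coefficient
$\beta_k = \gamma_k\theta_k$. When $\gamma_k = 0$, $\theta_k$ follows a
*pseudo-prior* centred on the posterior mean and s.d. of a pilot run fitted
without selection — the "global adaptation" that keeps the Gibbs sampler
mixing across models; when $\gamma_k = 1$, $\theta_k$ has a weakly
informative slab Normal(0, 2.5²). The slab scale matters: on z-scaled data
a very diffuse slab (s.d. 10, say) would shrink every inclusion Bayes
factor by roughly the log of the slab width — the Lindley/Bartlett effect —
and moderate real effects would never be selected. A scale of 2.5
comfortably covers the plausible range of standardised coefficients
(|β| ≲ 1) while keeping the penalty proportionate; it matches the
half-Cauchy(2.5) scale used for the standard deviations. Intercepts get
Normal(0, 10²); standard deviations (residual, site, mutualism)
half-Cauchy(2.5); residual correlations Uniform(−1, 1).
Path support is $2\ln BF_k$ from the posterior inclusion odds against the
prior odds, with categories none (<2), positive (2–6), strong (6–10),
decisive (>10); inclusion frequencies of exactly 0 or 1 are clipped to the
posterior sample's resolution and flagged saturated. Per endogenous variable
the marginal $r^2_m$ (fixed effects) and conditional $r^2_c$ (fixed plus
random) are computed per draw from the variance of the fixed linear
predictor and the variance components; $r^2_m \le r^2_c$ holds on every
draw by construction.

Sampling runs in JAGS via `rjags`, fully seed-reproducible (per-chain RNG
seeds derive from one integer). The reference schedule is 8 chains ×
51,000 iterations, 1,000 adaptation, thinning 100 (4,000 retained draws;
`sem_mcmc(reference = TRUE)`). The package default is 4 chains × 5,000 with
thinning 10 — the same retained sample size — and the test suite uses still
smaller schedules (down to 2 × 2,000) chosen to keep the full suite in the
tens of minutes on one CPU; at n = 126 these already separate true from null
paths cleanly. Convergence is summarised by split-chain R-hat (< 1.05) over
the continuous non-selection parameters — indicators and their conditional
coefficients are bimodal by design, where R-hat is not meaningful — plus
effective sample sizes; short schedules often flag the weakly-identified
mutualism-level standard deviation (3 groups), which is expected and honest.
Because `fit_sem()` z-scales internally, `scaled_truth()` maps generator
coefficients onto the fitted scale ($\beta' = \beta\,sd(x)/sd(y)$) for
recovery comparisons.

## The synthetic-data generator

`scenario_config()` fixes the reference study conditions once:

- **Design**: 53 sites along an 870–4400 m elevational gradient; three
  mutualisms observed on overlapping subsets of 39, 20 and 19 sites, the
  third resampled within sites to 67 observations — 126 observations total,
  53 sites, 3 mutualisms.
- **Climate shapes**: MAT decreases linearly with elevation (≈ −5.6 °C per
  km from 25.3 °C); MAP is unimodal, peaking near 2,200 m; both plus small
  sensor noise. These are fixed functions, not fitted — only their
  monotone/unimodal character matters downstream. Anthropogenic land use
  concentrates at low elevations via a logistic in elevation.
- **Trait pools**: per mutualism, 40 plant and 40 animal species; matching
  traits are squared shifted normals (so square-root transformed values are
  ~Normal with unit s.d.), energy traits log-normal, foraging traits
  (ratios) uniform on (0.1, 0.9).
- **Communities**: ~12 species per trophic level per site (Poisson-varying,
  so richness varies), sampled from the pool with weights that widen with
  MAP (plants) or MAT (animals) — that is how climate drives functional
  dispersion in the generator.
- **Interactions**: counts are Poisson (negative binomial optional) with
  intensity ∝ log-normal abundances × a Gaussian kernel on the
  square-root-scale matching-trait difference, width σ_match = 0.5
  trait-s.d. by default, modulated by weak energy (0.2) and foraging (0.1)
  log-linear terms; expected 300 counts per site. A threshold kernel
  (`kernel = "threshold"`) gives the strict forbidden-link variant in which
  animals cannot use plants whose matching trait exceeds their own by more
  than σ_match. `null_dataset()` removes *all* trait dependence (uniform
  community sampling, abundance-only intensities) for type-I-error studies.
- **Structural truth**: five nonzero standardised paths — MAP→FD_p and
  MAT→FD_a at 0.6, FD_p→niche_a and FD_a→niche_p at 0.6 (the bottom-up and
  top-down effects), MAT→niche_p/a at 0.3 — residual s.d. 1, residual
  correlations 0.3, site s.d. 0.3, mutualism s.d. 0.2. No quantitative
  effect sizes exist to copy for the kernel or the paths; these magnitudes
  are the package's own calibration, set once and documented as such.

`simulate_sem_table()` draws directly from the structural equations (the
exact process the SEM assumes); `simulate_dataset()` generates the full
record-level data for the ordination/FD/niche stages. Both are byte-level
reproducible from the seed, and every dataset ships its `synthetic_truth`.

What the generator does **not** emulate: phenology and sampling effort,
spatial autocorrelation among sites, taxonomic structure in traits,
detection bias, and the empirical trait covariances of any real system.
Passing tests therefore demonstrate statistical correctness of the methods
under the stated model, not field realism of any particular number.

## Numerical choices and degenerate inputs

- SVD of Ω rather than eigendecomposition of ΩᵀΩ, for numerical stability;
  identical eigenvalues by construction.
- Zero-degree species are an error at `rlq()` (prune when building the
  metaweb); constant trait columns under the degree weights are an error.
- Permutation ties count as extreme; p-values live in [1/(n+1), 1].
- Sites with fewer than two interacting species at a level get FD 0 with a
  `few_species` flag; identical-trait communities give FD 0 (zero-range
  Gower handled explicitly).
- $e^H$ excludes zero-total species; $d'$ clamps to [0, 1] and maps
  degenerate bounds to 0.
- Climate imputation refuses rank-deficient designs, naming the collinear
  columns, and refuses unseen habitat levels.
- All orderings lexicographic; all stage seeds derived deterministically
  from one global seed; the pipeline writes a manifest of seeds and
  checksums sufficient for exact re-runs.

## Problem sizes used in validation

The test suite validates at deliberately moderate sizes, chosen as the
package's own desk-scale conditions: 20 random instances for the RLQ oracle
equivalence; 200 trait-independent replicates (30+30 species, 999
permutations) for the type-I error of the combined test (bounded at 0.08,
i.e. the nominal 0.05 plus Monte-Carlo slack); 50 replicates each at 30, 50
and 100 species for power monotonicity; exhaustive enumeration for the d′
bounds; and 25 replicates at the reference size n = 126 for SEM path
recovery (pilot posterior within 3 posterior s.d. of truth) and selection
operating characteristics (2lnBF > 2 for the 0.6 paths, < 2 for null
paths). Larger schedules — 9,999 permutations, the full MCMC schedule —
are one argument away and change no code path.

## Known limitations

- The RLQ weighting convention is validated against its internal
  maximisation property, not against any particular dataset's eigenvalues;
  other software may standardise the correspondence table differently and
  produce numerically different (though monotonically related) eigenvalues.
- The $d'$ bounds are exact only where exhaustively verified (small
  matrices); elsewhere the extreme-point search is a well-behaved heuristic.
- Categorical or fuzzy traits are out of scope; the trait triad is strictly
  quantitative.
- Full prior-predictive calibration of the SEM under the diffuse slab prior
  is impractical at desk scale; the suite instead checks interval
  calibration on data drawn at the reference conditions and
  maximum-likelihood agreement with `lme4` when selection is disabled.
- Model comparison beyond per-path Bayes factors (WAIC/LOO), non-Gaussian
  likelihoods and latent measurement models are out of scope.
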