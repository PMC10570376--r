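---
title: "Phylogenetic distance between naturalized aliens and natives: models, nulls, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic distance between naturalized aliens and natives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Two of Darwin's hypotheses make opposite predictions about which alien
plants naturalize in a regional flora. Under *preadaptation*, aliens
closely related to the natives succeed, because relatives share the traits
that pass the region's environmental filter. Under *Darwin's naturalization
hypothesis*, close relatives fail, because they compete hardest with
natives and share their enemies. `natphylo` operationalizes the test at the
regional-flora scale and asks how its outcome moves along latitude,
climate, and human-modification gradients: environmental filtering should
dominate in harsh, seasonal, high-latitude climates (favouring
preadaptation), biotic resistance in benign tropical ones.

# The distance statistic and its null

The unit quantity is the cross-group mean pairwise distance between a
region's naturalized aliens $A$ and natives $B$ on a time-calibrated
phylogeny,

$$\mathrm{MPD} = \frac{1}{|A||B|}\sum_{a\in A}\sum_{b\in B} d(a,b),$$

with $d$ the patristic distance. `crossgroupMPD()` evaluates this by edge
contribution — one postorder pass in which each edge adds
$\ell_e \cdot [n_A^{(e)}(|B|-n_B^{(e)}) + n_B^{(e)}(|A|-n_A^{(e)})]$,
the counts being the alien/native tips below the edge — which is
algebraically identical to averaging the patristic submatrix and is tested
against that brute force at $10^{-9}$. The mean nearest-taxon distance is
provided (`crossgroupMNTD()`) as a utility; the headline analyses use MPD
only, since megaphylogeny tips (grafted polytomies) are too poorly resolved
for a nearest-neighbour statistic.

MPD alone confounds relatedness with richness and tree shape, so each
region is compared with a null model: hold the natives and the alien
*count* fixed, redraw the alien *identities* uniformly without replacement
from a source pool, and summarize

$$\Delta\mathrm{MPD} = \mathrm{MPD}_{obs} - \overline{\mathrm{MPD}}_{null},
\qquad
\mathrm{SES} = \Delta\mathrm{MPD} / \mathrm{sd}(\mathrm{MPD}_{null}).$$

Draws are without replacement because a species list cannot repeat a
species; the SES denominator is the sample (n−1) standard deviation; a
degenerate zero-variance null yields an undefined (NA) SES and weight
rather than ±Inf. Instead of rarefaction — which discards information in
species-poor regions — uncertainty is carried into the regression layer as
the weight $1/\mathrm{var}(\mathrm{MPD}_{null})$. The replicate count
defaults to 1000 (`n_reps`); each replicate costs O(alien count) after a
single linear-time pass (`distancesToSet()`), so the default is cheap.

Randomization streams: one master seed; every (region, pool) pair derives
its own substream by hashing (`substreamSeed()`), so results are identical
regardless of processing order or parallel scheduling.

## The six source pools

What "could have naturalized here" is contestable, so six nested-by-design
pools are implemented (`buildPool()`): all species non-native to the
region; economic-use species plus the global naturalized flora; the global
naturalized flora; species naturalized on the region's continent;
climatically suitable naturalized species; and the continent ∩ climate
intersection. Every pool excludes the focal region's natives (the statistic
requires disjoint groups) but keeps its observed aliens, so the null can
redraw them — the standard choice where the data supplier is silent. Region
area filtering is strict (`area > 5000` km² by default, with 0/1000/10000
as sensitivity settings), and records with conflicting native/naturalized
status resolve as native by default (`alien_wins` is the sensitivity
variant).

## Grafting and tree resolution

Species missing from the backbone are attached at the crown node (MRCA of
the present tips) of their genus, else of their family
(`graftMissingSpecies()`). The pendant length equals the attachment node's
height above the tip level, so an ultrametric backbone stays ultrametric —
the natural choice for a time-calibrated tree, where "the root of the
genus" names a point in time. A genus represented by a single tip has no
crown; by default the new species is joined halfway down that tip's pendant
edge (configurable to attach at the tip's parent). Attachment is exact edge
surgery on the edge matrix: round-tripping branch lengths through text was
measured to accumulate ~1e-9 depth error over hundreds of grafts and is
avoided. `collapseToRank()` produces the evenly-resolved sensitivity tree
in which every species hangs from its genus (or family) crown as a
polytomy; it requires the rank to be monophyletic, which clade-cut
taxonomies guarantee.

# Climate axes and the suitability stage

The 19 bioclim variables are transformed toward normality (per-variable
specs; the default is a data-fitted Yeo-Johnson exponent via `car`, with
identity/log1p/sqrt options), centered, scaled, and decomposed by PCA
(`fitClimatePCA()`). Axis signs are arbitrary in any PCA, so axis 1 is
oriented with mean annual temperature loading positive (high PC_Temp =
warm) and axis 2 with annual precipitation positive (high PC_Prec = wet).
The PCA is fitted on grid cells by default and region scores are the
unweighted mean of cell scores; a region-level fit is available because
non-linear transforms make the two orders of averaging differ.

The climate pools need a per-species suitability decision. The package
fits a Gaussian climatic envelope per species over six distribution-model
variables (mean diurnal range, temperature seasonality, max temperature of
the warmest month, precipitation seasonality, wettest- and driest-quarter
precipitation): suitability of a cell is
$\exp(-\tfrac12 D^2_{Mahalanobis})$ to the training-presence mean and
covariance, in (0, 1]. Species need more than 15 presence cells; presences
split 80/20 into training/test (seeded); a model is retained only when its
test AUC against the full-landscape background exceeds 0.7; the
presence/absence threshold maximizes training sensitivity + specificity
(ties toward the larger threshold); and a region is suitable when at least
one of its cells reaches the threshold. The scorer is a climatic envelope
by design — the pipeline only requires a monotone suitability score per
cell, and `buildPool()` equally accepts a precomputed external suitability
table so that scores from any external distribution model can be plugged
in. Near-singular training covariances are ridge-regularized with a logged
epsilon. Under the default generator, most synthetic species are
climatically broad, so the envelope stage retains only the narrow-niche
minority and the two climate pools act as the *strict* pools they are
meant to be: regions whose alien count exceeds the strict pool's size are
skipped for that pool with a logged reason.

# The regression layer

Region-level: (i) (weighted) linear regression of MPD and each
$\Delta$MPD on latitude; (ii) latitude × human-modification interaction
models; (iii) linear mixed models
`response ~ pc_temp*hm + pc_prec*hm + (1 | continent)`, inverse-variance
weighted for the $\Delta$MPD responses. Latitude enters as absolute
centroid latitude by default (signed is a config option). Mixed-model
p-values are two-sided Wald tests; standardized effect sizes are obtained
by refitting on unit-variance-scaled response and predictors — a
transparent definition chosen because "effect size" is
package-idiom-dependent. A single-group factor degenerates the mixed model
to the weighted fixed-effects fit (with a warning), and non-convergence
falls back the same way with the convergence flag cleared.

Species-level: every (species, region) pair with the species non-native
contributes a Bernoulli outcome, modelled with the complementary log-log
link (appropriate when successes are rare) as
`naturalized ~ mpd * abs_latitude + (1 + mpd*abs_latitude | species) +
(1 | region)`; predictors are standardized internally. The full
random-slope structure automatically falls back to random intercepts, then
to a plain cloglog GLM, when the optimizer fails — each fallback logged.
Partial-prediction curves (`partialPredictions()`) present interactions the
standard way: the focal predictor swept over its range with the moderator
fixed at the 10/50/90% sample quantiles (or at explicit values, as for the
latitude-sliced naturalization curves), random effects at zero, binomial
predictions on the probability scale. Completeness sensitivity refits
(subset above a completeness cutoff; completeness-weighted) are provided
as `completenessWeightedRefit()`.

# The synthetic world

`generateWorld()` builds the study system the pipeline assumes, with known
ground truth. Defaults (all overridable via `worldParams()`):

| parameter | default | meaning |
|---|---|---|
| `n_species`, `birth_rate` | 400, 1 | pure-birth tree size and rate |
| `n_genera`, `n_families` | 40, 12 | clade-cut taxonomy (monophyletic, nested) |
| `trait_sigma2` | 1 | Brownian rate of the thermal optimum |
| `n_regions`, `latitude_range` | 60, ±60° | uniform region centroids |
| `cells_per_region` | 10 | abstract climate cells per region |
| `climate_noise_sd` | 2 °C | cell-level temperature noise |
| `filtering_base_sd` | 2 | niche-filter width at the equator (trait SD units) |
| `filtering_latitude_coefficient` | 0.02 /° | poleward sharpening of the filter |
| `target_richness` | 80 | expected natives per region |
| `beta0, beta_mpd, beta_lat, beta_int` | −2.2, −0.4, 0.3, −0.5 | cloglog coefficients (standardized scales) |
| `sd_species, sd_region` | 0.5, 0.3 | random-effect SDs |
| `econ_rate` | 0.3 | economic-use flag rate |

The pieces: a forward Yule simulation (two starting lineages, exponential
waits, a final wait so tips do not end at the last split) whose lineage
count at depth *t* has the closed-form mean $2e^{bt}$ used as a test
oracle; Brownian thermal optima from a root value of 0 (variance
$\sigma^2 t$, covariance $\sigma^2 \times$ shared path — both asserted);
regions with a planetary climate template (temperature falling ~0.55 °C
per degree of absolute latitude, seasonality rising, precipitation
latitude-independent) so the PCA recovers a temperature axis
anticorrelated with |latitude| and a separate precipitation axis; native
assembly by a Gaussian niche kernel whose width shrinks exponentially
poleward, normalized to the target richness — producing the empirically
documented poleward phylogenetic clustering of native floras; and a
cloglog naturalization process over all non-native (species, region) pairs
whose negative `beta_int` makes MPD increasingly *penalized* toward the
poles (preadaptation) and neutral-to-favoured near the equator.

Default effect sizes were chosen once, as moderate values that a field
study of ~60 regions could plausibly detect: prevalence ≈ 11%
(`beta0 = −2.2`), half-SD main effects, and a half-SD interaction. The
filter widths (2 at the equator shrinking to ≈ 0.6 SD at 60°) span weak to
strong filtering.

What the generator does *not* emulate: dispersal limitation and
introduction effort, spatial autocorrelation and real geography, island
effects, taxonomic error, and abundance. Passing recovery tests therefore
shows the inferential chain is correct and adequately powered under its
own assumptions — not that the real-world estimates are unbiased under
violations of them.

## The calibration (null) condition

Two validation experiments deserve explanation. *Calibration of SES*: when
a region's aliens truly are uniform pool draws, SES is standard-normal-like
(mean ≈ 0, |SES| > 1.96 about 5% of the time); this is checked on 200
synthetic regions. *Type-I control of the latitude test*: the null world
sets the filter width constant across latitude **and** zeroes the
naturalization coefficients and random effects. Flat filter width alone is
not a null: native niche *positions* still track the latitude-sorted
climate, and an MPD-selective naturalization process (`beta_mpd ≠ 0`)
couples to that structure, producing a genuinely nonzero latitude slope —
a scientifically real pathway, not a test artifact. Under the full null
the weighted $\Delta$MPD-on-latitude test holds its nominal 5% size.

# Numerical and design choices

- Edge-contribution MPD and the two-pass distance-to-set engine are exact
  (no tolerance is consumed by the implementation); tests compare at 1e-9.
- Grafting preserves ultrametricity by construction; the backbone height is
  frozen once per grafting batch so rounding cannot compound.
- max-SSS ties break toward the largest threshold; AUC uses midranks, so
  it is invariant under strictly monotone score transforms.
- Weighted fits accept zero weights (an indicator weight reproduces the
  subset fit); mixed models require strictly positive weights.
- The GLMM default is the full random-slope structure at Laplace
  (`nAGQ = 1`); large validation batteries use the intercepts-only
  structure at `nAGQ = 0`, which recovered the interaction sign in every
  spot check at a fraction of the cost.
- Validation problem sizes: the recovery battery uses 100 default worlds
  with 200-replicate nulls; the type-I battery uses 400 null worlds of 150
  species × 40 regions with 150-replicate nulls; the SES calibration uses
  200 regions × 500 replicates. These sizes give binomial tolerances of a
  few percent on the rates being checked.

# Known limitations

- Polytomies are first-class but never resolved; metrics on heavily
  collapsed trees inherit the genus-level resolution floor.
- The envelope suitability model is unimodal and symmetric in transformed
  climate space; truncated or multimodal niches will be scored poorly.
  External suitability scores can be supplied instead.
- The continent random intercept is the only spatial structure in the
  mixed models; residual spatial autocorrelation is not modelled.
- `collapseToRank()` requires monophyletic ranks; real-world paraphyletic
  genera must be reconciled upstream.
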