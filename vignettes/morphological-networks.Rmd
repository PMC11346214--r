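---
title: "Individual morphological brain networks: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual morphological brain networks: model, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbnet)
```

## The model

A morphological brain network (MBN) treats atlas-defined brain regions as
nodes and quantifies, **within a single subject**, how similar two regions'
gray-matter morphology is. Unlike group-level structural covariance, each
subject gets their own network, so network properties can be compared between
groups and correlated with per-subject clinical variables.

The construction has three steps, applied to the vertex-level (voxel-level)
gray-matter feature values $X = \{x_1,\dots,x_{n_1}\}$ and
$Y = \{y_1,\dots,y_{n_2}\}$ of each region pair:

1. **Combined Euclidean distance** (an energy-distance V-statistic):
   $$e(X,Y) = \frac{n_1 n_2}{n_1+n_2}\left(
     \frac{2}{n_1 n_2}\sum_{i}\sum_{j}\|x_i-y_j\|_2
     - \frac{1}{n_1^2}\sum_{i}\sum_{j}\|x_i-x_j\|_2
     - \frac{1}{n_2^2}\sum_{i}\sum_{j}\|y_i-y_j\|_2\right).$$
   The within-region double sums keep their zero $i=j$ terms (the V-statistic
   convention); this guarantees $e \ge 0$, with $e = 0$ exactly when the two
   vertex-value distributions coincide. Vertices are scalar gray-matter
   volume-like values; the implementation also accepts feature vectors per
   vertex, with the 2-norm acting on them, and degenerates correctly to the
   scalar case.
2. **Per-subject min–max normalisation**: $e_n = (e - e_{min})/(e_{max} -
   e_{min})$, with the extremes taken over the subject's full off-diagonal
   pair set (6670 pairs for a 116-region parcellation). This is a single
   affine map per subject — it preserves the ordering of all pairs.
3. **Exponential similarity**: $c = \exp(-e_n)$. The minimal-distance pair
   gets edge weight 1; the maximal-distance pair gets $\exp(-1) \approx
   0.368$. The off-diagonal range is therefore $[\exp(-1), 1]$, a direct
   consequence of steps 2 and 3 (any looser statement of a $(0,1]$ range is
   not attainable after min–max normalisation). The diagonal is fixed at 0
   and excluded from normalisation and every downstream metric:
   self-similarity carries no information and would distort graph metrics.

## Graph topology across sparsity

Similarity matrices are thresholded into binary undirected graphs at a grid
of sparsity levels (fraction of the $P = R(R-1)/2$ possible edges retained).
The default grid is $\{0.05, 0.10, \dots, 0.40\}$ — eight levels covering the
range in which such networks are sparse yet estimable with a small-world
index above 1. We read the conventional interval statement inclusively at
both endpoints; with a step of 0.05 the analysis only has its usual eight
levels if the endpoints belong to the grid.

At each level the package computes the standard global profiles — clustering
coefficient $C_p$, characteristic path length $L_p$ (over connected pairs
only, with the number of unreachable pairs reported), global efficiency
$E_{glob}$, local efficiency $E_{loc}$, and the normalised ratios $\gamma =
C_p/C_p^{rand}$, $\lambda = L_p/L_p^{rand}$, $\sigma = \gamma/\lambda$ — and
the nodal profiles degree $D_i$, nodal efficiency $E_i$ and (unnormalised)
betweenness $B_i$. We take $\sigma = \gamma/\lambda$ as the small-world
index; a ratio stated the other way round is only consistent with the
criterion $\sigma > 1$ after inverting it. Random baselines are means over
100 degree-preserving double-edge-swap rewirings with $10|E|$ swap attempts
each, seeded and reproducible; the count is a convention choice, stated so
results can be reproduced exactly.

Because threshold choice is arbitrary within the grid, every profile is
summarised by its **area under the curve** across sparsity (trapezoidal
rule, exact for linear profiles; a missing level is an error, never
imputed). Group inference operates on these AUC scalars.

Numerical conventions worth stating:

* Edge counts are `round(S * P)` (R's round-half-to-even); ties in
  similarity are broken by ascending region-id pair after descending
  similarity, which makes thresholding deterministic and edge sets nested
  across the grid.
* Tiny negative distances from floating-point cancellation (within `1e-10`)
  are clamped to zero; larger negative values would indicate a genuine
  error and raise a warning before clamping.
* A subject whose pair distances are all equal has no well-defined
  normalisation and is rejected explicitly rather than silently divided by
  zero; graphs with fewer than 3 nodes, or no connected pair, are likewise
  errors.
* On small toy parcellations the lowest grid levels can produce graphs with
  no triangles, making $\gamma$ (hence its AUC) undefined; toy analyses in
  the tests therefore use a denser grid (e.g. 0.20–0.40) or skip the
  normalised ratios, mirroring the practice of choosing the sparsity range
  so networks remain estimable.

## Group inference

AUC metrics are compared between groups by ANCOVA — the partial F test for
the group factor in `metric ~ group + age + sex` — with sex coded as a
single indicator and no interactions. Multiple testing is controlled by
Benjamini–Hochberg FDR in separate families: the seven global metrics form
one family, and each nodal metric type (degree, efficiency, betweenness
across all regions) its own family. Mixed global/nodal thresholds in this
literature imply such a split; the package states its choice explicitly
rather than guessing a single pooled family.

Clinical associations use partial correlation: both variables are
residualised on age and sex, the residual correlation is tested on
$n - 2 - k$ degrees of freedom. These correlations are exploratory and are
reported with raw p-values explicitly flagged `"uncorrected"`.

## Network-based statistics

NBS asks whether group differences concentrate in a connected subnetwork.
The package implements two primary screens:

* **node-restricted** (default): regions significant at raw $p < \alpha$ in
  at least one of the three nodal AUC profiles are screened in, and the
  suprathreshold connections are all pairs between screened-in regions
  (an "any endpoint" rule is available as an option — how a node screen
  "results in" edges is underdetermined, so both readings are provided);
* **edge-wise**: the canonical NBS screen, ANCOVA on every edge's
  similarity values.

Connected components of the suprathreshold set are extracted (igraph's
component machinery, validated in the tests against an independent
union-find implementation), and each observed component's size (edge count)
is referred to the permutation null distribution of the **maximal**
component size: group labels are shuffled (5000 permutations by default),
covariates stay attached to their subjects and remain in the permuted fits,
and the whole screen-plus-components pipeline is re-run per permutation.
Per-component $p = (b+1)/(n_{perm}+1)$ (the add-one estimator, which cannot
produce zero p-values). The maximal-size null already controls family-wise
error across components; BH-FDR is additionally applied across observed
components so that a component-level FDR is always available, and both
values are reported.

## The synthetic cohort generator

No subject-level morphometry is publicly available for the study design this
package targets, so the generator is a first-class module: every downstream
stage is validated against cohorts with known ground truth. Vertex values
follow

$$x_{irv} = \mu_r + \beta_{age}(age_i - \bar a) + \beta_{sex}m_i + b_{ir}
  + \delta_r\,1[i \in A] + \varepsilon_{irv},$$

with region means $\mu_r \sim N(0.5, 0.1^2)$ (arbitrary modulated-GMV-like
units), subject-by-region deviations $b_{ir} \sim N(0, 0.02^2)$, vertex
noise $\varepsilon \sim N(0, 0.05^2)$, and linear age/sex effects
($-0.003$ per year, $+0.01$ for male) matching the linear covariate
adjustment used downstream. Defaults mirror the emulated cohort: 61 patients
vs 42 controls, ages 5–13, about two-thirds male, and 50–300 vertices per
region drawn once per cohort — region size is an atlas property, not a
subject property. Clinical variables (serum IGF-1 in ng/ml, stimulated GH
peak in μg/l, total behaviour-checklist score) are linear in a subject-level
network feature plus Gaussian noise, with marginal scales matching the
emulated cohort's clinical panel; the induced-correlation helper
`clinical_noise_sd()` converts a target correlation into a noise level.

Two planting mechanisms create group effects:

* **shift** — each planted region's mean moves by
  `effect_size * subject_sd` in group A, signs alternating. This is the
  natural "region X is larger/smaller in patients" effect. Its consequence
  for the network, however, is diffuse: thresholding retains a fixed number
  of edges, so rank displacement of planted-region edges necessarily
  changes unaffected regions' degrees too. The affected-pair ground truth
  therefore lists every pair touching a planted region, and the induced
  similarity shift is recorded empirically (by regeneration at large n via
  `planted_effect_profile()`) rather than claimed in closed form — the
  construction has no simple closed-form inverse.
* **exchange** — group A's planted regions permute their baseline means
  among themselves. Because the multiset of region means is unchanged,
  every unaffected region's connectivity profile has (up to a small
  vertex-count pairing effect) the same distribution in both groups, which
  makes the planted node set an exact recovery target for NBS. Since
  inter-regional distances are nearly symmetric in the region means about
  their centre, a region moved onto the mirror image of its old mean would
  keep an almost identical profile; the permutation is therefore chosen
  (deterministically, given the drawn means) to keep every planted region
  away from both its old mean and that mirror image.

What the generator does **not** emulate: spatial smoothness and
partial-volume structure of real segmentations, anatomically realistic
covariance between neighbouring regions, non-linear age effects,
site/scanner effects, and non-Gaussian vertex distributions. Passing tests
therefore demonstrate that the statistical machinery is correct and
calibrated under the stated model — not that any particular empirical
finding in real cohorts would reproduce.

## Validation design and problem sizes

The test suite validates every metric against independent brute-force
implementations (naive double-sum energy distance; Floyd–Warshall distances;
direct triangle counting; exhaustive shortest-path counting for betweenness;
union-find components) on hundreds of random instances, plus closed forms on
canonical graphs ($K_5$, $C_4$, $P_3$, stars). Statistical operating
characteristics are checked by simulation at deliberately modest sizes,
chosen as the smallest scales at which the binomial error bands are
meaningful: type-I error of the ANCOVA group test from 1000 null cohorts
(16 regions, 20+20 subjects, pair-level response) and of NBS from 200 null
cohorts at 500 permutations, both required to fall in $[0.03, 0.07]$ at
$\alpha = 0.05$; power from 500 replicates of a 1-pooled-SD metric shift at
the emulated cohort's 61+42 sample sizes; and subnetwork recovery from 100
cohorts with a 14-node exchange-planted subnetwork among 20 regions
(baseline spread 0.2 so exchanged means are well separated; 200
permutations), requiring node-set Jaccard overlap above 0.8 in at least 80%
of replicates. The recovery operating point was fixed from pilot
simulations before being adopted as a test.

## Interfaces

All user-facing functions take and return tibbles so analyses compose with
the pipe; result objects carry `tidy()`/`glance()` methods and `autoplot()`
visualisations. The end-to-end `run_pipeline()` validates its configuration
(unknown YAML keys are rejected), expands the master seed into per-stage
substreams so stages can be re-run in isolation, stamps every artifact with
the configuration hash and seed, and removes partial outputs on failure. As
this is an analysis package whose users work in R, the R functions are the
primary interface; a thin script (`inst/scripts/run-pipeline.R`) exposes the
same pipeline to the shell.

## Known limitations

* Weighted-graph metrics, rich-club/modularity analyses, and
  threshold-free cluster enhancement are out of scope.
* $\gamma$, $\lambda$, $\sigma$ are undefined on graphs whose random
  references have zero clustering (very sparse or very small graphs).
* The permutation test assumes group labels are exchangeable under the
  null given that covariates travel with their subjects; strong
  covariate–group confounding would require a different permutation scheme.
* Exchange planting's null invariance is exact in the region means but not
  in the pairing of means with region vertex counts; the residual effect is
  small but visible at large baseline spread.
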