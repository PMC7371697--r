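---
title: "Methods: models, parameters and design choices in phosmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in phosmarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the models behind
each stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the choices made where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## Data model

All intensities are stored on the log10 scale (arbitrary units); the linear
value of an entry `x` is `10^x`. Missing entries are explicit `NA`s, never
zero: zero on the log scale is a finite abundance, not absence, and
label-free panels are missing-not-at-random (MNAR) — low-abundance features
drop below the detection limit. No stage imputes; each stage states how it
handles missingness (pairwise-complete filters, observed-entry z-scores,
or — only inside the PLS fit, which requires complete matrices — mean-
equivalent zero-fill after standardization, with a logged count).

Drug sensitivities arrive in two conventions: GI50-like (a concentration;
lower = more sensitive) and sAUC-like (1 − standardized area under the
dose-response curve; higher = more sensitive). `drug_response_matrix()`
negates GI50-like input at ingest so that internally higher always means
more sensitive, and every direction label ("sensitivity" vs "resistance"
marker) is derived from that single canonical orientation.

## Phosphoprotein aggregation and reporting conventions

`aggregate_phosphoprotein()` sums the linear-scale intensities of a protein
group's observed p-sites per cell line and returns the log10 of the sum; the
result is missing only when every member site is missing. This is a
deliberate simplification — sites on one protein can be regulated in
opposite directions — which is why all downstream analyses are offered at
the protein, phosphoprotein and p-site level separately.

`fold_change(low, high)` implements the panel-range reporting convention
`10^(high − low)` on log10 extremes, with optional half-away-from-zero
integer rounding (so `(6.64, 8.82)` reports 151); `mode = "ratio"` divides
linear-scale values such as ED50 concentrations (6.96/0.40 rounds to 17).

Normalization: the upstream processing chain of real panels is
instrument-specific, so the package ships a single documented stand-in,
per-cell-line median centering over observed entries
(`median_center()`). It is shift-invariant and leaves the missingness
pattern untouched.

## Statistical kernel

* `pearson_test()` — two-sided p from the t transform with n − 2 df;
  constant series yield a flagged UNDEFINED result rather than an error,
  because flat features are routine after filtering.
* `moderated_t()` — empirical-Bayes variance shrinkage:
  `s_post^2 = (d0 s0^2 + d s^2) / (d0 + d)`, statistic referred to t with
  `d0 + d` df. The hyperparameters `(d0, s0^2)` are estimated by closed-form
  moment matching of the scaled-F model on the log-variance scale
  (`fit_variance_prior()`): `Var(log s^2) = trigamma(d/2) + trigamma(d0/2)`
  is inverted for `d0` (own trigamma-inverse Newton iteration) and `s0^2`
  follows from the mean. This is deterministic and testable; the suite
  verifies it reproduces limma's fit on shared inputs, and `d0 = 0` recovers
  the classical pooled t exactly.
* `hypergeom_enrich()` — one-sided upper tail `P(X >= overlap)`, identical
  to the one-sided Fisher exact test on the 2x2 enrichment table; the
  enrichment use-case never needs the two-sided variant.
* `bh_adjust()` — the Benjamini-Hochberg step-up adjustment, tested against
  the brute-force rejection-set definition at every alpha.
* `rv_coefficient()` — matrix-level correlation
  `tr(XX'YY') / sqrt(tr((XX')^2) tr((YY')^2))` on column-centered blocks;
  rotation-invariant, 1 on self, NA (with warning) for a zero
  configuration.

## Activity scores and landscapes

Raw activity is the mean member z-score: each feature is z-scored across
cell lines over its observed entries, and a pathway's raw score in a cell
line is the mean z over member proteins and p-sites on member proteins.
Kinases combine up to three evidence channels — kinase protein abundance,
mean z of the kinase's own p-sites, mean z of its substrate sites — as the
unweighted mean of the channels available; substrate sites annotated as
inhibitory enter with negated z, since high occupancy of an inhibitory site
argues for low kinase activity. Mean-z is a KSEA-style statistic and is the
simplest score satisfying the properties the interface promises
(per-feature affine invariance, channel-permutation invariance, 0-1
rescaling); it is deliberately kept behind a narrow interface so a different
scoring rule can be substituted.

*Relative activity* is the per-entity min-max rescaling across cell lines,
so 0 and 1 mark the panel's least and most active line for that entity;
entities with no spread are flagged FLAT and excluded from waterfalls.
Waterfalls sort descending with lexicographic tie-breaks, so output is
deterministic.

Landscapes embed cell lines by the first two principal components of the
entity x cell-line relative-score matrix (missing relative scores are set
to the neutral 0.5 for the embedding only). The sign of each component is
fixed by making its largest-magnitude loading positive, which makes the
layout reproducible without a seed. Heights are Nadaraya-Watson
Gaussian-kernel regressions of each entity's relative scores over a regular
grid; the default bandwidth is half the median inter-cell-line distance —
wide enough that a group of similar lines forms one mountain, narrow enough
that complementary groups stay separated. Heights are clipped to [0, 1].
The layout algorithm used by the original activity-landscape figures is not
specified at this level of detail anywhere we can implement from; the PCA +
kernel construction is this package's own choice, favored for determinism
and dependency-lightness over a self-organizing map.

## Correlation-network modules

Unsigned adjacency `|cor(x_i, x_j)|^beta` over pairwise-complete entries
with `beta = 6` (the conventional unsigned soft power; unsigned pools
anti-correlated regulation into one module, which is what the downstream
set-enrichment wants). The topological overlap measure and its
average-linkage dendrogram follow the standard WGCNA construction.

**Cut rule.** The tree is cut at a fixed dissimilarity height, default
`cut_height = 0.9` on 1 − TOM, keeping clusters of at least `min_size`
(default 10); everything else is label 0 (unassigned). A quantile-based cut
is exposed (`cut_height = NULL`, `cut_quantile`), but it is not the
default: with a soft power of 6 the dissimilarity distribution of a
realistic panel piles up within ~1e-3 of 1.0, so any low quantile of it
lands above typical between-noise merge heights and fuses the whole tree
into one cluster. A fixed cut at 0.9 sits in the wide valley between
within-module dissimilarities (about 0.5 at r ~ 0.9) and the noise shoulder
(> 0.99), and is insensitive to panel size. Dynamic tree cutting was
rejected for determinism.

The module eigenfeature is the first right singular vector of the
standardized member profiles, sign-oriented to correlate positively with
the module's mean profile and unit-normalized.

**Three-axis association.** Feature-level differential abundance between
the phenotype classes uses the matrix moderated t with BH across the
analyzed universe. The contract "module/set <-> phenotype edges from
moderated t on member features" leaves open how feature-level results
aggregate to one edge; this package forms the edge by hypergeometric
enrichment of the direction-consistent significant features within the
module or set (BH over all such tests, q < 0.05), which inherits the
member-level volcano semantics while yielding a single edge q-value.
Eigenfeature-level testing is exposed as `level = "eigenfeature"` for users
who prefer a per-module test. Guilt-by-association then emits, for every
significant (set, module) edge, the module members significant in the same
phenotype direction that are *not* already set members — the "in
databases−" candidates.

## Outlier calling

A feature observed in at least `min_observed = 10` lines is called in line
s when its value exceeds the *leave-one-out median* of the other observed
lines by `log10(threshold_fold)`. The median (not mean) reference is robust
to the outlier itself; the default `threshold_fold = 5` sits below the
7-10-fold regime of typical strong driver events so those are always
called. Features detected in exactly one line are separately flagged
`detection_only` when the single value exceeds the matrix's 25th intensity
percentile (single detections at noise level are not evidence of a
driver). Calls are shift-invariant by construction. The incidence matrix is
clustered by average linkage on Jaccard distance on both axes; co-outlier
groups (same cluster, sharing an outlier line) surface substrate sets of
hyperactive kinases.

## Drug-association models

The correlation screen tests every feature-drug pair with at least
`min_n = 7` pairwise-complete observations — pairs below that are absent
from the output entirely, not marked insignificant — with BH within each
drug. Elastic-net models (glmnet, mixing `alpha = 0.5`, penalty by
cross-validation with the 1-SE rule and seeded folds) use, per drug, only
cell lines with observed response and only features fully observed across
those lines; marker frequency counts drugs with a nonzero coefficient of a
given sign, mirroring "most common sensitivity marker" semantics.

The metabolic subset screen enumerates all C(14, 3..7) = 9,802 subsets and
ranks them by cross-validated Pearson r of a regression forest. No
random-forest package is part of the supported dependency set, so the
package ships a compact bagged-CART regressor (`bag_forest`): exhaustive
variance-reduction split search, `mtry` defaulting to all features (the
standard regression-forest choice; bootstrap resampling provides the
randomness), minimum 3 samples per leaf-side, 500 trees by default (tests
and screens scale this down). It is adequate for the <= 7-feature,
tens-of-lines panels it serves and is not intended as a general-purpose
forest.

## Sparse multiblock PLS

Each component solves, by NIPALS iteration with soft-thresholding: block
weights `w_b = S(X_b'u, lambda_b)` normalized; block scores `t_b = X_b
w_b`; block combination weights `a_b` proportional to
`max(cov(t_b, u), 0)^2`, summing to 1; super score `t = sum_b a_b t_b`
(unit-normalized); drug weights `q = S(Y't, lambda_y)` normalized; drug
score `u = Yq`; until `t` moves less than `tol = 1e-8`. Blocks and Y are
column-standardized, zero-filled at missing entries (logged), and deflated
on `t` between components. Sign indeterminacy is resolved by making each
component's largest-magnitude drug weight positive, so fits are bit
reproducible.

Three numerical choices depart from the plainest reading of those update
rules, each forced by observable failure modes on the synthetic panels and
each preserving the lambda = 0 limit (which reduces exactly to PLS-SVD of
X'Y, a tested invariant):

* **Squared block-combination weights.** Weights proportional to the plain
  covariance stabilize "mixture" components in which an uninformative block
  contributes selected-noise scores at ~50% weight; squaring suppresses the
  weak block and lets iterations purify toward the block carrying the
  signal.
* **Correlation-scale thresholds.** `lambda` values are minimum |Pearson r|
  levels with the current latent score (the cross-covariance vector is
  divided by `(n−1) sd` before thresholding), not fractions of the vector
  maximum. This makes them interpretable, independent of n and block size,
  and immune to the extreme-value statistics of the maximum. Defaults:
  `lambda_block = 0.4` (above the largest |r| a few hundred null features
  produce at n = 60), `lambda_y = 0.3` (a drug must share modest
  correlation with a component to join its cluster).
* **Dense warm start and multi-start.** Each component first converges the
  lambda = 0 iteration, then switches sparsity on, so thresholding prunes a
  converged covariance direction rather than the raw initialization. The
  initialization set comprises the first three left singular vectors of the
  residual Y plus the two largest-norm drug columns; when two drug clusters
  have near-equal strength the singular vectors are arbitrary rotations
  (mixtures) of the cluster factors, while the covariance objective of a
  pure component always exceeds a mixture's, so the run with the largest
  `|t'u|` at convergence is kept.

A component whose weight vector is entirely zeroed is an explicit
"over-sparsified" error naming the block; `on_oversparse = "truncate"`
instead stops extracting and returns the components found, which is the
right behavior when mining an unknown number of drug clusters.
`report_clusters()` reports as cluster members drugs whose |q| is at least
25% of the component's largest |q| (tiny residual weights are effect-size
noise, and the cluster plots the analysis mimics size nodes by |q|), and
drug-drug edges are pairwise-complete Pearson correlations of the observed
sensitivity columns. `select_sparsity()` chooses penalties by
cross-validated Y-reconstruction error with a 1-SE preference for sparser
grids.

## The synthetic world

`sim_config()` defaults describe the stated desk-scale panel: 60 cell lines
in 6 tissue groups, 300 proteins and 400 p-sites (the real panels are ~30x
larger; everything scales linearly), baseline abundances N(7.0, 0.8) log10
units (matching printed extremes of 10^5.9 to 10^10.1), tissue-group shifts
N(0, 0.1) per feature, measurement noise N(0, 0.12) (~30% CV), and logistic
MNAR missingness with midpoint 5.5 and steepness 4 — a few percent missing
overall, concentrated in low-abundance features, so high-abundance planted
features are essentially complete as real well-quantified markers are.

Planted structure, each in its own RNG stream derived from the master seed
(adding outputs never perturbs existing ones):

* **Correlation modules**: three 20-feature blocks (two pure, one also
  phenotype-shifted) driven by truncated-normal latent factors with loading
  0.15 and member noise 0.05, i.e. within-block r ~ 0.9. The tight member
  noise models abundant co-regulated proteins and, importantly, bounds any
  single line's structural deviation well below the 5-fold outlier
  threshold, so module structure and outlier calls can coexist in one
  panel. Module features carry no tissue shifts: the block is defined
  purely by its factor.
* **Active pathway**: pathway 1's 15 member proteins shifted +1.0 log10 in
  tissue group 1 (the "mountain" regime).
* **Active kinases**: each kinase is active in one distinct cell line; its
  protein, two own p-sites and ten substrate sites are shifted +1.0 there.
  These elevations are genuine single-line outliers, so the ground truth
  records them in `elevated_positions` alongside the dedicated
  `outlier_positions`; outlier precision is scored against the union.
* **Outliers**: n_outliers p-site carriers set, after missingness, to
  `median(observed others) + outlier_shift`, making the planted excess
  exact in the emitted matrix.
* **Drugs**: sensitivity = `marker_effect x mean(signed marker z) + N(0,
  0.5)` on the z scale, 10% of drug/line pairs unmeasured, emitted in both
  orientations. Two 6-drug clusters share marker sets (cluster 1: three
  protein markers; cluster 2: three p-site markers, so the multiblock model
  must use both blocks); all remaining drugs share one common protein
  sensitivity marker (the SLFN11-like regime) plus private markers with
  alternating signs. Marker features get high baselines (N(7.5, 0.3)), as
  real quantifiable markers do.
* **Phenotype**: 25% of lines positive (MSI-like); the differential module
  is shifted +0.5 in positive lines, and pathway 2 annotates 15 of its 20
  members, leaving 5 as planted guilt-by-association discoveries.

What the generator does **not** emulate: peptide-level structure (charge
states, missed cleavages), batch effects, heavy-tailed intensity noise,
correlated drug assay noise, dose-response curve shapes, and panel-scale
feature counts. A green recovery test therefore establishes that the
algorithms recover the planted statistical structure at realistic
signal-to-noise — not that they would reproduce any particular biological
finding on real panels.

## Degenerate inputs and determinism

Constant features give flagged UNDEFINED correlations and FLAT activity
rows; all-missing features are a named error in module detection (callers
drop them); empty columns are a named error in median centering; duplicate
ids are rejected by every reader with the offenders listed. Waterfall ties
break lexicographically; landscape and SMBPLS sign conventions are fixed;
all stochastic steps (CV folds, forests, the generator) take explicit seeds
kept within 32-bit range. The pipeline writes artifacts write-once and
records md5 checksums, parameters and seeds in a manifest; rerunning the
same configuration reproduces identical checksums.

## Known limitations

* The activity score, normalization chain, outlier thresholds and network
  cut are documented stand-ins for procedures whose originals live in
  supplementary material not reproduced here; each sits behind a narrow
  interface and is flagged as a substitution point.
* The SMBPLSR update rules are stated exhaustively above and claim only
  this contract; the original algorithm's deflation and sparsity operator
  may differ.
* The moment-matching moderated-t prior assumes a common residual df per
  fit; features with unusual missingness patterns are shrunk with the modal
  df's prior.
* At 40 or fewer cell lines the drug-cluster components lose power
  noticeably (the test suite's small fixtures show this); the defaults are
  tuned for ~60-line panels.
* `bag_forest` is a minimal regressor for tiny panels, not a general
  random-forest replacement.
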