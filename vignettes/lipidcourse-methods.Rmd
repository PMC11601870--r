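---
title: "Methods: multi-tissue time-course lipidomics with lipidcourse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue time-course lipidomics with lipidcourse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidcourse)
```

## The analysis problem

`lipidcourse` implements the statistical workflow for an endurance-training
lipidomics study design: eight tissues and plasma collected from male and
female rats after 1, 2, 4 or 8 weeks of treadmill training or a sedentary
control period (groups SED, 1w, 2w, 4w, 8w; n = 5 animals per sex per
group), profiled by untargeted LC-MS in both electrospray polarities plus a
targeted oxylipin/N-acylethanolamine assay. The package covers the path from
raw feature tables to biology-level summaries: nomenclature parsing and
lipid-set construction, quality control and normalization, internal-standard
semi-quantification, moderated time-course contrasts, rank-based lipid-set
enrichment, fuzzy trajectory clustering, and cross-tissue correlation
networks with co-expression modules. The real study's data are not required:
a synthetic-study generator reproduces the design with planted, known
effects, and every downstream stage is validated against that ground truth
or against independent oracles.

## Nomenclature and lipid sets

Shorthand names are parsed with a small grammar: a class token from an
editable vocabulary (seeded with RefMet-style subclasses; cholesteryl and
sitosteryl esters kept separate), chains in `C:D` notation separated by `/`
(sn-position known) or `_` (unknown), `O-`/`P-` prefixes for alkyl/alkenyl
ether linkages (which promote the class to its `O-` form), `d`/`t` sphingoid
prefixes, the acyl-only ceramide shorthand `Cer C16:0` (one N-acyl chain on
an unspecified, conventionally d18:1, base), and `(d7)`-style deuterium
labels marking spiked internal standards. Sum-composition names
(`"PC 40:6"`) yield no chain list; for single-chain classes
(lysophospholipids, acylcarnitines, sterol esters, free fatty acyls) a
single `C:D` token *is* the resolved chain. When chains are present the
totals always equal the chain sums, and chain-resolved names round-trip
through `format_lipid_name()` bit-for-bit.

Lipid-class sets (minimum size 10, unknowns excluded) drive the enrichment
stages. Triacylglycerols are additionally binned by saturation (0 / 1 / >= 2
double bonds) and total carbons: short-chain C30-48, medium-chain C49-52,
long-chain C53-55, very-long-chain C56-60. The DHA:ARA machinery selects
chain-resolved PC/PE species carrying a 20:4 or 22:6 chain next to a
16:0/16:1/18:0/18:1 anchor; sum-level species cannot be assessed and are
reported as skipped rather than guessed at via total composition.

## The synthetic-study generator

`simulate_study()` is first-class, tested code, not a fixture. Peak areas
follow a lognormal model: for lipid *i* and animal *a*,
`area = 2^(baseline_i + effect_i(sex_a, group_a) + loading_i * latent(a) +
noise) * drift(order)`, with

* `baseline_i ~ N(18, 2)` on the log2 scale (adipose TAG raised ~7 log2
  units so TAG dominates WAT-SC/BAT mass, as in adipose tissue);
* within-cell noise SD 0.25 log2 (~19% CV, a typical untargeted lipidomics
  figure) — **planted effect sizes are expressed as multiples of this SD**;
* per-animal latent factors for a TAG block and a phospholipid block
  (loadings 1.0 and 0.8 x noise SD). These create realistic co-expression
  structure for the module and phenotype stages; for any single lipid's
  group contrast they act as ordinary animal-level noise, so marginal test
  calibration is unaffected (measured null p < 0.05 fractions: 0.042-0.057).
  They do correlate tests *within* a block, which widens the seed-to-seed
  spread of discovery counts — exactly as shared biology does in real data;
* per-feature linear drift with slope SD 0.002 per injection, pooled-QC
  injections at every tenth position (the pooled sample is the equal-part
  mix of all study extracts), blank injections at the ends, and
  deuterated class standards spiked at fixed concentrations;
* intensity-dependent missingness: the logit of the missingness probability
  falls linearly in the cell's log2 abundance, calibrated so the overall
  missing fraction matches `missing_rate` (default 5%);
* a small set of unannotated junk features built to fail the blank-ratio or
  QC-CV filters, so the QC stage has real work;
* phenotypes (body weight, %fat, NEFA, glycerol, glucose, leptin, VO2max,
  max running speed, adipocyte area/count) from sex-specific temporal
  templates — males losing fat and gaining fitness strongly, NEFA and
  glycerol rising early then returning — with %fat, NEFA, leptin and
  adipocyte area linearly linked to the TAG latent factor and VO2max
  negatively linked to the phospholipid factor, so module-phenotype
  correlations have planted signs.

The default effect panel encodes the study's qualitative findings as
standardized sizes: a biphasic TAG response (up at 1-2w, down by 8w) in
liver, adipose and muscle; an early acylcarnitine rise in lung, liver and
plasma mirrored by a fall in heart; a female-higher baseline for
DHA-containing phospholipids; and a male-only heart response. Peak sizes of
3-3.5 noise-SD units (~1.7-1.8x fold changes) were chosen so that roughly
the reported share of lipids in the affected tissues is recoverable at 5%
FDR; weaker panels (peak 2.5) leave almost everything below the BH
threshold at n = 5, which emulates the study's headline recovery poorly.

What the generator does **not** emulate: retention-time structure, adducts
and in-source fragments beyond simple cross-mode duplicates, batch blocks,
heteroskedastic per-lipid CVs, tissue-specific class repertoires beyond the
adipose TAG share, or realistic inter-class concentration profiles. Passing
tests therefore demonstrate correctness of the statistical machinery under
a faithful *design*, not instrument-level realism.

## Preprocessing

Drift correction fits, per feature, an OLS line to pooled-QC areas against
injection order and divides all areas by `fit(order)/fit(ref)`; the
reference is the fitted value at the median QC order, which keeps corrected
areas on the raw scale (the anchor point is otherwise arbitrary). Features
with fewer than three observed QCs, or whose fit goes nonpositive at a
study injection, pass through flagged. QC filtering removes features below
5x the blank background (mean blank area, missing treated as 0 — "background
signal" left unspecified is taken as the mean), observed in under half the
QCs, or above 30% QC CV (CV on raw areas). Features annotated in both ESI
modes keep the lower-CV occurrence, ties to positive mode.

Normalization order matters and is fixed: log2, then per-feature
standardization to median 0 / SD 1, then per-sample median subtraction,
separately per mode, then row-concatenation. Two consequences are worth
knowing. First, feature standardization folds any group effect into the
scaling denominator, so features with real effects end up with *smaller*
residual variance than null features on the standardized scale; the
empirical-Bayes prior (estimated mostly from nulls) then shrinks their
variance upward, costing some power — an intrinsic property of
standardize-then-moderate workflows. Second, the per-sample median assumes
most features are unchanged *within a mode*; a direction-imbalanced signal
confined to one polarity shifts the medians and is partially absorbed. The
recovery analyses in the tests plant direction-balanced effects within each
mode for this reason.

Sample outliers are reported (never auto-removed) by two rules: median
inter-sample Pearson correlation on raw intensities below 0.75, or a score
beyond 3x IQR on one of the first three PCs (each retained only if it
explains >= 7.5% of variance; PCA on log2 feature-standardized data).
Cross-tissue PCA keeps lipids seen in >= 5 of the 9 compartments,
min-imputes, and median-centers samples only — feature scales are part of
what distinguishes tissues. A one-way method-of-moments variance-component
estimator attributes PC-score variance to tissue; on synthetic studies the
tissue share of PC1-PC4 comes out above 99%, matching the magnitude such
designs produce.

## Quantification

Concentrations are peak-area ratios to the class- and mode-matched
deuterated standard times its spiked concentration, scaled by extract
volume over sample amount (tissue: 10 mg in 400 uL, units ug/mg; plasma:
25 uL in 75 uL, units ug/uL). Class-level outliers are removed per
(tissue, mode, class): samples whose class concentration sum deviates from
the median by more than 5 raw (unscaled — deliberately, as "median absolute
deviations" reads literally) MADs lose the whole class; WAT-SC uses 15 MADs
because its dominant TAG pool is legitimately more dispersed. A zero MAD
with any deviation flags the deviating samples.

Missing cells (removed classes plus assay missingness) are imputed by
rank-2 principal-component completion: scores and loadings are fitted by
alternating least squares whose inner products skip missing cells, started
from the SVD of the mean-completed matrix. The components are fitted
jointly rather than sequentially deflated: sequential deflation (and a
centered EM variant) converge to non-exact fixed points even on exactly
rank-2 data, while the joint fit recovers well-conditioned low-rank
matrices to machine-level accuracy. Negative fills revert to the feature's
observed mean; observed cells are never modified. Rank 2, tolerance 1e-9 on
the residual-sum change, 500 iterations.

Targeted analytes are calibrated by OLS standard curves rejected below
R^2 = 0.9 (negative back-calculations floored at 0), filtered at 100%
concentration CV / 10% retention-time CV in pooled QCs / 20% missingness,
and KNN-imputed (k = 10 by default — the cited algorithm's usual default,
as no k is specified; with fewer than k candidate neighbours the feature
mean is used and flagged).

## Differential analysis

Per tissue and sex, a means model over the five groups is fitted by OLS per
lipid (lipids sharing a missingness pattern share the normal-equation
inverse). The variance prior is method-of-moments on log variances:
`trigamma(d0/2) = var(e) - mean(trigamma(df/2))` with
`e = log s^2 - digamma(df/2) + log(df/2)`, and `s0^2` from `mean(e)`;
non-positive right-hand sides give `d0 = Inf`. Moderated t uses
`s_post^2 = (d0 s0^2 + df s^2)/(d0 + df)` on `d0 + df` degrees of freedom;
the moderated F whitens the contrast estimates by the Cholesky factor of
their unscaled covariance — the mean of squared moderated t over the
orthogonalized contrasts — on `(k, d0 + df)`. At `d0 = 0` everything
reduces exactly to classical OLS t-tests, and the implementation agrees
with `limma::eBayes` to 1e-8 on shared fixtures (limma is a cross-check,
never the computation path). Contrast families: per-timepoint vs SED, the
overall training F (the definition of a "training-responsive" lipid), naive
male-female differences per group, and difference-of-differences
sex-dimorphism contrasts from a joint two-sex fit. BH adjustment is applied
within each family; targeted assays are selected on raw p < 0.05.

When scoring recovery against planted truth, one contrast family is
evaluated at a time. A lipid-level union over the four timewise families
multiplies the lipid-level false-discovery rate roughly fourfold by
construction and is avoided.

## Enrichment

The enrichment score is the classical weighted running-sum statistic
(weight exponent 1, hit increments proportional to |metric|, uniform miss
decrements, deterministic tie-break by feature id), computed in closed form
from the sorted hit positions and verified against brute-force evaluation
and `fgsea::calcGseaStat`. Significance uses a plain permutation null of
random same-size feature sets (the cited adaptive multilevel scheme is
replaced by the direct estimator; 10,000 permutations is the reference
setting, scaled down where a sweep over many rank lists is run):
`p = (1 + #{|null ES| >= |ES|}) / (1 + n_perm)`. The magnitude comparison
matches the two-sided extremum statistic; sign-conditional counting
double-counts the sign selection and inflates the null p < 0.05 fraction to
about 0.11. NES divides the ES by the mean |null ES| of matching sign.
F-score rankings (all nonnegative) use positive-only scoring.
Over-representation of a query (cluster cores at membership >= 0.5, module
hubs at |kME| >= 0.7) in class sets is the one-sided hypergeometric tail
against all named lipids, BH across sets.

## Trajectory clustering and logFC correlations

Clustering input is the z-scored matrix of (sex x group) mean profiles.
Fuzzy c-means uses the standard alternating updates with fuzzifier
m = 1.5, k-means++-style seeding, 10 restarts keeping the lowest objective,
and convergence on centroid shift < 1e-8; a point coinciding with a
centroid takes membership 1 there. The cluster-number diagnostic is the
minimum pairwise centroid distance over a candidate range, with the elbow
at the maximum forward second difference — the last c before the curve
collapses (which happens once c exceeds the number of distinct temporal
archetypes); a relative drop under 20% flags the choice low-confidence.
c = 9 is the documented default for full-scale runs, but on synthetic
studies with a handful of planted archetypes the diagnostic honestly
prefers 2-3, and the caller decides.

LogFC trajectories prepend an exact 0 baseline to the four timewise logFC
values; 5-point Pearson correlations compare males vs females per tissue
and tissue pairs per sex, with zero-variance or incomplete trajectories
flagged missing rather than set to 0.

## Networks and modules

The sample-level network correlates every (tissue, lipid) pair over animals
matched by id within a sex, Bonferroni-adjusts over all tested pairs, and
keeps adjusted p < 0.05 edges, split into intra- and inter-tissue scopes
with per-node degrees and signed tissue-pair counts. Pairs with fewer than
4 complete observations are skipped and counted.

Signed TOM: adjacency `a = ((1 + r)/2)^beta` (beta = 6 by default;
per-tissue values belong to configuration), topological overlap
`(A^2 + a)/(min(k_i, k_j) + 1 - a)` with unit diagonal. Identical profiles
attain TOM = 1 exactly only in a fully concordant background — with the
standard formula a duplicated pair in an arbitrary background gives
`(sum a^2 + 1)/(sum a + 1) < 1`; the tests exercise the exact case on a
concordant background and the [0, 1] bounds elsewhere. Modules come from
average-linkage clustering of 1 - TOM with a static cut chosen to maximize
weighted modularity over all dendrogram partitions (unassigned lipids are
scored as singleton communities so a large grey pool is penalized; this
replaces the cited dynamic tree cut, whose internals live in the original
package), a minimum size of 10, and iterative merging of modules whose
eigenprofiles correlate above 0.85. Eigenprofiles are unit-norm first
principal components of the standardized module submatrix, oriented to
correlate positively with the module mean. kME is the lipid-eigenprofile
correlation; hubs use the closed threshold |kME| >= 0.7. Module-phenotype
edges are reported at raw p < 0.05 (the figure-level convention), and the
Pearson kernel is used throughout (the biweight midcorrelation alternative
is a configuration stub, not the default).

## Problem sizes and numerical choices

The packaged analyses run at the study's own design scale: 9 compartments x
2 sexes x 5 groups x 5 animals and ~600 lipids per tissue (~510 after QC),
which takes about two minutes end to end on one core. Statistical
calibration and recovery checks use one-tissue studies (250-550 lipids) over
10-20 seeded replicates; oracle checks use exhaustively enumerable fixtures
(10-feature rankings, margins <= 30 tables). All randomness flows from a
single integer seed per run — identical seeds give byte-identical results
objects, which the tests assert by serializing two full runs.

Known limitations: the generator's homoskedastic noise makes the
empirical-Bayes prior degrees of freedom come out large (real data's
variance heterogeneity would moderate less aggressively); fuzzy clustering
at c = 9 on data with few archetypes yields mostly empty cores; the
network stage tests all pairwise correlations without sparsification, which
is quadratic in the number of (tissue, lipid) nodes; and the ISTD fallback
mapping ("closest structure and retention time") is configuration the user
must supply for classes without their own standard.
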