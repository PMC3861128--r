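---
title: "Methods: cross-drug epigenomic discovery of alcohol-tolerance genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-drug epigenomic discovery of alcohol-tolerance genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstol)
```

## The analysis in one paragraph

Sedative drugs such as benzyl alcohol and ethanol induce functional
tolerance in *Drosophila* — faster recovery from sedation after a prior
exposure — and leave genome-wide marks of histone H4 acetylation change in
neural tissue. `crosstol` implements the cross-drug strategy for turning
those marks into candidate tolerance genes: per-probe log2 difference tracks
(drug-treated IP over control IP) from two-channel tiling arrays, peak
calling calibrated by permutation against randomized tracks at an FDR below
0.05 with an enrichment-score filter, assignment of peaks to genes within a
bidirectional 500-bp window of the gene region (5′-most TSS to 3′-UTR end),
intersection of the two drugs' ranked gene cohorts (the shared-response
genes), co-expression clustering of the common genes across environmental
treatment conditions, annotation-term enrichment per cluster with Fisher
exact and EASE scores, and behavioral validation statistics built on
five-parameter Richards fits of sedation-recovery curves. A synthetic-data
module generates every input with known ground truth, so the full pipeline
is testable at desk scale with no array download.

## Signal model and normalization

Raw two-channel intensities are stabilized with a generalized-log
(arsinh-type) transform, `glog2(x) = log2((x + sqrt(x^2 + c^2))/2)`, with
the channel's MAD as the scale `c`; the probe value is the glog difference
of IP over input. At high intensity the glog converges to `log2`, so a
constant true ratio of 2 maps to a value of 1 exactly (the per-channel MAD
scales cancel); near zero the transform stays finite, taming the variance
blow-up of low-intensity log-ratios. By default the two channels are
robustly calibrated to each other so the output track has median 0
(`calibrate = TRUE`); disable calibration to read absolute channel ratios —
the two behaviors cannot coexist, since calibration removes exactly the
constant ratio that the uncalibrated transform reports. Masked probes (both
channels zero) are dropped, never interpolated: interpolation fabricates
evidence inside peaks. Replicate difference tracks are averaged probewise;
between-array normalization shifts each track's median to the grand median.
Array-quality normality checking (`track_normality_qc()`) is a *flag*, not a
filter — silent sample dropping is hostile to reproducibility.

## Peak calling and the permutation FDR

A candidate peak is a maximal run of probes at or above a threshold, with at
most `max_gap = 150` bp between consecutive qualifying probes and at least
`min_probes = 4` of them. Both defaults are set for a ~55 bp median probe
spacing: 150 bp tolerates one or two failed probes inside a domain, and four
probes (~200 bp) is the smallest span we are willing to call a domain. Peak
*magnitude* is the 10% trimmed mean of member-probe values, robust to a
single aberrant probe.

The null model permutes probe values across positions, preserving the value
multiset exactly while destroying all spatial structure; a block-permutation
option exists for locally correlated probe noise. Over a grid of 20
quantile-spaced thresholds (90th to 99.9th percentile of track values),

```
fdr(t) = min(1, mean null peak count at t / max(1, observed count at t)),
```

monotonized by a running minimum so a stricter threshold is never reported
as less reliable. `select_peaks()` takes the least stringent threshold with
`fdr < 0.05` and then applies the enrichment-score filter at 0.5.

**Enrichment score.** The score rescales the peak *summit* (its maximum
member-probe value) between the track median (0) and the track maximum (1).
An earlier design used the trimmed-mean magnitude in place of the summit and
failed its own recall goal: the track maximum is an extreme order statistic
of single probes, so a domain's *average* — roughly the effect size — sits
near half of it almost by construction, and calls hover uselessly around the
0.5 cutoff. Summit and track maximum are order statistics of the same
probe-level distribution, which makes the score self-calibrating across
noise levels; a peak culminating at the track maximum scores exactly 1.

Only acetylation *gains* are called by default (negate the track for
losses), matching the analysis the pipeline is designed for.

## Gene assignment and the cross-drug intersection

Coordinates are 0-based half-open internally; GFF3 (1-based inclusive) and
BED (0-based half-open) convert at the I/O boundary, which removes all
off-by-one ambiguity from the 500-bp rule. Isoforms are collapsed to one
span per gene (5′-most start, 3′-most end) before mapping. A peak is
assigned to the gene(s) whose span lies within 500 bp (inclusive),
bidirectionally and strand-blind; among equally distant genes the one
nearest the peak midpoint wins, and exact midpoint ties assign to *all*
tied genes with a flag — silently dropping a true target would corrupt the
intersection. Unassigned peaks stay visible with `gene_id = NA`. Cohorts
rank genes by their best peak magnitude (ties broken alphabetically for
determinism), and the intersection reports `|A∩B|` against the mean cohort
size as well as against each cohort separately, since the two drugs'
cohort sizes need not match.

## Co-expression clustering

Expression rows are scaled to unit sum of squares (a separate factor per
gene, recorded and idempotent). Similarity is the centered Pearson
correlation; the clustering distance is `1 − r`. A one-dimensional SOM
(default 10 nodes, correlation matching, bubble neighborhood shrinking from
k/2 to 0.5, learning rate decaying linearly 0.02 → 0.001 over 20,000
presentation steps) is trained first and used *only* to order the leaves of
the complete-linkage tree where the topology permits — cluster membership
never depends on it. The cut level `k` is a user parameter (default 7):
which count of clusters is "distinct" is a judgment call, so
`cohesion_scan()` reports per-cluster cohesion over a k-range for
inspection. Cohesion is the mean pairwise centered Pearson r over member
pairs — the conservative reading of a single per-cluster r (correlation to
the cluster centroid is available via `method = "centroid"`); clusters with
cohesion above 0.65 are flagged highly correlated, and singletons are
flagged as undefined rather than scored.

## Enrichment scores

For a cluster of `n` genes with `k` carrying a term that annotates `K` of
`N` universe genes, the Fisher exact p-value is the hypergeometric upper
tail `P(X ≥ k)`, and the EASE score is the same tail after removing one
annotated gene from the cluster (`P(X ≥ k−1)`, equal to 1 when `k ≤ 1`) — a
jackknifed, uniformly conservative variant that penalizes single-gene
overlaps in small clusters. Annotation sets come from local GMT files; the
default background universe is all genes in the annotation table, and no
multiple-testing correction is applied by default (enrichment tables of this
kind conventionally print raw scores; Benjamini–Hochberg is behind a flag).
The fuzzy term-grouping of hosted enrichment services is out of scope: the
per-term scores are what the pipeline needs.

## Behavioral tolerance statistics

Recovery of a fly population from sedation is fit with the five-parameter
Richards curve `Y(t) = A + (K − A)/(1 + exp(−B(t − M)))^(1/ν)`. `t50` is
defined as the time at which the *fitted curve crosses absolute 50%
recovered* — not the midpoint between asymptotes — because assays score
populations out of 100% and their curves saturate near 100%; it is solved in
closed form by inverting the curve (a bisection cross-check agrees to 1e−9
minutes). Five-parameter sigmoids are multi-modal, so fitting uses
Levenberg–Marquardt from a coarse 8-point start grid over (M, B, ν) with
A = 0 and K at the observed maximum, keeping the best SSE.

The tolerance magnitude of a line is `Δt50 = t50(control) −
t50(pre-exposed)`; positive values mean the pre-exposed group recovered
faster. Its SE prefers vial-level variability (SEM of per-vial t50s from
vial-restricted fits seeded at the pooled optimum) over the delta-method SE
of the pooled fit: cumulative recovery counts are strongly autocorrelated
within a vial, so least-squares SEs that assume independent residuals are
several-fold optimistic — in null simulations they produced 2-SE
exceedances at rates far above nominal, while vial-level SEs behave like a
t statistic with the expected few degrees of freedom. For cross-line
inference, per-vial magnitudes (control vial j minus pre-exposed vial j;
pairing keeps them independent) enter a one-way ANOVA with one-sided
Dunnett many-to-one comparisons against the reference line; a line is
called `reduced` when its magnitude is significantly lower at α = 0.05. In
200-replicate null simulations the false "reduced" rate stays at the
nominal level.

qPCR quantification uses ΔΔCt with the efficiency fixed at perfect doubling,
per-gene Dunnett comparisons on ΔCt against the untreated control, and
array-vs-qPCR cross-validation as the Pearson correlation between per-locus
qPCR ratios and the mean array signal of the 7 probes nearest each primer
locus (ties toward the lower coordinate; a center beyond the grid takes the
nearest 7).

## What the synthetic data emulate — and what they do not

The generators reproduce the statistical structure the analysis relies on,
with ground truth emitted alongside every dataset:

* **Tiling arrays** — a single chromosome tiled at a *median* 55 bp spacing
  with ±20% uniform jitter (downstream code must not assume a regular
  grid); a baseline acetylation elevation over each gene's TSS-proximal
  kilobase present in every condition; planted gain domains at the spiked
  genes (A-only, B-only, shared — the shared set is exactly what the
  intersection should recover); independent Gaussian probe noise per
  replicate, two biological replicates per condition by default.
* **Expression** — block-correlated profiles: one latent condition profile
  per cluster (latents mutually orthogonal, so between-cluster r ≈ 0),
  with noise solved from the target within-cluster correlation
  (`sd = sqrt(1/r − 1)`), plus per-gene scale and offset that Pearson
  correlation ignores. 21 conditions by default.
* **Recovery curves** — each fly's recovery time drawn by inverse-transform
  sampling from the Richards curve itself, so curve fitting is internally
  consistent with the generator and parameter recovery is a sharp test;
  counts accumulate per vial at the observation interval (5 min default).
* **qPCR** — Ct values constructed so `2^−ΔΔCt` recovers the specified fold
  in expectation.

Not emulated: dye bias, spatial array artifacts, probe GC effects, real
genome sequence, sedation-onset kinetics, or dose–response. Passing tests
therefore demonstrate the *statistical machinery* — FDR calibration,
distance-rule mapping, cluster recovery, t50 recovery, type-I control —
under the assumed noise model, not robustness to platform-specific
artifacts.

**Domain density.** The simulation study plants 100 one-kilobase domains of
log2 effect 1.0 (probe noise sd 0.5) on a 2 Mb chromosome — 5% of probes in
true domains. Density matters because the permutation null inherits the
track's value multiset: when planted signal covers a large share of probes
(e.g. 100 domains on only 500 kb, 20%), the permuted tracks are saturated
with signal-derived values, the estimated FDR becomes very conservative,
and the selected threshold climbs above the effect size — false discovery
stays controlled but recall collapses. At a few percent coverage, which is
far closer to a real genome where candidate domains are a small fraction of
the tiled sequence, the caller achieves both: across 20 datasets the mean
realized false-discovery proportion is well under the 0.05 cutoff and over
90% of planted domains are recovered.

## Problem sizes and numerical choices

The shipped simulation sizes are chosen to exercise each method at the
scale its statistics need: 20 datasets × 36,000 probes × 100 permutations
for the FDR study; 144-gene × 21-condition expression matrices (and 50
seeds of 48-gene matrices for recovery scoring); 50 parameter-recovery and
200 type-I behavioral replicates at 3 vials × 12 flies. Row normalization
is exact to 1e−9; t50 inversion to 1e−9 minutes; the hypergeometric tail
uses R's `phyper` (checked against exhaustive enumeration for all feasible
configurations up to N = 30). Degenerate inputs fail loudly: all-zero
channels, zero-variance profiles, all-zero expression rows, curves that
never cross 50%, infeasible count configurations, and mismatched probe
grids are errors or flagged results, never silent fixes. All randomness is
seed-controlled; identical seeds give byte-identical pipeline outputs.

## Known limitations

* The permutation null destroys local autocorrelation; with strongly
  correlated probe noise the simple permutation is anticonservative and the
  block-permutation option should be used.
* The FDR is estimated per track (genome-wide over supplied probes), not
  per array batch.
* Whether replicates are averaged before peak calling (default) or called
  separately and intersected is a genuine degree of freedom; both are
  available, and the default follows the averaging convention.
* Cohesion via mean pairwise r decreases slightly with cluster size for a
  fixed latent correlation; comparisons across very different cluster sizes
  should use the centroid variant.
* Richards fits on vials with few flies can fail to cross 50% (t50
  undefined); such vials are flagged and excluded from vial-level variance,
  which can reduce the effective degrees of freedom below the vial count.
* Non-recovering flies are right-censored observations that the least
  squares fit treats only through the upper asymptote; a survival-analysis
  treatment is out of scope.
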