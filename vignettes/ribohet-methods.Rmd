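---
title: "ribohet: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribohet: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribohet)
```

## The model

ribohet assumes a protection model: an RP incorporated into the ribosome
shields nearby rRNA from the RNase digestion step of Ribo-seq, so a change
in that RP's incorporation between two conditions perturbs the positional
abundance of sequenced rRNA fragments specifically around the RP's contact
points. The pipeline therefore needs three ingredients: a map from RPs to
the rRNA positions they touch (from a 3D structure), a per-position measure
of fragment abundance change (a count model), and a statistic that asks
whether large changes cluster in a given RP's contact set (set enrichment
with a spatial null).

Two caveats are inherent to the model and shape the interpretation of every
output. First, protection can cut both ways — extra protection can produce
*longer* fragments that are lost to size selection — so the method reports
that an RP's neighbourhood changed, never the direction of the
incorporation change. Second, structurally unresolved rRNA segments and RP
portions carry no distances and silently thin the contact sets.

## Coordinates

The selected rRNA variants (for human: one each of 28S, 18S, 5.8S, 5S,
totalling 7217 nt) are concatenated in a fixed, configurable order. Output
tables always report `rrna_id` plus a 1-based position; internally a 0-based
concatenated index is used, because the background-set construction treats
the concatenation as a circle and shifts positions modulo the total length.
`U`/`T` are collapsed at load time.

## The proximity matrix

`build_proximity_matrix()` computes, for every rRNA residue, the minimum
Euclidean distance to each RP chain, using the N1 base atom for RNA and the
alpha carbons for protein. Residues without an N1 atom are missing, not
dropped, and there is no fallback to another atom — one reference atom per
residue keeps the distance definition homogeneous. Every polypeptide chain
that is not an rRNA chain and not on an explicit deny-list counts as an RP;
the deny-list is where non-RP polypeptides (factors, tags) are excluded.
Before any distance is computed, the residue identities read from the
structure are checked against the reference sequence (>= 99% identity over
resolved residues by default); mismatch positions are recorded on the
result rather than silently used.

Cross-species transfer aligns each rRNA pair globally (match +2, mismatch
-1, gap open -5, gap extend -1 — standard nucleotide scoring; the contract
is the residue map, not one particular co-optimal alignment). Aligned target
residues copy the source distance; insertions between two aligned flanks are
linearly interpolated per RP *in distance space* (no 3D re-embedding);
insertions beyond the outermost aligned residue, or next to a flank with a
missing value, copy the single resolved side; between two missing flanks
they stay missing. Interpolated values therefore never leave the range of
their flanking values.

## Contact sets and their circular backgrounds

The contact threshold tau is the pooled 5th percentile of all present
matrix entries — one global cutoff for all RPs, which is what a single
published Å value implies (a per-RP percentile mode exists behind a flag
for sensitivity analysis). Quantiles use linear interpolation between order
statistics (type 7); the definition matters only in the second decimal.
Each RP's set keeps positions with d <= tau, closest first, capped at 5% of
the total rRNA length (360 for human). The percentile and the cap are
deliberately independent knobs even though both descend from the same 5%
rule. Ties in distance break by ascending concatenated position, so sets
are fully deterministic.

Backgrounds for the enrichment null are exact circular translations:
background *b* is the contact set shifted by `b * s` modulo the total
length. The shift `s` is a species preset (71 nt human, 67 nt mouse) when
the reference matches a bundled preset, otherwise `round(0.01 * L)`; the
presets take precedence because the published constants are only roughly 1%
of the rRNA length. Whether one shifts by `b * s` each time or re-shifts the
previous set by `s` is immaterial — the results are identical. When
`B * s` reaches `L` the collection wraps the full circle and a warning
points out that one background coincides with the contact set itself;
shifted positions falling outside the tested universe are simply dropped at
test time, mirroring what happens to the contact sets.

## Positional quantification

Coverage is full-read, per base: every counted alignment increments each
reference position under its aligned blocks. This matches the accepted
input types (nucleotide-level bedGraph tracks carry exactly this quantity)
and avoids committing to a 5'-end convention. Default read filters: drop
secondary, supplementary, unmapped, QC-fail and antisense records; *keep*
duplicates, because bona fide Ribo-seq fragments from an abundant rRNA are
expected to duplicate. A length window (e.g. 19–35 nt) is available but off
by default. Positions whose mean raw count across all samples falls below 1
are excluded before normalization; the cutoff is configurable and recorded
in the provenance file. Filtering precedes normalization because the
median-of-ratios estimator itself is what low-coverage positions would
distort.

## Differential abundance

Size factors are median-of-ratios over positions with non-zero counts in
every sample, without any rescaling afterwards — this keeps the classical
properties exactly (identical samples get factor 1; scaling a sample's
counts scales its factor). If no position is everywhere non-zero, factors
fall back to relative library size with a warning.

Dispersions are estimated per position as a MAP value: the NB likelihood at
the fitted group means combined with a log-normal prior centered on a
parametric mean–dispersion trend (`a0 + a1/mu`, gamma GLM fit to
method-of-moments estimates). The prior width is the spread of the
position-wise estimates around the trend in excess of their sampling noise
(`trigamma(df/2)`), floored at 0.25. The MAP form, rather than a direct
blend of the moment estimate with the trend, is what keeps the Wald test
calibrated at n = 3 + 3: raw moment estimates collapse to the floor whenever
the sample variance falls below shot noise, and any averaging with such
outliers produces near-Poisson dispersions and inflated test statistics. In
a seeded 2000-position null simulation (depth 50, dispersion 0.1) the
realized type-I error at alpha = 0.05 is 0.05–0.06, simulated dispersion 0.5
is recovered as ~0.4, Poisson data collapse to the 1e-8 floor, and the
acceptance suite asserts the [0.03, 0.07] band. Single-replicate designs
get a flat conservative dispersion of 0.1 and are flagged.

The Wald test itself exploits that the two-group NB GLM with log link and
size-factor offsets is saturated: the MLE of each group mean solves a
one-dimensional score equation, which is the depth ratio `sum(y)/sum(s)`
for equal size factors and is refined by a few Newton steps otherwise; the
standard error comes from the Fisher information at the fit. The tests
verify agreement with an IRLS `glm()` fit of the same model. An all-zero
group receives a 0.5 continuity correction on its summed count so the fold
change stays finite and extreme separations test as significant rather than
falling into the Hauck–Donner regime. There is no fold-change shrinkage and
no outlier refitting; p-values are BH-adjusted across retained positions,
and positions that are all-zero in both groups are excluded from the
adjustment.

## Ranking score

Positions are ranked by `|log2FC| * max(-log10(padj), 5)`. The `max()` is a
*floor*: any position with padj >= 1e-5 gets multiplier 5 exactly, so among
those — in practice almost all — the ordering is by |log2FC| alone, and the
adjusted p only differentiates the extreme tail. Because the floor
semantics surprise many readers, a `score_mode = "cap"` variant
(`min(..., 5)`) is available, but the floor is the default and is what the
acceptance checks pin down. Missing padj counts as 1 (multiplier 5); padj
is clamped at 1e-300 so the score stays finite.

## Enrichment

The walk is the classic pre-ranked weighted Kolmogorov–Smirnov statistic
with weight exponent 1; the implementation is checked against a
step-by-step walk oracle and against an independent reference
implementation. The null for normalization draws `n_perm` (default 1000)
random position sets of the same size from the tested universe. NES divides
the observed ES by the mean magnitude of same-sign null values, and the
permutation p is the same-sign tail with +1 smoothing; a seeded 200-replicate
calibration check confirms null p-values are uniform. Null distributions
are cached by set size, so an RP's 100 background sets — same cardinality by
construction — reuse the RP's null draw unless universe intersection has
changed their size, in which case a separate null is drawn for the deviant
size.

ES2 is the sample z-score of the RP's NES against its backgrounds' NES.
BH adjustment for the GSEA and ORA p-values runs across the RP sets only —
background sets exist to build ES2 and never enter multiple testing.
The candidate call is `ES2 >= 1` (inclusive), and ES2 alone gates it; ES1
and ORA are reported for triage. Note what a z-threshold of 1 means: under
a global null roughly one RP in six will exceed it by chance, so the
candidate flag is a ranking aid for follow-up, not an error-controlled
discovery claim — the p-values are the error-controlled quantities. The
self-consistency of the construction is tested directly: each background's
z-score against its siblings has mean ~0 and sd ~1.

## The synthetic generator

`make_toy_structure()` writes a deterministic mmCIF: RNA residues on a 3D
helix (~6.7 Å between neighbours) and each RP as a small cluster of alpha
carbons placed just outside the helix near its own residue range, so every
toy RP has a known contact neighbourhood. `simulate_positional_counts()`
draws per-position baseline means from a log-normal profile (sdlog 1, mean
= depth) and NB counts at the requested dispersion; the protection effect
multiplies condition-B means by `2^effect_log2fc` at a seeded random subset
of the target RP's contact positions. The defaults — 3 replicates per
group, depth 50, dispersion 0.1, effect 1.5 log2 units at 60% of the set —
define the standard validation conditions; the 60% fraction encodes the
observation that only hotspots within an RP's vicinity respond, which makes
recovery harder and more realistic than a full-set effect.

The generator emulates count noise, depth imbalance, and the spatial
localization of the signal. It does not emulate RNase sequence specificity,
fragment-length selection artifacts, rRNA-depletion dropout, or correlated
digestion changes spanning neighbouring RPs — so passing recovery tests
demonstrate the statistical machinery, not robustness to those real-data
phenomena. Problem sizes used by the test and acceptance suites: a 650-nt,
8-RP toy ribosome (a ~1/10-scale ribosome at the real ~90 nt-per-RP
density, chosen so the background circle is not degenerate at the default
shift), 2000-position null simulations, and 20-seed replication for
recovery and null-behaviour checks.

## Determinism

All stochastic steps (toy structure, count simulation, permutation null)
take explicit seeds, restore the caller's RNG state, and produce
byte-identical outputs under identical configuration; every `run_rp_analysis()`
invocation with an output directory writes a provenance YAML with the
resolved configuration, seed, and dropped-position counts.

## Known limitations

* Contact sets inherit every limitation of the structure: unresolved
  segments are absent, and a single static conformation stands in for an
  ensemble.
* ES2 >= 1 is a triage threshold with a substantial null exceedance rate by
  construction (see above).
* Neighbouring RPs share rRNA neighbourhoods; a strong signal at one RP
  routinely co-predicts its structural neighbours, which may equally
  reflect a broader local rearrangement.
* Only two-condition designs are supported; no paired or time-course
  models, and no translation-efficiency analysis.
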