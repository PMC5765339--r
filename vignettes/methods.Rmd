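---
title: "Calling and testing CNVs on a trisomic chromosome 21: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and testing CNVs on a trisomic chromosome 21}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

`tri21cnv` analyses array-CGH data from cohorts in which every sample —
and, critically, the hybridization reference — carries trisomy 21.  The
copy-neutral state on chromosome 21 is therefore three copies, and the
per-probe log2 ratio of a test sample against the reference is

    log2(test copies / reference copies) + noise,

so a deletion (3 to 2 copies) sits near `log2(2/3) = -0.585`, a
duplication (3 to 4) near `log2(4/3) = +0.415`, and a region where the
*reference* is deleted appears as an apparent duplication of
`+log2(3/2) = +0.585` in every non-carrier test sample.  The package
never calls absolute copy number: a called deletion may represent the
loss of one, two, or all three copies, which is exactly why the
calibration stage works with frequency *bounds* rather than frequencies.

The reference sample carries a known deletion at
chr21:45,555,257–45,615,042.  Its ubiquitous apparent duplication is both
a nuisance (all calls touching it are filtered before association) and an
internal positive control: a well-tuned caller must recover it in at
least 80% of test arrays.

## The simulator and what it does (not) emulate

`simulate_cohort()` generates per-probe log2 ratios as the analytic copy
ratio plus Gaussian probe noise (SD 0.15 by default), a per-array mean
offset (SD 0.01), a lognormal per-array noise multiplier (log-SD 0.2,
modelling the continuum of hybridization quality), a small fraction of
"bad" arrays (5% at 9x variance) and "bad" probes (0.5% at 49x variance
across all arrays), and an optional linear GC bias (slope 0 by default,
so the GC-correction stage is exercised as a near-no-op unless enabled).
The design is a jittered grid of 4,500 probes spanning
chr21:15.4–47 Mb — a scaled-down rendering of the real 52,944-probe
design with proportionally wider spacing, chosen so a cohort-scale
calibration sweep runs in about a minute on one CPU.

Two desk-scale choices deserve emphasis:

* **Planted-variant frequencies are chromosome-level (allele)
  frequencies**, matching how structural-variant catalogs report them.  A
  trisomic sample carries a variant if any of its three chromosome 21s
  does, so the carrier probability is `1 - (1 - f)^3`.  Treating the
  configured frequency as a carrier frequency instead would place the
  simulated data exactly on the boundary of the trisomy frequency band
  `[d/(3S), d/S]` and make the calibration criterion an unstable coin
  flip; with allele frequencies the expected carrier rate sits well
  inside the band, as it does for real common variants.
* **Per-array quality is continuous.**  With only binary clean/bad
  arrays, the spread of clean-array variances collapses to chi-square
  sampling noise, and the mean + 1 SD array-variance cut would then
  preferentially discard arrays that merely carry a real CNV — an
  artifact of scaling a 52,944-probe array down to 4,500 probes, where
  one CNV is a much larger fraction of the array.  The lognormal
  multiplier restores a realistic spread.

The simulator does not model dye bias, spatial gradients, wave artifacts,
or mosaicism, and plants at most one copy-state per variant (a deletion
is always 2-of-3).  Passing tests therefore demonstrate correctness of
the pipeline's logic under idealized noise, not robustness to every real
aCGH pathology.

The default planted set mirrors the study design: a common deletion at
allele frequency 0.227 restricted to the African American population
(the calibration anchor, echoing a common African-ancestry 1000 Genomes
deletion), a 0.064-frequency Caucasian deletion, a rare case-enriched
430 kb duplication large enough to envelope a gene, and a rare
control-enriched deletion.  The default cohort is 250 arrays (120 cases,
130 controls; 40% African American).  The calibration anchor is
deliberately the *common* variant evaluated within its own population:
for rare variants the band's upper bound `d/S` converges to `3f`, which
is also the expected carrier rate, so rare variants cannot provide a
stable bracketing criterion at any cohort size.

## Quality control

Stages run in the published order, each a single pass with sample (n−1)
standard deviations:

1. **DLR**: arrays with the SD of successive probe log2 differences at or
   above 0.3 are excluded (strictly-below retained).
2. **Probe interarray variance**: on the post-DLR arrays, probes with
   variance ≥ mean + 1 SD are excluded from all downstream calling.
3. **Array variance**, then **array mean**: arrays ≥ mean + 1 SD of
   intra-array variance, or ≥ 2 SD from the grand mean (two-sided), are
   excluded.
4. After calling: samples with deletion or duplication counts > 5 SD over
   the mean are excluded (evaluated once, not iterated).

When the spread of a criterion statistic is exactly zero the filter
excludes nothing: the intent of every rule is outlier removal, and a
literal reading would otherwise exclude every array.  The exact
interleaving of stage 2 with stages 3–4 is ambiguous in the source
protocol; `run_array_qc()` exposes the order as a parameter and defaults
to the order above.

## Segmentation with backward elimination

`segment_gada_like()` fits a piecewise-constant mean by sparse breakpoint
selection:

1. **Over-complete proposal.** Greedy binary splitting on the t-statistic
   of the adjacent-segment mean difference,
   `t = (mL - mR) / (sigma * sqrt(1/nL + 1/nR))`, taken to its exhaustive
   limit.  Splitting every segment at its maximal-|t| position down to
   single probes proposes every inter-probe boundary regardless of split
   order, so the implementation simply starts from all n−1 boundaries.
   A sparse proposal (stopping at a t floor) was evaluated and rejected:
   a short CNV in the middle of a long flat segment yields a tiny
   single-split t (the deviation is diluted over thousands of probes), so
   binary splitting with any early stopping systematically misses small
   variants — the sparse-Bayesian forward pass it replaces does not have
   this failure mode.
2. **Backward elimination.** The breakpoint with the smallest current |t|
   (recomputed against its live flanking segments) is removed repeatedly
   until every remaining |t| ≥ Tm.  The removal sequence does not depend
   on Tm, so one recorded elimination trajectory per array serves every
   Tm in the calibration sweep; breakpoint sets are provably nested
   across thresholds.
3. **Short-segment merging.** Segments shorter than MinSegLen (default 6
   probes) are merged into the flanking segment with the closer mean.
4. **Boundary refinement.** Each surviving breakpoint is moved, between
   its flanking breakpoints, to the position minimizing the residual sum
   of squares, iterated to a fixed point.  Greedy elimination can strand
   a boundary a probe or two from the optimum; refinement brings the
   final partition within a few percent of the exhaustive
   dynamic-programming optimum at the same breakpoint count.

The noise SD is estimated globally as `sd(diff(y)) / sqrt(2)`
(`estim.sigma2`-style), which is robust to piecewise-constant signal; a
zero estimate (constant profiles) is floored at 1e-10.  Segments with
|mean| ≥ 0.2 and ≥ MinSegLen probes become CNV candidates.  The default
Tm is 8: the protocol this follows prints both 8 and 0.8, but only 8
lies inside its own stated sweep range of 4.5–20.5, so 0.8 is treated as
a typographical variant and the discrepancy is surfaced here and in the
configuration documentation.

## The shift caller and consensus

The second caller (`segment_adm2_like()`) is a transparent surrogate for
proprietary shift-based callers: on the centralized (kernel-density-mode
centred; Silverman bandwidth; median fallback) and GC-corrected
(per-GC-decile median subtracted) profile, it scans all intervals up to
500 probes, scores them by `|mean| * sqrt(n)`, and keeps maximal
non-overlapping intervals with ≥ 6 probes, |mean| ≥ 0.2, and score
≥ 5 sigma-hat — the score floor standing in for "fuzzy zero"
suppression of long, low-amplitude calls, applied after centralization.
A segmentation call is reported only if a same-type shift-caller call
shares at least one probe (the concordance rule; segmentation breakpoints
win, since the surrogate exists only as a concordance check, and the
overlap rule is the package's choice where the protocol states
concordance without a criterion).

## Calibration by trisomy frequency bounds

For a variant called `d` times among `S` trisomic samples, the
chromosome-level frequency is bounded by `lower = d/(3S)` (every call a
single lost copy) and `upper = d/S` (every call a full loss);
`lower = upper/3` holds exactly and both are kept as integer rationals.
`sweep_tm()` walks Tm over 4.5–20.5 by half steps and requires (1)
reference-deletion detection ≥ 80% and (2) every designated calibration
variant's catalog frequency inside its band, evaluated within the
variant's own population, counting carriers at ≥ 50% reciprocal overlap.
Among qualifying values the largest Tm is selected (fewest false
positives); the analogous manual optimization picked its value by
inspection.  All designated calibration variants must bracket
simultaneously — where a protocol is ambiguous between "all" and "any",
the stricter reading is implemented.  If no Tm qualifies the result
carries an explicit failure status rather than a silent default.

## Post-call filtering and catalog validation

In order: calls ≥ 1 Mb; calls with either breakpoint inside the
reference deletion or the poorly mapped chr21:0–15.4 Mb region; samples
with outlying call counts.  Catalog validation flags calls with ≥ 50%
reciprocal overlap with a same-type catalog entry (`multiallelic`
entries match either type), ignoring catalog variants below the 1,798 bp
platform detection floor.  Regions are built by single-linkage
clustering of same-type calls under the 50% reciprocal-overlap relation
(union-find), and a region's frequency is its carrier count over the
cohort (one count per sample regardless of call multiplicity), with
rare defined as < 1%.

## Stratification

SNP QC drops missingness > 10%, Hardy–Weinberg exact p < 1e-6
(Wigginton-style recurrence, evaluated from the distribution mode for
stability), then MAF ≤ 0.05.  LD pruning slides 50 kb windows advancing
5 SNPs, removing the later SNP of any pair with genotypic r² > 0.2
(pairwise-complete dosage correlation — the haplotype-based alternative
requires phasing the package does not model), iterating to a fixed
point.  PCA standardizes dosages by `2p` and `sqrt(2p(1-p))`,
mean-imputes missing values, and eigen-decomposes the sample covariance;
round 2 runs per population with configurable PC1 cutoffs.  Because an
eigenvector's sign is arbitrary, a symmetric `|PC1|` mode is offered
alongside the signed cutoffs used when outliers are flagged by eye.

## Association and replication

Burden metrics per sample are RATE (call count), KBTOT (kilobases
covered), and GRATE (distinct genes intersected).  Tests are one-sided
by hypothesis — excess deletion burden in controls (protection by return
to disomy), excess duplication burden in cases (dosage beyond a
tolerable threshold) — with empirical p-values from label permutations
using the small-sample-safe `(k+1)/(B+1)` convention, which can never
return zero.  Region and gene tests permute a carrier indicator; the
permutation null of a carrier count is hypergeometric, so draws come
from `rhyper` directly.  The desk-scale default is 10,000 permutations;
`paper_mode` raises it to one million.  Carrier tables for Fisher tests
collapse samples (a sample with two qualifying duplications counts
once), the odds ratio is the sample cross-product, p-values are exact
hypergeometric tails, and one-sided 95% intervals come from exact
conditional inversion.  The replication-style probe test divides each
sample's count by the reference sample's count and compares case and
control ratios by a one-sided Mann–Whitney U test: exhaustive
enumeration (tie-safe) when both groups have ≤ 8 samples, otherwise a
normal approximation with tie-corrected variance and a 0.5 continuity
correction, which agrees with enumeration to within 0.02 on tie-free
data at those sizes.

## Problem sizes and runtime

Defaults are sized for a single CPU: 4,500 probes x 250 arrays simulate
in under a second; the full 33-point Tm sweep with per-array elimination
trajectories runs in about a minute; the complete pipeline (simulation
through association at 10,000 permutations) in under two minutes.  The
test suite's heaviest blocks — the 500-replicate null calibration of the
burden kernel and the exhaustive Fisher/HWE oracle comparisons — each
stay within a few minutes.

## Known limitations

* The shift caller is a documented surrogate, not a reimplementation of
  the proprietary algorithm it stands in for; only its published
  parameters are honored.
* Power calculations quoted alongside the original analyses are out of
  scope (their method is unspecified), as are gene-ontology analyses and
  wet-lab concerns.
* Real-cohort summary numbers cannot be reproduced without the raw
  arrays, which are deliberately not packaged; the acceptance checks
  substitute property-based criteria (calibration of the permutation
  kernel, oracle equivalence of the statistical kernels, planted-variant
  recovery) computed entirely from simulation.
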