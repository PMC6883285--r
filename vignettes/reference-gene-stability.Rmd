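---
title: "Choosing stable reference genes for miRNA RT-qPCR: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing stable reference genes for miRNA RT-qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative quantification by RT-qPCR expresses a target miRNA as a fold change
against one or more reference genes, assumed stable across samples and
conditions. Small nucleolar RNAs (sno202, sno234, ...) and the snRNA U6 are
the customary normalizers for miRNA assays, but none is guaranteed stable in
a given tissue under a given treatment — a normalizer regulated by the
condition biases every downstream fold change. `refstab` implements the
standard vetting workflow for candidate normalizers in a grouped design
(e.g. non-treated / sham / spared-nerve-injury mice, in neural tissues):
per-reaction efficiency and Cq estimation from raw amplification curves,
technical-replicate QC, four complementary stability statistics, a consensus
ranking, and the final multi-reference `2^-ddCq` quantification.

All statistics operate on Cq values (quantitation cycles). Under perfect
per-cycle doubling, Cq is `-log2` of the starting quantity up to a per-assay
constant, so cycle-scale SDs are log2-scale expression SDs — the units every
method below consumes.

## Efficiency and Cq from amplification curves

A reaction's fluorescence is modeled as baseline + amplicon signal. The
package estimates the baseline as the mean fluorescence over configurable
early cycles (default 3–15, the customary automatic-baseline window); curves
whose corrected amplitude never exceeds the baseline noise band are flagged
non-amplifying. On the corrected curve, the *window of linearity* is the
contiguous window (default 4 points) maximizing the R² of
log10(fluorescence) against cycle, restricted to the log-linear phase:
strictly increasing values, above a positivity floor, and below 90% of the
maximal fluorescence. Ties break toward earlier cycles, which makes the
estimator deterministic and recovers noiseless exponentials exactly.

From the window regression, efficiency is `E = 10^slope` (per-cycle fold
change, 2 = perfect doubling) and the regression Cq is where the fitted line
crosses `log10(threshold)`. The single-threshold Cq — what a plate
instrument reports at threshold 0.1 — is obtained by log-linear
interpolation between the bracketing cycles. On noiseless exponentials both
agree with the closed form `E^Cq = threshold / F0` to machine precision; on
noisy, saturating curves the maximal-R² window can reach into the
compression knee below the plateau, giving a small downward bias in `E`, a
known trait of regression-based efficiency estimation (estimates below 2
are the norm in practice). Reactions are flagged *no plateau* when the last
five cycles still grow by more than 20% per cycle — a reaction still in
exponential growth gains `E − 1` (70–100%) per cycle, so this cleanly
separates saturated tails — and per-amplicon summaries exclude them;
efficiency outliers (beyond 3 MADs from the per-amplicon median) are
included by default but can be excluded.

## Replicate QC

Technical duplicates are averaged per (sample, gene); the duplicate SD (for
two values, `|difference|/sqrt(2)`) measures technical noise. A candidate
whose tissue-level mean duplicate SD exceeds 0.167 cycles — the level at
which a 2-fold change is still resolved reliably — is excluded from the
candidate set. The summary statistic (mean, median, or max of per-sample
SDs) is configurable with mean as default, matching the quantity usually
plotted in duplicate-variability figures; whether the original screen used
mean or maximum is not documented, hence the switch. An explicit override
list can retain a flagged gene, because such retentions are judgment calls,
not algorithm: they are logged as warnings. A pair with a single surviving
replicate keeps its value as the mean but contributes no SD — fabricating
variability from one value would bias the screen.

## The four stability statistics

**BestKeeper.** Per-gene SD of Cq across all samples (pooled over groups,
n−1 denominator) and Pearson correlation `r` with the BestKeeper index, the
per-sample geometric mean of all candidates' Cq. Stable genes: low SD, high
`r`. Genes with SD > 1 cycle are inappropriate for normalization; the
package removes them from the candidate set and recomputes (none of the
usual candidates reach it on real data). The method score is the mean of
the SD rank (ascending) and the `r` rank (descending); correlation p values
are reported but do not gate ranking, and ranking uses signed `r` with a
message when negative correlations appear.

**Comparative delta-Cq.** For every gene pair, the SD across samples of
their Cq difference; a gene's score is the mean over its partners. Because
every pairwise difference cancels any per-sample constant, this statistic
is exactly invariant to loading differences — the property the synthetic
generator's loading term exercises end to end.

**geNorm.** The stability `M` of a gene is the mean SD of its pairwise log2
expression ratios. With efficiency fixed at 2 the log2 ratio of genes
(g, h) in sample s is `Cq[s,h] − Cq[s,g]`, so M coincides *exactly* with
the delta-Cq mean SD — a cross-module identity the test suite asserts.
Supplying per-assay efficiencies switches to
`log2 q[s,g] = (meanCq_g − Cq[s,g]) * log2(E_g)`. Stepwise exclusion
repeatedly removes the worst-M gene until a pair remains; the final pair is
unordered, so both members carry the tied rank 1.5 (the only convention
that reproduces half-integer consensus scores). Ties at the worst M break
by larger raw Cq SD, then lexicographically, and are logged. The pairwise
variation `V(n/n+1)` is the SD across samples of the log2 ratio of
normalization factors built from the n and n+1 best genes; the smallest n
with `V < 0.15` is the recommended reference count. The per-gene reference
point used for relative quantities (each gene's mean Cq) is a constant that
cancels in V — asserted by test, so the choice is cosmetic.

**NormFinder.** A two-way model on the log scale: value = gene effect +
sample effect + (group × gene) effect + noise. Per group, sample effects
are removed and double-centered residuals give a per-gene intra-group
variance, bias-corrected by `G/(G−2) * (u_g − S/(G(G−1)))` (removing sample
effects leaks every gene's noise into every residual; the correction undoes
it) and floored at zero. Inter-group deviations `d` are shrunken toward
zero by the empirical-Bayes factor `gamma² / (gamma² + var(d̂))`, where
`gamma²` is the dispersion of observed deviations in excess of sampling
variance. Stability is
`rho = mean over groups of (|d_shrunk| + sqrt(var(d_shrunk)))`; the best
two-gene combination minimizes the same expression with averaged deviations
and propagated variances, so genes with opposite group shifts cancel. Two
degenerate cases are handled explicitly: with one group, rho falls back to
the bias-corrected residual SD (flagged); when `gamma² ≤ 0` the literal
shrinkage would zero every deviation and rho falls back to the sampling SD
of `d̂` (flagged).

The variance estimator is unbiased but inherits an absolute noise floor of
roughly 0.05–0.1 cycles from its co-candidates through the fitted sample
effects, so planted intra-group SDs below ~0.2 cycles are recovered with
that absolute accuracy rather than a fixed relative one; the property tests
reflect this.

## Consensus ranking

Each method contributes a per-gene score: BestKeeper its (possibly
fractional) mean rank, delta-Cq and NormFinder their ordinal ranks, geNorm
its exclusion-order rank with 1.5 for both final-pair members. The overall
score is the arithmetic mean — geometric aggregation is available but
dampens extreme ranks, which is undesirable when the methods are treated as
equally informative — and genes are ordered by ascending overall score with
average ties. Rankings from different Cq settings (single threshold vs
regression-corrected) are compared by per-gene rank deltas and the Spearman
correlation of overall scores.

## Quantification

`2^-ddCq` with multi-reference normalization: the reference aggregate is
the arithmetic mean of reference Cq values, equivalent to the geometric
mean of reference quantities. Fold changes are calibrated so the calibrator
group's geometric mean is exactly 1. The group test is a one-way ANOVA on
linear fold changes by default — reproducing the customary analysis of
`2^-ddCq` reports — with a `log_scale` flag that analyzes `-ddCq` instead
and is the statistically preferable choice, since fold changes are
log-normal-like. Tukey HSD is always computed but flagged "not indicated"
when the overall p exceeds alpha. Degrees of freedom follow the actual
input sizes, (G−1, N−G).

## The synthetic-data generator

`sim_config()` defines the default study: three groups of 5/6/5 animals,
eleven candidates in technical duplicates, per-gene baseline Cq between
18.5 and 31.5 cycles (sno202 most abundant, sno412 least), a biological
noise ladder from 0.10 to 0.60 cycles in 0.05 steps, a shared per-sample
loading shift with SD 0.3 cycles, technical-replicate SD 0.08 cycles except
sno55 (0.35 cycles, so the duplicate-SD rule removes it, emulating a
candidate excluded on technical grounds), and a planted +0.8-cycle SNI
shift on sno292, a candidate plausibly regulated by the injury. The shifted
gene sits on the top retained noise rung so that the planted ground-truth
ordering — ascending total perturbation
`sqrt(noise² + between-group variance + replicate²/n_rep)` — places it
last. Noise is Gaussian on the Cq scale (multiplicative on quantities),
the scale all four methods consume.

Amplification curves are `baseline + sat(F0 · E^c) + noise` with a smooth
hyperbolic knee `sat(u) = plateau·u/(plateau + u)`; `F0` is anchored so the
noiseless unsaturated curve crosses the threshold exactly at the gene's
baseline Cq, giving closed-form true efficiencies and Cq values per well.
The knee is enough to exercise plateau handling; it does not model PCR
kinetics, probe chemistry, or inhibitors. Likewise the Cq generator is
exchangeable Gaussian — no outlier wells, no missing-not-at-random
dropouts, no between-day batch structure — so passing tests demonstrate
correctness of the statistics, not robustness to every pathology of real
plates.

A deliberate tension in this design is worth knowing about: NormFinder
shrinks a gene's group deviation by `gamma²/(gamma² + sigma_g²/n_a)`, so a
group-shifted gene on a *high* noise rung (which is what makes it worst
overall for the variance-based methods) has its deviation shrunken hardest,
and with 16 samples its rho separates only weakly from the top noise rungs.
Detecting a 0.8-cycle group shift as "worst by NormFinder" in nearly every
replicate would require either a larger shift, larger groups, or a
low-noise placement that would in turn keep the gene out of the overall
bottom ranks. The acceptance suite states both claims at face value and
reports the measured rates.

## Numerical conventions and limitations

- Window ties compare R² with a 1e-12 slack and resolve toward earlier
  cycles; all rank ties use average ranks.
- Cq values must lie in (0, 45); undetermined wells are read as missing,
  never as the cycle count, and downstream methods refuse missing cells
  rather than impute.
- The stability methods pool groups where the original procedures do
  (BestKeeper SD, delta-Cq, geNorm); NormFinder is the only
  group-aware statistic, and needs at least two samples per group.
- Problem sizes in the test and acceptance suites (matrices up to 8×6 for
  oracle checks, 200 replicate studies of 16 samples × 11 genes for
  recovery rates) were chosen as the smallest sizes at which the checked
  properties are statistically meaningful.
- Exact numerical agreement with proprietary regression software is not
  promised — only the documented parameter behavior (four-point window,
  strictly continuous log-linear phase, plateau exclusion, threshold 0.1).
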