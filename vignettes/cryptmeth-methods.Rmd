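---
title: "Methods: promoter methylation, CpG classes, and TF target calling with cryptmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter methylation, CpG classes, and TF target calling with cryptmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptmeth)
```

`cryptmeth` implements the computational core of a two-group promoter
methylation study on MeDIP tiling arrays — the kind of design used to compare
intestinal crypt epithelium of diabetic (db/db) mice against db/+ littermate
controls — together with the downstream assays such a study feeds:
CpG-density promoter classification, bisulfite clone scoring, ChIP-seq peak
annotation, and the qPCR/luciferase integration that decides whether a
transcription factor activates or represses a bound gene. This vignette
explains each model, its tunable parameters, and the design choices behind
them.

## The array model and the DMEP filter

Each of ~22,327 RefSeq promoter regions (about −1300 bp to +500 bp of the
TSS) is tiled by ~8 probes; each probe reports one log2(MeDIP/Input) ratio
per sample, three replicates per group. All computations start from these
ratios; scanner-level normalization is upstream and out of scope.

**Peak assembly.** Within a promoter, a maximal run of at least
`min_probes_per_peak` (default 2) consecutive probes whose pooled mean ratio
(over all six samples) exceeds `probe_call_threshold` (default 0.2) becomes
one enrichment peak. The original vendor peak detection is unpublished, so
this run-based rule is our own definition; every knob sits in
`dmep_params()`, and peaks never cross promoter boundaries.

**The differential statistic.** For a peak,

> M′ = mean(log2 MeDIP/Input, case) − mean(log2 MeDIP/Input, control),

the grand mean taken over the peak's probes × replicates. For complete data
this equals the mean of per-sample means, so no alternative estimator is
offered. A peak is a differential methylation enrichment peak (DMEP) when

1. at least one group's median enrichment over the peak is ≥ `median_min`
   (default 0.3), and |M′| > `m_prime_min`;
2. in *both* groups, at least `cv_pass_fraction_min` (default 0.5) of the
   peak's probes have a replicate coefficient of variability
   CV = sd/|mean| ≤ `cv_max` (default 0.8).

The sign of M′ orients the call: positive means the case group is more
methylated. Two readings of criterion 1 are supported. The literal reading
(`one_sided = TRUE`) accepts only M′ > 0; the default applies the criterion
direction-symmetrically, because a study reporting differential peaks *in
both directions* (control-higher and case-higher counts) cannot have used a
one-sided rule on a fixed orientation. The "median (log2 MeDIP/Input)" per
group is the median over the peak's probes of per-probe group means
(`median_over = "all_values"` switches to the median over all probe ×
replicate values), and the CV is computed on the log2 ratios as stored
(`cv_scale = "linear"` uses 2^ratio); neither convention is fixed by the
published criteria, so both are explicit parameters.

**`m_prime_min`.** With noisy data any peak has |M′| > 0, so the printed
filter alone classes *every* methylated peak as differential in one
direction or the other. The published totals (3,146 methylated promoters but
only 1,216 group-comparison DMEPs) imply an additional, unstated threshold
in the vendor pipeline. We default to the faithful `m_prime_min = 0` and use
0.3 — half the planted effect size, ~4 standard errors of M′ under the noise
model below — when the goal is to separate differential from merely
methylated peaks, as in `scripts/acceptance.R`.

**Group comparison.** `summarize_dmeps()` compares per-sample mean
enrichment over the DMEP probes between groups with a two-sided unpaired
Student's *t* test (the study's stated test). Welch's correction is
available via `var_equal = FALSE`, but note that with three replicates per
group Welch's true size is ≈3.5% at nominal 5%, visibly conservative;
Student's *t* is calibrated (≈4.6–5% rejection under the null in our
1000-replicate simulations).

## What the array generator emulates — and what it does not

`simulate_array()` draws per-probe, per-replicate ratios as
Normal(μ, `probe_noise_sd`), with μ = 0 for background probes,
μ = `peak_base_level` (default 0.5) in both groups within a planted
methylated peak, plus `effect_size` (default 0.6) in the higher group within
a differential peak. Planted peaks occupy 4–6 consecutive probes so that
assembly is non-trivial but unambiguous. A fraction
`cv_inflation_fraction` (default 0.1) of probes has its noise SD multiplied
by `cv_inflation_factor` (default 6), producing probes whose CV fails
criterion 2 — these exercise the quality filter and are the main source of
false assembled peaks.

Defaults mirror the study design: `methylated_fraction = 0.141`
(3,146/22,327 promoters carrying a methylated peak),
`dmep_fraction = 0.0545` (1,216/22,327 differential), and
`prop_control_higher = 0.625` (760/1,216). `peak_base_level = 0.5` places a
typical methylated peak comfortably above the 0.3 median criterion with a
CV of 0.4 at the default noise — a realistic margin for probes called
enriched on two-colour arrays. The generator does **not** model dye bias,
spatial artifacts, probe-affinity differences, or correlated noise between
neighbouring probes; passing recovery tests therefore demonstrates
correctness of the filter logic under idealized noise, not performance on
raw array data.

Under the recovery conditions used in the tests (2,000 promoters, 200
planted differential peaks, effect 0.6, noise SD 0.2, 10% inflated probes)
the caller reaches ≈0.99 sensitivity at ≈0.01–0.05 false-discovery
proportion. At the full emulated scale the same pipeline recovers
methylated-promoter and DMEP counts close to, but ~5–10% above, the planted
design values; the excess comes from variance-inflated probes that slip
past the CV criterion when they adjoin a genuine peak.

## CpG-density promoter classes

Promoters are classified on the −1300..+500 sequence with 500-bp sliding
windows:

- **HCP** — some window lying fully inside −700..+200 has GC fraction
  ≥ 0.55 *and* CpG O/E ≥ 0.6;
- **LCP** — no window anywhere in the promoter reaches CpG O/E ≥ 0.4;
- **ICP** — everything between.

CpG O/E follows the Gardiner-Garden convention,
(N~CpG~ × L)/(N~C~ × N~G~), with N bases excluded from every count and the
window length reduced accordingly; a window with no C or no G has O/E 0, so
HCP and LCP are mutually exclusive by construction. Three readings were
genuinely open and are resolved as follows: the HCP window must lie *fully
inside* the core region (the natural reading of "within"); the LCP search
region is the whole assayed promoter, not only the core; the window step
defaults to 1 bp (the exact scan — the implementation is cumulative-sum
based, so the exact scan is cheap; larger steps only trade exactness for
speed). Promoters shorter than 500 bp are judged by their single
full-length window; sequences that are more than half N have their label
withheld with a warning.

The sequence generator plants a high-density island (GC ≈ 0.83, O/E ≈ 1.9)
inside the core region for HCP, the same island *outside* the core (so it
defeats the LCP condition without creating a qualifying HCP window) for
ICP, and CpG-free AT-rich background for LCP. Margins are enormous by
construction, so generator labels are guaranteed ground truth rather than a
tuned calibration; real intermediate promoters sit far closer to the
thresholds than these fixtures.

## Bisulfite clone matrices

Each sequenced colony contributes one clone: a row of
methylated/unmethylated/undetermined calls over the region's CpG sites (10
clones per group in the emulated design). Undetermined calls are excluded
from numerator and denominator everywhere, never imputed. The overall
methylation ratio equals the mean of per-clone ratios exactly when every
clone has the same number of determined calls (a weighted mean otherwise —
asserted in the tests). Group comparison is a two-sided unpaired *t* test
on per-clone ratios, treating colonies as replicates to match bar-graph
annotations of such studies; a per-site variant is available
(`by = "site"`). A pooled 2×2 Fisher test would ignore clone identity and
overstate independence, so it is deliberately not the default. Identical
or otherwise zero-variance inputs yield `t_p = NA` rather than an error.

## ChIP peak annotation

Assignment is by peak summit (reproducible across peak-width conventions;
the summit is read from the BED column-7 offset when present, else the
interval midpoint). Windows, all configurable in `element_windows()`:
promoter = ±2 kb of TSS; enhancer = −50 kb upstream of the gene's 5′ end to
+5 kb past its 3′ end, in gene orientation, minus the gene body and the
promoter window; extended enhancer = the same with −100 kb. Within a gene,
categories are evaluated in precedence order promoter > exon > intron >
enhancer > extended enhancer; across genes the highest-precedence pair
wins, with ties broken by the smaller |TSS offset|; a summit qualifying
nowhere is intergenic. The precedence order is our resolution of
overlapping window definitions — element lists in such studies do not state
tie rules — and it guarantees that "extended enhancer" is only assigned
when no gene qualifies under a tighter definition. TSS offsets are signed
in gene orientation (negative = upstream), so a summit at genomic
TSS + 20,391 of a minus-strand gene reports −20,391.

## Relative expression and the regulation caller

`ddct_fold()` implements 2^(−ΔΔCt) with the reference gene subtracted per
sample and the reference condition's fold pinned to exactly 1; the SE is
propagated on the log2 scale and exponentiated. Ct values outside (0, 45)
are rejected. `luciferase_relative()` normalizes each well's firefly
reading by its renilla control and reports the mean-ratio fold of the
active over the empty-vector condition; non-positive renilla wells are
excluded with a warning.

`call_regulation()` encodes the perturbation-concordance logic: a gene is
an *activated* target iff knockdown of the TF significantly lowers it and
overexpression significantly raises it; a *repressed* target shows the
mirrored pattern; anything else — including both arms significant in the
same direction, which is flagged discordant — is *no regulation*. Both arms
must be significant (α = 0.05 per arm, no multiple-testing correction,
matching the per-gene reporting convention of such studies; this is a
documented limitation, and p-values can be pre-adjusted with `p.adjust`
before calling). A gene missing either arm has its call withheld rather
than guessed.

## Numerical choices and degenerate inputs

- All internal coordinates are 0-based half-open; GFF3's 1-based closed
  coordinates are converted only at the I/O boundary, so a double round
  trip is the identity.
- A probe whose replicate mean is exactly 0 has CV = +∞ and fails any
  finite `cv_max`.
- Zero assembled peaks propagate as empty data frames and `NA` test
  statistics, not errors; an all-undetermined clone matrix, by contrast,
  is an error because its ratio is undefined.
- Sequences are upper-cased on read; ambiguity codes other than N are
  rejected rather than silently dropped.
- Every generator takes an explicit integer seed and is bit-reproducible
  under it.

## Problem sizes used in the checks

The packaged checks run the oracle comparison on 500 random promoters of up
to 10 probes, the recovery study on 2,000 promoters with 200 planted peaks,
the null calibration on 1,000 simulated arrays of 40 promoters, and the
classifier oracle on 200 random 1800-mers; `scripts/acceptance.R`
additionally runs one full-scale array (22,327 promoters × 8 probes).
These sizes were chosen so the whole suite exercises every code path at
comfortable statistical resolution while remaining quick to run on a
laptop.

## Known limitations

- The peak-assembly rule and `m_prime_min` stand in for an unpublished
  vendor algorithm; peak *scores* here are |M′|-based and not comparable to
  vendor "probability of positive enrichment" scores.
- The array noise model is independent Gaussian per probe; correlated
  probe effects would lower the effective sensitivity below the values
  reported here.
- The CpG classifier labels promoter classes; it does not call CpG-island
  boundaries.
- The regulation caller is qualitative: it consumes per-gene fold/p pairs
  and does not model dose–response or indirect regulation.
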