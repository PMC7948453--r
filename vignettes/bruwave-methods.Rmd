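---
title: "Methods: wave-front elongation-rate inference on simulated Bru-seq data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wave-front elongation-rate inference on simulated Bru-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bruwave)
```

## The measurement

RNA polymerase II pauses 20–60 bp downstream of the transcription start
site and is released into productive elongation by P-TEFb. Blocking that
release pharmacologically (a CDK9 inhibitor such as flavopiridol) for long
enough empties gene bodies of elongating polymerases while paused ones
accumulate at the promoter. After washout, released polymerases move into
gene bodies as a synchronous cohort; labelling nascent RNA with
5-bromouridine for a short window `T` and sequencing it produces a read
density that falls to background at the most distal position the
pioneering polymerases have reached. The displacement of this **wave
front** between two labelling times measures the elongation rate
directly:

$$\hat v = \frac{x_{front}(T_2) - x_{front}(T_1)}{T_2 - T_1}.$$

Differencing two fronts cancels the release delay: a polymerase released
after an exponential wait contributes the same setback to both fronts, so
a perturbation acting on pause release (rather than elongation itself)
leaves the two-timepoint estimate unchanged. That separation — release
kinetics versus elongation kinetics — is the scientific point of the
design, and the bundled simulator is built to let you verify that the
estimator actually has that property.

## The kinetic simulator

`sim_config()` + `build_genome()` + `simulate_fp_washout()` generate
stranded binned coverage with known ground truth:

* At washout, each active gene holds a paused cohort of
  `min(Poisson(alpha * block_minutes), pause_capacity)` polymerases
  (capacity defaults to 1: steric occlusion at a 20–60 bp site).
* Each polymerase releases after an `Exponential(beta)` wait
  (default half-time 30 s), then elongates at `v` (default 2.2 kb/min),
  terminating prematurely with probability `pi_term` per kb.
* Initiation continues at `alpha` during labelling; newly initiated
  polymerases pause and release under the same law.
* The labelled RNA of a polymerase at time `T` spans from the pause site
  to its current position, capped at the gene end; reads are
  `Poisson(depth × labelled kb)` placed uniformly on that span, sense
  strand only, over a uniform two-strand background `bg`.

`simulate_steady_state()` generates the no-drug condition: a pause peak
with mass proportional to the occupancy `alpha / beta`, a gene body
decaying as `exp(-pi_term x)` (premature termination), post-TES
readthrough decaying over `term_distance`, bidirectional eRNA at
enhancers, and spike-in counts. A per-condition capture efficiency
scales the entire library including the spikes — exactly the confound
spike-in normalisation removes.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `v` | 2.2 kb/min | mid-range mESC elongation rate; the recovery target |
| `beta` | ln2 / 0.5 min⁻¹ | 30 s release half-time, so the pioneer front tracks `v·T` closely |
| `alpha` | 0.5 /min/gene | a paused cohort is essentially always present after a 60-min block; ~2–5 new initiations per labelling window |
| `block_minutes` | 60 | clears the longest allowed gene (`v · block ≥ 132 kb`); enforced as a precondition |
| `label_minutes` | 5, 10 | paired with gene filters > 15 kb and > 30 kb so the front stays inside gene bodies |
| `pi_term` | 0.02 /kb | gives a distal/proximal processivity ratio with a closed form `exp(-pi·d)` to test against |
| `depth` | 50 reads/labelled kb | desk-scale: full run in seconds, front detectable well above background |
| `bg` | 0.05 reads/kb/strand | nascent-RNA enrichment leaves little intergenic signal; keeps background RPKM well under the 0.5 expression cutoff at this library size |
| genome | 2 × 6 Mb, 500 genes | minutes-not-hours; gene lengths log-normal (median 10 kb, sdlog 0.8) so ~145 genes clear 15 kb and ~40 clear 30 kb |

Gene packing inserts occasional large "gene desert" gaps, which is where
intergenic enhancers and their clusters live.

## Wave-front calling

`build_metagene()` averages sense-strand density in TSS-anchored windows
(minus-strand genes exactly mirrored), after scaling each library to
reads per million; the profile is the unweighted mean over genes, so a
handful of very hot genes cannot move the front. `detect_wavefront()`
then:

1. smooths with a centred moving mean (default 5 bins of 50 bp);
2. estimates background as the **median of the most distal quarter** of
   the window — the window defaults (−2..18 kb for 5 min, −2..34 kb for
   10 min) leave that quarter beyond any plausible front;
3. sets the threshold at background + 5% of the dynamic range;
4. scans downstream **from the profile maximum** (so the pause peak
   cannot trigger a spurious crossing) for the first run of ≥ 3
   consecutive sub-threshold bins, interpolating linearly inside the
   crossing bin.

Design points that were genuinely open, and how they were settled:

* **Background definition.** "Approaches background" is a judgement call
  on a figure; a robust distal median is the most defensible
  operationalisation and is configurable (`distal_frac`).
* **Smoothing.** Whether fronts should be called on raw or smoothed
  profiles is not determined by the method description; smoothing is a
  parameter (`smooth_bins`, default 5) and the closed-form kinematic test
  runs with smoothing off.
* **Replicates.** Profiles are averaged first, then the front is called
  once (`average_replicates()`), matching the "average of two
  experiments" presentation style; calling per replicate and averaging
  positions is a caller-level choice.
* **Quantization.** Positions are bin-centre based; an anchor that sits
  mid-bin adds up to one bin of systematic offset. The threshold is
  anchored to the profile maximum, which is higher at 10 min (more
  accumulated initiations), pulling the 10-min front back slightly more
  than the 5-min front. Together these bias the two-timepoint rate a few
  percent low at 50 bp bins; the effect is visible in the bundled tests
  and is well inside the 2–2.4 kb/min acceptance band.
* **Bootstrap CI.** `bootstrap_rate()` resamples genes with replacement
  and re-runs the whole front-calling path; the percentile interval
  quantifies gene-sampling variability only. It does not cover the
  quantization/threshold bias above — a bootstrap cannot see a
  systematic offset of the estimator.

## Quantification and classification

* `count_windows()` integrates binned density pro-rata at window edges;
  it equals per-base summation exactly and is tested against an
  independent brute-force oracle.
* eRNA is quantified in ±1 kb windows around **intergenic** peaks with
  both strands summed (eRNA is bidirectional). Intragenic windows would
  mostly measure host-gene transcription.
* `normalize_counts()` offers spike-in (median of abundance/count per
  condition) and library-size modes side by side, because real designs
  use either; the simulator's efficiency confound is only removed by the
  spike mode.
* `fold_change()` implements the operative classifier: pseudocount 1,
  up if FC > 1.5, down if FC < 1/1.5. This is a deliberate
  simplification — no dispersion model — because the cutoff rule itself
  is the decision procedure being reproduced.
* `tes_readthrough()` clips its 10 kb window at the nearest same-strand
  downstream gene, so a neighbour's transcription is not mistaken for
  termination readthrough.
* `stratify_by_distance()` uses enhancer-edge-to-TSS distance with
  right-open bins: a gene at exactly 20 kb falls in the 20–40 kb
  stratum.
* `rank_sum_test()` wraps the two-sided Wilcoxon rank-sum test: exact
  enumeration for tie-free groups up to n = 20, normal approximation
  with tie and continuity correction beyond.

The simulator's enhancer effects are **cluster-coherent**: a
superenhancer (≥ 3 enhancers within 12.5 kb, single linkage) gains
activity as one unit in the perturbed condition. Mixed-multiplier
clusters would dilute each member's ±1 kb window below the FC cutoff and
make the classifier look miscalibrated for a purely geometric reason.
Each enhancer's eRNA transcript length is likewise a fixed property drawn
once at genome construction — redrawing it per library would randomise
the window-captured fraction across conditions and corrupt fold changes
with variance no real experiment has.

## Peak annotation

`assign_feature()` classifies peak midpoints with priority
promoter (TSS −1000..+100) > TTS (TES −100..+1000) > gene body >
intergenic — the common annotation convention; the windows are
parameters because conventions differ. Midpoint classification makes the
categories a partition, which the distribution pie requires.
`classify_intergenic()` and `bind_genes()` share one span definition
(TSS − 500 bp to TES, strand-aware) and are logical complements by
construction. Enrichment tertiles cut summed peak score at the 33.3/66.7
order-statistic percentiles; tied scores all fall in the lower tertile,
so an all-tied input lands in one group rather than being split
arbitrarily.

## What the synthetic data does and does not show

The generator reproduces the *kinetic structure* the analyses assume:
synchronous release, a moving labelled front, termination decay,
bidirectional enhancer output, spike-in confounds. It does not simulate
sequence-level reads, splicing, divergent antisense transcription at
promoters, mappability artefacts, or peak calling (peaks are consumed as
intervals). Passing tests therefore demonstrate that the estimators
recover known truth under the stated model — not that the model captures
every property of real nascent-RNA libraries. Real-data counts (peak
totals, numbers of misregulated enhancers) depend on a specific genome
and sequencing depth and are out of scope by design.

## Problem sizes and determinism

The default full run (500 genes, two conditions, two labelling times,
steady state, 200-resample bootstrap) completes in a few seconds on one
core; the test suite runs in under a minute. All randomness flows from a
single integer seed fanned out to per-stage child seeds by fixed
offsets, so `run_all()` is byte-deterministic (`report_json()`) and any
stage can be re-run in isolation with the same result.

```{r example, eval = FALSE}
report <- run_all(run_config(seed = 1))
report
```

## Known limitations

* Front positions inherit ±1 bin quantization from the 50 bp binning;
  use a smaller `bin_size` if sub-bin precision matters.
* The two-timepoint rate carries a small conservative bias from the
  max-anchored threshold (see above).
* `pause_capacity` caps the washout cohort at one polymerase by default;
  bursty promoters with multi-polymerase queues are not modelled.
* The single-transcript gene model has no isoforms; "genic body" is one
  category because the synthetic genome has no exon structure.
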