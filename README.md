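# bruwave

Analysis of nascent-RNA (Bru-seq) coverage for RNA polymerase II
elongation kinetics, enhancer-RNA synthesis, and peak annotation — with a
built-in stochastic simulator of promoter-proximal pause-release
kinetics, so every estimator in the package can be exercised and
validated against known ground truth without any sequencing data.

## The problem

Pol II pauses 20–60 bp downstream of the TSS and is released into
productive elongation by P-TEFb. Blocking release with a CDK9 inhibitor
for 60 min empties gene bodies; after washout, released polymerases move
as a synchronous cohort. Labelling nascent RNA with 5-bromouridine for a
short window *T* marks everything synthesised since washout, and the read
density falls to background at the **wave front** — the most distal
position reached by the pioneering polymerases. Two labelling times give
the elongation rate directly:

    v̂ = (x_front(T₂) − x_front(T₁)) / (T₂ − T₁)   [kb/min]

Because a release delay sets both fronts back equally, the two-timepoint
estimate isolates elongation speed from pause-release efficiency — which
is exactly the distinction needed when asking whether a putative
elongation factor actually changes how fast Pol II moves *in vivo*.

Around that core the package provides the companion quantifications such
experiments use: steady-state distal/proximal **processivity ratios**,
**termination readthrough** up to 10 kb past the TES (clipped at
neighbouring genes), **eRNA quantification** in ±1 kb windows around
intergenic peaks with spike-in or library-size normalisation and the
FC > 1.5 up/down/unchanged classifier, distance-stratified neighbour-gene
comparisons (Wilcoxon), and genomic-feature annotation of peak sets
(promoter / TTS / gene body / intergenic, enhancer and superenhancer
overlap, enrichment tertiles).

## Worked example

The full pipeline on simulated data — washout at a true rate of
2.2 kb/min, a "null" condition with 10% slower pause release but
identical elongation rate, and 50 intergenic enhancers doubled in the
null condition:

```r
library(bruwave)
report <- run_all(run_config(seed = 1, verbose = FALSE))
report
#> <bruwave_report>
#>   fronts (kb): wt_5=10.7437, wt_10=21.3813, null_5=10.7248, null_10=20.9438
#>   rate wt 2.127, null 2.044 kb/min (ratio 0.961), CI [2.001, 2.189]
#>   eRNA: 50 up / 1 down / 61 unchanged
#>   processivity ratio null/wt: 1.002; readthrough ratio: 1.029
#>   expressed genes: 469 (bound: 450)
```

Reading it: the 5- and 10-min fronts sit near 11 and 21 kb, giving a
wild-type rate of 2.13 kb/min (truth: 2.2); the null condition's rate is
within 4% of wild type — the release perturbation does not masquerade as
an elongation-rate change. All 50 truly doubled enhancer windows are
classified "up" with one false positive among the unchanged ones, and
processivity and readthrough ratios sit at ~1 because termination was
left untouched. Step-by-step use of the same machinery:

```r
cfg    <- sim_config(seed = 1)
genome <- build_genome(cfg)
sim    <- simulate_fp_washout(genome, cfg, conditions = "wt")

genes5 <- filter_genes_by_length(genome$genes, 15000)
prof5  <- build_metagene(sim$tracks$wt_5, genes5, "tss", c(-2000, 18000))
front5 <- detect_wavefront(prof5, estimate_background(prof5))
front5
#> <wavefront> position = 10744 bp (background 0, threshold 1.06)

autoplot(prof5, wavefront = front5)   # metagene with the front marked
```

See `vignette("bruwave-methods")` for the model, every tunable with its
default and rationale, and the package's numerical conventions.

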