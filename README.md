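# tripletnet

Inference of post-translational regulatory triplets — (modulator,
transcription factor, target) — from gene expression cohorts, cross-cohort
validation of the resulting motifs, and analysis of the three-layer
hierarchical regulatory network they form.

## The problem and who this is for

Oncogenes and tumour suppressor genes frequently influence transcription
indirectly, by modulating transcription-factor activity at the
post-translational level. That influence is invisible to ordinary
co-expression analysis, but it leaves a conditional signature: the
statistical dependence between a TF *f* and a target *t* changes with the
expression level of the modulator *m*. `tripletnet` is for researchers who
have several expression cohorts (genes × samples), lists of candidate
modulators and TFs, and want a reproducible, fully scriptable pipeline from
matrices to a validated hierarchical regulatory network — the kind of
analysis usually stitched together from a legacy modulator-inference tool,
spreadsheet intersections and Cytoscape.

## The statistic

Each candidate ordered triplet (*m*, *f*, *t*) is scored with a conditional
mutual information difference

ΔI = Î(f; t | m ∈ H) − Î(f; t | m ∈ L),

where H and L are the samples with the top and bottom ⌈q·n⌉ modulator
values (default q = 0.35), and Î is the plug-in MI on equal-frequency
discretized expression (default 4 bins, reported in bits). Triplets with
ΔI ≥ θ (default 0.1) are positive modulations: *m* enhances the *f*→*t*
interaction. Motifs called in a reference cohort and supported by
independent validation cohorts form the consistent set, which is assembled
into a directed three-layer network (modulation edges modulator→TF,
regulation edges TF→target) and analysed for degrees, betweenness, harmonic
closeness, Monte-Carlo topology significance, regulatory loops, binary
regulation profiles with hierarchical clustering, function-specific
subnetworks and hypergeometric over-representation.

A seeded multi-cohort synthetic generator plants modulator-gated TF→target
dependencies (target = β·g(m)·tf + noise, with g a within-cohort median
gate), so every stage of the pipeline can be benchmarked against known
truth without any external download.

## Worked example

```r
library(tripletnet)

sim <- generate_cohorts(synthetic_config(
  cohort_sizes = c(180, 100), seed = 3, n_background_genes = 20,
  n_targets = 10, n_planted = 10, shared_fraction = 0.5
))
ref  <- infer_triplets(sim$cohorts$cohort1, sim$catalog, cohort = "cohort1")
val  <- infer_triplets(sim$cohorts$cohort2, sim$catalog, cohort = "cohort2")
cons <- consistent_motifs(ref, list(val))
glance(cons)
#> # A tibble: 1 × 5
#>   n_motifs n_modulators n_tfs n_targets cohort
#>      <int>        <int> <int>     <int> <chr>
#> 1       53           10     5        28 cohort1
```

Of the 218 positive calls in the 180-sample reference cohort, 53 survive
validation against the 100-sample cohort; all 5 triplets planted in both
cohorts are among them (planted scores ≈ 0.9–1.3 bits; spurious survivors
sit just above the 0.1-bit threshold — rank by `score`):

```r
shared <- sim$planted[lengths(sim$planted$cohorts) == 2, ]
sum(paste(shared$modulator, shared$tf, shared$target) %in%
    paste(cons$modulator, cons$tf, cons$target))
#> [1] 5

cent <- centralities(build_network(cons, sim$catalog))
head(dplyr::arrange(cent, dplyr::desc(betweenness)), 3)
#> # A tibble: 3 × 6
#>   gene  in_degree out_degree degree betweenness closeness
#>   <chr>     <int>      <int>  <int>       <dbl>     <dbl>
#> 1 TF002        10         10     20      0.140      0.568
#> 2 TF004         6          7     13      0.0860     0.479
#> 3 TF001         8          9     17      0.0693     0.521
```

TFs dominate betweenness, as they must in a three-layer hierarchy: every
modulator→target path crosses the TF layer. The whole chain — simulate,
infer per cohort, validate, export the network (SIF/GraphML/TSV), topology
report, profiles, subnetworks, enrichment — runs from one configuration via
`run_pipeline()`, with per-stage counts and file digests recorded so
identical seeds give byte-identical outputs.

See `vignettes/triplet-inference.Rmd` for the model, the parameter
conventions and the design choices.

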