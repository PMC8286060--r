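---
title: "Inferring modulator-gated regulatory triplets and their hierarchical network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring modulator-gated regulatory triplets and their hierarchical network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model

Oncogenes and tumour suppressor genes (TSGs) often act on transcription not by
binding DNA themselves but by modulating the activity of transcription factors
(TFs) post-translationally. Expression data can expose this indirect layer:
when a modulator gene *m* is highly expressed, the statistical dependence
between a TF *f* and a target *t* strengthens; when *m* is low, it weakens or
vanishes. `tripletnet` scores every candidate ordered triplet
(*m*, *f*, *t*) with a conditional mutual information difference,

$$\Delta I \;=\; \widehat{I}(f; t \mid m \in H) \;-\; \widehat{I}(f; t \mid m \in L),$$

where $H$ and $L$ are the samples with the top and bottom
$\lceil q\,n \rceil$ values of the modulator, and $\widehat{I}$ is the plug-in
mutual information on equal-frequency discretized expression. A triplet is
called a *positive modulation* when $\Delta I \ge \theta$: the modulator
enhances the TF–target interaction. Negative modulators
($\Delta I \le -\theta$) can be requested with `keep_negative = TRUE` but are
not part of the default analysis.

The statistic assumes only that expression ranks are meaningful: because both
the stratification and the discretization are rank-based, $\Delta I$ is
invariant under strictly monotone transformations of each gene separately, so
it does not matter whether the input matrix is in linear or log scale
(`read_expression_matrix()` still records an optional `log2_transform` flag so
a run's provenance states what was fed in).

Positive calls from a reference cohort are then *validated* against
independent cohorts: a motif is consistent when the same
(modulator, TF, target) key is called in the reference and supported by the
validation cohorts under a chosen rule. Consistent motifs are assembled into
a three-layer directed network — modulators on top (`modulation` edges into
TFs), TFs in the middle (`regulation` edges into targets), targets at the
bottom — which is the substrate for topology statistics, loop detection,
binary regulation profiles and function-specific subnetworks.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `q` | 0.35 | conditioning fraction; each stratum holds $\lceil q\,n\rceil$ samples. Larger `q` mixes weakly-modulated samples into the strata; smaller `q` shrinks the strata and inflates estimator variance. 0.35 is the conventional operating point for this family of methods. |
| `bins` | 4 | equal-frequency bins per axis of the contingency table. Four bins keep the table occupied at stratum sizes of a few dozen samples while still resolving non-linear dependence. |
| `theta` | 0.1 | positive-call threshold on $\Delta I$, in `mi_units`. The conventional default score cutoff; note the units caveat below. |
| `mi_units` | bits | base of the MI logarithm (bits = log2, nats = ln). The 0.1 cutoff is applied in whichever units are selected; we declare bits as the package convention rather than inferring what any particular legacy implementation used. |
| `min_stratum` | 20 | smallest admissible stratum. At `q = 0.35` this requires cohorts of at least 58 samples; see "Small cohorts" below. |
| `modulator_min_iqr` | 0 | modulators whose IQR does not exceed this are skipped — a flat modulator cannot stratify samples. |

Consistency rules: `reference_plus_any` (default), `reference_plus_k`,
`all_cohorts`. Pairwise comparison of each validation cohort against one
reference, followed by keeping reference motifs supported anywhere, is the
weakest reading of a cross-validation design built around a primary cohort;
the stricter rules are one configuration switch away, and
`consistent_motifs()` records the rule and the supporting cohorts per motif.

## The synthetic study design

`generate_cohorts()` emulates the statistical structure the inference
assumes, not microarray realism. Per cohort, every gene is i.i.d. standard
normal across samples; each planted triplet overwrites its target with

$$t = \beta \cdot g(m) \cdot f + \varepsilon,\qquad
  \varepsilon \sim \mathcal N(0, \sigma^2),$$

where the gate $g(m)$ is a hard median switch on the modulator's
within-cohort expression. The hard gate (rather than a sigmoid) makes the
population contrast analytically clean: dependence is fully on in one stratum
and absent in the other, so recovery tests are sharp. Defaults mirror the
study design the package targets: four cohorts of 180/100/40/30 samples, 20
planted triplets with half shared across all cohorts, $\beta = 2$,
$\sigma = 0.5$, 50 background genes, and role pools of 5 TFs, 5 oncogenes,
5 TSGs and 20 targets — large enough that candidate space dwarfs truth,
small enough that a full study runs in seconds.

What the generator does **not** emulate: gene-specific scale and baseline
(all marginals are standard normal by design, keeping discretization bins
comparable), batch effects, missing values, probe-level noise, and correlated
background structure. Passing recovery tests therefore demonstrate that the
estimator detects the gating structure it models, at the stated sample sizes
and effect sizes — not that it is robust to everything real arrays do.

## Numerical choices

* **Equal-frequency discretization** by rank, ties broken by stable input
  order; bin sizes differ by at most one. Equal-width binning would be
  fragile under skewed scales.
* **Plug-in MI** over the joint contingency table; exactly zero when the
  table factorizes, clamped at zero against floating-point dips. The plug-in
  estimator is positively biased at small strata (roughly
  $(b-1)^2 / (2 m \ln 2)$ bits for $b$ bins and $m$ samples), but the bias
  largely cancels in the *difference* of two strata of equal size.
* **Stratum ties**: the top/bottom $\lceil qn \rceil$ samples are chosen by a
  stable sort, so ties at the stratum boundary resolve deterministically by
  input order; with continuous expression ties have probability zero.
* **Empirical topology p-values** use the add-one rule
  $p = (1 + \#\{\text{null} \ge \text{obs}\}) / (N + 1)$ — never zero, and
  conservative. On small networks with coarse integer metrics the
  tie-inclusive $\ge$ makes null p-values stochastically *larger* than
  uniform; calibration checks therefore use networks large enough that tie
  mass is negligible.
* **Harmonic closeness** on the directed graph:
  $(n-1)^{-1} \sum_{v \ne u} 1/d(u,v)$ with unreachable pairs contributing
  zero. A three-layer network is mostly unreachable top-to-bottom in reverse,
  which makes classic closeness ill-defined; the harmonic form needs no graph
  surgery.
* **Loops** are simple directed cycles in the union of typed edges,
  deduplicated up to rotation, capped at length 2 by default — the
  reciprocal TF/modulator pair is the loop pattern of interest in a
  three-layer hierarchy — with the cap configurable.
* **Profile clustering**: Jaccard distance with average linkage by default.
  Regulation profiles are sparse 0/1 vectors, for which Jaccard (share of
  disagreeing supports among occupied positions) is the natural metric;
  Hamming and complete linkage are available.
* **BH adjustment** delegates to `stats::p.adjust` behind a validating
  wrapper; the hypergeometric upper tail includes the observed overlap
  ($P[X \ge k]$), the conservative convention.

## Small cohorts

`min_stratum = 20` protects the contingency table from degenerate occupancy,
and at `q = 0.35` it rules out cohorts under 58 samples. Two of the four
cohort sizes in the package's reference study design (40 and 30 samples) fall
below that line. When the multi-cohort design is exercised end to end —
in the test suite and the acceptance script — `min_stratum = 10` is used for
the inference stage so that all four cohorts participate, which is the point
of the cross-validation design. The cost is real and visible in the results:
with stratum sizes of 11–14 samples, the null spread of $\Delta I$ is of the
order of 0.2–0.4 bits, far above `theta = 0.1`, so small validation cohorts
produce many spurious positive calls. Cross-cohort intersection absorbs most
of them, but a reference-specific spurious motif evades removal whenever it
is also spuriously called in at least one small validation cohort.

## Known limitations

* **Near-threshold false calls.** A target that genuinely depends on its TF
  (in a gated way) yields elevated $\Delta I$ *variance* for every other
  candidate modulator of that same TF–target pair. At `theta = 0.1` bits and
  $n = 1000$ this admits modulator-swapped false positives whose scores sit
  just above threshold (true planted triplets score an order of magnitude
  higher). The package reports scores, so users can rank rather than
  threshold; a permutation calibration (`delta_i_permutation()`) is provided
  for score-level inference.
* **Consistency is key-based.** Motifs are matched across cohorts by gene
  symbols only; no score meta-analysis or rank aggregation is attempted.
* **ORA is annotation-agnostic.** Enrichment takes user-supplied GMT sets
  against an explicit background; there is no ontology traversal, term
  redundancy reduction, or species mapping.
* **Exhaustive scoring is cubic** in the role list sizes. The implementation
  shares stratification and discretization across candidates but computes
  exactly the naive triple loop's scores; `restrict` narrows the candidate
  space without approximating.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run entirely on synthetic data:
single-cohort recovery uses 25 replicate studies at $n = 1000$; the
multi-cohort consistency check uses five replicate four-cohort studies at
180/100/40/30; topology calibration uses 200 null role sets of 10 nodes with
499 draws each on a ~75-node network; the profile-clustering check uses a
planted two-block design of 16 modulators. These sizes were chosen so the
Monte-Carlo error of each reported quantity is small relative to the margins
being checked while a full run stays in the tens of seconds.

## A worked run

```{r, eval = FALSE}
library(tripletnet)

prov <- run_pipeline(list(
  seed = 3,
  outdir = "run1",
  synthetic = list(cohort_sizes = c(180, 100), n_background_genes = 20,
                   n_targets = 10, n_planted = 10, shared_fraction = 0.5),
  inference = list(min_stratum = 20),
  topology = list(N = 499)
))
prov
```

The run directory then holds per-cohort motif tables, the consistent motif
table, SIF/GraphML/TSV network exports and dot-plot data; `prov` records the
per-stage counts and file digests that make two runs with the same seed
byte-identical.
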