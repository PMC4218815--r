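---
title: "Methods: cross-species expression deconvolution for xenograft arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species expression deconvolution for xenograft arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenodeconv)
```

## The problem

In orthotopic xenograft models of invasive glioma, laser microdissection
yields three tissue regions per animal: the tumor core (region A, almost
purely human graft cells), the invasion front (region B, a mixture of
invading human tumor cells and mouse host cells), and distant "normal"
brain (region C, mouse cells). Region-B RNA is hybridized on **both** a
human and a mouse expression array, so each compartment of the mixed
tissue can be profiled — provided probes that cross-hybridize with the
other species' transcripts are removed first. Without that mask, a human
probe that also binds an abundant mouse transcript reports a mixture of
the two compartments and biases every downstream fold change.

The package implements the full analysis chain: probe-level
cross-hybridization scoring and masking, normalization and probeset
summarization, per-line region-contrast differential expression with a
cross-line consensus, gene-set over-representation with membership-overlap
term clustering, orthology-aware inference of tumor–host protein-binding
crosstalk, and a count-platform concordance check. A synthetic-data
generator with planted ground truth makes every stage testable without any
external download.

## The synthetic study and what it emulates

`sim_config()` fixes the study conditions: 2 tumor lines × 4 animals × 3
regions, with region B hybridized on both array species (32 array samples
at the defaults). Each species has `n_genes_per_species` (default 600)
genes with one transcript and one probeset of 11 non-overlapping 25-mer
probes. Probe-level log2 intensity is

    log2( mix * 2^(baseline + region_effect + affinity) + leakage ) + noise

* `baseline` ~ N(8, 1) per gene; `affinity` ~ N(0, 0.5) per probe, shared
  across samples — the probe-effect structure that summarization must
  remove.
* `region_effect` is the planted log2 fold change, shared by both lines:
  region B vs A for human genes, B vs C for mouse genes. A fraction 0.10
  of genes per species is differentially expressed with |log2FC| drawn
  from N(1.5, 0.3) truncated below at 1, random sign.
* `mix` is the compartment fraction: the human fraction *f* of region-B
  tissue on human arrays, 1 − *f* on mouse arrays, 1 elsewhere. The
  source study does not state the compartment proportions at the invasion
  front, so *f* is a free parameter; the default 0.5 represents a heavily
  infiltrated front and exercises the normalization maximally.
* `leakage` affects only probes that carry a planted cross-hybridization
  implant, only in region B: a coupling κ (default 0.5) times the foreign
  compartment's raw-scale abundance. Regions A and C have zero leakage.
* `noise` is iid Gaussian with sd 0.25 log2 units, a typical residual
  scale for expression arrays.

A fraction 0.10 of each species' probes receives an implanted exact copy
of one of its subsequences (length uniform on 15..25 nt) inside a spacer
segment of a random foreign transcript; every implant is recorded in the
truth tables.

**Sequence model.** The two transcriptomes are generated over
deliberately distinguishable sequence spaces: graft text never contains
the dinucleotides `AA`/`TT`, host text carries a `TT` anchor every 12 nt.
Every host 15-mer therefore contains a `TT` that no graft probe (or its
reverse complement) can contain, so cross-species contiguous matches of
15 nt or more exist *only* where the generator planted them. Each implant
is additionally screened against the 15-mers of all other same-species
probes (both strands) and re-drawn on collision. The planted
cross-hybridization truth is therefore exact, which is what lets masking
be scored with sensitivity and specificity rather than approximately.

**What the generator does not emulate.** Partial-homology
cross-hybridization (mismatched duplexes), sequence-composition effects
(GC content, melting temperature), per-animal random effects, batch
structure, and background signal are all absent by design: the truth must
stay crisp for planted-recovery tests to be exact, and the noise model
must match the test statistic's assumptions for the calibration check to
be interpretable. Passing tests therefore demonstrate that the
*algorithms* are correct under their stated model, not that real arrays
meet that model. The identity-based flag rule (below) exists precisely
for the partial-homology case that the generator does not simulate.

**Why 600 genes.** Global normalization — any flavor — estimates a
per-array location from the data and therefore absorbs the *net* mass of
differential expression. With a small gene panel the planted up/down sign
split is a small-sample binomial draw, and a chance imbalance (say 12 up
vs 3 down out of 15) shifts every null gene by ~0.1 log2 in region B,
consistently across lines. Real arrays carry thousands of probesets,
making this net-mass term negligible; 600 genes per species is the
smallest panel where the artifact is comfortably below the per-gene
standard error while the full suite still runs in minutes.

## Probe masking

`score_cross_hybridization()` computes, per probe, the longest contiguous
exact match shared with the foreign transcriptome (both strands) and the
best full-length ungapped identity over alignments anchored at shared
12-mer seeds. A probe is flagged when the contiguous match reaches
`l_min` (default 15 nt) or the identity reaches `i_min` (default 0.75).
These defaults are standard short-probe cross-hybridization heuristics;
both are exposed as parameters.

The matcher is seed-and-extend (12-mer primary seed) with an 8-mer second
pass and an exact dynamic-programming fallback for probes whose true
maximum is below 8 nt, so the reported match length is exact for every
probe — verified in the tests against an independent pure-R
longest-common-substring dynamic programme, probe by probe. `best_identity`
is defined operationally as the best identity over 12-mer-anchored
ungapped alignments; a probe sharing no 12-mer with the reference reports
identity 0. `N` never matches anything.

`build_mask()` excludes flagged probes and drops probesets left with
fewer than `min_probes_per_set` (default 3) survivors, because the median
summary below needs a robust location estimate. In planted-recovery
experiments the identity rule is disabled (`i_min = 1`): the generator
plants exact contiguous matches only, and the identity heuristic would
flag chance anchored similarities that are not part of the planted truth.

## Normalization and summarization

Region-B arrays receive only a fraction of their species' RNA, which on
the log2 scale is a uniform per-array shift — exactly what per-array
normalization removes. The pipeline's default is robust
median-centering (`scale_normalize()`): each column minus its median,
plus the grand median. Full quantile normalization
(`quantile_normalize()`, ties resolved as the mean of tied ranks) is
available as an option and satisfies the usual contract (identical sorted
value multisets per column), but it is *not* the default: planted
differential expression stretches the region-B distribution tails, and
quantile mapping then compresses extreme-baseline null genes by a
per-gene-consistent amount in every region-B column — which, being shared
by both lines, survives the cross-line consensus as correlated false
positives. Location-only centering has no rank remapping and no such
failure mode. (On noise-free data any data-driven normalization distorts
slightly; the exact-recovery tests therefore run on the raw path.)

`summarize_probesets()` collapses surviving probes to one value per
probeset and sample: the member-probe median (default; robust to residual
unmasked leakage) or Tukey median-polish sample effects. Background
correction is deliberately omitted (the generator adds none); the
provenance attribute records that.

## Differential expression and consensus

`region_contrast()` runs a gene-wise Welch two-sample t-test on log2
expression — region B vs A on human arrays, B vs C on mouse arrays —
with two-sided p-values and Benjamini–Hochberg q within the contrast;
`log2fc = mean(B) − mean(reference)`. Genes with zero variance and equal
means get `t = 0, p = 1` by convention. Welch was chosen over a
moderated/empirical-Bayes statistic because the generator's noise is
Gaussian with per-gene scale and the assumption-light test keeps the
calibration experiment interpretable; a moderated variant can sit behind
the same contract.

The cross-line consensus (`intersect_lines()`) keeps genes with raw
p < 0.05 in *both* lines and the same direction of change — mirroring
the prioritization rule "significant change (p < 0.05) in both
xenografted lines"; BH-q selection is available behind a flag. On
calibration: at n = 4 vs 4 the Welch test is inherently mildly
conservative (empirical size ≈ 0.041 on pure normal draws — a property
of the Welch–Satterthwaite approximation, not of this implementation),
so the type-I calibration experiment uses the pipeline's pooled contrast
(both lines, 8 vs 8 arrays; empirical size ≈ 0.048 over 500 replicates
of 1,000 planted-null genes).

`cluster_samples()` is the segregation diagnostic: average-linkage
hierarchical clustering under 1 − Pearson distance on the consensus
genes, cut into two flat clusters and compared with the region labels by
adjusted Rand index. On the default synthetic bundle both array species
separate their regions with ARI 1.

## Gene-set enrichment and term clustering

`enrich()` is the upper-tail hypergeometric test P(X ≥ k) per term, with
the universe restricted to genes actually measured on the masked array
(unmeasured genes cannot be drawn). Terms with zero overlap are omitted
(their p is 1). `cluster_and_filter()` applies the reporting rule: keep
terms with p ≤ 0.05 whose membership overlaps at least one other
significant term by at least θ = 0.30, and report connected components of
the ≥ θ overlap graph as term clusters; singletons move to a side table.
The overlap denominator is min(|A|, |B|) — the overlap coefficient —
because "30% overlap with another category" reads as containment-style
sharing; the source leaves the denominator undefined, and Jaccard is
available behind a flag. Raw p is used for the filter (the quoted rule);
BH-q is reported alongside.

## Crosstalk inference

`infer_crosstalk()` nominates tumor–host protein-binding pairs: a human
consensus DEG and a mouse consensus DEG whose pair (after mapping the
mouse symbol through a one-to-one orthology table into the human
namespace) appears in a user-supplied unordered interaction reference.
Both up- and down-regulated genes are eligible — receptors up in the
graft can meet ligands enriched in the host — so direction is annotated,
never filtered. Pairs whose two sides are orthologs of each other are
tagged homotypic (meaningful for adhesion molecules, trivially
filterable). Symbols without an ortholog are carried with an explicit
unmapped flag, never silently matched. The output is deterministic and
sorted, and equals an exhaustive triple-loop enumeration on every tested
instance.

## Concordance with a counting platform

`simulate_count_platform()` emulates a species-specific digital counting
assay on a gene panel: negative-binomial counts (variance
μ + φμ², default φ = 0.05) with mean proportional to the planted
raw-scale expression, species-pure even in region B (validation probes
are designed without cross-species hybridization), log-normal library
size factors, and housekeeping genes with zero planted fold change.
`de_from_counts()` normalizes by the geometric mean of housekeeping
counts — making fold changes invariant to per-sample scaling — and runs
the same Welch statistic on log2(count + 1) for symmetry with the array
stage. `compare_platforms()` reports per-gene sign agreement, Spearman
correlation of log2 fold changes, and the validated proportion (significant
on the second platform with matching sign).

## Pipeline, determinism, and problem sizes

`run_pipeline()` executes the stages in dependency order for both
compartments from a single validated configuration
(`pipeline_config()` / `read_run_config()`); `validate_config()` returns
*every* violation, not just the first. All randomness descends from the
configuration seed, so a rerun reproduces identical outputs; the run
report records parameters, per-stage counts, and output files. A thin
command-line wrapper (`exec/xenodeconv`) exposes `simulate` and `run`.

Problem sizes used by the test suite and the acceptance script — chosen
so the full chain exercises every stage in a few minutes on one CPU:
600 genes × 11 probes per species for the default bundle; 1,000 genes ×
3 probes × 500 replicates for the calibration experiment; 20 independent
bundles for the masking-benefit comparison; 200 probes vs 50 kb for the
matcher-vs-oracle check. The acceptance script recomputes all headline
quantities from scratch at the seed given on its command line.

## Known limitations

* The mask addresses exact-substring cross-hybridization (plus an
  anchored-identity heuristic); thermodynamic duplex stability and
  same-species paralog cross-talk are out of scope.
* The planted-truth exactness guarantees hold under the generator's
  sequence model; on real probe designs the same code computes the same
  scores, but no ground truth exists to score them against.
* The consensus rule uses raw p-values by design fidelity to the quoted
  prioritization rule; at genome scale a q-based rule (provided) is the
  defensible default.
* Hierarchical-clustering ARI is reported for a 2-cluster cut only; finer
  region structure is not assessed.
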