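---
title: "Integrative gene–metabolite network workflow: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative gene–metabolite network workflow: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmnet)
```

This vignette is the package's account of its methods: the preprocessing
model for targeted metabolomics, the differential statistics, the network
reconstruction contract, the subnetwork scoring rule, and the design
choices made where the procedure was genuinely open.

## The analysis problem

Longitudinal case–control multi-omics designs — here the motivating setting
is an iPSC-derived cortical differentiation series with six sampling days
(d0, d7, d16, d27, d50, d100), two conditions (control and schizophrenia
lines), and culture batches — produce two feature spaces that are hard to
compare directly: transcript abundances and targeted metabolite
concentrations (µM). `gmnet` joins them through the wiring of a
stoichiometric reaction model: genes attach to the reactions they
catalyze, metabolites to the reactions that consume or produce them, and
per-transition fold changes of both modalities are displayed on one graph.

## Targeted-metabolomics preprocessing

The pipeline order is fixed: detection filter → LOD imputation →
class-mean imputation → batch centering. Each step's contract:

**80 % rule.** A feature is retained iff in at least one sample group the
fraction of detected cells is ≥ `threshold` (default 0.8, boundary
inclusive). The grouping is a parameter because the convention is
group-wise but the natural grouping depends on the design; the package
default, used by `preprocess_metabolomics()`, is time points — they are the
biological classes of this design, and grouping by time point retains
stage-specific metabolites that a global rule would discard. Raising the
threshold is monotone: it can only drop features.

**LOD imputation.** Metabolite cells below the limit of detection are
censored at acquisition, not missing at random. A censored cell whose
feature is detected at some *other* time point is treated as a true
below-detection measurement and imputed uniformly at random on
`[LOD/2, LOD]` (closed interval; every LOD is > 0, so imputed values are
strictly positive). Detected measurements are never altered, and detection
status is carried as a mask independent of the imputed magnitudes, so no
information is destroyed.

**Class-mean imputation.** Cells still missing afterwards — censored cells
of features whose only detections are in the cell's own time point — are
filled with the arithmetic mean of the non-missing values in their
(feature, time point) class. After the LOD step those class values may
themselves include LOD-imputed draws; this is intentional, as the two
steps form one ordered pipeline. An entirely empty class is an error
naming the feature and class: it indicates the detection filter was
skipped.

**Batch centering.** For each feature, each value has its (time point,
batch) cell mean subtracted and its time-point mean added back. Hence
within every time point all batch means coincide, time-point means are
preserved exactly (conservation is tested to 1e−12), the transform is
idempotent, and a singleton (time point, batch) cell maps onto the
time-point mean. Centering operates on log2-transformed values by default
(`scale = "log2"`): concentrations span orders of magnitude, and additive
batch effects are a better model on the log scale. Raw-scale centering is
available for data already transformed upstream.

**QC.** `qc_diagnostics()` reports the per-feature mean/SD diagnostic and
a sample PCA via SVD of the column-centered sample-by-feature matrix.
Explained-variance fractions are non-increasing by construction; a
constant matrix returns zeros with a `degenerate` flag rather than NaNs.

## Differential statistics

For each feature and each adjacent time-point pair, the log2 fold change
is the difference of group means on the log2 scale, and the p-value comes
from a Welch two-sample t-test (unequal variances), computed in closed
form across features. This pairwise test is deliberately a simple,
transparent stand-in for count-model machinery (e.g. negative-binomial
Wald/LRT tests): the network stage consumes `(log2FC, padj)` tuples
regardless of their producer, and `load_external_de()` ingests external DE
tables so a dedicated RNA-seq pipeline can be slotted in unchanged.

Multiple testing uses Benjamini–Hochberg step-up adjustment, applied
within each (comparison, feature kind) family — genes and metabolites are
reported separately per comparison, so each family is adjusted on its own.
Significance is the strict inequality `padj < α` with α = 0.1 by default.
Features with zero variance in both groups get `p = 1` and a `degenerate`
flag rather than an error, so constant features flow through harmlessly.

## Network reconstruction

The reconstruction contract, given a reaction list already filtered to
measured entities:

* **Vertices:** measured genes associated with ≥ 1 retained reaction;
  measured metabolites participating in ≥ 1 retained reaction; *connector*
  vertices for unmeasured metabolites participating in ≥ 2 retained
  reactions. Isolated vertices are dropped.
* **Edges:** per reaction, one directed metabolite→metabolite edge from
  every educt to every product (both directions when reversible), and one
  undirected edge from each associated measured gene to each participating
  non-blocked metabolite. PPI edges join pairs of existing gene vertices.
  Duplicates are collapsed; self-loops never arise.

Design choices behind this contract:

* **Gene-association flattening.** Boolean gene–protein–reaction rules
  like `(A and B) or C` flatten to the plain set `{A, B, C}`: the
  reconstruction asks only which genes are associated with a reaction,
  never whether a complex is complete.
* **Edge semantics.** Drawing genes as vertices adjacent to their
  reactions' metabolites (rather than as edge labels) reproduces the
  pathway-figure topology this encoding is meant for, and keeps the PPI
  layer well-defined (PPI edges need gene endpoints).
* **Connector rule.** "Bridges measured entities" is operationalized as
  *participates in ≥ 2 retained reactions* (`connector_min_reactions`,
  configurable). Degree ≥ 2 is the minimal notion of bridging; a
  one-reaction unmeasured metabolite is a dead end, not a bridge.
* **Currency blocklist.** Water, protons, ATP/ADP, NAD(H), NADP(H), CO2
  and phosphate are excluded by default (`currency_metabolites()`):
  educt×product expansion would otherwise wire most of the network through
  cofactor hubs. The list is fully configurable, including empty.
* **Measured-entity filter.** Default mode `"or"` (a reaction survives
  with at least one measured gene *or* metabolite), matching the rule that
  only reactions associated with *neither* are removed; `"and"` is
  available for stricter reconstructions.

Fold-change vectors attach per vertex with one slot per comparison; slots
without a result stay empty. Colors use a linear diverging map on
`[-clip, +clip]`: pure blue at −clip, white at 0, pure red at +clip,
saturating beyond, gray (`#BEBEBE`) for empty or non-significant slots.
The map is odd-symmetric (the hue mirror swaps the red and blue
channels). The default clip is the 97.5th percentile of the attached
|log2FC| values — robust to a few extreme fold changes while using most of
the color range.

## Subnetwork scoring

Each pathway induces the subgraph on its members present in the network,
plus connectors bridging ≥ 2 retained members. Pathways are ranked by

1. `de_count` — member vertices significant in ≥ 1 of the 5 comparisons
   (a vertex counts once however many comparisons flag it; connectors
   never count), descending;
2. `degree_distance` — the two-sample Kolmogorov–Smirnov statistic between
   the subnetwork's and the parental network's vertex degree sequences,
   ascending;
3. pathway id, ascending — making the ranking a deterministic total order.

The degree criterion needed two decisions the procedure left open: the
*reference* distribution is the parental network's (the natural notion of
a subnetwork "looking like" the network it came from), and the *metric* is
the KS statistic (bounded in [0, 1], scale-free, exact on tied integer
degrees via direct ECDF evaluation). Both are conventions of this package,
used only to break ties after differential content, which ranks first.

## Rendering

Each vertex is a pie glyph over the five comparisons: five equal 72°
sectors, contiguous, totalling 360°, with the first sector *centered* on
12 o'clock (spanning −36° to +36°) and subsequent comparisons proceeding
clockwise. Centering the first sector at the top (rather than starting at
the top edge) is an explicit convention fixed so that rendered output is
stable. Genes render as circles, metabolites as ellipses (aspect
1.35 × 0.8), connectors as small gray dots without sectors. Layouts are
either user-supplied coordinates (TSV: vertex, x, y; every rendered vertex
must have one) or a seeded Fruchterman–Reingold fallback. SVG was chosen
over raster output because byte-stable text output makes determinism
testable: identical inputs produce identical bytes. GraphML export is
lossless — empty fold-change slots round-trip as omitted attributes.

## The synthetic-data generator

The generator exists so every downstream stage is testable without
external data; its defaults *are* the emulated study conditions:

* six time points (d0…d100), two conditions, lines nested in two batches,
  with sexes alternating across lines;
* lognormal abundances: Gaussian on the log2 scale around per-feature
  baselines (genes ~ N(8, 2), metabolites ~ N(2, 1.5) log2-µM), noise
  σ = 0.5. No noise model was available to copy, so lognormality — the
  standard first-order model for both RNA abundance and concentration
  data — was chosen once and kept;
* per-metabolite LOD at the 10 % quantile of the feature's marginal
  distribution (`lod_quantile = 0.1`); detection rates for targeted panels
  vary widely, and 10 % censoring exercises both imputation paths without
  dominating the data. Censored cells carry a below-detection marker, not
  a zero, because the 80 % rule and imputation need detection status;
* planted effects are cumulative log2 shifts from a transition onward,
  optionally condition-restricted. `rosette_effects()` plants the
  motivating signal: magnitude-2 shifts at comparisons 2–3 (the rosette
  stages), SCZ-restricted, down for the canonical glutamate→GABA route
  (GAD1, GAD2, GABA) and up for the compensatory ornithine/putrescine
  route;
* the toy reaction model always contains that motif — glutamate →(GAD1,
  GAD2) GABA; ornithine →(ODC1) putrescine; putrescine →(AOC2)
  4-aminobutanal →(ALDH9A1) GABA; putrescine →(SAT1, ALDH1A1) GABA — plus
  configurable random decoy reactions. The aldehyde-dehydrogenase step is
  attributed to ALDH9A1, the enzyme of that oxidation in the polyamine
  literature.

What the generator does **not** emulate: count noise and library-size
effects in RNA-seq, correlated features, drift within batches,
plate-level LODs (the LOD is per metabolite by design — the simplest model
satisfying the imputation preconditions), missingness that is not
LOD-censoring, and any kinetic/flux behaviour of the reaction model.
Passing tests therefore demonstrate the pipeline's correctness on its
stated contracts and its statistical calibration under a clean lognormal
model — not robustness to every artefact of real acquisitions.

## Problem sizes and numerical choices

The test-suite and acceptance computations use deliberately small
instances chosen to make their statistical targets well-powered: toy
models with ≤ 20 reactions for exact brute-force network comparison (100
random models), 6 samples per (time point, condition) cell for power
checks (a +2 log2 shift at σ = 0.5 gives a Welch effect size near 7, so
≥ 90 % detection is expected with margin), ≥ 500 feature-comparisons for
the null false-positive bound (≤ 15 % at α = 0.1), and 100 seeded
full-pipeline runs for planted-pathway recovery (≥ 95 % top-1). Numerical
tolerances: centering conservation and idempotence at 1e−12; PCA versus an
independent eigendecomposition at 1e−8 (sign-invariant per component); BH
adjustment is compared *exactly* against a brute-force step-up oracle.
All generators are pure functions of their arguments and a seed, and the
caller's RNG state is never disturbed.

## Known limitations

* The Welch pairwise test ignores the repeated-measures structure (the
  same lines appear at every time point) and covariates such as sex; use
  `load_external_de()` with a dedicated longitudinal model when that
  matters.
* Reaction direction is taken from the model's reversibility flag; no
  thermodynamic or flux-based direction inference is attempted.
* Identifier mapping is a plain source→target table; it does not resolve
  compartment suffixes or chemical synonyms by itself.
* Subnetwork candidates are pathway-defined only; there is no de-novo
  module search.
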