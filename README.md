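# gmnet

Integrative gene–metabolite network reconstruction from longitudinal
multi-omics.

`gmnet` is for systems-biology analysts who have longitudinal transcriptomic
and targeted-metabolomic measurements of the same samples — for example an
iPSC-derived neuronal differentiation series sampled in cases and controls —
and want to view both modalities on one network whose wiring comes from a
genome-scale stoichiometric reaction model (Recon3D-style) enriched with
protein–protein interactions.

## What it computes

1. **Targeted-metabolomics preprocessing.** Features are filtered by a
   group-wise 80 % detection rule (keep a metabolite iff it is detected in
   ≥ 80 % of samples of at least one time point). Cells censored at the
   limit of detection (LOD) of a feature that is detected at another time
   point are imputed uniformly at random on `[LOD/2, LOD]`; remaining
   missing cells take the arithmetic mean of their (feature, time point)
   class. Batch effects are removed by centering within (time point, batch)
   cells while preserving time-point means. QC reports the per-feature
   mean/SD diagnostic and a sample PCA.

2. **Consecutive time-point differential tables.** For each feature and
   each adjacent time-point pair *k* (with six time points,
   k = 1…5: d0→d7, d7→d16, d16→d27, d27→d50, d50→d100):
   `log2FC_k = mean(log2 x_later) − mean(log2 x_earlier)`, a Welch
   two-sample t-test, and Benjamini–Hochberg adjustment within each
   (comparison, feature kind) family; significance is `p_adj < α` (default
   α = 0.1). Externally computed DE tables (e.g. DESeq2 exports) can be
   ingested instead via `load_external_de()`.

3. **Network reconstruction.** From a stoichiometric model (SBML or a JSON
   reaction table), the reactions associated with measured genes are
   extracted and filtered to measured entities. Each reaction contributes
   directed educt→product metabolite edges and undirected gene–metabolite
   edges; unmeasured metabolites bridging ≥ 2 retained reactions become
   connector vertices, currency metabolites (ATP, NAD(H), water, …) are
   blocked, and PPI edges join gene vertices. Every measured vertex carries
   a 5-slot fold-change vector with a diverging blue–white–red color
   encoding (gray when not significant).

4. **Pathway subnetwork extraction.** Candidate subnetworks induced by
   pathway membership (GMT) are scored by the number of member vertices
   differentially expressed in ≥ 1 comparison, tie-broken by the
   Kolmogorov–Smirnov distance between the subnetwork's and the parental
   network's degree distributions, and the top-ranked subnetwork selected.

5. **Visualization.** Pie-glyph SVG rendering: each node is a pie with five
   equal 72° sectors (first sector centered at 12 o'clock, clockwise in
   comparison order), circles for genes, ellipses for metabolites, small
   gray dots for connectors; deterministic byte-stable output, plus a
   lossless GraphML export.

A synthetic-data module (`make_toy_model()`, `simulate_longitudinal()`,
`make_ppi()`, `make_pathway_map()`) generates the full study design — six
time points, two conditions, batches, lognormal abundances with LOD
censoring, and planted rosette-stage effects on a glutamate→GABA /
ornithine→putrescine→GABA reaction motif — so the entire pipeline is
testable end to end without external data.

## Worked example

```r
library(gmnet)

model  <- make_toy_model(seed = 1, n_extra_reactions = 10)
design <- study_design(n_lines_per_condition = 6)
sim    <- simulate_longitudinal(model, design,
                                effects = rosette_effects(), seed = 42)
proc   <- preprocess_metabolomics(sim$metabolites, sim$samples, seed = 42)
de     <- rbind(
  consecutive_comparisons(as_log2(sim$genes), sim$samples, condition = "SCZ"),
  consecutive_comparisons(proc, sim$samples, condition = "SCZ"))
net    <- build_parental_network(model, features(sim$genes), features(proc),
                                 ppi = make_ppi(model, 6, seed = 42),
                                 results = de)
scores <- score_subnetworks(net, make_pathway_map(model, 4, seed = 42))
print(scores, digits = 3)
```

```
         pathway de_count degree_distance n_vertices n_edges
1 polyamine_gaba       11           0.473         12      19
2       decoy_02        1           0.423          8      14
3       decoy_03        1           0.484          6      10
4       decoy_01        0           0.423          8      11
5       decoy_04        0           0.484          7      11
```

The planted `polyamine_gaba` pathway ranks first: 11 of its 12 member
vertices are significant in at least one comparison, against ≤ 1 for the
decoys. The significant rows of `de` recover the planted rosette-stage
signal at its magnitude — e.g. `GAD2  d7 vs d16  log2FC −2.22,
padj 3.7e−04` and `putrescine  d16 vs d27  log2FC +2.56, padj 1.1e−04` for
planted shifts of −2 and +2. Render the winning subnetwork with:

```r
sub <- select_subnetwork(scores, net, make_pathway_map(model, 4, seed = 42))
render_svg(sub, compute_layout(sub, seed = 1), path = "polyamine_gaba.svg")
```

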