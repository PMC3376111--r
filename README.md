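# graftnet

Temporal, cell-type-resolved transcriptome analysis for vascular-injury
studies, culminating in **backpropagation interaction networks** and
**DMNC focus-hub signatures**.

## The problem

When a vein is grafted into the arterial circulation it suffers an
implantation injury that drives intimal hyperplasia, the main cause of
mid-term graft failure. Time-course expression profiling of the two
vessel compartments — endothelial cells (EC) and medial smooth muscle
cells (SMC), each sampled in graft and paired control vessel across
timepoints from hours to weeks — shows a genomic response that peaks
early and resolves late. The analytical challenge is to connect the
late, lesion-defining transcriptional state back to its earliest
upstream effectors, and to distill the response into a small set of
"focus hub" genes shared by both cell types.

`graftnet` implements that full analysis as a tested R pipeline:

1. **QC / normalization** — quantile normalization, sample PCA,
   correlation-distance (1 − Pearson r) complete-linkage clustering.
2. **Per-timepoint differential expression** — empirical-Bayes
   moderated t statistics. With per-gene pooled variance `s²_g` (df
   `d_g`) and a fitted scaled-inverse-χ² prior `(d₀, s₀²)`, the
   posterior variance is `s̃² = (d₀·s₀² + d_g·s²_g) / (d₀ + d_g)` and
   `t̃ = Δ / (s̃·√(1/n₁ + 1/n₂))` with `d₀ + d_g` df. A gene is DE when
   `|FC| ≥ 2` and BH-adjusted `p ≤ 0.05` (both inclusive).
3. **Time-course selection** — a moderated F over the J per-timepoint
   contrasts, `F̃ = (Σⱼ t̃ⱼ²)/J ~ F(J, d₀ + Σ d_g)`, selecting genes at
   raw `p < 0.01`; selected profiles are z-scored and K-means clustered
   into temporal archetypes.
4. **Gene-set over-representation** — one-sided hypergeometric
   (Fisher) tests against GMT collections, BH or Holm corrected, with
   up/down/unmodified directionality fractions per set.
5. **Backpropagation network** — layer 1 is the DE set at the final
   timepoint; each earlier layer keeps the genes DE at that timepoint
   with at least one interaction-network edge into the layer below.
   *Dominant pathways* cover ≥ 10% of the integrated network's genes
   and are significantly enriched.
6. **Focus hubs and signature** — each gene of the integrated network
   is scored by the density of its maximum neighborhood component,
   `DMNC(v) = |E(MNC)| / |V(MNC)|^ε` (ε = 1.7); the signature is the
   top-K (default 10) hubs common to both cell types by DMNC rank-sum.

A synthetic-data module generates full cohorts (expression + scale-free
interaction network + GMT collection) with planted DE genes, planted
dense-neighborhood hubs and a planted dominant pathway, so every stage
is validated against known truth.

## Worked example

```r
library(graftnet)

cfg <- sim_config(seed = 42)              # 1000 genes, EC+SMC, 5 timepoints,
bundle <- simulate_bundle(cfg, "sim")     # 3 animals/group, 50 planted DE genes
res <- run_pipeline(
  bundle$paths$expression, bundle$paths$metadata,
  bundle$paths$network, bundle$paths$gene_sets,
  outdir = "out", seed = 42)
```

The DE table holds one row per gene × cell type × timepoint:

```r
head(subset(res$de, is_de & cell_type == "EC" & timepoint == "12H"), 3)
#>          gene cell_type timepoint   log2fc signed_fc t_moderated        p_adj is_de
#> 1028 GENE0028        EC       12H  1.87266  3.662064    9.312479 3.712627e-09  TRUE
#> 1088 GENE0088        EC       12H -2.17011 -4.500587  -10.404518 4.285341e-10  TRUE
#> 1113 GENE0113        EC       12H  1.72070  3.295964    8.628550 1.598149e-08  TRUE
```

`signed_fc` uses the display convention of published DE tables: −4.5
means 4.5-fold *down*. The layered network walks the five timepoints
backward from 30 days, and the dominant-pathway rule recovers the
planted pathway (16% coverage of the 50-gene network, adjusted
p ≈ 2.5e−06):

```r
res$layered$EC
#> LayeredNetwork (EC): 5 layers
#>   30D  : 24 genes
#>   7D   : 24 genes
#>   24H  : 25 genes
#>   12H  : 25 genes
#>   2H   : 25 genes
#>   integrated: 50 nodes, 104 edges

res$dominant$EC
#>               set_name coverage n_covered n_network        p_raw        p_adj
#> 1 PWY_PLANTED_DOMINANT     0.16         8        50 2.107139e-07 2.528566e-06
```

The signature ranks the hubs common to both cell types by DMNC
rank-sum; the two planted hubs (`GENE0791`, `GENE0868`, DMNC
28/8^1.7 ≈ 0.816) come out on top:

```r
head(res$signature$hubs, 3)
#>       gene rank_a rank_b    dmnc_a    dmnc_b combined_rank signature_rank
#> 1 GENE0791      1      1 0.8164039 0.8164039             2              1
#> 2 GENE0868      2      2 0.8164039 0.8164039             4              2
#> 3 GENE0088      3      3 0.8164039 0.8164039             6              3
```

All tables, annotated GraphML/JSON networks and a checksummed run
manifest are written under `outdir`; reruns with the same inputs and
seed are byte-identical.

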