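# mepdiverge

Transcriptome and chromatin-accessibility divergence at the bifurcation of a
bipotential hematopoietic progenitor.

## The scientific problem

The megakaryocyte–erythroid progenitor (MEP) is a bipotential cell population
that produces two very different daughter lineages: megakaryocytes (MEG) and
erythroblasts (ERY). Across many functional-genomics studies the MEP groups
with multipotent progenitors and MEG when cell types are compared by stable
RNA, but with erythroid cells when compared by chromatin accessibility
(ATAC-seq). `mepdiverge` implements, as a tested and reusable pipeline, the
analysis that quantifies this discordance and the two hypotheses proposed to
explain it:

* **H1 — precocious actuation**: candidate *cis*-regulatory elements (cCREs)
  of genes expressed only later in ERY are already accessible in the MEP;
* **H2 — RNA retention**: genes expressed in MEP and MEG retain abundant
  stable RNA in MEP although their cCREs have lost accessibility there.

The package is aimed at computational biologists who want to re-run, probe,
or extend this analysis on their own expression/accessibility tables — or on
fully synthetic data with known ground truth.

## What it computes

1. **Expression calls** — FPKMs are transformed as `log2(FPKM + 1.1)` (so
   FPKM 0 maps to 0.1375) and a gene is *expressed* in a cell type only when
   its pooled level is strictly above `log2 FPKM = 3`. Genes are partitioned
   over the 8 subsets of {MEP, MEG, ERY} they are expressed in.
2. **Nine-category differential expression** — each gene gets a composite
   label over {U, D, N}² (MEG-vs-MEP then ERY-vs-MEP) by two independent
   routes: pairwise tests (FDR gate + expressed-in-either gate + direction)
   and k-means clustering of row-standardized patterns mapped to categories
   by a centroid margin of δ log2 units. The consensus keeps genes labelled
   identically (and not NN) by both routes.
3. **TF-occupancy enrichment** — ChIP-seq peaks are assigned to gene
   neighborhoods (gene span ± 10 kb); per category the percentage of occupied
   genes is compared with the non-differential background as
   `log2(%category / %background)` with a Haldane pseudocount. A co-bound
   pseudo-TF track (e.g. the TAL1/LYL1/LMO2/ERG/FLI1/GATA2/RUNX1 heptad) is
   built at base resolution.
4. **cCRE signal-state discordance** — cCREs pair with genes through the
   same ±10 kb window; per cell type the normalized ATAC signal (−log10 p) is
   discretized into L (< 1.3), M, or H (≥ 8.6, or the data mean) states; the
   27 cross-cell-type categories are tabulated and the informative subsets

   * H1: state(MEP) > state(MEG) and state(ERY) > state(MEG) —
     {HLH, HLM, HMH, MLH, MLM}
   * H2: state(MEP) = L and state(MEG) ∈ {M, H} —
     {LHH, LHL, LHM, LMH, LML, LMM}

   are tested by a 2×2 contingency table per cluster: odds ratio
   `OR = ad/(bc)`, Woolf 95 % CI `exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d))`, and
   an exact two-sided Fisher p-value.
5. **Synthetic data** — a seeded simulator generates gene models, a
   replicated trilineage FPKM matrix built from 12 expression archetypes, an
   upstream-style DE table, cCREs with expression-coupled ATAC signals
   (with injectable precocious-actuation and RNA-retention discordance), and
   TF peak sets with archetype-dependent occupancy — all with a ground-truth
   ledger for parameter-recovery experiments.

The per-category cCRE–gene pair counts of the original study are packaged in
`inst/extdata/` and `replicate_tables()` recomputes the full
hypothesis-by-cluster panel from them.

## Worked example

```r
library(mepdiverge)

cfg    <- simulation_config(f_precocious = 0.5, seed = 42)
sim    <- simulate_dataset(cfg)
report <- run_pipeline(sim$annotation, sim$expression, sim$de,
                       sim$ccres, sim$peaks, seed = 1)
print(report)
#> divergence_report
#>   expressed per cell type: MEP=1102, MEG=1031, ERY=1065
#>   DE genes: pairwise 1105, consensus 1086, background 895
#>   discordance tests:
#>     H1_precocious.cluster10      OR 4.10 [3.65, 4.59]
#>     H1_precocious.cluster3       OR 0.00 [NA, NA]
#>     H2_rna_retention.cluster10   OR 0.76 [0.64, 0.90]
#>     H2_rna_retention.cluster3    OR 0.00 [NA, NA]
```

About 23–25 % of the 2000 simulated genes are expressed per cell type (a
fraction the simulator shares with the study data). Half of the ERY-only
genes had their MEP cCRE signals drawn from the high-accessibility state
(`f_precocious = 0.5`), and the H1 test on the ERY-only cluster duly reports
a strong enrichment (OR 4.10) while the reciprocal H2 test reports
depletion; in this clean simulation the MEP-and-MEG cluster has *no* pairs
in the H1 subset (its MEG states are essentially always H), hence the
degenerate OR 0 rows.

The packaged study counts reproduce the printed results exactly:

```r
print(replicate_tables()$H1_precocious.cluster10)
#> cCRE-gene pair enrichment (Fisher's exact test)
#>   2x2 counts: a=1050 b=4173 c=4976 d=43725
#>   % in subset: cluster 20.1 vs all 10.2
#>   odds ratio 2.21, 95% CI [2.05, 2.38], p = 6.56e-88
```

i.e. of the 5223 cCRE–gene pairs for the ERY-only expression cluster, 20.1 %
fall in the five precocious-actuation categories versus 10.2 % expected — a
2.21-fold odds enrichment.

## Vignette

`vignettes/lineage-divergence.Rmd` documents the model and its assumptions,
every tunable threshold with its default and rationale, what the simulator
does and does not emulate, and the numerical conventions (boundary rules,
tie-breaks, degenerate tables).
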