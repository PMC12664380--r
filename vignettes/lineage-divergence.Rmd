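---
title: "Quantifying transcriptome / chromatin-accessibility discordance at a lineage bifurcation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptome / chromatin-accessibility discordance at a lineage bifurcation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepdiverge)
```

## The system and the question

A bipotential megakaryocyte–erythroid progenitor (MEP) gives rise to two
daughter lineages, megakaryocytes (MEG) and erythroblasts (ERY). Comparisons
of cell types by stable RNA place the MEP next to multipotent progenitors
and MEG; comparisons by chromatin accessibility place it next to erythroid
cells. `mepdiverge` implements the pipeline that quantifies this discordance
from three ingredients: a gene-level FPKM expression matrix with replicates,
per-comparison differential-expression statistics from any upstream tool,
and a table of candidate *cis*-regulatory elements (cCREs) with per-cell-type
normalized ATAC-seq signals (−log10 p of deviation from a negative-binomial
background).

Two mechanisms are tested. Under **precocious actuation (H1)**, regulatory
elements of genes destined for high ERY expression are already accessible in
the progenitor, so the informative accessibility patterns are those with a
higher state in MEP and ERY than in MEG. Under **RNA retention (H2)**, genes
expressed in MEP and MEG keep abundant stable RNA in MEP after their
elements lose accessibility there, so the informative patterns have a low
MEP state with a medium-or-high MEG state.

## Expression model and thresholds

FPKMs are transformed as `log2(FPKM + ε)` with ε = 1.1. The additive
constant avoids log-of-zero (an FPKM of 0 maps to the floor level 0.1375)
and damps ratio instability for weakly covered genes. A gene is called
*expressed* in a cell type only when its pooled level is **strictly** above
τ = 3 log2 units; a level of exactly 3 is silent. The strictness direction
matters at the archetype boundaries of the simulator and is asserted by the
test suite. The threshold itself is an empirical property of deeply
sequenced libraries — it sits where marker genes of foreign lineages plateau
— and is a parameter (`expressed_threshold`) rather than a constant.

Pooling defaults to the arithmetic mean of replicate FPKMs before
transformation; when an upstream quantifier provides pooled abundances they
can be supplied via `call_expressed(..., pooled_fpkm = )` and take
precedence. A `per_replicate` mode (every replicate above τ) is available
for conservative call sets. Replicate agreement is summarized by Spearman
correlation over genes with FPKM > 0 in *both* replicates; including
zero-FPKM genes would manufacture ties at the ε-floor and inflate the
coefficient.

Two auxiliary procedures mirror common upstream quirks. Read-heavy loci
masked during quantification (globin genes in erythroid samples) are
assigned FPKMs by the count-to-FPKM ratio of the most highly expressed
unmasked genes; the ratio is computed on sums over the top 20 genes rather
than as a mean of per-gene ratios, which a single low-FPKM outlier could
dominate. A weak replicate can be replaced by *pseudoreplicates*: the pooled
alignments are re-split into equal halves by a seeded permutation. Because
pseudoreplicates understate the true replicate variance, the pairwise DE
gate for a comparison based on them should be tightened (the `alpha`
argument accepts per-comparison thresholds; 0.02 instead of 0.05 is the
replication setting for the MEG comparison).

## Nine-category differential expression

Each gene receives a composite label over {U, D, N}² — the MEG-vs-MEP
outcome followed by the ERY-vs-MEP outcome — by two deliberately independent
routes.

**Pairwise route.** Per comparison a gene is U (or D) only if its q-value
passes the FDR threshold, the fold change is positive (negative), *and* the
gene is expressed in at least one of the two cell types compared; otherwise
N. The expressed-in-either reading (rather than expressed-in-both) is the
one under which silent-to-expressed activation — the biologically central
case for the U category — is scorable at all.

**Clustering route.** Genes that are DE candidates are clustered by k-means
on row-standardized log2 levels across the trio. Standardization uses an sd
floor of 1e-6 so constant rows do not divide by zero — but note that a
constant row standardized is pure noise of unit norm, which is *why* only
candidate DE genes are clustered: flat (NN) genes would scatter across
pattern space and contaminate every centroid. Lloyd iterations run to
convergence (300 iterations maximum) from seeded farthest-point
initializations, restarted `nstart` times with the best within-cluster sum
of squares (WSS) kept; the fit is deterministic given the seed. The WSS
curve over k is non-increasing, so an interior "minimum" cannot literally
exist; when k is scanned the package picks the elbow — the largest discrete
second difference of the curve — and `k = 12` is exposed as the fixed
replication default. Clusters become category labels through their centroid
on the *raw* log2 scale: a daughter is U (D) when the centroid difference
from the progenitor is at least +δ (at most −δ), with δ = 1 log2 unit (a
2-fold margin) by default. No published mapping rule exists for this step;
the margin rule is this package's explicit, configurable stand-in, and δ at
one third of the simulator's 3-unit archetype effect recovers planted labels
essentially perfectly.

**Consensus.** A gene is retained only when both routes agree on a non-NN
label. The operation is symmetric and idempotent, and per category the
consensus can be no larger than either input. Genes labelled NN by both
routes form the background for occupancy enrichment.

## TF occupancy

A peak is assigned to a gene when it overlaps, by at least one base, the
gene span extended by 10 kb on both ends (clamped at coordinate 0). The
extension is strand-symmetric: "upstream of the TSS" and "past the polyA
site" jointly extend both ends of a whole-gene interval, making strand
irrelevant for the geometry. One peak may hit several genes and vice versa.
Occupancy is binary per gene (≥ 1 peak), not peak-count weighted.

Enrichment per category is `log2(%occupied_category / %occupied_background)`
with a Haldane-style pseudocount of 0.5 occupied genes added symmetrically
to each percentage, keeping scores finite for zero-occupancy categories and
making the score antisymmetric under swapping category and background. The
co-bound "heptad" pseudo-track is computed at base resolution: a base
belongs to the track when at least `min_cobound` of the merged input tracks
cover it (default: all of them). Peak-level reciprocal-overlap definitions
would be an alternative; the base-sharing rule was chosen because it is
order-free, shard-invariant, and exactly testable against per-base counting.

## cCRE signal states and the discordance tests

cCREs pair with genes through the same ±10 kb window (any-overlap by
default; a full-containment mode is available, and any-overlap was chosen
for symmetry with peak assignment). Signals are discretized per cell type:
L below 1.3 — the peak-calling cutoff on the −log10 p scale — H at or above
the high threshold, M in between. The boundary conventions (1.3 → M,
8.6 → H) follow from the defining inequalities "below 1.3" and "at least
8.6" and are asserted by tests. The default high threshold 8.6 is the mean
signal over all cCRE–gene pairs and analysis cell types of the original
dataset; in `data_mean` mode the package recomputes it from the data at
hand (over pairs, i.e. a cCRE counts once per associated gene — the
convention is configuration, not hard-coded), which is the right default
for synthetic or foreign data.

The three states across MEP, MEG (immature-cell accessibility, as the
mature cell type lacks ATAC data; the column mapping is configuration) and
ERY give 27 categories. The H1-informative subset is derived by predicate —
state(MEP) > state(MEG) and state(ERY) > state(MEG) under L < M < H — and
equals {HLH, HLM, HMH, MLH, MLM}; the H2 subset — state(MEP) = L,
state(MEG) ∈ {M, H} — equals {LHH, LHL, LHM, LMH, LML, LMM}. The two
subsets are provably disjoint.

Each hypothesis × cluster test arranges pair counts in a 2×2 table:
cluster pairs in/not in the subset versus all-expressed-gene pairs in/not in
the subset. By default the all-genes column *includes* the cluster's pairs;
this is the convention under which the packaged study tables reproduce their
printed odds ratios exactly, and it is what "observed versus expected"
means when the expectation is the whole-population rate. The statistically
cleaner disjoint-column variant is available as `cluster_excluded = TRUE`
and is the right choice when the test's nominal calibration matters (see
below). The odds ratio is the sample cross-product estimate with the Woolf
log-normal confidence interval; a conditional-MLE variant
(`or_method = "cmle"`) is available but the sample estimator is the default
because it is the one that reproduces the packaged tables at printed
precision. The p-value is the exact two-sided Fisher probability, computed
by summing hypergeometric point probabilities not exceeding the observed one
(with the conventional 1e-7 relative tie tolerance); the test suite verifies
it against independent enumeration for every 2×2 table with total ≤ 60.
Tables with a zero margin are flagged degenerate: the OR is reported as
computed (possibly 0 or ∞), the CI and p as NA.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` generates: non-overlapping gene models with ≥ 25 kb
spacing (so ±10 kb neighborhoods are unambiguous); a replicated FPKM matrix
from 12 expression archetypes (`FPKM = 2^(level + noise) − ε`, floored at
0, noise sd 0.5 log2 units, differential effects of 3 log2 units around an
expressed baseline of 6 and silent baseline of 1.5); an upstream-style DE
table from a known-variance z-test on replicate means with BH adjustment
(emulating what a count-based DE tool would hand the pipeline); cCREs per
gene as Poisson(λ = 6.4 — the study's pairs-per-expressed-gene ratio) with
positions uniform in the flanked span and signals drawn per cell type from
truncated normals matched to the gene's expressed/silent truth (L mean 0.4,
M mean 4, H mean 12, sd 1.5, floored at 0 — generated directly on the
−log10 p scale the pipeline consumes, rather than via simulated counts);
and TF peaks with archetype-dependent occupancy probabilities (default: one
progenitor-cell factor at 0.2 baseline, 0.8 in one archetype — a planted
4-fold, log2 = 2 enrichment). Discordance is injected by overriding MEP
signals: a fraction `f_precocious` of ERY-only genes draws MEP signals from
the high state, a fraction `f_retention` of MEP∧MEG genes from the low
state. Everything is a pure function of the config seed.

The simulator does **not** emulate: read-level noise or mapping artifacts
(FPKMs are drawn, not estimated), overlapping or nested genes, distance-
dependent cCRE–gene regulation, correlated signals across neighboring cCREs,
cell-population heterogeneity (the proposed *explanation* of the discordance
— the simulator injects its *signature* instead), or realistic
between-archetype expression correlation. Passing parameter-recovery tests
therefore shows the pipeline's inferential machinery is correct under its
own assumptions, not that those assumptions hold in any real dataset.
Dataset-level aggregates of the original study (total expressed genes,
shared-set sizes, DE totals, replicate correlations) depend on the deposited
sequencing data and upstream aligners and are deliberately out of scope;
they are covered by conservation and concordance properties on synthetic
data only.

## Calibration of the null

The Fisher test assumes independent pairs, but pairs sharing a gene share
that gene's expression pattern, so category membership is correlated within
genes. Random *gene* clusters drawn across heterogeneous archetypes would
therefore be overdispersed relative to the hypergeometric null. The
package's calibration experiment controls this by drawing null clusters
within a single expression stratum (genes silent in MEP and MEG, expressed
in ERY — the very stratum the H1 test targets), where pair-level subset
membership is i.i.d. given the stratum, and by using the cluster-excluded
contrast (the cluster-included table is structurally conservative because
the cluster is part of its own expectation). Under these conditions 200
random clusters reject at about the nominal 5 % level. Interpreting the
default cluster-included test on real clusters, where archetype mixing and
within-gene correlation are present, should lean on the odds ratio and its
confidence interval rather than the raw p-value.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at 300–2500 genes, 2 replicates
× 3 cell types, ~6.4 cCREs per gene, and 200 null-cluster draws — sizes at
which every stochastic acceptance margin (label accuracy ≥ 0.9, planted
enrichment within ±0.2 log2 units, strict odds-ratio monotonicity over
injected fractions) holds with a comfortable buffer across seeds. Remaining
conventions, chosen once for determinism: canonical-transcript ties after
the three ordered keys (transcript length, CDS length, exon count, all
descending) break lexicographically by transcript id; exclusion filters
(random contigs, snoRNA ids — both configurable regexes) run *before* the
canonical lookup is consulted, so a lookup naming an excluded gene is
silently moot rather than resurrecting it; all internal coordinates are
0-based half-open with conversion at the I/O boundary only; expression
matrices are written with 17 significant digits so round trips are
bit-identical.

## Known limitations

* The cluster-to-category margin δ has no published counterpart; results
  downstream of the clustering route should be checked for δ-sensitivity.
* The k-means elbow on a WSS curve is a heuristic; `k_fixed` exists because
  reasonable curves can have ambiguous elbows.
* The discordance analysis treats every cCRE–gene pair equally; no
  weighting by distance, signal magnitude beyond the three states, or cCRE
  multiplicity per gene.
* Degenerate contingency tables (zero margins) are reported, not rescued;
  clusters whose state distributions make a subset impossible yield OR 0 or
  ∞ with NA intervals by design.
* The packaged study tables enter as transcribed counts; the package can
  verify and reproduce the statistics computed *from* them, but not re-derive
  the counts themselves without the original sequencing data.
* Published totals for the original dataset differ slightly between analysis
  stages (7570 versus 7590 genes expressed in at least one cell type),
  presumably because the expressed universe was recomputed at different
  stages upstream. This package computes the universe once, in
  `call_expressed()`, and uses it consistently; the report echoes the single
  count it used rather than attempting to reconcile the two.
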