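---
title: "Inferring cell-cell crosstalk in the aging neurogenic niche"
author: "nichecrosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell-cell crosstalk in the aging neurogenic niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecrosstalk)
```

## The problem

During brain aging, cytotoxic CD8⁺ T cells appear in the subventricular
zone, a neurogenic niche that is essentially devoid of them in young
animals. Explaining that infiltration from single-cell transcriptomes is a
communication-inference problem: which sender populations (inflammatory
microglia, activated venous endothelium) express ligands whose receptors
are up-regulated on the infiltrating cells, and are those ligand–receptor
co-expressions stronger than chance? This package provides the full chain
from raw counts to scored, permutation-tested gene pairs, together with a
ground-truth simulator so that every stage can be validated quantitatively.

## The model, stage by stage

### Quality control and normalization

Cells are kept when their detected-gene count lies in `[200, 2500]`
(inclusive — removal is defined by *fewer than* 200 or *more than* 2500)
and their mitochondrial fraction is at most 10%. Mitochondrial genes are
recognized by the mouse `mt-` prefix; the simulator uses the same rule so
the two stages cannot drift apart. Filtering is idempotent and preserves
cell order.

Expression is library-size normalized and log-transformed:
$v_{gc} = \ln\!\left(1 + 10^4\, x_{gc} / \sum_g x_{gc}\right)$.
Zeros map to zeros, so sparsity is preserved, and `expm1(v)` recovers the
scaled counts exactly.

### Differential expression

Each gene is tested with a two-sided Wilcoxon rank-sum test. For combined
sample sizes up to 12 with no ties the p-value is exact, by complete
enumeration of all `choose(n, n_a)` rank assignments; beyond that, a normal
approximation with tie-corrected variance and a 0.5 continuity correction
is used. The cutoff at 12 keeps enumeration costs trivial (at most 924
assignments) while the approximation error at that size is already below
0.02 (verified against the exact path in the tests). P-values are
Bonferroni-corrected over the genes actually tested; by default only genes
detected in ≥ 10% of cells in either group are tested, and that count is
the correction denominator. Fold change is computed on the de-logged scale
with a pseudocount of one,
$\log_2\frac{\overline{\mathrm{expm1}(v_a)} + 1}
            {\overline{\mathrm{expm1}(v_b)} + 1}$,
the convention of the standard single-cell toolkits, which makes
`deg_table(a, b)` exactly antisymmetric to `deg_table(b, a)`. A gene is a
DEG when `p_adj < 0.05` and `|log2fc| > 0.1`.

Two contrast modes are exposed, because figure-level analyses use both:
`"age"` (old vs young within one cell type — the aging contrast used
throughout) and `"marker"` (one type vs all the rest).

### Pair enumeration and scoring

The reference database holds *directed* records: `gene_a` is the sender
(ligand) side, `gene_b` the receiver side. A record is emitted as a
candidate pair when `gene_a` is an up-regulated DEG in the sender table and
`gene_b` in the receiver table (direction configurable; "up" is the
default because it is the direction of the biological question). Database
genes absent from the expression panel are skipped with a warning rather
than an error — reference databases are supersets of any given panel.

Two power conventions are implemented because both appear in practice:

* `sum_lfc`: `log2fc_a + log2fc_b` — emphasizes coordinated up-regulation;
* `product_expr`: `mean_a × mean_b` — emphasizes absolute expression.

Evidence-channel confidences (experimental, curated-database, text-mining)
are aggregated by noisy-OR, $1 - \prod_i (1 - c_i)$. The formula is
monotone non-decreasing in every channel, reduces to the single channel
when only one is present, and saturates at 1 — the natural semantics for
independent lines of evidence of an interaction's existence.

### Permutation significance

For a pair the observed statistic is the product of cluster means,
$T = \overline{v}_{a,\mathrm{sender}} \times
     \overline{v}_{b,\mathrm{receiver}}$,
the de-facto standard for ligand–receptor permutation testing. The null is
built by jointly shuffling the cluster labels of *all* cells and
recomputing $T$; with the add-one convention
$p = (1 + \#\{T^\ast \ge T\}) / (1 + B)$ the smallest attainable value is
$1/(B+1)$ and the test is one-sided in the upper tail (strong
communication means a large product). For the age contrast the shuffled
labels are type×age combinations and the statistic compares the two aged
clusters, matching the communication actually being scored. An
`exhaustive` mode enumerates every distinct assignment when the cell count
is tiny, which the tests use as an oracle anchor.

### Functional context

`term_restrict` keeps pairs whose members lie in a term (`both`) or touch
it (`either`); `filter_effect` selects by annotated action effect (the
positive-effect pairs are the activating ones). `summarize_cell_pairs`
aggregates to one row per (sender, receiver) type pair — pair count and
total power — which is what Sankey and dot-plot figures consume.

Preranked GSEA ranks genes by `sign(log2fc) × (−log10 p_raw)` — the
standard preranked metric that uses both effect direction and
significance; ties break by fold change, then gene name, so the ranking is
strictly deterministic. The enrichment score is the classic weighted
Kolmogorov–Smirnov running sum with weight exponent `p = 1` (configurable;
`p = 0` recovers the unweighted statistic); on an exact tie between the
positive and negative extremum the positive one is reported. The null uses
random gene-label sets of matched size — phenotype permutation is
impossible without sample-level replicates — with `NES = ES / mean(|ES*|)`
over same-sign null values, add-one nominal p, and the GSEA-style FDR
(pooled-null vs observed tail fractions on the NES scale, floored at the
smallest attainable nominal p, capped at 1). Nulls are shared across sets
of equal size, and the null-path ES is computed from hit positions alone
in O(set size), which is what makes 1000 permutations cheap.

Term over-representation is the one-sided hypergeometric upper tail
(`phyper`), and the activation z-score is
$z = (n_{up} - n_{down})/\sqrt{n_{up} + n_{down}}$ over the DEGs annotated
to a term, flagged significant at `|z| > 2` (strict, so exactly 4 up and 0
down is *not* flagged) and enrichment `p < 0.05`. With zero annotated DEGs
the z-score is reported as `NA` and never significant.

## The simulator: what it emulates and what it does not

`sim_config()` defines the study conditions: two age groups × seven cell
types (microglia, central/effector memory CD8 T cells, macrophages,
arterial/capillary/venous endothelium), 300 cells per type per age group,
negative-binomial counts with `var = μ + μ²/θ` (θ = 2 — mid-range
overdispersion for droplet data), lognormal(0, 0.3) library-size factors,
and planted fold-4 effects in the aged groups: Ccl3/Ccl4/Tnf/Spp1 in
microglia, Ccr2/Ccr5/Itgb1/Itgb2 in central-memory T cells, Vcam1/Icam1 in
venous endothelium, plus fold-0.25 *down*-regulation of the tight-junction
genes Cldn5/Ocln in aged capillaries. Fold 4 for the planted signals is a
strong but realistic aged-inflammation effect; 0.25 mirrors it for the
barrier-loss direction. Each cell type also carries a disjoint block of 20
marker genes (so clustering is recoverable) and the panel includes the 13
mouse mitochondrial genes, whose means are scaled to give a ~4%
mitochondrial fraction. The background panel has 2800 genes: the panel
must exceed the 2500-gene upper QC bound, otherwise over-detection decoy
cells could not exist.

QC decoys are ordinary simulated cells broken in one specific way: zeroed
down to ≤ 150 detected genes, padded with ones past 2600 detected genes,
or given a ~20% mitochondrial load. The truth table records planted
effects, planted pairs, and decoy identities, so tests recount everything
independently.

What the simulator does **not** model: batch effects, doublets beyond the
detection-bound decoys, spatial structure, gene–gene correlation beyond
the planted design, and ambient RNA. Passing tests therefore demonstrate
the *statistical machinery* is correct and calibrated under NB sampling;
they do not certify performance on real tissue, where those nuisances
exist.

## Numerical and design choices

* **Determinism**: one global seed; per-stage seeds are derived by adding a
  31-bit polynomial hash of the stage name, so stages can be re-run in
  isolation and the pipeline manifest (md5 per output) certifies
  reproducibility.
* **QC boundary semantics**: bounds are inclusive-keep, the literal reading
  of removal criteria stated as strict inequalities.
* **Wilcoxon degenerate cases**: zero variance (all values tied) yields
  p = 1; exact mode refuses ties rather than silently approximating.
* **Louvain resolution**: default 1. For coarse cell-type recovery on
  cleanly separated populations, resolution 0.5 avoids the occasional
  legitimate sub-splitting of one type; the recovery tests state that
  condition explicitly. All interaction-stage analyses consume the
  ground-truth labels carried in the cell metadata, so communication
  results never depend on community-detection behaviour.
* **Calibration testing**: add-one permutation p-values live on a
  `(B+1)`-atom grid; before a Kolmogorov–Smirnov uniformity check they are
  de-discretized by subtracting `U/(B+1)` with `U ~ Unif(0,1)`, which is
  exactly continuous-uniform under the null. Because a single fixed-seed
  KS draw at threshold 0.01 fails for 1% of seeds even when calibration is
  perfect, the check aggregates three replicate fixtures by Fisher's
  method and evaluates the false-positive rate on the pooled 600 pairs.
* **Problem sizes**: the test and acceptance workloads use 300 cells per
  type per age group and 1000 permutations for the headline recovery
  checks, 500 permutations × 200 pairs × 3 fixtures for calibration, and
  1000-gene ranked lists for GSEA power — sizes at which Monte-Carlo noise
  is far below the tested tolerances while a full run completes in a few
  minutes.
* **Open choice, DE contrast**: whether pair enumeration should use
  old-vs-young DEGs within each type or cluster-marker DEGs is genuinely
  underdetermined; both are implemented (`contrast = "age"` / `"marker"`)
  with `"age"` the default, since aging communication is the question the
  package is built around.

## Known limitations

The permutation statistic tests co-expression magnitude, not causal
signaling; confidences are annotation priors, not data-driven
probabilities; the GSEA gene-label null is known to be more liberal than
phenotype permutation when genes are co-expressed; and the shipped
interaction database and gene sets are synthetic stand-ins — real analyses
should supply curated resources in the same TSV/GMT formats.
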