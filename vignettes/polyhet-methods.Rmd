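---
title: "Methods: expression dominance and heterosis analysis in polyploid hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression dominance and heterosis analysis in polyploid hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyhet)
```

# The problem

When a diploid or autotetraploid F1 hybrid is compared with its two parents,
each expressed gene tells a small inheritance story: the hybrid can track the
parental average, mimic one parent, or escape the parental range altogether.
Aggregated over the transcriptome, the balance of these modes — and how it
shifts with ploidy — is informative about heterosis. polyhet implements the
full chain from count matrices to that classification, together with the
surrounding quantitative-genetic and genomic-context statistics, for designs
with two ploidy levels (2x, 4x), three genotype roles (maternal parent,
paternal parent, hybrid), two developmental stages and replicated libraries.

# Differential expression model

The unit of analysis is a two-group contrast on a gene-by-sample count
matrix.

**Normalization.** Median-of-ratios size factors: the reference for each gene
is its geometric mean across samples, computed over genes with no zero count;
each sample's factor is the median of its count/reference ratios, rescaled so
the factors have geometric mean 1. Multiplying one sample's counts by a
constant multiplies its factor by the same constant, leaving normalized
means — and hence every downstream log2 fold change — unchanged.

**Dispersion.** Counts are modelled as negative binomial with
`Var = mu + phi * mu^2`. Per gene, `phi` is estimated by method of moments
from the within-group sample variances pooled across the two groups, then
shrunk 50/50 toward the mean dispersion of similarly expressed genes (20
bins by mean-expression rank) and floored at `1e-4`. The shrinkage borrows
strength across genes, which is essential at the 2–3 replicates typical of
these designs; the floor prevents degenerate Wald statistics for genes whose
sample variance happens to fall below the Poisson line.

**Test.** The Wald statistic is formed on
`log2FC = log2((mean_a + 0.5)/(mean_b + 0.5))` with a delta-method standard
error from the NB variance of each group mean; two-sided p-values come from
the normal reference, and Benjamini–Hochberg q-values are computed per
contrast over the tested genes only. Genes with zero counts in every sample
of both groups are reported as untested and excluded from the BH family,
so the family is exactly the set of testable hypotheses. The pseudocount 0.5
stabilizes fold changes at low counts; it biases extreme fold changes toward
zero, which is conservative for the FC gate.

On 10,000-gene null simulations (both groups drawn from the same NB model,
`phi = 0.1`, three replicates) the observed fraction of `p < 0.05` sits near
0.065 — slightly liberal, a known property of per-gene Wald tests with
moment-based dispersions at n = 3, and acceptable here because DEG calling
additionally requires a 2-fold change, which dominates the operating
characteristics at these depths.

**DEG definition.** `FC >= 2` and `FDR <= 0.05`, both inclusive, both
configurable (`deg_thresholds()`). Calling is monotone in both thresholds.

**Replicate QC.** Within each (ploidy, role, stage) group, Pearson
correlation on `log2(normalized + 1)`; a sample is dropped when its best
within-group correlation is below `min_corr` (default 0.8). A group is never
reduced below two retained replicates — if the filter would do that, the two
best-correlated samples are kept and a warning is raised, because a
one-replicate group cannot be tested at all.

# Set algebra and dominance classification

For one (ploidy, stage) block the three contrasts are parents against each
other (`DEGs_PP`) and the hybrid against each parent; `DEGs_HP` is defined as
the **union** of the two hybrid–parent sets (a gene disturbed relative to
either parent is hybrid-responsive). Direction is deliberately ignored in the
set algebra: sets count genes, not up/down calls. Ploidy-specific sets are
plain set differences of the `DEGs_HP` sets at the same stage, computed on a
shared gene universe (the same count matrix feeds both ploidies).

Each `DEGs_HP` gene is classified from the triple of significance calls
`(hybrid vs P1, hybrid vs P2, P1 vs P2)`, each in `{+, -, 0}` under the same
dual FC/FDR criterion used for DEG calling — not raw p-values, so a single
significance definition governs the whole analysis. With H the parent with
the higher normalized mean and L the other:

* **transgressive up / down** — hybrid significantly above (below) both
  parents; three patterns each by the parental call (`+`, `0`, `-`);
* **additive** — parents significantly different and the hybrid
  significantly different from both in opposite directions (intermediate
  expression); two patterns by which parent is higher;
* **high-parent ELD** — parents differ, hybrid indistinguishable from H and
  significantly above L; two patterns;
* **low-parent ELD** — parents differ, hybrid indistinguishable from L and
  significantly below H; two patterns.

That is 12 patterns in five groups; every other call configuration —
including the all-`0` one and configurations whose calls cannot arise from a
single consistent ordering of the three means — is reported as
`unclassified` rather than forced into a group. The classifier is a total
function over all 27 call combinations crossed with both parent-mean
orderings (an exhaustively enumerated test asserts exclusivity and
exhaustiveness), and is invariant under relabelling the parents. Which
physical parent is "high" is decided by normalized means; an exact tie
without a significant parental contrast only reaches branches that do not
need the ordering.

Percentages in the dominance summary are of *classified* genes, rounded to
two decimals at the reporting layer only. Heterosis candidates are the union
of the high-parent-ELD and transgressive-up groups; candidate sets from two
stages can be intersected to find constitutive candidates.

# Trait heterosis and cytology

`MPH = 100 (F1 − MP)/MP` with `MP = (P1+P2)/2`, and `HPH = 100 (F1 − HP)/HP`
with `HP = max(P1, P2)`. HP is the algebraic maximum for every trait, even
where agronomically "better" means smaller — a documented caveat, not a
switch. Since `HP >= MP`, `HPH <= MPH` whenever parent means are positive.
Rounding to two decimals happens only when reporting; internals keep full
precision. Zero mid-parent or best-parent means are errors, not NaNs.

Cytology frequencies are pooled binomial proportions: the overall frequency
of normal cells across meiotic stages uses summed counts, never the mean of
per-stage percentages, so stages with different cell totals are weighted
correctly. Two-proportion comparisons default to the chi-square test with
continuity correction; `exact = TRUE` switches to Fisher's exact test where
counts are small.

# Interval mapping and enrichment

All interval arithmetic is 0-based half-open internally; GFF3 (1-based
inclusive) and QTL TSVs are converted at the IO boundary and back on export,
and the two conversions compose to the identity. A gene hits a QTL when they
share a chromosome and at least 1 bp (any-overlap, not containment — genes
straddling a QTL border should not vanish on a convention choice). Per-trait
summaries deduplicate genes within a trait but not across traits, since a
gene can legitimately support two traits. The overlap engine is
`GenomicRanges::findOverlaps`; tests pin it to an all-pairs brute-force
oracle.

Over-representation uses the hypergeometric upper tail `P(X >= k)` for `k`
annotated genes in a set of `n` from a universe of `N` containing `K`
annotated genes, with BH correction within each annotation namespace
(BP/MF/CC/KEGG-style), because significance is conventionally reported
per category. The universe is the set of genes actually tested in the
relevant contrasts, not the whole genome — the standard guard against
expression-level bias in ORA. Terms with fewer than `min_term_size = 3`
universe genes are skipped as untestable.

# The synthetic-data generator

`generate_experiment()` emulates the statistical structure the analysis
assumes: per-gene baseline log2 means drawn `N(7, 2)` (counts from single
digits to tens of thousands, as in typical anther RNA-seq), NB dispersion
0.1 by default, log-normal library-size factors with CV 0.3 renormalized to
geometric mean 1 (matching the normalization model), three replicates per
group, and planted dominance patterns. Genes are shuffled with the seeded
RNG and contiguous blocks assigned to groups in a fixed canonical order, so
the assignment is reproducible and auditable; true group means are stored
alongside the counts for white-box tests.

Planted effects place every significant pairwise difference exactly
`effect_log2fc` apart on the log2 scale. In particular, additive genes put
the hybrid at the **geometric (log-scale) mid-parent** with each parent
`effect_log2fc` away. Placing the hybrid at the arithmetic mid-parent of
parents separated by `effect_log2fc` would leave the hybrid–parent contrasts
at or below the FC >= 2 gate, making the additive group undetectable by
construction rather than by any property of the method; the geometric
placement keeps all planted contrasts at the same detectable effect size,
which is what a recovery experiment needs. The same per-gene pattern is
planted in every (ploidy, stage) block — consequently ploidy-specific sets
are near-empty on simulated data, and recovery tests classify a single
trio's `DEGs_HP` directly.

What the generator does **not** emulate: GC/length biases, batch effects,
outlier replicates (beyond what the QC test injects), correlated genes,
isoforms, or allele-specific expression. Passing recovery tests therefore
demonstrates the statistical machinery is correct under its own model, not
that real libraries meet that model.

# Problem sizes and numerical choices

The test suite validates on simulations of 400–2,000 genes (10,000 for the
null type-I check and the interval brute-force cross-check at 10,000 genes ×
1,000 QTLs), chosen as the smallest sizes at which the asserted properties
are statistically stable. Recovery assertions use dispersion 0.05 and 4-fold
planted effects at n = 3 — a strongly powered regime, since they test the
classification logic, not the power frontier. Deterministic behaviour is
enforced throughout: every stochastic entry point takes an explicit seed,
generators restore the caller's RNG state, and the pipeline writes
byte-identical outputs on rerun.

Known limitations: the DE test has no covariates or batch terms; dispersion
shrinkage weight (50/50) and bin count (20) are conventions, not estimates;
the twelve-pattern scheme needs all three contrasts testable for a gene —
genes untested in any contrast fall out at the DEG stage; and hypergeometric
enrichment ignores the GO DAG (no term propagation).
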