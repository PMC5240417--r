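# hybridmode

Expression-inheritance classification for F1 hybrid transcriptome trios.

## What problem this solves

When an F1 hybrid is profiled by RNA-seq alongside its two parents, each
gene's expression can be **additive** (hybrid mean equal to the mid-parent
value, MPV = (μ_P1 + μ_P2)/2), show **complete dominance** (equal to one
parent), **incomplete dominance** (between the parents but distinct from
both and from the MPV), or be **transgressive** (outside the parental
range: over- or under-dominant). Quantifying this spectrum is how hybrid
and polyploid studies ask whether novel phenotypes arise from additive
blending or from transgressive reprogramming.

`hybridmode` is for researchers with gene-level counts from three de novo
assemblies (two parents + hybrid) who want that classification with
explicit, testable statistics. It provides:

* **unigene selection** from transcript clusters — retain a transcript if
  FPKM > 2 *or* it has ortholog evidence, keep the longest representative
  per cluster (`select_unigenes()`, `compute_n50()`, `assembly_summary()`);
* **ortholog-group integration** — groups as connected components of the
  pairwise ortholog graph, a universal identifier per group, counts
  assigned per group with structural zeros for species-specific singletons
  (`build_groups()`, `counts_to_groups()`, `venn_counts()`);
* **negative-binomial DE testing** — median-of-ratios size factors,
  moment/shrinkage dispersion (Var = μ + αμ²), an exact conditional test
  plus a Wald test, and the dual-test consensus rule: DEG ⇔ both
  BH-adjusted p < 0.001 **and** |log2FC| > 1
  (`test_de()`, `adjust_bh()`, `deg_summary()`);
* **inheritance classification** of parent-vs-parent DEGs by contrasting
  the hybrid against each parent and the MPV (with delta-method parental
  uncertainty), transgressive branches evaluated first
  (`classify()`, `classify_all()`, `inheritance_table()`);
* a **seeded simulator** of count trios with known per-gene inheritance
  modes, singletons, tissues and library-size factors
  (`simulate_trio()`), so the full chain is validated by parameter
  recovery rather than trust.

A pipeline orchestrator (`run_pipeline()`, YAML-configurable, with a thin
CLI in `inst/cli/hybridmode.R`) runs simulate → select → groups → DE →
classify → report end to end, deterministically under a fixed seed.

## Worked example

Simulate a trio with known modes, analyse it, and compare calls to truth:

```r
library(hybridmode)

cfg <- sim_config(n_genes = 2000, replicates_per_tissue = 3, seed = 42)
sim <- simulate_trio(cfg)
ana <- analyze_trio(do.call(cbind, sim$counts), sim$metadata)
inheritance_table(ana$classification)
```

```
  tissue n_total n_F1a pct_F1a n_F1b_P1 pct_F1b_P1 n_F1b_P2 pct_F1b_P2 n_F1c
    leaf    1050     3    0.29      513      48.86      504      48.00     5
 corolla    1047     8    0.76      513      49.00      500      47.76     5
 Overall    1047     8    0.76      513      49.00      500      47.76     5
 pct_F1c n_F1d_over pct_F1d_over n_F1d_under pct_F1d_under
    0.48         16         1.52           9          0.86
    0.48         15         1.43           6          0.57
    0.48         15         1.43           6          0.57
```

Each row tabulates the genes classified in that tissue (the `Overall` row
deduplicates groups called in both tissues, corolla taking precedence on
conflicts). Counts and percentages cover the six resolvable modes;
`ambiguous` genes — indistinguishable from both parents — are excluded from
the denominator. In this run most classified genes are singletons or
strong dominance cases, so the two `F1b` columns dominate, and at three
replicates only a minority of truly additive genes have the power to be
resolved as `F1a`:

```r
rec <- recovery_metrics(ana$classification$calls, sim$truth)
round(rec$recall, 2)
```

```
   F1a    F1b_P1    F1b_P2       F1c  F1d_over F1d_under
  0.45      0.98      0.99      0.38      0.93      0.78
```

At six replicates (see `scripts/acceptance.R`) mean per-class recall rises
above 0.8 with transgressive precision above 0.99 — the quantitative basis
for trusting transgressive calls more than additive/incomplete ones at low
replication.

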