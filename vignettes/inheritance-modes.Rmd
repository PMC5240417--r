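---
title: "Classifying expression inheritance in an F1 hybrid transcriptome trio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying expression inheritance in an F1 hybrid transcriptome trio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridmode)
```

## The question

When two divergent plant genomes meet in an F1 hybrid, each gene's
expression level can behave in qualitatively different ways relative to the
parents. With the two parental means written $\mu_{P1}$ and $\mu_{P2}$ and
the mid-parent value $\mathrm{MPV} = (\mu_{P1} + \mu_{P2})/2$, the classical
quantitative-genetics vocabulary distinguishes:

* **additive** (semi-dominant) inheritance: hybrid mean $= \mathrm{MPV}$;
* **complete dominance**: hybrid mean equal to one parent while differing
  from the other;
* **incomplete dominance**: hybrid mean strictly between the parents but
  distinct from both and from the MPV;
* **transgressive** expression: hybrid mean outside the parental range —
  over-dominant above both parents, under-dominant below both.

`hybridmode` implements this classification for gene-level RNA-seq counts
from de novo assemblies of the three genotypes, together with the
scaffolding such a comparison needs: reduction of per-species transcript
clusters to unigenes, integration of the three gene universes through
ortholog groups, and negative-binomial differential-expression (DE) testing.
A seeded simulator generates trios with known inheritance modes so the whole
chain can be validated quantitatively.

## Upstream: unigenes and ortholog groups

De novo assemblies inflate gene counts through isoforms and fragments.
`select_unigenes()` applies two retention rules per transcript — FPKM
strictly greater than 2, **or** ortholog evidence in another species — and
keeps one representative per cluster: the longest ortholog-linked transcript
where such evidence exists, otherwise the longest retained isoform. The
strictness of "> 2" matters at the boundary (a transcript at exactly 2 with
no ortholog is dropped), so the simulator plants exact-threshold FPKM values
for testing. Ties on length resolve to the lexicographically smallest
transcript id, making selection deterministic. When the ortholog-linked
isoform is not the longest in its cluster, we keep the ortholog-linked one:
downstream ortholog groups need the linked gene, and this choice had to be
made here because no convention exists for it.

`build_groups()` forms ortholog groups as connected components of the
pairwise ortholog graph and assigns each a universal identifier. A component
with two genes of one species (many-to-many orthology) cannot provide "one
expression value per species per group", so the lexicographically first gene
of that species stays in the group and the rest become singleton groups —
a deterministic resolution chosen because upstream orthology tools do not
export their own. Genes with no ortholog anywhere become singleton groups,
and `counts_to_groups()` gives them **structural zeros** in the two absent
species' samples. This convention makes species-specific genes visible to
the DE stage as extreme fold changes rather than missing data; the
pseudo-count in the fold change (below) keeps them finite.

## The DE machinery

Counts are modelled as negative binomial with mean $\mu$ and dispersion
$\alpha$ under the parameterization $\mathrm{Var} = \mu + \alpha\mu^2$
($\alpha = 0$ recovers the Poisson). The parameterization is stated
explicitly everywhere to avoid the size/probability ambiguity of `rnbinom`.

**Normalization** is median-of-ratios: each sample's factor is the median
across genes (expressed in all samples) of the count over the gene's
geometric mean, rescaled to geometric mean one. Like every global-scaling
method it assumes that *most genes are not differentially expressed*;
simulations whose gene panels are dominated by DE genes violate this and
show a per-species scaling bias of tens of percent, which propagates into
every downstream contrast. Simulated validation panels therefore keep a
non-DE (conserved) share, and real analyses should too.

**Dispersion** is estimated per gene by the method of moments,
$\hat\alpha = \max\{0, (s^2 - \bar y)/\bar y^2\}$, pooled across design
groups by degrees of freedom, then shrunk toward the 10%-trimmed mean of
the gene-wise estimates with weight $1/\bar n$ (the mean replicates per
group). At the two replicates typical of this design the raw moment
estimate is extremely noisy; the shrinkage is the simplest estimator that
is consistent as replication grows while borrowing strength at small $n$.

**Two tests, one consensus.** Each two-group contrast is evaluated twice:

1. an **exact conditional test**: conditioning on the gene's total count,
   the split between the two group sums is enumerated over the whole
   lattice; each group's sum is treated as negative binomial with
   moment-matched size (exact when size factors are equal within a group,
   since NB sums with a common dispersion are NB). Two-sided p-values sum
   the probabilities of splits no more likely than the observed one. As
   $\alpha \to 0$ this converges to the binomial conditional (Poisson)
   test, which the test suite verifies to $10^{-6}$. Totals above 10,000
   switch to a normal approximation of the conditional law — a documented
   cutoff bounding runtime; at such totals the approximation error is far
   below the decision thresholds.
2. a **Wald test** on the difference of log normalized means, with
   delta-method variances from the NB moments.

A gene is a DEG only when **both** tests give BH-adjusted $p < 0.001$
*and* $|\log_2 \mathrm{FC}| > 1$. Requiring two tests with different
operating characteristics to agree mirrors the common practice of
intersecting the calls of two DE packages; both thresholds are exposed
(`padj_cutoff`, `log2fc_cutoff`). The BH step-up itself is part of the
package's own statistical core and is cross-checked against
`stats::p.adjust` in the tests. Fold changes use a pseudo-count of 0.5 on
normalized means so that structural-zero singleton groups yield finite
values instead of dominating the extreme tail.

**The MPV contrast** has no second group: the null mean
$(\hat\mu_{P1} + \hat\mu_{P2})/2$ is itself estimated, so the Wald variance
adds the parental estimation uncertainty by the delta method,
$\mathrm{Var}(\widehat{\mathrm{MPV}}) = (V_1 + V_2)/4$. Only the Wald form
applies here; there is no total to condition on. The MPV is defined on the
**linear** expected-count scale because the trait under study is expression
abundance itself; a log-scale mid-parent would implicitly test the
geometric mean.

## The classification tree

Only genes differentially expressed *between the parents* enter — without a
parental difference the modes are not distinguishable. For each entry gene,
three companion contrasts (hybrid vs each parent, hybrid vs MPV) are
reduced to `sig_up` / `sig_down` / `ns` using the dual-test adjusted-p rule
**without** the fold-change gate: an "equals parent" or "equals MPV"
judgment is about statistical indistinguishability, and gating it on a
2-fold change would misread modest but real displacements. (The gate can be
restored via `de_outcome(use_lfc_gate = TRUE)`.) The tree is evaluated so
that transgressive calls take precedence:

1. significantly above (below) both parents → over- (under-) dominant;
2. indistinguishable from exactly one parent and significant against the
   other → complete dominance toward the indistinguishable parent;
3. significant against both parents in opposite directions (strictly
   between them) → additive if indistinguishable from the MPV, otherwise
   incomplete dominance;
4. indistinguishable from both parents → `ambiguous`: the design lacks the
   resolution to place the gene, and such calls are excluded from summary
   denominators rather than forced into a mode.

Treating "hybrid equals MPV" as *non-rejection* of the MPV null is lenient
(an equivalence test would be stricter); it is the reading most consistent
with classifying every resolvable gene, and the `ambiguous` category
absorbs the genuinely unresolvable ones.

Per-tissue calls are merged into an overall set deduplicated by group id;
when tissues disagree the corolla call wins (the flower is the phenotype of
interest in the motivating design) and the conflict is flagged.

## The simulator

`simulate_trio()` draws, per gene and tissue, a reference parental mean
$2^u$ with $u \sim U(5, 10)$ — i.e. 32–1024 expected counts, the regime of
genes surviving an FPKM > 2 filter at bulk depths of tens of millions of
reads. Non-conserved genes get a parental $|\log_2$FC$|$ drawn uniformly
from $[\ell, \ell + 2]$ with $\ell$ = `parental_log2fc_min` (default 2, so
true effects sit above the DEG detection threshold of 1), random direction.
The hybrid mean then encodes the mode exactly: the linear MPV for additive
genes; one parental mean for dominance; at least the transgressive margin
(default 1 log2) outside the parental range for transgressive genes.

Incomplete-dominant means must lie strictly between the parents and at
least the margin away from the MPV in log2. The interval *above* the MPV
never has room — $\log_2(2r/(1+r)) < 1$ for any fold change $r$ — so these
means are placed below the MPV, toward the lower parent; the configuration
validator enforces the geometric feasibility condition
$2^{\ell} > 2^{m+1} - 1$ (margin $m$). A consequence worth knowing: some
incomplete-dominant genes sit close to the lower parent and are the
dominant source of confusion with complete dominance at realistic
replication.

Per-sample library-size factors are uniform on (0.7, 1.4); one dispersion
per gene is shared across species and tissues (the simplest structure the
estimator can be asked to recover); tissues get independent means because
the analysis treats tissues separately. A configurable fraction of genes
per species is species-specific, with structural zeros elsewhere — the
default of 0.2 per species makes roughly a third of each species' genes
singletons and one fifth of the union hybrid-specific, matching the shape
of real three-assembly comparisons. Default mode proportions put 70% of
genes in the conserved class and split the remainder in proportions that
mirror observed inheritance spectra (dominance ≫ transgressive >
incomplete > additive). Within-species biological variability is not pinned
by the motivating design (two replicates); dispersion stays a free
parameter with default 0.05, a mid-range value for biological replicates of
inbred plant material.

What the simulator does **not** emulate: read-level noise and mapping
ambiguity, correlated dispersion–mean structure, allele-specific
expression, partial orthology (the simulated ortholog map is exact), and
tissue-correlated effects. Passing recovery tests therefore demonstrates
the statistical chain is sound under its own assumptions, not that real
assemblies meet those assumptions.

## Validation problem sizes

The test suite validates the exact test against exhaustive NB-convolution
enumeration for totals up to 50 at $\alpha \in \{0, 0.1, 0.5\}$
(tolerance $10^{-10}$), the Poisson limit on 1,000 random cases
($10^{-6}$), and BH against the hand-computed step-up on 10,000 random
vectors. Classification recovery runs five seeded trios of 5,000 genes at
six replicates per tissue, dispersion 0.05, parental $|\log_2$FC$| \ge 2$
and margin 1; recovery is measured over the genes that actually enter the
classification (detected parental DEGs), since the tree cannot act on
genes the DE stage missed. `scripts/acceptance.R` re-runs the same
computation from scratch and also re-derives published-style summary
percentages from their integer counts through `percent()`, whose rounding
contract — half away from zero, two decimals — is fixed package-wide.

## Known limitations

* Median-of-ratios normalization requires a non-DE majority; panels
  dominated by DE genes (or sharply asymmetric DE) bias all contrasts.
* The MPV test is a non-rejection criterion: at low replication it
  over-assigns `F1a`, and at very high replication it over-assigns `F1c`
  (every tiny deviation from additivity eventually becomes significant).
  The margin-based simulator quantifies this trade-off.
* The exact test's moment-matched sum distribution is exact only for equal
  size factors within a group; with heterogeneous factors it is an
  approximation (the Wald arm of the consensus is unaffected).
* Two replicates — the motivating design — leave dispersion estimation
  heavily shrinkage-dependent; conclusions about individual borderline
  genes should not be over-read.
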