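---
title: "Identifying mitochondria-enriched microRNAs from compartment-fractionated small RNA-seq"
author: "mitomiRseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying mitochondria-enriched microRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomiRseq)
```

## The problem

Cardiomyocytes are packed with mitochondria, and heart failure is in large
part an energy-metabolism disease. A subset of microRNAs ("mitomiRs") is
found within or on mitochondria — mostly nuclear-encoded and imported — and
may regulate metabolic programs locally. Profiling them requires physically
fractionating heart tissue into a mitochondrial RNA pool and a whole-tissue
("total") pool, sequencing both, and asking which miRNAs rise specifically in
the mitochondrial fraction of the failing heart.

Two features of such studies drive every statistical choice in this package:

1. **No replicates.** RNA from many animals (here, 12 per group) is pooled
   into a single library per (compartment, condition) cell. Differential
   expression must therefore come from a two-library exact test, not a
   replicated model.
2. **Contamination.** However carefully mitochondria are purified and
   RNase-treated, the mitochondrial fraction retains cytosolic RNA. A miRNA
   that is simply abundant in cytosol will appear in the mitochondrial
   library; only the *cross-compartment contrast* — up in mitochondria, flat
   or down in total RNA — distinguishes genuine enrichment from carry-over.

## The exact two-library test

For one miRNA, let $x_1, x_2$ be its counts in two libraries with total
sizes $N_1, N_2$. Modelling the counts as independent Poisson variables with
means proportional to (library size) × (relative abundance), and
conditioning on the total $n = x_1 + x_2$, the first count follows

$$X_1 \mid n \;\sim\; \mathrm{Binomial}\!\left(n,\; \pi\right),\qquad
\pi = \frac{N_1}{N_1 + N_2}$$

under the null hypothesis of equal relative abundance. The two-sided p-value
is computed by the minimum-likelihood rule: sum the probabilities of all
outcomes $k \in [0, n]$ whose point mass does not exceed that of the observed
$x_1$ (with the same relative tolerance `binom.test()` uses). This is the
standard convention for exact binomial tests; a doubled-smaller-tail variant
is available via `method = "doubled"`. A total of $n = 0$ carries no
information and yields $p = 1$. The test is exact, hence conservative: its
empirical type-I error at $\alpha = 0.05$ sits near 0.04 (the test suite
verifies $\le 0.055$ on a 10,000-replicate Poisson null with expected count
20).

Fold changes are reported as $\log_2$ ratios of counts-per-million with a
pseudo-count (default 0.5 CPM) on both sides, so single-zero rows stay
finite; double-zero rows have no defined ratio and are reported missing
rather than $\pm\infty$. P-values are Benjamini–Hochberg adjusted
(`bhFdr()`, delegating to `stats::p.adjust`) across the miRNAs retained in
each pairwise comparison. Calls use strict inequalities — fold $> 2$ and
$p < 0.05$ for "up", fold $< 0.5$ for "down" — with raw p-values by default
and q-values behind `use_q = TRUE`: unreplicated pooled designs commonly
report raw exact-test p-values with FDR alongside, and both are always in
the output. A miRNA enters a pairwise table only if detected (count
$\ge$ `min_count`, default 1 read) in at least one of the two libraries.

Heatmap ordering uses agglomerative average-linkage clustering on
$1 - r$ (Pearson) distances, the most common convention for expression
heatmaps. Zero-variance rows have no defined correlation; they are assigned
maximal distance, excluded from the tree and appended last, with a warning.

## ΔΔCt quantification

Stem-loop qPCR validation uses triplicate Ct values, averaged per sample,
normalized against a small-RNA reference (U6; GAPDH for mRNA markers):

$$\Delta Ct = \overline{Ct}_{\text{target}} - \overline{Ct}_{\text{ref}},
\qquad \Delta\Delta Ct = \Delta Ct_{\text{treat}} - \Delta Ct_{\text{ctrl}},
\qquad \text{fold} = 2^{-\Delta\Delta Ct}.$$

Amplification efficiency is fixed at 2 (perfect doubling); efficiency
correction is out of scope. Replicate aggregation is a plain mean with no
outlier rejection; a QC check warns (only) when the within-triplicate spread
exceeds 0.5 cycles. Note a structural property verified by the tests: the
estimator is log-normally biased upward by
$\exp\{(\sigma_{\Delta\Delta Ct}\ln 2)^2/2\}$ under Gaussian Ct noise, and
the reference-gene noise of one run is shared by every target of that run,
so per-run fold changes are correlated.

## The mitomiR decision rule

`classifyMitomir()` encodes the cross-compartment contrast: a miRNA is
**enriched** when its mitochondrial-fraction fold change (TAC/sham) strictly
exceeds 2 with support (exact-test $p < 0.05$, or a qPCR estimate, which
carries no test), *and* its whole-tissue fold change is "decreased or
unchanged". The published rule gives no numeric meaning to "unchanged"; we
operationalize it as total fold $\le 1 + \texttt{unchanged\_tolerance}$ with
default tolerance 0.2, i.e. up to a 20 % rise still counts as flat. This is
a declared choice, configurable, not an inference. Raising the total fold
can only demote a call (monotonicity, property-tested). When both sequencing
and qPCR evidence exist for the mitochondrial side, qPCR takes precedence as
the validation instrument. No multiple-testing adjustment is applied across
the (typically ~15) candidates, matching practice for small validation
panels. Missing evidence on either side yields `indeterminate`, never a
silent default.

## Pathway enrichment

Targets of the enriched miRNAs are read from a scored target map
(TarBase/microT-style); edges with score strictly greater than 0.9 are
retained and their genes pooled into a union set. Each pathway of size $K$
in a universe of $M$ genes is tested by the one-sided hypergeometric upper
tail on the overlap $k$ of the $n$-gene target set, BH-adjusted across
pathways, and reported with the number of contributing miRNAs and distinct
target genes hit. The union-set hypergeometric is the documented default
behaviour of the mirPath-style tools this mirrors; per-miRNA p-value merging
modes are deliberately not implemented. The default universe is the union of
all pathway genes, overridable (e.g. to all genes in the target map); the
background is a genuine free parameter that published reports rarely state.

## What the simulator emulates

`simulateCounts()` draws the study design directly:

* **Baseline abundances** are log-normal (`sdlog` 1.5 by default) — the
  standard stylized fact that a few miRNAs dominate a small-RNA library.
* **Planted mitomiRs** (default 20 of 300) receive per-condition log2
  effects in the mitochondrial pool (default $(3, 1)$ at 4 and 8 weeks —
  strong early enrichment that partially recedes late) and independent
  effects in the whole-tissue pool (default 0, "unchanged in total"). Each
  pool is renormalized to sum to one, so planting an effect slightly dilutes
  every other miRNA, exactly as in real relative-abundance data.
* **Contamination**: the observed mitochondrial library mean is
  $N[(1-\phi)\,m + \phi\,t]$, a mixture of the true mitochondrial pool $m$
  and the whole-tissue pool $t$. The default $\phi = 0.2$ reflects that
  RNase treatment reduces but cannot eliminate cytosolic carry-over; no
  published estimate of the true level exists, so this moderate default is a
  stated choice that meaningfully exercises the classifier.
* **Counts** are Poisson (matching the exact test's assumption) at
  `dispersion = 0`, or negative-binomial with variance $m + d\,m^2$ to
  stress-test robustness.
* **qPCR records**: $Ct = Ct_0 - \log_2(a) + \varepsilon$, with $a$ the
  miRNA's relative abundance in the *observed* compartment RNA (mixture for
  the mitochondrial fraction), $\varepsilon \sim N(0, \sigma^2)$ per
  replicate, three replicates per (miRNA, compartment, condition). The
  default $\sigma = 0.15$ cycles is a typical triplicate technical SD for
  SYBR stem-loop assays; $Ct_0 = 20$ keeps simulated Cts inside the (0, 45)
  validity band. The reference gene is exactly invariant by default;
  a per-condition drift can be configured to study violations.
* **Annotation**: every miRNA receives above-threshold "true" target edges
  and below-threshold decoys; planted mitomiRs draw 80 % of their true
  targets from one designated pathway, so that pathway should rank first
  downstream. With `planted = FALSE` all targets are uniform and no pathway
  is preferred.

All randomness flows from the single config seed through a scoped generator
that restores the caller's RNG state, so identical configs are bit-identical
and independent stages (counts, qPCR, annotation) use fixed seed offsets.

What the simulator does **not** emulate: read-level artifacts (adapter
trimming, mapping multi-hits, isomiRs), biological replicate variance
(the design has none), compositional coupling between conditions beyond
renormalization, non-invariant reference genes (unless configured), and
cell-type mixture shifts in failing tissue. Passing recovery tests therefore
demonstrate that the *statistical pipeline* is correct and calibrated under
its stated model, not that any particular biological claim holds in real
hearts.

## Numerical and design choices

* Exact-test enumeration is over the full binomial support; with pooled
  library totals around $2\times 10^6$ this costs at most a few million
  density evaluations per comparison and needs no approximation.
* BH, hypergeometric tails and average-linkage clustering delegate to
  `stats::p.adjust`, `stats::phyper` and `stats::hclust`; the test suite
  re-derives each from first principles (step-up definition, coefficient
  enumeration, naive $O(n^3)$ UPGMA) and checks equality to $10^{-10}$ or
  better.
* Ties in the enrichment report break lexicographically by pathway id;
  clustering ties follow `hclust`'s deterministic input-order behaviour.
* Thresholds are strict inequalities throughout (fold $> 2$ means strictly
  greater; score $> 0.9$ likewise), so boundary values are never called.
* Library size defaults to the column sum of the count table; a declared
  larger total (reads not mapping to known miRNAs) is accepted, a smaller
  one rejected.
* Degenerate inputs have defined behaviour: $n = 0$ tests give $p = 1$,
  empty overlap gives $p = 1$, double-zero fold changes are missing,
  zero-variance rows cluster last, and empty qPCR evidence yields
  `indeterminate` calls.

## Problem sizes used in validation

The packaged validation runs 20 independent simulated studies at the default
design (300 miRNAs, 20 planted, $2\times10^6$ reads, $\phi = 0.2$) for the
recovery experiment; 10,000-replicate nulls for calibration and power
monotonicity; exhaustive exact-test checks for all totals $\le 50$ at three
library-size ratios; 1,000 random vectors for BH; and 200 random universes
up to 60 genes for the hypergeometric oracle. Under these conditions the
recovery experiment averages sensitivity ≈ 0.93 with a false-positive rate
of ≈ 0 and the planted pathway ranking first in every run; because the
shared reference-gene noise correlates misses within a run, 20-study
averages of sensitivity vary by a few points around that value.

## Known limitations

* The exact test inherits the pooled design's weakness: it quantifies
  sampling noise only, and a single-animal outlier in a pool is invisible.
* The "unchanged in total" tolerance (default 0.2) is narrower than the
  ΔΔCt measurement noise of a single triplicate at $\sigma = 0.15$; planted
  mitomiRs whose total-tissue estimate drifts above 1.2 are missed, which is
  the dominant (and honest) source of the ~7 % sensitivity loss in the
  recovery experiment.
* The hypergeometric model treats genes as exchangeable; correlated gene
  sets and target-map biases are not modelled.
* miRNA identifiers are opaque case-sensitive strings (miRBase-21 style);
  no alias resolution is attempted.
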