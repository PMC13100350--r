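---
title: "The Regulation Ratio: model, assumptions and design choices"
author: "RegRatio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Regulation Ratio: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RegRatio)
```

## The question and the metric

A gene's expression is shaped at two layers that are usually studied
separately: transcriptional control, visible as open-chromatin regions around
the gene (ATAC-seq peaks), and post-transcriptional control, visible as
RNA–protein contact sites on its transcripts (POP-seq peaks). RegRatio makes
the two layers comparable at single-gene resolution through two per-kb
densities and their ratio.

For a gene of length $L$ bp with $A$ significant ATAC-seq peaks in its
*expanded window* and $P$ significant POP-seq peaks in its *gene body*:

$$ \mathrm{TD} = \frac{A}{L/1000}, \qquad
   \mathrm{PTD} = \frac{P}{L/1000}, \qquad
   \mathrm{RR} = \frac{\mathrm{PTD}}{\mathrm{TD}} = \frac{P}{A}. $$

Because both densities normalise by the same gene length, RR reduces exactly
to a ratio of two integer counts. Genes with $A \ge 1$ and $P \ge 1$ "pass
the filter" and are classified:

* RR > 1 — predominantly **post-transcriptionally** regulated,
* RR = 1 — **balanced**,
* RR < 1 — predominantly **transcriptionally** regulated.

RR is computed as the exact ratio of the two integers, and balance is decided
by integer equality $P = A$, never by comparing a floating-point quotient
against 1, so no gene can be misclassified at the boundary by rounding.
`log2(RR)` is finite for every passing gene and is the score exported for
pre-ranked GSEA.

## Windows

The ATAC window extends the gene span by 5,000 bp on the upstream (promoter)
side and 500 bp on the downstream side — a compromise that captures proximal
promoters and nearby enhancers/silencers without swallowing neighbouring
genes. The POP window is the gene body itself. Both distances are parameters
of `expandWindows()` with those defaults.

Two reading choices deserve explanation:

* **Strandedness.** "Upstream" is interpreted relative to the gene's own
  orientation: for a minus-strand gene the 5,000 bp extension is applied at
  the right-hand coordinate end. This is the standard promoter-capture
  interpretation. Because the unstranded reading (always extend leftwards) is
  also defensible, it is available as `stranded = FALSE` (CLI
  `--unstranded-window`), so either convention is reproducible. Genes
  without strand annotation are treated as plus strand with a warning.
* **Overlap rule.** A peak is counted for a window when they intersect by at
  least `minOverlap` bp (default 1). Requiring containment would
  systematically discard peaks straddling window edges, which peak callers
  produce routinely. A peak overlapping the expanded windows of several genes
  counts for *every* one of them — overlapping gene neighbourhoods share
  regulatory elements, and deduplication would make the counts depend on an
  arbitrary gene ordering.

Internally all intervals live in `GRanges` (1-based, closed), the Bioconductor
convention; BED-family inputs and outputs are converted at the file boundary,
so the half-open file semantics are preserved exactly (a peak starting where
a window ends does not overlap it).

## Significance filtering

Peaks enter the counts only if significant at FDR-corrected $p < 0.05$
(strict inequality). Two routes cover the two peak-caller dialects:

* `method = "qvalue"` — narrowPeak input already carries FDR-adjusted
  q-values (MACS); peaks with $q < \alpha$ are kept.
* `method = "bh"` — BED input carries raw p-values (Piranha); the
  Benjamini–Hochberg step-up adjustment is computed across the whole file
  and the adjusted values filtered at $\alpha$. BH is the field-standard FDR
  procedure; whether correction should be per-file or genome-wide is not
  determined by the inputs, and per-file is the implemented reading.

## Group statistics

Differences in gene length, isoform count, transcript abundance (FPKM) and
protein expression across the three categories are assessed with
distribution-free machinery, orchestrated by `compareCovariate()`:

* **Kruskal–Wallis** across the populated categories
  (`stats::kruskal.test`, tie-corrected H, $\chi^2$ p).
* **Pairwise Mann–Whitney U** with Bonferroni correction over the three
  pairs. U counts 1 per winning pair and 1/2 per tie. For a combined sample
  of at most 16 the p-value is exact, by enumeration of all group
  assignments — chosen because the covariates contain heavy ties and
  `stats::wilcox.test` refuses exact p-values under ties. Above that, the
  normal approximation with tie correction and continuity correction is
  used; at such sizes its error is far below anything that would change an
  interpretation.
* **Cliff's delta** per pair, computed by sorted pair counting; it satisfies
  $\delta = 2U/(nm) - 1$ under the same tie convention, and the test suite
  verifies that identity rather than assuming it.
* **Median fold changes** between categories.

Transcript-biotype composition is compared per category against a background
of all annotated transcripts. Counting is at the *transcript* level (a gene
contributes one label per transcript), labels at or below 1% of a category's
transcripts are dropped, and each retained (category, label) pair is tested
with **Fisher's exact test** on the 2×2 transcript-count table; the reported
effect is the sample odds ratio $ad/bc$, with the Haldane–Anscombe 0.5
correction (flagged) when a cell is zero. A rank test cannot produce an odds
ratio, so the contingency construction is the one consistent with reporting
ORs; this choice is recorded in the output rather than hidden.

## Cross-sample agreement

For genes passing the filter in every sample, `agreementBreakdown()` assigns
each gene to exactly one class: *full* (same category everywhere), one
*exactly-one-pair-agrees* class per sample pair, or *none*. With three
categories and three samples these classes partition the common gene set, so
their percentages sum to 100. With four or more samples two disjoint pairs
can agree simultaneously and the single-pair classes no longer partition;
rather than silently redefine them, the function supports exactly 2 or 3
samples and errors otherwise.

## What the synthetic generator emulates

`syntheticConfig()` / `simulateRegulationData()` produce a complete,
self-contained dataset: a GTF annotation, a narrowPeak ATAC file, a BED+p
POP file, covariate tables and a truth table of generating regimes.

The generative model, and why each piece looks the way it does:

* **Peak counts are Poisson**, with per-gene rate
  $\lambda_{\text{assay}}[\text{regime}] \times \text{activity} \times L/1000$.
  Under this model the per-kb density is exactly the maximum-likelihood rate
  estimator, so the package's normalisation is the statistically right one
  for its own fixtures.
* **A shared log-normal "activity" factor** (sdlog 1.0, i.e. roughly an
  order-of-magnitude spread) multiplies both assays' rates. Genes that are
  regulatorily busy are busy at both layers; without this factor the regime
  structure alone would make the two log-densities *anti*-correlated, the
  opposite of real data. The factor cancels from RR, so it changes no
  classification in expectation.
* **Balanced genes reuse one Poisson draw for both assays**, so exact
  RR = 1 genes exist at any rate — with independent draws, exact equality
  would be a measure-zero coincidence at high rates.
* **Regime fractions default to 0.41 / 0.099 / 0.491**
  (transcriptional / balanced / post-transcriptional) and the covariate
  medians to FPKM 34 / 6.75 / 310, isoforms 5 / 2 / 7, protein roughly flat
  with a 1.2× shift in the post-transcriptional group — the magnitudes
  reported for human cell-line panels that motivated the package. Gene
  lengths are log10-normal with $\mu = 4.1$, $\sigma = 0.45$ (median
  ≈ 13 kb), a realistic human gene-length scale.
* **Significance structure is exact by construction.** Significant ATAC
  peaks draw $q \in (10^{-6}, 0.049)$ and decoys $q \ge 0.06$; significant
  POP peaks draw $p \le 10^{-4}$ and decoys $p \ge 0.3$, spaced so that the
  per-file BH adjustment at $\alpha = 0.05$ recovers exactly the intended
  significant set. Truth labels therefore remain exact under the pipeline's
  own filtering. Decoys are added per gene in proportion
  $(1-\text{sigFraction})/\text{sigFraction}$, plus intergenic decoys.
* **Determinism.** Every generator stage derives its RNG stream from
  `config$seed`, so one seed fixes every output byte, independent of call
  order.

What the generator does *not* emulate: spatial clustering of peaks within
promoters, chromatin domains or peak-width biology; correlation between gene
length and regime; mappability and blacklist artefacts; replicate structure
(the pipeline expects peaks already pooled and called). Tests passing on
these fixtures therefore validate the *computational contract* — counting,
filtering, arithmetic, statistics — not the biological accuracy of any
particular dataset.

## Numerical and degenerate-input choices

* Significance thresholds are strict (`<`), matching "$p < 0.05$".
* `filterSignificant` errors, naming the first offending record, if the
  required significance field is missing — silently dropping such peaks
  would bias counts downward.
* BED records with `start >= end` are rejected with a warning and counted
  in `metadata(x)$n_rejected`; ragged BED files read missing trailing
  fields as `NA`.
* The density correlation uses log10 densities of passing genes (both are
  strictly positive there); a zero-variance axis yields `NA` with a
  warning rather than an arbitrary number. Sign flips from plotting
  conventions do not affect $r^2$, which is the comparable quantity.
* Kruskal–Wallis on all-identical observations reports H = 0 and an `NA`
  p-value with a warning.
* In `.rnk` export, ties in `log2(RR)` are broken by gene id so the output
  is deterministic; duplicate identifiers (e.g. after symbol mapping) are
  an error rather than a silent collapse.

## Problem sizes in the test suite

The shipped tests exercise the oracles at sizes chosen to finish in a couple
of minutes while leaving no interesting case untested: 1,000 randomized
interval instances against a linear-scan oracle; exact Mann–Whitney
enumeration for all group-size pairs up to 6×6; Fisher tables up to n = 200
against hypergeometric tail sums; 2,000-replicate null calibration of the
Kruskal–Wallis rejection rate; 2,000-gene parameter-recovery runs at density
ratios 2 and 4; and 50,000 genes for the agreement-class frequencies against
the exact 27-vector enumeration.

## Known limitations

* RR weighs peak *counts* only; it carries no information about the
  direction or magnitude of any individual regulatory interaction.
* The metric is gene-level; isoform-resolved regulation is out of scope.
* Cross-sample comparison matches genes by identifier; annotations must
  already be harmonised.
* The Mann–Whitney normal approximation is used above a combined n of 16;
  p-values in the far tails at moderate sizes are approximate (as in every
  standard implementation).
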