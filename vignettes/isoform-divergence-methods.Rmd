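---
title: "Classifying cis and trans divergence of isoform usage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cis and trans divergence of isoform usage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isodiverge)
```

## The question

When two inbred strains differ in *which* isoforms a gene expresses (rather
than *how much* the gene is expressed overall), the regulatory mutation
responsible lies either *in cis* — linked to the target allele — or *in
trans* — in a diffusible factor acting on both alleles. An F1 hybrid
separates the two: both parental alleles share one nuclear environment, so
a cis change keeps showing up as an allelic difference inside the F1, while
a trans change equalises the two alleles and survives only as a difference
between the parental strains.

`isodiverge` implements this logic for genes expressing exactly two
overlapping isoforms: it selects analyzable genes, summarises each gene's
strain-level and allele-level isoform usage, assigns one of four regulatory
classes by Bayesian model comparison, classifies the structural differences
between the two isoforms, and cross-tabulates the two classifications.

## Isoform usage scale

All modelling happens on the natural-log odds of the two isoforms'
expression within a sample,

$$\ell = \log\frac{e_1 + \varepsilon}{e_2 + \varepsilon},$$

with a pseudocount $\varepsilon$ (default $10^{-3}\times$ the median
positive estimate) guarding against zeros; samples where both isoforms are
zero are treated as missing. This scale makes isoform usage orthogonal to
total gene expression, and strain or allelic differences additive.

Two statistics summarise a gene:

* $d_1$ — mean F0 BL6 log-odds minus mean F0 CAST log-odds (strain
  difference), with variance $v_1$;
* $d_2$ — mean over F1 replicates of the within-replicate BL6-allele minus
  CAST-allele log-odds (allelic difference), with variance $v_2$.

The variances combine replicate scatter with the per-estimate standard
errors (the role played by MMSEQ's Monte Carlo standard errors), propagated
onto the log-odds scale by the delta method and added to the group variance
before division by the replicate count. Poorly quantified transcripts are
therefore automatically down-weighted — the same inverse-variance weighting
idea used in strain-vs-allele fold-change summaries.

## The four models

Let $\sigma_0$ be the prior SD of a free effect (default 2.0 on the
log-odds scale, i.e. one prior SD corresponds to a ~7.4-fold isoform-ratio
change — weakly informative for realistic effect sizes). With zero-centred
normal effect priors, all four marginal likelihoods are closed-form
normals:

| model | interpretation | marginal of $(d_1, d_2)$ |
|---|---|---|
| conserved | no divergence | $N(0, v_1)\times N(0, v_2)$ |
| cis | one shared effect | bivariate normal, cov $\begin{bmatrix} v_1+\sigma_0^2 & \sigma_0^2 \\ \sigma_0^2 & v_2+\sigma_0^2\end{bmatrix}$ |
| trans | strain effect only | $N(0, v_1+\sigma_0^2)\times N(0, v_2)$ |
| cis&trans | independent effects | $N(0, v_1+\sigma_0^2)\times N(0, v_2+\sigma_0^2)$ |

The cis model's correlation term is what lets it beat cis&trans when
$d_1 \approx d_2$ (an Occam factor: one shared effect explains two
statistics). With a uniform prior of 0.25 per model, posteriors are the
normalised marginals. A gene is labelled only when one model's posterior
exceeds 0.5 — i.e. the model must be more likely than all others put
together — and is otherwise left `unclassified`; the posterior margin
(best minus second best) is recorded.

The tests cross-check these closed forms against brute-force numerical
integration of the likelihood over the effect priors (agreement to
$10^{-3}$ on the log scale) and verify frozen worked values, e.g.
$d_1=d_2=0, v_1=v_2=0.1 \Rightarrow P(\text{conserved}) \approx 0.77$.

```{r}
classify_divergence(list(gene_id = "demo", d1 = 2, d2 = 2,
                         v1 = 0.01, v2 = 0.01))
```

This design replaces the original hierarchical treatment of quantification
posteriors (polytomous regression on Gibbs traces) with an explicit,
oracle-checkable two-statistic comparison; equivalence with that earlier
machinery is deliberately not claimed — what is preserved is the decision
rule (four models, uniform 0.25 prior, 0.5 posterior threshold).

## Gene selection funnel

1. **Threshold** $t$ = minimum mean expression among transcripts with at
   least 10 unique reads: the level down to which quantification is
   anchored by uniquely mapping reads.
2. **Expressed** = estimate strictly above $t$ in ≥ 4 replicates of either
   F0 group, and in ≥ 4 F1 libraries (an F1 library's value is the sum of
   its two allele columns — the rule counts the 12 libraries, not the 24
   allele columns).
3. **Analysis set** = genes with exactly two expressed isoforms that
   overlap exonically (≥ 1 shared base on the same strand — span overlap
   would wrongly call intron-nested pairs overlapping), carrying at least
   one known strain-distinguishing variant. Non-overlapping pairs are
   counted separately, mirroring their separate removal in practice.

"Strictly above" resolves the threshold-equality ambiguity conservatively
and is pinned by a test. Per-transcript expression for thresholding is the
mean across all sample columns, matching the single-scalar phrasing of the
rule. An optional MCSE-style subsetting (`mcse_subset`) anchors an
uncertainty ceiling at the worst standard error among transcripts with
exactly 1 (`t1`) or 5 (`t5`) unique reads; transcripts at the ceiling are
kept, so the all-equal case is the identity.

## Structural classification

Strand-aware, for one pair of overlapping isoforms:

* **TSS** — first exons overlap but 5' ends differ; **AFE** — first exons
  do not overlap. Mutually exclusive by construction.
* **APA** — last exons overlap but 3' ends differ; **ALE** — last exons do
  not overlap. Mutually exclusive.
* **INT** — after excluding each transcript's 5' terminus and 3' terminus
  (and both boundaries of first exons under AFE, of last exons under ALE),
  the exon boundary sets differ. This covers both private internal exons
  and shared junctions with shifted donors/acceptors, while never
  re-counting a difference already attributed to a terminal category —
  keeping the five categories independent contributions in combination
  counts.

"Different" means any difference (≥ 1 bp): the strictest reading, with no
slack window. Whether a shifted first-exon donor in an AFE pair should
additionally count as INT is genuinely open; excluding it (as here) is the
consistent choice given the terminal-attribution principle, and the
exclusion is localised in one function for sensitivity work. The
implementation is verified against an independent brute-force boundary-set
oracle on randomised transcripts, and against mirror symmetries (mirroring
coordinates with a strand flip preserves all flags; mirroring without the
flip swaps AFE↔ALE and TSS↔APA and preserves INT).

```{r}
g <- example_isoform_pair()
classify_pair(g$transcripts[[1]], g$transcripts[[2]])
```

## The synthetic cohort generator

Because the original strain expression tables are not redistributable, the
package ships a generator whose outputs carry full ground truth; every
pipeline stage is tested against it.

* **Design**: 6 replicates per F0 strain and 12 F1 hybrids measured per
  allele — the study design this pipeline targets. Classes are drawn from
  `class_probs` (uniform by default; `balance_classes = TRUE` gives exact
  per-class counts for recovery experiments).
* **Effects**: magnitude 1.5 on the log-odds scale, random sign. A cis
  gene gets $\beta_{F0} = \beta_{F1} = c$; a trans gene
  $\beta_{F0} = \tau$, $\beta_{F1} = 0$; a cis&trans gene draws both
  components independently, $\beta_{F1} = c$, $\beta_{F0} = c + \tau$
  (opposite signs can make $\beta_{F0} \approx 0$ — still a genuine
  compound gene, and kept).
* **Noise**: normal on the log-odds scale (SD 0.2 per replicate), not
  count-level binomial — the pipeline's input contract is estimate tables
  with standard errors, so count-level read simulation belongs to the
  out-of-scope deconvolution stage. Effects are split $\pm\beta/2$ around
  the baseline so total expression stays orthogonal to isoform usage.
* **Expression scale**: per-gene totals are `20 + Lognormal(log 60, 1)`
  (arbitrary consistent units — absolute units are never interpreted);
  baseline log-odds uniform on $[-1.2, 1.2]$ keeps both isoforms
  comfortably expressed. Standard errors follow
  `0.05 + 1/sqrt(expression)`, reproducing the qualitative
  uncertainty-vs-expression relationship of Monte Carlo standard errors;
  unique reads are proportional to expression with a per-transcript
  mappability factor.
* **Structure**: per-gene structural flags are drawn so that category
  frequencies match the relative shares observed for divergent two-isoform
  pairs in mouse liver (ALE 15%, TSS 18%, AFE 20%, APA 22%, INT 25% of
  ~2.2 changes per pair), with AFE/TSS and ALE/APA exclusivity enforced at
  the draw. Empty flag sets are redrawn — two structurally identical
  transcripts are not two isoforms — which slightly inflates marginal flag
  frequencies relative to the configured probabilities.
* **DGE flag**: independent Bernoulli (p = 0.37, the observed co-occurrence
  level, consistent with chance) — a true-null companion annotation that
  lets the DIU×DGE independence test be calibrated.
* **Spike-ins and the anchor**: optional genes that fail exactly one funnel
  stage each (single-isoform, three-isoform, sub-threshold minor isoform,
  variant-free, non-overlapping pair), plus one dedicated low-expression,
  well-read anchor transcript (mean 0.5 units, 10 unique reads) that pins
  the threshold at $t = 0.5$, below every analysis transcript. This makes
  the funnel's planted composition exactly recoverable, which the tests
  assert at 1258 genes.
* **In-silico F1**: `make_insilico_f1` emulates building an artificial F1
  library from one BL6 and one CAST F0 column — allele expectations are
  the half-columns, with resampling noise from the uncertainty model. At
  the default noise the log-scale Pearson correlation between pseudo-F1
  allele estimates and their originating F0 columns exceeds 0.95 across
  ~600 transcripts (log scale, because expression spans orders of
  magnitude and the claim concerns relative accuracy across that range).
* **F1 cross direction is not modelled**: the 12 F1 replicates are
  exchangeable, matching the pooling of directional crosses; parent-of-
  origin effects are out of scope.

What passing tests on this generator do **not** show: robustness to
correlated quantification errors between isoforms (deconvolution ties the
two isoforms' errors together), to batch structure across replicates, to
heavy-tailed replicate noise, or to annotation error in the transcript
models. The generator is a stand-in whose parameters are config-exposed,
not a calibrated emulator of any particular dataset.

## Statistics

Fisher's exact test (two-sided by the minimum-likelihood convention, the
dominant one — stated so the enumeration oracle matches), Pearson's
chi-squared without continuity correction, and Benjamini–Hochberg
adjustment are delegated to R's `stats` functions behind the module
surface; the odds ratio is reported as the sample cross-product $ad/bc$.
Enrichment of structural categories across regulatory classes is tested
pairwise against the conserved class by default, with cis-vs-trans as a
named preset (both framings are standard). The INT-alone excess uses the
2×2 independence construction INT × any-other-flag — the null "expected by
chance" is not uniquely defined, and this is one defensible reading.
BH adjustment is *not* idempotent in general; only flat adjusted profiles
are fixed points, and the tests assert exactly that.

## Numerical and degenerate-input choices

* Log-odds pseudocount as above; a gene-sample with both isoforms at zero
  is dropped from group means; fewer than two usable replicates in any
  group is an error rather than a silent call.
* Major-isoform mode (genes with ≥ 3 isoforms): the major isoform is the
  one with the highest mean F0 expression (ties broken by lowest
  transcript id, with a warning); its log-odds are taken against the sum
  of the rest, pooled standard errors adding in quadrature.
* A zero margin in a 2×2 table yields p = 1 with an undefined odds ratio
  (the table admits only itself).
* All coordinates are 0-based half-open internally; conversion from
  1-based inclusive GTF happens only at the I/O boundary, and a write/read
  round trip is the identity.

## Problem sizes and determinism

The test suite and the acceptance script run, end to end, on: a balanced
400-gene cohort (recovery), a 1258-gene cohort with 80 spike-ins (full
pipeline and funnel exactness), 200 re-simulated 120-gene cohorts (null
calibration of the DIU×DGE test), 10^4 random transcript pairs (structure
invariants), and ~600-transcript tables (in-silico F1). These sizes give
stable Monte-Carlo estimates while keeping a full run in a few minutes on
one core. Every run is a pure function of its seed: cohort generation
seeds the RNG from the configuration, and `run_pipeline` writes
byte-identical outputs for identical configuration and seed.

## Known limitations

* The divergence model is a two-statistic approximation; it does not
  propagate full quantification posteriors, and genes with very few usable
  replicates are refused rather than modelled hierarchically.
* Only two-isoform genes (plus the major-isoform extension) are handled;
  pairwise structure classification does not generalise to full splice
  graphs.
* Real-data headline counts from any particular study depend on that
  study's unreleased expression tables; on synthetic cohorts this package
  reproduces such results in shape, not in number.
* Variant annotation consequences (protein-coding change, NMD), gene-set
  enrichment against ontology databases, and motif scanning are outside
  the package's scope.
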