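---
title: "Methods: consensus differential expression and symbiont quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus differential expression and symbiont quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiokern)
```

# The problem

Sea anemones of the genus *Anemonia* host photosynthetic dinoflagellates
(zooxanthellae) in their gastrodermal cell layer. Comparing the
transcriptomes of symbiotic and aposymbiotic (bleached) individuals on a
two-color oligonucleotide array is complicated by strong inter-individual
variability: a gene can look differentially expressed in the pooled
state-vs-state comparison while only a few individuals actually drive the
signal. `symbiokern` implements the full analysis chain for such a study —
scan ingestion, normalization, moderated per-gene statistics, a consensus
("Kern") gene-set rule that demands support from most individuals,
tissue-specificity assignment from a dual experimental design, Fisher-exact
GO enrichment, specimen clustering — plus qPCR machinery for symbiont:host
nuclei quantification and calibrator-relative expression, and a
synthetic-data generator with planted ground truth that exercises every
stage.

# Array preprocessing

Scans arrive as GenePix-like tables (per-spot foreground/background per
channel, print-tip block). Replicate spots are collapsed to per-channel
medians. Background correction subtracts the local background, floors at
0.5 and adds a positive offset (default 50), guaranteeing finite
log-ratios; M = log2(R/G) and A = mean log2 intensity follow, with the
dye-swap member of each pair sign-flipped into a common orientation.

Within-array normalization removes the intensity-dependent dye trend per
print-tip group by tricube-weighted local regression (span 0.3, local
degree 1, four bisquare robustness iterations). Two choices here deviate
from the plainest textbook recipe and are deliberate:

* **Robustness iterations.** A single robustness pass is insufficient on
  this platform. Probes of symbiont origin collapse to background wherever
  symbionts are absent (aposymbiotic samples, the reference), so on
  symbiotic arrays they form a coherent cloud at one low-A location with
  M around +4 that can locally outvote the trend — corrupting
  host genes of similar intensity. Four bisquare iterations (the lowess
  convention) are the default.
* **Trend-fitting subset.** `normalize_within_array(fit_probes = ...)`
  fits the trend on a probe subset and applies it to all probes. The
  pipeline fits on host-origin probes only: symbiont probes violate the
  mostly-unchanged assumption of MA normalization *by construction*, and
  the platform annotation says exactly which probes they are. This is an
  analysis-side fix; the data are untouched.

The local degree is exposed because a local fit of degree *d* reproduces a
global polynomial trend of degree at most *d* exactly — which is also how
the trend-removal tests are written.

Between-array normalization defaults to A-only quantile normalization
(`aquantile`): full quantile normalization of both channels can distort
two-color contrasts, so it is offered but not default. Ties share the mean
of the tied ranks' reference values.

# Per-gene statistics: M, moderated t, and B

Each specimen is hybridized as a dye-swap pair against one common
reference. Contrasts are fitted at **array level with specimen blocks**:
the model has one mean per specimen, so the per-gene residual is the
disagreement within a dye-swap pair (df = arrays − specimens), and the
contrast of interest — the pooled batch comparison, or one individual
against the opposing pooled batch — is a linear combination of block
means with every specimen weighted equally. This matters: if individual
contrasts were instead fitted on specimen profiles with the opposing batch
treated as replicates, the genuine inter-individual heterogeneity of
expression would inflate the per-gene variance and mask exactly the genes
the consensus rule is designed to find.

Variance moderation follows the standard hierarchical model: gene-wise
variances are shrunk toward a prior (d0, s0²) estimated by trigamma-based
moment matching of log s² against its scaled-F distribution (Newton
iterations, tolerance 1e-8; d0 = ∞ when the empirical spread does not
exceed the sampling floor). The moderated t has d0 + df degrees of
freedom. B is the log posterior odds of differential expression under a
two-component normal model on the coefficient, with prior probability
`prior_p` and prior variance `v0`; `v0 = "auto"` matches the top
`prior_p` fraction of |t| to the mixture tail, with the implied prior
coefficient standard deviation clamped to [0.1, 4] log2 units.

Two defaults deserve comment:

* `moderated_stats()` defaults to `prior_p = 0.01`, the documented default
  of the package the study's analysis used.
* `run_state_contrasts()` — the pipeline entry — defaults to
  `prior_p = 0.1`. The platform is a symbiosis-*dedicated* 2,000-feature
  array: probes were selected for likely involvement in the symbiosis, and
  on top of that the symbiont-origin probes respond to the state contrast
  by construction. A 1% DE prior is wrong for such a platform and, through
  the auto-estimated `v0`, makes B miss moderate (1.5 log2) effects. The
  study itself never states the prior it used; this is the package's
  resolution of that open point, and both values are plain arguments.

A gene is called differentially expressed iff |M| > 0.59 (that is, at
least 1.5-fold: 2^0.59 ≈ 1.505) **and** B > 0, both strict, so printed
boundary values are reproducible.

# The consensus ("Kern") rule

Twelve contrasts are run: one batch contrast (all symbiotic vs all
aposymbiotic specimens) and one per specimen against the opposing pooled
batch, all oriented symbiotic-minus-aposymbiotic. For every batch-called
gene, `n_support` counts the individual contrasts called in the *same*
direction (opposite-direction calls never count; a consensus gene carries
one direction). The Kern set keeps batch-called genes of cnidarian origin
with `n_support >= 8` of 11, sorted by |batch M| within direction. Genes
with missing or ambiguous annotation are excluded, not guessed.

If the reference individual itself is listed as a specimen without arrays
(the deposited design reuses one aposymbiotic animal as the universal
reference), it enters the contrasts as an exact-zero profile — its
expression relative to the reference is identically zero by construction.
The bundled generator instead hybridizes all 11 specimens against a
neutral reference pool so that every individual carries a measurable
profile; both layouts are supported.

# Tissue assignment and the Venn cross-classification

Two designs measure gastroderm (G) vs epidermis (E) expression: direct
G-vs-E hybridizations, and each tissue against the common reference, giving
M_trans = M(G vs ref) − M(E vs ref) by transitivity. Without noise the two
agree exactly. A gene is gastroderm-preferential iff *both* exceed +0.59,
epidermis-preferential iff both fall below −0.59; discordant signs are
unassigned. Assignment uses the cross-specimen mean (per-specimen values
are also emitted). The Venn cross-classification restricts to
cnidarian-origin probes — symbiont probes are gastroderm-restricted
trivially and reported separately — and its nine regions are disjoint and
sum to the number of cnidarian probes considered.

# Specimen clustering

Hierarchical clustering of specimens on their differential-expression
profiles supports centered-Pearson and uncentered correlation distances
with complete, average and centroid linkage (centroid = correlation
distance between mean cluster profiles), deterministic tie-breaking by
specimen order, and Newick export. Zero-variance profiles get correlation
0 with a warning rather than an error.

# qPCR

Standard curves are least-squares fits of Cq on log10(copies) over
six-point 10-fold dilution series; the amplification efficiency is
E = 10^(−1/slope) (perfect doubling: slope −3.3219). Copy numbers invert
the curve; values outside the fitted range are flagged as extrapolated.
Symbiont:host nuclei ratios divide curve-based copy numbers per (symbiont
locus, host locus) pair and are rescaled to a calibrator specimen; a
consensus over locus pairs is the geometric mean, clearly labelled as an
added convenience. Undetermined symbiont reactions are reported as
below-detection with the limit implied by Cq 40 — never silently as zero.
Within-organism locus-ratio diagnostics flag departures from the expected
1:1 (default factor 2), catching locus-specific amplification.

Reference-gene stability re-implements the average-pairwise-variation
statistic: M_j is the mean over partners k of the SD across samples of
log2(q_j/q_k), with iterative exclusion of the worst gene down to a panel
(default 3, the study's selected trio) and ties broken by gene label.
Relative quantities for this analysis are E^(ΔCq) against the per-gene
minimum Cq — the conventional input scale, which the study does not state.
The normalization factor is the geometric mean of the panel quantities;
relative expression divides the target quantity by it and rescales to the
calibrator specimen (AS6). Time-course folds normalize to two references
and express each time point relative to t0, with cross-specimen geometric
means and standard errors. Technical triplicates are averaged with a flag
above 0.5 cycles.

# GO enrichment

Fisher's exact test compares term frequencies between the
symbiotic-state gene set (test) and the aposymbiotic set (reference),
two-sided by point-probability summation; terms are used flat, exactly as
annotated (no ancestor propagation, matching the flat functional classes
the study used). The raw p < 0.05 screen reproduces the study's
convention; Benjamini-Hochberg adjustment is available by flag.

# The synthetic-data generator

The generator states a world the pipeline must recover, not a tunable
benchmark. Defaults emulate the study design: 5 symbiotic + 6 aposymbiotic
specimens, dye-swap pairs against one common reference, ~2,000 probes of
which ~10% are symbiont-origin and ~4% prokaryote controls, planted state
genes at 1.5 log2 with per-individual Bernoulli activity 0.9, per-probe
log2 noise 0.3, a smooth cubic dye bias per print-tip group, additive
background ~ Normal(50, 5) truncated at zero, and baseline intensities
~ Normal(10, 1.5) on the log2 scale (no intensity model is published;
these make MA plots realistic). Planted counts default to 60 + 80,
matching the scale of the study's reported 58 + 78 state gene sets.

**Activity semantics.** "Active in individual i" means individual i
expresses the gene at its own state's planted level; an *inactive*
individual retains the opposite state's level — it has not switched its
expression with its phenotype. This is the reading under which an
individual's contrast against the opposing batch tracks that individual's
own activity, so the per-individual support count matches the planted
activity count, which is what the consensus rule is meant to measure. At
extreme activity splits (e.g. exactly 7 of 11 active spread evenly) the
batch M falls below 0.59 and the gene is not batch-called at all; the
support of such genes is zero by the batch-gating invariant, a boundary
the tests respect.

Symbiont-origin probes collapse to background-level signal in aposymbiotic
individuals, the epidermis, and the reference. The qPCR generator plants
symbiont:host ratios spanning 1 to 1e-4 of the calibrator, locus
efficiencies in [1.8, 2], a reference panel with one deliberately unstable
candidate, target folds including the study's printed examples, and a
3-fold drop at 24/48 h of heat stress.

What the generator does *not* emulate: intensity-dependent noise,
spot-quality artifacts and missing spots, scanner saturation, cross-array
batch effects beyond the dye bias, and biological correlation between
genes. A green recovery test therefore establishes that the pipeline's
inference machinery is correct under the stated model — not that the model
captures every pathology of real scans.

With every noise parameter at zero the generators write background values
identical to the draws added to the foreground, so background subtraction
(offset 0) closes exactly and every downstream estimator returns the
planted truth to floating tolerance; the noiseless tests rely on this.

# Numerical choices and degenerate inputs

* Thresholds are strict inequalities everywhere (M, B, tissue).
* Hyperparameter estimation refuses fewer than 50 informative genes and
  fully degenerate (all-zero variance) data; the pipeline recognizes the
  noise-free case and reduces the B gate to "any nonzero contrast".
* Quantile-normalization ties share the mean of the tied reference values.
* geNorm exclusion ties break by gene label; clustering ties by specimen
  order.
* An undetermined Cq yields a below-detection record; a non-positive
  quantity is an error, not a silent zero.
* The type-I property is evaluated on an all-host null dataset: symbiont
  probes are genuinely state-dependent, so counting them as false
  positives would be a category error.

# Known limitations

Only single-contrast designs are supported (no multi-factor linear
models); spot-quality flags beyond missing values are not handled; GO
ancestor propagation is not implemented; the deposited array series is not
bundled, so the study-scale numbers (58/78 batch genes, the 1,715-gene
Venn, printed fold values) are not reproduced at desk scale — the GPR
reader accepts the deposited format so a user with the series can recompute
them.
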