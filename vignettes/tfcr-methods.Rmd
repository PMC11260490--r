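---
title: "Methods: TFCR calling, RegulatoryScore, and explainable prediction"
author: "tfcrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TFCR calling, RegulatoryScore, and explainable prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `tfcrkit`, in the spirit of a methods section: what is
computed, under which assumptions, and what a passing test does and
does not establish.

## The TFCR model

Transcription factor binding sites (TFBSs) cluster on the genome, and
clusters of many, tightly packed sites mark strong cis-regulatory
elements. `tfcrkit` formalises a cluster as a **TFCR**: a peak of the
kernel density

$$f(x) = \sum_i \exp\!\left(-\frac{(x - c_i)^2}{2h^2}\right),$$

where $c_i$ are TFBS midpoints and $h = 300$ bp. Three numerical
choices matter here.

**The kernel is unnormalised** ($K(0) = 1$), so an isolated TFBS has
density exactly 1 at its own position. The complexity rule — a TFBS
*contributes* to a peak iff its kernel value at the summit is at least
0.1 — only has an absolute meaning on this scale: with a normalised
kernel the threshold would depend on $h$ and the hit count. Under the
defaults, a contributor is any hit within
$h\sqrt{2\ln 10} \approx 644$ bp of the summit. A hit may contribute
to two adjacent peaks; nothing in the model forbids shared
contributors, and forbidding them would make complexity depend on
arbitrary tie-breaking between neighbouring peaks.

**Kernels are truncated at $8h$.** A single truncated kernel errs by
$e^{-32} \approx 1.3\times10^{-14}$, so even thousands of hits stay
within the $10^{-9}$ tolerance at which the caller is tested against a
brute-force per-bp oracle. (Truncating at $4h$, which seems natural,
errs by $e^{-8} \approx 3\times10^{-4}$ per hit — far too coarse for
that oracle.) Hits farther apart than $8h$ therefore live on
independent "islands", which is what makes the caller linear-time in
practice. One artifact must be handled: on the truncated profile, the
step where a far kernel enters or leaves the window can create a
strict local maximum of magnitude $\sim10^{-14}$ with no contributor
within 644 bp. Such contributor-less peaks are numerical noise and are
discarded.

**Peaks are strict local maxima on the 1-bp grid; flat summits
collapse to the floor of their midpoint.** Two hits an odd number of
base pairs apart produce an exact two-point plateau; the rule is
deterministic and resolution-independent. The TFCR interval is the
span of its contributors' intervals — the density model itself gives a
peak no natural width, and the contributor span is the smallest
interval that explains the complexity count.

Same-family overlapping motif hits are merged (transitively) before
calling, since overlapping matches of one TF family are one biological
signal reported under several motif ids.

Complexity deciles TFCR0–TFCR9 are equal-count groups (sizes differ by
at most one), ordered by complexity with deterministic tie-breaks
(strength, then coordinates); the published grouping rule does not say
how ties split, and any nondeterministic choice would break
reproducible pipelines.

## Dynamics, evolution, and the permutation test

Between consecutive developmental stages, a TFCR is **gained** if it
shares no base with any TFCR of the previous stage, **lost** if it
shares none with the next stage, and **stable** otherwise — the 1-bp
overlap rule. A TFCR can be both gained and lost; the summary label
reports gained first. "Dynamic" means gained or lost.

The claim that stable TFCRs sit in promoters more often than dynamic
ones is tested one-sidedly by permuting the stable/dynamic labels over
the pooled set, with add-one smoothing
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm}+1)$. Because the
statistic (a difference of proportions) is discrete, the estimator is
slightly conservative when group sizes are small: ties between the
observed and permuted statistic inflate $p$. The calibration test
therefore uses 600-interval groups, where the tie mass is a few
percent and the p-value distribution is uniform to within the KS
tolerance. This is a property of any permutation test with a discrete
statistic, not of this implementation.

Cross-species comparison scales by genome size: with $N$ the ratio of
a species' genome to yeast's (sacCer3, 12,157,105 bp), the top and
bottom $\mathrm{round}(50N)$ TFCRs by complexity are selected
(deterministic tie-breaks again), and association is promoter overlap
(≥ 1 bp). The distance summary of TFCR-to-gene distances is the mode
of a Gaussian KDE (Silverman's bandwidth — none is published for this
step) divided by $N$; of the two readings of "normalised by genome
size of yeast", dividing by the species/yeast *ratio* is implemented,
since dividing by the yeast size itself would leave the statistic
proportional to absolute genome size and defeat the comparison.

## RegulatoryScore

Both TFCR complexity (of the TFCR associated with each gene's
promoter) and gene expression are split into equal-count deciles 0–9,
and

$$\mathrm{score} = \frac{G_{tfcr}}{9}\cdot\frac{G_{expr}}{9}\cdot
  e^{-|G_{tfcr}-G_{expr}|/5}.$$

The score is symmetric, zero exactly when either group is 0, maximal
(= 1) only at (9, 9), and for fixed $|G_{tfcr}-G_{expr}|$ strictly
increasing in the product — all verified by grid enumeration. The
constants 9 and 5 are treated as fixed semantics, not tunables. A
score above 0.3 pins both groups into the 5–9 range (the converse of
that statement is not literally true: e.g. the (5, 7) cell scores
0.2896 < 0.3, while every cell with both groups ≥ 5 and gap ≤ 1 does
clear the threshold).

Association is nearest-promoter by gap distance with ties to the
smaller gene id; a gene hit by several TFCRs keeps the
maximum-complexity one. Genes with no promoter-associated TFCR are
reported with `NA` and excluded from ranking; an alternative would be
to force them into group 0, but that conflates "no cluster" with
"weakest cluster" and distorts the expression deciles.

Species-specific genes: over homolog groups scored in *all* species,
each species contributes its strict top $\lfloor 0.2n\rfloor$ genes by
score; a group in exactly one top set is species-specific, a group in
all is conserved. Boundary ties at the 20% cut are excluded (strict
floor) — the published rule does not address them. Species are
clustered with distance $1 - \rho_{Spearman}$ (average ranks for ties)
and complete-linkage `hclust`; enrichment uses the upper-tail
hypergeometric test.

## Explainable prediction

Features are one-hot sequence encodings (A/C/G/T rows, `N` all-zero,
right-padded with zero columns) of the promoter ($L_p$ columns) and
TFCR ($L_t$ columns) plus the TFCR-to-promoter gap distance as a final
scalar: $4L_p + 4L_t + 1$ features. Full scale is $L_p = 4000$,
$L_t = 11113$; desk-scale tests use 200/400 because $4 \times 15113$
features are needlessly heavy for CI and nothing in the contracts
depends on the padded length.

No gradient-boosting or SHAP backend is available offline, so the tree
machinery is implemented in the package (C++): an exact-greedy
second-order gradient-boosted tree engine with squared loss,
XGBoost-style leaf values $\sum g/(n+\lambda)$, Bernoulli row
subsampling and per-tree column subsampling, with a fast path for
binary (one-hot) features. The eleven-method registry maps the four
boosting profiles onto this engine with different defaults; decision
tree, random forest (bagging) and AdaBoost.R2 reuse its trees; kNN, a
small MLP and a linear $\varepsilon$-insensitive SVR are implemented
directly; the CNN entry is registered but has no offline backend and
errors with a clear message. AdaBoost.R2 uses a weighted-*mean*
combination rather than the weighted median so that its prediction
stays a linear function of tree outputs and the attribution contract
below applies to it too. The reference boosting profile documents the
published full-scale hyperparameters (RMSE loss, 2000 iterations,
learning rate 0.1, L2 = 5, depth 12, Bernoulli bootstrap);
backend-specific knobs it cannot honour (`border_count`, ordered
boosting) are accepted and dropped with a message. Acceptance-scale
runs train 120 trees of depth 5 — the distance-recovery property is
about attribution ranking, not about squeezing out the last decimal of
test error, and 10 replicates must fit the stated time budget.

Attributions are **path-dependent TreeSHAP** (the polynomial-time
Shapley algorithm over tree paths, cover-weighted). Local accuracy —
base value plus attributions equals the prediction, per sample — is
asserted at $10^{-6}$ for every tree method, and the implementation is
verified against an exponential-time Shapley enumeration oracle on
small trees. The per-feature importance is the mean absolute
attribution. The published per-feature loss-change diagnostic is
backend-specific; a model-agnostic permutation loss-change
(`importance_by_permutation`) stands in for it and is labelled as
such.

## The synthetic world

The generator emulates exactly the structure the analyses assume, so
every downstream stage is testable without downloads:

* **Clustered placement.** TFBS clusters (geometric sizes, mean 5 by
  default) are anchored inside promoters with probability 0.7, else
  uniformly; hit centers are Gaussian-jittered (SD 80 bp) so one
  cluster maps to one density peak at $h = 300$ and called complexity
  equals cluster size — a known ground truth.
* **Stage dynamics.** A cluster that survives keeps its binding sites;
  each stage loses a `loss_rate` fraction of clusters and gains new
  ones so the gained fraction matches `gain_rate` (0.3 off-burst),
  with a `zga_gain_rate` = 0.75 burst at the ZGA-like stage, matching
  the 70–80% gained fraction reported at zygotic genome activation
  versus 20–56% elsewhere. Measured downstream through calling and
  1-bp-overlap classification, the recovered fraction sits slightly
  below the configured rate because a "new" cluster occasionally lands
  on an old one; the ZGA acceptance fixture therefore uses a 50 Mb
  background-only genome where that collision term is ~3%.
* **Expression coupling.** Expression is lognormal with a Gaussian
  copula on the rank of promoter cluster size, using latent
  correlation $2\sin(\pi\rho/6)$ so the realised Spearman correlation
  targets `expr_coupling_rho`; tied sizes share a latent value, which
  makes the coupling exact at $\rho = 1$ and keeps the $\rho = 0.6$,
  $n = 2000$ check inside ±0.05.

What the generator does **not** emulate: motif content (sequences are
uniform random), nucleotide composition, overlapping regulatory
grammar, replication timing, or any chromatin biology. A green test
therefore establishes that the *algorithms* recover planted structure
at the stated rates — not that the biological claims hold on real
data, which requires the original accession-level inputs.

Reproducibility: every random draw in the package goes through an
explicit seed; the pipeline derives per-module child seeds by stable
hashing of module names, so toggling one module never shifts
another's random stream, and identical configs give byte-identical
outputs (checksummed in the manifest).

## Coordinate conventions and other decisions

Internally everything is a `GRanges` (1-based, closed — the
Bioconductor convention); BED and FIMO coordinates are converted at
the I/O boundary. This deviates from a 0-based-half-open-everywhere
design but achieves its goal (one convention, no off-by-one drift)
with the containers every other tool in this stack uses. Overlap means
≥ 1 shared bp unless a fraction is stated; the cross-library
comparison uses strictly more than 50% of a TFCR's own bases. The
interval shuffle preserves chromosome and length with uniform starts
(no exclusion zones — the published shuffle flags are unstated);
self-overlap among shuffled intervals is allowed unless requested
otherwise. Gene models are single-exon, so the annotation vocabulary
is promoter > exon > intergenic (promoter first, mirroring common
annotators); `intron` would require exon structure the inputs do not
carry. TFCR-BED round trips carry strength at full precision in an
extra column because the BED score field (×1000, rounded) cannot.

## Known limitations

* The caller evaluates density on a 1-bp grid; summits are integers.
* `svr` is linear-kernel only; `cnn` is unavailable offline.
* Multi-isoform genes use a single TSS; UTR/downstream annotation
  subcategories are out of scope.
* The permutation-test p-value is conservative for small groups (see
  above).
* Full-scale feature lengths (4000/11113) and the 2000-iteration
  reference model are supported but not exercised by the test suite,
  which runs at desk scale.
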