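---
title: "Multi-level differential Hi-C analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level differential Hi-C analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hictriad)
```

## The problem

Chromosome conformation capture (Hi-C) measures how often pairs of genomic
loci touch in the nucleus. Binned genome-wide, those counts reveal three
nested layers of 3D genome organization, each with its own statistical
signature and its own biology:

* **A/B compartments** — the megabase-scale checkerboard of mutually
  interacting active (A) and inactive (B) chromatin, read off the leading
  eigenvector of the correlation of the distance-corrected map. Compartment
  shifts are the signature of large-scale activation or silencing, e.g. of
  X-chromosome territory remodelling in female cells, where the signal is a
  mixture over the active and inactive X.
* **CTCF loops** — punctate, focal contact enrichments between pairs of
  CTCF-bound anchors, typically with convergent motifs, visible as bright
  pixels far above their local neighborhood.
* **Enhancer–promoter (E–P) interactions** — weaker pairwise enrichments
  between a promoter-containing bin and a distal accessible-chromatin
  element, detected against a global distance-decay model rather than a
  local background.

`hictriad` implements this three-level analysis as a reusable, tested
pipeline for *comparing conditions* — for example hormone states or sexes —
including the calibrated differential rules at each level, the integration
with ATAC peaks, TSSs, CTCF motifs and expression tables, and a synthetic
Hi-C generator that plants known structure so that every stage can be
verified against ground truth without downloading any data.

## Contact-map model and normalization

Contacts are binned counts on a genome-wide bin table (25 kb for
compartments, 10 kb for loops and interactions; any width is accepted).
The container stores the upper triangle of a symmetric sparse count matrix,
cis and trans.

**Balancing.** `balance_map()` computes per-bin multiplicative weights by
iterative correction to an equal-margin fixed point, per chromosome on the
cis matrix (tolerance `1e-6` on the margin coefficient of variation, at
most 500 iterations). Knight–Ruiz and iterative correction converge to the
same doubly-balanced matrix; iterative correction is simpler and easily
audited. Bins whose raw marginal is below 2% of the chromosome's median
positive marginal are filtered before balancing — low-coverage bins
otherwise blow up the weights. The weights are rescaled so the balanced
total equals the raw total; this keeps the balanced signal on a count-like
scale, which matters because of the pseudocount below.

**Distance normalization.** The per-distance expected profile is the mean
balanced signal over all non-filtered bin pairs at each separation (zeros
included). The working quantity for loop and interaction strength is

$$z(i,j) = \frac{\mathrm{observed}(i,j) + 1}{\mathrm{expected}(|i-j|) + 1},$$

a pseudocounted observed/expected ratio that is well behaved at zero
counts. By default `observed` is the balanced signal when weights exist and
the raw count otherwise; whether the original analyses applied the
pseudocount before or after balancing is not documented anywhere we could
find, so the choice is an explicit flag (`use_weights`) with balanced as
the default.

**Equal depth.** Condition comparisons are made at equal depth by exact
downsampling without replacement (`downsample_map()`), so each pixel's
count is multivariate-hypergeometric with expectation proportional to the
original. Replicate agreement is assessed by Euclidean distance on
log2-transformed z over the union of informative pixels, with a principal
coordinate embedding (`replicate_distances()`).

## Compartments

`call_eigenvector()` forms, per chromosome, the observed/expected matrix of
the balanced map, its Pearson correlation matrix over non-filtered bins,
and the eigenvector of the largest-magnitude eigenvalue. Two conventions
are deliberate:

* **Sign orientation** uses any monotone activity proxy — ATAC-peak counts
  per bin by default, TSS density as fallback — so that positive values
  mean the A compartment.
* **Unit-SD scaling.** Comparing eigenvectors across samples against an
  absolute threshold presupposes a common scale, but eigenvector norms are
  arbitrary. Each track is therefore scaled to unit standard deviation over
  unmasked bins before differencing. With that scaling the default
  differential threshold `tau = 0.42` is interpretable as a quartile shift:
  a bin moving from one quartile of the (approximately standard) eigenvector
  distribution to another. `tau = "auto"` recomputes the interquartile
  distance of the pooled track for data that are far from standard.

Differential bins are counted singly (no contiguity requirement), and the
reported Mb span is exactly `flagged bins x bin size` — a bookkeeping
identity asserted by the test suite. Group comparisons (X chromosome versus
autosomes) use a two-sided Wilcoxon rank-sum test on per-bin |Δe|;
direction concordance between two condition pairs is the sign-agreement
fraction over bins flagged in either, plus a Spearman correlation.

## The loop caller

The punctate-loop caller is a declared re-implementation of the
significant-interaction-peak contract — Gaussian smoothing with sigma = 1
bin, regional maxima, local-background significance, Benjamini–Hochberg at
FDR 0.01, a 2000-bin span cap — not a port of any existing tool. Its
statistical core was chosen to survive two failure modes that simpler
designs exhibit on calibrated synthetic data:

1. **Restricting the test family to pre-selected candidates destroys FDR
   control** (the selection step invalidates the p-values). The caller
   therefore scores *every* cis pixel in the tested range and corrects
   across that full family genome-wide.
2. **A single ring-shaped background mean is fooled by compartment
   structure**: at a block edge or corner, the ring averages across
   heterogeneous background levels and focal tests light up. The caller
   instead scans the eight half-bands flanking the pixel's 3x3 peak region
   inside a window of radius `window_r = 6` bins and takes the half-band
   with the highest mean z as the background — enrichment extending along a
   band (a block edge, a stripe) is background, only enrichment confined to
   the peak region is a loop. This is the same idea as the multi-filter
   (donut / horizontal / vertical / lower-left) guards in established
   HiCCUPS-style callers.

Significance is a **conditional binomial test**: the balanced counts summed
over the 3x3 peak region are compared with the chosen band's summed counts,
given their summed expected values — the exact conditional comparison of
two Poisson rates. Modelling the background as an observed count rather
than a known rate matters: the band holds only ~50 pixels, and treating its
mean as exact produces a 20–30% underestimate of the null standard
deviation that converts into hundreds of false calls after a 10^5-test
correction. Loops are reported at significant pixels that are regional
maxima of the background-corrected smoothed signal and exceed a weak
smoothed floor (`z_floor = 1.2`); anchors closer than `min_dist = 5` bins
(50 kb at 10 kb) are never tested, to stay clear of diagonal artefacts.

Per-sample loop lists are merged into a master list by single-linkage
clustering at a 25-kb anchor radius (both anchors within the radius), each
cluster represented by its strongest member; merging is idempotent. A
master loop is **differential** when its distance-normalized signal — read
as the maximum over a 3x3 neighborhood to absorb one-bin peak drift —
exceeds 2 in the stronger condition and the fold change between conditions
is at least 2.5. The z values already embed the +1 pseudocount; no further
pseudocount enters the fold.

Anchor annotation tests each anchor for overlap with ATAC peaks and CTCF
motifs, with the loop category the conjunction over both anchors
(both / CTCF-only / ATAC-only / neither) and motif orientation classified
as convergent, tandem, divergent, or ambiguous (precedence: convergent
first when multiple motifs are present).

**Aggregates.** APA is the element-wise mean of z windows centered on a
site list, excluding sites nearer than the half-window to the diagonal or
an edge; the score is the center pixel (the center-over-corner ratio is
reported as a secondary statistic, since score conventions differ between
tools). The insulation score is the log2 ratio of the mean signal in a
window-by-window square bridging each bin to the chromosome mean of such
squares; the aggregate domain analysis rescales padded domain submatrices
to a common size and averages them.

## The interaction caller

`call_significant()` is a deliberately one-pass distance model in the
Fit-Hi-C style: equal-occupancy distance strata (default 100 contiguous
distance ranges holding roughly equal total contacts) stand in for a
spline; within a stratum the per-pair contact probability is the stratum's
contact share divided by its possible pairs; each observed pair is tested
by a binomial upper tail at the genome's total cis count, with BH across
all tested pairs and `q < 0.05` kept. No bias regression and no spline
refinement: the contribution this package exists for is the downstream
chain — exclusion, classification, differential rule — and the simplified
caller is calibrated (empirical false-positive control on null
simulations is part of the test suite).

The chain then:

* removes interactions within 20 kb (anchor-pair distance; both anchors)
  of a called CTCF loop — those are better explained as loops;
* classifies bins: a **promoter bin** contains at least one TSS; an
  **enhancer bin** lacks a TSS and holds at least one ATAC peak more than
  10 kb from every TSS (the distal-accessible-chromatin enhancer proxy);
  interactions become E–P, E–E, P–P or "other" (kept for FDR accounting,
  excluded from E–P summaries);
* applies the same differential rule as loops (z > 2 and fold >= 2.5, 3x3
  maximum);
* summarises per-gene enhancer connectivity (distinct enhancer bins linked
  to a gene's promoter bins, binned 0–5 and >5) against expression.

Distances between intervals and TSS points are edge-to-point gap distances,
the conservative reading of "more than 10 kb from any TSS".

## X-escapee calls

An X-linked gene is called an escapee when its female TPM is at least 1 and
its female/male ratio at least 1.5. The fold is one-sided (female over
male) — escape from X inactivation raises female expression, so a
two-sided reading would mix in unrelated male-biased genes. A male TPM of
zero receives a 0.01 pseudocount. Expression-matched controls are chosen
greedily per target (nearest log10 TPM, without replacement, deterministic
in target order).

## The synthetic generator

`generate_hic()` draws every replicate as a single multinomial over cell
probabilities

$$p_{ij} \propto d^{-\alpha}\,(1 + \gamma\, e_i e_j)\times
  \mathrm{fold}_{\text{loops}} \times \mathrm{fold}_{\text{interactions}},$$

with uniform trans mass. The multinomial (rather than independent Poisson
cells) makes each replicate's total exactly `depth`, so equal-depth
comparisons hold by construction, mirroring the pipeline's downsampling
step. Defaults define the study conditions used throughout the tests: two
12.5-Mb chromosomes (an autosome and an X) of 500 bins, depth 2x10^6,
decay exponent 1, checkerboard strength gamma = 0.4 with period 40 bins,
trans rate 0.26 (cis fractions of 72–74% are typical of neuronal Hi-C),
three replicates per condition.

Three realism choices deserve explanation:

* **Compartment edges are softened** by a sigma = 1-bin Gaussian on the
  square-wave latent profile. A knife-edge checkerboard creates 3x3-scale
  corner features — the sharp tip where two blocks meet at a given
  separation — that are *focally* enriched and therefore indistinguishable
  from loops by any local caller; real eigenvector profiles transition over
  tens of kilobases and do not produce them.
* **Planted loops have a narrow Gaussian footprint** (sigma = 0.75 bins,
  full fold at the center pixel) rather than being single-pixel spikes;
  real loop foci are blurred over neighboring pixels, which is also why the
  caller smooths.
* **Planted anchors sit at half-block-interior lattice positions** on
  distinct phases for loops and interactions, so planted effects never
  collide with each other or straddle a block edge, keeping
  recall/precision against truth well defined.

Condition effects — compartment sign-flip windows, loop fold changes,
interaction fold changes — apply to the second condition; `null_pair()`
strips them to produce matched null datasets for calibrating the
differential callers' false-positive rates. Annotation files are generated
consistently with the planted structure: ATAC peaks in A bins and at loop
anchors and enhancer bins, TSSs at promoter bins plus a sparse background,
convergent CTCF motifs at loop anchors, and a TPM table whose planted
escapees satisfy (and whose matched non-escapees violate) the escapee rule.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: restriction-fragment and ligation artefacts,
coverage biases beyond what balancing removes (the generator is unbiased,
so balancing is near-trivial on it), haplotype-resolved Xa/Xi structure
(the X is simulated as a mixed signal only), TAD hierarchies beyond the
compartment blocks, and inter-chromosomal structure (trans contacts are
uniform). Calibration and recovery results transfer to real data only to
the extent that these features do not dominate.

## Problem sizes and runtime

All tests and the acceptance script run on the toy scale above (two
chromosomes x 500 bins, depth 2x10^6, 20 seeds for calibration batches,
3–10 seeds for recovery batches), chosen so the full suite completes in
minutes on one CPU while keeping every planted effect comfortably above
its detection threshold. Degenerate inputs are first-class: empty maps
refuse analysis with a clear error, constant matrices yield fully masked
compartment tracks with a warning, chromosomes with fewer than 10 usable
bins are skipped, and single-condition runs skip the differential stages
with a notice.

## Known limitations

* Balancing is per-chromosome cis; trans pixels are never balanced.
* The interaction model pools strata across chromosomes and ignores
  per-bin bias beyond balancing weights.
* The loop caller's half-band background assumes background varies on
  scales of at least a few bins; enrichment structures narrower than the
  peak region but longer than the window (fine stripes) could still be
  miscalled.
* Differential rules are threshold rules on two pooled conditions, as
  published; no replicate-level variance model is fitted.
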