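---
title: "Detecting gene conversion between paralogs with paraconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene conversion between paralogs with paraconv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Bacterial class-I release factors RF1 and RF2 arose by an ancient gene
duplication, so in a combined alignment of RF1 and RF2 sequences the two
paralog families are expected to be reciprocally monophyletic: every
alignment column should support the deep split between the RF1 clade and
the RF2 clade.  Non-reciprocal gene conversion breaks this expectation
locally — a tract copied from one paralog onto the other makes the
recipient's tract-columns group with the donor family while the rest of the
gene keeps its ancestral affinity.  `paraconv` implements a
maximum-likelihood pipeline for detecting such tracts between a
*pre-specified* candidate pair of paralogous sequences and for estimating
the tract's boundaries.  The same machinery applies to any pair of gene
families related by duplication, not only release factors.

## The test trees and the window score

Two topological hypotheses are contrasted.  `Tree_global` is the
unconstrained ML tree of the full alignment; for data without conversion it
shows the ancestral paralog split.  `Tree_conv` forces the candidate
converted pair (one sequence from each family, e.g. an RF1 and the RF2 of
the same genome) to be monophyletic — the topology a converted tract would
support.  The scan slides a window of `width` columns (default 50) in steps
of `step` columns (default 10) and scores each window by

\[
\Delta \ln L \;=\; \ln L(\mathrm{Tree}_{conv}) - \ln L(\mathrm{Tree}_{global}),
\]

where a *single* global topology (inferred once from all columns) is used
for every window with branch lengths re-optimized per window, while the
constrained tree is re-searched within each window.  Without conversion,
the constrained optimum can only approach the unconstrained one from below,
so \(\Delta\ln L \le 0\) up to search noise; windows inside a converted
tract give positive scores.

Substitution models: empirical amino-acid matrices LG and WAG, the GTR
nucleotide model, and the two-state Cavender–Felsenstein model (CF2) for
RY-recoded data, each with discrete-gamma rate variation (4 equal-weight
categories of mean-of-bin rates, renormalized to mean 1).  Site likelihoods
are computed by Felsenstein pruning; gaps and unknowns contribute
uninformative (all-ones) partials.

The gamma shape \(\alpha\) is estimated once, on the full alignment
jointly with `Tree_global`, and then held fixed for every window and both
test trees.  Fifty-column windows carry too little information to estimate
a shape stably, and re-estimating it per window would let \(\Delta\ln L\)
absorb shape noise rather than topology signal.

## Significance: parametric bootstrap

The null distribution of window scores is built by parametric bootstrap:
replicate alignments are simulated on the *fitted no-conversion tree* and
pushed through the identical scan.  All window scores from all replicates
are pooled into one distribution and the critical value of the 0.01-level
test is the nearest-rank 0.99 quantile (the `ceiling(0.99 n)`-th order
statistic — well defined for small replicate counts and slightly
conservative; no interpolation).  A window is called significant only if
its score *strictly exceeds* the critical value.  Pooling across windows
(rather than per-window nulls) mirrors drawing a single critical line
across the profile; per-window critical values are available via
`per_window = TRUE`.

Simulation classically uses WAG+\(\Gamma\) with parameters taken from the
fit of the observed data even when the observed-data scan uses
LG+\(\Gamma\) (a historical limitation of simulation software); `calibrate`
therefore takes its own `model_sim`, used both to simulate and to scan the
replicates, and defaults in the worked analyses to WAG.

## Boundary estimation: corrected t statistic

For precise tract boundaries the pipeline switches from windows of the scan
grid to *all* windows.  `build_site_table` infers the constrained and
unconstrained trees from the full alignment and records per-column
log-likelihood differences \(\Delta\mathrm{site}\text{-}\ln L\).  For every
window of every integer width 30–90 columns, a Welch-form two-sample t
statistic compares the mean inside the window against the mean outside
(unbiased variances; if both variances vanish the statistic is 0 for equal
means and \(\pm 10^{300}\) otherwise).  Because wider windows mechanically
yield larger statistics, each width receives a max-statistic permutation
test: the column order is permuted 10,000 times, the largest t over all
windows of that width is recorded, and the p-value is the proportion of
permuted maxima strictly greater than the observed per-width maximum (no
"+1" correction; the minimum attainable p is 0).  The reported region is
the window with the largest t among widths significant at the 0.01 level.
The scan over all widths (every integer width, every start) is chosen
because reported converted regions need not sit on a coarse width grid.
The "corrected" aspect is realized here as the unequal-variance (Welch)
form plus the max-statistic adjustment for window-size bias; the package
does not claim numerical identity with any particular published variance
correction.

Efficiency contract: per permutation the max-t over all windows of one
width is computed from prefix sums of the values and their squares, linear
in the sequence length, and is oracle-tested against a naive quadratic
scan.  Permutation streams are derived from the master seed independently
per width, so observed statistics never depend on the seed and widths can
be processed in any order.

## The synthetic generator

Real paralog data sets with known conversion tracts are not available at
desk scale, so the package ships a first-class generator.  The default
scenario emulates the study conditions of the release-factor analysis: 6
paralog pairs (12 sequences), 230 amino-acid columns, one converted pair,
and a contiguous tract at columns 111–190.  `template_trees` builds the
no-conversion tree as two mirrored paralog clades (same topology, one leaf
per pair on each side) joined by an inter-paralog branch of length
`2 * depth_scale`, with intra-clade branch lengths drawn from a seeded
exponential of mean `depth_scale` (default 0.3 substitutions/site — a deep
duplication with moderate within-family divergence; the true branch-length
regime of any particular data set is unknown, so the scale is an exposed
parameter rather than an assertion).  The focal (converted) pair is
assigned to a maximally *nested* leaf of the drawn clade shape: a focal
pair adjacent to the inter-paralog junction makes the window contrast
degenerate — per-window branch re-optimization of the global topology can
then mimic the converted pair's proximity, and the unconstrained
full-alignment tree tends to be captured by the tract — a regime outside
the detector's premise that the global tree recovers the paralog split
(a premise the windowed design presumes and real analyses verify on their
data).  The conversion tree relocates the
recipient leaf to sit as the sister of its partner, splitting the partner's
pendant branch at its midpoint.

Columns outside the tract are simulated on the no-conversion tree and
columns inside on the conversion tree (LG+\(\Gamma\), shape 0.7 by
default), with independent seed streams per region.  Simulating the tract
on the conversion tree — rather than splicing sequence from a second
independent simulation — matches the likelihood model the detector assumes,
which keeps recovery tests interpretable.  Per-site rate categories are
drawn i.i.d. uniformly over the discrete-gamma categories, mirroring the
likelihood's assumption.

The generator does *not* simulate indel evolution, lineage-specific
compositional heterogeneity, alignment error, or selection; passing
recovery tests therefore demonstrates correctness of the machinery under
its own model, not robustness to real-data pathologies.  By default no
motif block is inserted (scan alignments of interest exclude motif
columns); `generate(..., insert_motif = TRUE)` adds a labelled anchored
block (a 12-residue segment shared by the converted pair, 4-residue
segments elsewhere) for exercising the motif classifier.

## Motif classification and compositional utilities

`classify_motifs` labels each sequence by the exact number of non-gap
residues strictly between two anchor columns (defaults 150/151, the columns
flanking the excluded motif block in a 230-column release-factor
alignment).  Classification is by segment *length* only — homologous
position and length are what identify these loop variants — with the raw
segment retained for inspection; no consensus pattern is imposed because
motif content is not available in machine-readable form.  Anchors are
parameters, never auto-detected.

For rRNA-style organismal phylogenies the package provides `gc_screen`
(per-sequence G+C fraction over unambiguous bases with a Wald
normal-approximation 95% CI; a sequence is flagged when the across-sequence
grand mean falls outside its interval) and `ry_recode`
(purine/pyrimidine recoding, analyzed under CF2+\(\Gamma\)).  The Wald
interval is the simplest defensible choice at thousands of sites and is
recorded in the report metadata; at small n an exact interval would differ.
Gaps and ambiguity codes are excluded from G+C denominators so composition
reflects observed bases.

## Numerical choices

* Branch lengths live in \([10^{-8}, 10]\) substitutions/site; per-edge
  Brent optimization on exact conditional likelihoods, swept around the
  tree until the total log-likelihood improves by less than \(10^{-4}\).
* Transition matrices come from the symmetric eigendecomposition
  \(\mathrm{diag}(\pi)^{1/2} Q\, \mathrm{diag}(\pi)^{-1/2}\), numerically
  stable for reversible generators; tiny negative entries from round-off
  are clamped to zero.
* Tree search is randomized stepwise addition (leaf order seeded per
  start, insertion at the log-likelihood-best constraint-compatible edge,
  cheap branch refresh after each addition) followed by
  nearest-neighbour interchanges accepting strictly improving moves, with
  3 random starts per constrained window search; candidate topologies are
  memoized so restarts never re-optimize a topology already fitted.  Ties
  break toward the first-encountered candidate in a deterministic
  traversal order, and search results are invariant to alignment row
  order.  Exhaustive enumeration is available to 8 leaves and is used by
  the consistency tests.
* When the global topology itself satisfies the conversion constraint it
  is a member of the constrained space, so its per-window fit is used as a
  lower bound for the constrained optimum; this guards the
  \(\Delta\ln L \le 0\) invariant against optimizer slack.
* Coordinates are 1-based inclusive at every interface.

## Problem sizes in the shipped analyses and tests

The worked analysis scripts and the test suite run at desk scale, chosen
as the smallest sizes at which every statistical property is still
meaningfully exercised: the default 12-taxon scenario for recovery runs,
6-taxon alignments for exhaustive-search consistency and bootstrap
calibration (100 + 20 replicates), 10 recovery seeds with 1,000
permutations, and 50 null seeds at 500 permutations for the family-wise
error check.  The full 10,000-permutation boundary scan is used in the
analysis scripts.

## Limitations

* The converted pair is an *input*: the scan is a targeted test, not a
  genome-wide screen for which pair converted.
* Detection power depends on the depth of the paralog split relative to
  tract length; very short tracts (under one window) blur into adjacent
  windows.
* The bootstrap null conditions on the fitted no-conversion tree; model
  misspecification (e.g. compositional heterogeneity) is outside the null
  and can inflate scores on real data.
* Full-scale many-taxon tree inference is out of scope; the engine targets
  the small alignments of the windowed design (roughly up to ~15 taxa).
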