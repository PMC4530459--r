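# paraconv

Detection of gene conversion between paralogous genes by sliding-window
maximum likelihood.

## The problem

Gene families born of an ancient duplication — the motivating case is the
bacterial class-I release factors RF1 and RF2, which recognize stop codons
on the ribosome — are expected to be reciprocally monophyletic in a
combined alignment: every column should support the deep split between the
two families.  Gene conversion violates this locally: a tract copied
non-reciprocally from one paralog onto the other makes the recipient's
tract group with the donor family while the rest of the gene keeps its
ancestral affinity.  `paraconv` is for molecular evolutionists who have a
*candidate* converted pair (for instance flagged by a shared anchored
indel motif) and want to (i) test for a converted tract and (ii) estimate
its boundaries, from a protein or nucleotide alignment of paralog pairs.

## The method

Two topologies are contrasted in sliding windows (width 50 columns, step
10 by default):

* **Tree_global** — the unconstrained ML tree of the full alignment, the
  no-conversion hypothesis; one topology for all windows, branch lengths
  re-optimized per window.
* **Tree_conv** — the per-window ML tree under the constraint that the
  candidate pair is monophyletic, the conversion hypothesis.

Each window is scored by ΔlnL = lnL(Tree_conv) − lnL(Tree_global); without
conversion the constrained optimum cannot beat the unconstrained one, so
positive scores mark converted windows.  Significance comes from a
parametric bootstrap: replicates simulated on the fitted no-conversion
tree are scanned identically, all window scores are pooled, and the
0.99 nearest-rank quantile is the critical value of the 0.01-level test.
Tract boundaries are then refined with a corrected t statistic: per-column
log-likelihood differences between the two full-alignment trees are
scanned over *every* window of width 30–90, using a Welch-form t (mean
inside vs outside) with a per-width max-statistic permutation test
(10,000 permutations) to adjust for window-size bias.

Likelihoods use LG/WAG (amino acid), GTR (nucleotide) or the two-state
Cavender–Felsenstein model (RY-recoded data), all with 4-category
discrete-gamma rate variation, computed by Felsenstein pruning in a small
Rcpp engine with per-edge Brent branch-length optimization and a
constrained stepwise-addition + NNI tree search.  A first-class synthetic
generator implants conversion tracts with full ground truth so every stage
is testable without external downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate.R`, then `02`…`05`), writing tables
and trees under `results/`.  The same steps in the R console:

```r
library(paraconv)

sc <- conversion_scenario(seed = 2026)   # 6 pairs x 230 cols, tract 111-190
g  <- generate(sc)

prof <- delta_lnl_profile(g$alignment, sc$conv_clade,
                          build_model("LG", alpha = 0.7), seed = 2026)
null <- calibrate(prof$tree_global, build_model("WAG", alpha = 0.7),
                  n_reps = 25, length = 230, conv_clade = sc$conv_clade,
                  seed = 2026)
which(test_windows(prof, null))
#> [1] 10 11 12 13 14 15 16 17 18

st <- build_site_table(g$alignment, sc$conv_clade,
                       build_model("LG", alpha = 0.7), seed = 2026)
scan_boundaries(st, n_perm = 10000, seed = 2026)
#> <paraconv_boundary> best window 109-191 (width 83), t = 7.4917,
#>   p = 0 [10000 permutations]
```

Reading the output: the scan estimates the gamma shape at 0.672 on the
full alignment, the bootstrap critical value is ΔlnL = 2.67 (475 pooled
null scores), and the windows exceeding it (10–18) are exactly those
overlapping the implanted tract — windows 12–15, which lie fully inside
columns 111–190, score far above the line.  The boundary scan localizes
the tract to columns 109–191, within two columns of the true 111–190.

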