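---
title: "Quantifying subcellular mRNA distribution from fractionation RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subcellular mRNA distribution from fractionation RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracseq)
```

## The problem and the model

Bacterial cells can be separated by sucrose-gradient centrifugation and
membrane flotation into a total extract, a ribosome-free gradient top, a
70S (monosome) pool, and a purified membrane fraction; affinity
pull-downs from the ribosome-free pool add an input/elution pair.
Sequencing the RNA of each fraction asks a simple question per gene:
*where does this transcript sit?* The unit of analysis is the
**enrichment ratio**

$$ r_g = \frac{\mathrm{RPKM}_{g,\mathrm{fraction}}}{\mathrm{RPKM}_{g,\mathrm{reference}}}, $$

with the total extract (or the pull-down input) as reference and

$$ \mathrm{RPKM}_{g,s} = \frac{c_{g,s} \cdot 10^9}{L_g \cdot \sum_{g'} c_{g',s}}, $$

where $c_{g,s}$ is the read count of gene $g$ in library $s$ and $L_g$
its CDS length in nucleotides. Because ribosome-containing fractions are
dominated by rRNA, counts are filtered to mRNA features **before** the
RPKM denominator is computed (`filter_feature_classes()`), so that mRNA
RPKMs are comparable across fractions with very different rRNA loads.
The alternative denominator (all mapped reads) can be selected by
filtering with a larger `keep` set.

Two assumptions matter. First, the ratio is *compositional*: a library
measures relative, not absolute, abundance, so every gene's ratio in a
fraction carries a common scale factor. All landscape statistics below
are rank-based or class-versus-class comparisons and are invariant to
that factor. Where an absolute multiplier must be estimated (the
parameter-recovery checks), ratios are first divided by the all-gene
median ratio, which removes the shared factor whenever a majority of
genes is unaffected. Second, replicates are pooled by summation after a
pairwise Spearman consistency check (`pool_replicates()`, threshold
0.9): pooling matches how the counts will be used (a single deep
library per fraction) and avoids modelling replicate variance that the
downstream rank statistics would ignore anyway.

## Landscape statistics

Genes are ranked by $r_g$ ascending and assigned midpoint percentiles
$100\,(\mathrm{rank}-0.5)/N$; ties are broken by gene identifier so the
ranking is reproducible (`percentile_rank()`). Along this landscape:

* **Quota curves** (`quota_curve()`): in a moving window of width 10
  percentiles stepped by 1 (both configurable), the quota of a class is
  its share of the genes in the window. Edge windows are truncated.
  Disjoint decile counts (`decile_counts()`) always sum to the class
  size — a conservation property the tests assert on every landscape.
* **Tail overrepresentation** (`tail_overrepresentation()`): with $N$
  genes, class size $n$, tail size $K = \mathrm{round}(fN)$ (default
  $f = 0.30$; boundary genes included by rank), the p-value is the
  exact hypergeometric upper tail $P(X \ge k)$ computed by summation of
  point masses. Across the tails tested in one run, q-values are
  Benjamini–Hochberg (`bh_fdr()`). The original analyses used an
  annotation tool whose correction universe cannot be reconstructed, so
  BH over the performed tests is used instead; the package therefore
  does not attempt to match any published corrected p-value.
* **Rank tests**: Mann–Whitney (midrank ties; exact enumeration when
  $n_1 n_2 \le 400$ and tie-free, otherwise normal approximation with
  tie and continuity correction) and two-sample Kolmogorov–Smirnov
  (exact when $n_1 n_2 \le 100$, else asymptotic), both two-sided by
  default since no direction is privileged a priori.
* **Class summaries** (`class_summary()`): per-class median and mean
  ratio, and the class mean as percent change from the all-gene mean.
* **Binder groups** (`select_binder_groups()`): on a pull-down binding
  landscape, the weak group is the class members inside the bottom
  30% of *all* genes; the strong group is the same number of class
  members taken from the top of the binding-sorted list. Both are then
  intersected with user-supplied detection sets (e.g. genes detected in
  every fraction of every strain), which generally shrinks the two
  groups unequally.

## The recognition-element scanner

Five rules describe U-rich cold-shock-protein recognition elements on
the coding (sense) strand, scanned on the DNA alphabet with U mapped to
T and N never matching:

| rule | definition |
|------|------------|
| R1 | `TTCTTTT` |
| R2 | `GTCTTTT` or `GTCTTTG` |
| R3 | `GTCTTTT`/`GTCTTTA` or the hexamer `TTTTTT` |
| R4 | 7-base T run with exactly one purine interruption at positions 2–5, G excluded at position 3 |
| R5 | 7-base T run with at most one interruption at positions 2–6, G excluded at position 3, purines excluded at position 6 |

Every window position is tested; overlapping raw matches are collapsed
greedily left-to-right into maximal sites, because a single element such
as `TTTTATTTT` would otherwise be counted up to three times by adjacent
sliding windows. Raw window counts are retained in the `n_windows`
column for transparency, and `collapse = FALSE` disables merging. Two
deliberate interpretation choices are flagged here: (i) for R5, an
uninterrupted T7 run counts by default ("at most one" interruption
includes zero), since a pure U run is the limiting U-rich element; a
`require_interruption` flag excludes it. R4, by contrast, requires the
purine — a pure run there would be scored by R3's hexamer instead.
(ii) R3's prose ("GUCUUUU/A or UUUUUU") is read as the union of two
heptamers and one hexamer; hexamer sites collapse like any others.
Adjacent but non-overlapping matches are *not* merged (two abutting
elements remain two sites). Positions are 1-based inclusive;
`sites_to_bed()` converts to 0-based half-open BED.

## Expression-ratio clustering

`log2_ratio_matrix()` retains genes detected (RPKM $\ge$ `min_rpkm`,
default 1) in every listed library and forms
$\log_2(\mathrm{RPKM}_c/\mathrm{RPKM}_{\mathrm{ref}})$. Clustering is
K-means under Euclidean dissimilarity. The Lloyd loop is implemented in
the package rather than delegated, because the contract fixes the
initialization (k-means++), the restart policy (best within-cluster sum
of squares over 20 seeded restarts), determinism for a fixed seed, and
a per-iteration assertion that the WCSS never increases; `stats::kmeans`
serves as an independent cross-check in the tests. Rows are not
standardized by default — log2 ratios are already on one scale.

The number of clusters is chosen from the Davies–Bouldin index,

$$ \mathrm{DB} = \frac{1}{K}\sum_i \max_{j \ne i}
   \frac{S_i + S_j}{M_{ij}}, $$

with $S_i$ the mean member–centroid distance and $M_{ij}$ the centroid
separation; coincident centroids yield an `Inf` sentinel. `select_k()`
computes the profile over a k range and picks the **local minimum with
the lowest DB value** (smallest k on ties) — an automated surrogate for
choosing K by inspecting local minima for good separation. The simpler
"smallest k at any local minimum" rule was rejected during design: a
shallow minimum at the low end of the range would beat a much deeper
one at the true structure (it mis-selects even clean five-cluster
data). A monotone decreasing profile returns the largest k, flagged in
the result, and the full profile is always returned for manual
override. After fitting, `merge_singletons()` folds any single-gene
cluster into the cluster with the nearest centroid (ties to the lower
label, logged), recomputing centroids, WCSS and DB.

## qPCR mass balance

Relative concentration of a transcript in a fraction versus the extract
is $2^{\mathrm{Ct}_\mathrm{extract} - \mathrm{Ct}_\mathrm{fraction}}$;
the portion of the transcript in the fraction weights this by the RNA
yields, $\mathrm{portion} = \mathrm{rel}\cdot m_\mathrm{fraction} /
m_\mathrm{extract}$. Over disjoint exhaustive fractions portions sum
to 1, which the noise-free simulator round-trips exactly (bit-level up
to floating point). When endogenous-control Cts are supplied the
relative concentration is divided by the control's. Primer standard
curves pass QC when the fitted slope lies in $[-3.6, -3]$ cycles per
decade (perfect two-fold chemistry gives $-\log_2 10 \approx -3.32$)
and $R^2 > 0.995$.

## What the synthetic-data generator emulates — and what it does not

`sim_design()`/`make_sim_truth()`/`simulate_fraction_counts()` emulate:

* six fractions (extract, ribosome-free, 70S, membrane, pull-down
  input/elution), triplicate libraries, expected 5×10⁶ mapped reads;
* per-fraction rRNA load: ribosome-containing libraries lose most reads
  to non-mRNA features (defaults 0.85–0.95), the ribosome-free and
  pull-down libraries only 0.10 — reproducing the observation that
  mRNAs sequence far more efficiently from the gradient top;
* class-level enrichment effects (MPRs: ×2 ribosome-free, ×2 membrane,
  ×0.7 70S, ×4 pull-down elution; CPRs mildly opposite) with per-gene
  log2 scatter `gene_sd = 1.0`. The scatter is deliberately as large as
  the effects: real landscapes show classes overlapping broadly, with
  roughly half of the membrane-protein mRNAs inside the top 30% of the
  membrane landscape rather than all of them;
* negative-binomial counts with dispersion 0.01 (BCV 0.1), the
  conventional scale for replicate libraries of a genetically identical
  organism grown as one culture; 0 gives Poisson;
* seeding: one master seed; each library draws from a substream indexed
  by (fraction position × 1000 + replicate), so adding replicates or
  appending fractions never changes existing libraries.

It does **not** simulate raw reads, alignment, positional coverage
bias, gradient physics, partial transcript degradation, or operon
structure. Passing tests therefore demonstrate that the statistics
recover what they claim from count-level data under realistic
overdispersion — not that any particular biological conclusion holds in
real data. No abundance or dispersion parameters were fitted to the
original sequencing archive; all defaults are conventional choices.

The qPCR simulator inverts the mass-balance formulas exactly and adds
optional Gaussian Ct noise. The motif-planting simulator rejection
samples background from an A/C/G alphabet (no T, hence no accidental
U-rich matches), flanks each planted window with `CC` so windows cannot
bridge into the background or each other, and verifies the final
sequence by scanning; its recorded truth includes cross-rule matches,
because the element definitions overlap (a planted `TTCTTTT` satisfies
both R1 and R5).

## Numerical and degenerate-input choices

* Detection threshold `min_rpkm = 1` in both fraction and reference
  defines "detected"; genes failing it are dropped and reported, never
  pseudo-counted — a ratio invented from a zero would dominate the tails.
* Tail boundary: $K = \mathrm{round}(fN)$; boundary genes are included
  by rank order.
* Ties: midranks in Mann–Whitney; gene-id order in the landscape.
* Lloyd convergence: WCSS change below $10^{-12}$, cap 100 iterations;
  empty clusters re-seeded with the farthest point.
* Zero-total libraries, empty gene sets, all-singleton clusterings,
  fraction = reference, and infeasible motif plantings are all explicit
  errors naming the offending object.

## Problem sizes used in the validation suite

The shipped checks run at desk scale, chosen to make the Monte-Carlo
error comfortably smaller than the asserted margins: parameter recovery
uses 100 effect genes (×2) plus 500 null genes at 5×10⁶ reads and
triplicates over 100 simulated experiments; type-I calibration uses 200
genes at 2×10⁵ reads over 1000 simulations; the scanner is compared to
a brute-force window oracle on 1000 random 200-nt sequences per rule;
exact-test oracles enumerate all subsets up to $N = 12$ and all
permutations up to $n_1 = n_2 = 6$.

## Known limitations

* Headline gene counts from the original sequencing data (numbers of
  detected mRNAs, overlap-set sizes, specific tail counts) depend on
  that data and an unstated detection threshold; the package reproduces
  the *procedures* and validates them on synthetic ground truth.
* BH over the run's tests is not the annotation-tool correction used
  originally; corrected p-values are not comparable.
* Whether published element totals counted raw windows or collapsed
  sites is not stated; both are computed, collapsed is the default.
* The original clustering software's exact K-means variant is unknown;
  only the algorithmic contract (Euclidean Lloyd, DB selection,
  singleton merge) is reproduced.
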