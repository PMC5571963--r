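# fracseq

Where inside a bacterial cell do mRNAs sit? Cell fractionation followed
by RNA-seq and qPCR answers this per transcript: a culture is separated
into a total extract, a ribosome-free gradient top, a 70S ribosome
pool, flotation-purified membranes and affinity pull-down fractions,
and each fraction's RNA is quantified. `fracseq` implements the
statistical pipeline for such experiments, built around comparing
mRNAs encoding integral membrane proteins (MPRs) with mRNAs encoding
cytoplasmic proteins (CPRs). It is aimed at microbiologists and
computational biologists analysing fractionation RNA-seq count tables
or qPCR panels.

## What it computes

For gene *g* in library *s* with CDS length *L_g*,

```
RPKM(g,s) = count(g,s) * 1e9 / (L_g * total_mRNA_reads(s))
r_g       = RPKM(g, fraction) / RPKM(g, reference)
```

with rRNA/tRNA/ncRNA rows removed before normalization. Genes are
ranked by *r_g* into an enrichment landscape; the package then provides

- moving-window **class quota curves** (width 10 percentiles, step 1);
- exact **hypergeometric tail tests** for class overrepresentation in
  the top/bottom 30% of the landscape, with Benjamini-Hochberg FDR;
- **Mann-Whitney** (exact for small tie-free samples) and
  **Kolmogorov-Smirnov** class comparisons;
- selection of **weak/strong binder groups** from a pull-down landscape
  (bottom-30% class members vs an equal-sized top group);
- a scanner for the five **U-rich cold-shock-protein recognition
  elements** (exact heptamers, degenerate-end heptamers, interrupted
  T/U-run rules with positional exclusions), with per-group
  "genes (sites)" census tables and BED export;
- **K-means clustering** of log2 expression ratios (k-means++, seeded
  restarts) with Davies-Bouldin K selection and singleton merging;
- **qPCR mass balance**: portion = 2^(Ct_extract - Ct_fraction) *
  mass_fraction / mass_extract, endogenous-control normalization, and
  standard-curve QC (slope in [-3.6, -3], R² > 0.995);
- a seeded **synthetic-data generator** (negative-binomial counts with
  per-fraction rRNA load, qPCR panels, motif-planted transcripts) whose
  ground truth backs every test in the package.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script prints what it found and writes tables under `results/`.

```sh
Rscript analysis/01_simulate_experiment.R   # synthetic 6-fraction study
Rscript analysis/02_enrichment_landscapes.R # RPKM -> landscapes -> tests
Rscript analysis/03_binder_motifs.R         # binder groups + element census
Rscript analysis/04_clustering.R            # log2 ratios -> K-means
Rscript analysis/05_qpcr.R                  # delta-Ct mass balance
```

Stage 2 prints, for the simulated study (200 MPRs, 800 CPRs,
triplicates, 5e6 reads/library):

```
999 genes detected in all analyzed fractions.
ribosome-free  MPRs in top 30%: 140/200 (p = 4.21e-40, q = 1.26e-39); MW p = 8.19e-45; KS D = 0.509
70S            MPRs in top 30%: 28/200 (p = 1.00e+00, q = 1.00e+00); MW p = 2.57e-18; KS D = 0.301
membrane       MPRs in top 30%: 136/200 (p = 2.44e-36, q = 3.67e-36); MW p = 7.06e-44; KS D = 0.485
```

Read: of the 200 membrane-protein mRNAs followed across all fractions,
140 sit in the top 30% of the ribosome-free landscape and 136 in the
top 30% of the membrane landscape (exact hypergeometric p, then BH q
over the run's tests), while the 70S landscape shows no such
overrepresentation — MPRs concentrate on the membrane *and* in the
ribosome-free cytosol, not on free ribosomes. Stage 3 then contrasts
weak and strong pull-down binders (19 genes each after overlap
filtering) by recognition-element content:

```
   weak      strong
R1 "1 (1)"   "6 (7)"
R4 "6 (6)"   "18 (32)"
R5 "10 (10)" "19 (62)"
```

Each cell is "genes with at least one site (total sites)": strong
binders carry several-fold more U-rich elements, matching the planted
ground truth exactly (`R5 site check vs planted truth: found 72,
planted 72.`).

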