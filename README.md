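# barcodegap

Analysis toolkit for COI DNA barcoding of insect communities —
distances, trees, pseudogene quality control and barcoding-gap species
delimitation.

## The problem

A ~650 bp fragment of the mitochondrial cytochrome c oxidase subunit 1
(COI) gene is the standard animal DNA barcode: conspecific individuals
differ by well under 2% while species in the same genus typically differ
by several percent, so the gap between the two distance distributions
("the barcoding gap") lets unknown specimens be assigned to species by
sequence alone. This matters most where morphology fails — e.g. mosquito
disease-vector surveillance, where specimens are damaged, immature or
morphologically near-identical. `barcodegap` implements the complete
quantitative workflow for such surveys, and a sequence simulator with
truth tables so that every stage is testable without any downloads.

## What it computes

* **Kimura two-parameter (K2P) distances** with pairwise deletion, from
  transition (P) and transversion (Q) proportions:

  d = −½ ln[(1 − 2P − Q) √(1 − 2Q)]

  with its transitional component d_s = −½ ln(1 − 2P − Q) + ¼ ln(1 − 2Q)
  and transversional component d_v = −½ ln(1 − 2Q), so d_s + d_v = d
  exactly. Saturated pairs are flagged undefined rather than raising.
  The R-value (mean transition/transversion count ratio) summarizes the
  substitution spectrum.
* **Neighbor-joining trees** (Saitou–Nei Q-criterion, deterministic
  tie-breaks, clamp-and-transfer for negative branches), nonparametric
  **bootstrap supports** by alignment-column resampling, and
  **species-monophyly** tests via leaf bipartitions.
* **Per-codon-position composition** (A+T bias, zero-frequency checks).
* **Numt/pseudogene screening** under the invertebrate mitochondrial
  genetic code (table 5): internal stops, insertions/deletions,
  codon-position substitution profiles tested against the functional
  5:1:18 expectation, amino-acid differences, and a two-rate molecular
  clock for dating nuclear-transfer events.
* **Barcoding-gap delimitation**: conspecific / congeneric /
  intergeneric distance pools, best-close-match classification at the 2%
  K2P threshold, and cryptic-species / synonymy flags using the 1.1%
  transversion-distance boundary.
* **Community simulation**: a genus/species/individual hierarchy evolved
  under the K2P process with codon-position rate heterogeneity (5:1:18),
  transition/transversion bias, A+T-rich composition and injectable numt
  lesions, returning full truth tables.

## Worked example

```r
library(barcodegap)
sim <- simulate_community(sim_config(seed = 42))   # 5 genera x 4 species x 4
res <- run_barcodegap(run_config(sim$alignment, bootstrap_B = 100, seed = 42))
print(res$gap)
```

```
[setup] 80 sequences x 650 bp
[qc] 0 of 80 sequences failed (pseudogene signatures)
[distances] 80 taxa; 0 saturated pairs; R = 0.698
[tree] 20 of 20 species monophyletic
[gap] 0 cryptic and 0 synonymy candidates
gap_summary (theta_k2p = 0.02 , theta_tv = 0.011 )
  conspecific   n=120    K2P range 0.0000-0.0062 mean 0.0038
  congeneric    n=480    K2P range 0.0642-0.0846 mean 0.0745
  intergeneric  n=2560   K2P range 0.1308-0.1686 mean 0.1493
  congeneric/conspecific mean ratio: 19.7
  % conspecific < theta: 100.0; % congeneric > theta: 100.0
```

Reading the output: all 120 within-species distances sit far below the
2% threshold, all between-species distances far above it — a clean
barcoding gap; congeneric divergence is ~20x conspecific divergence at
these simulation depths; every species is a monophyletic clade on the
bootstrapped NJ tree (supports of 100 in `res$monophyly`); and the
transition/transversion R-value of ~0.7 reflects the configured
substitution bias. Real surveys use the same calls on an alignment from
`read_aligned_fasta()` with `attach_metadata()`.

Analysing your own data end to end:

```r
aln <- read_aligned_fasta("barcodes.fasta")          # Genus_species|acc|site headers
res <- run_barcodegap(run_config(aln, outdir = "out",
                                 exclusions = mimeticus_subgroup()))
```

writes distance matrices (PHYLIP/TSV), the Newick tree with supports,
composition and QC reports, the gap-report JSON and a summary JSON.

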