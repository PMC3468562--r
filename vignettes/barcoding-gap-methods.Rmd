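---
title: "Methods: distances, delimitation and pseudogene QC in barcodegap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distances, delimitation and pseudogene QC in barcodegap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

# The model

`barcodegap` analyses aligned, protein-coding COI barcode fragments.
The substitution model throughout is Kimura's two-parameter (K2P)
model: one rate for transitions (A↔G, C↔T) and one for transversions,
equal base frequencies, independent sites. From the per-pair transition
and transversion proportions P and Q (computed over the L alignment
columns where both sequences carry an unambiguous A/C/G/T — *pairwise
deletion*), the distances are

* total: d = −½ ln[(1 − 2P − Q) √(1 − 2Q)]
* transitional: d_s = −½ ln(1 − 2P − Q) + ¼ ln(1 − 2Q)
* transversional: d_v = −½ ln(1 − 2Q)

with d_s + d_v = d exactly. When an argument of a logarithm is
non-positive the pair is *saturated*: the distance is carried as an
explicit undefined flag (`NA`) and excluded from summaries with a
count, never silently dropped and never an exception — pooled analyses
over thousands of pairs must not abort on one saturated pair. Note
that d_s is an estimator and can be slightly negative when observed
transitions are scarcer than the transversion level implies; it is
reported as computed.

K2P's assumptions (no base-composition bias, homogeneous sites) are
knowingly violated by COI — third positions are extremely A+T rich and
evolve an order of magnitude faster than second positions. K2P is used
regardless because it is the fixed convention of the DNA-barcoding
literature, making distances comparable across studies; the package
deliberately offers no model selection (gamma or maximum-likelihood
distances are out of scope).

# Trees and supports

`neighbor_joining()` is the classical Saitou–Nei agglomeration on the
Q-criterion Q(i,j) = (n−2) d(i,j) − Σ_k d(i,k) − Σ_k d(j,k). Numerical
choices:

* **Ties** in Q are broken by the smallest (row, column) index pair, so
  results are deterministic in the input order.
* **Negative branch lengths** (possible on non-additive input) are
  clamped to zero with the deficit transferred to the sister branch,
  preserving the path length of the joined pair; total tree length never
  changes by more than the clamped deficit.
* On additive matrices the algorithm provably recovers the generating
  topology and branch lengths; the tests verify this exactly and, at
  n = 6, against an exhaustive least-squares search over all 105
  topologies.

Bootstrap supports resample alignment columns with replacement (the
unit is one column by default; whole codons by option), rebuild the
tree per replicate, and count, for each internal edge of the full-data
tree, the replicates containing the same leaf bipartition. Supports are
mapped onto the single full-data tree, not a consensus, matching how
barcode survey trees are presented. Replicates with saturated distances
are dropped and counted (warning above 10%). Replicate r draws from a
substream derived deterministically from (seed, r), so supports are
reproducible and invariant to leaf input order.

`species_monophyly()` declares a species monophyletic iff some edge
bipartition isolates exactly its leaves; singletons are trivially
monophyletic.

# Delimitation thresholds and flags

Two thresholds drive delimitation, both expressed as distances:

* `theta_k2p = 0.02` (2%): the conventional ceiling of conspecific COI
  divergence.
* `theta_tv = 0.011` (1.1%): the transversion-distance boundary below
  which almost all conspecific (and plesiomorphic between-species)
  comparisons fall. Transversions accumulate nearly linearly with time
  and overtake transitions at deep divergence, which makes the
  transversion distance a useful secondary index; `ts_tv_curve()`
  reports the binned d_s/d_v trends and their crossover.

Pairwise distances are pooled into conspecific, congeneric
(heterospecific, same genus) and intergeneric categories; the genus is
the first token of the species name. Within-species statistics report
both the mean and the **maximum**; flagging uses the maximum, because a
single deep split inside a nominal species is precisely the cryptic-
species signal, and published per-species intraspecific values read as
extrema. Between-species statistics report the mean (used for synonymy
flags) and the minimum (the gap floor). Where a survey prefers the
other reading, both numbers are present in `group_summary()` output.

Flags: a species is a *cryptic-species candidate* when its maximum
within-species K2P distance exceeds `theta_k2p`, sub-flagged *strong*
when the maximum within-species transversion distance also exceeds
`theta_tv`; a species pair is a *synonymy candidate* when its mean
between-species K2P distance falls below `theta_k2p`, sub-flagged
*plesiomorphic* when the mean transversion distance is at or below
`theta_tv`. Classification (`classify_query()`) is best-close-match to
the nearest reference individual (not a species centroid), assigning
only below `theta_k2p`, with exact-tie queries reported "ambiguous" and
the top three neighbors always returned.

Subspecies (trinomials) are kept as distinct terminal taxa by default,
with `collapse_subspecies()` available for pooling — surveys list
subspecies separately, but whether they should count as conspecific for
gap statistics is genuinely ambiguous, so both modes exist. A
configurable exclusion list (shipping with the *Culex mimeticus*
subgroup, `mimeticus_subgroup()`) removes taxa with known anomalous
barcodes before pooling.

The R-value is the unweighted mean over pairs of the per-pair
transition/transversion count ratio; pairs with zero transversions are
excluded and counted (an alternative — pooling counts over all sites —
is not used; the per-pair mean is the reading consistent with per-pair
distance analyses).

# Pseudogene (numt) quality control

Nuclear copies of mitochondrial fragments co-amplify with the true
barcode and must be removed. `screen_numt()` compares each sequence to
a majority-rule consensus (dataset-wide or within-species; alignment
ties break alphabetically for determinism) and applies the invertebrate
mitochondrial genetic code, table 5 (AGA/AGG = Ser, TGA = Trp; only
TAA/TAG are stops) — COI of mosquitoes uses this code, and a screen
under the standard code would miscall stops. The reading frame is
chosen to minimize internal stops in the consensus translation (ties to
the smallest offset).

The verdict is **fail** iff the sequence has an internal stop codon or
an indel relative to the reference (a gap on exactly one side of the
comparison) — the hard, unambiguous numt signatures. Without hard
flags, the codon-position profile (n1, n2, n3) of nucleotide mismatches
is tested against the functional expectation (default proportions
5:1:18 across positions 1:2:3) with an exact two-sided multinomial test
(total probability of outcomes no more likely than the observed one);
p < 0.01 yields **suspect**. The exact test replaces eyeballing of
ratios with a reproducible rule; 0.01 is deliberately conservative so
that ordinary functional divergence is not flagged. `insertion_scan()`
reports 1-based aligned columns where the record carries a residue
against a reference gap, and re-screening after `drop_columns()` is the
standard follow-up for suspected PCR frameshifts.

`divergence_time()` implements a linear two-rate clock: after nuclear
transfer the mitochondrial copy keeps rate r_mt while the numt evolves
at r_numt, so T = d / (r_mt + r_numt). The formula constants of the
cited clock literature are not fixed here; both rates are required
arguments with no shipped defaults. (For orientation: a numt 10.93%
diverged dates to 5.0e8 years under a summed rate of 2.186e-10
substitutions/site/year — the implied constant documented by the test
suite.)

# The community simulator

`simulate_community()` generates the structure the analysis assumes,
with a truth table, so every downstream stage has a known answer:

* a root sequence drawn from per-codon-position base frequencies
  (defaults: A+T ≈ 57% at positions 1 and 2 with A-rich firsts and
  T-rich seconds, A+T ≈ 93% at position 3, pooled ≈ 69% — the
  composition regime of culicid COI), resampled to avoid in-frame
  stops;
* a three-level hierarchy: genus ancestors, species ancestors,
  individuals, with branch lengths set so expected pairwise distances
  equal the configured depths — defaults 0.004 conspecific (matching
  observed within-species means of ~0.4%), 0.08 congeneric, 0.16
  intergeneric;
* the K2P jump process with transition/transversion rate ratio kappa
  (default 1.4, giving a count R-value near 0.7) and per-position rate
  multipliers 5:1:18 normalized to mean 1;
* each branch realizes its expected substitution-event count via
  stochastic rounding (events then land on sites in proportion to their
  rate multipliers). Conditioning on the expected count removes the
  large Poisson variance a single genus- or species-level branch would
  otherwise contribute, keeping realized divergence pools tightly
  centered on the programmed depths and cleanly separated — the
  property the delimitation tests rely on — while leaving the per-site
  law, and hence K2P estimator consistency, unchanged.
  `simulate_pair()`, used for estimator-recovery checks, keeps the
  unconditioned transition-probability sampling of the plain K2P
  process;
* functional lineages reject stop-creating mutations (the offending
  codon reverts to its parent), giving a clean zero-false-positive
  surface for QC tests;
* `inject_numt()` converts chosen individuals into pseudogene copies:
  background substitutions at position-uniform relaxed rates (default
  0.02/site) plus a lesion — internal TAA stop, 1-bp insertion (a new
  alignment column, gap in everyone else) or 1-bp deletion.

What the simulator does *not* emulate — and therefore what passing
tests cannot certify about real data: coalescent genealogies and shared
polymorphism within species (individuals are a star around the species
ancestor), selection and codon usage, indel evolution beyond single
numt lesions, ambiguity codes and ragged sequence ends, composition
drift is only approximated (the K2P process is composition-blind, so
deep branches drift slowly toward uniform composition from the biased
root — realized third-position A+T in a default community is ~86–87%
rather than the rooted 93%), and contamination or misidentification.
Estimates on real data also inherit K2P's bias under rate
heterogeneity, visible in the simulator as congeneric/intergeneric
pool means a few percent below the programmed depths.

# Problem sizes and reproducibility

The shipped tests run at desk scale by choice: communities of 5 genera
× 4 species × 4 individuals × 650 bp (the default configuration),
estimator recovery at 200 replicates per distance, NJ exactness on 100
random additive matrices (n ≤ 8) plus exhaustive 6-taxon search, and
bootstraps of B = 100 over 10 seeds; the full survey-scale screen (404
sequences) is exercised by the acceptance script. All randomness flows
from explicit integer seeds: the same seed reproduces alignments byte
for byte, bootstrap supports exactly, and the pipeline's summary JSON
bit-identically (modulo timestamps). The pipeline writes every artifact
with the configuration hash and seed, and `validate_summary()` checks
the summary JSON against its published field schema (version 1.0).

# Known limitations

* Distances beyond saturation are undefined by construction; datasets
  dominated by saturated pairs will exclude much of their signal (a
  count is always reported).
* The barcoding-gap thresholds are conventions, not estimates; no
  attempt is made to optimize them per dataset, and coalescent
  delimitation models are out of scope.
* The NJ implementation targets survey-scale matrices (hundreds of
  taxa); it is O(n³) in pure R and not intended for thousands of taxa.
* Input is assumed aligned and trimmed; the package neither aligns nor
  chooses the analyzed fragment.
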