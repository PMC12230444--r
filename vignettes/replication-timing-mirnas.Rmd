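---
title: "Methods: comparing miRNAs across DNA replication-timing domains"
author: "repliMir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing miRNAs across DNA replication-timing domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliMir)
```

# The scientific problem

DNA replication proceeds in a reproducible temporal program: some genomic
domains replicate early in S phase, others late. Late-replicating DNA
accumulates A/T-biased substitutions over evolutionary time, which poses a
structural problem for microRNAs encoded there: a pre-miRNA must fold into a
thermodynamically stable hairpin to be processed by Drosha and Dicer, and
A:U pairs are weaker than G:C pairs. `repliMir` implements, as a tested and
reusable pipeline, the comparative analysis of miRNAs located in early-
versus late-replicating domains: domain assignment from S/G1 ratio tracks,
hairpin sequence/structure/energy characterisation, flanking-sequence and
orthologue analysis, Dicer cleavage-motif clustering, CAGE-based promoter
calling, degree-preserving network null models, expression statistics, and a
sequence-based replication-timing classifier.

Every stage can be exercised on synthetic inputs with known ground truth, so
the statistical machinery is testable without any external download.

# Domain calling

Each sample's S/G1 ratio track is z-normalised per sample (subtract the
mean, divide by the standard deviation) and a window is called *early* when
its normalised ratio exceeds 0, *late* otherwise — a ratio of exactly 0 is
late. The population standard deviation (divide by *n*) is the default; the
source description does not fix the convention, so it is exposed as a
switch (`sd_type`), and normalisation is per sample track rather than
pooled, flagged for sensitivity analysis.

A miRNA locus is classified permissively: *late* if any overlapping window
in any sample is late (at least 1 bp of overlap counts, and a locus
spanning an early/late boundary takes the late label), *early* only if
every overlapping scored window in every sample is early, *unscored* when
no scored window is touched. Interval work uses `GenomicRanges`; tabular
inputs follow BED conventions (0-based half-open) and are converted at the
boundary, since 1-based closed coordinates are the natural convention for
the R containers used internally.

# The folding engine

The hairpin analyses need minimum free energy (MFE) structures, Boltzmann
ensembles and energy-term decompositions that agree with each other
exactly, and an acceptance oracle by exhaustive enumeration. The package
therefore ships its own simplified nearest-neighbour model rather than a
full published parameter set:

* canonical pairs (including GU), minimum hairpin loop of 3 nt;
* a 6×6 stacking matrix derived from per-pair strengths (CG/GC 2.6,
  AU/UA 1.3, GU/UG 0.8 kcal/mol): a step stacking pairs *p* and *q* scores
  `-(0.5 + (s_p + s_q)/2)` kcal/mol;
* hairpin, bulge and interior penalties with logarithmic
  (Jacobson–Stockmayer) size dependence: `5.0 + 1.75 RT ln(n/3)`,
  `3.8 + 1.75 RT ln(n)` and `4.0 + 1.75 RT ln(n/2)` kcal/mol;
* 1×1 interior loops (a stacked tri-nucleotide context with a middle
  mismatch) scored by a constant `+1.5` kcal/mol and bucketed separately as
  the *stack-mismatch* term; larger loops go to the interior term;
* an affine multibranch penalty `a + b·branches + c·unpaired`
  (3.4, 0.4, 0.1 kcal/mol) — the energy-term type gains an explicit
  `multi` bucket for it so that the total is always the exact sum of the
  buckets;
* no dangling ends or coaxial stacking; exterior bases are free; two-loops
  are capped at 30 unpaired nt (structures with larger two-loops are
  excluded from the model's structure space; their Boltzmann weight under
  the penalties above is negligible).

The MFE fold, the McCaskill-style partition function and the
outside recursion for base-pair probabilities are implemented in C++ over
the identical energy definition used by the R-level element scorer
`energyTerms()`, which iterates over parsed structure elements and shares
no code with the dynamic programming — the two routes check each other in
the test suite, and both are compared against exhaustive enumeration of all
well-nested structures at short lengths. Among co-minimal structures the
engine returns the lexicographically smallest dot-bracket
(`'(' < ')' < '.'`), which makes folding deterministic. Ensemble metrics at
37 °C use `RT = 0.6163` kcal/mol: the MFE frequency is
`exp(-dG/RT)/Z` and the ensemble diversity is the expected base-pair
distance of two independent draws, `2 Σ p_ij (1 - p_ij)` — diversity
conventions differ across tools by a factor, so the enumeration oracle pins
this one.

An external folding engine can stand in for the shipped table by computing
the same quantities upstream and feeding them to the statistics; every
numeric check in this package is defined against the shipped table.

The neutral set size of a structure (how many sequences have it as their
MFE fold) is estimated by uniform sampling of compatible sequences — each
pair drawn from the 6 pair types, unpaired positions uniform — scaled by
the compatible-sequence count `C = 6^bp · 4^unpaired`, with a binomial
standard error. Under the table above a 2-bp helix never beats the open
chain, so very short structures have empty neutral sets; the estimator and
the exhaustive count agree on that too.

# Flanks, orthologues and fold potential

GC profiles are per-site G+C fractions over the 200 bp upstream panel, the
two 50 bp precursor-end panels and the 200 bp downstream panel, extracted
strand-aware (for minus-strand loci all segments are reverse-complemented
and "upstream" is transcript 5'). The flank-versus-precursor comparison
treats per-site GC ratios as observations in a two-sided t test (Welch by
default); sites rather than loci are the units, matching the per-site
profile construction.

Orthologue identity uses Needleman–Wunsch global alignment with affine gaps
(match +5, mismatch −4, gap opening 10, extension 0.5 — an
EDNAFULL-like scheme) and defines identity as matches over alignment
length; pairs at or above 60% are retained (inclusive). Fold-potential
thresholds are the 95th percentiles (linear interpolation; nearest-rank
available) of MFE, MFE frequency and diversity over a reference set, and a
candidate passes only if it is at or below all three.

# Dicer cleavage motifs

Arm coordinates are 1-based inclusive within the precursor. The 5'
cleavage motif is the 2nd–9th nucleotide downstream of the 3' end of the
5p arm (`[end+2, end+9]`); the 3' motif is the −10th to −3rd nucleotide
upstream of the 5' end of the 3p arm (`[start-10, start-3]`); both are read
5'→3' on the precursor strand and are exactly 8 nt, or the record is
skipped and counted. Position-specific composition is compared primarily by
a 2×2 chi-square on A/U versus G/C (df = 1, no continuity correction; the
2×4 table is also emitted). Unique motifs form a Levenshtein distance
matrix; the 2-D embedding is metric MDS by SMACOF stress majorization from
a classical Torgerson start, so exactly embeddable configurations reach
numerically zero stress, and per-dimension group tests are run after
expanding unique motifs back to per-miRNA points.

# CAGE promoter calling

Tags within the 50 kb transcript-upstream window of each precursor are
candidates. The count matrix is quantile-normalised across samples (the
"position-specific" normalisation of the source description is interpreted
as standard across-sample quantile normalisation). Background tags come
from 1,000 random intergenic loci (±2,500 bp windows) with detection in
fewer than 5 samples. Three sequence features are computed on 1,000 bp
windows: the CpG ratio `(#CG · L)/(#C · #G)`, the TRAP expected occupancy
of a TATA-box weight matrix (`λ = 0.7`, `R0 = exp(0.584 W − 5.66)`, both
strands; a TATA matrix ships in `inst/extdata/tata_box.meme`) and mean
conservation (consumed as input, never computed). A logistic GLM on the
standardized features produces per-tag priors (with a ridge fallback,
penalty `1e-4`, under complete separation), which a semi-supervised
two-component Gaussian EM then combines with the log tag abundance:
the E-step weighs the component densities by the per-tag prior, the M-step
updates posterior-weighted means and standard deviations (floored at
`1e-3`), and the observed-data log-likelihood is non-decreasing — asserted
by the class validity. The mixture is fit on `log10(count + 1)` scale when
driven from counts; abundance is a free argument, so the latent scale of a
simulation can be used directly. Tags with posterior strictly above 0.5 are
promoter-class; per miRNA the retained tag with maximal density (normalized
counts within ±50 bp, half-width configurable) wins, ties break towards the
precursor 5' end, and same-strand miRNAs within 10 kb share one promoter
(the sharing distance is configurable; the source fixes none).

# Network null model

The bipartite miRNA→target network is randomized by attempted edge swaps:
two edges are selected uniformly at random, the miRNAs are exchanged
unless either replacement edge already exists. "100,000 times" counts
*attempted* selections (collisions skip without retry; a success-count mode
would simply run longer, and the attempt convention matches the stepwise
description of the procedure). Degrees on both sides are invariant and are
asserted on every call. Observed category counts — targets exclusively
regulated by one early miRNA, by ≥2 early, by one late, by ≥2 late, or by
both classes (a partition of the targets) — and domain-concordance edge
counts are compared against the null distribution over (by default) 100
randomized networks via `z = (obs − mean)/sd` with sd over n − 1 and a
two-sided normal p-value; edges to targets without domain information are
excluded from concordance only.

# Expression and function

Replicates are averaged per tissue; a miRNA is expressed at ≥1 RPM
(inclusive). Tissue specificity uses tau, `Σ(1 − x_i/x_max)/(N − 1)`, on
raw values by default (`log2_before` switch available, off to match the
minimal source description). Annotation-category proportions between the
two target sets are compared within annotated universes (genes carrying at
least one annotation) by 2×2 chi-square tests, df = 1, no correction, raw
p-values with a Benjamini–Hochberg column appended for convenience.

# Replication-timing classifier

The built-in embedder is 340-dimensional normalized k-mer frequencies
(k = 1..4), optionally augmented with hairpin scalars; 640-dimensional
externally computed vectors (e.g. column-averaged transformer hidden
states) load from TSV through the same interface, keeping the classifier
pipeline identical without bundling any pretrained weights. An RBF-SVM is
trained on a stratified 80/20 split with an exhaustive 5×5 grid
(`C ∈ {0.1..1000}`, `γ ∈ {1..1e-4}`) under 5-fold stratified
cross-validated accuracy (the refit criterion is not fixed by the source;
CV accuracy is used), class weights balanced, features standardized inside
the SVM. The late-class predicted probability is the late-propensity score;
evaluation reports ROC/AUC (trapezoidal, tie-grouped — equal by identity to
Mann–Whitney U/(n₁n₂), asserted in the tests) and a two-sided Mann–Whitney
comparison of scores between true classes.

# The synthetic data generators

The generators define the study conditions; each derives its own RNG
stream from `(seed, generator name)` so stages reproduce independently.

* **Replication track** — 2,000 windows × 2 samples by default; true
  domains in geometric blocks (mean 20 windows, emulating megabase-scale
  domains at 10 kb bins); per-sample ratios Gaussian around ±gap/2 with sd
  0.5 and a default gap of 1.5, giving realistic but imperfect separation.
* **Hairpins** — 631 early / 362 late by default (the class sizes of the
  mouse analysis). Stems of 22 bp (+4 bp stem extension for the late
  class) with 5% 1×1 mismatches and 8% 1-nt bulges per stem position,
  loops of 4–8 nt, Poisson overhangs (late 5' overhangs shorter: mean 1.5
  versus 4). The late class adds `at_bias = 0.10` to the A/U draw
  probability, and its flanks are drawn `gc_bump = 0.08` below the 0.42
  background GC, emulating precursors that hold their GC against A/T-drifted
  surroundings. The intended dot-bracket is a valid structure of the
  emitted sequence but not necessarily its MFE structure; stages choose the
  intended or folded structure explicitly (exact MFE control is not needed
  by any test).
* **CAGE** — promoter fraction 0.1; log10 abundance Gaussians
  N(2.5, 0.5) versus N(0.5, 0.5) — the 4σ separation used by the recovery
  tests — with Poisson sample counts and class-shifted CpG/TATA/conservation
  covariates. The latent abundance draws are returned alongside the counts.
* **Network** — 36,505 edges, 7,411 targets (the scale of the analysed
  regulatory network). With propensity `net_rho_late` a late edge targets
  the pool unclaimed by early miRNAs, half the time restricted to targets
  already late-hit. A pure rich-get-richer rule was rejected at design
  time: piling late edges onto few targets *lowers* the count of
  late-exclusive multi-regulated targets below the degree-preserving null,
  inverting the statistic the propensity is meant to drive.
* **Expression** — 7 tissues × 2 replicates; expressed with probability
  0.55 (+0.15 for late), expressed values ≥1 RPM from a gamma tail.

What the generators do **not** emulate: linked mutational processes along
the chromosome, realistic genome composition beyond first-order GC, read
sampling, alignment artefacts, or miRNA families with shared descent.
Passing tests therefore demonstrate the correctness and calibration of the
statistical machinery under the stated generative assumptions, not the
biological conclusions on real data.

# Numerical choices and degenerate inputs

Constant ratio tracks, empty groups, all-zero expression vectors,
single-class training labels and zero null standard deviations raise
errors rather than propagate NaN. EM standard deviations are floored at
`1e-3`; MDS stops on a raw-stress change below `1e-12` within 300
iterations; SMACOF distances of coincident points are guarded; the MFE
tie-break and the seeded generator streams remove all run-to-run
nondeterminism. Problem sizes in the test-suite recovery runs (10,000
windows for domain recovery, 5,000 tags for EM recovery, 200 enumerated
sequences at ≤14 nt plus 1,000 40-nt partition checks, 50 calibration
seeds on an 80×600 network, a full-scale 36,505-edge randomization) were
chosen so each check has clear statistical resolution while the whole
suite stays comfortably within an interactive run.

# Known limitations

The energy table is deliberately compact: absolute free energies are not
comparable to full Turner-parameter engines, only the comparative
statistics built on them are meaningful. The CAGE stage interprets
"position-specific quantile normalization" as the standard across-sample
procedure. The t test on GC profiles treats sites as observations, which
ignores between-locus correlation. The classifier's reported performance
on synthetic hairpins says nothing about accuracy on real genomes with a
pretrained embedder. The pipeline consumes pre-converted coordinates;
assembly liftover, conservation-score computation and external accession
handling are out of scope.
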