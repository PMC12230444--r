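# repliMir

Comparative analysis of microRNAs across DNA replication-timing domains.

DNA replicates in a defined temporal order, and late-replicating domains
accumulate A/T-biased substitutions over evolutionary time. Pre-miRNAs
encoded in those domains must nonetheless keep folding into stable
hairpins to be processed by Drosha and Dicer. `repliMir` is an R package
for researchers in regulatory genomics who want to ask, end to end, how
miRNAs in early versus late domains differ — in hairpin architecture and
folding thermodynamics, flanking-sequence GC structure, orthologue fold
potential, Dicer cleavage motifs, promoter architecture, network-level
co-regulation and tissue expression — and whether the timing class is
predictable from sequence alone.

## What is inside

* **Domain calling** — per-sample z-normalisation of S/G1 ratio tracks
  (window early iff normalised ratio > 0, late iff ≤ 0) and permissive
  locus classification (late in ≥1 sample ⇒ late-miRNA).
* **Folding engine** — a simplified nearest-neighbour model (C++): MFE
  structures with a deterministic tie-break, McCaskill partition function,
  base-pair probabilities, MFE frequency `exp(-dG/RT)/Z`, ensemble
  diversity `2 Σ p_ij (1 − p_ij)`, element/energy-term decomposition
  (stack-match, stack-mismatch, bulge, interior, hairpin, multibranch) and
  neutral-set-size estimation by compatible-sequence sampling.
* **Genomic context** — strand-aware flank extraction, per-site GC
  profiles with t tests, Needleman–Wunsch orthologue identity (≥60%
  retained), 95th-percentile fold-potential criteria
  (`dG`, `mfe_freq`, `diversity` all at or below threshold).
* **Dicer motifs** — 8-nt cleavage windows from mature-arm coordinates,
  per-position A/U-vs-G/C chi-squares, Levenshtein distance matrices and
  SMACOF multidimensional scaling with per-dimension group tests.
* **CAGE promoters** — 50 kb upstream windows, quantile normalisation,
  intergenic background labelling, CpG/TRAP-TATA/conservation features, a
  logistic prior and a semi-supervised two-component Gaussian EM with a
  strict posterior > 0.5 promoter boundary.
* **Network null model** — degree-preserving edge swapping (attempted
  selections, collision-safe), target category partitions, domain
  concordance, and `z = (obs − mean)/sd` statistics over simulated
  networks.
* **Expression & function** — replicate averaging, ≥1 RPM expressed
  fractions, tau tissue specificity, annotation-proportion chi-squares.
* **Classifier** — k-mer (340-d) or externally loaded embeddings into a
  grid-searched RBF-SVM with late-propensity scores, ROC/AUC and
  Mann–Whitney comparisons.
* **Synthetic data** — seeded generators with ground truth for every
  input, so each stage has parameter-recovery and calibration tests.

## Worked example

```r
library(repliMir)

## replication track -> domain calls
cfg   <- syntheticConfig(seed = 1, n_windows = 4000)
track <- genReplicationTrack(cfg)
norm  <- apply(track$ratios, 2, normalizeRatioTrack)
calls <- apply(norm, 2, callDomains)
mean(calls == track$truth)
#> [1] 0.936

## a hairpin's ensemble metrics under the shipped energy model
em <- ensembleMetrics("GGCUAGCUGAUGCCAAGUGGUUCAAGCUAAUGCAUCGGCUAGCC")
em$structure
#> [1] "(((((((((((((....((((....))))..)))))))))))))"
sprintf("dG = %.2f kcal/mol, mfe_freq = %.3f, diversity = %.2f",
        em$dG, em$mfe_freq, em$diversity)
#> [1] "dG = -25.65 kcal/mol, mfe_freq = 0.694, diversity = 1.21"

## co-regulation: observed category counts vs a degree-preserving null
classes <- setNames(rep(c("early", "late"), c(486, 323)),
                    sprintf("mmu-mir-%03d", 1:809))
net <- genNetwork(syntheticConfig(seed = 1, net_rho_late = 0.3),
                  classes)$network
obs  <- targetCategoryCounts(net)
sims <- simulateNull(net, targetCategoryCounts,
                     n_networks = 25, n_swaps = 20000, seed = 2)
zTest(obs[["excl_multi_late"]], sims[, "excl_multi_late"])
#> observed 326, null 198.4 +/- 11.4, z = 11.18, p = 4.9e-29
```

The domain recovery (93.6%) reflects the default noisy track (mean gap
1.5, sd 0.5); the z-score says that with a late-late co-targeting
propensity of 0.3 the generated network holds far more targets regulated
exclusively by two or more late miRNAs (326) than its degree-preserving
randomizations (198 ± 11), the network-level signature the pipeline is
designed to detect. `runPipeline(validateConfig(...))` chains all stages
on synthetic data and writes per-stage tables plus a checksummed manifest.

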