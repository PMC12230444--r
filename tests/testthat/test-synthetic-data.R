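cfgSmall <- function(...) {
  base <- list(n_windows = 200L, n_mirnas_early = 30L, n_mirnas_late = 30L,
               cage_n_tags = 300L, net_n_targets = 120L, net_n_edges = 400L)
  do.call(syntheticConfig, utils::modifyList(base, list(...)))
}

test_that("generators are deterministic under a fixed seed", {
  cfg <- cfgSmall(seed = 7L)
  expect_identical(genReplicationTrack(cfg), genReplicationTrack(cfg))
  expect_identical(genHairpinSet(cfg, "late", n = 10),
                   genHairpinSet(cfg, "late", n = 10))
  expect_identical(genCage(cfg), genCage(cfg))
  cls <- setNames(rep(c("early", "late"), each = 10), sprintf("m%02d", 1:20))
  expect_identical(networkEdges(genNetwork(cfg, cls)$network),
                   networkEdges(genNetwork(cfg, cls)$network))
  expect_identical(genExpression(cfg, cls), genExpression(cfg, cls))
})

test_that("replication track recovers truth at a large mean gap", {
  cfg <- syntheticConfig(seed = 2L, n_windows = 10000L,
                         domain_mean_gap = 10, domain_noise_sd = 0.1)
  tr <- genReplicationTrack(cfg)
  norm <- apply(tr$ratios, 2, normalizeRatioTrack)
  calls <- apply(norm, 2, callDomains)
  expect_gte(mean(calls == tr$truth), 0.99)
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(n_windows = 0), "count")
  expect_error(syntheticConfig(domain_mean_gap = -1), "domain_mean_gap")
  expect_error(syntheticConfig(cage_sigma_P = 0), "sigma")
  expect_error(syntheticConfig(cage_mu_P = 0, cage_mu_B = 1), "mu_P")
  expect_error(syntheticConfig(at_bias = 1.6), "at_bias|probability")
  expect_error(genNetwork(cfgSmall(net_n_edges = 10000L),
                          setNames(rep("early", 3), c("a", "b", "c"))),
               "impossible")
})

test_that("late hairpins carry the configured A/U excess", {
  cfg <- syntheticConfig(seed = 5L, at_bias = 0.10)
  e <- genHairpinSet(cfg, "early", n = 500)
  l <- genHairpinSet(cfg, "late", n = 500)
  au <- function(seqs) mean(vapply(seqs, function(s)
    sum(composition(s)$mono[c("A", "U")]), numeric(1)))
  diff <- au(l$sequence) - au(e$sequence)
  expect_gte(diff, 0.06)
  expect_lte(diff, 0.14)
  # null effect: at_bias = 0 leaves the classes with equal expected A+U
  cfg0 <- syntheticConfig(seed = 5L, at_bias = 0)
  e0 <- genHairpinSet(cfg0, "early", n = 400)
  l0 <- genHairpinSet(cfg0, "late", n = 400)
  expect_lt(abs(au(l0$sequence) - au(e0$sequence)), 0.02)
})

test_that("hairpin construction yields valid structures and in-bounds arms", {
  cfg <- cfgSmall(seed = 9L)
  hp <- genHairpinSet(cfg, "late", n = 50)
  for (i in seq_len(50)) {
    expect_identical(nchar(hp$sequence[i]), nchar(hp$structure[i]))
    # intended structure is realisable: every pair canonical
    expect_silent(energyTerms(hp$sequence[i], hp$structure[i]))
  }
  arms <- hp$arms
  L <- setNames(nchar(hp$sequence), hp$id)
  expect_true(all(arms$start >= 1))
  expect_true(all(arms$end <= L[arms$id]))
  expect_true(all(arms$start <= arms$end))
})

test_that("synthetic class effects shift downstream statistics monotonically", {
  au <- function(seqs) mean(vapply(seqs, function(s)
    sum(composition(s)$mono[c("A", "U")]), numeric(1)))
  diffs <- vapply(c(0.02, 0.08, 0.16), function(b) {
    cfg <- syntheticConfig(seed = 11L, at_bias = b)
    au(genHairpinSet(cfg, "late", n = 150)$sequence) -
      au(genHairpinSet(cfg, "early", n = 150)$sequence)
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
  gcgap <- vapply(c(0.02, 0.10), function(g) {
    cfg <- syntheticConfig(seed = 12L, gc_bump = g)
    hp <- genHairpinSet(cfg, "late", n = 150)
    mean(gcProfile(substring(hp$sequence, 1, 20))) -
      mean(gcProfile(substring(hp$flank5, 1, 200)))
  }, numeric(1))
  expect_gt(gcgap[2], gcgap[1])
})

test_that("generated networks have no duplicate edges and correct size", {
  cfg <- cfgSmall(seed = 3L, net_rho_late = 0.8)
  cls <- setNames(rep(c("early", "late"), each = 15), sprintf("m%02d", 1:30))
  net <- genNetwork(cfg, cls)$network
  e <- networkEdges(net)
  expect_identical(nrow(e), 400L)
  expect_identical(anyDuplicated(paste(e$mirna, e$target)), 0L)
})

test_that("co-targeting propensity raises the late-exclusive multi count", {
  cls <- setNames(rep(c("early", "late"), each = 20), sprintf("m%02d", 1:40))
  counts <- vapply(c(0, 1), function(rho) {
    mean(vapply(1:5, function(s) {
      cfg <- syntheticConfig(seed = s, net_n_targets = 300L,
                             net_n_edges = 900L, net_rho_late = rho)
      targetCategoryCounts(genNetwork(cfg, cls)$network)[["excl_multi_late"]]
    }, numeric(1)))
  }, numeric(1))
  expect_gt(counts[2], counts[1])
})

test_that("expression generator respects the class effect and cutoff", {
  cls <- setNames(rep(c("early", "late"), each = 200), sprintf("m%03d", 1:400))
  cfg0 <- syntheticConfig(seed = 4L, expr_effect = 0)
  ex <- genExpression(cfg0, cls)
  tl <- averageReplicates(ex$rpm, ex$replicate_map)
  fr <- expressedFraction(tl, cls)
  expect_lt(mean(abs(fr[, "early"] - fr[, "late"])), 0.12)
  # all-zero matrix at the 1-rpm cutoff
  zero <- matrix(0, 4, 3, dimnames = list(letters[1:4], c("t1", "t2", "t3")))
  fr0 <- expressedFraction(zero, setNames(rep("g", 4), letters[1:4]))
  expect_true(all(fr0 == 0))
})

test_that("emitted files round-trip through the package readers", {
  cfg <- cfgSmall(seed = 8L)
  hp <- genHairpinSet(cfg, "early", n = 5)
  tmp <- tempfile(fileext = ".fa")
  writeFastaFile(setNames(hp$sequence, hp$id), tmp)
  back <- readFastaFile(tmp, rna = TRUE)
  expect_identical(unname(back), hp$sequence)
  bed <- data.frame(chrom = "chrS", start = c(0L, 100L), end = c(50L, 180L),
                    id = c("a", "b"), score = 0L, strand = c("+", "-"))
  tmp2 <- tempfile(fileext = ".bed")
  writeBed6(bed, tmp2)
  expect_identical(readBed6(tmp2)[, c(1:4, 6)], bed[, c(1:4, 6)])
  tmp3 <- tempfile(fileext = ".gff3")
  writeGff3(bed, tmp3)
  gff <- readGff3(tmp3)
  expect_identical(gff$start, bed$start)
  expect_identical(gff$end, bed$end)
  tmp4 <- tempfile(fileext = ".tsv")
  tr <- genReplicationTrack(cfg)
  writeTsv(data.frame(chrom = "chrS",
                      start = GenomicRanges::start(tr$windows) - 1L,
                      end = GenomicRanges::end(tr$windows), tr$ratios), tmp4)
  rt <- readRatioTrack(tmp4)
  expect_equal(unname(rt$ratios), unname(tr$ratios), tolerance = 1e-12)
})
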