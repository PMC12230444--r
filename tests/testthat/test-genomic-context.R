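test_that("flank extraction is strand-aware and skips edge loci", {
  chr <- paste(rep(c("A", "C", "G", "T"), 250), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrT = chr))
  loci <- data.frame(id = "x", chrom = "chrT", start = 400L, end = 460L,
                     strand = "+")
  fl <- extractFlanks(genome, loci, up = 10L, inner = 5L)
  expect_identical(fl$up200, substring(chr, 391, 400))
  expect_identical(fl$first50, substring(chr, 401, 405))
  expect_identical(fl$last50, substring(chr, 456, 460))
  expect_identical(fl$down200, substring(chr, 461, 470))
  # minus strand: upstream lies at larger coordinates, reverse-complemented
  lociM <- transform(loci, strand = "-")
  flM <- extractFlanks(genome, lociM, up = 10L, inner = 5L)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  expect_identical(flM$up200, rc(substring(chr, 461, 470)))
  expect_identical(flM$first50, rc(substring(chr, 456, 460)))
  expect_identical(flM$down200, rc(substring(chr, 391, 400)))
  # locus too close to the chromosome start is skipped with a warning
  edge <- data.frame(id = "e", chrom = "chrT", start = 3L, end = 60L,
                     strand = "+")
  expect_warning(fle <- extractFlanks(genome, edge, up = 10L, inner = 5L),
                 "skipped")
  expect_identical(fle$skipped, "e")
})

test_that("GC profile equals a per-column tally", {
  expect_equal(gcProfile(c("GG", "GA")), c(1, 0.5))
  set.seed(41)
  seqs <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""), "")
  prof <- gcProfile(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  want <- vapply(seq_len(25), function(j) mean(m[, j] %in% c("G", "C")),
                 numeric(1))
  expect_equal(prof, want)
  expect_error(gcProfile(c("AA", "AAA")), "ragged")
  # pooled profile is the weighted mean of group profiles
  g1 <- seqs[1:10]; g2 <- seqs[11:30]
  expect_equal(gcProfile(seqs),
               (10 * gcProfile(g1) + 20 * gcProfile(g2)) / 30)
})

test_that("profile t test flags the synthetic GC bump", {
  expect_error(profileTtest(rep(0.5, 10), rep(0.5, 10)), "zero variance")
  cfg <- syntheticConfig(seed = 23L, gc_bump = 0.08)
  hp <- genHairpinSet(cfg, "late", n = 500)
  flank_sites <- gcProfile(substring(hp$flank5, 1, 200))
  end_sites <- gcProfile(substring(hp$sequence, 1, 20))
  ht <- profileTtest(flank_sites, end_sites)
  expect_lt(ht$p.value, 0.05)
  expect_lt(mean(flank_sites), mean(end_sites))
})

test_that("global identity matches hand and exhaustive alignment", {
  expect_equal(globalIdentity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(globalIdentity("ACGT", "ACGA"), 75)
  # identity is symmetric under the symmetric scoring
  set.seed(57)
  for (rep in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 5, TRUE), collapse = "")
    expect_equal(globalIdentity(a, b), globalIdentity(b, a))
  }
  expect_error(globalIdentity("", "ACGT"), "empty")
})

test_that("alignment scores equal exhaustive enumeration at tiny lengths", {
  set.seed(63)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4)
  for (rep in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(4:6, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:6, 1), TRUE),
               collapse = "")
    al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 10, gapExtension = 0.5)
    want <- oracleGlobalAlign(a, b)
    expect_equal(Biostrings::score(al), want$score, tolerance = 1e-9)
  }
})

test_that("orthologue filter keeps the 60% boundary inclusive", {
  p <- data.frame(id = c("a", "b", "c"), identity = c(60.0, 59.9, 80))
  kept <- orthologueFilter(p)
  expect_identical(kept$id, c("a", "c"))
  expect_identical(nrow(orthologueFilter(p[0, ])), 0L)
})

test_that("95th percentile thresholds use linear interpolation", {
  th <- percentileThresholds(1:100, seq(0, 1, length.out = 100),
                             (1:100) / 2)
  expect_equal(th$dg_max, 95.05)
  # constant vector yields that constant
  expect_equal(percentileThresholds(rep(3, 20), rep(0.5, 20),
                                    rep(10, 20))$dg_max, 3)
  # monotone under adding larger values
  th2 <- percentileThresholds(c(1:100, 200), c(seq(0, 1, length.out = 100), 2),
                              c((1:100) / 2, 60))
  expect_gte(th2$dg_max, th$dg_max)
  expect_error(percentileThresholds(1:5, 1:5, 1:5), ">= 20")
})

test_that("fold-potential filter is inclusive at the published thresholds", {
  crit <- list(dg_max = -19.1, freq_max = 0.54, div_max = 22.2)
  expect_true(foldPotentialFilter(-19.1, 0.54, 22.2, crit))
  expect_false(foldPotentialFilter(-19.0, 0.54, 22.2, crit))
  expect_true(foldPotentialFilter(-30, 0.1, 5, crit))
  expect_error(foldPotentialFilter(NA, 0.5, 10, crit), "missing")
})

test_that("each single criterion passes a ceiling(0.95 n) count on its set", {
  set.seed(71)
  dg <- rnorm(200, -25, 4)
  fr <- runif(200)
  dv <- rgamma(200, 4, 0.3)
  th <- percentileThresholds(dg, fr, dv)
  expect_gte(sum(dg <= th$dg_max), ceiling(0.95 * 200))
  expect_gte(sum(fr <= th$freq_max), ceiling(0.95 * 200))
  expect_gte(sum(dv <= th$div_max), ceiling(0.95 * 200))
})

test_that("neighbourhood statistics match a brute-force scan", {
  genes <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(start = c(20000, 60000, 900000),
                     end = c(30000, 70000, 910000)),
    strand = c("+", "-", "+"))
  loci <- data.frame(id = c("near", "far"), chrom = "c1",
                     start = c(34999, 85000), end = c(35100, 85100),
                     strand = "+")
  got <- neighborhoodStats(loci, genes)
  expect_identical(got$has_gene_10kb, c(TRUE, FALSE))
  expect_identical(got$n_genes_1Mb, c(3L, 3L))
  expect_identical(got$overlap_category, c("intergenic", "intergenic"))
  # host categories by strand
  host <- data.frame(id = c("same", "opp"), chrom = "c1",
                     start = c(25000, 65000), end = c(25100, 65100),
                     strand = "+")
  expect_identical(neighborhoodStats(host, genes)$overlap_category,
                   c("same_strand_host", "opposite_strand_host"))
  # random fixture vs direct counting
  set.seed(91)
  g2 <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(start = sample.int(5e5, 50), width = 2000),
    strand = sample(c("+", "-"), 50, TRUE))
  l2 <- data.frame(id = paste0("m", 1:20), chrom = "c1",
                   start = sample.int(5e5, 20), end = 0, strand = "+")
  l2$end <- l2$start + 100
  got2 <- neighborhoodStats(l2, g2, near_bp = 5000L, far_bp = 50000L)
  for (i in 1:20) {
    s <- l2$start[i] + 1; e <- l2$end[i]
    ov <- function(pad) sum(GenomicRanges::start(g2) <= e + pad &
                              GenomicRanges::end(g2) >= s - pad)
    expect_identical(got2$has_gene_10kb[i], ov(5000) > 0)
    expect_identical(got2$n_genes_1Mb[i], ov(50000))
  }
})
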