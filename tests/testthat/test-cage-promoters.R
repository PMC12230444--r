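test_that("upstream windows are strand-aware with exact boundaries", {
  loci <- data.frame(id = c("p", "m"), chrom = "c1",
                     start = c(100000L, 100000L), end = c(100100L, 100100L),
                     strand = c("+", "-"))
  tags <- data.frame(chrom = "c1",
                     position = c(100001L - 49999L, 100001L - 50001L,
                                  100100L + 50000L, 100100L + 50001L))
  got <- windowTags(tags, loci, window = 50000L)
  plus <- got[got$mirna == "p", ]
  minus <- got[got$mirna == "m", ]
  expect_identical(plus$tag, 1L)       # 49,999 bp upstream assigned
  expect_identical(minus$tag, 3L)      # minus strand: upstream = larger coords
  expect_false(2L %in% got$tag)        # 50,001 bp upstream not assigned
  expect_false(4L %in% got$tag)
})

test_that("quantile normalization matches the hand oracle", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  got <- quantileNormalize(m)
  expect_equal(unname(got), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  # identical columns unchanged
  m2 <- cbind(c(5, 1, 9), c(5, 1, 9))
  expect_equal(unname(quantileNormalize(m2)), unname(m2))
  # defining property (tie-free data): columns share one sorted multiset
  set.seed(141)
  m3 <- matrix(runif(60), 20, 3)
  q3 <- quantileNormalize(m3)
  ref <- sort(q3[, 1])
  expect_equal(sort(q3[, 2]), ref)
  expect_equal(sort(q3[, 3]), ref)
  # ties receive the mean of the order statistics they span
  mt <- cbind(c(1, 1, 2), c(3, 4, 5))
  qt <- quantileNormalize(mt)
  expect_equal(unname(qt), cbind(c(2.25, 2.25, 3.5), c(2, 2.5, 3.5)))
  expect_warning(quantileNormalize(m[, 1, drop = FALSE]), "identity")
})

test_that("background labelling uses the detected-in-fewer-than-5 rule", {
  set.seed(151)
  tags <- data.frame(chrom = "c1", position = c(1000L, 1200L, 500000L))
  counts <- rbind(c(1, 1, 1, 1, 0, 0),   # detected in 4 samples
                  c(2, 1, 3, 1, 1, 0),   # detected in 5 samples
                  c(1, 0, 0, 0, 0, 0))
  genes <- GenomicRanges::GRanges("c1", IRanges::IRanges(400000, 450000))
  bg <- backgroundModel(tags, counts, genes,
                        chrom_lengths = c(c1 = 600000L), n_loci = 400L,
                        half_window = 300000L, seed = 3L)
  expect_true(1L %in% bg$background)
  expect_false(2L %in% bg$background)
  # seeded reproducibility of the sampled loci
  bg2 <- backgroundModel(tags, counts, genes,
                         chrom_lengths = c(c1 = 600000L), n_loci = 400L,
                         half_window = 300000L, seed = 3L)
  expect_identical(bg$loci, bg2$loci)
})

test_that("sequence features follow their closed forms", {
  expect_equal(cpgRatio("CGCGCG"), 2)   # 3 overlapping CG, 3 C, 3 G, L = 6
  expect_equal(cpgRatio(strrep("A", 20)), 0)
  pwm <- readMemePwm(system.file("extdata", "tata_box.meme",
                                 package = "repliMir"))
  expect_identical(dim(pwm), c(4L, 8L))
  expect_equal(colSums(pwm), rep(1, 8), tolerance = 0.01)
  f <- computeFeatures(strrep("A", 40), pwm, conservation = c(0.2, 0.4))
  expect_equal(f[["cpg_ratio"]], 0)
  expect_gte(f[["tata_affinity"]], 0)
  expect_equal(f[["conservation"]], 0.3)
  expect_error(computeFeatures("ACGT", NULL), "PWM")
  # a consensus-bearing window outscores its shuffled version
  consensus <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
  set.seed(161)
  ctx <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  win <- paste0(ctx, consensus, ctx)
  shuf <- paste(sample(strsplit(win, "")[[1]]), collapse = "")
  expect_gt(trapAffinity(win, pwm), trapAffinity(shuf, pwm))
})

test_that("the GLM prior separates informative features and stays calibrated", {
  set.seed(171)
  # separable fixture triggers the ridge fallback with extreme priors
  x <- data.frame(f = c(rnorm(50, -3), rnorm(50, 3)))
  y <- rep(c(FALSE, TRUE), each = 50)
  expect_warning(fit <- fitGlmPrior(x, y), "ridge")
  expect_true(all(fit$prior[y] >= 0.99))
  expect_true(all(fit$prior[!y] <= 0.01))
  # uninformative features give priors near the base rate
  x2 <- data.frame(f1 = rnorm(2000), f2 = rnorm(2000))
  y2 <- runif(2000) < 0.3
  fit2 <- fitGlmPrior(x2, y2)
  expect_lt(max(abs(fit2$prior - mean(y2))), 0.05 + 0.05)
  expect_equal(mean(fit2$prior), mean(y2), tolerance = 0.05)
  # coefficient recovery on simulated logistic data
  n <- 5000
  f <- rnorm(n)
  eta <- -0.5 + 1.2 * f
  yy <- runif(n) < 1 / (1 + exp(-eta))
  fit3 <- fitGlmPrior(data.frame(f = f), yy)
  g <- glm(yy ~ f, family = binomial())
  se <- sqrt(diag(vcov(g)))[2]
  # fitGlmPrior standardizes internally; rescale its slope
  slope <- unname(fit3$coefficients[2]) / sd(f)
  expect_lt(abs(slope - 1.2), 3 * se)
})

test_that("EM posteriors follow the E-step algebra at degenerate priors", {
  set.seed(181)
  x <- rnorm(100)
  expect_warning(fit <- emMixture(x, rep(0, 100)), "degenerate")
  expect_true(all(posteriorProb(fit) == 0))
  expect_error(emMixture(x[1:5], rep(0.5, 5)), "at least 10")
  expect_error(emMixture(x, rep(2, 100)), "priors")
})

test_that("EM with uniform priors matches an independent implementation", {
  set.seed(191)
  x <- c(rnorm(600, 0, 0.5), rnorm(400, 3, 0.7))
  fit <- emMixture(x, rep(0.5, 1000))
  ref <- oracleEm(x)
  expect_equal(fit@mu_P, ref$mu_P, tolerance = 1e-3)
  expect_equal(fit@mu_B, ref$mu_B, tolerance = 1e-3)
  expect_equal(fit@sigma_P, ref$sigma_P, tolerance = 1e-3)
  expect_equal(fit@sigma_B, ref$sigma_B, tolerance = 1e-3)
  expect_equal(posteriorProb(fit), ref$q, tolerance = 1e-3)
  expect_true(all(diff(logLikTrace(fit)) > -1e-8))
})

test_that("promoter calls use the strict 0.5 boundary and maximal density", {
  loci <- data.frame(id = "m1", chrom = "c1", start = 10000L, end = 10100L,
                     strand = "+")
  tags <- data.frame(chrom = "c1", position = c(9000L, 9500L, 9600L, 9900L))
  assignments <- windowTags(tags, loci)
  abundance <- c(3, 7, 2, 5)
  # posterior exactly 0.5 is excluded (tag 1 carries density 3 otherwise)
  post <- c(0.5, 0.9, 0.8, 0.7)
  got <- callPromoters(assignments, post, abundance, tags, loci)
  expect_identical(got$tag, 2L)
  expect_equal(got$density, 7)
  # density ties break towards the tag nearest the miRNA 5' end
  tie <- callPromoters(assignments, post, c(3, 7, 7, 5), tags, loci)
  expect_identical(tie$tag, 3L)
  # all posteriors at the boundary give no call
  none <- callPromoters(assignments, rep(0.5, 4), abundance, tags, loci)
  expect_identical(nrow(none), 0L)
  expect_identical(attr(none, "no_call"), "m1")
})

test_that("clustered miRNAs share one promoter", {
  loci <- data.frame(id = c("mA", "mB"), chrom = "c1",
                     start = c(10000L, 15000L), end = c(10100L, 15100L),
                     strand = "+")
  tags <- data.frame(chrom = "c1", position = c(9500L, 120L))
  assignments <- windowTags(tags, loci)
  got <- callPromoters(assignments, c(0.9, 0.2), c(5, 1), tags, loci)
  expect_setequal(got$mirna, c("mA", "mB"))
  expect_identical(unique(got$tag), 1L)
})

test_that("end-to-end promoter recovery on generated CAGE data", {
  cfg <- syntheticConfig(seed = 29L, cage_n_tags = 5000L)
  cg <- genCage(cfg)
  gl <- fitGlmPrior(cg$features, cg$truth == "promoter")
  fit <- emMixture(cg$log_abundance, gl$prior)
  called <- posteriorProb(fit) > 0.5
  truthP <- cg$truth == "promoter"
  precision <- sum(called & truthP) / sum(called)
  expect_gte(precision, 0.9)
})
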