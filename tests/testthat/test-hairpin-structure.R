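par <- defaultEnergyParams()

test_that("composition frequencies follow the overlapping-window definition", {
  expect_equal(composition("AAAA")$mono[["A"]], 1)
  expect_equal(composition("AAAA")$di[["AA"]], 1)
  c4 <- composition("ACGU")
  expect_equal(unname(c4$mono), rep(0.25, 4))
  expect_equal(c4$di[c("AC", "CG", "GU")],
               c(AC = 1, CG = 1, GU = 1) / 3)
  expect_equal(sum(c4$di), 1)
  expect_error(composition(""), "empty")
  expect_error(composition("ACGX"), "non-ACGU")
  # U and T are unified on input
  expect_identical(composition("ACGT"), composition("ACGU"))
})

test_that("structure decomposition classifies elements and overhangs", {
  d <- decomposeStructure("((((....))))")
  kinds <- vapply(d$elements, `[[`, "", "kind")
  expect_setequal(kinds, c("stack_match", "hairpin_loop"))
  expect_identical(d$elements[[which(kinds == "stack_match")]]$n, 8L)
  expect_identical(d$n_match_nt, 8L)
  expect_identical(c(d$len_5p_overhang, d$len_3p_overhang), c(0L, 0L))

  d2 <- decomposeStructure("(((.((....)))))")
  k2 <- vapply(d2$elements, `[[`, "", "kind")
  expect_identical(sum(k2 == "stack_match"), 2L)  # 3 bp + 2 bp helices
  expect_identical(sum(k2 == "bulge"), 1L)
  expect_identical(d2$elements[[which(k2 == "bulge")]]$n, 1L)
  expect_identical(d2$elements[[which(k2 == "hairpin_loop")]]$n, 4L)

  d3 <- decomposeStructure("..((((....))))")
  expect_identical(d3$len_5p_overhang, 2L)

  expect_error(decomposeStructure("((..)"), "unbalanced")
})

test_that("decomposition partitions positions and round-trips the string", {
  set.seed(21)
  for (rep in 1:20) {
    s <- randomRna(sample(15:40, 1))
    db <- foldMfe(s, par)$structure
    d <- decomposeStructure(db)
    pos <- sort(unlist(lapply(d$elements, `[[`, "positions")))
    expect_identical(pos, seq_len(nchar(db)))
    # rebuild the dot-bracket from the pair table
    pt <- d$pair_table
    re <- rep(".", length(pt))
    re[pt > seq_along(pt)] <- "("
    re[pt > 0 & pt < seq_along(pt)] <- ")"
    expect_identical(paste(re, collapse = ""), db)
    expect_true(d$n_match_nt %% 2 == 0)
  }
})

test_that("energy terms sum linearly over elements", {
  flat <- par
  flat$stack[] <- -2
  flat$hairpin[] <- 4.5
  et <- energyTerms("GCGCAAAAGCGC", "((((....))))", flat)
  expect_equal(et[["stack_match"]], -6)
  expect_equal(et[["hairpin"]], 4.5)
  expect_equal(et[["total"]], -1.5)
  # all-dot structure carries no energy
  expect_true(all(energyTerms("ACGUACGU", "........", par) == 0))
  expect_error(energyTerms("AAGAAAAAAUAA", "((........))", par),
               "non-canonical")
})

test_that("engine energies agree with the element-wise scorer", {
  set.seed(33)
  for (rep in 1:15) {
    s <- randomRna(sample(20:60, 1))
    f <- foldMfe(s, par)
    expect_equal(unname(energyTerms(s, f$structure, par)["total"]), f$dG,
                 tolerance = 1e-9)
  }
})

test_that("unfoldable sequences return the open chain", {
  f <- foldMfe("AAAAA", par)
  expect_identical(f$structure, ".....")
  expect_identical(f$dG, 0)
  em <- ensembleMetrics("AAAAA", par)
  expect_equal(em$mfe_freq, 1)
  expect_equal(em$diversity, 0)
})

test_that("the 12-nt toy hairpin matches exhaustive enumeration", {
  s <- "GGGGAAAACCCC"
  o <- oracleEnsemble(s, par)
  f <- foldMfe(s, par)
  expect_identical(f$structure, o$structure)
  expect_equal(f$dG, o$dG, tolerance = 1e-9)
})

test_that("mfe frequency stays a probability on random 40-nt sequences", {
  set.seed(17)
  freqs <- vapply(1:150, function(i) {
    ensembleMetrics(randomRna(40), par, bpp = FALSE)$mfe_freq
  }, numeric(1))
  expect_true(all(freqs > 0 & freqs <= 1 + 1e-12))
})

test_that("neutral set size respects the compatible-sequence bound", {
  expect_identical(neutralSetSize("...")$estimate, 64)
  ns <- neutralSetSize("(((...)))", par, n_samples = 500, seed = 2)
  expect_lte(ns$estimate, ns$C)
  expect_error(neutralSetSize("(((...)))", par, n_samples = 50), ">= 100")
})

test_that("group comparison reproduces U and chi-square closed forms", {
  id <- groupCompare(1:10, 1:10)
  expect_gt(id$p.value, 0.99)
  # complete separation gives U = 0 for the first group
  sep <- groupCompare(1:20, 101:120)
  expect_identical(sep$statistic, 0)
  # binary comparison: 59/100 vs 48/100 by the df=1 hand formula
  a <- 59; b <- 41; c <- 48; d <- 52; n <- 200
  hand <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  bin <- groupCompare(rep(c(1, 0), c(59, 41)), rep(c(1, 0), c(48, 52)),
                      type = "binary")
  expect_equal(bin$statistic, hand, tolerance = 1e-12)
  expect_error(groupCompare(numeric(0), 1:3), "non-empty")
})

test_that("late-class construction shifts the downstream structure statistics", {
  cfg <- syntheticConfig(seed = 19L)
  e <- genHairpinSet(cfg, "early", n = 60)
  l <- genHairpinSet(cfg, "late", n = 60)
  stats <- function(hp) t(vapply(seq_along(hp$id), function(i) {
    d <- decomposeStructure(hp$structure[i])
    au <- sum(composition(hp$sequence[i])$mono[c("A", "U")])
    c(au = au, match = d$n_match_nt, ov5 = d$len_5p_overhang)
  }, numeric(3)))
  se <- stats(e); sl <- stats(l)
  expect_gt(mean(sl[, "au"]), mean(se[, "au"]))
  expect_gt(mean(sl[, "match"]), mean(se[, "match"]))
  expect_lt(mean(sl[, "ov5"]), mean(se[, "ov5"]))
})
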