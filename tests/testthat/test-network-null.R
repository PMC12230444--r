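toyNet <- function() {
  edges <- data.frame(
    mirna = c("e1", "e2", "l1", "l1", "l2", "e1"),
    target = c("t1", "t2", "t2", "t3", "t3", "t4"))
  mirnaNetwork(edges,
               mirnaClass = c(e1 = "early", e2 = "early",
                              l1 = "late", l2 = "late"),
               targetDomain = c(t1 = "early", t2 = "late", t3 = "late",
                                t4 = "unknown"))
}

test_that("duplicate edges and missing classes are rejected", {
  expect_error(mirnaNetwork(data.frame(mirna = c("a", "a"),
                                       target = c("t", "t")),
                            c(a = "early")),
               "duplicate")
  bad <- mirnaNetwork(data.frame(mirna = "a", target = "t"),
                      c(b = "early"))
  expect_error(targetCategoryCounts(bad), "without a class")
})

test_that("edge swapping preserves degrees and the edge count", {
  # two edges sharing a miRNA admit no executable swap
  stuck <- mirnaNetwork(data.frame(mirna = c("m1", "m1"),
                                   target = c("t1", "t2")),
                        c(m1 = "early"))
  r <- edgeSwapRandomize(stuck, 1000, seed = 1)
  expect_identical(sort(paste(networkEdges(r)$mirna, networkEdges(r)$target)),
                   sort(paste(networkEdges(stuck)$mirna,
                              networkEdges(stuck)$target)))
  expect_identical(attr(r, "n_performed"), 0L)
  # a two-edge disjoint network can only become the crossed pairing
  two <- mirnaNetwork(data.frame(mirna = c("m1", "m2"),
                                 target = c("t1", "t2")),
                      c(m1 = "early", m2 = "late"))
  swapped <- FALSE
  for (s in 1:20) {
    r2 <- edgeSwapRandomize(two, 50, seed = s)
    k <- sort(paste(networkEdges(r2)$mirna, networkEdges(r2)$target))
    expect_true(identical(k, c("m1 t1", "m2 t2")) ||
                  identical(k, c("m1 t2", "m2 t1")))
    if (identical(k, c("m1 t2", "m2 t1"))) swapped <- TRUE
  }
  expect_true(swapped)
})

test_that("degrees survive heavy randomization of a dense network", {
  cls <- setNames(rep(c("early", "late"), each = 25), sprintf("m%02d", 1:50))
  net <- genNetwork(syntheticConfig(seed = 37L, net_n_targets = 200L,
                                    net_n_edges = 1500L, net_rho_late = 0.5),
                    cls)$network
  r <- edgeSwapRandomize(net, 50000, seed = 9)   # internal assertion checks
  e0 <- networkEdges(net); e1 <- networkEdges(r)
  expect_identical(nrow(e1), nrow(e0))
  expect_identical(anyDuplicated(paste(e1$mirna, e1$target)), 0L)
  expect_gt(attr(r, "n_performed"), 0L)
})

test_that("category counts partition the targets of a toy network", {
  counts <- targetCategoryCounts(toyNet())
  expect_identical(counts[["excl_one_early"]], 2L)  # t1, t4
  expect_identical(counts[["excl_one_late"]], 0L)
  expect_identical(counts[["excl_multi_late"]], 1L) # t3
  expect_identical(counts[["both"]], 1L)            # t2
  expect_identical(sum(counts),
                   length(unique(networkEdges(toyNet())$target)))
  # all-early network has empty late categories
  allE <- mirnaNetwork(data.frame(mirna = c("a", "b"), target = c("t", "t2")),
                       c(a = "early", b = "early"))
  ce <- targetCategoryCounts(allE)
  expect_identical(unname(ce[c("excl_one_late", "excl_multi_late", "both")]),
                   c(0L, 0L, 0L))
})

test_that("category counts equal brute force on random toy networks", {
  set.seed(201)
  for (rep in 1:10) {
    nm <- 8; nt <- 12
    cls <- setNames(sample(c("early", "late"), nm, TRUE),
                    paste0("m", seq_len(nm)))
    pairs <- expand.grid(mirna = names(cls), target = paste0("t", 1:nt),
                         stringsAsFactors = FALSE)
    edges <- pairs[sample(nrow(pairs), 30), ]
    net <- mirnaNetwork(edges, cls)
    got <- targetCategoryCounts(net)
    want <- c(0, 0, 0, 0, 0)
    for (tg in unique(edges$target)) {
      regs <- cls[edges$mirna[edges$target == tg]]
      ne <- sum(regs == "early"); nl <- sum(regs == "late")
      slot <- if (ne >= 1 && nl >= 1) 5
        else if (ne == 1) 1 else if (ne >= 2) 2
        else if (nl == 1) 3 else 4
      want[slot] <- want[slot] + 1
    }
    expect_identical(unname(got), as.integer(want))
    expect_identical(sum(got), length(unique(edges$target)))
  }
})

test_that("concordance counts split classified edges exactly", {
  cc <- concordanceCounts(toyNet())
  # e1->t1 same; e2->t2 cross; l1->t2 same; l1->t3 same; l2->t3 same;
  # e1->t4 unknown, excluded
  expect_identical(cc[["same"]], 4L)
  expect_identical(cc[["cross"]], 1L)
  e <- networkEdges(toyNet())
  dom <- targetDomain(toyNet())[e$target]
  expect_identical(sum(cc), sum(dom != "unknown"))
  single <- mirnaNetwork(data.frame(mirna = "a", target = "t"),
                         c(a = "early"), c(t = "early"))
  expect_identical(unname(concordanceCounts(single)), c(1L, 0L))
})

test_that("z statistics follow the definition and reject degenerate input", {
  expect_error(zTest(5, simulated = 3), ">= 2")
  expect_error(zTest(5, sim_mean = 3, sim_sd = 0), "zero")
  zt <- zTest(10, simulated = c(10, 10, 10, 12, 8))
  expect_equal(zt$z, 0)
  expect_equal(zt$p, 1)
  expect_error(simulateNull(toyNet(), n_networks = 1), ">= 2")
})
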