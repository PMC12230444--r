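#' Degree-preserving edge-swap randomization
#'
#' Attempts `n_swaps` random selections of two edges
#' (miRNA1->target1, miRNA2->target2) and swaps the miRNAs between them
#' when neither miRNA1->target2 nor miRNA2->target1 already exists (a
#' colliding or self-selection attempt is counted but not executed). Per-node
#' degrees and the edge count are invariant; the degree invariant is asserted
#' on every call.
#'
#' @param network a [MirnaNetwork-class].
#' @param n_swaps attempted selections (default 100,000).
#' @param seed RNG seed.
#' @return a randomized `MirnaNetwork`; attribute `n_performed` gives the
#'   executed swap count.
#' @export
edgeSwapRandomize <- function(network, n_swaps = 100000L, seed = 1L) {
  e <- networkEdges(network)
  if (nrow(e) < 2) .stopf("need at least 2 edges")
  mir_ids <- sort(unique(e$mirna))
  tar_ids <- sort(unique(e$target))
  mi <- match(e$mirna, mir_ids) - 1L
  ti <- match(e$target, tar_ids) - 1L
  res <- withLocalSeed(seed, "edge_swap",
                       edge_swap_cpp(mi, ti, as.integer(n_swaps),
                                     length(tar_ids)))
  e2 <- data.frame(mirna = mir_ids[res$mirna + 1L],
                   target = tar_ids[res$target + 1L])
  deg <- function(x) { t <- table(x); t[order(names(t))] }
  stopifnot(identical(deg(e2$mirna), deg(e$mirna)),
            identical(deg(e2$target), deg(e$target)))
  out <- mirnaNetwork(e2, mirnaClass = regulatorClass(network),
                      targetDomain = targetDomain(network))
  attr(out, "n_performed") <- res$n_performed
  out
}

#' Target counts by regulator-class category
#'
#' Partitions the targets into five exclusive categories: regulated by
#' exactly one early miRNA, by two or more early miRNAs only, by exactly one
#' late miRNA, by two or more late miRNAs only, or by both classes.
#'
#' @param network a [MirnaNetwork-class].
#' @return named numeric vector `excl_one_early`, `excl_multi_early`,
#'   `excl_one_late`, `excl_multi_late`, `both` (sums to the target count).
#' @export
targetCategoryCounts <- function(network) {
  e <- networkEdges(network)
  cls <- regulatorClass(network)
  if (any(!e$mirna %in% names(cls)))
    .stopf("miRNA without a class entry")
  ec <- cls[e$mirna]
  nE <- tapply(ec == "early", e$target, sum)
  nL <- tapply(ec == "late", e$target, sum)
  c(excl_one_early = sum(nE == 1 & nL == 0),
    excl_multi_early = sum(nE >= 2 & nL == 0),
    excl_one_late = sum(nL == 1 & nE == 0),
    excl_multi_late = sum(nL >= 2 & nE == 0),
    both = sum(nE >= 1 & nL >= 1))
}

#' Same-domain versus cross-domain regulatory pair counts
#'
#' Counts edges whose miRNA class and target replication domain agree
#' (early->early plus late->late) and disagree; edges to targets with
#' unknown domain are excluded.
#'
#' @param network a [MirnaNetwork-class].
#' @return named numeric vector `same`, `cross` (their sum is the number of
#'   domain-classified edges).
#' @export
concordanceCounts <- function(network) {
  e <- networkEdges(network)
  cls <- regulatorClass(network)[e$mirna]
  dom <- targetDomain(network)[e$target]
  keep <- dom %in% c("early", "late")
  c(same = sum(keep & cls == dom),
    cross = sum(keep & cls != dom))
}

#' Null distribution of a network statistic over randomized networks
#'
#' Generates `n_networks` independent edge-swap randomizations (seeded as
#' `seed + index`) and evaluates the statistic on each.
#'
#' @param network a [MirnaNetwork-class].
#' @param statistic a function of a network returning a named numeric
#'   vector (e.g. [targetCategoryCounts] or [concordanceCounts]).
#' @param n_networks number of randomized networks (>= 2).
#' @param n_swaps attempted swaps per randomization.
#' @param seed base seed.
#' @return matrix of statistic values (networks x components) with
#'   attributes `mean` and `sd` (denominator n - 1).
#' @export
simulateNull <- function(network, statistic = targetCategoryCounts,
                         n_networks = 100L, n_swaps = 100000L, seed = 1L) {
  if (n_networks < 2)
    .stopf("need n_networks >= 2 for a standard deviation")
  vals <- t(vapply(seq_len(n_networks), function(k) {
    statistic(edgeSwapRandomize(network, n_swaps, seed = seed + k))
  }, statistic(network)))
  attr(vals, "mean") <- colMeans(vals)
  attr(vals, "sd") <- apply(vals, 2, sd)
  vals
}

#' Z-score of an observed count against simulated values
#'
#' `z = (observed - mean(simulated)) / sd(simulated)` with the two-sided
#' normal tail p-value.
#'
#' @param observed observed count.
#' @param simulated numeric vector of null statistic values (>= 2).
#' @param sim_mean,sim_sd alternatively, supply the summary directly.
#' @return list with `observed`, `sim_mean`, `sim_sd`, `z`, `p`.
#' @examples
#' zTest(1094, sim_mean = 1379, sim_sd = 21.95)
#' @export
zTest <- function(observed, simulated = NULL, sim_mean = NULL,
                  sim_sd = NULL) {
  if (!is.null(simulated)) {
    if (length(simulated) < 2) .stopf("need >= 2 simulated values")
    sim_mean <- mean(simulated)
    sim_sd <- sd(simulated)
  }
  if (is.null(sim_mean) || is.null(sim_sd))
    .stopf("supply simulated values or their mean and sd")
  if (sim_sd == 0) .stopf("null standard deviation is zero")
  z <- (observed - sim_mean) / sim_sd
  list(observed = observed, sim_mean = sim_mean, sim_sd = sim_sd, z = z,
       p = 2 * pnorm(-abs(z)))
}

#' Fraction of edges shared with another network
#'
#' @param a,b `MirnaNetwork` objects over the same node sets.
#' @return shared-edge fraction of `a`'s edge count, as a percentage.
#' @export
edgeOverlap <- function(a, b) {
  ka <- paste(networkEdges(a)$mirna, networkEdges(a)$target, sep = "\r")
  kb <- paste(networkEdges(b)$mirna, networkEdges(b)$target, sep = "\r")
  100 * length(intersect(ka, kb)) / length(ka)
}
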