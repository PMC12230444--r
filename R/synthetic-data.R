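#' Generate a synthetic S/G1 replication-timing track
#'
#' Emits contiguous fixed-width windows on a synthetic chromosome whose true
#' early/late domain labels are arranged in geometric-length runs (block
#' structure, as replication domains are megabase-scale). Per sample, the
#' S/G1 ratio of a window is drawn from a Gaussian centred at
#' `+domain_mean_gap/2` (early) or `-domain_mean_gap/2` (late) with sd
#' `domain_noise_sd`.
#'
#' @param config a [SyntheticConfig-class] object.
#' @param window_width window width in bp (default 10 kb).
#' @param run_mean mean run length of a domain block, in windows.
#' @return list with `windows` (a [GenomicRanges::GRanges]), `ratios`
#'   (windows x samples matrix), and `truth` (character early/late per
#'   window).
#' @export
genReplicationTrack <- function(config, window_width = 10000L,
                                run_mean = 20) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  if (config@n_windows < 2) .stopf("need at least 2 windows")
  withLocalSeed(config@seed, "replication_track", {
    n <- config@n_windows
    truth <- character(0)
    state <- sample(c("early", "late"), 1)
    while (length(truth) < n) {
      len <- rgeom(1, 1 / run_mean) + 1L
      truth <- c(truth, rep(state, len))
      state <- if (state == "early") "late" else "early"
    }
    truth <- truth[seq_len(n)]
    mu <- ifelse(truth == "early", config@domain_mean_gap / 2,
                 -config@domain_mean_gap / 2)
    ratios <- vapply(seq_len(config@n_samples),
                     function(s) mu + rnorm(n, 0, config@domain_noise_sd),
                     numeric(n))
    colnames(ratios) <- paste0("sample", seq_len(config@n_samples))
    windows <- GenomicRanges::GRanges(
      "chrS",
      IRanges::IRanges(start = (seq_len(n) - 1L) * window_width + 1L,
                       width = window_width))
    list(windows = windows, ratios = ratios, truth = truth)
  })
}

.BASES <- c("A", "C", "G", "U")

.classBaseProbs <- function(config, class_label) {
  p <- c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)
  if (class_label == "late") {
    p[c("A", "U")] <- p[c("A", "U")] + config@at_bias / 2
    p[c("C", "G")] <- p[c("C", "G")] - config@at_bias / 2
  }
  p
}

.revcompRna <- function(chars)
  rev(c(A = "U", C = "G", G = "C", U = "A")[chars])

#' Generate a set of synthetic pre-miRNA hairpins with ground truth
#'
#' Hairpins are built as 5' overhang + stem + loop + reverse-complemented
#' stem + 3' overhang, with occasional 1-nt bulges and 1x1 mismatches in the
#' stem, so that the intended dot-bracket is a realisable secondary
#' structure of the sequence (not necessarily its MFE structure; the folded
#' structure can be requested). The late class receives `+at_bias` A/U
#' probability, `+stem_extension` stem length and a shorter 5' overhang, and
#' its flanks are drawn `gc_bump` below the flank GC background, emulating
#' precursors that keep their GC against A/T-drifting surroundings.
#'
#' @param config a [SyntheticConfig-class].
#' @param class_label `"early"` or `"late"`.
#' @param n number of hairpins (defaults to the class count in `config`).
#' @param stem_base baseline stem length in bp.
#' @param flank_width flank length emitted on each side (bp).
#' @param fold also fold each sequence with [foldMfe()]?
#' @param par energy parameters used when `fold = TRUE`.
#' @return list with `id`, `sequence` (RNA strings), `structure` (intended
#'   dot-bracket), `folded` (optional), `arms` (data.frame id/arm/start/end,
#'   1-based inclusive within the precursor), `flank5`, `flank3` (DNA
#'   strings), and `class`.
#' @export
genHairpinSet <- function(config, class_label = c("early", "late"),
                          n = NULL, stem_base = 22L, flank_width = 250L,
                          fold = FALSE, par = defaultEnergyParams()) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  class_label <- match.arg(class_label)
  if (is.null(n))
    n <- if (class_label == "late") config@n_mirnas_late else config@n_mirnas_early
  stem_len <- stem_base + if (class_label == "late") config@stem_extension else 0L
  if (stem_len < 2) .stopf("stem shorter than 2 bp")
  p <- .classBaseProbs(config, class_label)
  gc_flank <- config@flank_gc - if (class_label == "late") config@gc_bump else 0
  pf <- c(A = (1 - gc_flank) / 2, C = gc_flank / 2,
          G = gc_flank / 2, T = (1 - gc_flank) / 2)

  withLocalSeed(config@seed, paste0("hairpins_", class_label), {
    ids <- sprintf("%s-mir-%04d", class_label, seq_len(n))
    seqs <- character(n)
    structs <- character(n)
    arms <- vector("list", n)
    flank5 <- character(n)
    flank3 <- character(n)
    for (i in seq_len(n)) {
      ov5 <- rpois(1, if (class_label == "late") 1.5 else 4)
      ov3 <- rpois(1, 4)
      loop_len <- sample(4:8, 1)
      s5 <- character(0); s3 <- character(0)   # 3' side built loop-outwards
      d5 <- character(0); d3 <- character(0)
      comp <- c(A = "U", C = "G", G = "C", U = "A")
      for (k in seq_len(stem_len)) {
        b <- sample(.BASES, 1, prob = p)
        r <- runif(1)
        if (r < 0.05) {                        # 1x1 mismatch
          nb <- sample(setdiff(.BASES, c(comp[[b]],
                  if (b %in% c("G", "U")) switch(b, G = "U", U = "G"))), 1)
          s5 <- c(s5, b); d5 <- c(d5, ".")
          s3 <- c(nb, s3); d3 <- c(".", d3)
        } else if (r < 0.13) {                 # paired step plus a 1-nt bulge
          s5 <- c(s5, b); d5 <- c(d5, "(")
          s3 <- c(comp[[b]], s3); d3 <- c(")", d3)
          xb <- sample(.BASES, 1, prob = p)
          if (runif(1) < 0.5) { s5 <- c(s5, xb); d5 <- c(d5, ".") }
          else { s3 <- c(xb, s3); d3 <- c(".", d3) }
        } else {
          s5 <- c(s5, b); d5 <- c(d5, "(")
          s3 <- c(comp[[b]], s3); d3 <- c(")", d3)
        }
      }
      ov5s <- sample(.BASES, ov5, replace = TRUE, prob = p)
      ov3s <- sample(.BASES, ov3, replace = TRUE, prob = p)
      loop <- sample(.BASES, loop_len, replace = TRUE, prob = p)
      seqs[i] <- paste(c(ov5s, s5, loop, s3, ov3s), collapse = "")
      structs[i] <- paste(c(rep(".", ov5), d5, rep(".", loop_len), d3,
                            rep(".", ov3)), collapse = "")
      L <- nchar(seqs[i])
      a5 <- c(ov5 + 1L, min(ov5 + 21L, ov5 + length(s5)))
      a3 <- c(max(L - ov3 - 20L, L - ov3 - length(s3) + 1L), L - ov3)
      arms[[i]] <- data.frame(id = ids[i], arm = c("5p", "3p"),
                              start = c(a5[1], a3[1]), end = c(a5[2], a3[2]))
      flank5[i] <- paste(sample(names(pf), flank_width, TRUE, prob = pf),
                         collapse = "")
      flank3[i] <- paste(sample(names(pf), flank_width, TRUE, prob = pf),
                         collapse = "")
    }
    out <- list(id = ids, sequence = seqs, structure = structs,
                arms = do.call(rbind, arms), flank5 = flank5,
                flank3 = flank3, class = rep(class_label, n))
    if (fold)
      out$folded <- vapply(seqs, function(s) foldMfe(s, par)$structure, "")
    out
  })
}

#' Generate a synthetic CAGE tag matrix with promoter/background truth
#'
#' Per-tag log10 abundances are drawn from the two-component Gaussian
#' mixture of the configuration (promoter vs background); sample-level
#' counts are Poisson around the shared abundance. CpG-ratio, TATA-affinity
#' and conservation covariates are drawn with class-dependent means so that
#' a feature-based prior is informative.
#'
#' @param config a [SyntheticConfig-class].
#' @return list with `counts` (tags x samples), `position`, `features`
#'   (data.frame cpg_ratio/tata_affinity/conservation), `truth`
#'   (promoter/background), `params`.
#' @export
genCage <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  if (config@cage_promoter_frac >= 1) .stopf("cage_promoter_frac must be < 1")
  withLocalSeed(config@seed, "cage", {
    n <- config@cage_n_tags
    truth <- ifelse(runif(n) < config@cage_promoter_frac,
                    "promoter", "background")
    x <- ifelse(truth == "promoter",
                rnorm(n, config@cage_mu_P, config@cage_sigma_P),
                rnorm(n, config@cage_mu_B, config@cage_sigma_B))
    lam <- pmax(10^x, 1e-6) / config@n_samples
    counts <- vapply(seq_len(max(2L, config@n_samples)),
                     function(s) rpois(n, lam), numeric(n))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    features <- data.frame(
      cpg_ratio = pmax(0, rnorm(n, ifelse(truth == "promoter", 0.8, 0.35), 0.15)),
      tata_affinity = pmax(0, rnorm(n, ifelse(truth == "promoter", 1.5, 0.7), 0.4)),
      conservation = ifelse(truth == "promoter", rbeta(n, 4, 2), rbeta(n, 2, 4)))
    list(counts = counts, log_abundance = x,
         position = sort(sample.int(1e6, n)),
         features = features, truth = truth,
         params = c(mu_P = config@cage_mu_P, sigma_P = config@cage_sigma_P,
                    mu_B = config@cage_mu_B, sigma_B = config@cage_sigma_B))
  })
}

#' Generate a synthetic bipartite miRNA-target network
#'
#' Edges are added one at a time with a uniformly chosen miRNA. For a
#' late-class miRNA, with probability `net_rho_late` the target is drawn
#' from the pool not yet claimed by any early miRNA -- half the time
#' restricted further to targets already hit by a late miRNA -- so late
#' edges both avoid early-covered genes and preferentially share targets
#' with other late miRNAs. This produces late-exclusive co-regulation
#' clusters that a degree-preserving null dissolves. At
#' `net_rho_late = 0` all targets are uniform and the network matches a
#' configuration-model draw.
#'
#' @param config a [SyntheticConfig-class].
#' @param mirna_classes named character vector (`early`/`late`) giving the
#'   regulator set.
#' @param target_domain_probs probabilities for early/late/unknown target
#'   domains.
#' @return list with `network` (a [MirnaNetwork-class]) and `truth`
#'   (generator propensities).
#' @export
genNetwork <- function(config, mirna_classes,
                       target_domain_probs = c(early = 0.45, late = 0.45,
                                               unknown = 0.10)) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  n_m <- length(mirna_classes)
  n_t <- config@net_n_targets
  n_e <- config@net_n_edges
  if (n_e > as.double(n_m) * n_t)
    .stopf("impossible edge count: %d > %d x %d", n_e, n_m, n_t)
  rho <- config@net_rho_late
  withLocalSeed(config@seed, "network", {
    mir_ids <- names(mirna_classes)
    if (is.null(mir_ids)) {
      mir_ids <- sprintf("mir%04d", seq_len(n_m))
      names(mirna_classes) <- mir_ids
    }
    is_late <- unname(mirna_classes[mir_ids] == "late")
    lateHit <- logical(n_t)
    earlyHit <- logical(n_t)
    have <- matrix(FALSE, n_m, n_t)
    em <- integer(n_e)
    et <- integer(n_e)
    for (e in seq_len(n_e)) {
      ok <- FALSE
      for (att in 1:200) {
        m <- sample.int(n_m, 1)
        t <- NA_integer_
        if (att <= 100 && is_late[m] && rho > 0 && runif(1) < rho) {
          pool <- if (runif(1) < 0.5) which(lateHit & !earlyHit)
                  else which(!earlyHit)
          if (!length(pool)) pool <- which(!earlyHit)
          t <- if (!length(pool)) sample.int(n_t, 1)
               else if (length(pool) == 1) pool
               else sample(pool, 1)
        } else t <- sample.int(n_t, 1)
        if (!have[m, t]) { ok <- TRUE; break }
      }
      if (!ok) .stopf("could not place edge %d without duplication", e)
      have[m, t] <- TRUE
      em[e] <- m
      et[e] <- t
      if (is_late[m]) lateHit[t] <- TRUE else earlyHit[t] <- TRUE
    }
    tar_ids <- sprintf("gene%05d", seq_len(n_t))
    dom <- sample(names(target_domain_probs), n_t, TRUE,
                  prob = target_domain_probs)
    names(dom) <- tar_ids
    net <- mirnaNetwork(data.frame(mirna = mir_ids[em], target = tar_ids[et]),
                        mirnaClass = mirna_classes, targetDomain = dom)
    list(network = net, truth = list(rho_late = rho, n_mirnas = n_m,
                                     n_targets = n_t, n_edges = n_e))
  })
}

#' Generate a synthetic tissue-expression matrix in RPM
#'
#' Each miRNA is expressed in a tissue with probability `expr_base`
#' (`+ expr_effect` for the late class); expressed entries draw an RPM value
#' of at least 1, silent entries fall below the 1-RPM cutoff. Two biological
#' replicates are emitted per tissue.
#'
#' @param config a [SyntheticConfig-class].
#' @param mirna_classes named character vector of classes.
#' @param n_replicates replicates per tissue.
#' @return list with `rpm` (miRNAs x columns), `replicate_map`
#'   (column/tissue) and `truth` (per-class expression probability).
#' @export
genExpression <- function(config, mirna_classes, n_replicates = 2L) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  if (config@expr_n_tissues < 2) .stopf("need at least 2 tissues")
  withLocalSeed(config@seed, "expression", {
    n <- length(mirna_classes)
    nt <- config@expr_n_tissues
    p_expr <- ifelse(mirna_classes == "late",
                     pmin(1, config@expr_base + config@expr_effect),
                     config@expr_base)
    cols <- as.vector(outer(paste0("tissue", seq_len(nt)),
                            paste0("rep", seq_len(n_replicates)),
                            paste, sep = "_"))
    rpm <- matrix(0, n, length(cols),
                  dimnames = list(names(mirna_classes) %||%
                                    sprintf("mir%04d", seq_len(n)), cols))
    for (ti in seq_len(nt)) {
      on <- runif(n) < p_expr
      base <- ifelse(on, 1 + rgamma(n, shape = 2, scale = 20), runif(n, 0, 0.9))
      for (r in seq_len(n_replicates)) {
        col <- paste0("tissue", ti, "_rep", r)
        rpm[, col] <- base * exp(rnorm(n, 0, 0.05))
      }
    }
    map <- data.frame(column = cols,
                      tissue = sub("_rep\\d+$", "", cols))
    list(rpm = rpm, replicate_map = map,
         truth = c(early = config@expr_base,
                   late = min(1, config@expr_base + config@expr_effect)))
  })
}
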