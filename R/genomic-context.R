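#' Extract strand-aware flanking segments around precursor loci
#'
#' For each locus, returns the 200 bp upstream, the first 50 bp from the 5'
#' end, the last 50 bp before the 3' end, and the 200 bp downstream, all in
#' transcript orientation: minus-strand loci yield reverse-complemented
#' segments and "upstream" means 5' of the transcript. Loci whose extension
#' exceeds the chromosome are skipped with a warning.
#'
#' @param genome a named [Biostrings::DNAStringSet] (one entry per
#'   chromosome).
#' @param loci a `GRanges` with strand, or a data.frame in BED convention
#'   with `chrom`, `start`, `end`, `strand` (and optionally `id`).
#' @param up,inner lengths of the upstream/downstream (200) and
#'   precursor-end (50) segments.
#' @return list of four character vectors (`up200`, `first50`, `last50`,
#'   `down200`), plus `id` and `skipped` (ids dropped at chromosome edges).
#' @export
extractFlanks <- function(genome, loci, up = 200L, inner = 50L) {
  gr <- if (is(loci, "GRanges")) loci else {
    stopifnot(all(c("chrom", "start", "end", "strand") %in% names(loci)))
    g <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$start + 1L, loci$end),
                                strand = loci$strand)
    names(g) <- loci$id %||% as.character(seq_len(nrow(loci)))
    g
  }
  ids <- names(gr) %||% as.character(seq_along(gr))
  sub <- function(chr, s, e) substring(as.character(genome[[chr]]), s, e)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  out <- list(up200 = character(0), first50 = character(0),
              last50 = character(0), down200 = character(0),
              id = character(0), skipped = character(0))
  for (i in seq_along(gr)) {
    chr <- as.character(GenomicRanges::seqnames(gr[i]))
    s <- GenomicRanges::start(gr[i])
    e <- GenomicRanges::end(gr[i])
    st <- as.character(GenomicRanges::strand(gr[i]))
    L <- nchar(as.character(genome[[chr]]))
    if (s - up < 1 || e + up > L || e - s + 1 < inner) {
      .warnf("locus %s skipped: flank extension exceeds chromosome", ids[i])
      out$skipped <- c(out$skipped, ids[i])
      next
    }
    if (st == "-") {
      segs <- c(up200 = rc(sub(chr, e + 1, e + up)),
                first50 = rc(sub(chr, e - inner + 1, e)),
                last50 = rc(sub(chr, s, s + inner - 1)),
                down200 = rc(sub(chr, s - up, s - 1)))
    } else {
      segs <- c(up200 = sub(chr, s - up, s - 1),
                first50 = sub(chr, s, s + inner - 1),
                last50 = sub(chr, e - inner + 1, e),
                down200 = sub(chr, e + 1, e + up))
    }
    out$up200 <- c(out$up200, segs[["up200"]])
    out$first50 <- c(out$first50, segs[["first50"]])
    out$last50 <- c(out$last50, segs[["last50"]])
    out$down200 <- c(out$down200, segs[["down200"]])
    out$id <- c(out$id, ids[i])
  }
  out
}

#' Per-site GC fraction profile of aligned flank segments
#'
#' At each site, counts the sequences carrying G or C and divides by the
#' number of sequences.
#'
#' @param seqs character vector of equal-length sequences.
#' @return numeric vector of per-site GC fractions.
#' @export
gcProfile <- function(seqs) {
  if (!length(seqs)) .stopf("need at least one sequence")
  L <- unique(nchar(seqs))
  if (length(L) != 1) .stopf("ragged segment lengths")
  m <- matrix(unlist(strsplit(toupper(seqs), "")), ncol = L, byrow = TRUE)
  colMeans(m == "G" | m == "C")
}

#' Compare GC ratios between a flank panel and a precursor-end panel
#'
#' Two-sided two-sample t test treating per-site GC ratios as observations
#' (e.g. the 200 upstream sites versus the 50 precursor 5'-end sites).
#' Welch by default.
#'
#' @param flank_sites,end_sites numeric vectors of per-site GC values.
#' @param var.equal pooled-variance test instead of Welch?
#' @return `htest` object from [stats::t.test].
#' @export
profileTtest <- function(flank_sites, end_sites, var.equal = FALSE) {
  if (length(flank_sites) < 2 || length(end_sites) < 2)
    .stopf("both site groups need >= 2 values")
  if (sd(flank_sites) == 0 && sd(end_sites) == 0)
    .stopf("zero variance in both groups")
  t.test(flank_sites, end_sites, var.equal = var.equal)
}

#' Global alignment percent identity
#'
#' Needleman-Wunsch global alignment with affine gaps via
#' [Biostrings::pairwiseAlignment] (defaults: match +5, mismatch -4, gap
#' opening 10, gap extension 0.5, so a gap of length L costs
#' `10 + 0.5 L`). Identity is matches divided by alignment length
#' (including gap columns), times 100.
#'
#' @param a,b DNA/RNA strings (T/U unified to T for alignment).
#' @param match,mismatch,gap_open,gap_extend scoring (penalties positive).
#' @return percent identity in `[0, 100]`.
#' @export
globalIdentity <- function(a, b, match = 5, mismatch = -4,
                           gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) .stopf("empty sequence")
  a <- chartr("Uu", "Tt", a)
  b <- chartr("Uu", "Tt", b)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  Biostrings::pid(al, type = "PID1")
}

#' Retain orthologue pairs above the identity cutoff
#'
#' @param pairs data.frame with an `identity` column (percent).
#' @param min_identity inclusive cutoff (default 60).
#' @return the retained rows.
#' @export
orthologueFilter <- function(pairs, min_identity = 60) {
  pairs[!is.na(pairs$identity) & pairs$identity >= min_identity, ,
        drop = FALSE]
}

#' Fold-potential thresholds from a reference miRNA set
#'
#' 95th percentiles (linear interpolation between order statistics, or
#' nearest-rank) of the MFE, MFE frequency and ensemble diversity over a
#' reference set.
#'
#' @param dg,mfe_freq,diversity numeric vectors over the reference set.
#' @param prob percentile (default 0.95).
#' @param method `"linear"` (type 7) or `"nearest"` (type 1).
#' @return named list with `dg_max`, `freq_max`, `div_max`.
#' @export
percentileThresholds <- function(dg, mfe_freq, diversity, prob = 0.95,
                                 method = c("linear", "nearest")) {
  method <- match.arg(method)
  type <- if (method == "linear") 7 else 1
  if (length(dg) < 20 || length(mfe_freq) < 20 || length(diversity) < 20)
    .stopf("need >= 20 reference values per metric")
  list(dg_max = unname(quantile(dg, prob, type = type)),
       freq_max = unname(quantile(mfe_freq, prob, type = type)),
       div_max = unname(quantile(diversity, prob, type = type)))
}

#' Test fold potential against the three ensemble criteria
#'
#' TRUE iff `dg <= dg_max` and `mfe_freq <= freq_max` and
#' `diversity <= div_max` (all boundaries inclusive).
#'
#' @param dg,mfe_freq,diversity metric values (vectorised).
#' @param criteria list from [percentileThresholds()] (or manual values).
#' @return logical vector.
#' @export
foldPotentialFilter <- function(dg, mfe_freq, diversity, criteria) {
  if (any(is.na(dg)) || any(is.na(mfe_freq)) || any(is.na(diversity)))
    .stopf("missing metric value")
  dg <= criteria$dg_max & mfe_freq <= criteria$freq_max &
    diversity <= criteria$div_max
}

#' Protein-coding neighbourhood statistics of a locus
#'
#' For each locus: whether any coding gene overlaps the +/-10 kb window, the
#' number of genes overlapping the +/-1 Mb window (any overlap, not
#' containment), and the host-overlap category from precursor-gene body
#' intersection and strand equality.
#'
#' @param loci named `GRanges` (with strand) or BED-convention data.frame.
#' @param genes `GRanges` of protein-coding gene bodies (with strand).
#' @param near_bp,far_bp window half-widths (10 kb / 1 Mb).
#' @return data.frame with `id`, `has_gene_10kb`, `n_genes_1Mb`,
#'   `overlap_category` in intergenic/same_strand_host/opposite_strand_host.
#' @export
neighborhoodStats <- function(loci, genes, near_bp = 10000L, far_bp = 1e6L) {
  gr <- if (is(loci, "GRanges")) loci else {
    g <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$start + 1L, loci$end),
                                strand = loci$strand %||% "+")
    names(g) <- loci$id %||% as.character(seq_len(nrow(loci)))
    g
  }
  ids <- names(gr) %||% as.character(seq_along(gr))
  near <- GenomicRanges::countOverlaps(gr + near_bp, genes,
                                       ignore.strand = TRUE) > 0
  nfar <- GenomicRanges::countOverlaps(gr + far_bp, genes,
                                       ignore.strand = TRUE)
  host <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE)
  cat <- rep("intergenic", length(gr))
  for (k in seq_along(host)) {
    q <- S4Vectors::queryHits(host)[k]
    s <- S4Vectors::subjectHits(host)[k]
    same <- as.character(GenomicRanges::strand(gr[q])) ==
      as.character(GenomicRanges::strand(genes[s]))
    # same-strand host takes precedence when a locus overlaps genes on both
    if (cat[q] == "same_strand_host") next
    cat[q] <- if (same) "same_strand_host" else "opposite_strand_host"
  }
  data.frame(id = ids, has_gene_10kb = as.logical(near),
             n_genes_1Mb = as.integer(nfar), overlap_category = cat)
}
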