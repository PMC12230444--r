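#' Average biological replicates per tissue
#'
#' @param mat genes/miRNAs x columns expression matrix.
#' @param replicate_map data.frame with `column`, `tissue`.
#' @return genes x tissues matrix of arithmetic means.
#' @export
averageReplicates <- function(mat, replicate_map) {
  mat <- as.matrix(mat)
  miss <- setdiff(colnames(mat), replicate_map$column)
  if (length(miss)) .stopf("unmapped columns: %s", paste(miss, collapse = ","))
  tissues <- unique(replicate_map$tissue)
  out <- matrix(0, nrow(mat), length(tissues),
                dimnames = list(rownames(mat), tissues))
  for (tz in tissues) {
    cols <- replicate_map$column[replicate_map$tissue == tz]
    out[, tz] <- rowMeans(mat[, cols, drop = FALSE])
  }
  out
}

#' Expressed fraction per tissue and group
#'
#' Proportion of each group's members at or above the RPM cutoff
#' (inclusive; the study criterion is >= 1 rpm).
#'
#' @param mat genes x tissues matrix.
#' @param groups named character vector (or factor) partitioning the rows.
#' @param cutoff expression threshold (default 1 rpm).
#' @return tissues x groups matrix of proportions.
#' @export
expressedFraction <- function(mat, groups, cutoff = 1) {
  mat <- as.matrix(mat)
  groups <- setNames(as.character(groups),
                     names(groups) %||% rownames(mat))
  lv <- unique(groups)
  if (!length(lv)) .stopf("no groups supplied")
  out <- matrix(0, ncol(mat), length(lv),
                dimnames = list(colnames(mat), lv))
  for (g in lv) {
    rows <- which(groups == g)
    if (!length(rows)) .stopf("empty group %s", g)
    out[, g] <- colMeans(mat[rows, , drop = FALSE] >= cutoff)
  }
  out
}

#' Tau tissue-specificity index
#'
#' `tau = sum_i (1 - x_i / max(x)) / (N - 1)`: 0 for uniform expression, 1
#' for single-tissue expression. Raw values are used by default; set
#' `log2_before` to log-transform (`log2(x + 1)`) first.
#'
#' @param x non-negative expression vector over N >= 2 tissues.
#' @param log2_before log-transform before computing tau?
#' @return tau in `[0, 1]`.
#' @examples
#' tauIndex(c(2, 1, 1))
#' @export
tauIndex <- function(x, log2_before = FALSE) {
  if (length(x) < 2) .stopf("need at least 2 tissues")
  if (any(x < 0)) .stopf("expression values must be non-negative")
  if (log2_before) x <- log2(x + 1)
  m <- max(x)
  if (m == 0) .stopf("all-zero expression vector: tau undefined")
  sum(1 - x / m) / (length(x) - 1)
}

#' Read a GMT gene-set file
#'
#' One named set per line: name, description, then member identifiers,
#' tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1)
  sets
}

#' Per-category annotation proportion tests between two target sets
#'
#' For each annotation category, compares the in-category proportions of
#' the two groups (within their annotated universes: genes carrying at
#' least one annotation in the collection) with a 2x2 chi-square, df = 1,
#' no continuity correction. Categories absent from both groups are skipped
#' with a note. A Benjamini-Hochberg column is appended.
#'
#' @param targets_a,targets_b character vectors of target gene ids.
#' @param collection named list of gene sets (see [readGmt()]).
#' @return data.frame with per-category counts, `chisq`, `p`, `p_bh`;
#'   attribute `skipped` lists categories absent from both groups.
#' @export
annotationProportionTest <- function(targets_a, targets_b, collection) {
  annotated <- unique(unlist(collection))
  ua <- intersect(unique(targets_a), annotated)
  ub <- intersect(unique(targets_b), annotated)
  rows <- list()
  skipped <- character(0)
  for (nm in names(collection)) {
    inA <- sum(ua %in% collection[[nm]])
    inB <- sum(ub %in% collection[[nm]])
    if (inA == 0 && inB == 0) { skipped <- c(skipped, nm); next }
    tab <- rbind(c(inA, length(ua) - inA), c(inB, length(ub) - inB))
    ht <- if (all(colSums(tab) > 0))
      suppressWarnings(chisq.test(tab, correct = FALSE))
    else list(statistic = 0, p.value = 1)
    rows[[nm]] <- data.frame(category = nm, in_a = inA, n_a = length(ua),
                             in_b = inB, n_b = length(ub),
                             chisq = unname(ht$statistic), p = ht$p.value)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(category = character(0), in_a = integer(0),
                         n_a = integer(0), in_b = integer(0),
                         n_b = integer(0), chisq = numeric(0), p = numeric(0))
  out$p_bh <- p.adjust(out$p, "BH")
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Compare a numeric property between two target sets
#'
#' Two-sided Mann-Whitney U with the tie-corrected normal approximation
#' (e.g. 3'-UTR lengths or tau values of exclusively early- versus
#' late-regulated targets).
#'
#' @param x,y numeric property vectors for the two sets.
#' @return list with `U` (statistic for the first set), `p.value`, sizes.
#' @export
targetPropertyCompare <- function(x, y) {
  if (!length(x) || !length(y)) .stopf("empty property vector")
  ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  list(U = unname(ht$statistic), p.value = ht$p.value,
       n_x = length(x), n_y = length(y))
}
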