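#' Extract a Dicer cleavage-recognition motif
#'
#' Arm coordinates are 1-based inclusive within the precursor (miRBase
#' dialect). The 5' cleavage motif spans precursor positions
#' `[end5p + 2, end5p + 9]` (second to ninth nucleotide downstream of the
#' 3' end of the 5p arm); the 3' cleavage motif spans
#' `[start3p - 10, start3p - 3]` (the -10th to -3rd nucleotide upstream of
#' the 5' end of the 3p arm). Motifs are always read 5' to 3' on the
#' precursor strand and are exactly 8 nt; records whose window exceeds the
#' precursor are skipped with a warning.
#'
#' @param sequences named character vector of precursor sequences (RNA).
#' @param arms data.frame with `id`, `arm` (`5p`/`3p`), `start`, `end`.
#' @param side which cleavage site, `"5p"` or `"3p"`.
#' @return data.frame with `id`, `side`, `motif` (skipped records omitted);
#'   attribute `n_skipped` reports the skip count.
#' @export
extractMotif <- function(sequences, arms, side = c("5p", "3p")) {
  side <- match.arg(side)
  sel <- arms[arms$arm == side, , drop = FALSE]
  out <- list()
  skipped <- 0L
  for (k in seq_len(nrow(sel))) {
    id <- as.character(sel$id[k])
    seqc <- sequences[[id]]
    if (is.null(seqc) || is.na(seqc)) next
    L <- nchar(seqc)
    win <- if (side == "5p") c(sel$end[k] + 2L, sel$end[k] + 9L)
           else c(sel$start[k] - 10L, sel$start[k] - 3L)
    if (win[1] < 1 || win[2] > L) {
      .warnf("motif window out of bounds for %s (%s side), record skipped",
             id, side)
      skipped <- skipped + 1L
      next
    }
    motif <- chartr("Tt", "Uu", toupper(substring(seqc, win[1], win[2])))
    out[[length(out) + 1L]] <- data.frame(id = id, side = side,
                                          motif = motif)
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(id = character(0), side = character(0),
                         motif = character(0))
  attr(res, "n_skipped") <- skipped
  res
}

#' Position-specific composition tests between two motif groups
#'
#' At each of the 8 motif positions, compares the two groups with a 2x2
#' chi-square on A/U versus G/C membership (df = 1, no continuity
#' correction by default, matching the hand formula
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`); a supplementary 2x4
#' nucleotide-by-group chi-square is also reported.
#'
#' @param motifs_a,motifs_b character vectors of 8-nt motifs.
#' @param correct continuity correction for the 2x2 test.
#' @return data.frame with one row per position: `chisq_au`, `p_au`,
#'   `chisq_4`, `p_4`, and the A/U counts per group.
#' @export
positionChisq <- function(motifs_a, motifs_b, correct = FALSE) {
  if (!length(motifs_a) || !length(motifs_b)) .stopf("empty motif group")
  W <- unique(c(nchar(motifs_a), nchar(motifs_b)))
  if (length(W) != 1) .stopf("motifs must share one width")
  ma <- do.call(rbind, strsplit(toupper(motifs_a), ""))
  mb <- do.call(rbind, strsplit(toupper(motifs_b), ""))
  res <- lapply(seq_len(W), function(pos) {
    au_a <- sum(ma[, pos] %in% c("A", "U", "T"))
    au_b <- sum(mb[, pos] %in% c("A", "U", "T"))
    tab2 <- rbind(c(au_a, nrow(ma) - au_a), c(au_b, nrow(mb) - au_b))
    h2 <- if (all(rowSums(tab2) > 0) && all(colSums(tab2) > 0))
      suppressWarnings(chisq.test(tab2, correct = correct))
    else list(statistic = 0, p.value = 1)
    lv <- c("A", "C", "G", "U")
    ca <- table(factor(chartr("T", "U", ma[, pos]), levels = lv))
    cb <- table(factor(chartr("T", "U", mb[, pos]), levels = lv))
    tab4 <- rbind(as.numeric(ca), as.numeric(cb))
    keep <- colSums(tab4) > 0
    h4 <- if (sum(keep) >= 2)
      suppressWarnings(chisq.test(tab4[, keep, drop = FALSE],
                                  correct = FALSE))
    else list(statistic = 0, p.value = 1)
    data.frame(position = pos, au_a = au_a, n_a = nrow(ma),
               au_b = au_b, n_b = nrow(mb),
               chisq_au = unname(h2$statistic), p_au = h2$p.value,
               chisq_4 = unname(h4$statistic), p_4 = h4$p.value)
  })
  do.call(rbind, res)
}

#' Levenshtein edit distance
#'
#' Unit-cost insertions, deletions and substitutions, via
#' [utils::adist].
#'
#' @param a,b character vectors (recycled).
#' @return integer distance(s).
#' @export
levenshteinDist <- function(a, b) {
  as.integer(diag(adist(a, b)))
}

#' Pairwise edit-distance matrix over unique motifs
#'
#' @param motifs character vector; duplicates are collapsed and the mapping
#'   from unique motif to contributing records is kept in the attributes.
#' @param ids optional record ids aligned with `motifs`.
#' @return symmetric integer matrix over the unique motifs, with attribute
#'   `members` (list of contributing ids per unique motif).
#' @export
motifDistanceMatrix <- function(motifs, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(motifs))
  uni <- unique(motifs)
  D <- adist(uni, uni)
  storage.mode(D) <- "integer"
  dimnames(D) <- list(uni, uni)
  attr(D, "members") <- split(ids, factor(motifs, levels = uni))
  D
}

#' 2-D metric MDS by stress majorization
#'
#' SMACOF-style iterations (Guttman transform with unit weights) starting
#' from classical Torgerson coordinates, run until the raw stress
#' `sum (d_ij - delta_ij)^2` changes by less than `tol`. Exactly embeddable
#' distance matrices (points on a line, an equilateral triangle) reach
#' numerically zero stress.
#'
#' @param D symmetric distance matrix (n >= 2).
#' @param seed seed recorded with the embedding (the Torgerson start makes
#'   the fit deterministic; the seed only perturbs a degenerate start).
#' @param max_iter,tol iteration controls.
#' @return list with `points` (n x 2), `stress` and `n_iter`.
#' @export
mds2d <- function(D, seed = 1L, max_iter = 300L, tol = 1e-12) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) .stopf("need at least 2 points")
  if (n == 2) {
    return(list(points = rbind(c(-D[1, 2] / 2, 0), c(D[1, 2] / 2, 0)),
                stress = 0, n_iter = 0L))
  }
  X <- suppressWarnings(cmdscale(D, k = 2))
  if (ncol(X) < 2) X <- cbind(X, 0)
  if (all(abs(X) < 1e-12)) {
    X <- withLocalSeed(seed, "mds_start",
                       matrix(rnorm(n * 2, sd = 1e-3), n, 2))
  }
  edist <- function(X) as.matrix(stats::dist(X))
  stress <- function(X) {
    d <- edist(X)
    sum((d[upper.tri(d)] - D[upper.tri(D)])^2)
  }
  s_old <- stress(X)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    d <- edist(X)
    ratio <- ifelse(d > 1e-12, D / d, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
    s_new <- stress(X)
    if (abs(s_old - s_new) < tol) { s_old <- s_new; break }
    s_old <- s_new
  }
  list(points = X, stress = s_old, n_iter = it)
}

#' Group separation along the two embedding dimensions
#'
#' Gaussian kernel density summaries (Scott-style bandwidth) and two-sided
#' two-sample t tests on the first and second coordinate separately.
#'
#' @param points n x 2 embedding coordinates.
#' @param groups factor/character of group labels (2 levels).
#' @return data.frame with one row per dimension: `t`, `p`, group means and
#'   bandwidths.
#' @export
groupSeparationTest <- function(points, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) .stopf("exactly two groups required")
  if (any(table(groups) < 2)) .stopf("each group needs >= 2 points")
  lv <- levels(groups)
  res <- lapply(1:2, function(dim) {
    x <- points[groups == lv[1], dim]
    y <- points[groups == lv[2], dim]
    eq <- isTRUE(all.equal(c(x, y), rep(c(x, y)[1], length(c(x, y))))) ||
      (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))
    ht <- if (eq) list(statistic = c(t = 0), p.value = 1)
          else t.test(x, y)
    data.frame(dimension = dim, t = unname(ht$statistic), p = ht$p.value,
               mean_a = mean(x), mean_b = mean(y),
               bw_a = if (length(unique(x)) > 1) bw.nrd(x) else NA_real_,
               bw_b = if (length(unique(y)) > 1) bw.nrd(y) else NA_real_)
  })
  do.call(rbind, res)
}
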