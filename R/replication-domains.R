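#' Normalize an S/G1 ratio track
#'
#' Centres and scales one sample's ratio vector: subtract the mean, divide
#' by the standard deviation. The population convention (divide by n) is the
#' default; the sample convention (n - 1) is available. Normalization is per
#' sample track, not pooled.
#'
#' @param ratios numeric vector (one sample).
#' @param sd_type `"population"` or `"sample"`.
#' @return normalized vector with mean 0 and sd 1 (in the chosen convention).
#' @examples
#' normalizeRatioTrack(c(1, 2, 3))
#' @export
normalizeRatioTrack <- function(ratios, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(ratios) < 2) .stopf("need at least 2 values")
  s <- sd(ratios)
  if (!is.finite(s) || s == 0) .stopf("zero variance in ratio track")
  if (sd_type == "population")
    s <- s * sqrt((length(ratios) - 1) / length(ratios))
  (ratios - mean(ratios)) / s
}

#' Call early/late domains from normalized ratios
#'
#' A window is an early domain if its normalized ratio is greater than 0 and
#' a late domain otherwise (a ratio of exactly 0 is late).
#'
#' @param normalized numeric vector of normalized ratios.
#' @return character vector of `"early"`/`"late"` labels.
#' @export
callDomains <- function(normalized) {
  ifelse(normalized > 0, "early", "late")
}

.asRanges <- function(x, what = "interval") {
  if (is(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$start >= x$end))
    .stopf("malformed %s: start >= end", what)
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Intersect two interval sets
#'
#' Returns every (query, subject) pair with at least 1 bp of overlap.
#' Data-frame inputs use BED conventions (0-based half-open, columns
#' `chrom`, `start`, `end`); `GRanges` inputs are used as-is.
#'
#' @param queries,subjects interval sets (data.frame or `GRanges`).
#' @return data.frame with `query`, `subject` (row indices) and
#'   `overlap` (bp).
#' @examples
#' a <- data.frame(chrom = "c", start = 0, end = 10)
#' b <- data.frame(chrom = "c", start = 9, end = 20)
#' intersectIntervals(a, b)
#' @export
intersectIntervals <- function(queries, subjects) {
  q <- .asRanges(queries, "query")
  s <- .asRanges(subjects, "subject")
  hits <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L,
                                      ignore.strand = TRUE)
  ov <- GenomicRanges::pintersect(q[S4Vectors::queryHits(hits)],
                                  s[S4Vectors::subjectHits(hits)],
                                  ignore.strand = TRUE)
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits),
             overlap = GenomicRanges::width(ov))
}

#' Classify miRNA loci by the replication domains they overlap
#'
#' A miRNA is `late` if any window it overlaps, in any sample, is a late
#' domain (permissive "at least one sample" rule); `early` if every
#' overlapping scored window in every sample is early; `unscored` if it
#' overlaps no scored window.
#'
#' @param loci miRNA loci (data.frame in BED convention with an `id` column,
#'   or a named `GRanges`).
#' @param windows genomic windows (data.frame/`GRanges`, same convention).
#' @param calls windows x samples matrix (or data.frame) of
#'   `"early"`/`"late"` labels.
#' @return data.frame with `id`, `class`, `n_samples_late` (number of
#'   samples in which the locus touches a late window).
#' @export
assignMirnaClass <- function(loci, windows, calls) {
  calls <- as.matrix(calls)
  ids <- if (is.data.frame(loci)) as.character(loci$id) else names(loci)
  if (is.null(ids)) ids <- as.character(seq_len(NROW(loci)))
  ov <- intersectIntervals(loci, windows)
  class <- rep("unscored", length(ids))
  n_late <- integer(length(ids))
  for (i in seq_along(ids)) {
    w <- ov$subject[ov$query == i]
    if (!length(w)) next
    lab <- calls[w, , drop = FALSE]
    late_by_sample <- apply(lab == "late", 2, any)
    n_late[i] <- sum(late_by_sample)
    class[i] <- if (any(late_by_sample)) "late" else "early"
  }
  data.frame(id = ids, class = class, n_samples_late = n_late)
}

#' Read a wide replication-ratio table
#'
#' Expects columns `chrom`, `start`, `end` (BED convention) followed by one
#' ratio column per sample.
#'
#' @param path TSV path.
#' @return list with `windows` data.frame and `ratios` matrix.
#' @export
readRatioTrack <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  list(windows = x[, c("chrom", "start", "end")],
       ratios = as.matrix(x[, setdiff(names(x), c("chrom", "start", "end")),
                            drop = FALSE]))
}

#' Write a miRNA class table
#'
#' @param classes data.frame from [assignMirnaClass()].
#' @param path output TSV.
#' @export
writeClassTable <- function(classes, path) {
  write.table(classes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
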