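#' Read and write the plain-text interchange formats
#'
#' Thin wrappers around Biostrings and base table I/O used by the pipeline:
#' FASTA for sequences, BED6 for loci (0-based half-open, strand in column
#' 6), GFF3 for gene models (1-based inclusive on disk, converted on read),
#' TSV for matrices/edge lists and JSON for truth sidecars.
#'
#' @param x object to write (named character vector / `XStringSet` for
#'   FASTA; data.frame for BED/TSV).
#' @param path file path.
#' @name pipelineIO
NULL

#' @rdname pipelineIO
#' @export
writeFastaFile <- function(x, path) {
  if (is.character(x)) {
    # route RNA through the DNA alphabet for on-disk storage
    x <- Biostrings::DNAStringSet(chartr("Uu", "Tt", x))
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname pipelineIO
#' @param rna return RNA-alphabet strings?
#' @export
readFastaFile <- function(path, rna = FALSE) {
  x <- Biostrings::readDNAStringSet(path)
  out <- setNames(as.character(x), names(x))
  if (rna) out <- chartr("Tt", "Uu", out)
  out
}

#' @rdname pipelineIO
#' @export
writeBed6 <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  bed <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    name = x$id %||% ".", score = x$score %||% 0,
                    strand = x$strand %||% "+")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname pipelineIO
#' @export
readBed6 <- function(path) {
  x <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(x)[1:6] <- c("chrom", "start", "end", "id", "score", "strand")
  x
}

#' @rdname pipelineIO
#' @param source GFF source field.
#' @export
writeGff3 <- function(x, path, source = "repliMir") {
  # x: BED-convention data.frame (0-based half-open); GFF3 is 1-based closed
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     x$chrom, source, x$start + 1L, x$end,
                     x$strand %||% "+", x$id))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipelineIO
#' @export
readGff3 <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  f <- strsplit(lines, "\t")
  data.frame(chrom = vapply(f, `[[`, "", 1),
             start = as.integer(vapply(f, `[[`, "", 4)) - 1L,
             end = as.integer(vapply(f, `[[`, "", 5)),
             strand = vapply(f, `[[`, "", 7),
             id = sub("^ID=", "", vapply(f, `[[`, "", 9)))
}

#' @rdname pipelineIO
#' @param row_names write/read row names?
#' @export
writeTsv <- function(x, path, row_names = FALSE) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = row_names,
              col.names = TRUE)
  invisible(path)
}

#' @rdname pipelineIO
#' @export
readTsv <- function(path, row_names = FALSE) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             row.names = if (row_names) 1 else NULL, check.names = FALSE)
}
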