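#' Simplified nearest-neighbour energy parameters
#'
#' The folding engine uses a deliberately compact thermodynamic table rather
#' than a full published parameter set: a 6x6 stacking matrix over the
#' canonical pair types (CG, GC, GU, UG, AU, UA), size-dependent hairpin,
#' bulge and interior-loop penalties with Jacobson-Stockmayer logarithmic
#' extrapolation, a constant term for 1x1 interior loops (a stacked
#' tri-nucleotide context with a middle mismatch), and an affine multibranch
#' penalty. Minimum hairpin loop is 3 nt; two-loops are capped at
#' `maxloop` total unpaired nucleotides; exterior bases are free.
#'
#' Stacking energies derive from per-pair strengths (CG/GC 2.6, AU/UA 1.3,
#' GU/UG 0.8 kcal/mol): a step stacking pair types p and q costs
#' `-(0.5 + (s_p + s_q)/2)` kcal/mol, reproducing the usual ordering of
#' Watson-Crick and wobble stabilities.
#'
#' @param maxloop maximum total unpaired size of a two-loop (nt).
#' @param max_size largest loop size for which penalties are tabulated;
#'   penalties for larger loops reuse the last entry (sequences analysed here
#'   are far shorter).
#' @return a named list with elements `stack` (6x6 matrix, kcal/mol),
#'   `hairpin`, `bulge`, `interior` (penalty vectors indexed by loop size),
#'   `mismatch`, `ml` (`c(a, b, c)` affine multiloop coefficients),
#'   `maxloop`, `min_hairpin`, `rt37`.
#' @examples
#' par <- defaultEnergyParams()
#' par$stack["CG", "GC"]
#' @export
defaultEnergyParams <- function(maxloop = 30L, max_size = 400L) {
  rt37 <- 0.0019872 * 310.15
  pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")
  s <- c(CG = 2.6, GC = 2.6, GU = 0.8, UG = 0.8, AU = 1.3, UA = 1.3)
  stack <- matrix(0, 6, 6, dimnames = list(pairs, pairs))
  for (p in pairs) for (q in pairs) stack[p, q] <- -(0.5 + (s[[p]] + s[[q]]) / 2)
  size <- seq_len(max_size)
  hairpin <- ifelse(size < 3, Inf, 5.0 + 1.75 * rt37 * log(pmax(size, 3) / 3))
  bulge <- 3.8 + 1.75 * rt37 * log(size)
  interior <- ifelse(size < 2, Inf, 4.0 + 1.75 * rt37 * log(pmax(size, 2) / 2))
  list(stack = stack, hairpin = hairpin, bulge = bulge, interior = interior,
       mismatch = 1.5, ml = c(a = 3.4, b = 0.4, c = 0.1),
       maxloop = as.integer(maxloop), min_hairpin = 3L, rt37 = rt37)
}

#' Write or read an energy parameter table as JSON
#'
#' @param par a parameter list as returned by [defaultEnergyParams()].
#' @param path file path.
#' @return `readEnergyParams` returns the parameter list.
#' @export
writeEnergyParams <- function(par, path) {
  out <- par
  out$stack <- list(pairs = colnames(par$stack), values = unname(par$stack))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeEnergyParams
#' @export
readEnergyParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stack <- matrix(unlist(x$stack$values), 6, 6)
  dimnames(stack) <- list(x$stack$pairs, x$stack$pairs)
  list(stack = stack, hairpin = as.numeric(x$hairpin),
       bulge = as.numeric(x$bulge), interior = as.numeric(x$interior),
       mismatch = x$mismatch,
       ml = c(a = x$ml[[1]], b = x$ml[[2]], c = x$ml[[3]]),
       maxloop = as.integer(x$maxloop), min_hairpin = as.integer(x$min_hairpin),
       rt37 = x$rt37)
}

# penalty lookups shared by the R element scorer; mirror src/fold.cpp
.hairpinPen <- function(n, par) par$hairpin[pmin(n, length(par$hairpin))]
.bulgePen <- function(n, par) par$bulge[pmin(n, length(par$bulge))]
.interiorPen <- function(n, par) par$interior[pmin(n, length(par$interior))]

.PAIR_TYPES <- c(CG = 1, GC = 2, GU = 3, UG = 4, AU = 5, UA = 6)

.pairType <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% names(.PAIR_TYPES)) unname(.PAIR_TYPES[key]) else 0L
}

#' Encode an RNA/DNA string as integer codes (A=0, C=1, G=2, U/T=3)
#' @noRd
.encodeSeq <- function(sequence) {
  if (!nzchar(sequence)) .stopf("empty sequence")
  chars <- strsplit(toupper(sequence), "")[[1]]
  chars[chars == "T"] <- "U"
  codes <- match(chars, c("A", "C", "G", "U")) - 1L
  if (anyNA(codes))
    .stopf("sequence contains non-ACGU(T) symbols: %s",
           paste(unique(chars[is.na(codes)]), collapse = ","))
  codes
}

.rtAt <- function(temperature) 0.0019872 * (273.15 + temperature)
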