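#' Mononucleotide and dinucleotide composition of a sequence
#'
#' Mononucleotide frequencies are counts divided by the length; dinucleotide
#' frequencies are overlapping-window counts divided by `L - 1`. U and T are
#' treated identically; output uses the RNA alphabet.
#'
#' @param sequence a single RNA or DNA string.
#' @return a list with numeric vectors `mono` (length 4) and `di`
#'   (length 16), each summing to 1 (single-nucleotide input has an empty
#'   dinucleotide block, returned as all-zero with `di_n = 0`).
#' @examples
#' composition("ACGU")$mono
#' @export
composition <- function(sequence) {
  codes <- .encodeSeq(sequence)
  alpha <- c("A", "C", "G", "U")
  chars <- alpha[codes + 1L]
  mono <- table(factor(chars, levels = alpha))
  mono <- as.numeric(mono) / length(chars)
  names(mono) <- alpha
  dinames <- as.vector(outer(alpha, alpha, paste0))
  if (length(chars) >= 2) {
    di <- paste0(chars[-length(chars)], chars[-1])
    di <- as.numeric(table(factor(di, levels = dinames))) / (length(chars) - 1)
  } else di <- rep(0, 16)
  names(di) <- dinames
  list(mono = mono, di = di)
}

#' Parse a dot-bracket string into a pair table
#'
#' @param structure dot-bracket string over `(`, `)`, `.`.
#' @return integer vector `pt` where `pt[i]` is the 1-based partner of
#'   position `i`, or 0 if unpaired.
#' @export
pairTable <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad)) .stopf("invalid dot-bracket symbols: %s", paste(bad, collapse = ","))
  pt <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (!length(stack)) .stopf("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) .stopf("unbalanced dot-bracket string")
  pt
}

#' Decompose a secondary structure into loop and stack elements
#'
#' Helices are split into contiguous stacked-pair runs (`stack_match`); 1x1
#' interior loops are reported as `stack_mismatch_context` (the two unpaired
#' nucleotides of a stacked tri-nucleotide alignment with a middle mismatch);
#' unpaired regions are classified as `bulge` (one side of a helix break),
#' `interior_loop` (both sides), `hairpin_loop` (closing a stem),
#' `multi_loop` (a loop with two or more enclosed branches) or `exterior`
#' (outside the outermost pairs, yielding the 5'/3' overhang lengths).
#'
#' @param structure dot-bracket string.
#' @return a list with `elements` (list of `kind`, `positions`, `n`),
#'   `pair_table`, and scalars `n_match_nt`, `n_loop_nt`, `len_5p_overhang`,
#'   `len_3p_overhang`.
#' @examples
#' d <- decomposeStructure("((((....))))")
#' sapply(d$elements, `[[`, "kind")
#' @export
decomposeStructure <- function(structure) {
  pt <- pairTable(structure)
  n <- length(pt)
  elements <- list()
  add <- function(kind, positions) {
    elements[[length(elements) + 1L]] <<- list(kind = kind,
                                               positions = as.integer(positions),
                                               n = length(positions))
  }

  # helices: maximal runs of directly stacked pairs
  opening <- which(pt > seq_len(n))
  inHelix <- logical(n)
  for (i in opening) {
    if (inHelix[i]) next
    run <- integer(0)
    a <- i
    repeat {
      run <- c(run, a, pt[a])
      b <- a + 1L
      if (b <= n && pt[a] - 1L >= 1L && pt[b] == pt[a] - 1L && pt[b] > b) a <- b
      else break
    }
    inHelix[run] <- TRUE
    add("stack_match", sort(run))
  }

  # loops closed by each pair; classify by branch count and side sizes
  for (i in opening) {
    j <- pt[i]
    unpaired <- integer(0)
    children <- list()
    k <- i + 1L
    while (k < j) {
      if (pt[k] == 0L) {
        unpaired <- c(unpaired, k)
        k <- k + 1L
      } else {
        children[[length(children) + 1L]] <- c(k, pt[k])
        k <- pt[k] + 1L
      }
    }
    nb <- length(children)
    if (nb == 0L) add("hairpin_loop", unpaired)
    else if (nb == 1L) {
      k1 <- children[[1]][1]; l1 <- children[[1]][2]
      n1 <- k1 - i - 1L; n2 <- j - l1 - 1L
      if (n1 == 0L && n2 == 0L) next           # stack step, already in a helix
      if (n1 == 1L && n2 == 1L) add("stack_mismatch_context", unpaired)
      else if (n1 == 0L || n2 == 0L) add("bulge", unpaired)
      else add("interior_loop", unpaired)
    } else if (length(unpaired)) add("multi_loop", unpaired)
  }

  ext <- which(pt == 0L & !outermostCovered(pt))
  len5 <- 0L
  len3 <- 0L
  if (any(pt > 0)) {
    firstPair <- min(which(pt > 0))
    lastPair <- max(which(pt > 0))
    len5 <- sum(ext < firstPair)
    len3 <- sum(ext > lastPair)
  } else {
    len5 <- n
    len3 <- 0L
  }
  if (length(ext)) add("exterior", ext)

  n_match_nt <- sum(pt > 0)
  n_loop_nt <- sum(pt == 0L) - length(ext)
  list(elements = elements, pair_table = pt, n_match_nt = n_match_nt,
       n_loop_nt = n_loop_nt, len_5p_overhang = len5, len_3p_overhang = len3)
}

# positions covered by any outermost pair
outermostCovered <- function(pt) {
  n <- length(pt)
  covered <- logical(n)
  i <- 1L
  while (i <= n) {
    if (pt[i] > i) {
      covered[i:pt[i]] <- TRUE
      i <- pt[i] + 1L
    } else i <- i + 1L
  }
  covered
}

#' Energy-term decomposition of a structure on a sequence
#'
#' Scores each element of the structure by table lookup under the shipped
#' simplified nearest-neighbour model and buckets the contributions into
#' `stack_match` (stacked pair steps), `stack_mismatch` (1x1 interior loops),
#' `bulge`, `interior`, `hairpin` and `multi` (affine multibranch penalty).
#' `total` is the exact sum of the terms and equals the folding free energy
#' the engine assigns to this structure.
#'
#' This scorer iterates over the parsed elements directly and shares no code
#' with the dynamic-programming engine, so the two act as mutual checks.
#'
#' @param sequence RNA/DNA string.
#' @param structure dot-bracket string of the same length.
#' @param par energy parameters ([defaultEnergyParams()]).
#' @return named numeric vector with the six term buckets and `total`.
#' @export
energyTerms <- function(sequence, structure, par = defaultEnergyParams()) {
  codes <- .encodeSeq(sequence)
  if (length(codes) != nchar(structure))
    .stopf("sequence and structure lengths differ")
  pt <- pairTable(structure)
  alpha <- c("A", "C", "G", "U")
  ptype <- function(i, j) {
    t <- .pairType(alpha[codes[i] + 1L], alpha[codes[j] + 1L])
    if (t == 0L)
      .stopf("non-canonical pair %s-%s at (%d,%d)",
             alpha[codes[i] + 1L], alpha[codes[j] + 1L], i, j)
    t
  }
  terms <- c(stack_match = 0, stack_mismatch = 0, bulge = 0, interior = 0,
             hairpin = 0, multi = 0)
  n <- length(pt)
  opening <- which(pt > seq_len(n))
  for (i in opening) {
    j <- pt[i]
    ptype(i, j) # validates pairability
    unpaired <- 0L
    children <- list()
    k <- i + 1L
    while (k < j) {
      if (pt[k] == 0L) { unpaired <- unpaired + 1L; k <- k + 1L }
      else { children[[length(children) + 1L]] <- c(k, pt[k]); k <- pt[k] + 1L }
    }
    nb <- length(children)
    if (nb == 0L) {
      terms["hairpin"] <- terms["hairpin"] + .hairpinPen(unpaired, par)
    } else if (nb == 1L) {
      k1 <- children[[1]][1]; l1 <- children[[1]][2]
      n1 <- k1 - i - 1L; n2 <- j - l1 - 1L
      if (n1 == 0L && n2 == 0L)
        terms["stack_match"] <- terms["stack_match"] +
          par$stack[ptype(i, j), ptype(k1, l1)]
      else if (n1 == 1L && n2 == 1L)
        terms["stack_mismatch"] <- terms["stack_mismatch"] + par$mismatch
      else if (n1 == 0L || n2 == 0L)
        terms["bulge"] <- terms["bulge"] + .bulgePen(n1 + n2, par)
      else
        terms["interior"] <- terms["interior"] + .interiorPen(n1 + n2, par)
    } else {
      terms["multi"] <- terms["multi"] +
        par$ml[["a"]] + par$ml[["b"]] * nb + par$ml[["c"]] * unpaired
    }
  }
  c(terms, total = sum(terms))
}

#' Minimum free energy structure under the shipped model
#'
#' Dynamic-programming fold over all well-nested structures (minimum hairpin
#' 3 nt, two-loops capped at `par$maxloop` unpaired nt). Among co-minimal
#' structures the lexicographically smallest dot-bracket string is returned,
#' which makes the fold deterministic.
#'
#' @param sequence RNA/DNA string (U/T unified).
#' @param par energy parameters.
#' @return list with `structure` (dot-bracket) and `dG` (kcal/mol).
#' @examples
#' foldMfe("GGGGAAAACCCC")
#' @export
foldMfe <- function(sequence, par = defaultEnergyParams()) {
  codes <- .encodeSeq(sequence)
  fold_mfe_cpp(codes, par)
}

#' Ensemble metrics: partition function, MFE frequency and diversity
#'
#' Computes the Boltzmann partition function over the same structure space as
#' [foldMfe()] at `RT = 0.0019872 * (273.15 + temperature)` kcal/mol,
#' the frequency of the MFE structure in the ensemble
#' (`exp(-dG/RT) / Z`), and the ensemble diversity: the expected base-pair
#' distance of two independent draws, `2 * sum p_ij * (1 - p_ij)` over
#' base-pair probabilities from the outside recursion.
#'
#' @param sequence RNA/DNA string.
#' @param par energy parameters.
#' @param temperature Celsius; default 37.
#' @param bpp compute base-pair probabilities (needed for `diversity`)?
#' @return list with `dG`, `structure`, `Z`, `mfe_freq`, `diversity` (NA when
#'   `bpp = FALSE`) and the `bpp` matrix.
#' @export
ensembleMetrics <- function(sequence, par = defaultEnergyParams(),
                            temperature = 37, bpp = TRUE) {
  codes <- .encodeSeq(sequence)
  rt <- .rtAt(temperature)
  mfe <- fold_mfe_cpp(codes, par)
  pf <- partition_cpp(codes, par, rt, bpp)
  mfe_freq <- exp(-mfe$dG / rt) / pf$Z
  diversity <- NA_real_
  P <- pf$bpp
  if (bpp) diversity <- 2 * sum(P * (1 - P))
  list(dG = mfe$dG, structure = mfe$structure, Z = pf$Z,
       mfe_freq = mfe_freq, diversity = diversity, bpp = P)
}

#' Neutral set size of a secondary structure
#'
#' Estimates the number of sequences whose MFE structure equals the target
#' structure. `C = 6^bp * 4^unpaired` counts the sequences compatible with
#' the structure under canonical (incl. GU) pairing; a seeded uniform sample
#' of compatible sequences is folded and the hit fraction scales `C`. For a
#' pair-free structure shorter than 7 nt every sequence folds open, so the
#' exact count `4^L` is returned.
#'
#' @param structure dot-bracket string.
#' @param par energy parameters.
#' @param n_samples number of sampled compatible sequences (>= 100).
#' @param seed RNG seed.
#' @return list with `estimate`, `log10` value, `se` (binomial sampling
#'   error on the estimate), `C`, `f_hat`, `n_samples`.
#' @export
neutralSetSize <- function(structure, par = defaultEnergyParams(),
                           n_samples = 1000L, seed = 1L) {
  pt <- pairTable(structure)
  bp <- sum(pt > 0) / 2
  unpaired <- sum(pt == 0)
  L <- length(pt)
  C <- 6^bp * 4^unpaired
  if (bp == 0 && L < 7) {
    est <- 4^L
    return(list(estimate = est, log10 = log10(est), se = 0, C = C,
                f_hat = 1, n_samples = 0L))
  }
  if (n_samples < 100) .stopf("n_samples must be >= 100")
  res <- withLocalSeed(seed, "neutral_set",
                       neutral_sample_cpp(structure, par, as.integer(n_samples)))
  f_hat <- res$hits / res$n
  se <- C * sqrt(f_hat * (1 - f_hat) / res$n)
  est <- C * f_hat
  list(estimate = est, log10 = if (est > 0) log10(est) else -Inf, se = se,
       C = C, f_hat = f_hat, n_samples = res$n)
}

#' Compare a metric between the early and late groups
#'
#' Continuous metrics: two-sided Mann-Whitney U with the tie-corrected normal
#' approximation. Binary metrics (e.g. "has any bulge energy contribution"):
#' a 2x2 chi-square with df = 1 and no continuity correction.
#'
#' @param x,y numeric (or logical for `type = "binary"`) vectors for the two
#'   groups.
#' @param type `"continuous"` or `"binary"`.
#' @param correct continuity correction for the chi-square (default off).
#' @return list with `statistic`, `p.value`, `method`, group sizes.
#' @export
groupCompare <- function(x, y, type = c("continuous", "binary"),
                         correct = FALSE) {
  type <- match.arg(type)
  if (!length(x) || !length(y)) .stopf("both groups must be non-empty")
  if (type == "continuous") {
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         method = "mann-whitney", n_x = length(x), n_y = length(y))
  } else {
    tab <- rbind(c(sum(x != 0), sum(x == 0)), c(sum(y != 0), sum(y == 0)))
    ht <- suppressWarnings(chisq.test(tab, correct = correct))
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         method = "chi-square", n_x = length(x), n_y = length(y))
  }
}
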