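# Independent oracles used across the suite.
#
# The enumeration oracle builds every well-nested structure (minimum hairpin
# 3 nt) of a short sequence and scores each by the element-wise scorer
# energyTerms(), which shares no code with the C++ dynamic programming.

enumStructures <- function(sequence, par = defaultEnergyParams()) {
  codes <- repliMir:::.encodeSeq(sequence)
  n <- length(codes)
  alpha <- c("A", "C", "G", "U")
  canPair <- function(i, j)
    repliMir:::.pairType(alpha[codes[i] + 1], alpha[codes[j] + 1]) > 0
  minh <- par$min_hairpin
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return("")
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- paste0(".", rec(i + 1, j))
    k <- i + minh + 1
    while (k <= j) {
      if (canPair(i, k)) {
        inner <- rec(i + 1, k - 1)
        rest <- rec(k + 1, j)
        out <- c(out, as.vector(outer(paste0("(", inner, ")"), rest, paste0)))
      }
      k <- k + 1
    }
    memo[[key]] <- out
    out
  }
  rec(1, n)
}

# full Boltzmann bookkeeping by brute force
oracleEnsemble <- function(sequence, par = defaultEnergyParams(),
                           temperature = 37) {
  rt <- 0.0019872 * (273.15 + temperature)
  structs <- enumStructures(sequence, par)
  E <- vapply(structs, function(db)
    unname(energyTerms(sequence, db, par)["total"]), numeric(1))
  w <- exp(-E / rt)
  Z <- sum(w)
  dG <- min(E)
  co <- structs[E <= dG + 1e-9]
  mfe_struct <- sort(co)[1]
  n <- nchar(sequence)
  P <- matrix(0, n, n)
  for (s in seq_along(structs)) {
    pt <- pairTable(structs[[s]])
    op <- which(pt > seq_len(n))
    for (i in op) P[i, pt[i]] <- P[i, pt[i]] + w[s]
  }
  P <- P / Z
  list(dG = dG, structure = mfe_struct, Z = Z,
       mfe_freq = exp(-dG / rt) / Z,
       diversity = 2 * sum(P * (1 - P)), bpp = P,
       n_structures = length(structs))
}

randomRna <- function(L, p = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "U"), L, TRUE, prob = p), collapse = "")
}

# brute-force all-pairs interval intersection (BED convention, half-open)
bruteIntersect <- function(queries, subjects) {
  out <- list()
  for (i in seq_len(nrow(queries))) for (j in seq_len(nrow(subjects))) {
    if (queries$chrom[i] != subjects$chrom[j]) next
    ov <- min(queries$end[i], subjects$end[j]) -
      max(queries$start[i], subjects$start[j])
    if (ov >= 1)
      out[[length(out) + 1]] <- data.frame(query = i, subject = j,
                                           overlap = ov)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(query = integer(0), subject = integer(0),
                  overlap = integer(0))
}

# memoized recursive-definition Levenshtein distance
oracleLevenshtein <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(A) + 1, length(B) + 1)
  d[, 1] <- 0:length(A)
  d[1, ] <- 0:length(B)
  for (i in seq_along(A)) for (j in seq_along(B))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (A[i] != B[j]))
  d[length(A) + 1, length(B) + 1]
}

# exhaustive global alignment score by recursion over edit operations
oracleGlobalAlign <- function(a, b, match = 5, mismatch = -4,
                              gap_open = 10, gap_extend = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  # enumerate alignments recursively, tracking whether a gap is open
  best <- -Inf
  bestId <- 0
  rec <- function(i, j, score, matches, len, gapA, gapB) {
    if (i > length(A) && j > length(B)) {
      if (score > best + 1e-9 ||
          (abs(score - best) <= 1e-9 && matches / len > bestId)) {
        best <<- score
        bestId <<- matches / len
      }
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      s <- if (A[i] == B[j]) match else mismatch
      rec(i + 1, j + 1, score + s, matches + (A[i] == B[j]), len + 1,
          FALSE, FALSE)
    }
    if (i <= length(A))
      rec(i + 1, j, score - (if (gapA) gap_extend else gap_open + gap_extend),
          matches, len + 1, TRUE, FALSE)
    if (j <= length(B))
      rec(i, j + 1, score - (if (gapB) gap_extend else gap_open + gap_extend),
          matches, len + 1, FALSE, TRUE)
  }
  rec(1, 1, 0, 0, 0, FALSE, FALSE)
  list(score = best)
}

# simple unsupervised two-component Gaussian EM with fixed equal weights,
# mirroring the semi-supervised updates at p_i = 1/2 (independent code path)
oracleEm <- function(x, tol = 1e-6, max_iter = 500, floor = 1e-3) {
  hi <- x >= stats::median(x)
  muP <- mean(x[hi]); muB <- mean(x[!hi])
  sP <- max(stats::sd(x[hi]), floor); sB <- max(stats::sd(x[!hi]), floor)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    fP <- 0.5 * stats::dnorm(x, muP, sP)
    fB <- 0.5 * stats::dnorm(x, muB, sB)
    q <- fP / (fP + fB)
    ll <- sum(log(fP + fB))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    muP <- sum(q * x) / sum(q)
    sP <- max(sqrt(sum(q * (x - muP)^2) / sum(q)), floor)
    muB <- sum((1 - q) * x) / sum(1 - q)
    sB <- max(sqrt(sum((1 - q) * (x - muB)^2) / sum(1 - q)), floor)
  }
  list(mu_P = muP, sigma_P = sP, mu_B = muB, sigma_B = sB, q = q)
}
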