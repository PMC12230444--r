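#' Assign CAGE tags to miRNA upstream windows
#'
#' A tag is assigned to a miRNA when it lies within the 50 kb region
#' upstream of the precursor 5' end, in transcript orientation: for a
#' plus-strand miRNA with 5' end at `s` (1-based) the window is
#' `[s - window, s - 1]`; for a minus-strand miRNA with 5' end at `e` it is
#' `[e + 1, e + window]`. A tag may be assigned to several miRNAs.
#'
#' @param tags data.frame with `chrom`, `position` (1-based bp).
#' @param loci data.frame with `id`, `chrom`, `start`, `end` (BED
#'   convention, 0-based half-open) and `strand`.
#' @param window upstream window size in bp (default 50,000).
#' @return data.frame with `tag` (row index into `tags`), `mirna`, and
#'   `distance` (bp from the tag to the precursor 5' end).
#' @export
windowTags <- function(tags, loci, window = 50000L) {
  out <- list()
  for (i in seq_len(nrow(loci))) {
    onPlus <- loci$strand[i] != "-"
    five <- if (onPlus) loci$start[i] + 1L else loci$end[i]
    sameChrom <- tags$chrom == loci$chrom[i]
    if (onPlus) {
      hit <- which(sameChrom & tags$position >= five - window &
                     tags$position <= five - 1L)
      dist <- five - tags$position[hit]
    } else {
      hit <- which(sameChrom & tags$position >= five + 1L &
                     tags$position <= five + window)
      dist <- tags$position[hit] - five
    }
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(tag = hit,
                                            mirna = loci$id[i],
                                            distance = dist)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(tag = integer(0), mirna = character(0),
                  distance = integer(0))
}

#' Quantile-normalize a tag count matrix
#'
#' Classic across-sample quantile normalization (each column's order
#' statistics are replaced by the across-sample mean of order statistics;
#' ties receive the mean of their spanned order statistics), via
#' [limma::normalizeQuantiles]. A single-sample matrix is returned
#' unchanged with a warning.
#'
#' @param counts tags x samples numeric matrix.
#' @return normalized matrix of the same shape.
#' @export
quantileNormalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) {
    .warnf("single sample: quantile normalization is the identity")
    return(counts)
  }
  out <- limma::normalizeQuantiles(counts, ties = TRUE)
  dimnames(out) <- dimnames(counts)
  out
}

#' Label background tags from random intergenic windows
#'
#' Samples `n_loci` intergenic positions uniformly (seeded), collects the
#' tags within `+/- half_window` bp of each, and labels as background noise
#' those detected (count > 0) in fewer than `min_samples` samples.
#'
#' @param tags data.frame with `chrom`, `position`.
#' @param counts tags x samples count matrix aligned with `tags` rows.
#' @param genes `GRanges` of gene bodies defining non-intergenic space.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n_loci,half_window,min_samples see description.
#' @param seed RNG seed.
#' @return list with `background` (row indices into `tags`), `loci`
#'   (sampled positions data.frame).
#' @export
backgroundModel <- function(tags, counts, genes, chrom_lengths,
                            n_loci = 1000L, half_window = 2500L,
                            min_samples = 5L, seed = 1L) {
  counts <- as.matrix(counts)
  chroms <- names(chrom_lengths)
  withLocalSeed(seed, "background_model", {
    picks <- data.frame(chrom = character(0), position = integer(0))
    guard <- 0L
    while (nrow(picks) < n_loci) {
      guard <- guard + 1L
      if (guard > 50L * n_loci) break
      chr <- sample(chroms, 1)
      pos <- sample.int(chrom_lengths[[chr]], 1)
      g <- GenomicRanges::GRanges(chr, IRanges::IRanges(pos, pos))
      if (length(genes) == 0 ||
          GenomicRanges::countOverlaps(g, genes, ignore.strand = TRUE) == 0)
        picks <- rbind(picks, data.frame(chrom = chr, position = pos))
    }
    if (!nrow(picks)) .stopf("no intergenic space available")
    inWin <- rep(FALSE, nrow(tags))
    for (k in seq_len(nrow(picks)))
      inWin <- inWin | (tags$chrom == picks$chrom[k] &
                          abs(tags$position - picks$position[k]) <= half_window)
    detected <- rowSums(counts > 0)
    list(background = which(inWin & detected < min_samples), loci = picks)
  })
}

#' CpG ratio, TRAP TATA affinity and mean conservation of a tag window
#'
#' `cpg_ratio = (#CG dinucleotides * L) / (#C * #G)` (0 when either count is
#' zero; overlapping dinucleotide scan). TATA affinity is the TRAP expected
#' occupancy `sum_sites 1 / (1 + R0^-1 * exp(lambda * E_site))` with
#' position-specific mismatch energies
#' `E_site = sum_j log(p_max,j / p_j(base))`, `lambda = 0.7`,
#' `R0 = exp(0.584 * W - 5.66)` (W = motif width), summed over both strands.
#' Conservation is the mean of the provided per-base values.
#'
#' @param window_seq the sequence of the (nominally 1,000 bp) window centred
#'   on the tag; shorter windows at chromosome edges are accepted.
#' @param pwm position weight matrix (4 x W, rows A/C/G/T) as read by
#'   [readMemePwm()].
#' @param conservation numeric vector of per-base scores (may be `NULL`).
#' @param lambda,R0 TRAP parameters; `R0 = NULL` uses the width formula.
#' @return named numeric vector `cpg_ratio`, `tata_affinity`,
#'   `conservation`.
#' @export
computeFeatures <- function(window_seq, pwm, conservation = NULL,
                            lambda = 0.7, R0 = NULL) {
  if (is.null(pwm)) .stopf("missing PWM")
  c(cpg_ratio = cpgRatio(window_seq),
    tata_affinity = trapAffinity(window_seq, pwm, lambda, R0),
    conservation = if (is.null(conservation)) NA_real_
                   else mean(conservation))
}

#' @rdname computeFeatures
#' @export
cpgRatio <- function(window_seq) {
  s <- chartr("Uu", "Tt", toupper(window_seq))
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  nC <- sum(chars == "C")
  nG <- sum(chars == "G")
  if (nC == 0 || nG == 0 || L < 2) return(0)
  di <- paste0(chars[-L], chars[-1])
  nCG <- sum(di == "CG")
  nCG * L / (nC * nG)
}

#' @rdname computeFeatures
#' @export
trapAffinity <- function(window_seq, pwm, lambda = 0.7, R0 = NULL) {
  s <- chartr("Uu", "Tt", toupper(window_seq))
  W <- ncol(pwm)
  if (is.null(R0)) R0 <- exp(0.584 * W - 5.66)
  p <- pwm + 0.01                     # pseudocount against zero entries
  p <- sweep(p, 2, colSums(p), "/")
  emax <- apply(p, 2, max)
  Emat <- log(emax) - log(p)          # mismatch energy per base and column
  scan <- function(chars) {
    L <- length(chars)
    if (L < W) return(0)
    idx <- match(chars, c("A", "C", "G", "T"))
    tot <- 0
    for (i in seq_len(L - W + 1)) {
      cols <- idx[i:(i + W - 1)]
      if (anyNA(cols)) next
      E <- sum(Emat[cbind(cols, seq_len(W))])
      tot <- tot + 1 / (1 + exp(lambda * E) / R0)
    }
    tot
  }
  chars <- strsplit(s, "")[[1]]
  rcc <- rev(c(A = "T", C = "G", G = "C", T = "A")[chars])
  scan(chars) + scan(unname(rcc))
}

#' Read a MEME-format position weight matrix
#'
#' Minimal reader for the MEME text format: locates the first
#' `letter-probability matrix` block and returns it as a 4 x W matrix with
#' rows A, C, G, T.
#'
#' @param path MEME text file.
#' @return 4 x W numeric matrix.
#' @export
readMemePwm <- function(path) {
  lines <- readLines(path)
  hdr <- grep("letter-probability matrix", lines)
  if (!length(hdr)) .stopf("no letter-probability matrix in %s", path)
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr[1]]))
  rows <- lines[(hdr[1] + 1):(hdr[1] + w)]
  vals <- t(vapply(strsplit(trimws(rows), "\\s+"),
                   function(x) as.numeric(x[1:4]), numeric(4)))
  m <- t(vals)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

#' Logistic prior for promoter versus background tags
#'
#' Binomial GLM (logit link, IRLS via [stats::glm]) on internally
#' standardized features. Complete separation (or non-convergence) triggers
#' a ridge-penalised refit (penalty 1e-4) with a warning.
#'
#' @param features data.frame/matrix of numeric features.
#' @param labels logical or 0/1 vector (TRUE = candidate promoter).
#' @return list with `prior` (fitted probabilities), `coefficients`,
#'   `ridge` (fallback used?).
#' @export
fitGlmPrior <- function(features, labels) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) .stopf("both classes must be present")
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ Xs, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!sep && fit$converged) {
    return(list(prior = unname(fitted(fit)),
                coefficients = coef(fit), ridge = FALSE))
  }
  .warnf("separation detected: refitting with ridge penalty 1e-4")
  co <- .ridgeLogistic(cbind(1, Xs), y, penalty = 1e-4)
  eta <- as.vector(cbind(1, Xs) %*% co)
  list(prior = 1 / (1 + exp(-eta)),
       coefficients = setNames(co, c("(Intercept)", colnames(Xs))),
       ridge = TRUE)
}

# IRLS with an L2 penalty (intercept unpenalized)
.ridgeLogistic <- function(X, y, penalty = 1e-4, max_iter = 200L,
                           tol = 1e-10) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(penalty, p - 1)), p)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    wts <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / wts
    H <- crossprod(X, X * wts) + pen
    bnew <- solve(H, crossprod(X, wts * z))
    if (max(abs(bnew - beta)) < tol) { beta <- as.vector(bnew); break }
    beta <- as.vector(bnew)
  }
  beta
}

#' Semi-supervised two-component Gaussian EM on log tag abundance
#'
#' E-step: `q_i = p_i N(x_i; mu_P, s_P) / (p_i N(x_i; mu_P, s_P) +
#' (1 - p_i) N(x_i; mu_B, s_B))`, with the per-tag GLM priors `p_i` held
#' fixed. M-step: posterior-weighted means and standard deviations per
#' component (sds floored at 1e-3). Initialisation uses prior-weighted
#' moments; when the priors are uninformative (components start closer than
#' 1e-6), the upper/lower halves of `x` seed the two components instead.
#' Iteration stops when the observed-data log-likelihood changes by less
#' than `tol`.
#'
#' @param x numeric vector of log10(normalized count + 1) tag abundances.
#' @param priors per-tag promoter priors in `[0,1]`.
#' @param tol,max_iter convergence controls.
#' @param sigma_floor lower bound for both sds.
#' @return a [MixtureFit-class] object.
#' @export
emMixture <- function(x, priors, tol = 1e-6, max_iter = 500L,
                      sigma_floor = 1e-3) {
  n <- length(x)
  if (n < 10) .stopf("need at least 10 observations")
  if (any(priors < 0 | priors > 1)) .stopf("priors must lie in [0,1]")
  if (all(priors == 0) || all(priors == 1)) {
    .warnf("degenerate priors: single-component fit")
    q <- priors
    m <- mean(x); s <- max(sd(x), sigma_floor)
    return(new("MixtureFit", mu_P = m, sigma_P = s, mu_B = m, sigma_B = s,
               prior = priors, posterior = q,
               loglik = sum(dnorm(x, m, s, log = TRUE)), n_iter = 0L,
               converged = TRUE))
  }
  wP <- sum(priors); wB <- n - wP
  muP <- sum(priors * x) / wP
  muB <- sum((1 - priors) * x) / wB
  if (abs(muP - muB) < 1e-6) {
    hi <- x >= stats::median(x)
    muP <- mean(x[hi]); muB <- mean(x[!hi])
  }
  sP <- max(sqrt(sum(priors * (x - muP)^2) / wP), sigma_floor)
  sB <- max(sqrt(sum((1 - priors) * (x - muB)^2) / wB), sigma_floor)
  if (!is.finite(sP) || sP == 0) sP <- max(sd(x), sigma_floor)
  if (!is.finite(sB) || sB == 0) sB <- max(sd(x), sigma_floor)
  ll <- numeric(0)
  q <- numeric(n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fP <- priors * dnorm(x, muP, sP)
    fB <- (1 - priors) * dnorm(x, muB, sB)
    tot <- fP + fB
    tot[tot == 0] <- .Machine$double.xmin
    q <- fP / tot
    ll <- c(ll, sum(log(tot)))
    if (it > 1 && abs(ll[it] - ll[it - 1]) < tol) { converged <- TRUE; break }
    wP <- sum(q); wB <- sum(1 - q)
    if (wP > 0) {
      muP <- sum(q * x) / wP
      sP <- max(sqrt(sum(q * (x - muP)^2) / wP), sigma_floor)
    }
    if (wB > 0) {
      muB <- sum((1 - q) * x) / wB
      sB <- max(sqrt(sum((1 - q) * (x - muB)^2) / wB), sigma_floor)
    }
  }
  new("MixtureFit", mu_P = muP, sigma_P = sP, mu_B = muB, sigma_B = sB,
      prior = priors, posterior = q, loglik = ll,
      n_iter = length(ll), converged = converged)
}

#' Call high-confidence promoters per miRNA
#'
#' Retains tags with posterior strictly greater than 0.5, computes each
#' tag's density (normalized counts summed over a `+/- density_halfwidth`
#' bp neighbourhood), and selects per miRNA the retained tag of maximal
#' density (ties broken by proximity to the miRNA 5' end). miRNAs whose
#' precursors lie within `cluster_gap` bp on the same strand form a cluster
#' and share the promoter of the best member.
#'
#' @param assignments data.frame from [windowTags()].
#' @param posterior per-tag posterior probabilities.
#' @param tag_abundance per-tag normalized abundance (summed across
#'   samples).
#' @param tags data.frame with `chrom`, `position`.
#' @param loci miRNA loci data.frame (`id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param density_halfwidth neighbourhood half-width in bp (default 50).
#' @param cluster_gap maximum same-strand inter-precursor gap for promoter
#'   sharing (default 10 kb).
#' @return data.frame with `mirna`, `tag`, `posterior`, `density`; miRNAs
#'   without a retained tag are reported in attribute `no_call`.
#' @export
callPromoters <- function(assignments, posterior, tag_abundance, tags, loci,
                          density_halfwidth = 50L, cluster_gap = 10000L) {
  dens <- vapply(seq_len(nrow(tags)), function(i) {
    hit <- tags$chrom == tags$chrom[i] &
      abs(tags$position - tags$position[i]) <= density_halfwidth
    sum(tag_abundance[hit])
  }, numeric(1))
  calls <- list()
  no_call <- character(0)
  for (id in unique(loci$id)) {
    a <- assignments[assignments$mirna == id, , drop = FALSE]
    a <- a[posterior[a$tag] > 0.5, , drop = FALSE]
    if (!nrow(a)) { no_call <- c(no_call, id); next }
    d <- dens[a$tag]
    best <- which(d == max(d))
    if (length(best) > 1) best <- best[which.min(a$distance[best])]
    calls[[id]] <- data.frame(mirna = id, tag = a$tag[best],
                              posterior = posterior[a$tag[best]],
                              density = d[best])
  }
  out <- if (length(calls)) do.call(rbind, calls)
         else data.frame(mirna = character(0), tag = integer(0),
                         posterior = numeric(0), density = numeric(0))
  # clustered miRNAs (same strand, gap <= cluster_gap) share one promoter
  if (nrow(loci) > 1 && nrow(out)) {
    ord <- order(loci$chrom, loci$start)
    lo <- loci[ord, ]
    cluster <- cumsum(c(1, !(lo$chrom[-1] == lo$chrom[-nrow(lo)] &
                               lo$strand[-1] == lo$strand[-nrow(lo)] &
                               lo$start[-1] - lo$end[-nrow(lo)] <= cluster_gap)))
    for (cl in unique(cluster)) {
      members <- lo$id[cluster == cl]
      have <- out[out$mirna %in% members, , drop = FALSE]
      if (!nrow(have) || length(members) < 2) next
      lead <- have[which.max(have$density), ]
      for (m in setdiff(members, have$mirna)) {
        out <- rbind(out, data.frame(mirna = m, tag = lead$tag,
                                     posterior = lead$posterior,
                                     density = lead$density))
        no_call <- setdiff(no_call, m)
      }
    }
  }
  rownames(out) <- NULL
  attr(out, "no_call") <- no_call
  out
}
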