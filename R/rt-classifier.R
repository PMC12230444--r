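#' Embed miRNA sequences as fixed-length feature vectors
#'
#' The built-in embedder concatenates normalized k-mer frequencies for
#' k = 1..4 (4 + 16 + 64 + 256 = 340 dimensions); optionally, hairpin
#' scalar features (MFE, MFE frequency, ensemble diversity, matched and
#' loop nucleotide counts, overhang lengths) are appended. External
#' embeddings (e.g. column-averaged transformer hidden states) are loaded
#' from a TSV whose first column is the id followed by a fixed number of
#' numeric columns.
#'
#' @param sequences named character vector of RNA sequences (ignored for
#'   `embedder = "external"` except to check ids).
#' @param embedder `"kmer"` or `"external"`.
#' @param kmax largest k for the built-in k-mer embedder.
#' @param structure append hairpin structure scalars (built-in only)?
#' @param par energy parameters for the structure scalars.
#' @param file TSV path for external embeddings.
#' @return numeric matrix, one row per sequence, rownames = ids.
#' @export
embedSequences <- function(sequences, embedder = c("kmer", "external"),
                           kmax = 4L, structure = FALSE,
                           par = defaultEnergyParams(), file = NULL) {
  embedder <- match.arg(embedder)
  if (embedder == "external") {
    if (is.null(file)) .stopf("external embedder needs a file")
    x <- read.table(file, header = TRUE, sep = "\t", row.names = 1)
    X <- as.matrix(x)
    if (any(!is.finite(X))) .stopf("non-finite values in external embedding")
    dims <- ncol(X)
    if (!is.null(names(sequences))) {
      miss <- setdiff(names(sequences), rownames(X))
      if (length(miss))
        .stopf("external embedding missing ids: %s",
               paste(head(miss, 3), collapse = ","))
      X <- X[names(sequences), , drop = FALSE]
    }
    if (length(unique(apply(X, 1, length))) != 1 || dims < 1)
      .stopf("dimension mismatch in external embedding file")
    return(X)
  }
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  alpha <- c("A", "C", "G", "U")
  kmerNames <- unlist(lapply(seq_len(kmax), function(k) {
    apply(expand.grid(rep(list(alpha), k))[, k:1, drop = FALSE], 1, paste,
          collapse = "")
  }))
  emb <- t(vapply(sequences, function(s) {
    chars <- alpha[.encodeSeq(s) + 1L]
    unlist(lapply(seq_len(kmax), function(k) {
      L <- length(chars)
      nm <- apply(expand.grid(rep(list(alpha), k))[, k:1, drop = FALSE], 1,
                  paste, collapse = "")
      if (L < k) return(setNames(rep(0, length(nm)), nm))
      km <- vapply(seq_len(L - k + 1),
                   function(i) paste(chars[i:(i + k - 1)], collapse = ""), "")
      tab <- table(factor(km, levels = nm))
      as.numeric(tab) / (L - k + 1)
    }))
  }, numeric(sum(4^seq_len(kmax)))))
  colnames(emb) <- kmerNames
  rownames(emb) <- ids
  if (structure) {
    sc <- t(vapply(sequences, function(s) {
      em <- ensembleMetrics(s, par)
      d <- decomposeStructure(em$structure)
      c(dG = em$dG, mfe_freq = em$mfe_freq, diversity = em$diversity,
        n_match_nt = d$n_match_nt, n_loop_nt = d$n_loop_nt,
        len5 = d$len_5p_overhang, len3 = d$len_3p_overhang)
    }, numeric(7)))
    emb <- cbind(emb, sc)
  }
  emb
}

#' Classifier configuration: RBF-SVM hyperparameter grids
#'
#' @param C,gamma grids for the exhaustive search.
#' @param folds cross-validation folds.
#' @param test_fraction held-out fraction of the data.
#' @param seed RNG seed for the stratified split and folds.
#' @return a named list.
#' @export
rtClassifierConfig <- function(C = c(0.1, 1, 10, 100, 1000),
                               gamma = c(1, 0.1, 0.01, 0.001, 0.0001),
                               folds = 5L, test_fraction = 0.2, seed = 1L) {
  stopifnot(length(C) > 0, length(gamma) > 0)
  list(C = C, gamma = gamma, folds = as.integer(folds),
       test_fraction = test_fraction, seed = as.integer(seed))
}

#' Train the replication-timing SVM
#'
#' Stratified 80/20 split (seeded), exhaustive grid search over C x gamma
#' maximizing cross-validated accuracy (stratified folds), then a refit of
#' the best combination on the full training set with probability outputs
#' and balanced class weights.
#'
#' @param X embedding matrix.
#' @param y class labels (`early`/`late`; factor or character).
#' @param config list from [rtClassifierConfig()].
#' @return list with `model` (an [e1071::svm] fit), `cv_table`
#'   (C, gamma, cv_accuracy; one row per grid point), `best`, `train_idx`,
#'   `test_idx`.
#' @export
trainRtClassifier <- function(X, y, config = rtClassifierConfig()) {
  y <- factor(as.character(y), levels = c("early", "late"))
  if (nlevels(droplevels(y)) < 2) .stopf("both classes must be present")
  n <- nrow(X)
  withLocalSeed(config$seed, "svm_split", {
    test_idx <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      sample(idx, max(1, round(length(idx) * config$test_fraction)))
    }))
    train_idx <- setdiff(seq_len(n), test_idx)
    ytr <- droplevels(y[train_idx])
    Xtr <- X[train_idx, , drop = FALSE]
    folds <- integer(length(train_idx))
    for (lv in levels(ytr)) {
      idx <- which(ytr == lv)
      folds[idx] <- sample(rep(seq_len(config$folds), length.out = length(idx)))
    }
    cw <- length(ytr) / (nlevels(ytr) * table(ytr))
    grid <- expand.grid(C = config$C, gamma = config$gamma)
    grid$cv_accuracy <- vapply(seq_len(nrow(grid)), function(g) {
      acc <- vapply(seq_len(config$folds), function(f) {
        tr <- folds != f
        if (nlevels(droplevels(ytr[tr])) < 2) return(NA_real_)
        fit <- suppressWarnings(
          e1071::svm(Xtr[tr, , drop = FALSE], ytr[tr],
                     kernel = "radial", cost = grid$C[g],
                     gamma = grid$gamma[g], class.weights = cw))
        mean(predict(fit, Xtr[!tr, , drop = FALSE]) == ytr[!tr])
      }, numeric(1))
      mean(acc, na.rm = TRUE)
    }, numeric(1))
    best <- grid[which.max(grid$cv_accuracy), ]
    model <- suppressWarnings(
      e1071::svm(Xtr, ytr, kernel = "radial", cost = best$C,
                 gamma = best$gamma, class.weights = cw,
                 probability = TRUE))
    list(model = model, cv_table = grid, best = best,
         train_idx = train_idx, test_idx = test_idx)
  })
}

#' ROC curve and AUC from scores
#'
#' Standard ROC construction over score thresholds (ties grouped), AUC by
#' trapezoidal integration.
#'
#' @param scores numeric scores, larger = more likely positive.
#' @param labels logical or 0/1 positives.
#' @return list with `roc` (data.frame fpr/tpr) and `auc`.
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.logical(labels > 0 | labels == TRUE)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) .stopf("AUC undefined: single-class labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(l, grp, sum)
  fp <- tapply(!l, grp, sum)
  tpr <- c(0, cumsum(tp) / n1)
  fpr <- c(0, cumsum(fp) / n0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate the replication-timing classifier
#'
#' Late-propensity scores are the predicted probabilities of the late
#' class; reports the ROC curve and AUC on the held-out set and a
#' two-sided Mann-Whitney comparison of scores between the true classes.
#'
#' @param model fitted SVM from [trainRtClassifier()].
#' @param X test embedding matrix.
#' @param y true test labels.
#' @return list with `auc`, `accuracy`, `roc`, `scores` (late propensity),
#'   `mwu` (list with U and p.value).
#' @export
evaluateRtClassifier <- function(model, X, y) {
  y <- factor(as.character(y), levels = c("early", "late"))
  if (nlevels(droplevels(y)) < 2) .stopf("AUC undefined: single-class test set")
  pred <- predict(model, X, probability = TRUE)
  pr <- attr(pred, "probabilities")
  scores <- pr[, "late"]
  rc <- rocCurve(scores, y == "late")
  mw <- suppressWarnings(wilcox.test(scores[y == "late"],
                                     scores[y == "early"],
                                     exact = FALSE, correct = FALSE))
  list(auc = rc$auc, accuracy = mean(pred == y), roc = rc$roc,
       scores = scores,
       mwu = list(U = unname(mw$statistic), p.value = mw$p.value))
}
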