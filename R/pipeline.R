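.PIPELINE_DEFAULTS <- list(
  seed = 1L,
  outdir = "repliMir-out",
  stages = c("generate", "domains", "structure", "context", "motifs",
             "cage", "network", "expression", "classify"),
  n_windows = 500L, n_samples = 2L,
  n_mirnas_early = 60L, n_mirnas_late = 40L,
  at_bias = 0.10, stem_extension = 4L, gc_bump = 0.08,
  cage_n_tags = 2000L, cage_promoter_frac = 0.1,
  net_n_targets = 600L, net_n_edges = 3000L, net_rho_late = 0.3,
  expr_n_tissues = 7L,
  rpm_cutoff = 1,
  min_identity = 60,
  upstream_window = 50000L,
  posterior_boundary = 0.5,
  n_swaps = 100000L, n_networks = 100L,
  svm_C = c(0.1, 1, 10, 100, 1000),
  svm_gamma = c(1, 0.1, 0.01, 0.001, 0.0001),
  cv_folds = 5L, test_fraction = 0.2)

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, and rejects unknown
#' keys. The numeric defaults are the study settings: 50 kb upstream CAGE
#' windows, 1 rpm expression cutoff, 60% orthologue identity, 100,000
#' attempted swaps and 100 null networks, a 0.5 posterior decision
#' boundary, and the 5x5 SVM grid with 5-fold cross-validation.
#'
#' @param config path to a YAML file, or a named list.
#' @return the effective configuration list (class `repliMirConfig`).
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  unknown <- setdiff(names(config), names(.PIPELINE_DEFAULTS))
  if (length(unknown))
    .stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  out <- .PIPELINE_DEFAULTS
  out[names(config)] <- config
  bad <- setdiff(out$stages, .PIPELINE_DEFAULTS$stages)
  if (length(bad)) .stopf("unknown stages: %s", paste(bad, collapse = ", "))
  structure(out, class = "repliMirConfig")
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic data with
#' known ground truth: track generation and domain calling, hairpin
#' structure statistics, flank GC context, Dicer motif clustering, CAGE
#' promoter calling, network null-model Z-scores, expression proportions
#' and the replication-timing classifier. Each stage writes TSV/JSON
#' outputs into `config$outdir`; a manifest records the enabled stages,
#' seeds, output files and their checksums.
#'
#' @param config a validated configuration (see [validateConfig()]).
#' @return the manifest (invisibly also written to `manifest.json`).
#' @export
runPipeline <- function(config = validateConfig()) {
  if (!inherits(config, "repliMirConfig")) config <- validateConfig(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(x, name, row_names = FALSE) {
    p <- file.path(config$outdir, name)
    writeTsv(x, p, row_names = row_names)
    outputs <<- c(outputs, p)
    p
  }
  sc <- syntheticConfig(seed = config$seed, n_windows = config$n_windows,
                        n_samples = config$n_samples,
                        n_mirnas_early = config$n_mirnas_early,
                        n_mirnas_late = config$n_mirnas_late,
                        at_bias = config$at_bias,
                        stem_extension = config$stem_extension,
                        gc_bump = config$gc_bump,
                        cage_n_tags = config$cage_n_tags,
                        cage_promoter_frac = config$cage_promoter_frac,
                        net_n_targets = config$net_n_targets,
                        net_n_edges = config$net_n_edges,
                        net_rho_late = config$net_rho_late,
                        expr_n_tissues = config$expr_n_tissues)
  st <- list()
  has <- function(s) s %in% config$stages
  if (has("generate")) {
    st$track <- genReplicationTrack(sc)
    st$early <- genHairpinSet(sc, "early")
    st$late <- genHairpinSet(sc, "late")
    st$cage <- genCage(sc)
    classes <- setNames(c(st$early$class, st$late$class),
                        c(st$early$id, st$late$id))
    st$classes <- classes
    st$net <- genNetwork(sc, classes)
    st$expr <- genExpression(sc, classes)
    emit(data.frame(id = names(classes), class = classes),
         "truth_classes.tsv")
  } else .stopf("this pipeline runs on generated data; enable 'generate'")

  if (has("domains")) {
    norm <- apply(st$track$ratios, 2, normalizeRatioTrack)
    calls <- apply(norm, 2, callDomains)
    acc <- mean(calls == st$track$truth)
    emit(data.frame(window = seq_len(nrow(calls)), truth = st$track$truth,
                    calls), "domain_calls.tsv")
    st$domain_accuracy <- acc
  }
  hp <- list(id = c(st$early$id, st$late$id),
             sequence = c(st$early$sequence, st$late$sequence),
             class = c(st$early$class, st$late$class))
  if (has("structure")) {
    feats <- t(vapply(hp$sequence, function(s) {
      em <- ensembleMetrics(s)
      d <- decomposeStructure(em$structure)
      c(dG = em$dG, mfe_freq = em$mfe_freq, diversity = em$diversity,
        n_match_nt = d$n_match_nt, len5 = d$len_5p_overhang)
    }, numeric(5)))
    tab <- data.frame(id = hp$id, class = hp$class, feats)
    emit(tab, "hairpin_features.tsv")
    cmp <- groupCompare(tab$n_match_nt[tab$class == "late"],
                        tab$n_match_nt[tab$class == "early"])
    emit(data.frame(metric = "n_match_nt", U = cmp$statistic,
                    p = cmp$p.value), "structure_tests.tsv")
  }
  if (has("context")) {
    prof_e <- gcProfile(substring(st$early$sequence, 1, 20))
    prof_l <- gcProfile(substring(st$late$sequence, 1, 20))
    flank_l <- gcProfile(substring(st$late$flank5, 1, 200))
    tt <- profileTtest(flank_l, prof_l)
    emit(data.frame(site = seq_along(prof_e), gc_early = prof_e,
                    gc_late = prof_l), "gc_profiles.tsv")
    emit(data.frame(comparison = "late_flank_vs_precursor",
                    t = unname(tt$statistic), p = tt$p.value),
         "context_tests.tsv")
  }
  if (has("motifs")) {
    seqs <- setNames(hp$sequence, hp$id)
    arms <- rbind(st$early$arms, st$late$arms)
    mot <- extractMotif(seqs, arms, "5p")
    mot$class <- st$classes[mot$id]
    emit(mot, "motifs_5p.tsv")
    ok <- table(mot$class)
    if (length(ok) == 2 && all(ok >= 5)) {
      pc <- positionChisq(mot$motif[mot$class == "early"],
                          mot$motif[mot$class == "late"])
      emit(pc, "motif_position_tests.tsv")
      D <- motifDistanceMatrix(mot$motif, mot$id)
      emb <- mds2d(D, seed = config$seed)
      emit(data.frame(motif = rownames(D), emb$points), "motif_mds.tsv")
    }
  }
  if (has("cage")) {
    qn <- quantileNormalize(st$cage$counts)
    xab <- log10(rowSums(qn) + 1)
    gl <- fitGlmPrior(st$cage$features,
                      st$cage$truth == "promoter")
    fit <- emMixture(xab, gl$prior)
    emit(data.frame(tag = seq_along(xab), abundance = xab,
                    prior = gl$prior, posterior = posteriorProb(fit),
                    truth = st$cage$truth), "cage_posteriors.tsv")
    st$cage_fit <- fit
  }
  if (has("network")) {
    obs <- targetCategoryCounts(st$net$network)
    sims <- simulateNull(st$net$network, targetCategoryCounts,
                         n_networks = min(config$n_networks, 50L),
                         n_swaps = min(config$n_swaps, 20000L),
                         seed = config$seed)
    zrows <- lapply(names(obs), function(nm) {
      zt <- zTest(obs[[nm]], sims[, nm])
      data.frame(category = nm, observed = zt$observed,
                 sim_mean = zt$sim_mean, sim_sd = zt$sim_sd, z = zt$z,
                 p = zt$p)
    })
    emit(do.call(rbind, zrows), "network_zscores.tsv")
  }
  if (has("expression")) {
    tl <- averageReplicates(st$expr$rpm, st$expr$replicate_map)
    fr <- expressedFraction(tl, st$classes[rownames(tl)],
                            cutoff = config$rpm_cutoff)
    emit(data.frame(tissue = rownames(fr), fr), "expressed_fraction.tsv")
  }
  if (has("classify")) {
    X <- embedSequences(setNames(hp$sequence, hp$id))
    y <- hp$class
    tr <- trainRtClassifier(X, y,
                            rtClassifierConfig(C = config$svm_C,
                                               gamma = config$svm_gamma,
                                               folds = config$cv_folds,
                                               test_fraction = config$test_fraction,
                                               seed = config$seed))
    ev <- evaluateRtClassifier(tr$model, X[tr$test_idx, , drop = FALSE],
                               y[tr$test_idx])
    emit(tr$cv_table, "svm_cv_table.tsv")
    emit(data.frame(auc = ev$auc, accuracy = ev$accuracy), "svm_eval.tsv")
  }
  manifest <- list(
    stages = as.list(config$stages),
    seed = config$seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
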