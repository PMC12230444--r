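#' Synthetic study configuration
#'
#' Parameters of the synthetic-data generators. The defaults are the study
#' conditions emulated throughout the package: two replication-timing
#' samples over a blocky two-domain chromosome, 631 early / 362 late
#' hairpins with an A/U compositional bias and stem extension in the late
#' class, a two-component CAGE tag abundance mixture separated by four
#' standard deviations, a 36,505-edge bipartite regulatory network over
#' 7,411 targets, and seven expression tissues.
#'
#' @slot seed integer RNG seed.
#' @slot n_windows,n_samples replication track dimensions.
#' @slot domain_mean_gap separation of the early/late S/G1 ratio means.
#' @slot domain_noise_sd per-window ratio noise sd.
#' @slot n_mirnas_early,n_mirnas_late hairpin counts per class.
#' @slot at_bias added A/U probability in late-class hairpins.
#' @slot stem_extension extra stem length (bp) for the late class.
#' @slot gc_bump GC-fraction increment inside late precursors relative to
#'   their flanks.
#' @slot flank_gc background flank GC fraction.
#' @slot cage_n_tags,cage_promoter_frac,cage_mu_P,cage_mu_B,cage_sigma_P,cage_sigma_B
#'   CAGE mixture parameters (log10 count units).
#' @slot net_n_targets,net_n_edges,net_rho_late network size and late-late
#'   co-targeting propensity in `[0,1]`.
#' @slot expr_n_tissues,expr_base,expr_effect expression matrix dimensions
#'   and the class effect on the expressed fraction.
#' @export
setClass("SyntheticConfig",
  representation(
    seed = "integer", n_windows = "integer", n_samples = "integer",
    domain_mean_gap = "numeric", domain_noise_sd = "numeric",
    n_mirnas_early = "integer", n_mirnas_late = "integer",
    at_bias = "numeric", stem_extension = "integer", gc_bump = "numeric",
    flank_gc = "numeric",
    cage_n_tags = "integer", cage_promoter_frac = "numeric",
    cage_mu_P = "numeric", cage_mu_B = "numeric",
    cage_sigma_P = "numeric", cage_sigma_B = "numeric",
    net_n_targets = "integer", net_n_edges = "integer",
    net_rho_late = "numeric",
    expr_n_tissues = "integer", expr_base = "numeric", expr_effect = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msg <- character(0)
  counts <- c(n_windows = object@n_windows, n_samples = object@n_samples,
              n_mirnas_early = object@n_mirnas_early,
              n_mirnas_late = object@n_mirnas_late,
              cage_n_tags = object@cage_n_tags,
              net_n_targets = object@net_n_targets,
              net_n_edges = object@net_n_edges,
              expr_n_tissues = object@expr_n_tissues)
  if (any(counts <= 0))
    msg <- c(msg, paste("non-positive count:",
                        paste(names(counts)[counts <= 0], collapse = ",")))
  probs <- c(at_bias = object@at_bias, gc_bump = object@gc_bump,
             flank_gc = object@flank_gc,
             cage_promoter_frac = object@cage_promoter_frac,
             net_rho_late = object@net_rho_late,
             expr_base = object@expr_base, expr_effect = object@expr_effect)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, paste("probability out of [0,1]:",
                        paste(names(probs)[probs < 0 | probs > 1], collapse = ",")))
  if (object@domain_mean_gap <= 0) msg <- c(msg, "domain_mean_gap must be > 0")
  if (object@domain_noise_sd <= 0) msg <- c(msg, "domain_noise_sd must be > 0")
  if (object@cage_sigma_P <= 0 || object@cage_sigma_B <= 0)
    msg <- c(msg, "cage sigmas must be > 0")
  if (object@cage_mu_P <= object@cage_mu_B)
    msg <- c(msg, "cage_mu_P must exceed cage_mu_B")
  if (0.25 + object@at_bias / 2 >= 1 || 0.25 - object@at_bias / 2 <= 0)
    msg <- c(msg, "at_bias leaves a base probability outside (0,1)")
  if (object@stem_extension < 0) msg <- c(msg, "stem_extension must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticConfig constructor with study-condition defaults.
#' @param seed,n_windows,n_samples,domain_mean_gap,domain_noise_sd see slots.
#' @param n_mirnas_early,n_mirnas_late,at_bias,stem_extension,gc_bump,flank_gc
#'   see slots.
#' @param cage_n_tags,cage_promoter_frac,cage_mu_P,cage_mu_B see slots.
#' @param cage_sigma_P,cage_sigma_B,net_n_targets,net_n_edges,net_rho_late
#'   see slots.
#' @param expr_n_tissues,expr_base,expr_effect see slots.
#' @export
syntheticConfig <- function(seed = 1L, n_windows = 2000L, n_samples = 2L,
                            domain_mean_gap = 1.5, domain_noise_sd = 0.5,
                            n_mirnas_early = 631L, n_mirnas_late = 362L,
                            at_bias = 0.10, stem_extension = 4L,
                            gc_bump = 0.08, flank_gc = 0.42,
                            cage_n_tags = 5000L, cage_promoter_frac = 0.1,
                            cage_mu_P = 2.5, cage_mu_B = 0.5,
                            cage_sigma_P = 0.5, cage_sigma_B = 0.5,
                            net_n_targets = 7411L, net_n_edges = 36505L,
                            net_rho_late = 0.3,
                            expr_n_tissues = 7L, expr_base = 0.55,
                            expr_effect = 0.15) {
  new("SyntheticConfig", seed = as.integer(seed),
      n_windows = as.integer(n_windows), n_samples = as.integer(n_samples),
      domain_mean_gap = domain_mean_gap, domain_noise_sd = domain_noise_sd,
      n_mirnas_early = as.integer(n_mirnas_early),
      n_mirnas_late = as.integer(n_mirnas_late),
      at_bias = at_bias, stem_extension = as.integer(stem_extension),
      gc_bump = gc_bump, flank_gc = flank_gc,
      cage_n_tags = as.integer(cage_n_tags),
      cage_promoter_frac = cage_promoter_frac,
      cage_mu_P = cage_mu_P, cage_mu_B = cage_mu_B,
      cage_sigma_P = cage_sigma_P, cage_sigma_B = cage_sigma_B,
      net_n_targets = as.integer(net_n_targets),
      net_n_edges = as.integer(net_n_edges), net_rho_late = net_rho_late,
      expr_n_tissues = as.integer(expr_n_tissues), expr_base = expr_base,
      expr_effect = expr_effect)
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig (seed", object@seed, ")\n")
  cat("  replication:", object@n_windows, "windows x", object@n_samples,
      "samples, gap", object@domain_mean_gap, "sd", object@domain_noise_sd, "\n")
  cat("  hairpins:", object@n_mirnas_early, "early /", object@n_mirnas_late,
      "late, at_bias", object@at_bias, "\n")
  cat("  network:", object@net_n_edges, "edges,", object@net_n_targets,
      "targets, rho_late", object@net_rho_late, "\n")
})

#' Semi-supervised two-component Gaussian mixture fit
#'
#' Result of [emMixture()]: component means/sds on the log tag-abundance
#' scale, the per-tag priors and posteriors, and the log-likelihood trace.
#'
#' @slot mu_P,sigma_P,mu_B,sigma_B component parameters (log-count units).
#' @slot prior,posterior per-tag promoter prior and posterior probabilities.
#' @slot loglik log-likelihood trace across EM iterations.
#' @slot n_iter number of iterations run.
#' @slot converged logical.
#' @export
setClass("MixtureFit",
  representation(mu_P = "numeric", sigma_P = "numeric", mu_B = "numeric",
                 sigma_B = "numeric", prior = "numeric",
                 posterior = "numeric", loglik = "numeric",
                 n_iter = "integer", converged = "logical"))

setValidity("MixtureFit", function(object) {
  msg <- character(0)
  if (object@sigma_P <= 0 || object@sigma_B <= 0)
    msg <- c(msg, "component sds must stay above the floor")
  if (any(object@posterior < 0 | object@posterior > 1))
    msg <- c(msg, "posteriors must lie in [0,1]")
  if (length(object@loglik) > 1 &&
      any(diff(object@loglik) < -1e-8))
    msg <- c(msg, "log-likelihood must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn MixtureFit posterior promoter probabilities.
#' @param object a `MixtureFit`.
#' @export
posteriorProb <- function(object) object@posterior

#' @describeIn MixtureFit log-likelihood trace.
#' @export
logLikTrace <- function(object) object@loglik

#' @describeIn MixtureFit component parameters as a named vector.
#' @export
mixtureParams <- function(object)
  c(mu_P = object@mu_P, sigma_P = object@sigma_P,
    mu_B = object@mu_B, sigma_B = object@sigma_B)

setMethod("show", "MixtureFit", function(object) {
  cat("MixtureFit:", length(object@posterior), "tags,",
      object@n_iter, "iterations",
      if (object@converged) "(converged)" else "(max_iter reached)", "\n")
  cat(sprintf("  promoter  N(%.3f, %.3f)\n", object@mu_P, object@sigma_P))
  cat(sprintf("  background N(%.3f, %.3f)\n", object@mu_B, object@sigma_B))
})

#' Bipartite miRNA-target regulatory network
#'
#' Unique miRNA-to-target edges with the replication-timing class of each
#' miRNA (`early`/`late`) and, optionally, the replication domain of each
#' target (`early`/`late`/`unknown`).
#'
#' @slot edges data.frame with character columns `mirna`, `target`.
#' @slot mirnaClass named character vector, one of `early`/`late` per miRNA.
#' @slot targetDomain named character vector per target
#'   (`early`/`late`/`unknown`).
#' @export
setClass("MirnaNetwork",
  representation(edges = "data.frame", mirnaClass = "character",
                 targetDomain = "character"))

setValidity("MirnaNetwork", function(object) {
  msg <- character(0)
  e <- object@edges
  if (!all(c("mirna", "target") %in% names(e)))
    msg <- c(msg, "edges needs columns mirna, target")
  else if (anyDuplicated(paste(e$mirna, e$target, sep = "\r")))
    msg <- c(msg, "duplicate edges")
  if (length(object@mirnaClass) &&
      !all(object@mirnaClass %in% c("early", "late")))
    msg <- c(msg, "mirnaClass values must be early/late")
  if (length(object@targetDomain) &&
      !all(object@targetDomain %in% c("early", "late", "unknown")))
    msg <- c(msg, "targetDomain values must be early/late/unknown")
  if (length(msg)) msg else TRUE
})

#' @describeIn MirnaNetwork constructor; targets without a domain entry are
#'   recorded as `unknown`.
#' @param edges data.frame with columns `mirna`, `target`.
#' @param mirnaClass named character vector of miRNA classes.
#' @param targetDomain optional named character vector of target domains.
#' @export
mirnaNetwork <- function(edges, mirnaClass, targetDomain = NULL) {
  edges$mirna <- as.character(edges$mirna)
  edges$target <- as.character(edges$target)
  tars <- unique(edges$target)
  dom <- setNames(rep("unknown", length(tars)), tars)
  if (!is.null(targetDomain)) {
    hit <- intersect(names(targetDomain), tars)
    dom[hit] <- targetDomain[hit]
  }
  new("MirnaNetwork", edges = edges[, c("mirna", "target")],
      mirnaClass = mirnaClass, targetDomain = dom)
}

#' @describeIn MirnaNetwork edge table.
#' @param object a `MirnaNetwork`.
#' @export
networkEdges <- function(object) object@edges

#' @describeIn MirnaNetwork miRNA class map.
#' @export
regulatorClass <- function(object) object@mirnaClass

#' @describeIn MirnaNetwork target domain map.
#' @export
targetDomain <- function(object) object@targetDomain

setMethod("show", "MirnaNetwork", function(object) {
  cat("MirnaNetwork:", nrow(object@edges), "edges,",
      length(unique(object@edges$mirna)), "miRNAs,",
      length(unique(object@edges$target)), "targets\n")
  cat("  miRNA classes:", sum(object@mirnaClass == "early"), "early /",
      sum(object@mirnaClass == "late"), "late\n")
})
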