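#' Fit single- and two-topology models to paired cytoplasmic alignments
#'
#' Tests whether the endosymbiont and mtDNA genomes share one genealogy.
#' The two-topology model infers an independent neighbor-joining topology
#' with maximum-likelihood HKY+Gamma branch lengths for each genome; the
#' single-topology model infers one topology from the concatenated data,
#' shares its branch lengths across both genomes, and gives the second
#' partition a free rate multiplier. Model fits are compared by AIC (and by
#' a log10 Bayes factor when harmonic-mean marginal likelihoods are
#' supplied to [model_comparison()]).
#'
#' Parameter counts: each partition contributes kappa, Gamma shape, and
#' three free base frequencies (5); the two-topology model has two
#' independent sets of `2n - 3` branch lengths, the single-topology model
#' one set plus one free rate multiplier.
#'
#' @param wol_aln,mt_aln [partitioned_alignment]s over the same strain set
#'   (the infected strains).
#' @param ncat Discrete-Gamma categories.
#' @param outer_iters,branch_sweeps Optimisation effort per fit.
#' @return List with elements `single` and `two`, each containing `lnL`,
#'   `k`, `AIC`, and the fitted trees/models, plus `delta_aic`
#'   (`AIC_two - AIC_single`; positive favours the single topology).
#' @export
fit_topology_models <- function(wol_aln, mt_aln, ncat = 4L,
                                outer_iters = 2, branch_sweeps = 2) {
  if (!setequal(rownames(wol_aln$mat), rownames(mt_aln$mat)))
    stop("the two alignments must contain the same strains")
  strains <- rownames(mt_aln$mat)
  wol <- collapse_classes(subset_alignment(wol_aln, strains), "wol")
  mt <- collapse_classes(subset_alignment(mt_aln, strains), "mt")
  n <- length(strains)
  if (n < 4) stop("congruence test requires at least 4 shared strains")

  fit_one <- function(aln) {
    tr <- neighbor_joining(pairwise_distances(aln, "JC"))
    fit_partition_models(tr, aln, ncat = ncat, outer_iters = outer_iters,
                         branch_sweeps = branch_sweeps)
  }
  fw <- fit_one(wol)
  fm <- fit_one(mt)
  two <- list(lnL = fw$loglik + fm$loglik,
              k = 2 * (2 * n - 3) + 2 * 5,
              trees = list(wol = fw$tree, mt = fm$tree),
              models = list(wol = fw$models, mt = fm$models))
  two$AIC <- 2 * two$k - 2 * two$lnL

  comb <- concat_alignments(wol = wol, mt = mt)
  tr_s <- neighbor_joining(pairwise_distances(comb, "JC"))
  single_fit <- fit_single_topology(tr_s, comb, ncat, outer_iters,
                                    branch_sweeps)
  single <- list(lnL = single_fit$loglik,
                 k = (2 * n - 3) + 2 * 5 + 1,
                 tree = single_fit$tree, models = single_fit$models,
                 rate_mult = single_fit$rate_mult)
  single$AIC <- 2 * single$k - 2 * single$lnL

  list(single = single, two = two, delta_aic = two$AIC - single$AIC)
}

# Shared-topology fit: per-class HKY+Gamma plus one free rate multiplier on
# the second partition (the first is the reference partition at rate 1).
fit_single_topology <- function(tree, aln, ncat, outer_iters,
                                branch_sweeps) {
  classes <- unique(aln$site_class)
  models <- stats::setNames(lapply(classes, function(cl) {
    hky_model(2, empirical_freqs(aln$mat[, aln$site_class == cl,
                                         drop = FALSE]), 1, ncat)
  }), classes)
  rates <- stats::setNames(c(1, rep(1, length(classes) - 1)), classes)
  cur <- tree
  for (it in seq_len(outer_iters)) {
    fit <- optimize_branch_lengths(cur, aln, models, rates,
                                   max_sweeps = branch_sweeps, tol = 1e-3)
    cur <- fit$tree
    pd <- prep_partition_data(aln, cur)
    for (cl in classes[-1]) {
      o <- stats::optimize(function(lr) {
        rates[cl] <- exp(lr)
        sum(class_logliks(pd, models, rates, pd$edge_len))
      }, c(-6, 6), maximum = TRUE, tol = 1e-4)
      rates[cl] <- exp(o$maximum)
    }
    for (cl in classes) {
      m <- models[[cl]]
      cls_ll <- function(m2) cpp_partition_loglik(
        pd$edge, pd$edge_len, pd$ntip, pd$patterns[[cl]]$tip_pat,
        pd$patterns[[cl]]$weights, m2$eigen$V, m2$eigen$d, m2$eigen$Vinv,
        m2$freqs, m2$cat_rates, rates[[cl]])
      ok <- stats::optimize(function(k) cls_ll(hky_model(k, m$freqs,
                                                         m$alpha, ncat)),
                            c(0.2, 40), maximum = TRUE, tol = 1e-3)
      m <- hky_model(ok$maximum, m$freqs, m$alpha, ncat)
      oa <- stats::optimize(function(a) cls_ll(hky_model(m$kappa, m$freqs,
                                                         a, ncat)),
                            c(0.05, 50), maximum = TRUE, tol = 1e-3)
      models[[cl]] <- hky_model(m$kappa, m$freqs, oa$maximum, ncat)
    }
  }
  fit <- optimize_branch_lengths(cur, aln, models, rates,
                                 max_sweeps = branch_sweeps, tol = 1e-3)
  list(tree = fit$tree, models = models, loglik = fit$loglik,
       rate_mult = rates)
}

collapse_classes <- function(aln, label) {
  partitioned_alignment(aln$mat, rep(label, ncol(aln$mat)),
                        seq_len(ncol(aln$mat)), aln$ref_id)
}

#' Assemble a model-comparison record
#'
#' Pure arithmetic: `AIC = 2k - 2 lnL` per model and
#' `log10 BF = (lnML_single - lnML_two) / ln 10` from harmonic-mean log
#' marginal likelihoods. A positive log10 Bayes factor (or a positive
#' `delta_aic = AIC_two - AIC_single`) supports the single-topology model,
#' i.e. strict maternal co-transmission.
#'
#' @param lnml_single,lnml_two Log marginal likelihoods (optional, `NA` to
#'   skip the Bayes factor).
#' @param k_single,k_two Parameter counts.
#' @param lnl_single,lnl_two Maximised log-likelihoods.
#' @return An object of class `"model_comparison"`.
#' @export
model_comparison <- function(lnml_single = NA_real_, lnml_two = NA_real_,
                             k_single = NA_real_, k_two = NA_real_,
                             lnl_single = NA_real_, lnl_two = NA_real_) {
  aic_s <- 2 * k_single - 2 * lnl_single
  aic_t <- 2 * k_two - 2 * lnl_two
  structure(list(
    lnL_single = lnl_single, lnL_two = lnl_two,
    k_single = k_single, k_two = k_two,
    AIC_single = aic_s, AIC_two = aic_t,
    delta_aic = aic_t - aic_s,
    lnML_single = lnml_single, lnML_two = lnml_two,
    log10_BF = (lnml_single - lnml_two) / log(10)),
    class = "model_comparison")
}

#' @exportS3Method base::print
print.model_comparison <- function(x, ...) {
  cat("Topology-congruence model comparison\n")
  cat(sprintf("  lnL  single: %.2f  two: %.2f\n", x$lnL_single, x$lnL_two))
  cat(sprintf("  AIC  single: %.1f  two: %.1f  (delta = %.1f)\n",
              x$AIC_single, x$AIC_two, x$delta_aic))
  if (!is.na(x$log10_BF))
    cat(sprintf("  log10 Bayes factor (single vs two): %.2f\n", x$log10_BF))
  verdict <- if (isTRUE(x$delta_aic > 0) || isTRUE(x$log10_BF > 0))
    "single topology (congruent genealogies)" else "two topologies"
  cat("  favoured:", verdict, "\n")
  invisible(x)
}

#' Harmonic-mean estimate of the log marginal likelihood
#'
#' Computes `ln( m / sum_i exp(-lnL_i) )` with log-sum-exp stabilisation,
#' the harmonic mean of the posterior likelihood samples on the log scale.
#'
#' @param lnl Numeric vector of posterior log-likelihood samples.
#' @return Log marginal likelihood estimate (lies between `min(lnl)` and
#'   `max(lnl)`).
#' @export
harmonic_mean_lnml <- function(lnl) {
  if (!length(lnl) || any(!is.finite(lnl)))
    stop("lnl must be a non-empty vector of finite log-likelihoods")
  x <- -lnl
  c <- max(x)
  -(c + log(sum(exp(x - c))) - log(length(x)))
}

#' Randomize endosymbiont-host associations
#'
#' Permutes the endosymbiont-to-host pairing uniformly within geographic
#' strata, as a negative control for the congruence test: `"location"`
#' permutes within identical latitude/longitude, `"continent"` within
#' region, `"global"` across the whole sample. The multiset of endosymbiont
#' sequences is preserved and strata are never mixed.
#'
#' @param metadata Data frame with `strain_id`, `latitude`, `longitude`,
#'   `region` (restricted to the strains being permuted, i.e. the infected
#'   set).
#' @param level `"location"`, `"continent"`, or `"global"`.
#' @param seed Integer seed.
#' @return Named character vector: for each host strain, the strain whose
#'   endosymbiont it receives.
#' @export
randomize_associations <- function(metadata,
                                   level = c("location", "continent",
                                             "global"),
                                   seed = 1) {
  level <- match.arg(level)
  strata <- switch(level,
    location = paste(metadata$latitude, metadata$longitude),
    continent = metadata$region,
    global = rep("all", nrow(metadata)))
  mapping <- stats::setNames(metadata$strain_id, metadata$strain_id)
  with_seed(seed, {
    for (st in unique(strata)) {
      idx <- which(strata == st)
      if (length(idx) > 1)
        mapping[idx] <- metadata$strain_id[idx[sample.int(length(idx))]]
    }
  })
  mapping
}

#' Simulate one congruence-test dataset and report its AIC comparison
#'
#' Generates paired endosymbiont/mtDNA alignments on one shared coalescent
#' genealogy (full co-inheritance, no loss), optionally destroys the
#' association by permuting the endosymbiont rows within geographic strata,
#' and fits both topology models.
#'
#' @param params A [synthetic_params()] object.
#' @param randomize `"none"` or a level for [randomize_associations()].
#' @param seed Integer seed.
#' @return The [fit_topology_models()] result, with the permutation used
#'   (if any) as attribute `"mapping"`.
#' @export
congruence_experiment <- function(params, randomize = "none", seed = 1) {
  seeds <- derive_seeds(seed, 3)
  p <- params
  p$loss_rate <- 0  # all strains co-infected: both genomes observed
  hist <- simulate_cytoplasmic_history(p, seed = seeds[1])
  truth <- evolve_alignments(hist$tree, hist$infected, p, seed = seeds[2])
  wol <- truth$wol
  mapping <- NULL
  if (randomize != "none") {
    meta <- assign_metadata(rownames(wol$mat))
    mapping <- randomize_associations(meta, randomize, seed = seeds[3])
    mat <- wol$mat[mapping, , drop = FALSE]
    rownames(mat) <- names(mapping)
    wol <- partitioned_alignment(mat, wol$site_class, wol$ref_pos,
                                 wol$ref_id)
  }
  out <- fit_topology_models(wol, truth$mt)
  attr(out, "mapping") <- mapping
  out
}
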