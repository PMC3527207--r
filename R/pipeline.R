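#' Pipeline configuration
#'
#' Collects inputs, thresholds (with their standard defaults: infection
#' called at depth > 1 and breadth > 0.90; consensus depth window 10-100),
#' replicate counts, and seeds for [run_pipeline()].
#'
#' @param synthetic A [synthetic_params()] object (used when `input_dir` is
#'   `NULL`).
#' @param input_dir Optional fixture-bundle directory from
#'   [make_fixture_bundle()].
#' @param output_dir Optional directory for TSV/Newick/JSON outputs.
#' @param depth_min,breadth_min Infection-call thresholds.
#' @param consensus_min_depth,consensus_max_depth Consensus depth window.
#' @param kst_permutations Permutations for the Kst test.
#' @param null_reps Coalescent replicates for Tajima's D p-values.
#' @param run_dating Run the dating MCMC stage (slower).
#' @param dating_iter MCMC sweeps when dating is run.
#' @param seed Master seed; every stochastic stage derives its own stream.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synthetic = synthetic_params(),
                            input_dir = NULL, output_dir = NULL,
                            depth_min = 1, breadth_min = 0.90,
                            consensus_min_depth = 10,
                            consensus_max_depth = 100,
                            kst_permutations = 1000, null_reps = 2000,
                            run_dating = FALSE, dating_iter = 2000,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full co-inheritance analysis pipeline
#'
#' Sequences the analysis end to end: infection calling from coverage,
#' consensus assembly, ungapped partitioned alignments, neighbor-joining
#' genealogies, the single- versus two-topology congruence comparison,
#' diversity statistics with conditional-coalescent p-values, the patristic
#' Kst permutation test, marker genotyping, and (optionally) the
#' rate-calibrated dating MCMC. Works on a synthetic in-memory dataset or
#' on a file bundle; when `output_dir` is set, per-stage TSV/Newick files
#' and a machine-readable `summary.json` are written.
#'
#' @param config A [pipeline_config()].
#' @return List with per-stage results and `summary` (the JSON-ready
#'   record).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 6)
  params <- config$synthetic

  if (!is.null(config$input_dir)) {
    bundle <- read_fixture_bundle(config$input_dir)
    profiles <- bundle$profiles
    metadata <- bundle$metadata
    references <- bundle$references
    ann <- bundle$annotation
    tracks <- lapply(stats::setNames(nm = c("mtDNA", "wolbachia")),
                     function(ref) {
      out <- rep("noncoding", nchar(references[[ref]]))
      a <- ann[ann$reference_id == ref, , drop = FALSE]
      for (i in seq_len(nrow(a))) out[a$start[i]:a$end[i]] <- a$class[i]
      out
    })
    truth_infected <- unlist(bundle$truth_record$infected)
  } else {
    sim <- simulate_cytoplasm(params)
    profiles <- sim$profiles
    metadata <- sim$metadata
    references <- sim$truth$references
    tracks <- reference_tracks(params)
    truth_infected <- sim$history$infected
  }
  ref_lengths <- vapply(references, nchar, numeric(1))

  # ---- stage 1: infection calling -----------------------------------------
  calls <- call_infection_table(profiles, metadata, ref_lengths,
                                config$depth_min, config$breadth_min,
                                config$consensus_min_depth,
                                config$consensus_max_depth)
  infected <- calls$strain_id[calls$status == "infected"]

  # ---- stage 2: consensus + alignments ------------------------------------
  mt_cons <- vapply(calls$strain_id, function(s) call_consensus(
    profiles[[s]]$mtDNA$counts, ref_lengths[["mtDNA"]],
    config$consensus_min_depth, config$consensus_max_depth,
    strain_id = s, reference_id = "mtDNA")$sequence, character(1))
  mt_aln <- build_ungapped_alignment(mt_cons, tracks$mtDNA, "mtDNA")
  wol_cons <- attr(calls, "consensus")[infected]
  wol_aln <- if (length(infected) >= 2)
    build_ungapped_alignment(wol_cons, tracks$wolbachia, "wolbachia")
  else NULL

  # ---- stage 3: genealogies ------------------------------------------------
  mt_tree <- if (nrow(mt_aln$mat) >= 3 && ncol(mt_aln$mat) >= 1)
    midpoint_root(neighbor_joining(pairwise_distances(mt_aln, "raw")))
  else NULL

  # ---- stage 4: congruence -------------------------------------------------
  congr <- NULL
  if (!is.null(wol_aln) && length(infected) >= 4 &&
      ncol(wol_aln$mat) >= 1) {
    fit <- fit_topology_models(wol_aln, subset_alignment(mt_aln, infected))
    congr <- model_comparison(k_single = fit$single$k, k_two = fit$two$k,
                              lnl_single = fit$single$lnL,
                              lnl_two = fit$two$lnL)
  }

  # ---- stage 5: diversity + Kst -------------------------------------------
  diversity <- do.call(rbind, Filter(Negate(is.null), list(
    if (!is.null(wol_aln) && ncol(wol_aln$mat) > 0)
      cbind(genome = "wolbachia_infected",
            diversity_summary(wol_aln, config$null_reps, seeds[2])),
    if (length(infected) >= 2)
      cbind(genome = "mtDNA_infected",
            diversity_summary(subset_alignment(mt_aln, infected),
                              config$null_reps, seeds[3])),
    cbind(genome = "mtDNA_all",
          diversity_summary(mt_aln, config$null_reps, seeds[4])))))
  kst <- NULL
  if (!is.null(mt_tree) && length(unique(calls$status)) == 2) {
    D <- patristic_distances(mt_tree)
    ord <- match(rownames(D), calls$strain_id)
    kst <- try(kst_permutation_test(
      D, calls$status[ord],
      metadata$population[match(rownames(D), metadata$strain_id)],
      config$kst_permutations, seeds[5]), silent = TRUE)
    if (inherits(kst, "try-error")) kst <- NULL
  }

  # ---- stage 6: marker genotyping -----------------------------------------
  coi_window <- c(1657, 2211)
  genotypes <- NULL
  if (ref_lengths[["mtDNA"]] >= coi_window[2]) {
    coi <- vapply(calls$strain_id, function(s)
      extract_coi(mt_cons[[s]]), character(1))
    hap <- assign_coi_haplotype(
      coi, c("2" = extract_coi(references[["mtDNA"]])))
    genotypes <- data.frame(
      strain_id = calls$strain_id,
      mt_snp_type = vapply(calls$strain_id, function(s)
        classify_mt_snp_type(mt_cons[[s]]), character(1)),
      coi_haplotype = hap$assignments$haplotype[
        match(calls$strain_id, hap$assignments$strain_id)],
      stringsAsFactors = FALSE)
  }

  # ---- stage 7: dating (optional) -----------------------------------------
  dating <- NULL
  if (config$run_dating && !is.null(wol_aln) && length(infected) >= 4) {
    concat <- concat_alignments(mt = subset_alignment(mt_aln, infected),
                                wol = wol_aln)
    concat <- merge_codon12(concat)
    topo <- midpoint_root(neighbor_joining(pairwise_distances(concat,
                                                              "raw")))
    chain <- run_dating_mcmc(concat, topo, n_iter = config$dating_iter,
                             seed = seeds[6])
    dating <- summarize_posterior(chain)
  }

  truth_eval <- NULL
  if (!is.null(truth_infected)) {
    obs <- stats::setNames(calls$status == "infected", calls$strain_id)
    truth_eval <- concordance(obs, truth_infected[calls$strain_id])
  }

  summary <- list(
    seed = config$seed,
    n_strains = nrow(calls),
    n_infected = length(infected),
    infected_fraction = length(infected) / nrow(calls),
    infection_accuracy_vs_truth =
      if (!is.null(truth_eval)) truth_eval$fraction else NULL,
    mean_copy_number_infected =
      mean(calls$relative_copy_number[calls$status == "infected"]),
    congruence = if (!is.null(congr))
      list(delta_aic = congr$delta_aic,
           favoured = if (congr$delta_aic > 0) "single_topology"
                      else "two_topology") else NULL,
    diversity = diversity,
    kst = if (!is.null(kst)) list(kst = kst$kst, p_value = kst$p_value)
          else NULL,
    dating = if (!is.null(dating))
      list(root_age_years = dating$root_age_years,
           rates = dating$rates) else NULL)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$output_dir
    utils::write.table(calls, file.path(od, "infection_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(mt_tree))
      ape::write.tree(mt_tree, file.path(od, "mt_tree.nwk"))
    if (!is.null(diversity))
      utils::write.table(diversity, file.path(od, "diversity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(genotypes))
      utils::write.table(genotypes, file.path(od, "genotypes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(calls = calls, mt_alignment = mt_aln, wol_alignment = wol_aln,
       mt_tree = mt_tree, congruence = congr, diversity = diversity,
       kst = kst, genotypes = genotypes, dating = dating,
       summary = summary)
}

#' Merge first and second codon positions into one rate class
#'
#' Relabels `*.codon1` and `*.codon2` columns as `*.codon12`, yielding the
#' five dating rate classes (mt codon12/codon3, endosymbiont
#' codon12/codon3/noncoding).
#'
#' @param aln A concatenated [partitioned_alignment].
#' @return The relabelled alignment.
#' @export
merge_codon12 <- function(aln) {
  cls <- sub("codon[12]$", "codon12", aln$site_class)
  partitioned_alignment(aln$mat, cls, aln$ref_pos, aln$ref_id)
}
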