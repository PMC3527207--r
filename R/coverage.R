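#' Per-base depth profile
#'
#' @param reference_id Reference identifier.
#' @param depth Non-negative integer vector, one entry per reference
#'   position.
#' @return An object of class `"depth_profile"`.
#' @export
depth_profile <- function(reference_id, depth) {
  if (!length(depth)) stop("depth profile must cover at least one position")
  if (any(depth < 0)) stop("depths must be non-negative")
  structure(list(reference_id = reference_id, depth = as.numeric(depth)),
            class = "depth_profile")
}

#' Mean depth of coverage
#'
#' Arithmetic mean read depth over all reference positions, including
#' zero-depth positions.
#'
#' @param profile A [depth_profile] (or bare numeric vector of depths).
#' @return Mean reads per site.
#' @export
mean_depth <- function(profile) {
  depth <- if (inherits(profile, "depth_profile")) profile$depth else profile
  if (!length(depth)) stop("empty depth profile")
  mean(depth)
}

#' Call a consensus sequence from per-site base counts
#'
#' Per site: total depth below `min_depth` or above `max_depth` gives N;
#' a plurality of deletion-supporting reads gives N (deletions relative to
#' the reference are coded as ambiguous); otherwise the majority base is
#' called, with ties giving N. Insertions relative to the reference are
#' ignored entirely. The result is forced to reference length by 3'
#' N-padding or truncation.
#'
#' @param counts Matrix with columns A, C, G, T, del and one row per
#'   reference position covered by the count table.
#' @param ref_length Reference length the consensus must match.
#' @param min_depth,max_depth Inclusive depth window outside which a site
#'   is masked (defaults 10 and 100).
#' @param strain_id,reference_id Identifiers stored on the result.
#' @return A list of class `"consensus_sequence"` with fields `strain_id`,
#'   `reference_id`, and `sequence` (string over A/C/G/T/N of length
#'   `ref_length`).
#' @export
call_consensus <- function(counts, ref_length = nrow(counts),
                           min_depth = 10, max_depth = 100,
                           strain_id = NA_character_,
                           reference_id = NA_character_) {
  counts <- as.matrix(counts)
  if (!all(c("A", "C", "G", "T", "del") %in% colnames(counts)))
    stop("counts must have columns A, C, G, T, del")
  counts <- counts[, c("A", "C", "G", "T", "del"), drop = FALSE]
  total <- rowSums(counts)
  base_part <- counts[, 1:4, drop = FALSE]
  top <- max.col(base_part, ties.method = "first")
  top_count <- base_part[cbind(seq_len(nrow(counts)), top)]
  tie <- rowSums(base_part == top_count) > 1
  call <- BASES[top]
  call[tie] <- "N"
  call[counts[, "del"] >= top_count] <- "N"  # plurality deletion
  call[total < min_depth | total > max_depth] <- "N"
  if (length(call) < ref_length) {
    call <- c(call, rep("N", ref_length - length(call)))
  } else if (length(call) > ref_length) {
    call <- call[seq_len(ref_length)]
  }
  structure(list(strain_id = strain_id, reference_id = reference_id,
                 sequence = paste(call, collapse = "")),
            class = "consensus_sequence")
}

#' Breadth of coverage of a consensus sequence
#'
#' Proportion of reference positions with a non-N base call.
#'
#' @param consensus A `"consensus_sequence"` (or bare string over
#'   A/C/G/T/N).
#' @return Fraction in `[0, 1]`.
#' @export
breadth_of_coverage <- function(consensus) {
  s <- if (inherits(consensus, "consensus_sequence")) consensus$sequence
       else consensus
  ch <- strsplit(toupper(s), "")[[1]]
  mean(ch != "N")
}

#' Classify endosymbiont infection status from coverage metrics
#'
#' A strain is scored infected when breadth of coverage exceeds
#' `breadth_min` (default 90% of the endosymbiont genome) and mean depth of
#' coverage exceeds `depth_min` (default one read per site). Both
#' inequalities are strict.
#'
#' @param mean_depth Mean reads per site (>= 0).
#' @param breadth Fraction of the genome with non-N consensus calls, in
#'   `[0, 1]`.
#' @param depth_min,breadth_min Exclusive thresholds.
#' @return `"infected"` or `"uninfected"`.
#' @export
classify_infection <- function(mean_depth, breadth,
                               depth_min = 1, breadth_min = 0.90) {
  if (is.na(breadth) || breadth < 0 || breadth > 1)
    stop("breadth must lie in [0, 1]")
  if (is.na(mean_depth) || mean_depth < 0)
    stop("mean depth must be non-negative")
  if (breadth > breadth_min && mean_depth > depth_min) "infected"
  else "uninfected"
}

#' Relative cytoplasmic genome copy number
#'
#' Mean target depth normalised by the mean depth of a nuclear control
#' locus, divided by the source ploidy, giving copies per haploid genome
#' equivalent: values for haploid-embryo libraries (1C) are used as is,
#' while diploid-adult libraries (2C) are halved.
#'
#' @param target_mean_depth Mean depth of the cytoplasmic assembly.
#' @param nuclear_mean_depth Mean depth of the nuclear control locus (> 0).
#' @param ploidy 1 or 2 (source DNA ploidy).
#' @return Copies per haploid genome.
#' @export
relative_copy_number <- function(target_mean_depth, nuclear_mean_depth,
                                 ploidy = 2) {
  if (!ploidy %in% c(1, 2)) stop("ploidy must be 1 or 2")
  if (is.na(nuclear_mean_depth) || nuclear_mean_depth <= 0)
    stop("nuclear control assembly failed (mean depth <= 0)")
  (target_mean_depth / nuclear_mean_depth) / ploidy
}

#' Consensus support at variable sites (heteroplasmy proxy)
#'
#' For one strain: the mean, over the supplied variable sites, of the
#' fraction of individual read calls supporting the consensus call at that
#' site. Sites where the consensus is N (or with zero reads) are skipped.
#' Values near 1 indicate negligible within-strain heteroplasmy or
#' contamination.
#'
#' @param counts Base-count matrix (columns A, C, G, T, del).
#' @param consensus Consensus sequence (object or string).
#' @param variable_sites 1-based reference positions of variable sites.
#' @return Mean support fraction, or `NA` (with a warning) when no usable
#'   site remains.
#' @export
consensus_support <- function(counts, consensus, variable_sites) {
  s <- if (inherits(consensus, "consensus_sequence")) consensus$sequence
       else consensus
  ch <- strsplit(toupper(s), "")[[1]]
  if (any(variable_sites > length(ch)))
    stop("variable sites outside the reference")
  use <- variable_sites[ch[variable_sites] %in% BASES]
  counts <- as.matrix(counts)[, BASES, drop = FALSE]
  tot <- rowSums(counts)[use]
  match_n <- counts[cbind(use, match(ch[use], BASES))]
  ok <- tot > 0
  if (!any(ok)) {
    warning("no usable variable sites for consensus support")
    return(NA_real_)
  }
  mean(match_n[ok] / tot[ok])
}

#' Infection calls for a set of strains
#'
#' Convenience wrapper running consensus calling, depth/breadth metrics,
#' classification, and relative copy-number estimation over the per-strain
#' profiles of a dataset (in-memory simulation or file bundle).
#'
#' @param profiles Nested list `profiles[[strain]][[reference]]` with
#'   `depth` and `counts` entries (see [simulate_depth_profiles()]).
#' @param metadata Data frame with `strain_id` and `ploidy` (`"1C"`/`"2C"`).
#' @param ref_lengths Named lengths of the references.
#' @param depth_min,breadth_min Classification thresholds.
#' @param min_depth,max_depth Consensus depth window.
#' @return Data frame with one row per strain: `strain_id`, `mean_depth`,
#'   `breadth`, `status`, `relative_copy_number`, plus the endosymbiont
#'   consensus sequences as attribute `"consensus"`.
#' @export
call_infection_table <- function(profiles, metadata, ref_lengths,
                                 depth_min = 1, breadth_min = 0.90,
                                 min_depth = 10, max_depth = 100) {
  strains <- names(profiles)
  cons <- character(0)
  rows <- lapply(strains, function(s) {
    p <- profiles[[s]]
    wd <- mean_depth(depth_profile("wolbachia",
                                   p$wolbachia$depth %||%
                                     integer(ref_lengths[["wolbachia"]])))
    cc <- call_consensus(p$wolbachia$counts %||%
                           matrix(0L, ref_lengths[["wolbachia"]], 5,
                                  dimnames = list(NULL, c(BASES, "del"))),
                         ref_lengths[["wolbachia"]], min_depth, max_depth,
                         strain_id = s, reference_id = "wolbachia")
    cons[s] <<- cc$sequence
    br <- breadth_of_coverage(cc)
    nuc <- mean_depth(p$nuclear$depth)
    ploidy <- if (!is.null(metadata)) {
      pl <- metadata$ploidy[match(s, metadata$strain_id)]
      if (identical(pl, "1C")) 1 else 2
    } else 2
    data.frame(strain_id = s, mean_depth = wd, breadth = br,
               status = classify_infection(wd, br, depth_min, breadth_min),
               relative_copy_number =
                 if (nuc > 0) relative_copy_number(wd, nuc, ploidy)
                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "consensus") <- cons
  out
}
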