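#' Parameters of the synthetic cytoplasmic-genome generator
#'
#' Bundles every knob of the synthetic-data generator: a shared Kingman
#' coalescent genealogy for the cytoplasmic genomes, imperfect maternal
#' transmission (Poisson loss events of the endosymbiont on branches),
#' per-site-class substitution rates (mtDNA third positions evolving roughly
#' two orders of magnitude faster than the endosymbiont classes), and
#' Poisson read-depth profiles with infected, uninfected, and
#' low-level-contaminated strains.
#'
#' Default class rates are typical median short-term evolutionary rates for
#' a *Drosophila*-*Wolbachia* system (substitutions/site/host generation),
#' and the default effective size places the sample's most recent common
#' ancestor around eight thousand years ago at ten host generations per
#' year. Sequence lengths are desk-scaled: the mtDNA coding partition is
#' full-length while the endosymbiont partitions are scaled down by roughly
#' a factor of six, preserving the expected count of variable sites needed
#' by the genealogy-congruence machinery.
#'
#' @param n_strains Number of sampled strains (>= 2).
#' @param effective_size Haploid effective population size; coalescent times
#'   are multiplied by it, so branch lengths come out in host generations.
#' @param loss_rate Endosymbiont loss events per branch per generation
#'   (imperfect maternal transmission); the root lineage is infected and a
#'   strain is uninfected iff at least one loss occurred on its
#'   root-to-tip path.
#' @param class_rates Named substitutions/site/generation for the five rate
#'   classes `mt_codon12`, `mt_codon3`, `wol_codon12`, `wol_codon3`,
#'   `wol_noncoding`.
#' @param mt_codons,wol_codons Number of codons in the mtDNA and
#'   endosymbiont coding regions.
#' @param wol_noncoding,nuclear_length Lengths (bp) of the endosymbiont
#'   noncoding region and of the nuclear control locus.
#' @param kappa,base_freqs,gamma_shape,gamma_ncat HKY+Gamma parameters
#'   shared by all classes (each class keeps its own rate).
#' @param depth_means Expected mean read depth per genome role
#'   (`mtDNA`, `wolbachia`, `nuclear`).
#' @param contamination_fraction Fraction of uninfected strains receiving
#'   low-level endosymbiont contamination.
#' @param contamination_depth Mean read depth inside contaminated blocks.
#' @param contamination_breadth Fraction of the endosymbiont genome covered
#'   by contaminated blocks (produces the intermediate-breadth strains seen
#'   in real shotgun panels).
#' @param error_rate Per-read per-base sequencing error rate.
#' @param seed Integer seed; every generator function is deterministic given
#'   the parameter set.
#' @return An object of class `"synthetic_params"`.
#' @export
synthetic_params <- function(n_strains = 15,
                             effective_size = 40000,
                             loss_rate = 6e-6,
                             class_rates = c(mt_codon12 = 1.36e-8,
                                             mt_codon3 = 6.89e-8,
                                             wol_codon12 = 6.42e-10,
                                             wol_codon3 = 6.87e-10,
                                             wol_noncoding = 8.00e-10),
                             mt_codons = 3300,
                             wol_codons = 40000,
                             wol_noncoding = 27000,
                             nuclear_length = 10000,
                             kappa = 5,
                             base_freqs = c(0.3, 0.2, 0.2, 0.3),
                             gamma_shape = 1,
                             gamma_ncat = 4L,
                             depth_means = c(mtDNA = 50, wolbachia = 20,
                                             nuclear = 10),
                             contamination_fraction = 0.15,
                             contamination_depth = 12,
                             contamination_breadth = 0.4,
                             error_rate = 0.001,
                             seed = 1L) {
  req <- c("mt_codon12", "mt_codon3", "wol_codon12", "wol_codon3",
           "wol_noncoding")
  if (!all(req %in% names(class_rates)))
    stop("class_rates must name all of: ", paste(req, collapse = ", "))
  if (n_strains < 2) stop("n_strains must be at least 2")
  if (any(class_rates < 0) || loss_rate < 0 || error_rate < 0)
    stop("rates must be non-negative")
  if (abs(sum(base_freqs) - 1) > 1e-8)
    stop("base frequencies must sum to 1")
  if (any(depth_means[c("mtDNA", "nuclear")] <= 0))
    stop("mtDNA and nuclear depth means must be positive")
  structure(as.list(environment()), class = "synthetic_params")
}

#' @exportS3Method base::print
print.synthetic_params <- function(x, ...) {
  cat(sprintf(paste0("synthetic_params: %d strains, Ne = %g generations, ",
                     "loss rate = %g/branch/generation, seed = %d\n"),
              x$n_strains, x$effective_size, x$loss_rate, x$seed))
  invisible(x)
}

#' Simulate the shared cytoplasmic genealogy and infection labels
#'
#' Draws a Kingman coalescent genealogy for the sampled strains (branch
#' lengths in host generations, via `effective_size`), infects the root
#' lineage, and drops Poisson(`loss_rate` x branch length) endosymbiont
#' loss events on branches. A strain is uninfected iff at least one loss
#' event lies on its root-to-tip path; once lost, the infection is never
#' regained.
#'
#' @param params A [synthetic_params()] object.
#' @param seed Optional seed override.
#' @return List with `tree` (rooted ultrametric `phylo`, branch lengths in
#'   generations), `infected` (named logical per strain), `ages` (node ages
#'   in generations), and `loss_edges` (indices of edges carrying a loss).
#' @export
simulate_cytoplasmic_history <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "synthetic_params"))
  with_seed(seed, {
    tree <- ape::rcoal(params$n_strains,
                       tip.label = sprintf("s%02d", seq_len(params$n_strains)))
    tree$edge.length <- tree$edge.length * params$effective_size
    losses <- stats::rpois(nrow(tree$edge),
                           params$loss_rate * tree$edge.length)
    infected <- !vapply(seq_len(params$n_strains), function(tip) {
      any(losses[path_edges(tree, tip)] > 0)
    }, logical(1))
    names(infected) <- tree$tip.label
    depth <- ape::node.depth.edgelength(tree)
    ages <- max(depth) - depth
    list(tree = tree, infected = infected, ages = ages,
         loss_edges = which(losses > 0))
  })
}

# Edge indices on the root-to-tip path of one tip.
path_edges <- function(tree, tip) {
  out <- integer(0)
  node <- tip
  repeat {
    e <- which(tree$edge[, 2] == node)
    if (!length(e)) break
    out <- c(out, e)
    node <- tree$edge[e, 1]
  }
  out
}

# Per-position site-class tracks for the two cytoplasmic references.
reference_tracks <- function(params) {
  list(
    mtDNA = rep(c("codon1", "codon2", "codon3"), params$mt_codons),
    wolbachia = c(rep(c("codon1", "codon2", "codon3"), params$wol_codons),
                  rep("noncoding", params$wol_noncoding))
  )
}

# Map per-position track classes of one reference to the five rate classes.
rate_class_of <- function(ref, track_class) {
  prefix <- if (ref == "mtDNA") "mt" else "wol"
  ifelse(track_class == "codon3", paste0(prefix, "_codon3"),
         ifelse(track_class %in% c("codon1", "codon2"),
                paste0(prefix, "_codon12"), paste0(prefix, "_noncoding")))
}

#' Evolve cytoplasmic alignments along the shared genealogy
#'
#' Simulates mtDNA sequences for every strain and endosymbiont sequences for
#' the infected strains only (on the induced subtree), site by site under
#' HKY with discrete-Gamma rate multipliers and the per-class substitution
#' rate. The root sequences double as the mapping references, so the true
#' alignments are reference-anchored by construction.
#'
#' @param tree Rooted `phylo` with branch lengths in generations.
#' @param infected Named logical vector of infection labels.
#' @param params A [synthetic_params()] object.
#' @param seed Optional seed override.
#' @return List with `mt` and `wol` [partitioned_alignment]s of the true
#'   sequences and `references` (named character: root sequences per
#'   reference, plus the nuclear control).
#' @export
evolve_alignments <- function(tree, infected, params, seed = params$seed) {
  tracks <- reference_tracks(params)
  with_seed(seed, {
    refs <- character(0)
    alns <- list()
    for (ref in c("mtDNA", "wolbachia")) {
      track <- tracks[[ref]]
      rates <- params$class_rates[rate_class_of(ref, track)]
      if (ref == "wolbachia") {
        keep <- names(infected)[infected]
        if (!length(keep)) {
          warning("no infected strains: endosymbiont alignment is empty")
          alns[[ref]] <- NULL
          refs[ref] <- paste(sample(BASES, length(track), TRUE,
                                    params$base_freqs), collapse = "")
          next
        }
        use_tree <- if (length(keep) == 1) NULL else
          ape::keep.tip(tree, keep)
      } else use_tree <- tree
      sim <- sim_sequences(use_tree, rates, params)
      refs[ref] <- sim$root
      alns[[ref]] <- partitioned_alignment(sim$mat, track,
                                           seq_along(track), ref)
    }
    refs["nuclear"] <- paste(sample(BASES, params$nuclear_length, TRUE,
                                    params$base_freqs), collapse = "")
    list(mt = alns$mtDNA, wol = alns$wolbachia, references = refs)
  })
}

# Simulate one set of sequences along `tree` with per-site rates.
# `tree = NULL` means a single lineage: the tip equals the root sequence.
sim_sequences <- function(tree, site_rates, params) {
  L <- length(site_rates)
  cat_rates <- gamma_cat_rates(params$gamma_shape, params$gamma_ncat)
  site_cat <- sample.int(params$gamma_ncat, L, replace = TRUE)
  root <- sample.int(4, L, replace = TRUE, prob = params$base_freqs)
  eig <- hky_eigen(params$kappa, params$base_freqs)
  if (is.null(tree)) {
    mat <- matrix(BASES[root], nrow = 1)
    return(list(mat = mat, root = paste(BASES[root], collapse = "")))
  }
  tree <- ape::reorder.phylo(tree, "cladewise")  # preorder traversal
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- matrix(0L, nnode, L)
  seqs[ntip + 1L, ] <- root
  rate_groups <- split(seq_len(L), paste(site_rates, site_cat))
  group_scale <- vapply(rate_groups, function(idx)
    site_rates[idx[1]] * cat_rates[site_cat[idx[1]]], numeric(1))
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    gens <- tree$edge.length[e]
    out <- seqs[par, ]
    for (g in seq_along(rate_groups)) {
      t_sub <- gens * group_scale[g]
      if (t_sub == 0) next
      P <- hky_pmatrix_from_eigen(eig, t_sub)
      idx <- rate_groups[[g]]
      cur <- seqs[par, idx]
      for (b in 1:4) {
        sel <- idx[cur == b]
        if (length(sel))
          out[sel] <- sample.int(4, length(sel), replace = TRUE, prob = P[b, ])
      }
    }
    seqs[chd, ] <- out
  }
  mat <- matrix(BASES[seqs[seq_len(ntip), ]], ntip, L,
                dimnames = list(tree$tip.label, NULL))
  list(mat = mat, root = paste(BASES[root], collapse = ""))
}

hky_pmatrix_from_eigen <- function(eig, t) {
  P <- eig$V %*% (exp(eig$d * t) * eig$Vinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate per-base read-depth profiles and base counts
#'
#' For every strain and reference, per-base depths are Poisson with the
#' configured mean. Uninfected strains receive endosymbiont depth zero,
#' except a configurable fraction that get low-level contamination: blocks
#' covering `contamination_breadth` of the genome at mean depth
#' `contamination_depth`, emulating intermediate-breadth assemblies. Base
#' counts at covered sites reflect the strain's true base with a per-read
#' error rate.
#'
#' @param truth Result of [evolve_alignments()] (true sequences and
#'   references).
#' @param infected Named logical vector of infection labels.
#' @param params A [synthetic_params()] object.
#' @param seed Optional seed override.
#' @return Nested list `profiles[[strain]][[reference]]`, each a list with
#'   `depth` (integer vector) and `counts` (matrix with columns
#'   A, C, G, T, del), plus an attribute `"contaminated"` naming the
#'   contaminated strains.
#' @export
simulate_depth_profiles <- function(truth, infected, params,
                                    seed = params$seed) {
  if (any(params$depth_means < 0)) stop("depth means must be non-negative")
  strains <- names(infected)
  with_seed(seed, {
    uninf <- strains[!infected]
    n_cont <- round(params$contamination_fraction * length(uninf))
    contaminated <- if (n_cont > 0) sort(sample(uninf, n_cont)) else character(0)
    profiles <- stats::setNames(vector("list", length(strains)), strains)
    for (s in strains) {
      profiles[[s]] <- list()
      for (ref in c("mtDNA", "wolbachia", "nuclear")) {
        L <- nchar(truth$references[[ref]])
        true_seq <- true_sequence_of(truth, s, ref)
        if (ref == "wolbachia" && !infected[[s]]) {
          if (s %in% contaminated) {
            depth <- contamination_depth_profile(L, params)
          } else depth <- integer(L)
        } else {
          mean_depth <- params$depth_means[[if (ref == "nuclear") "nuclear"
                                            else ref]]
          depth <- stats::rpois(L, mean_depth)
        }
        profiles[[s]][[ref]] <- list(
          depth = depth,
          counts = base_counts_from_depth(depth, true_seq, params$error_rate))
      }
    }
    attr(profiles, "contaminated") <- contaminated
    profiles
  })
}

true_sequence_of <- function(truth, strain, ref) {
  if (ref == "nuclear") return(strsplit(truth$references[["nuclear"]], "")[[1]])
  aln <- if (ref == "mtDNA") truth$mt else truth$wol
  if (!is.null(aln) && strain %in% rownames(aln$mat))
    return(aln$mat[strain, ])
  strsplit(truth$references[[ref]], "")[[1]]
}

contamination_depth_profile <- function(L, params) {
  depth <- integer(L)
  block <- 500L
  starts <- seq(1L, L, by = block)
  covered <- sort(sample(seq_along(starts),
                         max(1, round(params$contamination_breadth *
                                        length(starts)))))
  for (i in covered) {
    idx <- starts[i]:min(L, starts[i] + block - 1L)
    depth[idx] <- stats::rpois(length(idx), params$contamination_depth)
  }
  depth
}

# Multinomial base counts per site given depth, the true base, and a
# uniform per-read error model (errors hit each other base equally).
base_counts_from_depth <- function(depth, true_seq, error_rate) {
  L <- length(depth)
  counts <- matrix(0L, L, 5, dimnames = list(NULL,
                                             c("A", "C", "G", "T", "del")))
  b <- match(true_seq, BASES)
  errs <- stats::rbinom(L, depth, error_rate)
  counts[cbind(seq_len(L), b)] <- depth - errs
  hit <- which(errs > 0)
  for (i in hit) {
    others <- setdiff(1:4, b[i])
    alloc <- stats::rmultinom(1, errs[i], rep(1 / 3, 3))[, 1]
    counts[i, others] <- counts[i, others] + alloc
  }
  counts
}

#' Generate a complete synthetic dataset in memory
#'
#' Runs [simulate_cytoplasmic_history()], [evolve_alignments()] and
#' [simulate_depth_profiles()] under one seed and attaches strain metadata
#' and the truth record.
#'
#' @param params A [synthetic_params()] object.
#' @return List with `history`, `truth` (alignments + references),
#'   `profiles`, `metadata` (data frame), and `truth_record`.
#' @export
simulate_cytoplasm <- function(params) {
  seeds <- derive_seeds(params$seed, 3)
  history <- simulate_cytoplasmic_history(params, seed = seeds[1])
  truth <- evolve_alignments(history$tree, history$infected, params,
                             seed = seeds[2])
  profiles <- simulate_depth_profiles(truth, history$infected, params,
                                      seed = seeds[3])
  metadata <- assign_metadata(names(history$infected))
  record <- list(
    tree = ape::write.tree(history$tree),
    infected = as.list(history$infected),
    class_rates = as.list(params$class_rates),
    contaminated = attr(profiles, "contaminated"),
    variable_sites = list(
      mtDNA = variable_positions(truth$mt),
      wolbachia = variable_positions(truth$wol)),
    seed = params$seed)
  list(history = history, truth = truth, profiles = profiles,
       metadata = metadata, truth_record = record)
}

variable_positions <- function(aln) {
  if (is.null(aln) || nrow(aln$mat) < 2) return(integer(0))
  aln$ref_pos[vapply(seq_len(ncol(aln$mat)), function(j)
    length(unique(aln$mat[, j])) > 1, logical(1))]
}

# Deterministic population metadata emulating a mixed panel: one large North
# American sample of diploid adults plus smaller African and European
# samples of haploid embryos.
assign_metadata <- function(strains) {
  pops <- data.frame(
    population = c("Raleigh", "Gikongoro", "Dodola", "Kampala",
                   "Montpellier"),
    latitude = c(35.79, -2.49, 6.98, 0.32, 43.61),
    longitude = c(-78.64, 29.56, 39.11, 32.58, 3.88),
    region = c("NorthAmerica", "Africa", "Africa", "Africa", "Europe"),
    ploidy = c("2C", "1C", "1C", "1C", "1C"),
    weight = c(0.60, 0.15, 0.10, 0.10, 0.05))
  n <- length(strains)
  counts <- floor(pops$weight * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(pops$weight * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  idx <- rep(seq_len(nrow(pops)), counts)
  data.frame(strain_id = strains, population = pops$population[idx],
             latitude = pops$latitude[idx], longitude = pops$longitude[idx],
             region = pops$region[idx], ploidy = pops$ploidy[idx],
             stringsAsFactors = FALSE)
}

#' Write a synthetic dataset as a plain-text file bundle
#'
#' Produces the on-disk input layout the pipeline readers consume:
#' reference FASTA, per-strain depth and base-count TSVs, a partition
#' annotation track, strain metadata, the truth tree in Newick, and a JSON
#' truth record. Identical parameters (including seed) produce identical
#' file contents.
#'
#' @param params A [synthetic_params()] object.
#' @param output_dir Directory to create/populate.
#' @return Invisibly, the `simulate_cytoplasm()` result that was written.
#' @export
make_fixture_bundle <- function(params, output_dir) {
  sim <- simulate_cytoplasm(params)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stop("cannot create directory: ", output_dir)
  write_fasta(sim$truth$references, file.path(output_dir, "references.fasta"))
  tracks <- reference_tracks(params)
  ann <- do.call(rbind, lapply(names(tracks), function(ref) {
    cls <- tracks[[ref]]
    r <- rle(cls)
    ends <- cumsum(r$lengths)
    data.frame(reference_id = ref, start = ends - r$lengths + 1L,
               end = ends, class = r$values)
  }))
  data.table::fwrite(ann, file.path(output_dir, "annotation.tsv"), sep = "\t")
  for (d in c("depth", "counts")) dir.create(file.path(output_dir, d),
                                             showWarnings = FALSE)
  for (s in names(sim$profiles)) {
    for (ref in names(sim$profiles[[s]])) {
      p <- sim$profiles[[s]][[ref]]
      data.table::fwrite(
        data.frame(reference_id = ref, position = seq_along(p$depth),
                   depth = p$depth),
        file.path(output_dir, "depth", paste0(s, ".", ref, ".tsv")),
        sep = "\t")
      data.table::fwrite(
        cbind(data.frame(reference_id = ref,
                         position = seq_along(p$depth)),
              as.data.frame(p$counts)),
        file.path(output_dir, "counts", paste0(s, ".", ref, ".tsv")),
        sep = "\t")
    }
  }
  utils::write.table(sim$metadata, file.path(output_dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$truth_record$tree, file.path(output_dir, "truth_tree.nwk"))
  jsonlite::write_json(sim$truth_record,
                       file.path(output_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' Read a synthetic fixture bundle from disk
#'
#' @param dir Directory written by [make_fixture_bundle()].
#' @return List with `references`, `profiles`, `metadata`, `annotation`,
#'   `truth_tree`, and `truth_record`.
#' @export
read_fixture_bundle <- function(dir) {
  refs <- read_fasta(file.path(dir, "references.fasta"))
  metadata <- utils::read.table(file.path(dir, "metadata.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  ann <- data.table::fread(file.path(dir, "annotation.tsv"),
                           data.table = FALSE)
  strains <- metadata$strain_id
  profiles <- stats::setNames(lapply(strains, function(s) {
    out <- list()
    for (ref in names(refs)) {
      dfile <- file.path(dir, "depth", paste0(s, ".", ref, ".tsv"))
      cfile <- file.path(dir, "counts", paste0(s, ".", ref, ".tsv"))
      if (!file.exists(dfile)) next
      d <- data.table::fread(dfile, data.table = FALSE)
      co <- data.table::fread(cfile, data.table = FALSE)
      out[[ref]] <- list(depth = d$depth,
                         counts = as.matrix(co[, c("A", "C", "G", "T",
                                                   "del")]))
    }
    out
  }), strains)
  list(references = refs, profiles = profiles, metadata = metadata,
       annotation = ann,
       truth_tree = ape::read.tree(file.path(dir, "truth_tree.nwk")),
       truth_record = jsonlite::read_json(file.path(dir, "truth.json"),
                                          simplifyVector = TRUE))
}
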