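#' Neighbor-joining genealogy from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]) with negative
#' estimated branch lengths clamped to zero. Used in place of a heuristic
#' maximum-likelihood topology search; fixed-topology maximum-likelihood
#' branch lengths can be fitted afterwards with
#' [optimize_branch_lengths()].
#'
#' @param D Symmetric, non-negative distance matrix with at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("neighbor joining requires at least 3 taxa")
  if (any(D < 0) || max(abs(D - t(D))) > 1e-8)
    stop("distance matrix must be symmetric and non-negative")
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for neighbor-joining clades
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each pseudo-replicate, and reports the percentage of replicates in which
#' each bipartition of the full-data tree is recovered.
#'
#' @param aln A [partitioned_alignment].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for reproducibility.
#' @param model Distance model passed to [pairwise_distances()].
#' @return The full-data NJ tree with `node.label` set to integer percentage
#'   support on internal nodes (NA on the root).
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = 1, model = "raw") {
  stopifnot(n_reps >= 1)
  full <- neighbor_joining(pairwise_distances(aln, model))
  reps <- with_seed(seed, lapply(seq_len(n_reps), function(i) {
    cols <- sample.int(ncol(aln$mat), replace = TRUE)
    b <- partitioned_alignment(aln$mat[, cols, drop = FALSE],
                               aln$site_class[cols],
                               seq_along(cols), aln$ref_id)
    neighbor_joining(pairwise_distances(b, model))
  }))
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- round(100 * counts / n_reps)
  full
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest tip-to-tip path (for
#' visualization and for orienting genealogies when no outgroup is
#' available). When several paths tie for the diameter, the
#' lexicographically smallest tip pair is used, which makes the rooting
#' deterministic.
#'
#' @param tree Unrooted `phylo` tree with branch lengths.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (sum(tree$edge.length) == 0) {
    warning("zero-diameter tree: rooting at the first internal node")
    return(ape::root(tree, node = ape::Ntip(tree) + 1L, resolve.root = TRUE))
  }
  D <- patristic_distances(tree)
  ties <- which(D >= max(D) - 1e-12 & upper.tri(D), arr.ind = TRUE)
  pairs <- t(apply(ties, 1, function(r) sort(rownames(D)[r])))
  best <- pairs[order(pairs[, 1], pairs[, 2])[1], ]
  a <- best[1]; b <- best[2]
  half <- D[a, b] / 2
  path <- ape::nodepath(tree, match(a, tree$tip.label),
                        match(b, tree$tip.label))
  cum <- 0
  for (k in seq_len(length(path) - 1)) {
    e <- which((tree$edge[, 1] == path[k] & tree$edge[, 2] == path[k + 1]) |
                 (tree$edge[, 1] == path[k + 1] & tree$edge[, 2] == path[k]))
    step <- tree$edge.length[e]
    if (cum + step >= half - 1e-12) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      from_k <- half - cum
      # phytools::reroot measures `position` from the rootward (parent) end
      pos_from_parent <- if (parent == path[k]) from_k else step - from_k
      rooted <- phytools::reroot(tree, child,
                                 position = min(max(pos_from_parent, 0), step))
      return(rooted)
    }
    cum <- cum + step
  }
  stop("internal error: midpoint not located on the diameter path")
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree `phylo` tree with branch lengths.
#' @return Symmetric matrix of tip-to-tip path lengths.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  as.matrix(stats::cophenetic(tree))
}
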