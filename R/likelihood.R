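#' Partitioned HKY+Gamma log-likelihood on a fixed topology
#'
#' Computes the Felsenstein pruning log-likelihood of a gap-free partitioned
#' alignment on a fixed tree. Each site class is assigned its own HKY+Gamma
#' model and an optional per-class rate multiplier that scales every branch
#' length, so the same tree (in time or substitution units) can carry
#' partitions evolving at very different rates.
#'
#' @param aln A [partitioned_alignment] whose rows match the tree tips.
#' @param tree `phylo` tree with branch lengths; may be rooted or unrooted.
#' @param models A single [hky_model()] applied to every class, or a named
#'   list mapping each site class to its model.
#' @param rates Optional named numeric vector of per-class rate multipliers
#'   (default 1 for every class).
#' @return Total log-likelihood (sum over alignment columns).
#' @export
partition_loglik <- function(aln, tree, models, rates = NULL) {
  pd <- prep_partition_data(aln, tree)
  models <- normalize_models(models, pd$classes)
  rates <- normalize_rates(rates, pd$classes)
  tot <- 0
  for (cl in pd$classes) {
    m <- models[[cl]]
    tot <- tot + cpp_partition_loglik(
      pd$edge, pd$edge_len, pd$ntip, pd$patterns[[cl]]$tip_pat,
      pd$patterns[[cl]]$weights, m$eigen$V, m$eigen$d, m$eigen$Vinv,
      m$freqs, m$cat_rates, rates[[cl]])
  }
  tot
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Coordinate-wise (Brent) optimisation of every branch length of a fixed
#' topology under the partitioned HKY+Gamma likelihood of
#' [partition_loglik()]. Branch lengths are constrained to be non-negative
#' and the returned log-likelihood never decreases across sweeps.
#'
#' @inheritParams partition_loglik
#' @param max_sweeps Maximum number of full passes over the branches.
#' @param tol Convergence tolerance on the log-likelihood between sweeps.
#' @return List with elements `tree` (branch lengths replaced by their ML
#'   estimates), `loglik`, and `converged`.
#' @export
optimize_branch_lengths <- function(tree, aln, models, rates = NULL,
                                    max_sweeps = 5, tol = 1e-3) {
  pd <- prep_partition_data(aln, tree)
  models <- normalize_models(models, pd$classes)
  rates <- normalize_rates(rates, pd$classes)
  len <- pd$edge_len
  ll_of <- function(len) class_logliks(pd, models, rates, len)
  ll <- sum(ll_of(len))
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    for (e in seq_along(len)) {
      f <- function(x) {
        len[e] <- x
        sum(ll_of(len))
      }
      upper <- max(0.5, 5 * len[e])
      opt <- stats::optimize(f, c(0, upper), maximum = TRUE, tol = 1e-7)
      if (opt$objective >= ll) {
        len[e] <- opt$maximum
        ll <- opt$objective
      }
    }
    new_ll <- sum(ll_of(len))
    if (new_ll - ll < tol && sweep > 1) {
      converged <- TRUE
      ll <- new_ll
      break
    }
    ll <- new_ll
  }
  if (!converged && max_sweeps > 1)
    warning("branch-length optimisation stopped at max_sweeps; ",
            "returning best lengths so far")
  out <- pd$tree
  out$edge.length <- len
  # tiny lengths are genuine zeros up to Brent tolerance
  out$edge.length[out$edge.length < 1e-9] <- 0
  list(tree = out, loglik = ll, converged = converged || max_sweeps == 1)
}

# Fit per-class kappa and alpha (empirical base frequencies) together with
# branch lengths, by alternating Brent updates. Returns models, tree, loglik.
fit_partition_models <- function(tree, aln, ncat = 4L, outer_iters = 2,
                                 branch_sweeps = 2) {
  pd0 <- prep_partition_data(aln, tree)
  classes <- pd0$classes
  models <- list()
  for (cl in classes) {
    f <- empirical_freqs(aln$mat[, aln$site_class == cl, drop = FALSE])
    models[[cl]] <- hky_model(kappa = 2, freqs = f, alpha = 1, ncat = ncat)
  }
  cur <- tree
  ll <- -Inf
  for (it in seq_len(outer_iters)) {
    fit <- optimize_branch_lengths(cur, aln, models,
                                   max_sweeps = branch_sweeps, tol = 1e-3)
    cur <- fit$tree
    pd <- prep_partition_data(aln, cur)
    for (cl in classes) {
      m <- models[[cl]]
      cls_ll <- function(m2) cpp_partition_loglik(
        pd$edge, pd$edge_len, pd$ntip, pd$patterns[[cl]]$tip_pat,
        pd$patterns[[cl]]$weights, m2$eigen$V, m2$eigen$d, m2$eigen$Vinv,
        m2$freqs, m2$cat_rates, 1)
      ok <- stats::optimize(function(k) cls_ll(hky_model(k, m$freqs, m$alpha,
                                                         ncat)),
                            c(0.2, 40), maximum = TRUE, tol = 1e-3)
      m <- hky_model(ok$maximum, m$freqs, m$alpha, ncat)
      oa <- stats::optimize(function(a) cls_ll(hky_model(m$kappa, m$freqs, a,
                                                         ncat)),
                            c(0.05, 50), maximum = TRUE, tol = 1e-3)
      models[[cl]] <- hky_model(m$kappa, m$freqs, oa$maximum, ncat)
    }
    ll <- sum(class_logliks(pd, models, normalize_rates(NULL, classes),
                            pd$edge_len))
  }
  fit <- optimize_branch_lengths(cur, aln, models,
                                 max_sweeps = branch_sweeps, tol = 1e-3)
  list(tree = fit$tree, models = models, loglik = fit$loglik)
}

empirical_freqs <- function(mat) {
  counts <- table(factor(mat, levels = BASES))
  f <- as.numeric(counts) + 1  # add-one smoothing keeps frequencies positive
  f / sum(f)
}

# ---- internal plumbing -----------------------------------------------------

# Precompute everything the C++ kernel needs: a postorder edge matrix, the
# tip row order, and per-class compressed site patterns.
prep_partition_data <- function(aln, tree) {
  if (!setequal(tree$tip.label, rownames(aln$mat)))
    stop("tree tips and alignment rows must contain the same strains")
  tree <- ape::reorder.phylo(tree, "postorder")
  mat <- aln$mat[tree$tip.label, , drop = FALSE]
  codes <- matrix(match(mat, BASES) - 1L, nrow = nrow(mat))
  classes <- unique(aln$site_class)
  patterns <- stats::setNames(lapply(classes, function(cl) {
    compress_patterns(codes[, aln$site_class == cl, drop = FALSE])
  }), classes)
  list(tree = tree, edge = tree$edge,
       edge_len = tree$edge.length %||% rep(0, nrow(tree$edge)),
       ntip = length(tree$tip.label), classes = classes, patterns = patterns)
}

compress_patterns <- function(codes) {
  if (ncol(codes) == 0)
    return(list(tip_pat = matrix(integer(), nrow(codes), 0),
                weights = numeric(0)))
  keys <- do.call(paste0, lapply(seq_len(nrow(codes)), function(i) codes[i, ]))
  idx <- match(keys, unique(keys))
  first <- !duplicated(idx)
  list(tip_pat = codes[, first, drop = FALSE],
       weights = as.numeric(tabulate(idx, max(idx))))
}

class_logliks <- function(pd, models, rates, edge_len) {
  vapply(pd$classes, function(cl) {
    m <- models[[cl]]
    cpp_partition_loglik(pd$edge, edge_len, pd$ntip,
                         pd$patterns[[cl]]$tip_pat, pd$patterns[[cl]]$weights,
                         m$eigen$V, m$eigen$d, m$eigen$Vinv, m$freqs,
                         m$cat_rates, rates[[cl]])
  }, numeric(1))
}

normalize_models <- function(models, classes) {
  if (inherits(models, "hky_model"))
    return(stats::setNames(rep(list(models), length(classes)), classes))
  missing <- setdiff(classes, names(models))
  if (length(missing))
    stop("no model supplied for class(es): ", paste(missing, collapse = ", "))
  models
}

normalize_rates <- function(rates, classes) {
  if (is.null(rates))
    return(stats::setNames(rep(1, length(classes)), classes))
  missing <- setdiff(classes, names(rates))
  if (length(missing))
    stop("no rate multiplier for class(es): ", paste(missing, collapse = ", "))
  rates
}
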