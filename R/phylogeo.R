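#' Discrete phylogeography: ML rate matrix and ancestral locations
#'
#' Models strain locations over a dated genealogy as a continuous-time
#' Markov chain on a small set of regions (by default Africa, Europe,
#' NorthAmerica) with a non-reversible rate matrix: every off-diagonal rate
#' is free, so e.g. the Africa-to-Europe rate can differ from the
#' Europe-to-Africa rate. The rate matrix is estimated by maximum
#' likelihood on the fixed tree (Felsenstein pruning over the location
#' states, uniform root prior), and marginal ancestral-state probabilities
#' are computed for every internal node by combining below- and above-tree
#' partial likelihoods.
#'
#' @param tree Rooted `phylo` with branch lengths (typically ages in
#'   generations or years).
#' @param tip_locations Named character vector mapping every tip to one of
#'   `locations`.
#' @param locations State space (default the three study regions).
#' @param Q Optional fixed rate matrix; when supplied no optimisation is
#'   performed.
#' @param root_prior Root state frequencies; `NULL` (default) uses the
#'   stationary distribution of `Q`, the usual convention of Bayesian
#'   discrete phylogeography.
#' @return List with `Q` (fitted generator matrix), `loglik`,
#'   `node_probs` (matrix of marginal location probabilities, one row per
#'   node including tips), and `root_probs`.
#' @export
phylogeo_ancestral_states <- function(tree, tip_locations,
                                      locations = c("Africa", "Europe",
                                                    "NorthAmerica"),
                                      Q = NULL, root_prior = NULL) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  miss <- setdiff(tree$tip.label, names(tip_locations))
  if (length(miss))
    stop("unlabeled tips: ", paste(miss, collapse = ", "))
  states <- match(tip_locations[tree$tip.label], locations)
  if (anyNA(states)) stop("tip locations outside the location set")
  k <- length(locations)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  # scale branch lengths to mean 1 so rate magnitudes are well-conditioned
  scale <- mean(tree$edge.length)
  if (scale <= 0) scale <- 1
  elen <- tree$edge.length / scale

  loglik_Q <- function(Qm) {
    ctmc_pruning(tree$edge, elen, ntip, states, Qm, root_prior)$loglik
  }
  if (is.null(Q)) {
    noff <- k * (k - 1)
    fit <- stats::optim(rep(log(0.5), noff), function(lr) {
      if (any(abs(lr) > 12)) return(1e10)  # keep expm well-conditioned
      -loglik_Q(build_Q(exp(lr), k))
    }, method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-10))
    Qs <- build_Q(exp(pmin(pmax(fit$par, -12), 12)), k)
  } else {
    Qs <- Q * scale  # user Q is on the original branch-length scale
  }
  pr <- ctmc_pruning(tree$edge, elen, ntip, states, Qs, root_prior)
  up <- ctmc_above(tree$edge, elen, ntip, Qs, pr$partials, pr$pi0)
  node_probs <- pr$partials * up
  rs <- rowSums(node_probs)
  bad <- !is.finite(rs) | rs <= 0  # numerically extinguished rows
  if (any(bad))  # fall back to the below-tree conditionals
    node_probs[bad, ] <- pr$partials[bad, , drop = FALSE] /
      pmax(rowSums(pr$partials[bad, , drop = FALSE]), 1e-300)
  node_probs[!bad, ] <- node_probs[!bad, , drop = FALSE] / rs[!bad]
  dimnames(node_probs) <- list(NULL, locations)
  root <- tree$edge[nrow(tree$edge), 1]
  list(Q = Qs / scale, loglik = pr$loglik, node_probs = node_probs,
       root_probs = node_probs[root, ], tree = tree,
       locations = locations)
}

build_Q <- function(off_rates, k) {
  Q <- matrix(0, k, k)
  Q[row(Q) != col(Q)] <- off_rates
  diag(Q) <- -rowSums(Q)
  Q
}

ctmc_P <- function(Q, t) {
  P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0] <- 0
  P / rowSums(P)
}

# Stationary distribution of a generator matrix (root prior of the CTMC);
# falls back to uniform when Q is degenerate.
ctmc_stationary <- function(Q) {
  k <- nrow(Q)
  x <- tryCatch(qr.solve(rbind(t(Q), rep(1, k)), c(rep(0, k), 1)),
                error = function(e) rep(1 / k, k))
  x[!is.finite(x) | x < 0] <- 0
  if (sum(x) <= 0) return(rep(1 / k, k))
  x / sum(x)
}

# below-tree partial likelihoods and total log-likelihood; the root prior
# defaults to the stationary distribution of Q
ctmc_pruning <- function(edge, elen, ntip, states, Q, root_prior = NULL) {
  k <- nrow(Q)
  nnode <- ntip + nrow(edge) / 2 + 1
  part <- matrix(1, nnode, k)
  for (i in seq_len(ntip)) {
    part[i, ] <- 0
    part[i, states[i]] <- 1
  }
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; c <- edge[e, 2]
    part[p, ] <- part[p, ] * as.vector(ctmc_P(Q, elen[e]) %*% part[c, ])
  }
  root <- edge[nrow(edge), 1]
  pi0 <- root_prior %||% ctmc_stationary(Q)
  list(loglik = log(sum(pi0 * part[root, ])), partials = part, pi0 = pi0)
}

# above-tree partials G[v, s] = P(data outside subtree of v | state(v) = s)
# times the root prior, via a preorder recursion
ctmc_above <- function(edge, elen, ntip, Q, part, pi0 = NULL) {
  k <- nrow(Q)
  nnode <- nrow(part)
  G <- matrix(0, nnode, k)
  root <- edge[nrow(edge), 1]
  G[root, ] <- pi0 %||% ctmc_stationary(Q)
  D <- matrix(0, nrow(edge), k)  # D[e, s_p] = sum_s P(s_p,s) part[child, s]
  for (e in seq_len(nrow(edge)))
    D[e, ] <- as.vector(ctmc_P(Q, elen[e]) %*% part[edge[e, 2], ])
  for (e in rev(seq_len(nrow(edge)))) {  # preorder
    p <- edge[e, 1]; v <- edge[e, 2]
    sib <- which(edge[, 1] == p & edge[, 2] != v)
    above_p <- G[p, ]
    for (se in sib) above_p <- above_p * D[se, ]
    G[v, ] <- as.vector(above_p %*% ctmc_P(Q, elen[e]))
  }
  G
}
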