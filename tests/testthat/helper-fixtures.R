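# Small parameter sets and reusable fixtures for the test suite.
# Everything is generated in code; sizes are kept small so the whole suite
# runs quickly.

small_params <- function(...) {
  defaults <- list(n_strains = 8, effective_size = 40000,
                   mt_codons = 400, wol_codons = 600, wol_noncoding = 300,
                   nuclear_length = 1000, seed = 101L)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_params, args)
}

# base-count matrix for a single site
site_counts_row <- function(A = 0, C = 0, G = 0, T = 0, del = 0) {
  matrix(c(A, C, G, T, del), 1, 5,
         dimnames = list(NULL, c("A", "C", "G", "T", "del")))
}

# uniform base-count table supporting `seq` at depth `depth` everywhere
counts_for_sequence <- function(seq, depth = 20) {
  ch <- strsplit(seq, "")[[1]]
  counts <- matrix(0L, length(ch), 5,
                   dimnames = list(NULL, c("A", "C", "G", "T", "del")))
  counts[cbind(seq_along(ch), match(ch, c("A", "C", "G", "T")))] <- depth
  counts
}

random_alignment <- function(n, L, seed = 1, classes = "all") {
  withr::with_seed(seed, {
    mat <- matrix(sample(c("A", "C", "G", "T"), n * L, TRUE), n, L,
                  dimnames = list(sprintf("t%02d", seq_len(n)), NULL))
  })
  partitioned_alignment(mat, rep_len(classes, L), seq_len(L))
}

# brute-force partition log-likelihood by enumerating internal-node states
brute_force_loglik <- function(aln, tree, model, rate = 1) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  mat <- aln$mat
  tot <- 0
  for (s in seq_len(ncol(mat))) {
    like <- 0
    for (cat in model$cat_rates) {
      P <- lapply(seq_len(nrow(tr$edge)), function(e)
        cytosym:::hky_pmatrix_from_eigen(model$eigen,
                                         tr$edge.length[e] * cat * rate))
      states <- as.matrix(expand.grid(rep(list(1:4), tr$Nnode)))
      for (r in seq_len(nrow(states))) {
        st <- function(node)
          if (node <= ntip) match(mat[tr$tip.label[node], s],
                                  c("A", "C", "G", "T"))
          else states[r, node - ntip]
        pr <- model$freqs[st(ntip + 1)]
        for (e in seq_len(nrow(tr$edge)))
          pr <- pr * P[[e]][st(tr$edge[e, 1]), st(tr$edge[e, 2])]
        like <- like + pr / length(model$cat_rates)
      }
    }
    tot <- tot + log(like)
  }
  tot
}
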