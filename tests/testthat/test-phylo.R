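test_that("column removal drops exactly the N-bearing columns", {
  cons <- c(a = "ACGTACGTAC", b = "ACNTACGTAC", c = "ACGTACGTAC")
  cls <- rep(c("codon1", "codon2"), 5)
  aln <- build_ungapped_alignment(cons, cls)
  expect_equal(ncol(aln$mat), 9)
  expect_false(3 %in% aln$ref_pos)
  expect_equal(aln$site_class, cls[-3])
  # no Ns anywhere: unchanged
  aln2 <- build_ungapped_alignment(cons[c(1, 3)], cls)
  expect_equal(ncol(aln2$mat), 10)
  # all-N column removed by the same rule
  cons3 <- c(a = "ANGT", b = "ANGT")
  expect_equal(build_ungapped_alignment(cons3, rep("x", 4))$ref_pos,
               c(1L, 3L, 4L))
})

test_that("column removal is order independent over strains", {
  cons <- c(a = "ACGTNCGTAC", b = "ACNTACGTAC", c = "ACGTACGTNN")
  cls <- rep("codon1", 10)
  pos1 <- build_ungapped_alignment(cons, cls)$ref_pos
  pos2 <- build_ungapped_alignment(cons[c(3, 1, 2)], cls)$ref_pos
  expect_identical(pos1, pos2)
})

test_that("pairwise distances follow the raw and Jukes-Cantor formulas", {
  mat <- rbind(a = strsplit(strrep("A", 100), "")[[1]],
               b = c("C", rep("A", 99)))
  aln <- partitioned_alignment(mat, rep("x", 100), 1:100)
  expect_equal(unname(pairwise_distances(aln, "raw")["a", "b"]), 0.01)
  expect_equal(unname(pairwise_distances(aln, "JC")["a", "b"]),
               -0.75 * log(1 - 4 / 3 * 0.01), tolerance = 1e-9)
  expect_equal(unname(pairwise_distances(aln, "JC")["a", "b"]), 0.010067,
               tolerance = 1e-4)
  same <- partitioned_alignment(mat[c(1, 1), ], rep("x", 100), 1:100)
  expect_equal(unname(pairwise_distances(same)[1, 2]), 0)
  # JC saturation
  big <- partitioned_alignment(rbind(a = rep("A", 4), b = rep("C", 4)),
                               rep("x", 4), 1:4)
  expect_error(pairwise_distances(big, "JC"), "saturation")
})

test_that("neighbor joining reproduces the three-point closed form", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("neighbor joining exactly recovers additive trees", {
  set.seed(5)
  for (i in 1:5) {
    tr <- ape::rtree(6)
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
    D <- patristic_distances(tr)
    rec <- neighbor_joining(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), rec)), 0)
    expect_equal(patristic_distances(rec)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("neighbor joining is invariant to taxon input order", {
  set.seed(9)
  tr <- ape::rtree(7)
  D <- patristic_distances(tr)
  perm <- sample(nrow(D))
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("midpoint rooting splits the longest tip-to-tip path", {
  tr <- ape::read.tree(text = "(a:1,b:2);")
  r <- midpoint_root(tr)
  d <- patristic_distances(r)
  depths <- ape::node.depth.edgelength(r)
  expect_equal(max(depths[1:2]) - min(depths[1:2]), 0, tolerance = 1e-9)
  # caterpillar with known lengths: root lies on the a-d path at half 6.5
  cat_tr <- ape::unroot(ape::read.tree(
    text = "(((a:1,b:0.5):1,c:0.5):2,d:2.5);"))
  rooted <- midpoint_root(cat_tr)
  dd <- ape::node.depth.edgelength(rooted)
  tipd <- setNames(dd[1:4], rooted$tip.label)
  expect_equal(unname(tipd["a"]), 3.25)
  expect_equal(unname(tipd["d"]), 3.25)
})

test_that("patristic distances sum branch lengths along paths", {
  tr <- ape::read.tree(text = "(a:1,b:2);")
  expect_equal(patristic_distances(tr)["a", "b"], 3)
  sym <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  D <- patristic_distances(sym)
  expect_equal(D["a", "b"], 2)
  expect_equal(D["a", "c"], 4)
})

test_that("bootstrap support is deterministic and saturates on clean signal", {
  # two clades separated by many identical supporting columns
  block <- function(ch, n) matrix(ch, n, 40)
  mat <- rbind(cbind(block("A", 3), block("C", 3)),
               cbind(block("C", 3), block("A", 3)))
  rownames(mat) <- sprintf("t%d", 1:6)
  mat[, 1:5] <- matrix(sample(c("A", "C", "G", "T"), 30, TRUE), 6)
  aln <- partitioned_alignment(mat, rep("x", 80), 1:80)
  b1 <- bootstrap_support(aln, n_reps = 50, seed = 3)
  b2 <- bootstrap_support(aln, n_reps = 50, seed = 3)
  expect_identical(b1$node.label, b2$node.label)
  expect_true(any(b1$node.label == 100))
  b3 <- bootstrap_support(aln, n_reps = 1, seed = 3)
  expect_true(all(b3$node.label %in% c(0, 100)))
})

test_that("partitioned likelihood equals brute-force enumeration", {
  set.seed(11)
  for (ntaxa in c(4, 5)) {
    tr <- ape::rtree(ntaxa)
    tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.4)
    aln <- random_alignment(ntaxa, 30, seed = ntaxa)
    rownames(aln$mat) <- tr$tip.label
    m <- hky_model(kappa = 4, freqs = c(0.4, 0.1, 0.2, 0.3), alpha = 0.6,
                   ncat = 4)
    expect_equal(partition_loglik(aln, tr, m),
                 brute_force_loglik(aln, tr, m), tolerance = 1e-8)
  }
})

test_that("zero branch lengths with identical sequences give the base-frequency likelihood", {
  tr <- ape::rtree(4)
  tr$edge.length <- rep(0, nrow(tr$edge))
  seqchars <- sample(c("A", "C", "G", "T"), 20, TRUE)
  mat <- matrix(rep(seqchars, each = 4), 4,
                dimnames = list(tr$tip.label, NULL))
  aln <- partitioned_alignment(mat, rep("x", 20), 1:20)
  m <- hky_model(2, c(0.1, 0.2, 0.3, 0.4), alpha = 1)
  expect_equal(partition_loglik(aln, tr, m),
               sum(log(m$freqs[match(seqchars, c("A", "C", "G", "T"))])))
})

test_that("two-taxon single-site likelihood matches the closed form", {
  # equal frequencies, kappa = 1, no Gamma: the Jukes-Cantor 2-sequence
  # formula pi * (1/4 + 3/4 e^{-4/3 t}) or pi * (1/4 - 1/4 e^{-4/3 t})
  tr <- ape::read.tree(text = "(a:0.05,b:0.1);")
  m <- hky_model(1, rep(0.25, 4), alpha = Inf, ncat = 1)
  t_tot <- 0.15
  same <- partitioned_alignment(rbind(a = "A", b = "A"), "x", 1)
  diff <- partitioned_alignment(rbind(a = "A", b = "G"), "x", 1)
  expect_equal(partition_loglik(same, tr, m),
               log(0.25 * (0.25 + 0.75 * exp(-4 / 3 * t_tot))),
               tolerance = 1e-10)
  expect_equal(partition_loglik(diff, tr, m),
               log(0.25 * (0.25 - 0.25 * exp(-4 / 3 * t_tot))),
               tolerance = 1e-10)
})

test_that("per-class rate multipliers rescale branch lengths", {
  tr <- ape::rtree(5)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.2)
  aln <- random_alignment(5, 40, seed = 2)
  rownames(aln$mat) <- tr$tip.label
  m <- hky_model(2, rep(0.25, 4), alpha = 1)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 0.37
  expect_equal(partition_loglik(aln, tr, m, rates = c(all = 0.37)),
               partition_loglik(aln, tr2, m), tolerance = 1e-10)
})

test_that("ML branch length equals the JC distance in the 2-taxon JC case", {
  L <- 200; k <- 14
  mat <- rbind(a = rep("A", L), b = c(rep("G", k), rep("A", L - k)))
  aln <- partitioned_alignment(mat, rep("x", L), 1:L)
  tr <- ape::read.tree(text = "(a:0.01,b:0.01);")
  m <- hky_model(1, rep(0.25, 4), alpha = Inf, ncat = 1)
  fit <- optimize_branch_lengths(tr, aln, m, max_sweeps = 6)
  p <- k / L
  expect_equal(sum(fit$tree$edge.length), -0.75 * log(1 - 4 / 3 * p),
               tolerance = 1e-4)
  # identical sequences: lengths collapse to zero
  same <- partitioned_alignment(mat[c(1, 1), ], rep("x", L), 1:L)
  rownames(same$mat) <- c("a", "b")
  fit0 <- optimize_branch_lengths(tr, same, m, max_sweeps = 3)
  expect_lt(sum(fit0$tree$edge.length), 1e-6)
})

test_that("branch-length optimisation never decreases the likelihood", {
  set.seed(21)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.2)
  aln <- random_alignment(6, 60, seed = 3)
  rownames(aln$mat) <- tr$tip.label
  m <- hky_model(3, rep(0.25, 4), alpha = 1)
  before <- partition_loglik(aln, tr, m)
  fit <- optimize_branch_lengths(tr, aln, m, max_sweeps = 3)
  expect_gte(fit$loglik, before)
  expect_true(all(fit$tree$edge.length >= 0))
})
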