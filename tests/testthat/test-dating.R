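test_that("the lognormal rate prior exposes the implied central rate", {
  pr <- lognormal_rate_prior(-16.59613, 1 / 3)
  expect_equal(pr$central_rate, 6.2e-8, tolerance = 0.05e-8 / 6.2e-8)
  expect_equal(pr$quantile(c(0.025, 0.975)),
               exp(-16.59613 + c(-1, 1) * 1.96 / 3), tolerance = 1e-4)
  pt <- lognormal_rate_prior(-16.59613, 0)
  expect_equal(pt$quantile(c(0.1, 0.9)), rep(exp(-16.59613), 2))
  expect_error(lognormal_rate_prior(-16, -0.1), "non-negative")
})

test_that("the coalescent age prior matches the exponential closed form", {
  # n = 2: log density = -log N - t / N
  expect_equal(coalescent_tree_log_prior(5, 10), -log(10) - 5 / 10)
  # rescaling ages and Ne by c shifts the density by the Jacobian only
  ages <- c(3, 7, 12)
  for (c_fac in c(2, 10)) {
    expect_equal(coalescent_tree_log_prior(ages * c_fac, 100 * c_fac),
                 coalescent_tree_log_prior(ages, 100) -
                   length(ages) * log(c_fac),
                 tolerance = 1e-12)
  }
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  expect_error(coalescent_tree_log_prior(c(2, 1), 10, tree = tr), NA)
  expect_error(coalescent_tree_log_prior(c(0.5, 1), 10, tree = tr),
               "older than its parent")
})

test_that("prior-only MCMC recovers the calibration prior quantiles", {
  # prior recovery does not look at the data, so iid columns suffice
  concat <- random_alignment(6, 100,
                             classes = c("mt.codon12", "mt.codon3",
                                         "wol.codon12", "wol.codon3",
                                         "wol.noncoding"))
  topo <- withr::with_seed(2, ape::rcoal(6, tip.label = rownames(concat$mat)))
  prior <- lognormal_rate_prior()
  ch <- run_dating_mcmc(concat, topo, prior, n_iter = 6000, thin = 2,
                        seed = 7, prior_only = TRUE)
  draws <- ch$samples$rate_mt.codon3
  draws <- draws[-seq_len(500)]
  qs <- quantile(log(draws), c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(qs[2], prior$mu_log, tolerance = 0.02 * abs(prior$mu_log))
  expect_equal(qs[3] - qs[1], 2 * qnorm(0.75) * prior$sigma_log,
               tolerance = 0.2)
})

test_that("dating chains are reproducible under a fixed seed", {
  p <- small_params(n_strains = 5, mt_codons = 300, wol_codons = 300,
                    wol_noncoding = 150, loss_rate = 0)
  h <- simulate_cytoplasmic_history(p, seed = 4)
  tr <- evolve_alignments(h$tree, h$infected, p, seed = 4)
  concat <- merge_codon12(concat_alignments(mt = tr$mt, wol = tr$wol))
  ch1 <- suppressWarnings(
    run_dating_mcmc(concat, h$tree, n_iter = 200, thin = 2, seed = 9))
  ch2 <- suppressWarnings(
    run_dating_mcmc(concat, h$tree, n_iter = 200, thin = 2, seed = 9))
  expect_identical(ch1$samples, ch2$samples)
  expect_error(suppressWarnings(
    run_dating_mcmc(concat, ape::unroot(h$tree), n_iter = 10)), "rooted")
})

test_that("posterior summaries convert generations to years by division", {
  p <- small_params(n_strains = 5, mt_codons = 300, wol_codons = 200,
                    wol_noncoding = 100, loss_rate = 0)
  h <- simulate_cytoplasmic_history(p, seed = 4)
  tr <- evolve_alignments(h$tree, h$infected, p, seed = 4)
  concat <- merge_codon12(concat_alignments(mt = tr$mt, wol = tr$wol))
  ch <- suppressWarnings(
    run_dating_mcmc(concat, h$tree, n_iter = 400, thin = 2, seed = 9))
  s <- summarize_posterior(ch, generations_per_year = 10)
  expect_equal(s$ages$median_years, s$ages$median_gen / 10)
  expect_true(all(s$rates$ci_lower <= s$rates$median &
                    s$rates$median <= s$rates$ci_upper))
  # the spec-level arithmetic: 76,287 generations -> 7,628.7 years
  expect_equal(76287 / 10, 7628.7)
  # constant chain has zero CI width
  const <- ch
  const$samples[] <- lapply(const$samples, function(col) rep(col[1],
                                                             length(col)))
  s0 <- summarize_posterior(const)
  expect_equal(s0$rates$ci_lower, s0$rates$ci_upper)
  expect_error(summarize_posterior(structure(list(samples =
    ch$samples[0, ], classes = ch$classes, acceptance = ch$acceptance,
    settings = ch$settings), class = "dating_mcmc")), "post-burn-in")
})

test_that("burn-in removal discards the first phase of a two-phase chain", {
  ch <- structure(list(
    samples = data.frame(rate_x = c(rep(100, 50), rep(1, 50)),
                         Ne = 1, root_age = 1, age_6 = 1, loglik = 0),
    classes = "x", acceptance = c(age = 0.5),
    settings = list(seed = 1)), class = "dating_mcmc")
  s <- summarize_posterior(ch, burnin = 0.5)
  expect_equal(s$rates$median, 1)
})

test_that("phylogeography: uniform tips pin the root, mixed tips stay proper", {
  set.seed(31)
  tr <- ape::rcoal(6)
  locs <- setNames(rep("Africa", 6), tr$tip.label)
  f <- phylogeo_ancestral_states(tr, locs)
  expect_equal(unname(f$root_probs["Africa"]), 1, tolerance = 1e-4)
  expect_true(all(abs(rowSums(f$node_probs) - 1) < 1e-9))
  expect_error(phylogeo_ancestral_states(tr, locs[-1]), "unlabeled")
  locs2 <- setNames(c("Africa", "Africa", "Europe", "Europe",
                      "NorthAmerica", "Africa"), tr$tip.label)
  f2 <- phylogeo_ancestral_states(tr, locs2)
  expect_true(all(diag(f2$Q) <= 0))
  expect_equal(unname(rowSums(f2$Q)), rep(0, 3), tolerance = 1e-9)
})

test_that("the 3-state likelihood equals brute-force enumeration on 3 taxa", {
  set.seed(17)
  tr <- ape::rcoal(3)
  locs <- setNames(c("Africa", "Europe", "NorthAmerica"), tr$tip.label)
  Q <- matrix(c(-1.5, 1, 0.5, 0.3, -0.8, 0.5, 0.2, 0.6, -0.8), 3, 3,
              byrow = TRUE)
  f <- phylogeo_ancestral_states(tr, locs, Q = Q)
  # enumeration over the 3^2 internal-state assignments, same root prior
  tr2 <- ape::reorder.phylo(tr, "postorder")
  P <- lapply(seq_len(4), function(e)
    as.matrix(Matrix::expm(Q * tr2$edge.length[e])))
  states <- match(locs[tr2$tip.label], c("Africa", "Europe", "NorthAmerica"))
  pi0 <- cytosym:::ctmc_stationary(Q)
  tot <- 0
  for (r in 1:3) for (v in 1:3) {
    st <- function(n) if (n <= 3) states[n] else c(r, v)[n - 3]
    pr <- pi0[st(4)]
    for (e in 1:4) pr <- pr * P[[e]][st(tr2$edge[e, 1]), st(tr2$edge[e, 2])]
    tot <- tot + pr
  }
  expect_equal(f$loglik, log(tot), tolerance = 1e-8)
})

test_that("a symmetric 2-location reduction matches the 2-state closed form", {
  # collapse to 2 states by never using the third: symmetric rate r gives
  # P(stay) = 1/2 + 1/2 exp(-2 r t)
  tr <- ape::read.tree(text = "(a:0.4,b:0.7);")
  r <- 0.9
  Q <- matrix(c(-r, r, 0, r, -r, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  Q[3, 3] <- -1e-12  # keep the generator well-defined
  Q[3, 1] <- 1e-12
  locs <- c(a = "Africa", b = "Europe")
  f <- phylogeo_ancestral_states(tr, locs, Q = Q,
                                 root_prior = c(0.5, 0.5, 0))
  t_tot <- 1.1
  p_change <- 0.5 - 0.5 * exp(-2 * r * t_tot)
  expect_equal(f$loglik, log(0.5 * p_change), tolerance = 1e-6)
})
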