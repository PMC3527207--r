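# 4-sequence fixture with 3 singleton sites over L = 16 used repeatedly:
# hand enumeration of the 6 pairs gives sum of differences 9, pi = 1.5/16
singleton_alignment <- function() {
  base <- strrep("A", 16)
  mat <- do.call(rbind, strsplit(c(base, base, base, base), ""))
  rownames(mat) <- paste0("s", 1:4)
  mat[1, 1] <- "C"; mat[2, 5] <- "G"; mat[3, 9] <- "T"
  mat
}

test_that("pi matches hand-enumerated pairwise differences", {
  two <- rbind(a = strsplit("ACGTACGTAC", "")[[1]],
               b = strsplit("ACGTACGTAG", "")[[1]])
  expect_equal(nucleotide_diversity_pi(two), 0.1)
  expect_equal(nucleotide_diversity_pi(two[c(1, 1), ]), 0)
  expect_equal(nucleotide_diversity_pi(singleton_alignment()),
               (9 / 6) / 16)
  expect_error(nucleotide_diversity_pi(two[1, , drop = FALSE]), "two")
})

test_that("Watterson's theta uses the harmonic number and mutation count", {
  two <- rbind(a = strsplit(strrep("A", 100), "")[[1]],
               b = c(rep("C", 5), rep("A", 95)))
  expect_equal(watterson_theta(two), 0.05)  # n = 2, a1 = 1
  expect_equal(watterson_theta(two[c(1, 1), ]), 0)
  expect_equal(watterson_theta(singleton_alignment()),
               3 / ((1 + 1 / 2 + 1 / 3) * 16), tolerance = 1e-12)
  # a tri-allelic site counts twice under eta, once under S
  tri <- rbind(a = c("A", "A"), b = c("C", "A"), c = c("G", "A"))
  expect_equal(watterson_theta(tri, "eta") / watterson_theta(tri, "S"), 2)
  expect_gte(watterson_theta(tri, "eta"), watterson_theta(tri, "S"))
})

test_that("Tajima's D reproduces the hand-computed singleton case", {
  # independent evaluation of the 1989 formulas for n=4, S=3, L=16:
  # a1 = 1.83333, e1 = 0.005510, e2 = 0.002690 -> D = -0.7544
  expect_equal(tajimas_d(singleton_alignment()), -0.754, tolerance = 1e-3)
  expect_lt(tajimas_d(singleton_alignment()), 0)  # singletons skew negative
  mono <- matrix("A", 3, 10)
  expect_error(tajimas_d(mono), "undefined")
})

test_that("conditional-on-S null is reproducible and covers extreme observations", {
  cc1 <- conditional_coalescent_null(10, 8, n_reps = 500, seed = 3,
                                     observed_d = -10)
  cc2 <- conditional_coalescent_null(10, 8, n_reps = 500, seed = 3)
  expect_identical(cc1$d, cc2$d)
  expect_lte(cc1$p_value, 1 / 500)
  cc3 <- conditional_coalescent_null(10, 8, n_reps = 500, seed = 3,
                                     observed_d = 10)
  expect_equal(cc3$p_value, 1)
})

test_that("the simulated D distribution is stable across runs", {
  m1 <- mean(conditional_coalescent_null(20, 30, 4000, seed = 1)$d)
  m2 <- mean(conditional_coalescent_null(20, 30, 4000, seed = 2)$d)
  expect_lt(abs(m1 - m2), 0.05)
})

test_that("Kst matches hand-enumerated cases", {
  # groups {a,b} and {c,d}: within = 1, between = 3
  D <- matrix(3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  D["a", "b"] <- D["b", "a"] <- 1
  D["c", "d"] <- D["d", "c"] <- 1
  labels <- c(1, 1, 2, 2)
  expect_equal(kst_statistic(D, labels), 1 - (6 / 14), tolerance = 1e-12)
  # within-group 0, between > 0 -> Kst = 1
  D2 <- D; D2["a", "b"] <- D2["b", "a"] <- 0
  D2["c", "d"] <- D2["d", "c"] <- 0
  expect_equal(kst_statistic(D2, labels), 1)
  # all distances equal -> Kst = 0
  D3 <- matrix(2, 4, 4); diag(D3) <- 0
  expect_equal(kst_statistic(D3, labels), 0)
  # invariant to strain permutations preserving the label partition
  perm <- c(2, 1, 4, 3)
  expect_equal(kst_statistic(D[perm, perm], labels[perm]),
               kst_statistic(D, labels))
  expect_true(is.na(kst_statistic(D3, c(1, 1, 1, 1))))
})

test_that("permutation p-values agree with exhaustive enumeration at n = 5", {
  set.seed(44)
  tr <- ape::rcoal(5)
  D <- patristic_distances(tr)
  labels <- c(1, 1, 2, 2, 2)
  pops <- rep("p1", 5)
  obs <- kst_statistic(D, labels)
  # exhaustive: all label arrangements within the single population
  combos <- combn(5, 2)
  exact <- mean(apply(combos, 2, function(idx) {
    labs <- rep(2, 5); labs[idx] <- 1
    kst_statistic(D, labs) >= obs
  }))
  mc <- kst_permutation_test(D, labels, pops, n_perm = 4000, seed = 1)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_equal(mc$p_value, exact, tolerance = max(2.5 * se / exact, 0.05))
})

test_that("populations with uniform labels contribute no permutation variation", {
  set.seed(45)
  tr <- ape::rcoal(8)
  D <- patristic_distances(tr)
  labels <- c(1, 2, 1, 2, 1, 1, 1, 1)
  pops <- c(rep("a", 4), rep("b", 4))  # population b: all label 1
  r <- kst_permutation_test(D, labels, pops, n_perm = 50, seed = 2)
  expect_equal(r$per_population$weight[r$per_population$population == "b"], 0)
  expect_true(all(is.na(r$per_population$kst[
    r$per_population$population == "b"])))
  expect_gt(r$p_value, 0)
  expect_lte(r$p_value, 1)
})

test_that("Clopper-Pearson intervals match published-style rounding", {
  ci <- binomial_proportion_ci(88, 116)
  expect_equal(round(unname(ci), 2), c(0.67, 0.83))
  expect_equal(unname(binomial_proportion_ci(0, 10)["lower"]), 0)
  expect_equal(unname(binomial_proportion_ci(10, 10)["upper"]), 1)
  # agrees with the exact binomial test machinery
  bt <- binom.test(88, 116)$conf.int
  expect_equal(unname(ci), as.numeric(bt), tolerance = 1e-9)
  expect_error(binomial_proportion_ci(11, 10), "x <= n")
})

test_that("concordance counts agreements and lists discordant strains", {
  a <- setNames(rep("infected", 5), paste0("s", 1:5))
  b <- a; b["s3"] <- "uninfected"
  cc <- concordance(a, b)
  expect_equal(cc$fraction, 0.8)
  expect_equal(cc$discordant, "s3")
  expect_equal(concordance(a, a)$fraction, 1)
  expect_error(concordance(a, setNames(b, paste0("x", 1:5))), "same strains")
})

test_that("pi and theta recover the generator's diversity scale", {
  # on neutral coalescent data E[pi] = E[theta_w] = theta_true
  p <- small_params(n_strains = 10, mt_codons = 2000, loss_rate = 1,
                    gamma_shape = Inf,
                    class_rates = c(mt_codon12 = 1e-8, mt_codon3 = 1e-8,
                                    wol_codon12 = 0, wol_codon3 = 0,
                                    wol_noncoding = 0))
  theta_true <- 2 * p$effective_size * 1e-8  # haploid coalescent scaling
  pis <- thetas <- numeric(40)
  for (s in seq_len(40)) {
    h <- simulate_cytoplasmic_history(p, seed = s)
    a <- suppressWarnings(  # all strains uninfected by design
      evolve_alignments(h$tree, h$infected, p, seed = s))
    pis[s] <- nucleotide_diversity_pi(a$mt)
    thetas[s] <- watterson_theta(a$mt)
  }
  se_pi <- sd(pis) / sqrt(40)
  se_th <- sd(thetas) / sqrt(40)
  expect_lt(abs(mean(pis) - theta_true), 2.5 * se_pi + 0.05 * theta_true)
  expect_lt(abs(mean(thetas) - theta_true), 2.5 * se_th + 0.05 * theta_true)
})
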