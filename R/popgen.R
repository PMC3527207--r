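#' Nucleotide diversity (pi)
#'
#' Mean pairwise difference per site over all `n(n-1)/2` sequence pairs.
#'
#' @param aln A [partitioned_alignment] (or bare character matrix) with at
#'   least two rows.
#' @return Per-site pi.
#' @export
nucleotide_diversity_pi <- function(aln) {
  mat <- if (inherits(aln, "partitioned_alignment")) aln$mat else aln
  n <- nrow(mat)
  if (n < 2) stop("pi requires at least two sequences")
  if (ncol(mat) < 1) stop("alignment has no sites")
  diffs <- 0
  for (i in seq_len(n - 1))
    diffs <- diffs + sum(mat[rep(i, n - i), , drop = FALSE] !=
                           mat[(i + 1):n, , drop = FALSE])
  diffs / choose(n, 2) / ncol(mat)
}

# Count of variable sites (S) and total mutations (eta; a site with a
# alleles contributes a - 1 mutations under an infinite-ish-sites reading).
site_counts <- function(mat) {
  alleles <- apply(mat, 2, function(col) length(unique(col)))
  list(S = sum(alleles > 1), eta = sum(alleles - 1L))
}

#' Watterson's theta
#'
#' `theta = count / (a1 * L)` with `a1 = sum_{i=1}^{n-1} 1/i`. The default
#' count is eta, the total number of mutations (a site with more than two
#' alleles contributes one mutation per extra allele); `count = "S"` uses
#' the number of variable sites instead.
#'
#' @param aln Alignment (object or character matrix), `n >= 2` rows.
#' @param count `"eta"` (default) or `"S"`.
#' @return Per-site theta.
#' @export
watterson_theta <- function(aln, count = c("eta", "S")) {
  count <- match.arg(count)
  mat <- if (inherits(aln, "partitioned_alignment")) aln$mat else aln
  n <- nrow(mat)
  if (n < 2) stop("theta requires at least two sequences")
  sc <- site_counts(mat)
  a1 <- sum(1 / seq_len(n - 1))
  (if (count == "eta") sc$eta else sc$S) / (a1 * ncol(mat))
}

# Tajima (1989) variance constants, from n and S.
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Normalised difference between pairwise diversity and Watterson's
#' estimator from the number of segregating sites, sensitive to skews in
#' the site-frequency spectrum (an excess of rare variants gives negative
#' D). The variance constants use S, as in the original derivation.
#'
#' @param aln Alignment (object or character matrix).
#' @return Tajima's D. Errors when no site is variable (the statistic is
#'   undefined, not zero).
#' @export
tajimas_d <- function(aln) {
  mat <- if (inherits(aln, "partitioned_alignment")) aln$mat else aln
  n <- nrow(mat)
  sc <- site_counts(mat)
  if (sc$S == 0) stop("Tajima's D is undefined when S = 0")
  k <- tajima_constants(n)
  pi_total <- nucleotide_diversity_pi(mat) * ncol(mat)
  (pi_total - sc$S / k$a1) / sqrt(k$e1 * sc$S + k$e2 * sc$S * (sc$S - 1))
}

#' Neutral coalescent null distribution of Tajima's D, conditional on S
#'
#' Simulates constant-size Kingman coalescent genealogies without
#' recombination, places exactly `S` mutations on branches with probability
#' proportional to branch length, and computes Tajima's D for each
#' replicate. The p-value of an observed D is the lower-tail fraction of
#' simulated values `<=` the observation (matching tests against an excess
#' of rare variants), or twice the smaller tail when `tail = "two-sided"`.
#'
#' @param n Sample size (>= 2).
#' @param S Number of variable sites to condition on (>= 1).
#' @param n_reps Number of coalescent replicates.
#' @param seed Integer seed.
#' @param observed_d Optional observed D to be assigned a p-value.
#' @param tail `"lower"` (default) or `"two-sided"`.
#' @return List with `d` (simulated values), and when `observed_d` is
#'   given, `p_value`.
#' @export
conditional_coalescent_null <- function(n, S, n_reps = 10000, seed = 1,
                                        observed_d = NULL,
                                        tail = c("lower", "two-sided")) {
  tail <- match.arg(tail)
  stopifnot(n >= 2, S >= 1, n_reps >= 1)
  k <- tajima_constants(n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  npairs <- choose(n, 2)
  nseg <- n * (n + 1) / 2 - 1
  d <- with_seed(seed, vapply(seq_len(n_reps), function(rep) {
    w <- numeric(nseg)
    f <- integer(nseg)
    sizes <- rep(1L, n)
    pos <- 0L
    for (kk in n:2) {
      t_k <- stats::rexp(1, kk * (kk - 1) / 2)
      idx <- pos + seq_len(kk)
      w[idx] <- t_k
      f[idx] <- sizes
      pos <- pos + kk
      pair <- sample.int(kk, 2)
      sizes[pair[1]] <- sizes[pair[1]] + sizes[pair[2]]
      sizes <- sizes[-pair[2]]
    }
    hits <- sample.int(pos, S, replace = TRUE, prob = w[seq_len(pos)])
    freq <- f[hits]
    pi_total <- sum(freq * (n - freq)) / npairs
    (pi_total - S / k$a1) / denom
  }, numeric(1)))
  out <- list(d = d, n = n, S = S)
  if (!is.null(observed_d)) {
    lower <- mean(d <= observed_d)
    out$p_value <- if (tail == "lower") lower
                   else min(1, 2 * min(lower, mean(d >= observed_d)))
  }
  out
}

#' Kst differentiation statistic from a distance matrix
#'
#' `Kst = 1 - Ks / Kt` with `Ks = sum_i (n_i / n) Ki` (Ki the mean
#' pairwise distance within group i) and `Kt` the mean distance over all
#' pairs. Distances are typically patristic distances on a genealogy.
#'
#' @param D Symmetric distance matrix.
#' @param labels Binary group labels (logical or two-level vector), one per
#'   row of `D`.
#' @return Kst, or `NA` when undefined (both groups smaller than 2, or
#'   `Kt = 0`).
#' @export
kst_statistic <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (length(labels) != n) stop("one label per strain is required")
  groups <- split(seq_len(n), labels)
  if (length(groups) != 2) return(NA_real_)
  sizes <- lengths(groups)
  if (all(sizes < 2)) return(NA_real_)
  ut <- upper.tri(D)
  Kt <- mean(D[ut])
  if (Kt == 0) return(NA_real_)
  Ki <- vapply(groups, function(idx) {
    if (length(idx) < 2) return(0)
    sub <- D[idx, idx]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  Ks <- sum(sizes / n * Ki)
  1 - Ks / Kt
}

#' Permutation test of the weighted mean Kst across populations
#'
#' The observed statistic is the mean of per-population Kst values between
#' the two label groups, weighted by population sample size. Each
#' permutation shuffles the labels independently within each population
#' (samples from the same latitude/longitude), so geographic structure is
#' preserved under the null. Populations with an undefined Kst (uniform
#' labels, or fewer than two members in both groups) drop out of the
#' weighted mean in the observed and every permuted statistic alike.
#'
#' @param D Symmetric distance matrix (e.g. [patristic_distances()]).
#' @param labels Binary labels (e.g. infected/uninfected), one per strain.
#' @param populations Population identifier per strain.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return Object of class `"kst_result"`: `kst` (weighted mean),
#'   `per_population` (data frame of per-population Kst, sizes, weights),
#'   `p_value` (`(1 + #{perm >= obs}) / (1 + n_perm)`), `n_perm`, `seed`.
#' @export
kst_permutation_test <- function(D, labels, populations, n_perm = 1000,
                                 seed = 1) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(length(labels) == n, length(populations) == n, n_perm >= 1)
  pop_idx <- split(seq_len(n), populations)
  weighted_kst <- function(labs) {
    ks <- vapply(pop_idx, function(idx)
      kst_statistic(D[idx, idx, drop = FALSE], labs[idx]), numeric(1))
    ok <- !is.na(ks)
    if (!any(ok)) return(NA_real_)
    wt <- lengths(pop_idx)[ok]
    sum(ks[ok] * wt / sum(wt))
  }
  obs <- weighted_kst(labels)
  if (is.na(obs))
    stop("Kst undefined in every population (uniform labels?)")
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    labs <- labels
    for (idx in pop_idx) labs[idx] <- labels[idx][sample.int(length(idx))]
    weighted_kst(labs)
  }, numeric(1)))
  per_pop <- data.frame(
    population = names(pop_idx), n = lengths(pop_idx),
    kst = vapply(pop_idx, function(idx)
      kst_statistic(D[idx, idx, drop = FALSE], labels[idx]), numeric(1)))
  ok <- !is.na(per_pop$kst)
  per_pop$weight <- ifelse(ok, per_pop$n / sum(per_pop$n[ok]), 0)
  structure(list(kst = obs, per_population = per_pop,
                 p_value = (1 + sum(perm >= obs, na.rm = TRUE)) /
                   (1 + n_perm),
                 n_perm = n_perm, seed = seed, perm = perm),
            class = "kst_result")
}

#' @exportS3Method base::print
print.kst_result <- function(x, ...) {
  cat(sprintf("weighted mean Kst = %.4f, P = %.3g (%d permutations)\n",
              x$kst, x$p_value, x$n_perm))
  invisible(x)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
binomial_proportion_ci <- function(x, n, level = 0.95) {
  if (n < 1 || x < 0 || x > n) stop("need 0 <= x <= n and n >= 1")
  a <- (1 - level) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Concordance between two call sets
#'
#' @param calls_a,calls_b Named vectors over the same strain keys.
#' @return List with `n_agree`, `n_total`, `fraction`, and `discordant`
#'   (strain ids where the calls differ).
#' @export
concordance <- function(calls_a, calls_b) {
  if (!setequal(names(calls_a), names(calls_b)) || is.null(names(calls_a)))
    stop("both call sets must cover the same strains")
  b <- calls_b[names(calls_a)]
  agree <- calls_a == b
  list(n_agree = sum(agree), n_total = length(agree),
       fraction = mean(agree),
       discordant = names(calls_a)[!agree])
}

#' Diversity summary for one alignment
#'
#' N, L, S, eta, per-site pi and Watterson's theta (mutation-count
#' convention), Tajima's D, and its p-value under the conditional-on-S
#' neutral coalescent null.
#'
#' @param aln Alignment (object or matrix).
#' @param n_reps Coalescent replicates for the null (0 to skip).
#' @param seed Integer seed.
#' @return One-row data frame.
#' @export
diversity_summary <- function(aln, n_reps = 10000, seed = 1) {
  mat <- if (inherits(aln, "partitioned_alignment")) aln$mat else aln
  sc <- site_counts(mat)
  d <- if (sc$S > 0) tajimas_d(mat) else NA_real_
  p <- if (sc$S > 0 && n_reps > 0)
    conditional_coalescent_null(nrow(mat), sc$S, n_reps, seed,
                                observed_d = d)$p_value else NA_real_
  data.frame(N = nrow(mat), L = ncol(mat), S = sc$S, eta = sc$eta,
             pi = nucleotide_diversity_pi(mat),
             theta_w = watterson_theta(mat, "eta"),
             tajimas_d = d, p_value = p)
}
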