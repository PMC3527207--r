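#' Lognormal prior on a substitution rate
#'
#' Calibration prior for the mutation rate of a site class, parameterised
#' on the log scale: `mu_log` is the mean of `ln(rate)` and `sigma_log` its
#' standard deviation. The implied central rate is `exp(mu_log)` (the
#' distribution's median). The default values calibrate mitochondrial
#' third codon positions to a central rate of 6.2e-8
#' substitutions/site/generation.
#'
#' @param mu_log Mean of `ln(rate)`.
#' @param sigma_log Standard deviation of `ln(rate)` (>= 0).
#' @return Object of class `"rate_prior"` with fields `mu_log`,
#'   `sigma_log`, `central_rate`, and functions `density(rate)` (log
#'   density) and `quantile(p)`.
#' @export
lognormal_rate_prior <- function(mu_log = -16.59613, sigma_log = 1 / 3) {
  if (sigma_log < 0) stop("sigma_log must be non-negative")
  structure(list(
    mu_log = mu_log, sigma_log = sigma_log,
    central_rate = exp(mu_log),
    density = function(rate) {
      if (sigma_log == 0)
        return(ifelse(rate == exp(mu_log), Inf, -Inf))
      stats::dlnorm(rate, mu_log, sigma_log, log = TRUE)
    },
    quantile = function(p) {
      if (sigma_log == 0) return(rep(exp(mu_log), length(p)))
      stats::qlnorm(p, mu_log, sigma_log)
    }),
    class = "rate_prior")
}

#' @exportS3Method base::print
print.rate_prior <- function(x, ...) {
  cat(sprintf(paste0("lognormal rate prior: mu_log = %.5f, sigma_log = %.4f",
                     " (central rate %.3g)\n"),
              x$mu_log, x$sigma_log, x$central_rate))
  invisible(x)
}

#' Constant-size Kingman coalescent log prior on node ages
#'
#' Log density of the ordered coalescence times of an ultrametric genealogy
#' (tips at age zero) under a constant haploid effective population size:
#' with `k` lineages the waiting time is exponential with rate
#' `choose(k, 2) / Ne`, giving
#' `-(n-1) log Ne - sum_k choose(k,2) dt_k / Ne`.
#'
#' @param ages Ages of the `n - 1` internal nodes, in generations. When
#'   `tree` is supplied, `ages` must be indexed by ape node id
#'   (`ntip + 1 ... 2 ntip - 1`) and is validated for parent > child
#'   consistency.
#' @param effective_size Haploid effective size `Ne` (> 0), in generations.
#' @param tree Optional rooted `phylo` used only for consistency checking.
#' @return Log prior density.
#' @export
coalescent_tree_log_prior <- function(ages, effective_size, tree = NULL) {
  if (effective_size <= 0) stop("effective_size must be positive")
  if (any(ages < 0)) stop("ages must be non-negative")
  if (!is.null(tree)) {
    ntip <- ape::Ntip(tree)
    full <- c(rep(0, ntip), ages)
    internal <- tree$edge[, 2] > ntip
    if (any(full[tree$edge[, 1]] < full[tree$edge[, 2]] - 1e-9))
      stop("inconsistent ages: a child is older than its parent")
    ages <- full[(ntip + 1):(2 * ntip - 1)]
  }
  n <- length(ages) + 1
  s <- c(0, sort(ages))
  k <- n:2
  -(n - 1) * log(effective_size) -
    sum(choose(k, 2) * diff(s)) / effective_size
}

#' Fixed-topology Bayesian dating MCMC with site-class rate calibration
#'
#' Metropolis-Hastings sampler over node ages, per-class substitution
#' rates, per-class HKY+Gamma parameters (kappa, shape), and the coalescent
#' effective size, on a fixed rooted topology. Branch lengths for class
#' `c` are `rate_c x duration`, so a lognormal calibration prior on one
#' class (by default mitochondrial third codon positions) converts relative
#' node heights into absolute host generations; all other rates carry vague
#' log-uniform priors. Node ages get a constant-size Kingman coalescent
#' prior whose effective size is itself sampled.
#'
#' Proposals per sweep: uniform age re-draws for a random subset of
#' internal nodes, a multiplicative root-age move, a joint
#' ages-up/rates-down rescaling (likelihood-invariant, decorrelates the
#' time scale), and log-scale random walks on every rate, kappa, shape, and
#' the effective size.
#'
#' @param aln Concatenated [partitioned_alignment] whose classes are the
#'   rate categories (classes with no columns are dropped with a warning).
#' @param tree Rooted binary `phylo` topology over the alignment strains
#'   (branch lengths, if any, are ignored).
#' @param rate_prior A [lognormal_rate_prior()] for the calibration class.
#' @param calibration_class Name of the calibrated class (default
#'   `"mt.codon3"`).
#' @param n_iter Number of MCMC sweeps.
#' @param thin Keep every `thin`-th sweep.
#' @param seed Integer seed (chains are reproducible).
#' @param prior_only Switch the likelihood off (prior-recovery validation).
#' @param ncat Discrete-Gamma categories.
#' @param n_age_moves Internal-node age proposals per sweep.
#' @return Object of class `"dating_mcmc"`: `samples` (data frame of
#'   retained states), `tree`, `classes`, `calibration_class`,
#'   `acceptance` (per move type), and `settings`.
#' @export
run_dating_mcmc <- function(aln, tree, rate_prior = lognormal_rate_prior(),
                            calibration_class = "mt.codon3",
                            n_iter = 4000, thin = 5, seed = 1,
                            prior_only = FALSE, ncat = 4L,
                            n_age_moves = 5) {
  if (!ape::is.rooted(tree)) stop("topology must be rooted")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  # invariant classes carry no dating signal and destabilise the rate walk:
  # drop them (they re-enter nothing downstream) with a warning
  variant <- vapply(unique(aln$site_class), function(cl) {
    m <- aln$mat[, aln$site_class == cl, drop = FALSE]
    ncol(m) > 0 && any(m != m[rep(1, nrow(m)), ])
  }, logical(1))
  if (any(!variant)) {
    warning("dropping invariant/empty classes: ",
            paste(names(variant)[!variant], collapse = ", "))
    keep_cols <- aln$site_class %in% names(variant)[variant]
    aln <- partitioned_alignment(aln$mat[, keep_cols, drop = FALSE],
                                 aln$site_class[keep_cols],
                                 aln$ref_pos[keep_cols], aln$ref_id)
  }
  if (!calibration_class %in% aln$site_class)
    stop("calibration class not present in alignment: ", calibration_class)

  pd <- prep_partition_data(aln, tree)
  tree <- pd$tree
  ntip <- pd$ntip
  nint <- ntip - 1
  edge <- tree$edge
  classes <- pd$classes
  ncl <- length(classes)

  # crude empirical initialisation: anchor the time scale on the
  # calibration class at the prior's central rate
  pdist <- vapply(classes, function(cl) {
    m <- aln$mat[, aln$site_class == cl, drop = FALSE]
    if (ncol(m) == 0) return(0)
    mean(pairwise_distances(partitioned_alignment(
      m, rep(cl, ncol(m)), seq_len(ncol(m))), "raw"))
  }, numeric(1))
  L_cal <- sum(aln$site_class == calibration_class)
  root_guess <- max(pdist[calibration_class], 1 / L_cal) /
    (2 * rate_prior$central_rate)
  rates <- pmax(pdist / (2 * root_guess), 1e-13)
  rates[calibration_class] <- max(rates[calibration_class],
                                  rate_prior$central_rate)

  # valid starting ages: postorder stacking scaled to the root guess
  ages <- numeric(ntip + nint)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]
    ages[p] <- max(ages[p], ages[edge[e, 2]] + 1)
  }
  root <- edge[nrow(edge), 1]
  ages <- ages / ages[root] * root_guess

  kappa <- stats::setNames(rep(2, ncl), classes)
  alpha <- stats::setNames(rep(1, ncl), classes)
  Ne <- root_guess / 2
  freqs <- lapply(stats::setNames(classes, classes), function(cl)
    empirical_freqs(aln$mat[, aln$site_class == cl, drop = FALSE]))

  models <- lapply(stats::setNames(classes, classes), function(cl)
    hky_model(kappa[[cl]], freqs[[cl]], alpha[[cl]], ncat))
  durations <- function(ages) ages[edge[, 1]] - ages[edge[, 2]]
  class_ll_one <- function(cl, dur, rate, model) {
    if (prior_only) return(0)
    cpp_partition_loglik(edge, dur, ntip, pd$patterns[[cl]]$tip_pat,
                         pd$patterns[[cl]]$weights, model$eigen$V,
                         model$eigen$d, model$eigen$Vinv, model$freqs,
                         model$cat_rates, rate)
  }
  rate_log_prior <- function(cl, r) {
    if (r <= 0) return(-Inf)
    if (cl == calibration_class) rate_prior$density(r)
    else if (r < 1e-13 || r > 1e-5) -Inf else -log(r)
  }
  log_unif <- function(x, lo, hi) if (x < lo || x > hi) -Inf else -log(x)

  dur <- durations(ages)
  ll <- vapply(classes, function(cl)
    class_ll_one(cl, dur, rates[[cl]], models[[cl]]), numeric(1))
  age_prior <- coalescent_tree_log_prior(ages[(ntip + 1):(ntip + nint)], Ne)
  rp <- vapply(classes, function(cl) rate_log_prior(cl, rates[[cl]]),
               numeric(1))

  internal_nonroot <- setdiff((ntip + 1):(ntip + nint), root)
  parent_of <- integer(ntip + nint)
  parent_of[edge[, 2]] <- edge[, 1]
  children_of <- split(edge[, 2], edge[, 1])

  n_keep <- floor(n_iter / thin)
  cols <- c(paste0("rate_", classes), paste0("kappa_", classes),
            paste0("alpha_", classes), "Ne", "root_age",
            paste0("age_", (ntip + 1):(ntip + nint)), "loglik")
  samples <- matrix(NA_real_, n_keep, length(cols),
                    dimnames = list(NULL, cols))
  acc <- c(age = 0, root = 0, scale = 0, rate = 0, kappa = 0, alpha = 0,
           Ne = 0)
  try_n <- acc

  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      # -- individual node ages ------------------------------------------
      for (v in sample(internal_nonroot,
                       min(n_age_moves, length(internal_nonroot)))) {
        lo <- max(ages[children_of[[as.character(v)]]])
        hi <- ages[parent_of[v]]
        prop <- ages
        prop[v] <- stats::runif(1, lo, hi)
        pdur <- durations(prop)
        pll <- vapply(classes, function(cl)
          class_ll_one(cl, pdur, rates[[cl]], models[[cl]]), numeric(1))
        pap <- coalescent_tree_log_prior(prop[(ntip + 1):(ntip + nint)], Ne)
        try_n["age"] <- try_n["age"] + 1
        if (log(stats::runif(1)) < sum(pll) - sum(ll) + pap - age_prior) {
          ages <- prop; ll <- pll; age_prior <- pap
          acc["age"] <- acc["age"] + 1
        }
      }
      # -- root age ------------------------------------------------------
      f <- exp(stats::runif(1, -0.2, 0.2))
      prop <- ages
      prop[root] <- ages[root] * f
      try_n["root"] <- try_n["root"] + 1
      if (prop[root] > max(ages[children_of[[as.character(root)]]])) {
        pdur <- durations(prop)
        pll <- vapply(classes, function(cl)
          class_ll_one(cl, pdur, rates[[cl]], models[[cl]]), numeric(1))
        pap <- coalescent_tree_log_prior(prop[(ntip + 1):(ntip + nint)], Ne)
        if (log(stats::runif(1)) <
            sum(pll) - sum(ll) + pap - age_prior + log(f)) {
          ages <- prop; ll <- pll; age_prior <- pap
          acc["root"] <- acc["root"] + 1
        }
      }
      # -- joint time rescaling (likelihood invariant) -------------------
      f <- exp(stats::runif(1, -0.3, 0.3))
      prop_ages <- ages * f
      prop_rates <- rates / f
      pap <- coalescent_tree_log_prior(
        prop_ages[(ntip + 1):(ntip + nint)], Ne)
      prp <- vapply(classes, function(cl)
        rate_log_prior(cl, prop_rates[[cl]]), numeric(1))
      try_n["scale"] <- try_n["scale"] + 1
      if (all(is.finite(prp)) &&
          log(stats::runif(1)) < pap - age_prior + sum(prp) - sum(rp) +
            (nint - ncl) * log(f)) {
        ages <- prop_ages; rates <- prop_rates
        age_prior <- pap; rp <- prp
        acc["scale"] <- acc["scale"] + 1
      }
      dur <- durations(ages)
      # -- per-class parameters ------------------------------------------
      for (cl in classes) {
        r2 <- rates[[cl]] * exp(stats::rnorm(1, 0, 0.25))
        prp1 <- rate_log_prior(cl, r2)
        try_n["rate"] <- try_n["rate"] + 1
        if (is.finite(prp1)) {
          pll1 <- class_ll_one(cl, dur, r2, models[[cl]])
          if (log(stats::runif(1)) <
              pll1 - ll[[cl]] + prp1 - rp[[cl]] + log(r2 / rates[[cl]])) {
            rates[[cl]] <- r2; ll[[cl]] <- pll1; rp[[cl]] <- prp1
            acc["rate"] <- acc["rate"] + 1
          }
        }
        if (!prior_only) {
          k2 <- kappa[[cl]] * exp(stats::rnorm(1, 0, 0.2))
          try_n["kappa"] <- try_n["kappa"] + 1
          if (is.finite(log_unif(k2, 0.2, 60))) {
            m2 <- hky_model(k2, freqs[[cl]], alpha[[cl]], ncat)
            pll1 <- class_ll_one(cl, dur, rates[[cl]], m2)
            if (log(stats::runif(1)) <
                pll1 - ll[[cl]] + log(k2 / kappa[[cl]])) {
              kappa[[cl]] <- k2; models[[cl]] <- m2; ll[[cl]] <- pll1
              acc["kappa"] <- acc["kappa"] + 1
            }
          }
          a2 <- alpha[[cl]] * exp(stats::rnorm(1, 0, 0.3))
          try_n["alpha"] <- try_n["alpha"] + 1
          if (is.finite(log_unif(a2, 0.05, 50))) {
            m2 <- hky_model(kappa[[cl]], freqs[[cl]], a2, ncat)
            pll1 <- class_ll_one(cl, dur, rates[[cl]], m2)
            if (log(stats::runif(1)) <
                pll1 - ll[[cl]] + log(a2 / alpha[[cl]])) {
              alpha[[cl]] <- a2; models[[cl]] <- m2; ll[[cl]] <- pll1
              acc["alpha"] <- acc["alpha"] + 1
            }
          }
        }
      }
      # -- effective size (prior-only update) ----------------------------
      N2 <- Ne * exp(stats::rnorm(1, 0, 0.4))
      try_n["Ne"] <- try_n["Ne"] + 1
      if (N2 >= 1e2 && N2 <= 1e9) {
        pap <- coalescent_tree_log_prior(ages[(ntip + 1):(ntip + nint)], N2)
        if (log(stats::runif(1)) < pap - age_prior + log(N2 / Ne)) {
          Ne <- N2; age_prior <- pap
          acc["Ne"] <- acc["Ne"] + 1
        }
      }
      if (it %% thin == 0) {
        samples[it / thin, ] <- c(rates, kappa, alpha, Ne, ages[root],
                                  ages[(ntip + 1):(ntip + nint)], sum(ll))
      }
    }
  })
  structure(list(samples = as.data.frame(samples), tree = tree,
                 classes = classes, calibration_class = calibration_class,
                 acceptance = acc / pmax(try_n, 1),
                 settings = list(n_iter = n_iter, thin = thin, seed = seed,
                                 prior_only = prior_only, ncat = ncat)),
            class = "dating_mcmc")
}

#' Summarise a dating posterior
#'
#' Medians and central 95% credible intervals for the per-class rates and
#' node ages after burn-in, with ages converted from host generations to
#' years by a fixed generations-per-year factor (default 10).
#'
#' @param chain A `"dating_mcmc"` object (or a list of chains from
#'   independent seeds, which are pooled after a split-Rhat check).
#' @param generations_per_year Generations per year (default 10).
#' @param burnin Fraction of retained samples to discard (default 0.25).
#' @return Object of class `"posterior_summary"`: data frames `rates`
#'   (median and 95% CI per class, substitutions/site/generation) and
#'   `ages` (per node, generations and years), `effective_size` median,
#'   `acceptance`, `rhat` (split-Rhat per rate), and `seed`.
#' @export
summarize_posterior <- function(chain, generations_per_year = 10,
                                burnin = 0.25) {
  chains <- if (inherits(chain, "dating_mcmc")) list(chain) else chain
  post <- lapply(chains, function(ch) {
    s <- ch$samples[stats::complete.cases(ch$samples), , drop = FALSE]
    nb <- floor(nrow(s) * burnin)
    if (nb > 0) s <- s[-seq_len(nb), , drop = FALSE]
    s
  })
  if (!nrow(post[[1]])) stop("no post-burn-in samples")
  classes <- chains[[1]]$classes
  rhat <- vapply(paste0("rate_", classes), function(v)
    split_rhat(lapply(post, function(p) p[[v]])), numeric(1))
  pooled <- do.call(rbind, post)
  q <- function(v) stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE)
  rates <- do.call(rbind, lapply(classes, function(cl) {
    qq <- q(pooled[[paste0("rate_", cl)]])
    data.frame(class = cl, median = qq[1], ci_lower = qq[2],
               ci_upper = qq[3])
  }))
  age_cols <- grep("^age_", names(pooled), value = TRUE)
  ages <- do.call(rbind, lapply(age_cols, function(v) {
    qq <- q(pooled[[v]])
    data.frame(node = as.integer(sub("age_", "", v)),
               median_gen = qq[1], ci_lower_gen = qq[2],
               ci_upper_gen = qq[3],
               median_years = qq[1] / generations_per_year,
               ci_lower_years = qq[2] / generations_per_year,
               ci_upper_years = qq[3] / generations_per_year)
  }))
  structure(list(rates = rates, ages = ages,
                 root_age_years = q(pooled$root_age)[1] /
                   generations_per_year,
                 effective_size = stats::median(pooled$Ne),
                 generations_per_year = generations_per_year,
                 acceptance = chains[[1]]$acceptance, rhat = rhat,
                 seed = vapply(chains, function(ch) ch$settings$seed,
                               numeric(1))),
            class = "posterior_summary")
}

#' @exportS3Method base::print
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary (ages in years at",
      x$generations_per_year, "generations/year)\n")
  cat(sprintf("  root age (median): %.0f years\n", x$root_age_years))
  print(x$rates, row.names = FALSE)
  invisible(x)
}

# Split-Rhat of one scalar parameter over one or more chains.
split_rhat <- function(draws_per_chain) {
  halves <- unlist(lapply(draws_per_chain, function(v) {
    m <- floor(length(v) / 2)
    list(v[seq_len(m)], v[(m + 1):(2 * m)])
  }), recursive = FALSE)
  mns <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  n <- length(halves[[1]])
  W <- mean(vars)
  B <- n * stats::var(mns)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
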