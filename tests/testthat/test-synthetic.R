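test_that("parameter validation rejects impossible settings", {
  expect_error(synthetic_params(n_strains = 1), "at least 2")
  expect_error(synthetic_params(loss_rate = -1), "non-negative")
  expect_error(synthetic_params(base_freqs = c(0.5, 0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("loss-rate limits give all-infected and all-uninfected samples", {
  p0 <- small_params(loss_rate = 0)
  h0 <- simulate_cytoplasmic_history(p0)
  expect_true(all(h0$infected))
  pbig <- small_params(loss_rate = 1)  # ~40k expected losses per branch
  hbig <- simulate_cytoplasmic_history(pbig)
  expect_false(any(hbig$infected))
})

test_that("coalescent ages have the analytic expected TMRCA", {
  # E[TMRCA] = 2(1 - 1/n) in units of the effective size
  p <- small_params(n_strains = 4, effective_size = 1)
  tmrca <- vapply(seq_len(3000), function(i) {
    max(simulate_cytoplasmic_history(p, seed = i)$ages)
  }, numeric(1))
  expect_equal(mean(tmrca), 2 * (1 - 1 / 4), tolerance = 0.05)
})

test_that("infection labels are consistent with single gain, multiple loss", {
  # no strain is infected if any ancestor edge carries a loss
  for (s in 1:10) {
    h <- simulate_cytoplasmic_history(small_params(loss_rate = 2e-5), seed = s)
    for (tip in seq_along(h$infected)) {
      on_path <- cytosym:::path_edges(h$tree, tip)
      expect_identical(unname(h$infected[tip]),
                       !any(on_path %in% h$loss_edges))
    }
  }
})

test_that("zero rates copy the root sequence to every strain", {
  p <- small_params(class_rates = c(mt_codon12 = 0, mt_codon3 = 0,
                                    wol_codon12 = 0, wol_codon3 = 0,
                                    wol_noncoding = 0), loss_rate = 0)
  h <- simulate_cytoplasmic_history(p)
  tr <- evolve_alignments(h$tree, h$infected, p)
  expect_equal(unname(apply(tr$mt$mat, 1, paste, collapse = "")),
               rep(tr$references[["mtDNA"]], p$n_strains))
  expect_equal(nrow(tr$wol$mat), p$n_strains)
})

test_that("two-strain divergence matches the small-rate expansion", {
  # expected raw pairwise difference ~ 2 t r per site for small t*r
  r <- 5e-9
  p <- small_params(n_strains = 2, mt_codons = 30000,
                    class_rates = c(mt_codon12 = r, mt_codon3 = r,
                                    wol_codon12 = 0, wol_codon3 = 0,
                                    wol_noncoding = 0),
                    loss_rate = 1, gamma_shape = Inf)
  divs <- ts <- numeric(8)
  for (s in seq_len(8)) {
    h <- simulate_cytoplasmic_history(p, seed = s)
    ts[s] <- max(h$ages)
    a <- suppressWarnings(  # deliberately uninfected sample
      evolve_alignments(h$tree, h$infected, p, seed = s))
    divs[s] <- mean(a$mt$mat[1, ] != a$mt$mat[2, ])
  }
  expect_equal(mean(divs), mean(2 * ts * r), tolerance = 0.15)
})

test_that("raising the third-position rate does not reduce variable sites", {
  count_var <- function(mult, seed) {
    p <- small_params(class_rates = c(mt_codon12 = 1.36e-8,
                                      mt_codon3 = 6.89e-8 * mult,
                                      wol_codon12 = 0, wol_codon3 = 0,
                                      wol_noncoding = 0),
                      loss_rate = 1, mt_codons = 2000, seed = seed)
    h <- simulate_cytoplasmic_history(p, seed = seed)
    a <- suppressWarnings(  # deliberately uninfected sample
      evolve_alignments(h$tree, h$infected, p, seed = seed))
    third <- a$mt$mat[, a$mt$site_class == "codon3", drop = FALSE]
    sum(apply(third, 2, function(x) length(unique(x)) > 1))
  }
  base <- vapply(1:6, function(s) count_var(1, s), numeric(1))
  doubled <- vapply(1:6, function(s) count_var(2, s), numeric(1))
  expect_gte(mean(doubled), mean(base))
})

test_that("depth profiles follow the configured means and infection labels", {
  p <- small_params(contamination_fraction = 0, loss_rate = 2e-5)
  sim <- simulate_cytoplasm(p)
  uninf <- names(sim$history$infected)[!sim$history$infected]
  for (s in uninf)
    expect_true(all(sim$profiles[[s]]$wolbachia$depth == 0))
  inf <- names(sim$history$infected)[sim$history$infected]
  if (length(inf)) {
    md <- mean(sim$profiles[[inf[1]]]$wolbachia$depth)
    expect_equal(md, p$depth_means[["wolbachia"]], tolerance = 0.1)
  }
  # high depth at 10 kb scale gives near-complete consensus breadth
  cc <- call_consensus(sim$profiles[[inf[1]]]$mtDNA$counts)
  expect_gt(breadth_of_coverage(cc), 0.99)
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_cytoplasm(small_params(seed = 42))
  b <- simulate_cytoplasm(small_params(seed = 42))
  expect_identical(a$truth$mt$mat, b$truth$mt$mat)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$truth_record, b$truth_record)
})

test_that("fixture bundles round-trip through the readers", {
  dir <- withr::local_tempdir()
  p <- small_params(n_strains = 5, mt_codons = 800)
  sim <- make_fixture_bundle(p, dir)
  bundle <- read_fixture_bundle(dir)
  expect_setequal(bundle$metadata$strain_id, names(sim$profiles))
  s1 <- bundle$metadata$strain_id[1]
  expect_equal(bundle$profiles[[s1]]$mtDNA$depth,
               sim$profiles[[s1]]$mtDNA$depth)
  expect_equal(unname(bundle$references["mtDNA"]),
               unname(sim$truth$references["mtDNA"]))
  expect_equal(sort(names(which(unlist(bundle$truth_record$infected)))),
               sort(names(which(sim$history$infected))))
  # strains with any endosymbiont coverage = truth-infected + contaminated
  with_depth <- vapply(bundle$profiles, function(pr)
    mean(pr$wolbachia$depth) > 0, logical(1))
  expect_setequal(names(which(with_depth)),
                  union(names(which(unlist(bundle$truth_record$infected))),
                        bundle$truth_record$contaminated))

  # identical seed, identical file contents
  dir2 <- withr::local_tempdir()
  make_fixture_bundle(p, dir2)
  f1 <- list.files(dir, recursive = TRUE)
  expect_identical(f1, list.files(dir2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})
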