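---
title: "Models and methods behind cytosym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cytosym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

cytosym analyses maternally co-inherited cytoplasmic genomes — an
intracellular endosymbiont such as *Wolbachia* and the host mitochondrial
genome — from whole-genome shotgun data. The pipeline covers: calling
endosymbiont infection status from depth and breadth of coverage;
consensus assembly from per-site base counts; relative copy-number
estimation; gap-free partitioned alignments; neighbor-joining genealogies
with bootstrap support; a single- versus two-topology congruence test;
fixed-topology Bayesian dating with a mutation-rate calibration prior;
discrete phylogeography; population-genetic statistics; and marker-level
genotyping (IS5 insertion junctions, diagnostic mtDNA SNPs, COI
haplotypes). A coalescent synthetic-data generator makes every stage
testable without any external sequence downloads.

# The transmission model and the synthetic generator

The biological model is a single ancestral infection transmitted strictly
through the maternal cytoplasm with occasional loss (imperfect maternal
transmission). Under this model the endosymbiont and the mtDNA share one
genealogy, and uninfected strains are scattered across the mtDNA tree
rather than forming their own clade.

`synthetic_params()` encodes these assumptions:

* **Genealogy.** A Kingman coalescent for `n_strains` samples
  (`ape::rcoal`), with branch lengths multiplied by the haploid effective
  size so that all times are in host generations. The default
  `effective_size = 40000` puts the expected sample MRCA near
  `2(1 - 1/n) * 40000 ~ 75,000` generations, i.e. roughly 7,500 years at
  the ten-generations-per-year convention used throughout.
* **Infection.** The root lineage is infected; loss events are Poisson
  with rate `loss_rate` per branch per generation, and a strain is
  uninfected iff a loss lies on its root-to-tip path. No quantitative
  loss rate is available for this system, so the default
  (`6e-6`/generation) was chosen once so that the expected infected
  fraction is near the ~60% observed in large resequencing panels; it is
  documented as arbitrary and is a parameter, not a constant.
* **Sequence evolution.** Five site classes evolve under a shared
  HKY+Gamma model with class-specific rates: mt codon 1+2, mt codon 3,
  endosymbiont codon 1+2, codon 3, and noncoding. Default class rates are
  the median short-term evolutionary rates estimated for this system
  (6.9e-8 substitutions/site/generation at mt third positions, ~100-fold
  lower for the endosymbiont classes). The discrete-Gamma uses four
  equal-probability categories with category means (Yang-style); the
  category count is configurable.
* **Sequence lengths.** The mtDNA coding partition is kept at its real
  scale (9,900 coding sites). The endosymbiont partitions are
  desk-scaled to ~147 kb (about one sixth of the real genome), chosen so
  the expected number of endosymbiont variable sites (~25 under default
  rates) preserves the topological signal that the congruence test needs.
  Tests that need different sizes set them explicitly.
* **Coverage.** Per-base depths are Poisson with role-specific means
  (mtDNA 50, endosymbiont 20, nuclear control 10 by default). Uninfected
  strains have zero endosymbiont depth, except a configurable
  contamination fraction that receives 500-bp blocks of low coverage over
  ~40% of the genome — reproducing the "intermediate breadth" strains
  seen in real panels, which the breadth threshold correctly leaves
  uninfected. Base counts carry a 0.1% default per-read error rate, so
  consensus support at variable sites sits near 99.9% at depth 20.

What the generator does **not** emulate: read-level artefacts (mapping
error, strand bias, indels beyond the deletion column), recombination,
paternal or horizontal transmission, and within-strain heteroplasmy.
Green tests therefore demonstrate correctness of the statistical
machinery under the co-inheritance model, not robustness to alignment
artefacts in real data.

# Infection calling

A strain is scored infected when consensus breadth exceeds 0.90 of the
endosymbiont genome **and** mean depth exceeds 1 read/site; both
inequalities are strict, and both thresholds are exposed as configuration
with these defaults. Mean depth averages over all reference positions,
including uncovered ones. The consensus rule is a majority call with a
10–100x depth window: sites below 10 or above 100 reads become N, a
plurality of deletion-supporting reads becomes N, and ties become N;
insertions relative to the reference are ignored. This majority-with-tie
rule replaces the original pileup-tool consensus (the published analysis
pinned a tool, not a rule) and is documented as a dialect. All
coordinates in files and reports are 1-based inclusive; internally R's
1-based indexing is used throughout.

Relative copy number is `(target depth / nuclear depth) / ploidy`, where
ploidy is 2 for libraries made from diploid adults and 1 for haploid
embryos, giving copies per haploid genome equivalent.

# Likelihoods, trees, and the congruence test

The likelihood engine is Felsenstein pruning over HKY+Gamma with
per-class rate multipliers, implemented in C++ on compressed site
patterns; it is validated in the test suite against exhaustive
internal-state enumeration (<= 5 taxa, 1e-8 agreement) and against an
independent phylogenetic likelihood implementation. Topologies come from
neighbor joining (negative branch estimates clamped to zero) rather than
a heuristic ML search — a deliberate scope reduction; fixed-topology ML
branch lengths are then fitted by coordinate-wise Brent optimisation.
Bootstrap support is column resampling with NJ rebuilds. Midpoint
rooting places the root on the longest tip-to-tip path, breaking ties by
the lexicographically smallest tip pair.

The congruence test compares a single-topology model (one topology from
the concatenated data, shared branch lengths, one free rate multiplier
for the second partition) against a two-topology model (independent NJ
topology and branch lengths per genome). Each partition contributes
kappa, Gamma shape, and three free base frequencies (empirical
frequencies, counted in k); the AIC penalty difference is therefore
`2((2n-3) - 1)`. A positive `delta AIC = AIC_two - AIC_single` supports
co-inheritance. The published analysis also reports a log10 Bayes factor
from harmonic-mean marginal likelihoods; `harmonic_mean_lnml()` and
`model_comparison()` implement that arithmetic (the AICM variant of the
information criterion is not implemented, as its exact penalty is not
recoverable). Negative controls permute the endosymbiont-to-host pairing
within geographic strata (location, continent, or globally).

# Dating MCMC

`run_dating_mcmc()` is a fixed-topology Metropolis–Hastings sampler over
node ages, five class rates, per-class kappa and Gamma shape, and the
coalescent effective size. Branch lengths for class *c* are
`rate_c x duration`, a strict clock per class. The time scale is
identified by a lognormal prior on the mt third-position rate with
`mu_log = -16.59613` and `sigma_log = 1/3`: the mean of ln(rate), so the
implied central rate is `exp(mu_log) = 6.2e-8` substitutions/site/
generation (the distribution's median). Other rates carry log-uniform
priors on [1e-13, 1e-5]; kappa, shape and the effective size carry
log-uniform priors on generous ranges. Node ages take a constant-size
Kingman coalescent prior whose effective size is itself sampled.

Proposals per sweep: uniform re-draws of a random subset of internal-node
ages within their parent/child bounds (Hastings ratio 1), a
multiplicative root move, a joint "ages up / rates down" rescaling that
leaves the likelihood invariant and decorrelates the time scale from the
rates, and log-scale random walks on every scalar. Invariant site
classes are dropped with a warning before sampling — they carry no
dating signal and destabilise the rate walk. Ages are converted to years
by dividing by ten generations per year, exactly. Convergence can be
checked by running chains under several seeds and inspecting the
split-Rhat column of `summarize_posterior()`.

Default problem sizes in the tests and the acceptance script — 15
strains, 3 kb of mt third positions, 10 kb of endosymbiont sequence,
2,000–2,500 sweeps thinned by 5 with 25% burn-in — were chosen as the
smallest sizes at which prior-recovery and parameter-recovery checks are
stable; they are the package's reference configuration for replicate
experiments, and all are arguments.

# Phylogeography

Ancestral locations are modelled by a three-state non-reversible CTMC
(all six off-diagonal rates free) estimated by maximum likelihood on the
fixed dated tree, rather than jointly inside the MCMC. The root prior is
the stationary distribution of the fitted rate matrix — the convention
of Bayesian discrete phylogeography. This choice matters: under a
uniform root prior the all-tips-in-one-region case becomes
unidentifiable, because an absorbing rate matrix explains the data
perfectly from any root state; under the stationary prior the root
collapses onto the observed region, as it should. Marginal node
probabilities combine below- and above-tree partial likelihoods; a
`root_prior` argument allows overriding the default.

# Population genetics

pi is the mean pairwise difference per site; Watterson's theta uses the
total number of mutations eta by default (a site with *a* alleles
contributes *a* - 1), with `count = "S"` available; Tajima's D uses S in
its variance constants, as its derivation requires, even when theta is
reported from eta. Significance of D comes from a neutral coalescent
null conditioned on S: exactly S mutations are placed on branches with
probability proportional to branch length, with a lower-tail p-value by
default. A property worth knowing: conditioning on S makes the null mean
of D slightly negative (about -0.10 at n = 91, S = 115; verified against
an independent coalescent simulator), so "centred near zero" holds only
to that accuracy.

The Kst statistic (1 minus the size-weighted within-group mean distance
over the total mean distance) is computed from **patristic** distances
on the genealogy, a deliberate variant of the classical
sequence-difference version. The cross-population summary weights
per-population Kst values by population sample size — the published
weighting is unspecified, so this choice is exposed as the
`per_population` table. Significance comes from permuting infection
labels within populations (same latitude/longitude); the p-value uses
the +1 correction so it can never be zero.

The exact binomial confidence interval is Clopper–Pearson. A two-sided
Fisher exact test is the recommended route for comparing infection
frequencies between panels; the originally reported "binomial test" for
that contrast is ambiguous and is not reproduced.

# Marker genotyping

IS5 presence at the two diagnostic loci is decided by junction-read
counting: probes spanning each junction (default overhang 20 bp on each
side) are matched exactly (or with a configurable substitution budget)
against the reads in both orientations; `present` requires at least
`min_junction_reads = 3` insertion-junction reads with the empty-site
signal below threshold, and reads of 75 bp or shorter are refused as
indeterminate. This replaces the original BLAT-based mapping with a
self-contained seed-matching procedure. The genotype truth table is:
present/absent = wMel-like, absent/present = wMelCS-like, absent/absent
= wMel3, anything else indeterminate. Diagnostic mtDNA SNPs at
positions 2160/2187 (T/C = wMelCS-type, C/T = wMel-type) are read from
the consensus; their anchoring to the mtDNA reference frame is a
configurable argument because the original coordinate system is not
fully specified. COI haplotypes are matched N-tolerantly against a
reference table, with novel haplotypes numbered sequentially from 20; a
query matching several table entries after N-masking is left
unassigned.

# Numerical choices and degenerate inputs

* HKY transition probabilities come from the symmetrised eigen
  decomposition; tiny negative entries are clamped and rows
  renormalised.
* Site patterns are compressed before likelihood evaluation; site
  likelihoods are floored at 1e-300 before logging.
* Brent optimisation of branch lengths uses tolerance 1e-7 per branch;
  lengths below 1e-9 are reported as exact zeros.
* Jukes–Cantor distances refuse p >= 0.75 (saturation) with an error.
* A zero-diameter tree is rooted at its first internal node with a
  warning. Kst is NA when both groups have fewer than two members or
  the total mean distance is zero; populations with undefined Kst drop
  out of the weighted mean consistently in the observed and permuted
  statistics.
* Tajima's D raises an error at S = 0 rather than returning 0.

# Known limitations

Topologies are never sampled (fixed NJ topologies stand in for ML/BEAST
searches); the harmonic-mean marginal likelihood estimator is known to
be upward-biased and is provided because it is the published comparison,
not because it is the best available estimator; the generator's
contamination model is block-uniform rather than read-level; and the
dating sampler assumes a strict clock per class. Real-data BAM/VCF
ingestion is out of scope — the readers accept per-base depth and
base-count tables, which standard tooling produces readily.
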