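# cytosym

Co-inheritance analysis of endosymbiont and mitochondrial genomes from
whole-genome shotgun data.

Maternally transmitted endosymbionts such as *Wolbachia* ride in the same
cytoplasm as the host's mitochondria. If transmission is strictly
maternal from a single ancestral infection, the endosymbiont and the
mtDNA share one genealogy; imperfect transmission then scatters
uninfected strains across that genealogy instead of clustering them.
cytosym implements the complete analysis that tests and exploits this
model in a resequencing panel:

* **Infection calling** from shotgun coverage: a strain is infected when
  consensus breadth > 0.90 of the endosymbiont genome **and** mean depth
  > 1 read/site (strict inequalities, both configurable), with majority
  consensus calling inside a 10–100x depth window and relative copy
  number `(target/nuclear)/ploidy`.
* **Genealogies**: gap-free partitioned alignments (every column with an
  N in any strain removed), neighbor joining with column-resampling
  bootstrap, midpoint rooting, patristic distances.
* **Congruence test**: single- vs two-topology fits under partitioned
  HKY+Γ likelihoods, compared by `ΔAIC = AIC_two − AIC_single` and by a
  log10 Bayes factor from harmonic-mean log marginal likelihoods
  (`log10 BF = (lnML_single − lnML_two)/ln 10`), with geographic
  randomization controls.
* **Dating**: fixed-topology Bayesian MCMC over node ages and five
  site-class rates (mt codon 1+2, mt codon 3, endosymbiont codon 1+2,
  codon 3, noncoding), calibrated by a lognormal prior on the mt
  third-position rate (`μ_log = −16.59613`, `σ_log = 1/3`, central rate
  `exp(μ_log) = 6.2×10⁻⁸` substitutions/site/generation), ages converted
  to years at 10 generations/year; plus a 3-region non-reversible CTMC
  phylogeography on the dated tree.
* **Population genetics**: π, Watterson's θ (from total mutations),
  Tajima's D with significance from a neutral coalescent null
  conditioned on the number of variable sites, a patristic-distance Kst
  permutation test (labels permuted within populations), Clopper–Pearson
  intervals, and call-set concordance.
* **Marker genotyping**: IS5 insertion presence at the two diagnostic
  loci by junction-read counting (wMel-like / wMelCS-like / wMel3),
  diagnostic mtDNA SNPs at 2160/2187, and COI haplotype assignment with
  novel haplotypes numbered from 20.
* **Synthetic data**: a coalescent generator with imperfect maternal
  transmission (Poisson loss events on branches), five-class HKY+Γ
  sequence evolution, and Poisson depth/base-count profiles — so the
  entire pipeline is testable offline, against a known truth record.

## Worked example

```r
library(cytosym)

params <- synthetic_params(n_strains = 8, seed = 7)
cfg <- pipeline_config(synthetic = params, kst_permutations = 500,
                       null_reps = 1000, seed = 7)
out <- run_pipeline(cfg)

out$calls[, c("strain_id", "mean_depth", "breadth", "status",
              "relative_copy_number")]
#>   strain_id mean_depth breadth     status relative_copy_number
#> 1       s07          0   0.000 uninfected                0.000
#> 2       s04         20   0.995   infected                1.001
#> ...
#> 6       s01         20   0.995   infected                2.007
#> 7       s03          0   0.000 uninfected                0.000

out$congruence
#> Topology-congruence model comparison
#>   lnL  single: -208760.38  two: -208752.47
#>   AIC  single: 417560.8  two: 417560.9  (delta = 0.2)
#>   favoured: single topology (congruent genealogies)

out$diversity[, c("genome", "N", "L", "S", "pi", "theta_w",
                  "tajimas_d", "p_value")]
#>               genome N      L  S       pi  theta_w tajimas_d p_value
#> 1 wolbachia_infected 6 142599  9 0.000021 2.76e-05     -1.42   0.097
#> 2     mtDNA_infected 6   9900 34 0.001266 1.50e-03     -1.01   0.184
#> 3          mtDNA_all 8   9900 43 0.001266 1.68e-03     -1.31   0.098
```

Reading the output: six of eight strains carry the endosymbiont at full
breadth (0.995) and ~1–2 genome copies per haploid genome equivalent;
the two uninfected strains arose by loss events on the shared genealogy.
The congruence comparison favours the single-topology model (positive
ΔAIC), i.e. the endosymbiont and mtDNA data are consistent with one
shared genealogy — as they must be, since this dataset was simulated
under strict co-transmission. The diversity table mirrors the standard
per-genome polymorphism summary (N strains, L sites, S variable sites,
π, θ per site, Tajima's D with its conditional-coalescent p-value).

Lower-level entry points (`call_consensus()`, `classify_infection()`,
`fit_topology_models()`, `run_dating_mcmc()`, `kst_permutation_test()`,
`detect_is5_presence()`, ...) are documented individually; the methods
vignette (`vignettes/cytosym-methods.Rmd`) explains the models, priors,
defaults, and their rationale. A thin command-line wrapper is installed
at `inst/cli/cytosym` (subcommands `simulate`, `call-infection`,
`congruence`, `diversity`, `kst`, `run-all`).

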