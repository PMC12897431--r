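# breedkit

Genetic evaluation of livestock conservation populations from diploid
biallelic SNP genotypes, written for conservation geneticists and breeding
programme managers working with small, closed populations (the motivating
system is local pig breeds genotyped on a targeted SNP panel, but nothing
is pig-specific beyond the default autosome labels).

The package covers the full desk workflow around such a panel:

* **Breed-informative marker selection.** For each target breed, every SNP
  is scored by ΔMAF = |MAF_target − MAF_other|, where MAF_other is the
  pooled minor-allele frequency over all remaining breeds. Sites are
  ranked per breed, selected per chromosome under a uniform-coverage rule
  (equal-width positional bins, best site per bin, backfill by rank), and
  the per-breed lists are merged and deduplicated into a genomic
  breed-composition (GBC) panel.
* **Genomic breed composition.** Supervised-admixture maximum likelihood:
  with breed allele frequencies f fixed from a labelled reference, each
  individual's ancestry vector q (on the K-simplex) maximises

      ℓ(q) = Σ_j [ g_j log(Σ_k q_k f_kj) + (2 − g_j) log(1 − Σ_k q_k f_kj) ]

  via EM. Individuals are called *pure* when max_k q_k ≥ 0.95. Random
  Forest and multilayer-perceptron baselines are available behind the same
  evaluation interface.
* **Quality control.** The PLINK-style chain (individual call rate ≥ 90%,
  autosomes, site call rate ≥ 90%, MAF ≥ 0.01, exact Hardy–Weinberg
  p ≥ 1e-6) plus the panel-design pre-screen (site missingness < 0.1,
  heterozygosity < 0.5). The HWE test is the exact two-sided
  "no-more-probable" test.
* **Diversity statistics.** Per population: MAF, observed and expected
  heterozygosity (Ho, He = 2p(1−p)), nucleotide diversity
  (Pi = He·n/(n−1) on n allele copies), polymorphic marker proportion
  (Pn) and PIC, with a Mann–Whitney rank-sum comparison between
  populations.
* **Inbreeding.** PLINK-style sliding-window runs of homozygosity
  (500 kb minimum, 30-SNP windows, ≤1 heterozygote and ≤5 missing) and
  F_ROH = ΣL_ROH / L_AUTO, with length-class summaries.
* **Structure.** Composite-LD decay curves (genotype r² by distance bin)
  and standardised-genotype PCA.
* **Mate selection.** IBS similarity, average-linkage molecular families,
  exclusion of F_ROH > 0.3 animals, and cross-family mating plans with a
  Mendelian offspring simulator to audit the expected diversity gain.
* **Simulator.** A Balding–Nichols multi-breed generator with admixed
  individuals of known q, implanted autozygous tracts, haplotype-pool LD
  and family structure — every statistical feature the analyses assume,
  with known truth.

## Worked example

```r
library(breedkit)

cfg <- sim_config(n_breeds = 5, fst = 0.15, n_markers = 2000,
                  n_chromosomes = 5, samples_per_breed = 30,
                  missing_rate = 0.01, seed = 2024)
g <- simulate_genotypes(simulate_frequencies(cfg), cfg)
g
#> geno_matrix: 150 samples x 2000 markers (5 chromosomes), 1.03% missing

qc <- filter_sites(filter_individuals(g)$geno,
                   qc_thresholds(autosomes = as.character(1:5)))
qc$report
#>  stage      rule removed retained
#>  sites  autosome       0     2000
#>  sites call_rate       0     2000
#>  sites       maf      12     1988
#>  sites       hwe       0     1988

pr <- build_gbc_panel(qc$geno,
                      spec = panel_spec(per_chromosome_target = 60,
                                        coverage_bins = 60))
pr
#> GBC marker panel: 1053 markers on 5 chromosomes, mean dMAF 0.279

ref <- panel_frequencies(qc$geno, marker_ids = pr)
fit <- fit_ancestry(subset_geno(qc$geno, marker_ids = pr$marker_id), ref)
head(summary(fit), 3)
#>   sample_id top_breed    purity purity_call     loglik n_iter converged
#> 1    ind001        B1 0.9939177        pure  -996.7471    500     FALSE
#> 2    ind002        B1 0.9865565        pure  -994.3789    500     FALSE
#> 3    ind003        B1 0.9997301        pure -1000.7392    500     FALSE

population_report(qc$geno)
#>  population n_samples n_sites maf_mean maf_sd ho_mean  ho_sd he_mean ...
#>          B1        30    1988   0.2284 0.1541  0.3081 0.1800  0.3050
#>          B2        30    1988   0.2281 0.1503  0.3108 0.1784  0.3070
#>          ...

fr <- froh(detect_roh(qc$geno), qc$geno)
summary(fr$froh)
#>      Min.   1st Qu.    Median      Mean   3rd Qu.      Max.
#> 0.0000000 0.0000000 0.0000000 0.0008709 0.0000000 0.0187997

pca_geno(qc$geno, 2)
#> geno_pca: 150 samples, 2 components
#> explained fraction: 6.00% 5.73%
```

Reading the output: every simulated animal is assigned to its true breed
(accuracy 1.00 on this fixture) and 95% are called pure at the 95%
threshold; the `converged = FALSE` flag records that the EM improvement
was still above the 1e-6 tolerance at the 500-iteration cap — continuing
to 5000 iterations moves no q entry by more than 0.003.
Diversity sits where moderate-differentiation breeds should (He ≈ 0.30,
Pn ≈ 0.93); F_ROH is near zero because this simulation implants no
autozygosity; PCA explained fractions are small because five breeds at
FST 0.15 spread variance over four between-breed axes.

`run_pipeline(pipeline_config(...))` chains these stages (QC → panel →
GBC → diversity → PCA → ROH/F_ROH → LD → mate selection) and writes
TSVs with a version/config-hash/seed header; identical configs reproduce
byte-identical outputs.

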