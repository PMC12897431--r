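---
title: "Methods: panel design, breed composition and conservation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel design, breed composition and conservation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical methods it
implements, their assumptions, the defaults it ships, and the choices that
were genuinely open when it was written.

## The data model

Everything operates on a `geno_matrix`: an individuals × markers matrix of
diploid allele dosages in {0, 1, 2, NA}, a marker map (chromosome as a
string label, 1-based bp position, two alleles), and a sample table.
Missingness is a distinct `NA` sentinel, never conflated with dosage 0.
Dosage counts copies of a designated *counted* allele (ALT in VCF, A1 in
PLINK bim); every statistic in the package is invariant to flipping that
orientation at any site, so no statistic depends on which allele a file
happened to count. Coordinates are 1-based inclusive everywhere and
interval lengths are `end − start + 1`. The autosome set is configurable
and defaults to `"1".."18"` (the pig karyotype), since all analyses here
restrict to autosomes.

PLINK 1.9 bed/bim/fam I/O is implemented directly against the public
binary layout (SNP-major, magic `0x6C 0x1B 0x01`, two-bit codes packed
low-bits-first) and is exercised by a byte-level fixture in the tests; VCF
reading goes through vcfR and keeps only biallelic SNP records, mapping
half-calls and non-diploid GTs to missing.

## Quality control

Two distinct layers, as the workflow demands:

* the **analysis chain**: individuals with call rate < 90% first, then per
  site — autosome restriction, call rate ≥ 90%, MAF ≥ 0.01, exact
  Hardy–Weinberg p ≥ 1e-6. Site statistics are recomputed after individual
  removal, and the chain is idempotent. Boundary semantics are strict
  exactly where the conventions say so (call rate *below* 90% removes; MAF
  *at* 0.01 is retained; HWE p *below* 1e-6 removes).
* the **panel-design pre-screen**: site missingness strictly below 0.1 and
  observed heterozygosity strictly below 0.5. The heterozygosity cap is a
  paralogue-collapse guard, not a population-genetic filter, which is why
  it exists only in the design screen.

The HWE test is the exact conditional test: given the observed allele
counts, the p-value sums the probabilities of all heterozygote counts no
more probable than the observed one, with the conditional distribution
evaluated in log space from its closed form. A chi-square alternative was
considered and rejected as the default because the exact test is what
PLINK applies and the chain's 1e-6 threshold sits deep in the tail where
the asymptotic approximation is at its worst. When breed labels are
present the test runs within each breed and a site fails if it fails in
any breed — pooling differentiated breeds would reject sound sites through
the Wahlund effect. The tests verify the implementation against an
independent enumeration oracle on every genotype table with n ≤ 50, to
1e-12.

## ΔMAF panel design

Marker informativeness for a target breed is ΔMAF = |MAF_target −
MAF_other|. Two points were genuinely open:

* **"Combined" other-breed MAF.** Implemented as the pooled-genotype MAF
  of all non-target individuals (weighting breeds by sample size), with an
  unweighted mean-of-breed-MAFs option. Pooling is the default because it
  is what "combine the other breeds and compute MAF" literally does to a
  genotype file.
* **Folding.** ΔMAF compares *folded* frequencies (both ≤ 0.5) by
  definition. Folding can mask differentiation when the minor allele
  differs between target and pool; an unfolded |p_t − p_o| option exists
  but is not the default, because the folded form is the published
  definition of the score.

Uniform chromosomal coverage is realised as equal-width positional bins
spanning the first-to-last candidate marker on each chromosome, taking the
highest-ΔMAF unpicked site per bin, and backfilling unfilled bins with the
globally next-best remaining sites until the per-chromosome target is
reached. This is the simplest rule that delivers both stated goals (high
ΔMAF, even coverage), it is deterministic and seed-free, and it reduces to
per-bin argmax — which the tests check against a brute-force oracle. The
per-chromosome target defaults to 1200, matching the scale at which such
panels are built (≈1200 × 18 autosomes before deduplication ≈ 19–22K
markers after); desk-scale examples in the tests use much smaller targets.
Per-breed lists are merged and deduplicated, recording every breed that
nominated a marker.

## Supervised-admixture breed composition

With reference breed frequencies `f[k, j]` fixed, an individual's ancestry
vector q maximises the binomial mixture log-likelihood given in the
README. The package fits the *supervised* model rather than re-running
unsupervised clustering with the test animals included: it is
deterministic, answers the same "what fraction of this genome is breed k"
question, and needs no K-selection. The reference frequencies are pooled
per breed and clamped to [1e-4, 1 − 1e-4] so no fixed site contributes
−∞; sites unobserved in a breed are set to 0.5 for that breed (maximally
uninformative) and counted.

Numerics: EM with standard allele-copy responsibilities, flat start
q = 1/K (the likelihood is concave in q, so multi-start is unnecessary
and the flat start is the unique symmetric choice), stopping at
Δℓ < 1e-6 or 500 iterations. The log-likelihood is non-decreasing by
construction and the tests assert it per iteration. Missing genotypes are
skipped in the likelihood; the machine-learning baselines (Random Forest,
single-hidden-layer perceptron) instead receive mean-imputed dosages, as
classifiers need complete vectors.

Convergence near a simplex corner is sublinear, so purebred animals often
carry `converged = FALSE` at the default cap while their q is stable to
~1e-3; the cap is kept because downstream calls (argmax breed, purity at
0.95) are insensitive at that scale.

A practical finding the tests quantify: at 1000 markers and breed
differentiation around FST 0.15, the maximum-likelihood q̂ of a genuinely
purebred animal retains a few percent of spillover ancestry often enough
that roughly one purebred in twelve falls below a 95% purity threshold.
This is a property of the estimator at that marker count, not noise in
the implementation (a quasi-Newton optimiser on the same likelihood finds
the same or worse optima). Purity screening at the 95% level should
therefore use panels of several thousand informative markers — which is
precisely what a ΔMAF-designed panel provides.

## Diversity statistics

Per site with counted-allele frequency p on n non-missing allele copies:
He = 2p(1−p) (no small-sample correction), Ho = heterozygote fraction,
Pi = He·n/(n−1), PIC = 1 − (p² + q²) − 2p²q². Keeping He uncorrected
makes Ho > He possible — an observation of real interest in conservation
cohorts — instead of forcing Ho ≤ He by construction. Pi carries the
n/(n−1) factor because it *is* the mean pairwise allelic difference (the
tests verify this against an O(n²) enumeration). Pn is the fraction of
panel markers segregating (MAF > 0) among markers with at least one call
in the population; both the threshold and the denominator are arguments,
because published Pn values rarely state either. Population means are
plain means over per-site vectors — no weighting surprises — and sites
entirely missing in a population are excluded from that population's
means. Between-population comparisons use the Mann–Whitney rank-sum test
(normal approximation with tie correction, via `stats::wilcox.test`).

## Runs of homozygosity and F_ROH

The scan mirrors the PLINK sliding-window semantics: 30-SNP windows are
scored homozygous when they hold ≤1 heterozygote and ≤5 missing calls; a
SNP is a candidate when more than 5% of the windows covering it are
homozygous; maximal candidate stretches are trimmed to sub-stretches that
respect the same het/missing caps at the segment level, and reported when
they have ≥30 SNPs and span ≥500 kb. The het/missing allowances are
enforced at both window and segment level deliberately — window-only
enforcement lets two distant heterozygotes share one long segment.

F_ROH = ΣL_ROH / L_AUTO. L_AUTO defaults to the analysed map's span
(per-chromosome last-minus-first marker position + 1, summed), because an
assembly constant would silently disagree with a subset panel; a fixed
denominator is a parameter for users who want assembly totals. Length
classes are left-closed [min, 5), [5, 10), [10, ∞) Mb.

Detection accuracy is audited by implant-and-recover: on a heterozygous
background at 50 SNPs/Mb, implanted tracts ≥1 Mb are recovered with
precision and recall 1.0 and boundary error of at most one inter-SNP gap,
and sub-500 kb tracts are never reported. On real data the background is
not uniformly heterozygous, so chance runs of homozygosity can extend a
true segment by a few SNPs; the window hit-rate rule bounds that
extension.

## LD and PCA

r² is the squared Pearson correlation of dosage vectors over jointly
non-missing samples (composite LD): phase-free, deterministic, and the
standard choice for decay curves; an EM haplotype-frequency r² is out of
scope. Decay curves average r² in half-open distance bins (defaults 10 kb
bins to 1000 kb), with an optional seeded per-chromosome pair cap that is
recorded in the output. PCA standardises each site by 2p̂ and
√(2p̂(1−p̂)), zeroes missing entries after centring, drops monomorphic
sites, and takes the SVD; explained fractions are eigenvalue ratios. Both
are deterministic (PCA up to component sign).

## IBS, molecular families and mate selection

IBS(i, j) is the mean of (2 − |g_i − g_j|)/2 over shared sites. Families
are average-linkage clusters of 1 − IBS cut at a fixed family count — the
number of families is a biological input, not estimated, because
molecular-pedigree practice fixes it from husbandry records. Candidates
with F_ROH > 0.3 (strictly) are excluded. The mating planner is a greedy
round-robin over sire families — every family with an eligible sire gets
its first mating before any family gets a second — pairing each sire with
a dam from the least-used other family, breaking ties by lower pair IBS
and then input order, so plans are deterministic. The offspring simulator
draws one allele per parent per marker (no linkage): for single-generation
heterozygosity comparisons, recombination is irrelevant.

## The simulator: what it emulates, what it does not

`sim_config()` defaults encode the conditions the test-suite studies:
5 breeds at FST 0.15, 1000 markers over 5 chromosomes, 40 individuals per
breed, ancestral frequencies Uniform(0.05, 0.95). Breed frequencies follow
Balding–Nichols (Beta with mean p and variance F·p(1−p)) — the minimal
model that produces the breed-level MAF differentiation that ΔMAF design
exploits. Admixed individuals draw each allele copy's source breed from
their q; LD mode builds individuals from recombinant mosaics of a finite
per-breed haplotype pool (Poisson crossovers), giving controllable,
distance-decaying r²; `implant_roh()` forces sampled-haplotype
homozygosity over intervals; `simulate_families()` produces founder pairs
and Mendelian full sibs. Everything is bit-reproducible under its seed.

What it does *not* emulate: mutation, realistic demography (bottlenecks,
migration), linked selection, genotyping error, and the shared drift
structure of real breed phylogenies (breeds are conditionally independent
given the ancestral frequency). Passing tests therefore demonstrate
correctness of the estimators under the stated generative model, not
performance guarantees on any particular livestock dataset.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by choice:
panels of 400–2000 markers, 100–200 individuals, 50-replicate recovery
suites, 20-seed paired enrichment comparisons. These sizes give
Monte-Carlo error comfortably below every asserted tolerance while keeping
the whole suite in a few minutes; the estimators themselves are vectorised
(the EM runs all individuals simultaneously) and scale linearly in
markers × individuals.

## Known limitations

* The supervised model assumes the reference panel spans the test
  animals' true ancestry; ancestry from an unrepresented breed is
  projected onto the nearest represented ones without warning.
* Purity calling at 95% needs several thousand informative markers (see
  above); with ~1000 generic markers expect a visible false-admixed rate
  among true purebreds.
* ROH calling below ~30 SNPs per segment is deliberately impossible with
  the default parameters; sparse maps need retuned windows.
* The mating planner optimises coverage and pairwise IBS greedily; it is
  not an optimal-contribution selector.
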