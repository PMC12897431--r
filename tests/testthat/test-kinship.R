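test_that("IBS matrix matches the brute-force oracle", {
  expect_equal(unname(ibs_matrix(make_geno(rbind(c(0L, 1L, 2L),
                                                 c(0L, 1L, 2L))))$ibs),
               matrix(1, 2, 2))
  expect_equal(ibs_matrix(make_geno(rbind(rep(0L, 5),
                                          rep(2L, 5))))$ibs[1, 2], 0)
  set.seed(81)
  d <- matrix(sample(c(0:2, NA), 10 * 50, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), 10, 50)
  g <- make_geno(d)
  ib <- ibs_matrix(g)
  expect_equal(unname(ib$ibs), oracle_ibs(d), tolerance = 1e-12)
  # invariant to marker permutation; decreasing in Hamming distance
  gp <- subset_geno(g, marker_ids = sample(g$map$marker_id))
  expect_equal(ibs_matrix(gp)$ibs, ib$ibs[rownames(ib$ibs), colnames(ib$ibs)])
  base <- rep(0L, 40)
  near <- replace(base, 1:2, 1L); far <- replace(base, 1:20, 2L)
  gg <- make_geno(rbind(base, near, far))
  expect_gt(ibs_matrix(gg)$ibs[1, 2], ibs_matrix(gg)$ibs[1, 3])
})

test_that("family clustering recovers simulated sib groups", {
  cfg <- sim_config(n_breeds = 1, fst = 0.2, n_markers = 600,
                    n_chromosomes = 2, samples_per_breed = 2, seed = 82)
  pan <- simulate_frequencies(cfg)
  fam <- simulate_families(pan, cfg, n_families = 2, sibs_per_family = 5)
  ib <- ibs_matrix(fam$geno)
  cl <- cluster_families(ib, 2)
  agreement <- table(cl$family_id, fam$truth$family_id)
  expect_equal(sum(apply(agreement, 1, max)), nrow(fam$truth))
  # degenerate cuts
  expect_equal(length(unique(cluster_families(ib, 1)$family_id)), 1)
  n <- nrow(ib$ibs)
  expect_equal(length(unique(cluster_families(ib, n)$family_id)), n)
})

test_that("high-F_ROH exclusion uses a strict threshold", {
  fr <- data.frame(sample_id = c("a", "b", "c", "d"),
                   froh = c(0.31, 0.30, 0.05, 0.45))
  keep <- exclude_high_froh(c("a", "b", "c", "d"), fr)
  expect_identical(keep, c("b", "c"))
  expect_error(exclude_high_froh("zz", fr), "zz")
  set.seed(83)
  frs <- data.frame(sample_id = sprintf("i%d", 1:50),
                    froh = runif(50, 0, 0.6))
  kept <- exclude_high_froh(frs$sample_id, frs)
  expect_setequal(kept, frs$sample_id[frs$froh <= 0.3])
})

test_that("mating plans cross families and avoid high kinship", {
  # 2 families x (1 sire + 1 dam): two cross-family pairs
  fam <- data.frame(sample_id = c("s1", "d1", "s2", "d2"),
                    family_id = c(1, 1, 2, 2))
  class(fam) <- c("family_assignment", "data.frame")
  sexes <- c(s1 = "M", d1 = "F", s2 = "M", d2 = "F")
  plan <- propose_matings(fam, sexes)
  expect_equal(nrow(plan), 2)
  expect_true(all(plan$sire_family != plan$dam_family))
  # all animals in one family: blocked
  fam1 <- data.frame(sample_id = c("s1", "d1"), family_id = c(1, 1))
  class(fam1) <- c("family_assignment", "data.frame")
  expect_error(propose_matings(fam1, c(s1 = "M", d1 = "F")), "family")
  # 7-family cohort: plan covers all sire families, low mean kinship
  cfg <- sim_config(n_breeds = 1, fst = 0.2, n_markers = 500,
                    n_chromosomes = 2, samples_per_breed = 2, seed = 84)
  pan <- simulate_frequencies(cfg)
  sim <- simulate_families(pan, cfg, n_families = 7, sibs_per_family = 4)
  g <- sim$geno
  ib <- ibs_matrix(g)
  cl <- cluster_families(ib, 7)
  set.seed(84)
  sexes7 <- setNames(sample(c("M", "F"), nrow(g$dosage), replace = TRUE),
                     g$samples$sample_id)
  plan7 <- propose_matings(cl, sexes7, ibs = ib)
  expect_true(all(plan7$sire_family != plan7$dam_family))
  sire_fams <- unique(cl$family_id[match(names(sexes7)[sexes7 == "M"],
                                         cl$sample_id)])
  expect_setequal(unique(plan7$sire_family), sire_fams)
  off <- ib$ibs[upper.tri(ib$ibs)]
  expect_lt(mean(plan7$pair_ibs), mean(off))
})

test_that("planned cross-family offspring beat within-family matings on Ho", {
  cfg <- sim_config(n_breeds = 1, fst = 0.25, n_markers = 800,
                    n_chromosomes = 2, samples_per_breed = 2, seed = 85)
  pan <- simulate_frequencies(cfg)
  sim <- simulate_families(pan, cfg, n_families = 6, sibs_per_family = 2)
  g <- sim$geno
  truth <- sim$truth
  ib <- ibs_matrix(g)
  cl <- cluster_families(ib, 6)
  sexes <- setNames(ifelse(grepl("sire|sib1", truth$sample_id), "M", "F"),
                    truth$sample_id)
  plan <- propose_matings(cl, sexes, ibs = ib)
  off_plan <- simulate_offspring(g, plan, offspring_per_pair = 6, seed = 85)
  # within-family alternative: mate full sibs of the same family
  within <- data.frame(
    sire_id = truth$sample_id[truth$role == "sib" &
                                grepl("sib1", truth$sample_id)],
    dam_id = truth$sample_id[truth$role == "sib" &
                               grepl("sib2", truth$sample_id)])
  off_within <- simulate_offspring(g, within, offspring_per_pair = 6,
                                   seed = 85)
  ho <- function(gg) mean(gg$dosage == 1L, na.rm = TRUE)
  expect_gt(ho(off_plan), ho(off_within))
})
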