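test_that("exact HWE p-values match the enumeration oracle", {
  expect_equal(hwe_exact_pvalue(0, 0, 10), 1.0)
  expect_equal(hwe_exact_pvalue(10, 0, 0), 1.0)
  # (1, 0, 1): 2 a and 2 b alleles, het counts {0, 2}
  expect_equal(hwe_exact_pvalue(1, 0, 1), oracle_hwe(1, 0, 1),
               tolerance = 1e-12)
  cases <- rbind(c(25, 50, 25), c(1, 0, 1), c(5, 1, 5), c(0, 2, 0),
                 c(12, 3, 9), c(40, 2, 1), c(3, 30, 2), c(7, 7, 7))
  for (i in seq_len(nrow(cases))) {
    expect_equal(hwe_exact_pvalue(cases[i, 1], cases[i, 2], cases[i, 3]),
                 oracle_hwe(cases[i, 1], cases[i, 2], cases[i, 3]),
                 tolerance = 1e-12,
                 label = paste("table", paste(cases[i, ], collapse = "/")))
  }
  expect_error(hwe_exact_pvalue(0, 0, 0), "undefined|missing")
})

test_that("HWE test is symmetric in homozygote classes and calibrated", {
  set.seed(21)
  for (i in 1:50) {
    cnts <- sample(0:30, 3, replace = TRUE)
    if (sum(cnts) == 0) next
    expect_equal(hwe_exact_pvalue(cnts[1], cnts[2], cnts[3]),
                 hwe_exact_pvalue(cnts[3], cnts[2], cnts[1]))
  }
  # under simulated HWE genotypes the rejection rate at 0.05 stays near
  # (at or below, exact-test conservativeness) the nominal level
  set.seed(22)
  n <- 200; m <- 5000
  p <- runif(m, 0.1, 0.9)
  reject <- vapply(seq_len(m), function(j) {
    d <- rbinom(n, 2, p[j])
    hwe_exact_pvalue(sum(d == 0), sum(d == 1), sum(d == 2)) < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("individual call-rate filter removes exactly the right samples", {
  # 4 samples x 20 markers with prescribed missing counts 0/1/2/5 (=25%)
  d <- matrix(1L, 4, 20)
  d[2, 1] <- NA; d[3, 1:2] <- NA; d[4, 1:5] <- NA
  g <- make_geno(d)
  res <- filter_individuals(g)  # threshold 0.10 -> only 5/20 removed
  expect_identical(res$geno$samples$sample_id, c("s1", "s2", "s3"))
  expect_equal(res$report$removed, 1)
  # a fully missing sample is removed
  d2 <- rbind(matrix(1L, 2, 10), NA)
  res2 <- filter_individuals(make_geno(d2))
  expect_equal(nrow(res2$geno$dosage), 2)
  # no missingness -> identity
  res3 <- filter_individuals(make_geno(matrix(0:2, 3, 9)))
  expect_equal(res3$report$removed, 0)
})

test_that("site filter chain applies each rule and is idempotent", {
  set.seed(23)
  n <- 60
  base <- function() rbinom(n, 2, 0.4)
  d <- cbind(base(),                       # clean
             base(),                       # on chrom X (rule: autosome)
             replace(base(), 1:10, NA),    # 16.7% missing (rule: call rate)
             rep(0L, n),                   # monomorphic (rule: MAF)
             rep(1L, n),                   # all het (rule: HWE)
             base())                       # clean
  storage.mode(d) <- "integer"
  g <- make_geno(d, chrom = c("1", "X", "1", "1", "1", "1"))
  res <- filter_sites(g)
  expect_equal(res$report$removed[res$report$rule == "autosome"], 1)
  expect_equal(res$report$removed[res$report$rule == "call_rate"], 1)
  expect_equal(res$report$removed[res$report$rule == "maf"], 1)
  expect_equal(res$report$removed[res$report$rule == "hwe"], 1)
  expect_identical(res$geno$map$marker_id, c("m1", "m6"))
  # removed + retained = input at each stage
  expect_true(all(res$report$removed + res$report$retained ==
                    c(6, 5, 4, 3)))
  # idempotence
  res2 <- filter_sites(res$geno)
  expect_identical(res2$geno$dosage, res$geno$dosage)
  expect_true(all(res2$report$removed == 0))
})

test_that("HWE filtering is per population when labels exist", {
  set.seed(24)
  # two breeds fixed for opposite alleles: pooled would fail HWE badly,
  # per-population it is monomorphic (p = 1) and must be retained
  d <- rbind(matrix(0L, 30, 1), matrix(2L, 30, 1))
  g <- make_geno(d, breed = rep(c("A", "B"), each = 30))
  res <- filter_sites(g, qc_thresholds(min_maf = 0))
  expect_equal(ncol(res$geno$dosage), 1)
  pooled <- suppressWarnings(filter_sites(g, qc_thresholds(min_maf = 0),
                                          hwe_by_population = FALSE))
  expect_equal(ncol(pooled$geno$dosage), 0)
})

test_that("panel-design screen drops high-het and high-missing sites", {
  n <- 20
  d <- cbind(rep(0L, n),                          # clean
             rep(1L, n),                          # 100% het
             c(rep(1L, 12), rep(0L, 8)),          # 60% het
             replace(rep(0L, n), 1:2, NA),        # 10% missing (strict <)
             c(rep(1L, 9), rep(0L, 11)))          # 45% het: retained
  storage.mode(d) <- "integer"
  res <- panel_design_screen(make_geno(d))
  expect_identical(res$geno$map$marker_id, c("m1", "m5"))
  # removal fraction matches a direct recount
  miss <- colMeans(is.na(d))
  het <- vapply(seq_len(ncol(d)), function(j)
    mean(d[!is.na(d[, j]), j] == 1L), numeric(1))
  expect_equal(ncol(res$geno$dosage), sum(miss < 0.1 & het < 0.5))
})
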