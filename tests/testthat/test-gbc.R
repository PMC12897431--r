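test_that("reference frequencies are pooled, clamped and aligned", {
  d <- rbind(c(0L, 2L, 1L), c(0L, 2L, 1L), c(0L, 2L, 2L))
  g <- make_geno(d, breed = rep("A", 3))
  pan <- panel_frequencies(g)
  # single-breed reference equals per-site frequency, clamped
  expect_equal(unname(pan$freqs["A", ]),
               c(1e-4, 1 - 1e-4, 4 / 6))
  # frequencies match a recount oracle on constructed two-breed data
  set.seed(51)
  d2 <- matrix(sample(c(0:2, NA), 20 * 10, replace = TRUE), 20, 10)
  g2 <- make_geno(d2, breed = rep(c("A", "B"), each = 10))
  pan2 <- panel_frequencies(g2)
  for (b in c("A", "B")) {
    rows <- if (b == "A") 1:10 else 11:20
    p <- apply(d2[rows, ], 2, function(x)
      sum(x, na.rm = TRUE) / (2 * sum(!is.na(x))))
    expect_equal(unname(pan2$freqs[b, ]),
                 unname(pmin(pmax(p, 1e-4), 1 - 1e-4)))
  }
})

test_that("degenerate ancestry fits behave as forced", {
  set.seed(52)
  d <- matrix(sample(0:2, 10 * 50, replace = TRUE), 10, 50)
  g <- make_geno(d, breed = rep("A", 10))
  pan <- panel_frequencies(g)
  fit <- fit_ancestry(g, pan)
  # K = 1: the simplex is a point
  expect_true(all(fit$q == 1))
  expect_true(all(fit$converged))
  # identical frequencies for all breeds: likelihood flat, uniform returned
  pan2 <- pan
  pan2$freqs <- rbind(A = pan$freqs[1, ], B = pan$freqs[1, ],
                      C = pan$freqs[1, ])
  pan2$breeds <- c("A", "B", "C")
  fit2 <- fit_ancestry(g, pan2)
  expect_true(all(abs(fit2$q - 1 / 3) < 1e-9))
  # zero marker overlap errors
  g3 <- g; g3$map$marker_id <- paste0("other_", g3$map$marker_id)
  colnames(g3$dosage) <- g3$map$marker_id
  expect_error(fit_ancestry(g3, pan), "overlap")
})

test_that("EM log-likelihood is monotone and q stays on the simplex", {
  cfg <- sim_config(samples_per_breed = 8,
                    admixed = list(list(q = c(0.5, 0.5, 0, 0, 0), count = 4)),
                    seed = 53)
  pan <- simulate_frequencies(cfg)
  g <- simulate_genotypes(pan, cfg)
  ref <- panel_frequencies(g, ifelse(grepl("^admx", breed_labels(g)), NA,
                                     breed_labels(g)))
  lls <- sapply(1:12, function(k) fit_ancestry(g, ref, max_iter = k)$loglik)
  for (i in seq_len(nrow(lls)))
    expect_true(all(diff(lls[i, ]) >= -1e-8),
                label = paste("monotone loglik, individual", i))
  fit <- fit_ancestry(g, ref)
  expect_true(all(abs(rowSums(fit$q) - 1) < 1e-8))
  expect_true(all(fit$q >= 0))
  # invariant to marker-order permutation
  set.seed(54)
  perm <- sample(n_markers(g))
  gp <- subset_geno(g, marker_ids = g$map$marker_id[perm])
  fitp <- fit_ancestry(gp, ref)
  expect_equal(fit$q, fitp$q, tolerance = 1e-6)
})

test_that("ancestry recovery: purebred and half-and-half admixture", {
  maes <- c(); q3 <- c(); q12 <- c()
  for (s in 1:10) {
    cfg <- sim_config(samples_per_breed = 40,
                      admixed = list(list(q = c(0.5, 0.5, 0, 0, 0),
                                          count = 2)),
                      seed = 530 + s)
    pan <- simulate_frequencies(cfg)
    g <- simulate_genotypes(pan, cfg)
    truth <- attr(g, "true_q")
    lab <- breed_labels(g)
    ref_lab <- ifelse(grepl("^admx", lab), NA, lab)
    ref <- panel_frequencies(g, ref_lab)
    tg <- subset_geno(g, sample_ids = c("ind003", g$samples$sample_id[
      which(grepl("^admx", lab))]))
    fit <- fit_ancestry(tg, ref)
    q3 <- c(q3, fit$q[1, "B1"])
    q12 <- c(q12, abs(fit$q[2:3, "B1"] - 0.5), abs(fit$q[2:3, "B2"] - 0.5))
    maes <- c(maes, mean(abs(fit$q - truth[c(3, 201, 202), ])))
  }
  expect_gt(mean(q3), 0.95)            # purebred recovered
  expect_lt(mean(q12), 0.05)           # F1 fractions recovered
  expect_lt(mean(maes), 0.05)
})

test_that("purity calls: purebreds pure, F1s admixed", {
  q <- c(1, rep(0, 24))
  expect_equal(purity_call(q), "pure")
  expect_equal(purity_call(rep(1 / 25, 25)), "admixed")
  cfg <- sim_config(samples_per_breed = 30,
                    admixed = list(list(q = c(0.5, 0.5, 0, 0, 0),
                                        count = 10)),
                    seed = 55)
  pan <- simulate_frequencies(cfg)
  g <- simulate_genotypes(pan, cfg)
  lab <- breed_labels(g)
  ref <- panel_frequencies(g, ifelse(grepl("^admx", lab), NA, lab))
  f1 <- subset_geno(g, sample_ids = g$samples$sample_id[grepl("^admx", lab)])
  fit <- fit_ancestry(f1, ref)
  expect_true(all(purity_call(fit) == "admixed"))
})

test_that("train/test split is stratified, disjoint and seeded", {
  labels <- rep(c("A", "B", "C"), each = 10)
  sp <- split_train_test(labels, 0.7, seed = 56)
  expect_equal(length(sp$train), 21)
  for (b in c("A", "B", "C"))
    expect_equal(sum(labels[sp$train] == b), 7)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_identical(sp, split_train_test(labels, 0.7, seed = 56))
  expect_length(split_train_test(labels, 1.0, seed = 1)$test, 0)
})

test_that("breed assignment beats chance and hits high accuracy", {
  cfg <- sim_config(fst = 0.2, samples_per_breed = 40, seed = 57)
  pan <- simulate_frequencies(cfg)
  g <- simulate_genotypes(pan, cfg)
  sp <- split_train_test(breed_labels(g), 0.7, seed = 57)
  adm <- evaluate_assignment("admixture", g, sp)
  expect_gte(adm$accuracy, 0.95)
  # label-permuted truth: accuracy near 1/K
  set.seed(58)
  permuted <- sample(adm$truth)
  expect_lt(mean(adm$predicted == permuted), 0.45)
  # rf and mlp run and do much better than chance on this easy problem
  rf <- evaluate_assignment("rf", g, sp, seed = 57)
  expect_gt(rf$accuracy, 0.8)
  mlp <- evaluate_assignment("mlp", g, sp, seed = 57)
  expect_gt(mlp$accuracy, 0.6)
})
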