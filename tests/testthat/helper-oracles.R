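# Independent oracles and fixture builders shared across test files.

# Exact HWE oracle: conditional distribution of the genotype table given the
# allele counts, obtained by enumerating every table and normalising
# multinomial HWE probabilities (a different route from the closed-form
# implementation under test).
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  if (na == 0 || na == 2 * n) return(1.0)
  p <- na / (2 * n)
  hets <- seq.int(min(na, 2 * n - na) %% 2, min(na, 2 * n - na), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    bb <- n - aa - h
    stats::dmultinom(c(aa, h, bb), prob = c(p^2, 2 * p * (1 - p), (1 - p)^2))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# O(n^2) pairwise-difference oracle for per-site nucleotide diversity
oracle_pi <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  alleles <- unlist(lapply(d, function(x) c(rep(1, x), rep(0, 2 - x))))
  n <- length(alleles)
  if (n < 2) return(0)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    s <- s + as.integer(alleles[i] != alleles[j])
  s / choose(n, 2)
}

# brute-force IBS oracle
oracle_ibs <- function(dosage) {
  n <- nrow(dosage)
  M <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    ok <- !is.na(dosage[i, ]) & !is.na(dosage[j, ])
    if (any(ok))
      M[i, j] <- mean((2 - abs(dosage[i, ok] - dosage[j, ok])) / 2)
  }
  M
}

# brute-force per-bin argmax oracle for uniform coverage selection
oracle_bin_argmax <- function(ranked, chromosome, n_bins) {
  cand <- ranked[ranked$chrom == chromosome, , drop = FALSE]
  lo <- min(cand$pos); hi <- max(cand$pos)
  w <- (hi - lo) / n_bins
  picks <- character(0)
  for (b in seq_len(n_bins)) {
    blo <- lo + (b - 1) * w; bhi <- lo + b * w
    inb <- cand[cand$pos >= blo & (cand$pos < bhi | b == n_bins), ,
                drop = FALSE]
    if (nrow(inb) == 0) next
    best <- inb[order(-inb$delta_maf, inb$chrom, inb$pos, inb$marker_id)[1], ]
    picks <- c(picks, best$marker_id)
  }
  picks
}

# tiny geno_matrix from a dosage matrix (one chromosome, unit spacing)
make_geno <- function(dosage, chrom = "1", pos = NULL, breed = NULL) {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  map <- data.frame(marker_id = sprintf("m%d", seq_len(m)),
                    chrom = chrom, pos = pos,
                    allele_a = "A", allele_b = "G",
                    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("s%d", seq_len(nrow(dosage))),
                        stringsAsFactors = FALSE)
  if (!is.null(breed)) samples$breed <- breed
  geno_matrix(dosage, map, samples)
}

# a mixed-differentiation reference: background fst with a fraction of
# highly differentiated sites spliced in (same map and ancestral freqs)
make_mixed_panel <- function(seed, n_markers = 2000, n_breeds = 5,
                             fst_bg = 0.02, fst_hi = 0.4, frac_hi = 0.10,
                             samples_per_breed = 30) {
  cfg_bg <- sim_config(n_breeds = n_breeds, fst = fst_bg,
                       n_markers = n_markers, n_chromosomes = 5,
                       samples_per_breed = samples_per_breed, seed = seed)
  cfg_hi <- sim_config(n_breeds = n_breeds, fst = fst_hi,
                       n_markers = n_markers, n_chromosomes = 5,
                       samples_per_breed = samples_per_breed, seed = seed)
  pan <- simulate_frequencies(cfg_bg)
  pan_hi <- simulate_frequencies(cfg_hi)
  set.seed(seed + 10000)
  hi <- sample(n_markers, round(frac_hi * n_markers))
  pan$freqs[, hi] <- pan_hi$freqs[, hi]
  g <- simulate_genotypes(pan, cfg_bg)
  list(panel = pan, geno = g, hi_sites = hi, cfg = cfg_bg)
}
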