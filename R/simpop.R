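#' Simulation configuration for a multi-breed genotype panel
#'
#' Describes the statistical structure the analysis assumes: breed-level
#' allele-frequency differentiation (Balding-Nichols), known admixture
#' fractions, distance-decaying LD via a finite haplotype pool, implanted
#' autozygous tracts and genotype missingness.
#'
#' @param n_breeds number of breeds; default 5
#' @param fst per-breed differentiation, recycled to \code{n_breeds};
#'   default 0.15
#' @param n_markers total marker count; default 1000
#' @param n_chromosomes chromosomes the markers are spread over; default 5
#' @param chrom_length_bp chromosome length in bp; default 5e7
#' @param samples_per_breed purebred individuals per breed; default 40
#' @param ancestral_freq_range ancestral allele frequencies drawn uniform
#'   in this range; default c(0.05, 0.95)
#' @param missing_rate per-genotype missingness; default 0
#' @param ld_pool_haplotypes per-breed haplotype pool size for LD mode
#'   (0 disables LD, genotypes are then site-independent); default 0
#' @param recomb_rate_per_bp crossover rate for LD mode; default 1e-8
#' @param admixed list of \code{list(q = simplex vector, count = n)}
#'   describing admixed individuals to add; default none
#' @param seed mandatory RNG seed
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_breeds = 5, fst = 0.15, n_markers = 1000,
                       n_chromosomes = 5, chrom_length_bp = 5e7,
                       samples_per_breed = 40,
                       ancestral_freq_range = c(0.05, 0.95),
                       missing_rate = 0, ld_pool_haplotypes = 0,
                       recomb_rate_per_bp = 1e-8,
                       admixed = list(), seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  fst <- rep_len(fst, n_breeds)
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie in (0, 1)")
  for (a in admixed) {
    if (abs(sum(a$q) - 1) > 1e-8 || any(a$q < 0))
      stop("admixed q vectors must lie on the simplex")
    if (length(a$q) != n_breeds)
      stop("admixed q vectors must have length n_breeds")
  }
  structure(list(n_breeds = n_breeds, fst = fst, n_markers = n_markers,
                 n_chromosomes = n_chromosomes,
                 chrom_length_bp = chrom_length_bp,
                 samples_per_breed = samples_per_breed,
                 ancestral_freq_range = ancestral_freq_range,
                 missing_rate = missing_rate,
                 ld_pool_haplotypes = ld_pool_haplotypes,
                 recomb_rate_per_bp = recomb_rate_per_bp,
                 admixed = admixed, seed = seed),
            class = "sim_config")
}

sim_map <- function(cfg) {
  per <- diff_round(cfg$n_markers, cfg$n_chromosomes)
  rows <- list()
  for (ch in seq_len(cfg$n_chromosomes)) {
    m <- per[ch]
    pos <- sort(sample.int(cfg$chrom_length_bp, m))
    rows[[ch]] <- data.frame(
      marker_id = sprintf("snp_%d_%d", ch, seq_len(m)),
      chrom = as.character(ch), pos = pos,
      allele_a = "A", allele_b = "G", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

diff_round <- function(total, k) {
  base <- rep(total %/% k, k)
  extra <- total %% k
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  base
}

#' Simulate breed allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies \eqn{p_j \sim U(a, b)}; breed \eqn{k} frequencies
#' \eqn{f_{kj} \sim Beta(p_j (1-F_k)/F_k,\; (1-p_j)(1-F_k)/F_k)}, so that
#' \eqn{E[f_{kj}] = p_j} and \eqn{Var[f_{kj}] = F_k\, p_j (1-p_j)}.
#'
#' @param cfg a \code{\link{sim_config}}
#' @return a \code{breed_freq_panel}-shaped list: \code{freqs} (K x M),
#'   \code{breeds}, \code{markers}, \code{map}, and the \code{ancestral}
#'   frequencies.
#' @export
simulate_frequencies <- function(cfg) {
  set.seed(cfg$seed)
  map <- sim_map(cfg)
  m <- nrow(map)
  p <- stats::runif(m, cfg$ancestral_freq_range[1], cfg$ancestral_freq_range[2])
  breeds <- sprintf("B%d", seq_len(cfg$n_breeds))
  freqs <- matrix(NA_real_, cfg$n_breeds, m,
                  dimnames = list(breeds, map$marker_id))
  for (k in seq_len(cfg$n_breeds)) {
    Fk <- cfg$fst[k]
    freqs[k, ] <- stats::rbeta(m, p * (1 - Fk) / Fk, (1 - p) * (1 - Fk) / Fk)
  }
  structure(list(freqs = freqs, breeds = breeds, markers = map$marker_id,
                 map = map, ancestral = p, eps = 0,
                 n_unobserved = 0L),
            class = "breed_freq_panel")
}

#' Simulate genotypes from breed frequencies
#'
#' Purebred individuals draw dosages \eqn{Binomial(2, f_{kj})} per site;
#' admixed individuals draw, independently per allele copy, a source breed
#' from their \eqn{q} and then an allele from that breed's frequency. In
#' LD mode each breed first receives a finite pool of
#' \code{ld_pool_haplotypes} haplotypes (alleles Bernoulli(\eqn{f_{kj}}));
#' individuals are then formed from recombinant mosaics of two pool
#' haplotypes with Poisson crossovers, which produces distance-decaying
#' \eqn{r^2}. Missingness is Bernoulli per genotype. Fully reproducible:
#' the same config (including seed) gives identical output.
#'
#' @param panel a \code{\link{simulate_frequencies}} result
#' @param cfg the same \code{\link{sim_config}}
#' @return a \code{geno_matrix}; the sample table carries \code{breed}
#'   (\code{"admx<i>"} for admixed individuals) and the true ancestry
#'   vectors in \code{attr(, "true_q")}.
#' @export
simulate_genotypes <- function(panel, cfg) {
  set.seed(cfg$seed + 1L)
  map <- panel$map
  m <- nrow(map)
  K <- cfg$n_breeds
  qs <- diag(K)[rep(seq_len(K), each = cfg$samples_per_breed), , drop = FALSE]
  labels <- rep(panel$breeds, each = cfg$samples_per_breed)
  for (i in seq_along(cfg$admixed)) {
    a <- cfg$admixed[[i]]
    qs <- rbind(qs, matrix(a$q, nrow = a$count, ncol = K, byrow = TRUE))
    labels <- c(labels, rep(sprintf("admx%d", i), a$count))
  }
  n <- nrow(qs)
  pools <- NULL
  if (cfg$ld_pool_haplotypes > 0) {
    pools <- lapply(seq_len(K), function(k)
      matrix(stats::rbinom(cfg$ld_pool_haplotypes * m, 1L,
                           rep(panel$freqs[k, ], each = cfg$ld_pool_haplotypes)),
             nrow = cfg$ld_pool_haplotypes, ncol = m))
  }
  dosage <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    if (is.null(pools)) {
      pure <- which(qs[i, ] == 1)
      if (length(pure) == 1L) {
        dosage[i, ] <- stats::rbinom(m, 2L, panel$freqs[pure, ])
      } else {
        h1 <- sample.int(K, m, replace = TRUE, prob = qs[i, ])
        h2 <- sample.int(K, m, replace = TRUE, prob = qs[i, ])
        f1 <- panel$freqs[cbind(h1, seq_len(m))]
        f2 <- panel$freqs[cbind(h2, seq_len(m))]
        dosage[i, ] <- stats::rbinom(m, 1L, f1) + stats::rbinom(m, 1L, f2)
      }
    } else {
      k <- sample.int(K, 1L, prob = qs[i, ])  # LD mode: one source breed/gamete
      k2 <- sample.int(K, 1L, prob = qs[i, ])
      dosage[i, ] <- recomb_haplotype(pools[[k]], map, cfg) +
        recomb_haplotype(pools[[k2]], map, cfg)
    }
  }
  if (cfg$missing_rate > 0) {
    mis <- stats::runif(n * m) < cfg$missing_rate
    dosage[mis] <- NA_integer_
  }
  ids <- sprintf("ind%03d", seq_len(n))
  rownames(dosage) <- ids
  g <- geno_matrix(dosage, map,
                   data.frame(sample_id = ids, breed = labels,
                              stringsAsFactors = FALSE))
  attr(g, "true_q") <- qs
  g
}

# one recombinant gamete from a haplotype pool (markers sorted within chrom)
recomb_haplotype <- function(pool, map, cfg) {
  H <- nrow(pool)
  out <- integer(nrow(map))
  for (ch in unique(map$chrom)) {
    ci <- which(map$chrom == ch)
    pos <- map$pos[ci]
    a <- sample.int(H, 1L); b <- sample.int(H, 1L)
    ncx <- stats::rpois(1L, cfg$recomb_rate_per_bp * cfg$chrom_length_bp)
    if (ncx == 0L) {
      out[ci] <- pool[a, ci]
    } else {
      cx <- sort(stats::runif(ncx, 1, cfg$chrom_length_bp))
      seg <- findInterval(pos, cx)  # 0..ncx
      use_a <- seg %% 2L == 0L
      out[ci] <- ifelse(use_a, pool[a, ci], pool[b, ci])
    }
  }
  out
}

#' Implant autozygous tracts
#'
#' Forces the target sample homozygous across each implant interval by
#' duplicating one sampled haplotype: at every covered marker the genotype
#' becomes 0 or 2, drawn once per marker from the current genotype
#' (heterozygotes resolve to either homozygote with probability 1/2).
#'
#' @param g a \code{geno_matrix}
#' @param implants data.frame with columns \code{sample_id}, \code{chrom},
#'   \code{start_bp}, \code{end_bp}
#' @param seed RNG seed
#' @return the modified \code{geno_matrix}; implanted intervals contain no
#'   heterozygotes.
#' @export
implant_roh <- function(g, implants, seed = 1) {
  set.seed(seed)
  for (k in seq_len(nrow(implants))) {
    si <- match(implants$sample_id[k], g$samples$sample_id)
    ci <- which(g$map$chrom == as.character(implants$chrom[k]) &
                g$map$pos >= implants$start_bp[k] &
                g$map$pos <= implants$end_bp[k])
    if (length(ci) == 0L) {
      warning("implant ", k, " covers zero markers; skipped")
      next
    }
    d <- g$dosage[si, ci]
    het <- !is.na(d) & d == 1L
    d[het] <- 2L * stats::rbinom(sum(het), 1L, 0.5)
    g$dosage[si, ci] <- d
  }
  g
}

#' Simulate family-structured genotypes
#'
#' Founder pairs are drawn per family from one breed's allele frequencies;
#' full sibs are produced by Mendelian gamete sampling per marker. The
#' truth table records the family of every individual.
#'
#' @param panel a \code{\link{simulate_frequencies}} result
#' @param cfg the matching \code{\link{sim_config}}
#' @param n_families number of founder pairs
#' @param sibs_per_family full sibs per pair; 0 gives founders only
#' @param breed breed whose frequencies found the families; default first
#' @return list with \code{geno} (a \code{geno_matrix}) and \code{truth}
#'   (data.frame \code{sample_id}, \code{family_id}, \code{role}).
#' @export
simulate_families <- function(panel, cfg, n_families, sibs_per_family,
                              breed = panel$breeds[1]) {
  set.seed(cfg$seed + 2L)
  f <- panel$freqs[breed, ]
  m <- length(f)
  rows <- list(); meta <- list()
  for (fam in seq_len(n_families)) {
    sire <- stats::rbinom(m, 2L, f)
    dam <- stats::rbinom(m, 2L, f)
    rows[[length(rows) + 1L]] <- sire
    meta[[length(meta) + 1L]] <- c(sprintf("fam%d_sire", fam), fam, "founder")
    rows[[length(rows) + 1L]] <- dam
    meta[[length(meta) + 1L]] <- c(sprintf("fam%d_dam", fam), fam, "founder")
    for (s in seq_len(sibs_per_family)) {
      off <- stats::rbinom(m, 1L, sire / 2) + stats::rbinom(m, 1L, dam / 2)
      rows[[length(rows) + 1L]] <- off
      meta[[length(meta) + 1L]] <- c(sprintf("fam%d_sib%d", fam, s), fam, "sib")
    }
  }
  dosage <- do.call(rbind, rows)
  truth <- as.data.frame(do.call(rbind, meta), stringsAsFactors = FALSE)
  names(truth) <- c("sample_id", "family_id", "role")
  truth$family_id <- as.integer(truth$family_id)
  rownames(dosage) <- truth$sample_id
  g <- geno_matrix(dosage, panel$map,
                   data.frame(sample_id = truth$sample_id,
                              breed = breed, stringsAsFactors = FALSE))
  list(geno = g, truth = truth)
}
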