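#' Per-site allele frequency
#'
#' Frequency of the counted allele among non-missing genotype calls at one
#' site.
#'
#' @param dosages integer vector of dosages in \{0, 1, 2, NA\}
#' @return list with \code{p} (counted-allele frequency), \code{maf}
#'   (folded, <= 0.5), and \code{n} (non-missing allele count, i.e. twice
#'   the genotype count).
#' @export
site_freq <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) stop("site has no non-missing genotypes")
  p <- sum(d) / (2 * length(d))
  list(p = p, maf = min(p, 1 - p), n = 2L * length(d))
}

#' Observed heterozygosity at one site
#'
#' @param dosages integer vector of dosages
#' @return fraction of heterozygotes among non-missing genotypes.
#' @export
site_ho <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) stop("site has no non-missing genotypes")
  mean(d == 1L)
}

#' Expected heterozygosity
#'
#' \eqn{He = 2p(1-p)}, with no small-sample correction; this allows
#' \eqn{Ho > He} in populations with excess heterozygotes.
#'
#' @param p allele frequency in [0, 1]
#' @return expected heterozygosity in [0, 0.5].
#' @export
site_he <- function(p) 2 * p * (1 - p)

#' Nucleotide diversity at one biallelic site
#'
#' Average pairwise allelic difference over the \eqn{n} non-missing allele
#' copies: \eqn{\pi = \frac{n}{n-1} 2\hat p(1-\hat p)}. Equals the mean
#' Hamming distance over all \eqn{\binom{n}{2}} allele pairs.
#'
#' @param dosages integer vector of dosages
#' @return nucleotide diversity; 0 for a monomorphic site.
#' @export
site_pi <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) stop("site has no non-missing genotypes")
  n <- 2L * length(d)
  if (n < 2L) return(0)
  p <- sum(d) / n
  (n / (n - 1)) * 2 * p * (1 - p)
}

#' Polymorphic information content
#'
#' For a biallelic marker, \eqn{PIC = 1 - (p^2 + q^2) - 2p^2q^2} with
#' \eqn{q = 1 - p}.
#'
#' @param p allele frequency in [0, 1]
#' @return PIC in [0, 0.375].
#' @export
site_pic <- function(p) {
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

# vectorized per-site statistics for a dosage matrix (one population)
site_stats_matrix <- function(dosage) {
  cnt <- per_site_counts(dosage)
  n_alleles <- 2 * cnt$n
  p <- ifelse(cnt$n > 0L, (2 * cnt$n_bb + cnt$n_ab) / pmax(1, n_alleles), NA)
  maf <- pmin(p, 1 - p)
  ho <- ifelse(cnt$n > 0L, cnt$n_ab / pmax(1L, cnt$n), NA)
  he <- 2 * p * (1 - p)
  pi <- ifelse(n_alleles > 1L, he * n_alleles / pmax(1, n_alleles - 1), 0)
  pic <- 1 - (p^2 + (1 - p)^2) - 2 * p^2 * (1 - p)^2
  data.frame(marker_id = colnames(dosage), n_genotypes = cnt$n,
             p = p, maf = maf, ho = ho, he = he, pi = pi, pic = pic,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Proportion of polymorphic markers
#'
#' Fraction of panel markers segregating within a population. The
#' denominator is all panel markers with at least one called genotype in
#' the population; the default polymorphism criterion is MAF strictly
#' greater than \code{threshold} = 0 (i.e. segregating at all).
#'
#' @param g a \code{geno_matrix} restricted to one population
#' @param marker_ids panel markers to assess (default: all markers in
#'   \code{g})
#' @param threshold MAF above which a marker counts as polymorphic
#' @return Pn in [0, 1].
#' @export
proportion_polymorphic <- function(g, marker_ids = NULL, threshold = 0) {
  if (!is.null(marker_ids)) g <- subset_geno(g, marker_ids = marker_ids)
  st <- site_stats_matrix(g$dosage)
  ok <- st$n_genotypes > 0L
  if (!any(ok)) return(NA_real_)
  mean(st$maf[ok] > threshold)
}

#' Per-population diversity report
#'
#' Means and standard deviations across sites, per population, of MAF, Ho,
#' He, Pi and PIC, plus the proportion of polymorphic markers (Pn) — the
#' standard per-breed genetic-diversity table. Sites entirely missing in a
#' population are excluded from that population's means.
#'
#' @param g a \code{geno_matrix}
#' @param labels per-sample population labels (default: breed labels of
#'   \code{g}); samples with NA labels are ignored
#' @return a \code{diversity_report}: data.frame with one row per
#'   population and columns \code{maf_mean/maf_sd}, \code{ho_mean/ho_sd},
#'   \code{he_mean/he_sd}, \code{pi_mean/pi_sd}, \code{pic_mean/pic_sd},
#'   \code{pn}, \code{n_samples}, \code{n_sites}. Per-site vectors are kept
#'   in \code{attr(, "per_site")} for downstream tests.
#' @export
population_report <- function(g, labels = breed_labels(g)) {
  labels <- as.character(labels)
  pops <- unique(stats::na.omit(labels))
  if (length(pops) == 0L) stop("no population labels available")
  per_site <- list()
  rows <- lapply(pops, function(b) {
    d <- g$dosage[which(labels == b), , drop = FALSE]
    st <- site_stats_matrix(d)
    st <- st[st$n_genotypes > 0L, , drop = FALSE]
    per_site[[b]] <<- st
    data.frame(
      population = b,
      n_samples = sum(labels == b, na.rm = TRUE),
      n_sites = nrow(st),
      maf_mean = mean(st$maf), maf_sd = stats::sd(st$maf),
      ho_mean = mean(st$ho), ho_sd = stats::sd(st$ho),
      he_mean = mean(st$he), he_sd = stats::sd(st$he),
      pi_mean = mean(st$pi), pi_sd = stats::sd(st$pi),
      pic_mean = mean(st$pic), pic_sd = stats::sd(st$pic),
      pn = mean(st$maf > 0),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_site") <- per_site
  class(out) <- c("diversity_report", "data.frame")
  out
}

#' @exportS3Method base::print
print.diversity_report <- function(x, digits = 4, ...) {
  cat("Per-population diversity (means across sites):\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Rank-sum comparison of two per-site statistic vectors
#'
#' Two-sided Mann-Whitney U test with normal approximation and tie
#' correction, as used to compare diversity indices between an offspring
#' and a parental population site-by-site. Wraps \code{stats::wilcox.test}.
#'
#' @param x,y numeric vectors of per-site statistics
#' @return the p-value.
#' @export
rank_sum_compare <- function(x, y) {
  stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
}
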