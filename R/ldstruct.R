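#' Composite LD between two sites
#'
#' Squared Pearson correlation of the dosage vectors over jointly
#' non-missing samples (composite LD: phase-free, the standard convention
#' for genotype-based decay curves). Symmetric and invariant to allele
#' flips at either site.
#'
#' @param dosage_a,dosage_b integer dosage vectors of equal length
#' @return r-squared in [0, 1]; \code{NA} when either site is monomorphic
#'   in the complete-pairs subset.
#' @export
pair_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (length(a) < 2L) return(NA_real_)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Linkage-disequilibrium decay curve
#'
#' Mean pairwise \eqn{r^2} in physical-distance bins. All within-chromosome
#' marker pairs closer than \code{max_dist_bp} enter (optionally capped per
#' chromosome by seeded subsampling for tractability); bins are half-open
#' \code{[lo, hi)} of width \code{bin_width_bp}.
#'
#' @param g a \code{geno_matrix}
#' @param max_dist_bp maximum pair distance; default 1e6 (1000 kb)
#' @param bin_width_bp bin width; default 1e4 (10 kb)
#' @param max_pairs_per_chrom optional cap on pairs per chromosome
#' @param seed seed for the subsampling cap
#' @return data.frame of bins: \code{distance_lo_bp},
#'   \code{distance_hi_bp}, \code{mean_r2}, \code{n_pairs}; attribute
#'   \code{subsampled} records whether the cap was hit.
#' @export
ld_decay <- function(g, max_dist_bp = 1e6, bin_width_bp = 1e4,
                     max_pairs_per_chrom = NULL, seed = 1) {
  nb <- ceiling(max_dist_bp / bin_width_bp)
  sum_r2 <- n_pair <- rep(0, nb)
  subsampled <- FALSE
  for (ch in unique(g$map$chrom)) {
    ci <- which(g$map$chrom == ch)
    if (length(ci) < 2L) next
    ci <- ci[order(g$map$pos[ci])]
    pos <- g$map$pos[ci]
    pr <- list()
    for (i in seq_len(length(ci) - 1L)) {
      j <- which(pos > pos[i] & pos - pos[i] < max_dist_bp)
      j <- j[j > i]
      if (length(j)) pr[[length(pr) + 1L]] <- cbind(i, j)
    }
    if (!length(pr)) next
    pairs <- do.call(rbind, pr)
    if (!is.null(max_pairs_per_chrom) && nrow(pairs) > max_pairs_per_chrom) {
      set.seed(seed)
      pairs <- pairs[sample(nrow(pairs), max_pairs_per_chrom), , drop = FALSE]
      subsampled <- TRUE
    }
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      r2 <- pair_r2(g$dosage[, ci[i]], g$dosage[, ci[j]])
      if (is.na(r2)) next
      b <- 1L + floor((pos[j] - pos[i]) / bin_width_bp)
      sum_r2[b] <- sum_r2[b] + r2
      n_pair[b] <- n_pair[b] + 1
    }
  }
  out <- data.frame(
    distance_lo_bp = (seq_len(nb) - 1L) * bin_width_bp,
    distance_hi_bp = seq_len(nb) * bin_width_bp,
    mean_r2 = ifelse(n_pair > 0, sum_r2 / pmax(1, n_pair), NA_real_),
    n_pairs = n_pair
  )
  attr(out, "subsampled") <- subsampled
  out
}

#' Principal component analysis of genotypes
#'
#' Standardised-genotype PCA: each site is centred by \eqn{2\hat p} and
#' scaled by \eqn{\sqrt{2\hat p(1-\hat p)}}; missing entries become 0 after
#' centring; monomorphic sites are dropped. Scores are the projections on
#' the eigenvectors of the sample covariance of the standardised matrix;
#' explained fractions are eigenvalue ratios. Deterministic up to component
#' sign.
#'
#' @param g a \code{geno_matrix}
#' @param n_components number of components to keep; default 10
#' @return an object of class \code{geno_pca}: list with \code{scores}
#'   (n x k matrix), \code{explained_fraction}, \code{sdev}.
#' @export
pca_geno <- function(g, n_components = 10) {
  X <- standardize_dosage(g$dosage)
  n <- nrow(X)
  k <- min(n_components, n - 1L, ncol(X))
  if (k < 1L) stop("not enough samples/markers for PCA")
  Xc <- sweep(X, 2, colMeans(X))  # re-centre across retained samples
  sv <- svd(Xc, nu = k, nv = 0)
  ev <- sv$d^2 / (n - 1)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- g$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 explained_fraction = ev[seq_len(k)] / sum(ev),
                 sdev = sqrt(ev[seq_len(k)])),
            class = "geno_pca")
}

standardize_dosage <- function(dosage) {
  p <- counted_freq(dosage)
  keep <- !is.na(p) & p > 0 & p < 1
  X <- dosage[, keep, drop = FALSE]
  p <- p[keep]
  mu <- 2 * p
  sc <- sqrt(2 * p * (1 - p))
  X <- sweep(X, 2, mu)
  X <- sweep(X, 2, sc, "/")
  X[is.na(X)] <- 0
  X
}

#' @exportS3Method base::print
print.geno_pca <- function(x, ...) {
  cat(sprintf("geno_pca: %d samples, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("explained fraction:",
      paste(sprintf("%.2f%%", 100 * x$explained_fraction), collapse = " "),
      "\n")
  invisible(x)
}
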