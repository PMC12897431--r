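#' Quality-control thresholds
#'
#' The two QC layers used throughout: the analysis-time PLINK-style chain
#' (individual call rate, autosomes, site call rate, MAF, Hardy-Weinberg)
#' and the panel-design pre-screen (site missingness and heterozygosity).
#'
#' Boundary semantics follow the PLINK conventions: an individual with call
#' rate strictly below 90\% is removed; a SNP is retained at MAF equality
#' with \code{min_maf}; HWE removes strictly below \code{hwe_alpha}; the
#' design-screen bounds are strict ("below 0.1", "below 0.5").
#'
#' @param max_individual_missing remove individuals with missing fraction
#'   above this (call rate < 1 - value); default 0.10
#' @param max_site_missing remove sites with missing fraction above this;
#'   default 0.10
#' @param min_maf retain sites with minor allele frequency >= this;
#'   default 0.01
#' @param hwe_alpha remove sites with exact HWE p-value < this;
#'   default 1e-6
#' @param max_site_het design-screen only: drop sites with observed
#'   heterozygote fraction >= this; default 0.5
#' @param autosomes_only restrict to autosomes; default TRUE
#' @param autosomes chromosome labels counted as autosomes; default
#'   \code{as.character(1:18)} (Sus scrofa)
#' @return a list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(max_individual_missing = 0.10,
                          max_site_missing = 0.10,
                          min_maf = 0.01,
                          hwe_alpha = 1e-6,
                          max_site_het = 0.5,
                          autosomes_only = TRUE,
                          autosomes = as.character(1:18)) {
  vals <- c(max_individual_missing, max_site_missing, min_maf, max_site_het)
  if (any(vals < 0) || any(vals > 1))
    stop("QC fractions must lie in [0, 1]")
  structure(list(max_individual_missing = max_individual_missing,
                 max_site_missing = max_site_missing,
                 min_maf = min_maf,
                 hwe_alpha = hwe_alpha,
                 max_site_het = max_site_het,
                 autosomes_only = autosomes_only,
                 autosomes = autosomes),
            class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test for a biallelic site: conditioning on the observed
#' allele counts, the p-value is the total probability of all heterozygote
#' counts no more probable than the observed one. Probabilities are computed
#' in log space from the closed-form conditional distribution
#' \deqn{P(n_{Aa}) = \frac{n!\,2^{n_{Aa}}\,n_A!\,n_a!}
#'   {n_{AA}!\,n_{Aa}!\,n_{aa}!\,(2n)!}.}
#'
#' @param n_aa count of allele-a homozygotes
#' @param n_ab heterozygote count
#' @param n_bb count of allele-b homozygotes
#' @return p-value in (0, 1]; symmetric in \code{n_aa} and \code{n_bb}.
#' @examples
#' hwe_exact_pvalue(25, 50, 25)
#' @export
hwe_exact_pvalue <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("all genotypes missing: HWE undefined")
  na <- 2L * n_aa + n_ab   # copies of allele a
  nb <- 2L * n_bb + n_ab
  rare <- min(na, nb)
  if (rare == 0L) return(1.0)  # monomorphic: single configuration
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- lfactorial(n) + hets * log(2) + lfactorial(na) + lfactorial(nb) -
    lfactorial((na - hets) / 2) - lfactorial(hets) -
    lfactorial((nb - hets) / 2) - lfactorial(2L * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  min(1.0, sum(p[p <= obs * (1 + 1e-12)]))
}

per_site_counts <- function(dosage) {
  nhet <- colSums(dosage == 1L, na.rm = TRUE)
  n0 <- colSums(dosage == 0L, na.rm = TRUE)
  n2 <- colSums(dosage == 2L, na.rm = TRUE)
  list(n_aa = n0, n_ab = nhet, n_bb = n2, n = n0 + nhet + n2)
}

qc_report <- function(stage, rule, removed, retained) {
  structure(data.frame(stage = stage, rule = rule,
                       removed = removed, retained = retained,
                       stringsAsFactors = FALSE),
            class = c("qc_report", "data.frame"))
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Remove low-call-rate individuals
#'
#' Drops individuals whose missing-genotype fraction exceeds
#' \code{max_individual_missing} (call rate strictly below the complement).
#'
#' @param g a \code{geno_matrix}
#' @param thresholds a \code{\link{qc_thresholds}}
#' @return list with elements \code{geno} (filtered matrix) and
#'   \code{report} (a \code{qc_report}).
#' @export
filter_individuals <- function(g, thresholds = qc_thresholds()) {
  m <- ncol(g$dosage)
  fr <- rowSums(is.na(g$dosage)) / max(1L, m)
  keep <- fr <= thresholds$max_individual_missing
  out <- g
  out$dosage <- g$dosage[keep, , drop = FALSE]
  out$samples <- g$samples[keep, , drop = FALSE]
  rownames(out$samples) <- NULL
  list(geno = out,
       report = qc_report("individuals", "call_rate", sum(!keep), sum(keep)))
}

#' PLINK-style site filter chain
#'
#' Applies, in order: autosome restriction, site call rate, minimum MAF,
#' exact Hardy-Weinberg. Site statistics are recomputed on the current
#' sample set. When breed labels are present and
#' \code{hwe_by_population = TRUE} (default) the HWE test is run within each
#' labelled population and a site is removed only if it fails in at least
#' one population — pooling across differentiated breeds would reject sound
#' sites through the Wahlund effect.
#'
#' @param g a \code{geno_matrix}
#' @param thresholds a \code{\link{qc_thresholds}}
#' @param hwe_by_population test HWE within breed labels when available
#' @return list with elements \code{geno} and \code{report}; an empty
#'   result is permitted with a warning.
#' @export
filter_sites <- function(g, thresholds = qc_thresholds(),
                         hwe_by_population = TRUE) {
  rep_rows <- list()
  # (1) autosomes
  if (thresholds$autosomes_only) {
    keep <- g$map$chrom %in% thresholds$autosomes
    rep_rows[[length(rep_rows) + 1L]] <-
      qc_report("sites", "autosome", sum(!keep), sum(keep))
    g <- drop_sites(g, keep)
  }
  # (2) site call rate
  n <- nrow(g$dosage)
  fr <- colSums(is.na(g$dosage)) / max(1L, n)
  keep <- fr <= thresholds$max_site_missing
  rep_rows[[length(rep_rows) + 1L]] <-
    qc_report("sites", "call_rate", sum(!keep), sum(keep))
  g <- drop_sites(g, keep)
  # (3) MAF
  cnt <- per_site_counts(g$dosage)
  p <- (2 * cnt$n_bb + cnt$n_ab) / pmax(1L, 2 * cnt$n)
  maf <- pmin(p, 1 - p)
  keep <- maf >= thresholds$min_maf & cnt$n > 0L
  rep_rows[[length(rep_rows) + 1L]] <-
    qc_report("sites", "maf", sum(!keep), sum(keep))
  g <- drop_sites(g, keep)
  # (4) HWE
  labels <- breed_labels(g)
  use_pops <- hwe_by_population && any(!is.na(labels)) &&
    length(unique(stats::na.omit(labels))) > 1L
  pv <- hwe_site_pvalues(g$dosage, if (use_pops) labels else NULL)
  keep <- pv >= thresholds$hwe_alpha
  rep_rows[[length(rep_rows) + 1L]] <-
    qc_report("sites", "hwe", sum(!keep), sum(keep))
  g <- drop_sites(g, keep)
  if (ncol(g$dosage) == 0L)
    warning("no sites remain after QC")
  report <- do.call(rbind, rep_rows)
  class(report) <- c("qc_report", "data.frame")
  list(geno = g, report = report)
}

drop_sites <- function(g, keep) {
  g$dosage <- g$dosage[, keep, drop = FALSE]
  g$map <- g$map[keep, , drop = FALSE]
  rownames(g$map) <- NULL
  g
}

# minimum per-population HWE p-value per site (or pooled when labels NULL);
# sites with zero genotypes in every population get p = 1
hwe_site_pvalues <- function(dosage, labels = NULL) {
  one <- function(d) {
    cnt <- per_site_counts(d)
    vapply(seq_along(cnt$n), function(j) {
      if (cnt$n[j] == 0L) return(1.0)
      hwe_exact_pvalue(cnt$n_aa[j], cnt$n_ab[j], cnt$n_bb[j])
    }, numeric(1))
  }
  if (is.null(labels)) return(one(dosage))
  pv <- rep(1.0, ncol(dosage))
  for (b in unique(stats::na.omit(labels))) {
    pv <- pmin(pv, one(dosage[labels == b, , drop = FALSE]))
  }
  pv
}

#' Panel-design site pre-screen
#'
#' The screen applied to candidate variants before breed-informative marker
#' selection: a site is retained when its missing fraction is strictly
#' below \code{max_site_missing} and its observed heterozygote fraction is
#' strictly below \code{max_site_het}. High-heterozygosity sites are
#' enriched for paralogue-collapse artefacts.
#'
#' @inheritParams filter_sites
#' @return list with elements \code{geno} and \code{report}.
#' @export
panel_design_screen <- function(g, thresholds = qc_thresholds()) {
  n <- nrow(g$dosage)
  fr <- colSums(is.na(g$dosage)) / max(1L, n)
  keep1 <- fr < thresholds$max_site_missing
  r1 <- qc_report("sites", "missingness", sum(!keep1), sum(keep1))
  g <- drop_sites(g, keep1)
  cnt <- per_site_counts(g$dosage)
  het <- ifelse(cnt$n > 0L, cnt$n_ab / cnt$n, 0)
  keep2 <- het < thresholds$max_site_het
  r2 <- qc_report("sites", "heterozygosity", sum(!keep2), sum(keep2))
  g <- drop_sites(g, keep2)
  report <- rbind(r1, r2)
  class(report) <- c("qc_report", "data.frame")
  list(geno = g, report = report)
}
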