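#' Panel-design specification
#'
#' Parameters for breed-informative marker selection: per-chromosome
#' selection target, positional coverage bins and the pooling rule for the
#' non-target ("other breeds") allele frequency.
#'
#' @param per_chromosome_target markers to select per chromosome per breed;
#'   default 1200
#' @param coverage_bins equal-width positional bins per chromosome; default
#'   equals \code{per_chromosome_target}
#' @param dedupe drop duplicate nominations when merging per-breed lists
#' @param other_maf \code{"pooled"} (pool genotypes of all non-target
#'   individuals, weighting breeds by sample size) or \code{"mean"}
#'   (unweighted mean of per-breed MAFs)
#' @param folded compare folded MAFs (both sides folded to <= 0.5, the
#'   printed definition) or unfolded counted-allele frequencies
#' @return a list of class \code{panel_spec}.
#' @export
panel_spec <- function(per_chromosome_target = 1200,
                       coverage_bins = per_chromosome_target,
                       dedupe = TRUE,
                       other_maf = c("pooled", "mean"),
                       folded = TRUE) {
  if (per_chromosome_target < 1 || coverage_bins < 1)
    stop("targets must be >= 1")
  structure(list(per_chromosome_target = as.integer(per_chromosome_target),
                 coverage_bins = as.integer(coverage_bins),
                 dedupe = isTRUE(dedupe),
                 other_maf = match.arg(other_maf),
                 folded = isTRUE(folded)),
            class = "panel_spec")
}

#' Breed-informativeness score of a marker
#'
#' \eqn{\Delta MAF = |MAF_{target} - MAF_{other}|}: the absolute difference
#' between the minor-allele frequency in the target breed and the combined
#' MAF of all remaining breeds.
#'
#' @param maf_target MAF in the target breed, in [0, 0.5]
#' @param maf_other combined MAF of the other breeds, in [0, 0.5]
#' @return the absolute difference, in [0, 0.5].
#' @export
delta_maf <- function(maf_target, maf_other) {
  if (any(maf_target < 0 | maf_target > 0.5, na.rm = TRUE) ||
      any(maf_other < 0 | maf_other > 0.5, na.rm = TRUE))
    stop("MAFs must lie in [0, 0.5]")
  abs(maf_target - maf_other)
}

# per-site frequency of the counted allele in a dosage matrix
counted_freq <- function(dosage) {
  n <- colSums(!is.na(dosage))
  s <- colSums(dosage, na.rm = TRUE)
  ifelse(n > 0L, s / (2 * n), NA_real_)
}

#' Combined MAF of all breeds except the target
#'
#' Pools the genotypes of every individual not in the target breed
#' (sample-size-weighted, the default) or averages per-breed MAFs
#' unweighted, and folds to the minor allele.
#'
#' @param g a \code{geno_matrix}
#' @param labels per-sample breed labels
#' @param target_breed the breed excluded from the pool
#' @param method \code{"pooled"} or \code{"mean"}
#' @return per-site numeric vector of combined MAFs.
#' @export
other_breeds_maf <- function(g, labels = breed_labels(g), target_breed,
                             method = c("pooled", "mean")) {
  method <- match.arg(method)
  labels <- as.character(labels)
  other <- which(!is.na(labels) & labels != target_breed)
  if (length(other) == 0L) stop("no individuals outside breed ", target_breed)
  if (method == "pooled") {
    p <- counted_freq(g$dosage[other, , drop = FALSE])
    return(unname(pmin(p, 1 - p)))
  }
  breeds <- unique(labels[other])
  mafs <- vapply(breeds, function(b) {
    p <- counted_freq(g$dosage[which(labels == b), , drop = FALSE])
    pmin(p, 1 - p)
  }, numeric(ncol(g$dosage)))
  unname(rowMeans(matrix(mafs, ncol = length(breeds)), na.rm = TRUE))
}

#' Rank sites by breed informativeness
#'
#' Computes per-site \eqn{\Delta MAF} for one target breed and returns
#' sites in descending order, ties broken by genomic order
#' (chromosome, position, marker id) so the ranking is deterministic.
#'
#' @param g a \code{geno_matrix}
#' @param labels per-sample breed labels
#' @param breed target breed
#' @param spec a \code{\link{panel_spec}}
#' @return data.frame with columns \code{marker_id}, \code{chrom},
#'   \code{pos}, \code{maf_target}, \code{maf_other}, \code{delta_maf},
#'   sorted by decreasing \code{delta_maf}.
#' @export
rank_sites_for_breed <- function(g, labels = breed_labels(g), breed,
                                 spec = panel_spec()) {
  labels <- as.character(labels)
  tgt <- which(!is.na(labels) & labels == breed)
  if (length(tgt) == 0L) stop("no individuals in breed ", breed)
  p_t <- counted_freq(g$dosage[tgt, , drop = FALSE])
  if (spec$folded) {
    maf_t <- pmin(p_t, 1 - p_t)
    maf_o <- other_breeds_maf(g, labels, breed, spec$other_maf)
    dm <- abs(maf_t - maf_o)
  } else {
    other <- which(!is.na(labels) & labels != breed)
    p_o <- counted_freq(g$dosage[other, , drop = FALSE])
    maf_t <- p_t; maf_o <- p_o
    dm <- abs(p_t - p_o)
  }
  df <- data.frame(marker_id = g$map$marker_id, chrom = g$map$chrom,
                   pos = g$map$pos, maf_target = maf_t, maf_other = maf_o,
                   delta_maf = dm, stringsAsFactors = FALSE)
  df <- df[!is.na(df$delta_maf), , drop = FALSE]
  o <- order(-df$delta_maf, df$chrom, df$pos, df$marker_id)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Uniform-coverage selection along one chromosome
#'
#' Balances the twin goals of high \eqn{\Delta MAF} and even chromosomal
#' coverage: the span from the first to the last candidate marker is cut
#' into \code{coverage_bins} equal-width bins and the highest-ranked
#' unpicked site in each bin is selected; bins with no eligible site are
#' backfilled with the globally next-best remaining sites on the
#' chromosome until \code{per_chromosome_target} markers are selected or
#' candidates are exhausted. Deterministic and seed-free.
#'
#' @param ranked data.frame as returned by
#'   \code{\link{rank_sites_for_breed}} (any subset of its rows)
#' @param chromosome chromosome label to select on
#' @param spec a \code{\link{panel_spec}}
#' @return the selected subset of \code{ranked}, with a \code{bin} column
#'   (NA for backfilled picks).
#' @export
select_uniform <- function(ranked, chromosome, spec = panel_spec()) {
  cand <- ranked[ranked$chrom == chromosome, , drop = FALSE]
  if (nrow(cand) == 0L) {
    message("no eligible sites on chromosome ", chromosome)
    cand$bin <- integer(0)
    return(cand)
  }
  target <- min(spec$per_chromosome_target, nrow(cand))
  lo <- min(cand$pos); hi <- max(cand$pos)
  nb <- spec$coverage_bins
  if (hi == lo) {
    bin <- rep(1L, nrow(cand))
  } else {
    bin <- pmin(nb, 1L + floor((cand$pos - lo) / ((hi - lo) / nb) ))
  }
  cand$bin <- as.integer(bin)
  # per-bin argmax: cand rows are already in rank order, keep first per bin
  first_in_bin <- !duplicated(cand$bin)
  picked <- which(first_in_bin)
  if (length(picked) > target)
    picked <- picked[seq_len(target)]
  if (length(picked) < target) {
    rest <- setdiff(seq_len(nrow(cand)), picked)
    extra <- rest[seq_len(min(target - length(picked), length(rest)))]
    cand$bin[extra] <- NA_integer_
    picked <- c(picked, extra)
  }
  out <- cand[sort(picked), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a breed-composition marker panel
#'
#' The full panel-design pipeline: site pre-screen
#' (\code{\link{panel_design_screen}}), per-breed \eqn{\Delta MAF} ranking,
#' per-chromosome uniform-coverage selection for each breed, union of the
#' per-breed lists and deduplication (recording every breed that nominated
#' a marker).
#'
#' @param g a \code{geno_matrix} of the labelled reference panel
#' @param labels per-sample breed labels
#' @param spec a \code{\link{panel_spec}}
#' @param thresholds screen thresholds, a \code{\link{qc_thresholds}}
#' @return a \code{panel_result}: data.frame with one row per selected
#'   marker (\code{marker_id}, \code{chrom}, \code{pos}, \code{breeds}
#'   (comma-joined nominating breeds), \code{delta_maf} (maximum over
#'   nominations), \code{bin}), plus the screen report in
#'   \code{attr(, "screen_report")}.
#' @export
build_gbc_panel <- function(g, labels = breed_labels(g), spec = panel_spec(),
                            thresholds = qc_thresholds()) {
  labels <- as.character(labels)
  scr <- panel_design_screen(g, thresholds)
  gs <- scr$geno
  breeds <- unique(stats::na.omit(labels))
  if (length(breeds) < 2L) stop("panel design needs >= 2 labelled breeds")
  picks <- list()
  for (b in breeds) {
    ranked <- rank_sites_for_breed(gs, labels, b, spec)
    for (ch in unique(gs$map$chrom)) {
      sel <- select_uniform(ranked, ch, spec)
      if (nrow(sel)) {
        sel$breed <- b
        picks[[length(picks) + 1L]] <- sel
      }
    }
  }
  all <- do.call(rbind, picks)
  if (spec$dedupe) {
    agg_breeds <- tapply(all$breed, all$marker_id,
                         function(x) paste(sort(unique(x)), collapse = ","))
    agg_dm <- tapply(all$delta_maf, all$marker_id, max)
    first <- all[!duplicated(all$marker_id), , drop = FALSE]
    first$breeds <- as.character(agg_breeds[first$marker_id])
    first$delta_maf <- as.numeric(agg_dm[first$marker_id])
    first$breed <- NULL
    out <- first
  } else {
    all$breeds <- all$breed
    all$breed <- NULL
    out <- all
  }
  out <- out[order(out$chrom, out$pos, out$marker_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "screen_report") <- scr$report
  class(out) <- c("panel_result", "data.frame")
  out
}

#' @exportS3Method base::print
print.panel_result <- function(x, ...) {
  cat(sprintf("GBC marker panel: %d markers on %d chromosomes, mean dMAF %.3f\n",
              nrow(x), length(unique(x$chrom)), mean(x$delta_maf)))
  invisible(x)
}
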