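#' Identity-by-state similarity matrix
#'
#' \eqn{IBS(i,j)} is the mean over jointly non-missing sites of
#' \eqn{(2 - |g_i - g_j|)/2}: 1 for identical genotypes, 0 for opposite
#' homozygotes. Computed with matrix algebra over a missingness mask.
#'
#' @param g a \code{geno_matrix}
#' @return an \code{ibs_matrix}: list with \code{ibs} (n x n symmetric
#'   matrix, diagonal 1) and \code{n_shared} (jointly non-missing site
#'   counts).
#' @export
ibs_matrix <- function(g) {
  D <- g$dosage
  W <- !is.na(D)
  Dz <- D; Dz[!W] <- 0L
  storage.mode(Dz) <- "double"; storage.mode(W) <- "double"
  n_shared <- W %*% t(W)
  # sum |gi - gj| over shared sites: split by genotype class
  I0 <- (Dz == 0) * W; I1 <- (Dz == 1) * W; I2 <- (Dz == 2) * W
  absdiff <- I0 %*% t(I1) + I1 %*% t(I0) +      # |0-1| = 1
    2 * (I0 %*% t(I2) + I2 %*% t(I0)) +         # |0-2| = 2
    I1 %*% t(I2) + I2 %*% t(I1)                 # |1-2| = 1
  ibs <- ifelse(n_shared > 0, (2 * n_shared - absdiff) / (2 * n_shared),
                NA_real_)
  dimnames(ibs) <- list(g$samples$sample_id, g$samples$sample_id)
  structure(list(ibs = ibs, n_shared = n_shared), class = "ibs_matrix")
}

#' @exportS3Method base::print
print.ibs_matrix <- function(x, ...) {
  off <- x$ibs[upper.tri(x$ibs)]
  cat(sprintf("ibs_matrix: %d individuals, mean off-diagonal IBS %.4f\n",
              nrow(x$ibs), mean(off, na.rm = TRUE)))
  invisible(x)
}

#' Cluster individuals into molecular families
#'
#' Average-linkage hierarchical clustering on the distance \eqn{1 - IBS},
#' cut at a fixed family count. Deterministic: ties resolve by the sample
#' order of the input matrix.
#'
#' @param ibs an \code{\link{ibs_matrix}} (or a plain similarity matrix)
#' @param n_families number of families to cut the tree into
#' @return a \code{family_assignment}: data.frame \code{sample_id},
#'   \code{family_id} (integer 1..n_families); the \code{hclust} tree is
#'   kept in \code{attr(, "tree")}.
#' @export
cluster_families <- function(ibs, n_families) {
  M <- if (inherits(ibs, "ibs_matrix")) ibs$ibs else as.matrix(ibs)
  if (n_families < 1L || n_families > nrow(M))
    stop("n_families must be between 1 and the number of individuals")
  hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
  fam <- stats::cutree(hc, k = n_families)
  out <- data.frame(sample_id = rownames(M), family_id = unname(fam),
                    stringsAsFactors = FALSE)
  attr(out, "tree") <- hc
  class(out) <- c("family_assignment", "data.frame")
  out
}

#' Exclude highly inbred candidates
#'
#' Drops individuals whose genomic inbreeding coefficient exceeds the
#' threshold (strictly; \eqn{F_{ROH} = 0.30} is retained at the default).
#'
#' @param candidates character vector of sample ids
#' @param froh_records data.frame from \code{\link{froh}}
#' @param threshold exclusion threshold; default 0.3
#' @return the retained sample ids.
#' @export
exclude_high_froh <- function(candidates, froh_records, threshold = 0.3) {
  f <- froh_records$froh[match(candidates, froh_records$sample_id)]
  if (anyNA(f)) stop("candidates missing from froh records: ",
                     paste(candidates[is.na(f)], collapse = ", "))
  candidates[f <= threshold]
}

#' Propose cross-family purebred matings
#'
#' Greedy round-robin mate allocation for conservation breeding: every
#' family holding an eligible sire contributes; each sire is paired with
#' dams from other families, preferring the least-used dam family (ties
#' broken by the lower pair IBS, then by sample order). Candidates with
#' \eqn{F_{ROH}} above the exclusion threshold never enter the plan.
#'
#' @param families a \code{\link{cluster_families}} assignment
#' @param sexes named character vector (\code{"M"}/\code{"F"}) per sample
#' @param froh_records data.frame from \code{\link{froh}} (optional; when
#'   given, high-F_ROH animals are excluded first)
#' @param ibs an \code{\link{ibs_matrix}} for tie-breaking (optional)
#' @param matings_per_sire dams allocated per sire; default 2
#' @param froh_max exclusion threshold; default 0.3
#' @return a \code{mating_plan}: data.frame \code{sire_id}, \code{dam_id},
#'   \code{sire_family}, \code{dam_family}, \code{pair_ibs}.
#' @export
propose_matings <- function(families, sexes, froh_records = NULL, ibs = NULL,
                            matings_per_sire = 2, froh_max = 0.3) {
  ids <- families$sample_id
  fam <- stats::setNames(families$family_id, ids)
  eligible <- ids
  if (!is.null(froh_records))
    eligible <- exclude_high_froh(eligible, froh_records, froh_max)
  sx <- sexes[eligible]
  sires <- eligible[sx == "M"]
  dams <- eligible[sx == "F"]
  if (length(sires) == 0L || length(dams) == 0L)
    stop("no eligible sires or dams after exclusions")
  M <- if (inherits(ibs, "ibs_matrix")) ibs$ibs else ibs
  dam_left <- stats::setNames(rep(TRUE, length(dams)), dams)
  fam_use <- stats::setNames(rep(0L, length(unique(fam))),
                             sort(unique(fam)))
  sire_left <- stats::setNames(rep(as.integer(matings_per_sire),
                                   length(sires)), sires)
  plan <- list()
  sire_fams <- unique(fam[sires])
  # round-robin over sire families: every family gets its first mating
  # before any family gets a second, so the plan covers all sire families
  # while eligible dams remain
  repeat {
    allocated <- FALSE
    for (sf in sire_fams) {
      cand_s <- sires[fam[sires] == sf & sire_left[sires] > 0L]
      if (length(cand_s) == 0L) next
      s <- cand_s[which.max(sire_left[cand_s])]  # spread within the family
      avail <- dams[fam[dams] != sf & dam_left[dams]]
      if (length(avail) == 0L) { sire_left[s] <- 0L; next }
      # least-used dam family first, then lower pair IBS, then input order
      use_f <- fam_use[as.character(fam[avail])]
      cand <- avail[use_f == min(use_f)]
      if (length(cand) > 1L && !is.null(M)) cand <- cand[which.min(M[s, cand])]
      d <- cand[1]
      plan[[length(plan) + 1L]] <- data.frame(
        sire_id = s, dam_id = d,
        sire_family = unname(fam[s]), dam_family = unname(fam[d]),
        pair_ibs = if (is.null(M)) NA_real_ else unname(M[s, d]),
        stringsAsFactors = FALSE)
      dam_left[d] <- FALSE
      fam_use[as.character(fam[d])] <- fam_use[as.character(fam[d])] + 1L
      sire_left[s] <- sire_left[s] - 1L
      allocated <- TRUE
    }
    if (!allocated) break
  }
  if (length(plan) == 0L)
    stop("no cross-family sire/dam pairing is possible: ",
         "all eligible animals fall in one family")
  out <- do.call(rbind, plan)
  rownames(out) <- NULL
  class(out) <- c("mating_plan", "data.frame")
  out
}

#' Simulate offspring of a mating plan
#'
#' Mendelian gamete sampling per marker (no linkage): each offspring draws
#' one allele from each parent's genotype at every site. Used to compare
#' the expected diversity of planned cross-family litters against
#' alternatives.
#'
#' @param g parental \code{geno_matrix}
#' @param plan a \code{\link{propose_matings}} plan (or any data.frame with
#'   \code{sire_id}/\code{dam_id})
#' @param offspring_per_pair litter size simulated per pair; default 4
#' @param seed RNG seed
#' @return a \code{geno_matrix} of offspring; sample table records
#'   \code{sire_id} and \code{dam_id}.
#' @export
simulate_offspring <- function(g, plan, offspring_per_pair = 4, seed = 1) {
  set.seed(seed)
  m <- ncol(g$dosage)
  rows <- list(); meta <- list()
  gam <- function(d) {
    # P(transmit counted allele) = d/2; missing parent site -> missing allele
    out <- rep(NA_integer_, length(d))
    ok <- !is.na(d)
    out[ok] <- stats::rbinom(sum(ok), 1L, d[ok] / 2)
    out
  }
  for (k in seq_len(nrow(plan))) {
    ds <- g$dosage[match(plan$sire_id[k], g$samples$sample_id), ]
    dd <- g$dosage[match(plan$dam_id[k], g$samples$sample_id), ]
    for (o in seq_len(offspring_per_pair)) {
      rows[[length(rows) + 1L]] <- gam(ds) + gam(dd)
      meta[[length(meta) + 1L]] <- data.frame(
        sample_id = sprintf("off_%d_%d", k, o),
        sire_id = plan$sire_id[k], dam_id = plan$dam_id[k],
        stringsAsFactors = FALSE)
    }
  }
  dosage <- do.call(rbind, rows)
  samples <- do.call(rbind, meta)
  rownames(dosage) <- samples$sample_id
  geno_matrix(dosage, g$map, samples)
}
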