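#' Run-of-homozygosity scan parameters
#'
#' PLINK-style sliding-window parameterisation: a minimum segment length of
#' 500 kb, 30-SNP scanning windows, and at most 1 heterozygote and 5
#' missing calls allowed inside a run. \code{hit_proportion} is the
#' fraction of homozygous windows a SNP must reach to become part of a
#' candidate run (PLINK's default 0.05).
#'
#' @param min_length_bp minimum segment length; default 500,000
#' @param window_snp SNPs per scanning window; default 30
#' @param max_het_per_window heterozygotes tolerated per window (and per
#'   final segment); default 1
#' @param max_missing_per_window missing calls tolerated per window (and
#'   per final segment); default 5
#' @param hit_proportion homozygous-window fraction above which a SNP is a
#'   candidate; default 0.05
#' @param min_snp_in_roh minimum SNPs per segment; default
#'   \code{window_snp}
#' @return a list of class \code{roh_params}.
#' @export
roh_params <- function(min_length_bp = 500000, window_snp = 30,
                       max_het_per_window = 1, max_missing_per_window = 5,
                       hit_proportion = 0.05,
                       min_snp_in_roh = window_snp) {
  if (min_length_bp < 1) stop("min_length_bp must be >= 1")
  vals <- c(window_snp, max_het_per_window, max_missing_per_window,
            hit_proportion, min_snp_in_roh)
  if (any(vals < 0)) stop("ROH parameters must be >= 0")
  structure(list(min_length_bp = as.numeric(min_length_bp),
                 window_snp = as.integer(window_snp),
                 max_het_per_window = as.integer(max_het_per_window),
                 max_missing_per_window = as.integer(max_missing_per_window),
                 hit_proportion = hit_proportion,
                 min_snp_in_roh = as.integer(min_snp_in_roh)),
            class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' Sliding-window scan in the PLINK style. Per chromosome and individual,
#' every window of \code{window_snp} consecutive SNPs is scored homozygous
#' when it holds at most \code{max_het_per_window} heterozygotes and
#' \code{max_missing_per_window} missing calls; each SNP's hit rate is the
#' homozygous fraction of the windows covering it; SNPs whose rate exceeds
#' \code{hit_proportion} are candidates. Maximal candidate stretches are
#' then trimmed to sub-stretches respecting the het/missing caps at the
#' segment level and reported when they contain at least
#' \code{min_snp_in_roh} SNPs and span at least \code{min_length_bp}
#' (1-based inclusive, length = end - start + 1).
#'
#' @param g a \code{geno_matrix} with markers sorted by (chrom, pos)
#' @param params a \code{\link{roh_params}}
#' @return data.frame of segments: \code{sample_id}, \code{chrom},
#'   \code{start_bp}, \code{end_bp}, \code{length_bp}, \code{n_snps},
#'   \code{n_het}, \code{n_missing}.
#' @export
detect_roh <- function(g, params = roh_params()) {
  if (!map_is_sorted(g$map))
    stop("marker map must be sorted by (chromosome, position); ",
         "sort markers before calling detect_roh")
  segs <- list()
  chroms <- unique(g$map$chrom)
  for (ch in chroms) {
    ci <- which(g$map$chrom == ch)
    pos <- g$map$pos[ci]
    m <- length(ci)
    if (m == 0L) next
    D <- g$dosage[, ci, drop = FALSE]
    for (si in seq_len(nrow(D))) {
      d <- D[si, ]
      cand <- candidate_snps(d, params)
      if (!any(cand)) next
      r <- rle(cand)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        sub <- segment_trim(d[starts[k]:ends[k]], params)
        for (sg in sub) {
          a <- starts[k] + sg[1] - 1L
          b <- starts[k] + sg[2] - 1L
          n_snp <- b - a + 1L
          len <- pos[b] - pos[a] + 1
          if (n_snp < params$min_snp_in_roh || len < params$min_length_bp)
            next
          dd <- d[a:b]
          segs[[length(segs) + 1L]] <- data.frame(
            sample_id = g$samples$sample_id[si], chrom = ch,
            start_bp = pos[a], end_bp = pos[b], length_bp = len,
            n_snps = n_snp, n_het = sum(dd == 1L, na.rm = TRUE),
            n_missing = sum(is.na(dd)), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(segs) == 0L)
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      length_bp = numeric(0), n_snps = integer(0),
                      n_het = integer(0), n_missing = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# per-SNP candidate flags for one individual on one chromosome
candidate_snps <- function(d, params) {
  m <- length(d)
  w <- params$window_snp
  if (m < w) return(rep(FALSE, m))
  het <- as.integer(!is.na(d) & d == 1L)
  mis <- as.integer(is.na(d))
  ch <- cumsum(c(0L, het))
  cm <- cumsum(c(0L, mis))
  nw <- m - w + 1L
  ws <- seq_len(nw)                       # window start indices
  whet <- ch[ws + w] - ch[ws]
  wmis <- cm[ws + w] - cm[ws]
  hom <- as.integer(whet <= params$max_het_per_window &
                    wmis <= params$max_missing_per_window)
  chom <- cumsum(c(0L, hom))
  idx <- seq_len(m)
  lo <- pmax(1L, idx - w + 1L)            # first window covering SNP i
  hi <- pmin(nw, idx)                     # last window covering SNP i
  ncov <- pmax(0L, hi - lo + 1L)
  nhit <- ifelse(ncov > 0L, chom[hi + 1L] - chom[lo], 0L)
  ncov > 0L & (nhit / pmax(1L, ncov)) > params$hit_proportion
}

# split a candidate stretch into maximal sub-stretches meeting segment caps;
# greedy left-to-right two-pointer, returns list of c(start, end) offsets
segment_trim <- function(d, params) {
  m <- length(d)
  het <- as.integer(!is.na(d) & d == 1L)
  mis <- as.integer(is.na(d))
  out <- list()
  a <- 1L
  while (a <= m) {
    h <- 0L; x <- 0L; b <- a - 1L
    while (b < m) {
      nh <- h + het[b + 1L]; nx <- x + mis[b + 1L]
      if (nh > params$max_het_per_window ||
          nx > params$max_missing_per_window) break
      h <- nh; x <- nx; b <- b + 1L
    }
    if (b >= a) {
      out[[length(out) + 1L]] <- c(a, b)
      a <- b + 2L
    } else {
      a <- a + 1L
    }
  }
  out
}

#' Genomic inbreeding coefficient from ROH
#'
#' \eqn{F_{ROH} = \sum L_{ROH} / L_{AUTO}}: total autosomal ROH length over
#' total autosomal length. When \code{autosome_bp} is not given it defaults
#' to the span of the analysed map (per chromosome, last minus first marker
#' position + 1, summed).
#'
#' @param segments segment table from \code{\link{detect_roh}}
#' @param g the \code{geno_matrix} the segments came from (used for sample
#'   ids and the default denominator)
#' @param autosome_bp denominator \eqn{L_{AUTO}} in bp (optional)
#' @return data.frame: \code{sample_id}, \code{sum_roh_bp},
#'   \code{autosome_bp}, \code{froh}.
#' @export
froh <- function(segments, g, autosome_bp = NULL) {
  if (is.null(autosome_bp)) {
    spans <- tapply(g$map$pos, g$map$chrom, function(x) max(x) - min(x) + 1)
    autosome_bp <- sum(spans)
  }
  ids <- g$samples$sample_id
  tot <- rep(0, length(ids))
  names(tot) <- ids
  if (nrow(segments)) {
    agg <- tapply(segments$length_bp, segments$sample_id, sum)
    tot[names(agg)] <- agg
  }
  data.frame(sample_id = ids, sum_roh_bp = unname(tot),
             autosome_bp = autosome_bp,
             froh = unname(tot) / autosome_bp,
             stringsAsFactors = FALSE)
}

#' ROH length-class counts
#'
#' Classifies segments into length classes, by default
#' \code{[min, 5 Mb)}, \code{[5, 10 Mb)} ("long") and \code{>= 10 Mb}
#' ("extra-long"), left-closed.
#'
#' @param segments segment table from \code{\link{detect_roh}}
#' @param bounds_bp internal class boundaries in bp; default
#'   \code{c(5e6, 1e7)}
#' @param by optional vector mapping each segment's sample to a population
#'   label (same order as \code{segments} rows); default one pooled class
#' @return data.frame of counts per class (and population when given).
#' @export
roh_length_classes <- function(segments, bounds_bp = c(5e6, 1e7), by = NULL) {
  brk <- c(0, bounds_bp, Inf)
  lab <- character(length(brk) - 1L)
  for (i in seq_along(lab)) {
    lo <- brk[i] / 1e6; hi <- brk[i + 1L] / 1e6
    lab[i] <- if (is.finite(hi)) sprintf("[%g,%g)Mb", lo, hi)
              else sprintf(">=%gMb", lo)
  }
  cls <- cut(segments$length_bp, breaks = brk, labels = lab, right = FALSE)
  if (is.null(by)) {
    out <- as.data.frame(table(class = cls), stringsAsFactors = FALSE)
    names(out) <- c("class", "n")
  } else {
    out <- as.data.frame(table(population = by, class = cls),
                         stringsAsFactors = FALSE)
    names(out) <- c("population", "class", "n")
  }
  out
}

#' Population-level ROH summary
#'
#' Per population: total segment count, mean single-segment length, mean
#' per-individual segment count, and mean per-individual total ROH length,
#' the usual breed-comparison summary.
#'
#' @param segments segment table from \code{\link{detect_roh}}
#' @param g the source \code{geno_matrix} (for sample-to-population
#'   mapping; individuals with no segments count as zeros)
#' @param labels per-sample population labels
#' @return data.frame, one row per population; populations with no
#'   segments get zeros and \code{n_roh = 0}.
#' @export
roh_population_summary <- function(segments, g, labels = breed_labels(g)) {
  labels <- as.character(labels)
  pops <- unique(stats::na.omit(labels))
  seg_pop <- labels[match(segments$sample_id, g$samples$sample_id)]
  rows <- lapply(pops, function(b) {
    ids <- g$samples$sample_id[which(labels == b)]
    sb <- segments[which(seg_pop == b), , drop = FALSE]
    per_n <- per_len <- stats::setNames(rep(0, length(ids)), ids)
    if (nrow(sb)) {
      tn <- tapply(sb$length_bp, sb$sample_id, length)
      tl <- tapply(sb$length_bp, sb$sample_id, sum)
      per_n[names(tn)] <- tn
      per_len[names(tl)] <- tl
    }
    data.frame(population = b, n_individuals = length(ids),
               n_roh = nrow(sb),
               mean_length_mb = if (nrow(sb)) mean(sb$length_bp) / 1e6 else 0,
               mean_count_per_ind = mean(per_n),
               mean_total_mb_per_ind = mean(per_len) / 1e6,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
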