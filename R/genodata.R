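#' Construct a genotype matrix object
#'
#' The central data container: an individuals x markers matrix of diploid
#' allele dosages (copies of the counted allele, \code{allele_b}), with a
#' marker map and a sample table. Missing genotypes are \code{NA}, never 0.
#'
#' @param dosage integer matrix, n_samples x n_markers, entries in
#'   \{0, 1, 2, NA\}. Row and column names, if present, must agree with
#'   \code{samples} and \code{map}.
#' @param map data.frame with columns \code{marker_id}, \code{chrom}
#'   (character), \code{pos} (bp, 1-based), \code{allele_a}, \code{allele_b}.
#'   Markers must be unique; within a chromosome positions must be strictly
#'   increasing.
#' @param samples data.frame with column \code{sample_id} (unique) and
#'   optionally \code{breed}, \code{sex}, \code{cohort}. Defaults to the
#'   dosage rownames.
#' @param counted which allele the dosage counts; recorded so that
#'   downstream frequency code stays orientation-agnostic.
#' @return An object of class \code{geno_matrix}: a list with elements
#'   \code{dosage}, \code{map}, \code{samples}, \code{counted}.
#' @export
geno_matrix <- function(dosage, map, samples = NULL, counted = "allele_b") {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(samples)) {
    ids <- rownames(dosage)
    if (is.null(ids)) ids <- sprintf("S%d", seq_len(nrow(dosage)))
    samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  req <- c("marker_id", "chrom", "pos", "allele_a", "allele_b")
  miss <- setdiff(req, names(map))
  if (length(miss))
    stop("marker map is missing columns: ", paste(miss, collapse = ", "))
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker_ids in map")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_ids")
  if (nrow(dosage) != nrow(samples))
    stop("dosage has ", nrow(dosage), " rows but ", nrow(samples), " samples")
  if (ncol(dosage) != nrow(map))
    stop("dosage has ", ncol(dosage), " columns but ", nrow(map), " markers")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosage entries must be in {0, 1, 2, NA}")
  if (any(map$pos < 1L, na.rm = TRUE))
    stop("positions must be >= 1 (1-based coordinates)")
  if (any(map$allele_a == map$allele_b))
    stop("allele_a must differ from allele_b at every marker")
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- map$marker_id
  structure(
    list(dosage = dosage, map = map, samples = samples, counted = counted),
    class = "geno_matrix"
  )
}

#' @exportS3Method base::print
print.geno_matrix <- function(x, ...) {
  nmis <- sum(is.na(x$dosage))
  cat(sprintf(
    "geno_matrix: %d samples x %d markers (%d chromosomes), %.2f%% missing\n",
    nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom)),
    100 * nmis / max(1L, length(x$dosage))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Number of samples / markers
#' @param g a \code{geno_matrix}
#' @return integer count.
#' @export
n_samples <- function(g) nrow(g$dosage)

#' @rdname n_samples
#' @export
n_markers <- function(g) ncol(g$dosage)

# sort markers by (chrom, pos); required by ROH and LD scans
sort_markers <- function(g) {
  o <- order(g$map$chrom, g$map$pos)
  if (!identical(o, seq_len(nrow(g$map)))) {
    g$map <- g$map[o, , drop = FALSE]
    g$dosage <- g$dosage[, o, drop = FALSE]
    rownames(g$map) <- NULL
  }
  g
}

map_is_sorted <- function(map) {
  !is.unsorted(order(map$chrom, map$pos)) &&
    identical(order(map$chrom, map$pos), seq_len(nrow(map)))
}

#' Subset a genotype matrix
#'
#' Order-preserving subset by sample and/or marker ids. Unknown ids are an
#' error that lists the offenders.
#'
#' @param g a \code{geno_matrix}
#' @param sample_ids character vector of sample ids to keep (default all)
#' @param marker_ids character vector of marker ids to keep (default all)
#' @return a \code{geno_matrix}
#' @export
subset_geno <- function(g, sample_ids = NULL, marker_ids = NULL) {
  if (!is.null(sample_ids)) {
    if (length(sample_ids) == 0L) stop("empty sample selection")
    bad <- setdiff(sample_ids, g$samples$sample_id)
    if (length(bad))
      stop("unknown sample ids: ", paste(bad, collapse = ", "))
    ri <- match(sample_ids, g$samples$sample_id)
  } else ri <- seq_len(nrow(g$dosage))
  if (!is.null(marker_ids)) {
    if (length(marker_ids) == 0L) stop("empty marker selection")
    bad <- setdiff(marker_ids, g$map$marker_id)
    if (length(bad))
      stop("unknown marker ids: ", paste(bad, collapse = ", "))
    ci <- match(marker_ids, g$map$marker_id)
  } else ci <- seq_len(ncol(g$dosage))
  out <- g
  out$dosage <- g$dosage[ri, ci, drop = FALSE]
  out$map <- g$map[ci, , drop = FALSE]
  out$samples <- g$samples[ri, , drop = FALSE]
  rownames(out$map) <- NULL
  rownames(out$samples) <- NULL
  out
}

#' Breed labels of a genotype matrix
#'
#' @param g a \code{geno_matrix}
#' @return character vector of per-sample breed labels (NA where unknown).
#' @export
breed_labels <- function(g) {
  if ("breed" %in% names(g$samples)) as.character(g$samples$breed)
  else rep(NA_character_, nrow(g$samples))
}

## ---- PLINK 1.9 bed/bim/fam -------------------------------------------------
## SNP-major .bed, magic bytes 0x6C 0x1B 0x01. Two-bit codes per sample,
## low bits first within each byte:
##   00 = homozygous A1 (dosage 2 of A1), 01 = missing,
##   10 = heterozygous,                   11 = homozygous A2 (dosage 0).
## Dosage counts A1 (bim column 5), which PLINK treats as the minor allele.

#' Read a PLINK 1.9 fileset
#'
#' Reads \code{prefix.bed/.bim/.fam}. The returned dosage counts copies of
#' the bim A1 allele (column 5), stored as \code{allele_b}.
#'
#' @param prefix path prefix of the fileset (no extension)
#' @return a \code{geno_matrix}; the fam IID becomes \code{sample_id}, the
#'   FID is kept as \code{breed} (PLINK has no breed field; the writer stores
#'   breed labels in FID).
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  bimd <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           "numeric", "integer",
                                           "character", "character"))
  names(bimd) <- c("chrom", "marker_id", "cm", "pos", "a1", "a2")
  famd <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(famd); m <- nrow(bimd)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L ||
      raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b) || raw[3] != as.raw(0x01))
    stop("not a SNP-major PLINK 1.9 .bed file (bad magic bytes): ", bed)
  bps <- ceiling(n / 4)  # bytes per SNP
  expected <- 3L + bps * m
  if (length(raw) != expected)
    stop(sprintf(
      "bed payload size mismatch in %s: expected %d bytes for %d samples x %d markers, found %d",
      bed, expected, n, m, length(raw)))
  payload <- as.integer(raw[-(1:3)])
  codes <- matrix(0L, nrow = 4L * bps, ncol = m)
  block <- matrix(payload, nrow = bps, ncol = m)
  for (k in 0:3) {
    codes[seq.int(k + 1L, by = 4L, length.out = bps), ] <-
      block %% 4L
    block <- block %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # code -> dosage of A1: 0->2, 2->1, 3->0, 1->NA
  lut <- c(2L, NA_integer_, 1L, 0L)
  dosage <- matrix(lut[codes + 1L], nrow = n, ncol = m)
  map <- data.frame(marker_id = bimd$marker_id, chrom = bimd$chrom,
                    pos = bimd$pos, allele_a = bimd$a2, allele_b = bimd$a1,
                    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = as.character(famd[[2]]),
                        breed = as.character(famd[[1]]),
                        stringsAsFactors = FALSE)
  geno_matrix(dosage, map, samples)
}

#' Write a PLINK 1.9 fileset
#'
#' Lossless counterpart of \code{\link{read_plink}}: the counted allele is
#' written as bim A1, breed labels (if any) as the fam FID.
#'
#' @param g a \code{geno_matrix}
#' @param prefix output path prefix
#' @return invisibly, the three file paths written.
#' @export
write_plink <- function(g, prefix) {
  if (ncol(g$dosage) == 0L) stop("refusing to write an empty marker set")
  bimd <- data.frame(g$map$chrom, g$map$marker_id, 0, g$map$pos,
                     g$map$allele_b, g$map$allele_a)
  utils::write.table(bimd, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fid <- breed_labels(g)
  fid[is.na(fid)] <- "0"
  famd <- data.frame(fid, g$samples$sample_id, 0, 0, 0, -9)
  utils::write.table(famd, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(g$dosage); m <- ncol(g$dosage)
  bps <- ceiling(n / 4)
  # dosage -> two-bit code: 2->0, 1->2, 0->3, NA->1
  cd <- matrix(3L, nrow = 4L * bps, ncol = m)
  d <- g$dosage
  code <- ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  cd[seq_len(n), ] <- code
  weights <- c(1L, 4L, 16L, 64L)
  bytes <- matrix(0L, nrow = bps, ncol = m)
  for (k in 0:3)
    bytes <- bytes + weights[k + 1L] *
      cd[seq.int(k + 1L, by = 4L, length.out = bps), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

## ---- VCF -------------------------------------------------------------------

#' Read genotypes from a VCF file
#'
#' Biallelic SNP records only; multiallelic or indel records are skipped and
#' counted. GT is mapped to the ALT-allele dosage; half-calls and
#' non-diploid GTs become missing. Parsing is delegated to
#' \code{vcfR::read.vcfR}.
#'
#' @param path VCF file (plain or gzipped)
#' @return a \code{geno_matrix}; attribute \code{n_skipped} records how many
#'   non-biallelic-SNP records were dropped.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ref <- fix$REF
  alt <- fix$ALT
  ok <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!ok)
  if (!any(ok)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[ok, , drop = FALSE]
  fix <- fix[ok, , drop = FALSE]
  gt[is.na(gt)] <- "./."
  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  dosage <- suppressWarnings(as.integer(a1) + as.integer(a2))
  dosage[!(sep %in% c("/", "|")) | nchar(gt) != 3L] <- NA_integer_
  dosage <- matrix(dosage, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
  ids <- fix$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix$CHROM[noid], "_", fix$POS[noid])
  map <- data.frame(marker_id = ids, chrom = fix$CHROM,
                    pos = as.integer(fix$POS),
                    allele_a = fix$REF, allele_b = fix$ALT,
                    stringsAsFactors = FALSE)
  g <- geno_matrix(t(dosage), map,
                   data.frame(sample_id = colnames(gt),
                              stringsAsFactors = FALSE))
  attr(g, "n_skipped") <- n_skipped
  g
}

#' Write genotypes to a VCF file
#'
#' Minimal VCF v4.2 with a GT FORMAT field; the counted allele
#' (\code{allele_b}) is written as ALT so that \code{\link{read_vcf}}
#' round-trips the dosage.
#'
#' @param g a \code{geno_matrix}
#' @param path output file
#' @return invisibly, \code{path}.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$sample_id), collapse = "\t")
  ), con)
  gtmap <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$dosage))) {
    d <- g$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gtmap[d + 1L])
    writeLines(paste(c(g$map$chrom[j], g$map$pos[j], g$map$marker_id[j],
                       g$map$allele_a[j], g$map$allele_b[j], ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
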