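#' Pipeline configuration
#'
#' Validated configuration for \code{\link{run_pipeline}}. Unknown keys are
#' rejected before any computation.
#'
#' @param geno a \code{geno_matrix}, or a PLINK prefix / VCF path to read
#' @param out_dir output directory (created if absent)
#' @param seed seed used by every stochastic stage
#' @param qc a \code{\link{qc_thresholds}}
#' @param panel a \code{\link{panel_spec}} (set NULL to skip panel design)
#' @param roh a \code{\link{roh_params}}
#' @param n_families molecular families for the selection stage (NULL
#'   skips mate selection)
#' @param ld_max_bp,ld_bin_bp LD decay range and bin width
#' @param pca_components principal components to keep
#' @param froh_max F_ROH exclusion threshold for mate selection
#' @return a list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(geno, out_dir, seed = 1,
                            qc = qc_thresholds(), panel = panel_spec(),
                            roh = roh_params(), n_families = NULL,
                            ld_max_bp = 1e6, ld_bin_bp = 1e4,
                            pca_components = 10, froh_max = 0.3) {
  cfg <- list(geno = geno, out_dir = out_dir, seed = seed, qc = qc,
              panel = panel, roh = roh, n_families = n_families,
              ld_max_bp = ld_max_bp, ld_bin_bp = ld_bin_bp,
              pca_components = pca_components, froh_max = froh_max)
  if (!inherits(qc, "qc_thresholds")) stop("qc must be qc_thresholds()")
  if (!is.null(panel) && !inherits(panel, "panel_spec"))
    stop("panel must be panel_spec() or NULL")
  if (!inherits(roh, "roh_params")) stop("roh must be roh_params()")
  structure(cfg, class = "pipeline_config")
}

#' Run the full genetic-evaluation pipeline
#'
#' Executes, in fixed order: QC (individuals then sites), panel design
#' (when >= 2 breeds are labelled), GBC estimation against the
#' leave-self-in reference frequencies, per-population diversity, PCA,
#' ROH + F_ROH, LD decay, and IBS-based family clustering with a mating
#' plan. Every output TSV starts with comment lines recording the package
#' version, a configuration hash and the seed, so a re-run with the same
#' config is byte-identical.
#'
#' @param cfg a \code{\link{pipeline_config}}
#' @return invisibly, a named list of the result objects; files
#'   \code{qc_report.tsv}, \code{stats.tsv}, \code{gbc.tsv},
#'   \code{pca.tsv}, \code{roh.tsv}, \code{froh.tsv}, \code{ld.tsv},
#'   \code{plan.tsv} (stage-dependent) are written under
#'   \code{cfg$out_dir}.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config"))
    stop("cfg must be built with pipeline_config()")
  g <- cfg$geno
  if (is.character(g)) {
    g <- if (grepl("\\.vcf(\\.gz)?$", g)) read_vcf(g) else read_plink(g)
  }
  if (!inherits(g, "geno_matrix")) stop("stage input: not a geno_matrix")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  hdr <- c(sprintf("# breedkit %s",
                   as.character(utils::packageVersion("breedkit"))),
           sprintf("# config_hash %s", hash),
           sprintf("# seed %d", cfg$seed))
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    suppressWarnings(utils::write.table(
      df, con, sep = "\t", quote = FALSE, row.names = FALSE))
    close(con)
    path
  }
  results <- list()

  # 1. QC
  fi <- filter_individuals(g, cfg$qc)
  fs <- filter_sites(fi$geno, cfg$qc)
  gq <- sort_markers(fs$geno)
  results$qc_report <- rbind(fi$report, fs$report)
  emit(results$qc_report, "qc_report.tsv")
  jsonlite::write_json(as.list(results$qc_report),
                       file.path(cfg$out_dir, "qc_report.json"))

  labels <- breed_labels(gq)
  multi <- length(unique(stats::na.omit(labels))) >= 2L

  # 2. panel design + GBC
  if (multi && !is.null(cfg$panel)) {
    results$panel <- build_gbc_panel(gq, labels, cfg$panel, cfg$qc)
    emit(as.data.frame(results$panel), "panel.tsv")
    gpan <- subset_geno(gq, marker_ids = results$panel$marker_id)
    ref <- panel_frequencies(gpan, labels)
    fit <- fit_ancestry(gpan, ref)
    results$gbc <- summary(fit)
    results$gbc_fit <- fit
    emit(cbind(results$gbc,
               stats::setNames(as.data.frame(fit$q), paste0("q_", fit$breeds))),
         "gbc.tsv")
  }

  # 3. diversity
  if (any(!is.na(labels))) {
    results$stats <- population_report(gq, labels)
    emit(as.data.frame(results$stats), "stats.tsv")
  }

  # 4. PCA
  results$pca <- pca_geno(gq, cfg$pca_components)
  emit(data.frame(sample_id = rownames(results$pca$scores),
                  results$pca$scores), "pca.tsv")

  # 5. ROH + F_ROH
  results$roh <- detect_roh(gq, cfg$roh)
  emit(results$roh, "roh.tsv")
  results$froh <- froh(results$roh, gq)
  emit(results$froh, "froh.tsv")

  # 6. LD decay
  results$ld <- ld_decay(gq, cfg$ld_max_bp, cfg$ld_bin_bp,
                         max_pairs_per_chrom = 20000, seed = cfg$seed)
  emit(results$ld, "ld.tsv")

  # 7. mate selection
  if (!is.null(cfg$n_families)) {
    ib <- ibs_matrix(gq)
    fam <- cluster_families(ib, cfg$n_families)
    sexes <- if ("sex" %in% names(gq$samples))
      stats::setNames(gq$samples$sex, gq$samples$sample_id)
    else  # alternate M/F deterministically when no sexes are recorded
      stats::setNames(rep(c("M", "F"), length.out = nrow(gq$samples)),
                      gq$samples$sample_id)
    results$plan <- propose_matings(fam, sexes, results$froh, ib,
                                    froh_max = cfg$froh_max)
    emit(results$plan, "plan.tsv")
  }
  invisible(results)
}

config_hash <- function(cfg) {
  clean <- cfg
  clean$geno <- if (is.character(cfg$geno)) cfg$geno else "<in-memory>"
  clean$out_dir <- NULL  # hash the analysis parameters, not the destination
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(clean, file = tmp, control = c("all", "digits17"))
  unname(tools::md5sum(tmp))
}
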