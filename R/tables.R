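#' Bundled study bookkeeping tables
#'
#' Two small reference tables describing the genotyping study the package
#' workflow is built around: the sizes of the five Shanghai conservation
#' populations plus the purebred-selection offspring cohort (six groups,
#' 1451 animals in total), and the 25-breed reference panel (1248
#' reference individuals) used for genomic breed composition. The
#' reference-panel table carries area, breed name and code; its total
#' sample count is stored in \code{attr(, "total_samples")}.
#'
#' @return \code{conservation_cohort()}: data.frame with columns
#'   \code{breed}, \code{n_samples}, \code{source}.
#' @export
conservation_cohort <- function() {
  utils::read.csv(system.file("extdata", "conservation_cohort.csv",
                              package = "breedkit"),
                  stringsAsFactors = FALSE)
}

#' @rdname conservation_cohort
#' @return \code{reference_panel_breeds()}: data.frame with columns
#'   \code{area}, \code{breed}, \code{code}; one row per reference breed.
#' @export
reference_panel_breeds <- function() {
  df <- utils::read.csv(system.file("extdata", "reference_panel_breeds.csv",
                                    package = "breedkit"),
                        stringsAsFactors = FALSE)
  attr(df, "total_samples") <- 1248L
  df
}
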