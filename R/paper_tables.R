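#' Published creatinase variant measurements
#'
#' Characterization tables for the engineered *Alcaligenes faecalis*
#' creatinase (afCR) variants, shipped as plain-text data:
#' `afcr_single_mutants()` — the 21 single-site consensus mutants plus the
#' M0 parent, with consensus frequency, modeled active-site distance,
#' half-life at 55 C, and relative activity; `afcr_combination_mutants()`
#' — the combinatorial variants (M1 through M4-2) with half-lives at 57 C;
#' `afcr_stability_summary()` — T50 (15-min) and Tm values per variant.
#' Half-lives feed [summarize_variants()] and the assay-curve simulators, so
#' the published fold improvements and success rate can be recomputed
#' through the package's own fitting machinery.
#'
#' @return A data.frame (one row per variant).
#' @name afcr_tables
NULL

read_extdata_tsv <- function(name) {
  path <- system.file("extdata", name, package = "phyloconsensus",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname afcr_tables
#' @export
afcr_single_mutants <- function() read_extdata_tsv("afcr_single_mutants.tsv")

#' @rdname afcr_tables
#' @export
afcr_combination_mutants <- function() read_extdata_tsv("afcr_combination_mutants.tsv")

#' @rdname afcr_tables
#' @export
afcr_stability_summary <- function() read_extdata_tsv("afcr_stability_summary.tsv")
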