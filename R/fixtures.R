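#' Bundled reference result tables
#'
#' Small plain-text transcriptions of the published result tables of an
#' integrative analysis of age-associated miRNA regulation in a primary
#' prostate tumor cohort, bundled for regression tests and worked
#' examples:
#'
#' * `reference_concordant_mirnas()` — the ranked set of 20 concordant
#'   miRNAs with per-year expression and promoter-methylation
#'   percentage changes, direction/status calls, the published
#'   (z-normalized) concordance score, and the covariate-robustness
#'   flag from the Gleason/stage-adjusted sensitivity analysis.
#' * `reference_external_directions()` — the matching external-cohort
#'   direction calls (expression panel and methylation array), with
#'   `NA` where the external platform did not cover a miRNA.
#' * `reference_target_edges()` — the validated miRNA-target edge list
#'   of the degree-filtered convergence network.
#'
#' @return a data.frame; see each description. Identifier spellings are
#'   kept exactly as published (including one hyphen-less variant) so
#'   the tables also exercise identifier harmonization.
#' @name reference_tables
NULL

ref_path <- function(file) {
  system.file("extdata", file, package = "mirdrift", mustWork = TRUE)
}

#' @rdname reference_tables
#' @export
reference_concordant_mirnas <- function() {
  d <- utils::read.delim(ref_path("reference_concordant_mirnas.tsv"),
                         stringsAsFactors = FALSE)
  d$base_id <- harmonize_mirna_id(d$mirna_id)
  d
}

#' @rdname reference_tables
#' @export
reference_external_directions <- function() {
  d <- utils::read.delim(ref_path("reference_external_directions.tsv"),
                         stringsAsFactors = FALSE)
  d$base_id <- harmonize_mirna_id(d$mirna_id)
  d
}

#' @rdname reference_tables
#' @export
reference_target_edges <- function() {
  utils::read.delim(ref_path("reference_target_edges.tsv"),
                    stringsAsFactors = FALSE)
}
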