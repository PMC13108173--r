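#' Join expression and methylation layers per miRNA
#'
#' Inner-joins per-miRNA expression age trends with promoter methylation
#' summaries on the harmonized base id. miRNAs present in only one layer
#' are excluded (a message reports how many). When several expression
#' records collapse to one base id (e.g. both mature arms of a locus),
#' the record with the smallest adjusted p-value is kept — preserving
#' the strongest evidence while avoiding redundant rows; ties break by
#' raw p-value and then lexicographic raw id.
#'
#' @param expr_results data.frame from [fit_expression_age_model()]
#'   (usually the final selected set).
#' @param meth_summaries data.frame from
#'   [summarize_promoter_methylation()].
#' @return data.frame with one row per integrated miRNA: `base_id`,
#'   `mirna_id`, `expr_b` (log2/year), `expr_pct_per_year`,
#'   `expr_direction`, `expr_fdr`, `meth_b` (beta/year),
#'   `meth_pct_per_year`, `meth_status`, `meth_min_fdr`, `n_cpgs`,
#'   `concordance_class`.
#' @export
integrate_layers <- function(expr_results, meth_summaries) {
  expr <- dedup_expression(expr_results)
  keep <- intersect(expr$base_id, meth_summaries$base_id)
  n_drop <- (nrow(expr) - length(keep)) +
    (nrow(meth_summaries) - length(keep))
  if (n_drop > 0) {
    message(n_drop, " record(s) lacked the other molecular layer and ",
            "were excluded from integration")
  }
  if (length(keep) == 0L) {
    return(empty_integrated())
  }
  e <- expr[match(keep, expr$base_id), , drop = FALSE]
  m <- meth_summaries[match(keep, meth_summaries$base_id), , drop = FALSE]
  out <- data.frame(
    base_id = keep,
    mirna_id = e$mirna_id,
    expr_b = e$log2fc_per_year,
    expr_pct_per_year = e$pct_per_year,
    expr_direction = e$direction,
    expr_fdr = e$fdr,
    meth_b = m$mean_slope_per_year,
    meth_pct_per_year = m$pct_per_year,
    meth_status = m$status,
    meth_min_fdr = m$min_fdr,
    n_cpgs = m$n_cpgs,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out$concordance_class <- classify_concordance(out$expr_direction,
                                                out$meth_status)
  out
}

empty_integrated <- function() {
  data.frame(base_id = character(0), mirna_id = character(0),
             expr_b = numeric(0), expr_pct_per_year = numeric(0),
             expr_direction = character(0), expr_fdr = numeric(0),
             meth_b = numeric(0), meth_pct_per_year = numeric(0),
             meth_status = character(0), meth_min_fdr = numeric(0),
             n_cpgs = integer(0), concordance_class = character(0),
             stringsAsFactors = FALSE)
}

# one expression record per base id: smallest fdr, then p, then raw id
dedup_expression <- function(expr_results) {
  if (nrow(expr_results) == 0L) return(expr_results)
  ord <- order(expr_results$base_id, expr_results$fdr,
               expr_results$p_value, expr_results$mirna_id)
  e <- expr_results[ord, , drop = FALSE]
  e[!duplicated(e$base_id), , drop = FALSE]
}

#' Classify methylation-expression concordance
#'
#' A miRNA follows the canonical epigenetic repression model when its
#' promoter methylation trend opposes its expression trend:
#' hypomethylation with rising expression (`Up`/`Hypo`) or
#' hypermethylation with falling expression (`Down`/`Hyper`). Those
#' pairs are `concordant`; the same-direction pairs are `discordant`.
#'
#' @param expr_direction character vector, `"Up"` or `"Down"`.
#' @param meth_status character vector, `"Hyper"` or `"Hypo"`.
#' @return character vector, `"concordant"` or `"discordant"`.
#' @export
classify_concordance <- function(expr_direction, meth_status) {
  if (anyNA(expr_direction) || anyNA(meth_status) ||
      !all(expr_direction %in% c("Up", "Down")) ||
      !all(meth_status %in% c("Hyper", "Hypo"))) {
    stop("direction must be Up/Down and status Hyper/Hypo, with no NA")
  }
  ifelse((expr_direction == "Up" & meth_status == "Hypo") |
           (expr_direction == "Down" & meth_status == "Hyper"),
         "concordant", "discordant")
}

#' Score integrated miRNAs by joint effect magnitude
#'
#' The raw concordance score is the product of the absolute per-year
#' expression and methylation coefficients, both on the %/year scale:
#' `|expr_pct_per_year| * |meth_pct_per_year|`. In `znorm` mode both
#' coefficient vectors are additionally z-standardized (mean 0, sd 1)
#' across the record set before taking the product of absolute values,
#' which removes the scale asymmetry between the two layers; the raw
#' score is always reported alongside.
#'
#' @param records integrated data.frame (from [integrate_layers()]).
#' @param mode `"znorm"` (default) or `"raw"`.
#' @return `records` with a `raw_score` column and, in znorm mode, a
#'   `z_score` column; `score` holds the ranking score for the chosen
#'   mode.
#' @export
concordance_score <- function(records, mode = c("znorm", "raw")) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) stop("no records to score")
  records$raw_score <- abs(records$expr_pct_per_year) *
    abs(records$meth_pct_per_year)
  if (mode == "znorm") {
    if (nrow(records) < 2L) {
      stop("znorm scoring requires at least 2 records")
    }
    sd_e <- stats::sd(records$expr_pct_per_year)
    sd_m <- stats::sd(records$meth_pct_per_year)
    if (sd_e == 0 || sd_m == 0) {
      stop("znorm scoring requires nonzero spread in both coefficients")
    }
    z_e <- (records$expr_pct_per_year - mean(records$expr_pct_per_year)) / sd_e
    z_m <- (records$meth_pct_per_year - mean(records$meth_pct_per_year)) / sd_m
    records$z_score <- abs(z_e) * abs(z_m)
    records$score <- records$z_score
  } else {
    records$score <- records$raw_score
  }
  records
}

#' Rank concordant miRNAs by concordance score
#'
#' Restricts to concordant records, orders by descending score with
#' deterministic lexicographic base-id tie-breaking, and assigns ranks
#' 1..n.
#'
#' @param records scored data.frame from [concordance_score()].
#' @return the concordant subset with a `rank` column, in rank order.
#' @export
rank_candidates <- function(records) {
  stopifnot("score" %in% names(records))
  conc <- records[records$concordance_class == "concordant", , drop = FALSE]
  ord <- order(-conc$score, conc$base_id)
  conc <- conc[ord, , drop = FALSE]
  conc$rank <- seq_len(nrow(conc))
  rownames(conc) <- NULL
  conc
}

#' Covariate sensitivity re-analysis
#'
#' Re-fits both association stages with clinical covariates in the
#' design, re-runs selection, promoter summarization and integration,
#' and returns the base ids that remain in the final age-associated set
#' *and* remain concordant after adjustment. A concordant miRNA from the
#' primary analysis is covariate-robust iff it appears in this set.
#'
#' @param counts,betas,clinical,loci,probes study inputs.
#' @param covariates character vector of clinical covariate columns
#'   (e.g. `c("gleason", "t_stage")`).
#' @param params analysis parameter list, see [default_params()].
#' @return character vector of adjusted concordant base ids.
#' @export
sensitivity_reanalysis <- function(counts, betas, clinical, loci, probes,
                                   covariates, params = default_params()) {
  adj <- run_layers(counts, betas, clinical, loci, probes,
                    covariates = covariates, params = params)
  adj$integrated$base_id[adj$integrated$concordance_class == "concordant"]
}

#' Default analysis parameters
#'
#' Thresholds and modes used throughout the pipeline: expression filter
#' (`min_count` reads in `min_fraction` of samples), two-stage selection
#' (`fdr_exploratory`, `fdr_final`, `min_abs_log2fc`), promoter
#' `half_width` in bp, `score_mode` for ranking, and `min_gene_degree`
#' for network hub filtering.
#'
#' @return named list of defaults.
#' @export
default_params <- function() {
  list(min_count = 5L, min_fraction = 0.2,
       fdr_exploratory = 0.10, fdr_final = 0.015, min_abs_log2fc = 0.015,
       half_width = 2000L, score_mode = "znorm",
       min_gene_degree = 5L)
}

# single pass over both molecular layers; covariates optional
run_layers <- function(counts, betas, clinical, loci, probes,
                       covariates = character(),
                       params = default_params()) {
  filtered <- filter_low_expression(counts, params$min_count,
                                    params$min_fraction)
  expr_res <- fit_expression_age_model(filtered, clinical, covariates)
  sel <- select_age_associated(expr_res, params$fdr_exploratory,
                               params$fdr_final, params$min_abs_log2fc)
  cpg_res <- fit_cpg_age_model(betas, clinical, covariates)
  windows <- define_promoters(loci, params$half_width)
  mapping <- map_cpgs_to_promoters(probes, windows)
  meth_sum <- summarize_promoter_methylation(mapping, cpg_res)
  integrated <- integrate_layers(sel$final, meth_sum)
  list(filtered = filtered, expr_results = expr_res, selection = sel,
       cpg_results = cpg_res, windows = windows, mapping = mapping,
       meth_summaries = meth_sum, integrated = integrated)
}
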