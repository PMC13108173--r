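#' Per-CpG linear regression of beta values on age
#'
#' Ordinary least squares of each probe's beta values on mean-centered
#' age (plus optional covariates), fitted for all probes at once via
#' [limma::lmFit()] and reported with ordinary (non-moderated)
#' t-statistics, i.e. exactly the per-probe OLS slope, standard error,
#' and p-value. Benjamini-Hochberg adjustment is applied genome-wide
#' across all probes with a valid fit, before any promoter restriction.
#'
#' Probes with zero variance across samples are assigned slope 0 and a
#' missing p-value and are excluded from the BH adjustment.
#'
#' @param betas numeric matrix in `[0,1]`, probes x samples.
#' @param clinical clinical table (`sample_id`, `age_years`, covariates).
#' @param covariates character vector of clinical covariate names.
#' @return data.frame: `probe_id`, `slope_per_year` (beta units/year),
#'   `std_error`, `p_value`, `fdr`.
#' @export
fit_cpg_age_model <- function(betas, clinical, covariates = character()) {
  al <- align_samples(betas, clinical, covariates)
  betas <- al$mat
  clinical <- al$clinical
  if (ncol(betas) < 3L) stop("need at least 3 samples")
  X <- build_design(clinical, covariates)
  j_age <- match("age_c", colnames(X))

  zero_var <- apply(betas, 1L, function(y) all(y == y[1L]))
  fit <- limma::lmFit(betas, design = X)
  slope <- fit$coefficients[, j_age]
  se <- fit$stdev.unscaled[, j_age] * fit$sigma
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df = fit$df.residual)

  slope[zero_var] <- 0
  p[zero_var] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- stats::p.adjust(p[ok], method = "BH")

  data.frame(
    probe_id = rownames(betas),
    slope_per_year = unname(slope),
    std_error = unname(ifelse(zero_var, NA_real_, se)),
    p_value = unname(p),
    fdr = fdr,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Define strand-aware promoter windows around miRNA TSSs
#'
#' The transcription start site is the locus start on the `+` strand and
#' the locus end on the `-` strand; the promoter is the closed interval
#' `[TSS - half_width, TSS + half_width]` in 1-based coordinates,
#' floored at position 1.
#'
#' @param loci data.frame with `locus_id`, `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`, required).
#' @param half_width promoter half-width in bp (default 2000).
#' @return data.frame: `base_id`, `locus_id`, `chrom`, `window_start`,
#'   `window_end`, `tss`, `strand`.
#' @export
define_promoters <- function(loci, half_width = 2000L) {
  stopifnot(half_width > 0)
  if (anyNA(loci$strand) || !all(loci$strand %in% c("+", "-"))) {
    stop("every locus must have strand '+' or '-'")
  }
  stopifnot(all(loci$start <= loci$end))
  tss <- ifelse(loci$strand == "+", loci$start, loci$end)
  data.frame(
    base_id = harmonize_mirna_id(loci$locus_id),
    locus_id = loci$locus_id,
    chrom = loci$chrom,
    window_start = pmax(1L, as.integer(tss - half_width)),
    window_end = as.integer(tss + half_width),
    tss = as.integer(tss),
    strand = loci$strand,
    stringsAsFactors = FALSE
  )
}

#' Map CpG probes into promoter windows
#'
#' Assigns every probe to every promoter window containing its position
#' (closed intervals, boundaries inclusive, many-to-many: a probe inside
#' two overlapping promoters contributes to both). Implemented with
#' [GenomicRanges::findOverlaps()].
#'
#' @param probes data.frame with `probe_id`, `chrom`, `position`
#'   (1-based point positions).
#' @param windows promoter windows from [define_promoters()].
#' @return data.frame with one row per (miRNA, probe) assignment:
#'   `base_id`, `probe_id`. Probes falling in no window are absent.
#' @export
map_cpgs_to_promoters <- function(probes, windows) {
  if (nrow(probes) == 0L || nrow(windows) == 0L) {
    return(data.frame(base_id = character(0), probe_id = character(0),
                      stringsAsFactors = FALSE))
  }
  if (!any(probes$chrom %in% windows$chrom)) {
    warning("no shared chromosome names: ",
            length(unique(probes$chrom)), " probe chromosome(s) vs ",
            length(unique(windows$chrom)), " window chromosome(s)")
  }
  gr_p <- GenomicRanges::GRanges(
    probes$chrom, IRanges::IRanges(probes$position, width = 1L))
  gr_w <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(windows$window_start, windows$window_end))
  # disjoint seqlevel sets are expected when decoy probes sit on
  # chromosomes without loci; the count warning above already covers
  # genuine naming mismatches
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_p, gr_w, ignore.strand = TRUE))
  data.frame(
    base_id = windows$base_id[S4Vectors::subjectHits(hits)],
    probe_id = probes$probe_id[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE
  )
}

#' Summarize CpG-level age trends to miRNA promoter level
#'
#' For each miRNA, the promoter methylation drift is the arithmetic mean
#' of the age slopes of all its mapped, successfully fitted CpGs; the
#' minimum adjusted p-value across those CpGs is retained as the
#' promoter-level significance. miRNAs whose mapped probes all lack fits
#' (or that have no mapped probes) are omitted and surface as missing
#' methylation downstream.
#'
#' @param mapping data.frame (`base_id`, `probe_id`) from
#'   [map_cpgs_to_promoters()].
#' @param cpg_results data.frame from [fit_cpg_age_model()].
#' @return data.frame: `base_id`, `mean_slope_per_year` (beta
#'   units/year), `min_fdr`, `n_cpgs`, `pct_per_year`
#'   (= 100 * mean slope), `status` ("Hyper"/"Hypo").
#' @export
summarize_promoter_methylation <- function(mapping, cpg_results) {
  m <- merge(mapping, cpg_results, by = "probe_id")
  m <- m[!is.na(m$p_value), , drop = FALSE]
  if (nrow(m) == 0L) {
    return(data.frame(base_id = character(0),
                      mean_slope_per_year = numeric(0),
                      min_fdr = numeric(0), n_cpgs = integer(0),
                      pct_per_year = numeric(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(m)), m$base_id)
  out <- data.frame(
    base_id = names(sp),
    mean_slope_per_year = vapply(sp, function(i) mean(m$slope_per_year[i]),
                                 numeric(1)),
    min_fdr = vapply(sp, function(i) min(m$fdr[i]), numeric(1)),
    n_cpgs = vapply(sp, length, integer(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out$pct_per_year <- 100 * out$mean_slope_per_year
  out$status <- ifelse(out$mean_slope_per_year > 0, "Hyper", "Hypo")
  out
}
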