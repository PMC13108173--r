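#' Remove lowly expressed miRNAs
#'
#' Keeps features observed at `min_count` or more reads in at least
#' `min_fraction` of samples. Samples are never dropped.
#'
#' @param counts integer matrix, features x samples.
#' @param min_count minimum read count per sample.
#' @param min_fraction minimum fraction of samples reaching `min_count`.
#' @return the filtered count matrix (possibly with zero rows, with a
#'   warning).
#' @export
filter_low_expression <- function(counts, min_count = 5L,
                                  min_fraction = 0.2) {
  stopifnot(min_fraction >= 0, min_fraction <= 1, min_count >= 0)
  keep <- rowSums(counts >= min_count) >= min_fraction * ncol(counts)
  out <- counts[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no features pass the expression filter")
  out
}

#' Median-of-ratios library size factors
#'
#' Thin wrapper around [DESeq2::estimateSizeFactorsForMatrix()]; when no
#' feature has all-positive counts (so geometric means are undefined) it
#' falls back to library-size ratios with a warning.
#'
#' @param counts integer matrix, features x samples.
#' @return numeric vector of per-sample size factors (geometric mean 1
#'   in the fallback case).
#' @export
estimate_size_factors <- function(counts) {
  tryCatch(
    DESeq2::estimateSizeFactorsForMatrix(counts),
    error = function(e) {
      warning("median-of-ratios undefined (", conditionMessage(e),
              "); falling back to total-count ratios")
      ls <- colSums(counts)
      sf <- ls / exp(mean(log(ls)))
      stats::setNames(sf, colnames(counts))
    }
  )
}

#' Per-miRNA negative-binomial age-trend regression
#'
#' Fits, for each miRNA, a negative-binomial log-linear model of raw
#' counts on mean-centered age (plus optional clinical covariates) with
#' a median-of-ratios library-size offset. The age coefficient is
#' reported on the per-year log2 scale together with its Wald standard
#' error and p-value; Benjamini-Hochberg adjustment is applied across
#' all successfully fitted features.
#'
#' The NB dispersion is estimated per feature by method of moments on
#' size-factor-normalized counts and moderated toward the across-feature
#' median (geometric mean of the raw and median estimates), giving
#' stable Wald tests without an external differential-expression tool.
#'
#' Constant features (identical counts in every sample) carry no age
#' information and are dropped before fitting; non-convergent fits are
#' flagged, given missing p-values, and excluded from the BH adjustment.
#'
#' @param counts integer matrix, features x samples (row names are raw
#'   miRNA ids).
#' @param clinical clinical table with `sample_id`, `age_years` and any
#'   covariate columns; must cover all count columns.
#' @param covariates character vector of clinical column names to adjust
#'   for (default none). Covariate columns constant across samples are
#'   dropped from the design with a warning. Samples missing a covariate
#'   value are dropped listwise.
#' @param size_factors optional precomputed per-sample size factors.
#' @return data.frame with one row per fitted feature: `mirna_id`,
#'   `base_id`, `log2fc_per_year`, `std_error`, `p_value`, `fdr`,
#'   `pct_per_year`, `direction` ("Up"/"Down"), `converged`. The number
#'   of dropped constant / non-convergent features is attached as
#'   attributes `n_constant` and `n_nonconverged`.
#' @export
fit_expression_age_model <- function(counts, clinical,
                                     covariates = character(),
                                     size_factors = NULL) {
  al <- align_samples(counts, clinical, covariates)
  counts <- al$mat
  clinical <- al$clinical
  if (ncol(counts) < 3L) stop("need at least 3 samples")

  if (is.null(size_factors)) {
    size_factors <- estimate_size_factors(counts)
  } else {
    size_factors <- size_factors[colnames(counts)]
  }
  off <- log(size_factors)

  constant <- apply(counts, 1L, function(y) all(y == y[1L]))
  n_constant <- sum(constant)
  if (n_constant > 0) {
    message(n_constant, " constant feature(s) dropped before fitting")
  }
  counts <- counts[!constant, , drop = FALSE]
  if (nrow(counts) == 0L) stop("no non-constant features to fit")

  X <- build_design(clinical, covariates)
  norm <- sweep(counts, 2L, size_factors, "/")
  mu_hat <- rowMeans(norm)
  v_hat <- apply(norm, 1L, stats::var)
  alpha_raw <- pmax((v_hat - mu_hat) / mu_hat^2, 1e-8)
  alpha_med <- stats::median(alpha_raw)
  alpha <- exp((log(alpha_raw) + log(alpha_med)) / 2)

  j_age <- match("age_c", colnames(X))
  fits <- lapply(seq_len(nrow(counts)), function(i) {
    fam <- MASS::negative.binomial(theta = 1 / alpha[i])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, counts[i, ], family = fam,
                                      offset = off,
                                      control = list(maxit = 50))),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      return(c(b = NA_real_, se = NA_real_, conv = 0))
    }
    info <- crossprod(X * sqrt(fit$weights))
    cov <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(cov)) return(c(b = NA_real_, se = NA_real_, conv = 0))
    c(b = unname(fit$coefficients[j_age]),
      se = sqrt(cov[j_age, j_age]), conv = 1)
  })
  fits <- do.call(rbind, fits)

  b_log2 <- fits[, "b"] / log(2)
  se_log2 <- fits[, "se"] / log(2)
  p <- 2 * stats::pnorm(-abs(b_log2 / se_log2))
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  n_nonconv <- sum(!ok)
  if (n_nonconv > 0) {
    message(n_nonconv, " feature(s) failed to converge; excluded from BH")
  }

  res <- data.frame(
    mirna_id = rownames(counts),
    base_id = harmonize_mirna_id(rownames(counts)),
    log2fc_per_year = b_log2,
    std_error = se_log2,
    p_value = p,
    fdr = fdr,
    pct_per_year = log2fc_to_pct_per_year(b_log2),
    direction = ifelse(b_log2 > 0, "Up", "Down"),
    converged = fits[, "conv"] == 1,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(res, "n_constant") <- n_constant
  attr(res, "n_nonconverged") <- n_nonconv
  res
}

#' Convert a per-year log2 fold change to a percentage change per year
#'
#' `(2^b - 1) * 100`: a coefficient of 0.015 log2 units/year is
#' approximately a 1% expression change per year.
#'
#' @param b per-year log2 fold change (vectorized).
#' @return percentage change per year.
#' @export
log2fc_to_pct_per_year <- function(b) (2^b - 1) * 100

#' Two-stage selection of age-associated miRNAs
#'
#' Stage one keeps features at an exploratory FDR; stage two additionally
#' requires a stringent FDR and a minimum absolute effect size, defining
#' the final set carried into integration.
#'
#' @param results data.frame from [fit_expression_age_model()].
#' @param fdr_exploratory exploratory FDR threshold (default 0.10).
#' @param fdr_final stringent FDR threshold (default 0.015).
#' @param min_abs_log2fc minimum `|log2fc_per_year|` (default 0.015,
#'   about 1%/year).
#' @return list with data.frames `exploratory` and `final`.
#' @export
select_age_associated <- function(results,
                                  fdr_exploratory = 0.10,
                                  fdr_final = 0.015,
                                  min_abs_log2fc = 0.015) {
  stopifnot(fdr_exploratory > 0, fdr_exploratory <= 1,
            fdr_final > 0, fdr_final <= 1, min_abs_log2fc >= 0)
  ok <- !is.na(results$fdr)
  exploratory <- results[ok & results$fdr <= fdr_exploratory, , drop = FALSE]
  final <- results[ok & results$fdr <= fdr_final &
                     abs(results$log2fc_per_year) >= min_abs_log2fc, ,
                   drop = FALSE]
  list(exploratory = exploratory, final = final)
}

# --- shared design helpers -------------------------------------------------

# subset/reorder a matrix and clinical table to their common samples,
# dropping samples with missing covariate values (listwise)
align_samples <- function(mat, clinical, covariates = character()) {
  stopifnot(all(c("sample_id", "age_years") %in% names(clinical)),
            !anyNA(clinical$age_years))
  missing_cov <- setdiff(covariates, names(clinical))
  if (length(missing_cov)) {
    stop("covariate(s) not in clinical table: ",
         paste(missing_cov, collapse = ", "))
  }
  common <- intersect(colnames(mat), clinical$sample_id)
  if (length(common) == 0L) stop("no shared samples between matrix and clinical table")
  clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  if (length(covariates)) {
    complete <- stats::complete.cases(clinical[, covariates, drop = FALSE])
    if (any(!complete)) {
      message(sum(!complete), " sample(s) dropped for missing covariates")
    }
    clinical <- clinical[complete, , drop = FALSE]
    common <- clinical$sample_id
  }
  list(mat = mat[, common, drop = FALSE], clinical = clinical)
}

# design matrix: intercept + centered age + covariates (factors expanded);
# constant covariate columns are dropped with a warning
build_design <- function(clinical, covariates = character()) {
  clinical$age_c <- clinical$age_years - mean(clinical$age_years)
  keep <- character(0)
  for (cv in covariates) {
    v <- clinical[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      warning("covariate ", sQuote(cv), " is constant; dropped from design")
    } else {
      keep <- c(keep, cv)
    }
  }
  fml <- stats::reformulate(c("age_c", keep))
  X <- stats::model.matrix(fml, data = clinical)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  X
}
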