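#' Generate a synthetic tumor cohort clinical table
#'
#' Draws patient ages from a truncated normal distribution on
#' `[age_range[1], age_range[2]]` and, optionally, ordinal tumor
#' covariates (Gleason score 6-10 and pathological T stage T2a-T4) from
#' proportional-odds models whose dependence on centered age is
#' controlled by `covariate_config`. With the default zero age
#' coefficients the covariates are independent of age.
#'
#' @param n_samples number of patients (>= 2).
#' @param age_range numeric length-2, inclusive truncation bounds in years.
#' @param age_mean target mean age in years; must lie inside `age_range`.
#' @param age_sd standard deviation (years) of the parent normal before
#'   truncation. The default reproduces an interquartile range close to
#'   10 years, typical of prostate tumor cohorts.
#' @param covariate_config list with elements `gleason` and `t_stage`,
#'   each either `NULL` (omit the covariate) or a list with `base_probs`
#'   (marginal category probabilities) and `age_coef` (log-odds shift per
#'   centered year). See [default_covariate_config()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return data.frame with columns `sample_id`, `age_years`, and, when
#'   configured, ordered factors `gleason` and `t_stage`.
#' @export
generate_cohort <- function(n_samples,
                            age_range = c(43.5, 78.6),
                            age_mean = 61.6,
                            age_sd = 7.3,
                            covariate_config = default_covariate_config(),
                            seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 2) {
    stop("n_samples must be a single number >= 2")
  }
  if (length(age_range) != 2L || diff(age_range) <= 0) {
    stop("age_range must be an increasing pair of ages")
  }
  if (age_mean < age_range[1] || age_mean > age_range[2]) {
    stop("age_mean must lie within age_range")
  }
  stopifnot(age_sd > 0)
  n_samples <- as.integer(n_samples)
  withr::local_seed(seed)

  # inverse-CDF sampling from the truncated normal
  lo <- stats::pnorm(age_range[1], age_mean, age_sd)
  hi <- stats::pnorm(age_range[2], age_mean, age_sd)
  age <- stats::qnorm(stats::runif(n_samples, lo, hi), age_mean, age_sd)

  clin <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    age_years = age,
    stringsAsFactors = FALSE
  )
  age_c <- age - mean(age)
  if (!is.null(covariate_config$gleason)) {
    clin$gleason <- sample_ordinal(age_c, covariate_config$gleason,
                                   levels = as.character(6:10))
  }
  if (!is.null(covariate_config$t_stage)) {
    clin$t_stage <- sample_ordinal(age_c, covariate_config$t_stage,
                                   levels = c("T2a", "T2b", "T2c",
                                              "T3a", "T3b", "T4"))
  }
  clin
}

#' Default covariate configuration for the cohort generator
#'
#' Marginal category frequencies loosely follow the composition of
#' primary prostate tumor series (Gleason 7 the modal score, T2c/T3a the
#' modal stages); `age_coef` defaults to 0 because the joint age-grade
#' distribution of the motivating cohort is not published.
#'
#' @return list with `gleason` and `t_stage` sub-configurations.
#' @export
default_covariate_config <- function() {
  list(
    gleason = list(base_probs = c(0.25, 0.40, 0.18, 0.12, 0.05),
                   age_coef = 0),
    t_stage = list(base_probs = c(0.05, 0.08, 0.42, 0.28, 0.12, 0.05),
                   age_coef = 0)
  )
}

# proportional-odds draw: P(Y <= k | a) = plogis(theta_k - age_coef * a)
sample_ordinal <- function(age_c, cfg, levels) {
  p <- cfg$base_probs
  stopifnot(length(p) == length(levels), all(p > 0))
  p <- p / sum(p)
  theta <- stats::qlogis(cumsum(p)[-length(p)])
  u <- stats::runif(length(age_c))
  cum <- vapply(theta, function(th) stats::plogis(th - cfg$age_coef * age_c),
                numeric(length(age_c)))
  idx <- rowSums(u > cbind(cum)) + 1L
  factor(levels[idx], levels = levels, ordered = TRUE)
}

#' Generate synthetic miRNA loci and CpG probe annotation
#'
#' Places `n_mirna` non-overlapping miRNA loci on a synthetic genome,
#' assigns each a strand, and scatters promoter CpG probes uniformly
#' within `half_width` bp of the strand-aware transcription start site.
#' A configurable fraction of additional decoy probes are placed outside
#' every promoter window, emulating the genome-wide background of a
#' methylation array. Locus identifiers deliberately exercise the
#' identifier-harmonization rule (species prefix, hyphens, occasional
#' locus-number suffixes); the matching expression feature ids returned
#' in the truth table add mature-arm suffixes.
#'
#' @param n_mirna number of miRNA loci (>= 1).
#' @param cpgs_per_promoter integer length-2 range; each promoter
#'   receives a uniform draw from `cpgs_per_promoter[1]:cpgs_per_promoter[2]`
#'   probes (0 allowed, producing miRNAs with no methylation coverage).
#' @param genome_config list: `n_chrom`, `chrom_length` (bp).
#' @param decoy_fraction fraction of all probes that map to no promoter.
#' @param half_width promoter half-width in bp used for probe placement.
#' @param seed integer seed.
#' @return list with `loci` (data.frame: locus_id, chrom, start, end,
#'   strand) and `probes` (data.frame: probe_id, chrom, position,
#'   source_locus — the generating locus, `NA` for decoys; downstream
#'   mapping code ignores this ground-truth column).
#' @export
generate_annotation <- function(n_mirna,
                                cpgs_per_promoter = c(2L, 6L),
                                genome_config = list(n_chrom = 4L,
                                                     chrom_length = 5e7),
                                decoy_fraction = 0.2,
                                half_width = 2000L,
                                seed = 1L) {
  stopifnot(n_mirna >= 1, length(cpgs_per_promoter) == 2L,
            cpgs_per_promoter[1] >= 0,
            cpgs_per_promoter[2] >= cpgs_per_promoter[1],
            decoy_fraction >= 0, decoy_fraction < 1)
  withr::local_seed(seed)
  n_chrom <- genome_config$n_chrom
  clen <- genome_config$chrom_length

  # lay loci on a jittered grid so promoter windows cannot collide
  per_chrom <- ceiling(n_mirna / n_chrom)
  spacing <- floor(clen / (per_chrom + 1))
  if (spacing < 4 * half_width + 200) {
    warning("loci packed closer than two promoter widths; ",
            "windows may overlap")
  }
  chrom <- paste0("chr", rep(seq_len(n_chrom), length.out = n_mirna))
  slot <- unlist(lapply(table(factor(chrom, paste0("chr", seq_len(n_chrom)))),
                        seq_len), use.names = FALSE)
  start <- slot * spacing +
    floor(stats::runif(n_mirna, -spacing / 8, spacing / 8))
  width <- sample(60:120, n_mirna, replace = TRUE)
  strand <- sample(c("+", "-"), n_mirna, replace = TRUE)

  num <- 100L + seq_len(n_mirna)
  locus_suffix <- ifelse(stats::runif(n_mirna) < 0.2,
                         paste0("-", sample(1:2, n_mirna, replace = TRUE)),
                         "")
  loci <- data.frame(
    locus_id = paste0("hsa-mir-", num, locus_suffix),
    chrom = chrom,
    start = as.integer(start),
    end = as.integer(start + width),
    strand = strand,
    stringsAsFactors = FALSE
  )

  tss <- ifelse(loci$strand == "+", loci$start, loci$end)
  n_cpg <- if (cpgs_per_promoter[1] == cpgs_per_promoter[2]) {
    rep(cpgs_per_promoter[1], n_mirna)
  } else {
    sample(cpgs_per_promoter[1]:cpgs_per_promoter[2], n_mirna,
           replace = TRUE)
  }
  prom_pos <- unlist(mapply(function(t, k) {
    if (k == 0) return(integer(0))
    pmax(1L, as.integer(round(stats::runif(k, t - half_width,
                                           t + half_width))))
  }, tss, n_cpg, SIMPLIFY = FALSE), use.names = FALSE)
  prom <- data.frame(
    chrom = rep(loci$chrom, n_cpg),
    position = prom_pos,
    source_locus = rep(loci$locus_id, n_cpg),
    stringsAsFactors = FALSE
  )

  n_decoy <- if (decoy_fraction > 0) {
    max(1L, round(decoy_fraction / (1 - decoy_fraction) * nrow(prom)))
  } else 0L
  decoy <- NULL
  if (n_decoy > 0) {
    win_lo <- tss - half_width
    win_hi <- tss + half_width
    dch <- paste0("chr", sample(n_chrom, 4L * n_decoy, replace = TRUE))
    dpos <- as.integer(ceiling(stats::runif(4L * n_decoy, 1, clen)))
    inside <- vapply(seq_along(dpos), function(i) {
      any(loci$chrom == dch[i] & dpos[i] >= win_lo & dpos[i] <= win_hi)
    }, logical(1))
    keep <- which(!inside)[seq_len(min(n_decoy, sum(!inside)))]
    decoy <- data.frame(chrom = dch[keep], position = dpos[keep],
                        source_locus = NA_character_,
                        stringsAsFactors = FALSE)
  }
  probes <- rbind(prom, decoy)
  probes <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(nrow(probes))),
    probes,
    stringsAsFactors = FALSE
  )
  list(loci = loci, probes = probes)
}

#' Plant per-year effects and concordance classes for simulated miRNAs
#'
#' Assigns each locus a per-year log2 expression effect and a per-year
#' promoter methylation slope (beta units/year) so that the planted sign
#' pattern matches the requested concordance class: concordant miRNAs
#' pair rising expression with falling methylation or vice versa,
#' discordant miRNAs move both layers in the same direction, null
#' miRNAs have both effects exactly 0.
#'
#' @param locus_ids character vector of locus identifiers (from
#'   [generate_annotation()]).
#' @param n_concordant,n_discordant numbers of planted non-null miRNAs;
#'   the remainder are null.
#' @param log2fc_range magnitude range of planted expression effects
#'   (log2 units per year).
#' @param beta_slope_range magnitude range of planted methylation slopes
#'   (beta units per year).
#' @param seed integer seed.
#' @return data.frame (the truth table) with columns `locus_id`,
#'   `mirna_id` (arm-suffixed expression feature id), `base_id`,
#'   `planted_log2fc_per_year`, `planted_beta_slope_per_year`,
#'   `planted_class`.
#' @export
make_truth_table <- function(locus_ids,
                             n_concordant = 30L,
                             n_discordant = 30L,
                             log2fc_range = c(0.03, 0.25),
                             beta_slope_range = c(0.002, 0.005),
                             seed = 1L) {
  n <- length(locus_ids)
  stopifnot(n_concordant + n_discordant <= n,
            log2fc_range[1] > 0, beta_slope_range[1] > 0)
  withr::local_seed(seed)
  cls <- rep("null", n)
  planted <- sample(n, n_concordant + n_discordant)
  cls[planted[seq_len(n_concordant)]] <- "concordant"
  cls[planted[n_concordant + seq_len(n_discordant)]] <- "discordant"

  b <- numeric(n)
  s <- numeric(n)
  nz <- cls != "null"
  b[nz] <- stats::runif(sum(nz), log2fc_range[1], log2fc_range[2]) *
    sample(c(-1, 1), sum(nz), replace = TRUE)
  mag <- stats::runif(sum(nz), beta_slope_range[1], beta_slope_range[2])
  # concordant: methylation sign opposite to expression; discordant: same
  s[nz] <- ifelse(cls[nz] == "concordant", -sign(b[nz]), sign(b[nz])) * mag

  arm <- sample(c("", "-5p", "-3p"), n, replace = TRUE,
                prob = c(0.4, 0.3, 0.3))
  mirna_id <- paste0(sub("^hsa-mir", "hsa-miR", locus_ids), arm)
  data.frame(
    locus_id = locus_ids,
    mirna_id = mirna_id,
    base_id = harmonize_mirna_id(locus_ids),
    planted_log2fc_per_year = b,
    planted_beta_slope_per_year = s,
    planted_class = cls,
    stringsAsFactors = FALSE
  )
}

#' Simulate a negative-binomial miRNA count matrix with planted age trends
#'
#' Counts for feature *i* in sample *j* are drawn from a negative
#' binomial with mean `mu0_i * 2^(b_i * (age_j - mean(age))) * sf_j` and
#' variance `mu + dispersion * mu^2`, where `b_i` is the planted per-year
#' log2 effect, `mu0_i` a lognormal baseline, and `sf_j` an optional
#' lognormal library-size factor.
#'
#' @param clinical cohort table from [generate_cohort()].
#' @param truth truth table from [make_truth_table()].
#' @param baseline_config list: `mu_meanlog`, `mu_sdlog` (log-scale
#'   baseline mean distribution) and `libsize_sdlog` (sd of the log
#'   library-size factors; 0 disables them). A fixed per-feature
#'   baseline can be forced with `mu0` (recycled across features),
#'   which must be positive.
#' @param dispersion NB dispersion alpha (> 0), shared across features.
#' @param seed integer seed.
#' @return integer matrix, features x samples, rownames `truth$mirna_id`,
#'   colnames `clinical$sample_id`.
#' @export
simulate_counts <- function(clinical, truth,
                            baseline_config = list(mu_meanlog = log(500),
                                                   mu_sdlog = 1,
                                                   libsize_sdlog = 0.2),
                            dispersion = 0.1,
                            seed = 1L) {
  stopifnot(dispersion > 0)
  withr::local_seed(seed)
  n_f <- nrow(truth)
  n_s <- nrow(clinical)
  mu0 <- if (!is.null(baseline_config$mu0)) {
    rep_len(baseline_config$mu0, n_f)
  } else {
    stats::rlnorm(n_f, baseline_config$mu_meanlog,
                  baseline_config$mu_sdlog)
  }
  if (any(mu0 <= 0)) stop("baseline means must be positive")
  sdl <- baseline_config$libsize_sdlog %||% 0
  sf <- if (sdl > 0) stats::rlnorm(n_s, 0, sdl) else rep(1, n_s)
  age_c <- clinical$age_years - mean(clinical$age_years)
  mu <- outer(mu0, rep(1, n_s)) *
    2 ^ (truth$planted_log2fc_per_year %o% age_c) *
    rep(sf, each = n_f)
  counts <- matrix(stats::rnbinom(n_f * n_s, mu = mu, size = 1 / dispersion),
                   nrow = n_f,
                   dimnames = list(truth$mirna_id, clinical$sample_id))
  counts
}

#' Simulate a CpG beta-value matrix with planted methylation drift
#'
#' Each promoter probe inherits the planted per-year slope of its source
#' miRNA; decoy probes drift with slope 0. Beta values are
#' `clip(beta0_p + slope_p * (age_j - mean(age)) + eps, 0, 1)` with
#' Gaussian noise `eps ~ N(0, noise_sd^2)` and per-probe baselines
#' `beta0_p ~ U(beta0_range[1], beta0_range[2])`.
#'
#' @param clinical cohort table.
#' @param probes probe annotation from [generate_annotation()] (must
#'   carry the `source_locus` ground-truth column).
#' @param truth truth table keyed by `locus_id`.
#' @param noise_sd Gaussian noise sd in beta units (>= 0).
#' @param beta0_range range of the uniform per-probe baseline.
#' @param seed integer seed.
#' @return numeric matrix in `[0, 1]`, probes x samples.
#' @export
simulate_betas <- function(clinical, probes, truth,
                           noise_sd = 0.03, beta0_range = c(0.1, 0.9),
                           seed = 1L) {
  stopifnot(noise_sd >= 0,
            "source_locus" %in% names(probes))
  withr::local_seed(seed)
  slope <- truth$planted_beta_slope_per_year[
    match(probes$source_locus, truth$locus_id)]
  slope[is.na(slope)] <- 0
  n_p <- nrow(probes)
  n_s <- nrow(clinical)
  beta0 <- stats::runif(n_p, beta0_range[1], beta0_range[2])
  age_c <- clinical$age_years - mean(clinical$age_years)
  beta <- outer(beta0, rep(1, n_s)) + slope %o% age_c
  if (noise_sd > 0) {
    beta <- beta + matrix(stats::rnorm(n_p * n_s, 0, noise_sd), nrow = n_p)
  }
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(probes$probe_id, clinical$sample_id)
  beta
}

#' Simulate a complete synthetic multi-omics study
#'
#' Convenience wrapper tying the generator together under one seed. The
#' defaults are the package's reference study conditions: 449 patients
#' aged 43.5-78.6 years (mean 61.6), 300 miRNA loci of which 30 carry
#' planted concordant effects, 30 discordant, and 240 are null;
#' expression effects of 0.03-0.25 log2 units/year, methylation drift of
#' 0.002-0.005 beta units/year, NB dispersion 0.1, beta noise sd 0.03.
#'
#' @param n_samples,n_mirna,n_concordant,n_discordant cohort dimensions.
#' @param age_range,age_mean passed to [generate_cohort()].
#' @param dispersion,noise_sd passed to the matrix simulators.
#' @param cpgs_per_promoter,decoy_fraction passed to
#'   [generate_annotation()].
#' @param log2fc_range,beta_slope_range passed to [make_truth_table()].
#' @param seed master seed; stage seeds are derived deterministically.
#' @return list with `clinical`, `loci`, `probes`, `truth`, `counts`,
#'   `betas`, and `params` (the echoed generation parameters).
#' @export
simulate_study <- function(n_samples = 449L,
                           n_mirna = 300L,
                           n_concordant = 30L,
                           n_discordant = 30L,
                           age_range = c(43.5, 78.6),
                           age_mean = 61.6,
                           dispersion = 0.1,
                           noise_sd = 0.03,
                           cpgs_per_promoter = c(2L, 6L),
                           decoy_fraction = 0.2,
                           log2fc_range = c(0.03, 0.25),
                           beta_slope_range = c(0.002, 0.005),
                           seed = 1L) {
  seed <- as.integer(seed)
  sub <- (seed * 7L + 1:5) %% .Machine$integer.max
  clinical <- generate_cohort(n_samples, age_range, age_mean, seed = sub[1])
  ann <- generate_annotation(n_mirna, cpgs_per_promoter,
                             decoy_fraction = decoy_fraction, seed = sub[2])
  truth <- make_truth_table(ann$loci$locus_id, n_concordant, n_discordant,
                            log2fc_range, beta_slope_range, seed = sub[3])
  counts <- simulate_counts(clinical, truth, dispersion = dispersion,
                            seed = sub[4])
  betas <- simulate_betas(clinical, ann$probes, truth,
                          noise_sd = noise_sd, seed = sub[5])
  list(clinical = clinical, loci = ann$loci, probes = ann$probes,
       truth = truth, counts = counts, betas = betas,
       params = list(n_samples = n_samples, n_mirna = n_mirna,
                     n_concordant = n_concordant,
                     n_discordant = n_discordant,
                     age_range = age_range, age_mean = age_mean,
                     dispersion = dispersion, noise_sd = noise_sd,
                     cpgs_per_promoter = cpgs_per_promoter,
                     decoy_fraction = decoy_fraction,
                     log2fc_range = log2fc_range,
                     beta_slope_range = beta_slope_range,
                     seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
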