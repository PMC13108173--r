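test_that("cohort ages respect range, mean, and determinism", {
  clin <- generate_cohort(449, c(43.5, 78.6), 61.6, seed = 1)
  expect_equal(nrow(clin), 449L)
  expect_false(anyDuplicated(clin$sample_id) > 0)
  expect_true(all(clin$age_years >= 43.5 & clin$age_years <= 78.6))
  expect_gt(mean(clin$age_years), 60.6)
  expect_lt(mean(clin$age_years), 62.6)

  big <- generate_cohort(10000, c(50, 70), 60, seed = 2)
  expect_lt(abs(mean(big$age_years) - 60), 0.5)

  two_a <- generate_cohort(2, c(50, 70), 60, seed = 7)
  two_b <- generate_cohort(2, c(50, 70), 60, seed = 7)
  expect_identical(two_a, two_b)
  expect_length(unique(two_a$sample_id), 2L)

  expect_error(generate_cohort(1), "n_samples")
  expect_error(generate_cohort(10, c(70, 50), 60), "age_range")
  expect_error(generate_cohort(10, c(50, 70), 80), "age_mean")
})

test_that("covariates are drawn with a configurable age dependence", {
  cfg <- default_covariate_config()
  cfg$gleason$age_coef <- 0.3
  clin <- generate_cohort(4000, c(43.5, 78.6), 61.6,
                          covariate_config = cfg, seed = 5)
  # positive age coefficient shifts older patients to higher grades
  r <- cor(clin$age_years, as.integer(clin$gleason), method = "spearman")
  expect_gt(r, 0.2)

  clin0 <- generate_cohort(4000, c(43.5, 78.6), 61.6, seed = 5)
  r0 <- cor(clin0$age_years, as.integer(clin0$gleason),
            method = "spearman")
  expect_lt(abs(r0), 0.05)
})

test_that("promoter CpGs land within the half-width of the strand-aware TSS", {
  ann <- generate_annotation(5, c(2L, 4L), seed = 7)
  tss <- ifelse(ann$loci$strand == "+", ann$loci$start, ann$loci$end)
  names(tss) <- ann$loci$locus_id
  planted <- ann$probes[!is.na(ann$probes$source_locus), ]
  expect_gt(nrow(planted), 0)
  expect_true(all(abs(planted$position - tss[planted$source_locus]) <= 2000))

  none <- generate_annotation(4, c(0L, 0L), seed = 8)
  expect_true(all(is.na(none$probes$source_locus)))
  win <- define_promoters(none$loci)
  expect_equal(nrow(map_cpgs_to_promoters(none$probes, win)), 0L)
})

test_that("decoy probes fall outside all promoters at the configured rate", {
  ann <- generate_annotation(50, c(3L, 5L), decoy_fraction = 0.5, seed = 9)
  win <- define_promoters(ann$loci)
  mapped <- map_cpgs_to_promoters(ann$probes, win)
  frac_unmapped <- 1 - length(unique(mapped$probe_id)) / nrow(ann$probes)
  expect_gt(frac_unmapped, 0.4)
  expect_lt(frac_unmapped, 0.6)
  # and the oracle agrees no decoy is inside any window
  decoys <- ann$probes[is.na(ann$probes$source_locus), ]
  expect_equal(nrow(brute_force_map(decoys, win)), 0L)
})

test_that("crowded genomes warn about potential promoter overlap", {
  expect_warning(
    generate_annotation(200, c(1L, 2L),
                        genome_config = list(n_chrom = 1L,
                                             chrom_length = 1e6),
                        seed = 3),
    "overlap")
})

test_that("counts follow the planted NB age model and are reproducible", {
  clin <- generate_cohort(400, c(43.5, 78.6), 61.6, seed = 10)
  ann <- generate_annotation(50, c(1L, 1L), decoy_fraction = 0, seed = 11)

  null_truth <- make_truth_table(ann$loci$locus_id, 0, 0, seed = 12)
  cts <- simulate_counts(clin, null_truth, seed = 13)
  expect_true(all(cts >= 0) && all(cts == floor(cts)))
  rho <- apply(log1p(cts), 1, cor, y = clin$age_years,
               method = "spearman")
  expect_lt(abs(mean(rho)), 0.03)

  up <- make_truth_table(ann$loci$locus_id, 0, 0, seed = 12)
  up$planted_log2fc_per_year <- 0.1
  cts_up <- simulate_counts(clin, up,
                            baseline_config = list(mu0 = 1000,
                                                   libsize_sdlog = 0),
                            dispersion = 0.01, seed = 14)
  dec <- quantile(clin$age_years, c(0.1, 0.9))
  young <- clin$age_years <= dec[1]
  old <- clin$age_years >= dec[2]
  lfc <- log2(mean(cts_up[, old]) / mean(cts_up[, young]))
  expect_gt(lfc, 0)

  expect_identical(simulate_counts(clin, up, seed = 99),
                   simulate_counts(clin, up, seed = 99))
  expect_error(simulate_counts(clin, up,
                               baseline_config = list(mu0 = 0),
                               seed = 1),
               "positive")
})

test_that("beta values follow the planted linear drift and stay in [0,1]", {
  clin <- toy_clinical(20)
  probes <- data.frame(probe_id = sprintf("cg%02d", 1:5),
                       chrom = "chr1", position = 1:5 * 1000,
                       source_locus = "hsa-mir-101",
                       stringsAsFactors = FALSE)
  truth <- data.frame(locus_id = "hsa-mir-101", mirna_id = "hsa-miR-101",
                      base_id = "mir101",
                      planted_log2fc_per_year = 0,
                      planted_beta_slope_per_year = 0.001,
                      planted_class = "discordant",
                      stringsAsFactors = FALSE)
  noiseless <- simulate_betas(clin, probes, truth, noise_sd = 0, seed = 4)
  age_c <- clin$age_years - mean(clin$age_years)
  for (p in seq_len(nrow(probes))) {
    fit <- lm(noiseless[p, ] ~ age_c)
    expect_equal(unname(coef(fit)[2]), 0.001, tolerance = 1e-10)
  }
  expect_true(all(noiseless >= 0 & noiseless <= 1))

  clipped <- simulate_betas(clin, probes, truth, noise_sd = 0,
                            beta0_range = c(0.99, 0.99), seed = 4)
  expect_true(max(clipped) <= 1)
  expect_true(any(clipped == 1))

  expect_identical(simulate_betas(clin, probes, truth, seed = 5),
                   simulate_betas(clin, probes, truth, seed = 5))
})

test_that("planted classes are consistent with the concordance sign rule", {
  truth <- make_truth_table(sprintf("hsa-mir-%d", 1:300), 30, 30, seed = 6)
  expect_equal(sum(truth$planted_class == "concordant"), 30L)
  expect_equal(sum(truth$planted_class == "discordant"), 30L)
  nul <- truth$planted_class == "null"
  expect_true(all(truth$planted_log2fc_per_year[nul] == 0))
  expect_true(all(truth$planted_beta_slope_per_year[nul] == 0))
  nz <- !nul
  dir <- ifelse(truth$planted_log2fc_per_year[nz] > 0, "Up", "Down")
  stat <- ifelse(truth$planted_beta_slope_per_year[nz] > 0, "Hyper", "Hypo")
  expect_identical(classify_concordance(dir, stat),
                   truth$planted_class[nz])
})

test_that("null cohorts give approximately uniform age-association p-values", {
  clin <- generate_cohort(200, c(43.5, 78.6), 61.6, seed = 15)
  probes <- data.frame(probe_id = sprintf("cg%04d", 1:600),
                       chrom = "chr1", position = 1:600 * 100,
                       source_locus = NA_character_,
                       stringsAsFactors = FALSE)
  truth <- make_truth_table("hsa-mir-1", 0, 0, seed = 16)
  betas <- simulate_betas(clin, probes, truth, noise_sd = 0.03, seed = 17)
  res <- fit_cpg_age_model(betas, clin)
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a simulated study round-trips through its file formats", {
  st <- simulate_study(n_samples = 20, n_mirna = 10, n_concordant = 2,
                       n_discordant = 2, seed = 21)
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))

  counts2 <- read_matrix_tsv(paths["counts"])
  expect_equal(unname(counts2), unname(st$counts))
  expect_identical(rownames(counts2), rownames(st$counts))

  clin2 <- read_clinical_tsv(paths["clinical"])
  expect_equal(clin2$age_years, st$clinical$age_years)

  loci_gff <- read_loci(paths["loci_gff3"])
  expect_setequal(loci_gff$locus_id, st$loci$locus_id)
  m <- match(st$loci$locus_id, loci_gff$locus_id)
  expect_equal(loci_gff$start[m], st$loci$start)
  expect_equal(loci_gff$strand[m], st$loci$strand)

  loci_bed <- read_loci(paths["loci_bed"])
  m <- match(st$loci$locus_id, loci_bed$locus_id)
  expect_equal(loci_bed$end[m], st$loci$end)

  params <- yaml::read_yaml(paths["params"])
  expect_equal(params$n_samples, 20)
})
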