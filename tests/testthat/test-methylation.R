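test_that("noiseless linear drift is recovered exactly", {
  clin <- toy_clinical(20)
  age_c <- clin$age_years - mean(clin$age_years)
  betas <- rbind(cg1 = 0.3 + 0.001 * age_c,
                 cg2 = 0.5 - 0.002 * age_c)
  colnames(betas) <- clin$sample_id
  res <- fit_cpg_age_model(betas, clin)
  expect_equal(res$slope_per_year[res$probe_id == "cg1"], 0.001,
               tolerance = 1e-10)
  expect_equal(res$slope_per_year[res$probe_id == "cg2"], -0.002,
               tolerance = 1e-10)
})

test_that("planted slopes are recovered within 3 SE on noisy data", {
  clin <- generate_cohort(400, c(43.5, 78.6), 61.6, seed = 51)
  probes <- data.frame(probe_id = sprintf("cg%04d", 1:300),
                       chrom = "chr1", position = 1:300 * 500,
                       source_locus = "hsa-mir-500",
                       stringsAsFactors = FALSE)
  truth <- data.frame(locus_id = "hsa-mir-500", mirna_id = "hsa-miR-500",
                      base_id = "mir500", planted_log2fc_per_year = 0,
                      planted_beta_slope_per_year = 0.002,
                      planted_class = "discordant",
                      stringsAsFactors = FALSE)
  betas <- simulate_betas(clin, probes, truth, noise_sd = 0.01, seed = 52)
  res <- fit_cpg_age_model(betas, clin)
  covered <- abs(res$slope_per_year - 0.002) <= 3 * res$std_error
  expect_gte(mean(covered), 0.95)
})

test_that("permuting ages against a planted-effect matrix nullifies p-values", {
  # repeated permutations give independent draws from the permutation
  # null; the resulting p-values must look uniform
  clin <- generate_cohort(150, c(43.5, 78.6), 61.6, seed = 53)
  probes <- data.frame(probe_id = "cg0001",
                       chrom = "chr1", position = 500,
                       source_locus = "hsa-mir-501",
                       stringsAsFactors = FALSE)
  truth <- data.frame(locus_id = "hsa-mir-501", mirna_id = "hsa-miR-501",
                      base_id = "mir501", planted_log2fc_per_year = 0,
                      planted_beta_slope_per_year = 0.003,
                      planted_class = "discordant",
                      stringsAsFactors = FALSE)
  betas <- simulate_betas(clin, probes, truth, noise_sd = 0.02, seed = 54)
  set.seed(55)
  p <- unlist(lapply(1:300, function(r) {
    perm <- clin
    perm$age_years <- sample(perm$age_years)
    fit_cpg_age_model(betas, perm)$p_value
  }))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero-variance probes get slope 0 and are excluded from BH", {
  clin <- toy_clinical(10)
  betas <- rbind(cg_flat = rep(0.4, 10),
                 cg_var = 0.3 + 0.001 * (clin$age_years - 60) +
                   seq(-0.01, 0.01, length.out = 10))
  colnames(betas) <- clin$sample_id
  res <- fit_cpg_age_model(betas, clin)
  flat <- res[res$probe_id == "cg_flat", ]
  expect_equal(flat$slope_per_year, 0)
  expect_true(is.na(flat$p_value) && is.na(flat$fdr))
  expect_false(is.na(res$fdr[res$probe_id == "cg_var"]))
})

test_that("promoter windows are strand-aware, closed, and floored at 1", {
  loci <- data.frame(
    locus_id = c("hsa-mir-1", "hsa-mir-2", "hsa-mir-3"),
    chrom = "chr1",
    start = c(10000L, 5000L, 500L),
    end = c(10090L, 6000L, 590L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE
  )
  win <- define_promoters(loci, half_width = 2000L)
  expect_equal(win$tss, c(10000L, 6000L, 500L))
  expect_equal(win$window_start, c(8000L, 4000L, 1L))
  expect_equal(win$window_end, c(12000L, 8000L, 2500L))

  loci$strand[1] <- NA
  expect_error(define_promoters(loci), "strand")
})

test_that("window boundaries are inclusive on both sides", {
  win <- define_promoters(data.frame(locus_id = "hsa-mir-9",
                                     chrom = "chr1", start = 10000L,
                                     end = 10090L, strand = "+",
                                     stringsAsFactors = FALSE))
  probes <- data.frame(probe_id = c("in_lo", "in_hi", "out_hi", "out_lo"),
                       chrom = "chr1",
                       position = c(8000L, 12000L, 12001L, 7999L),
                       stringsAsFactors = FALSE)
  m <- map_cpgs_to_promoters(probes, win)
  expect_setequal(m$probe_id, c("in_lo", "in_hi"))
})

test_that("interval mapping matches the brute-force oracle on random instances", {
  set.seed(61)
  for (i in 1:25) {
    n_w <- sample(3:20, 1)
    loci <- data.frame(
      locus_id = sprintf("hsa-mir-%d", seq_len(n_w)),
      chrom = sample(paste0("chr", 1:3), n_w, replace = TRUE),
      start = sample(1:60000, n_w),
      strand = sample(c("+", "-"), n_w, replace = TRUE),
      stringsAsFactors = FALSE
    )
    loci$end <- loci$start + sample(50:150, n_w, replace = TRUE)
    win <- define_promoters(loci)
    probes <- data.frame(
      probe_id = sprintf("cg%05d", 1:200),
      chrom = sample(paste0("chr", 1:3), 200, replace = TRUE),
      position = sample(1:70000, 200),
      stringsAsFactors = FALSE
    )
    expect_identical(sort_mapping(map_cpgs_to_promoters(probes, win)),
                     sort_mapping(brute_force_map(probes, win)))
  }
})

test_that("disjoint chromosome naming warns instead of silently dropping", {
  win <- define_promoters(data.frame(locus_id = "hsa-mir-9",
                                     chrom = "1", start = 10000L,
                                     end = 10090L, strand = "+",
                                     stringsAsFactors = FALSE))
  probes <- data.frame(probe_id = "cg1", chrom = "chr1",
                       position = 10000L, stringsAsFactors = FALSE)
  expect_warning(m <- map_cpgs_to_promoters(probes, win), "chromosome")
  expect_equal(nrow(m), 0L)
})

test_that("promoter summarization averages slopes and keeps the minimum FDR", {
  mapping <- data.frame(base_id = c("mir1", "mir1", "mir1", "mir2"),
                        probe_id = c("cg1", "cg2", "cg3", "cg4"),
                        stringsAsFactors = FALSE)
  cpg <- data.frame(probe_id = c("cg1", "cg2", "cg3", "cg4"),
                    slope_per_year = c(0.002, -0.001, 0.005, 0.001),
                    std_error = 0.001,
                    p_value = c(0.1, 0.01, 0.3, 0.05),
                    fdr = c(0.2, 0.04, 0.5, 0.1),
                    stringsAsFactors = FALSE)
  s <- summarize_promoter_methylation(mapping, cpg)
  r1 <- s[s$base_id == "mir1", ]
  expect_equal(r1$mean_slope_per_year, 0.002)
  expect_equal(r1$min_fdr, 0.04)
  expect_equal(r1$n_cpgs, 3L)
  expect_equal(r1$pct_per_year, 0.2)
  expect_identical(r1$status, "Hyper")

  r2 <- s[s$base_id == "mir2", ]
  expect_equal(r2$mean_slope_per_year, 0.001)
  expect_equal(r2$n_cpgs, 1L)

  # permutation invariance in CpG order
  shuf <- sample(nrow(mapping))
  s2 <- summarize_promoter_methylation(mapping[shuf, ], cpg)
  expect_equal(s2[order(s2$base_id), ], s[order(s$base_id), ])

  # unfitted probes are excluded; fully unfitted miRNAs are omitted
  cpg$p_value[4] <- NA
  s3 <- summarize_promoter_methylation(mapping, cpg)
  expect_false("mir2" %in% s3$base_id)
})

test_that("noiseless planted drift is recovered exactly through the full layer", {
  clin <- generate_cohort(60, c(43.5, 78.6), 61.6, seed = 62)
  ann <- generate_annotation(10, c(2L, 3L), decoy_fraction = 0, seed = 63)
  truth <- make_truth_table(ann$loci$locus_id, 3, 3, seed = 64)
  betas <- simulate_betas(clin, ann$probes, truth, noise_sd = 0, seed = 65)
  res <- fit_cpg_age_model(betas, clin)
  win <- define_promoters(ann$loci)
  mapping <- map_cpgs_to_promoters(ann$probes, win)
  s <- summarize_promoter_methylation(mapping, res)
  m <- match(s$base_id, truth$base_id)
  expect_equal(s$mean_slope_per_year,
               truth$planted_beta_slope_per_year[m], tolerance = 1e-8)
})
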