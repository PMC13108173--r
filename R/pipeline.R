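#' Assemble a pipeline configuration
#'
#' A configuration either points at input files (`counts`, `betas`,
#' `clinical`, `loci`, `probes`) or requests simulation
#' (`simulate = list(...)` with [simulate_study()] arguments). Optional
#' inputs switch on optional stages: `covariates` (sensitivity
#' re-analysis), `external_directions` (cross-cohort direction
#' validation), `target_edges` (bipartite network analysis). Analysis
#' thresholds live in `params` (see [default_params()]); unspecified
#' entries take their defaults. Configurations round-trip losslessly
#' through YAML or JSON via [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param outdir output directory for the report bundle.
#' @param simulate `NULL` or list of [simulate_study()] arguments.
#' @param counts,betas,clinical,loci,probes input file paths (ignored
#'   when `simulate` is given).
#' @param covariates character vector of clinical covariate columns.
#' @param external_directions optional path to an external-cohort
#'   direction TSV ([read_external_directions()] formats).
#' @param target_edges optional path to a validated miRNA-target edge
#'   TSV; `evidence_filter` optionally restricts evidence types.
#' @param evidence_filter optional character vector of evidence labels.
#' @param params named list overriding [default_params()] entries.
#' @param seed integer seed governing all randomness in the run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            simulate = NULL,
                            counts = NULL, betas = NULL, clinical = NULL,
                            loci = NULL, probes = NULL,
                            covariates = character(),
                            external_directions = NULL,
                            target_edges = NULL,
                            evidence_filter = NULL,
                            params = list(),
                            seed = 1L) {
  p <- utils::modifyList(default_params(), params)
  stopifnot(p$fdr_exploratory > 0, p$fdr_exploratory <= 1,
            p$fdr_final > 0, p$fdr_final <= 1,
            p$min_abs_log2fc >= 0, p$half_width > 0,
            p$min_gene_degree >= 1,
            p$score_mode %in% c("znorm", "raw"))
  if (is.null(simulate)) {
    for (f in c(counts, betas, clinical, loci, probes,
                external_directions, target_edges)) {
      if (!is.null(f) && !file.exists(f)) stop("input not found: ", f)
    }
    if (is.null(counts) || is.null(betas) || is.null(clinical) ||
        is.null(loci) || is.null(probes)) {
      stop("either supply all five input paths or a simulate block")
    }
  }
  structure(list(
    outdir = outdir, simulate = simulate,
    counts = counts, betas = betas, clinical = clinical,
    loci = loci, probes = probes,
    covariates = covariates,
    external_directions = external_directions,
    target_edges = target_edges,
    evidence_filter = evidence_filter,
    params = p, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) file.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw$covariates <- as.character(raw$covariates %||% character())
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Run the integrative age-association pipeline end to end
#'
#' Executes identifier harmonization, expression and methylation
#' age-trend models, promoter mapping and summarization, integration
#' with concordance classification, scoring and ranking; then, when
#' configured, the covariate sensitivity re-analysis, external
#' direction validation, and target-network analysis. All stage tables,
#' a headline summary, and a reproducibility log are written under
#' `config$outdir`; a rerun with an identical configuration produces a
#' byte-identical bundle.
#'
#' @param config a `pipeline_config` (or path to one).
#' @return invisibly, a list with all stage results (`study`, the
#'   `run_layers()` stages, `ranked`, `summary`, and any optional-stage
#'   outputs) plus `paths` of written files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    study <- do.call(simulate_study, sim_args)
  } else {
    study <- list(
      counts = read_matrix_tsv(config$counts),
      betas = read_matrix_tsv(config$betas),
      clinical = read_clinical_tsv(config$clinical),
      loci = read_loci(config$loci),
      probes = read_probes_tsv(config$probes)
    )
  }

  stages <- run_layers(study$counts, study$betas, study$clinical,
                       study$loci, study$probes, params = p)
  integrated <- stages$integrated
  ranked <- NULL
  if (nrow(integrated) > 0) {
    integrated <- concordance_score(integrated, p$score_mode)
    ranked <- rank_candidates(integrated)
  }

  if (length(config$covariates) > 0 && !is.null(ranked) &&
      nrow(ranked) > 0) {
    robust_ids <- sensitivity_reanalysis(
      study$counts, study$betas, study$clinical, study$loci, study$probes,
      covariates = config$covariates, params = p)
    ranked$covariate_robust <- ranked$base_id %in% robust_ids
  }

  validation <- NULL
  if (!is.null(config$external_directions) && !is.null(ranked)) {
    primary <- rbind(
      data.frame(base_id = ranked$base_id, layer = "expression",
                 call = ranked$expr_direction, stringsAsFactors = FALSE),
      data.frame(base_id = ranked$base_id, layer = "methylation",
                 call = ranked$meth_status, stringsAsFactors = FALSE)
    )
    external <- read_external_directions(config$external_directions)
    records <- compare_directions(primary, external)
    validation <- list(records = records,
                       summary = summarize_validation(records))
  }

  network <- NULL
  if (!is.null(config$target_edges)) {
    edges <- utils::read.delim(config$target_edges,
                               stringsAsFactors = FALSE)
    net <- build_bipartite(edges, config$evidence_filter)
    network <- list(full = net,
                    filtered = degree_filter(net, p$min_gene_degree),
                    hubs = hub_genes(net))
  }

  summary <- summarize_integration(
    integrated,
    n_input = nrow(study$counts),
    n_filtered = nrow(stages$filtered),
    n_exploratory = nrow(stages$selection$exploratory),
    n_final = nrow(stages$selection$final)
  )

  result <- list(study = study, stages = stages, integrated = integrated,
                 ranked = ranked, sensitivity_covariates = config$covariates,
                 validation = validation, network = network,
                 summary = summary, config = config)
  result$paths <- write_report_bundle(result, config$outdir)
  invisible(result)
}

#' Headline counts for an integrated result set
#'
#' Counts concordant and discordant miRNAs and reports the concordant
#' percentage rounded half-away-from-zero to an integer, together with
#' the upstream funnel counts when supplied.
#'
#' @param integrated integrated data.frame with `concordance_class`.
#' @param n_input,n_filtered,n_exploratory,n_final optional upstream
#'   feature counts.
#' @return one-row data.frame of counts.
#' @export
summarize_integration <- function(integrated, n_input = NA_integer_,
                                  n_filtered = NA_integer_,
                                  n_exploratory = NA_integer_,
                                  n_final = NA_integer_) {
  n_conc <- sum(integrated$concordance_class == "concordant")
  n_disc <- sum(integrated$concordance_class == "discordant")
  n_int <- nrow(integrated)
  data.frame(
    n_input = n_input, n_filtered = n_filtered,
    n_exploratory = n_exploratory, n_final = n_final,
    n_integrated = n_int, n_concordant = n_conc, n_discordant = n_disc,
    pct_concordant = if (n_int > 0) {
      round_half_away(100 * n_conc / n_int)
    } else NA_real_
  )
}

# half-away-from-zero rounding (base round() is round-half-even)
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Format report tables at printed precision
#'
#' Renders the ranked candidate table (and, when present, validation
#' and hub tables) with per-year percentages and scores at 3 decimal
#' places, matching the publication-style layout; full-precision values
#' stay in the machine-readable stage tables.
#'
#' @param ranked ranked candidate data.frame from [rank_candidates()].
#' @param validation optional validation list (`records`, `summary`).
#' @param network optional network list (with `hubs`).
#' @return named list of formatted data.frames (`candidates`, and
#'   optionally `validation`, `hubs`).
#' @export
make_report <- function(ranked, validation = NULL, network = NULL) {
  fmt <- function(x) formatC(x, format = "f", digits = 3)
  cand <- data.frame(
    rank = ranked$rank,
    mirna = ranked$base_id,
    expr_pct_per_year = fmt(ranked$expr_pct_per_year),
    expr_direction = ranked$expr_direction,
    meth_pct_per_year = fmt(ranked$meth_pct_per_year),
    meth_status = ranked$meth_status,
    raw_score = fmt(ranked$raw_score),
    stringsAsFactors = FALSE
  )
  if (!is.null(ranked$z_score)) cand$conc_score <- fmt(ranked$z_score)
  if (!is.null(ranked$covariate_robust)) {
    cand$covariate_robust <- ranked$covariate_robust
  }
  out <- list(candidates = cand)
  if (!is.null(validation)) {
    v <- validation$records
    wide <- merge(
      v[v$layer == "expression",
        c("base_id", "primary_call", "external_call", "concordant")],
      v[v$layer == "methylation",
        c("base_id", "primary_call", "external_call", "concordant")],
      by = "base_id", suffixes = c("_expr", "_meth")
    )
    names(wide) <- c("mirna", "expr_direction", "expr_external",
                     "expr_concordance", "meth_status", "meth_external",
                     "meth_concordance")
    out$validation <- wide
  }
  if (!is.null(network)) out$hubs <- network$hubs
  out
}

# write every stage table + summary + log; returns named paths
write_report_bundle <- function(result, outdir) {
  paths <- c()
  wt <- function(d, name) {
    path <- file.path(outdir, name)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[sub("\\.tsv$", "", name)]] <<- path
    path
  }
  st <- result$stages
  wt(st$expr_results, "expression_results.tsv")
  wt(st$selection$exploratory, "expression_exploratory.tsv")
  wt(st$selection$final, "expression_final.tsv")
  wt(st$cpg_results, "cpg_results.tsv")
  wt(st$windows, "promoter_windows.tsv")
  wt(st$mapping, "cpg_promoter_mapping.tsv")
  wt(st$meth_summaries, "promoter_methylation.tsv")
  wt(result$integrated, "integrated.tsv")
  if (!is.null(result$ranked)) {
    wt(result$ranked, "candidates_full.tsv")
    rep <- make_report(result$ranked, result$validation, result$network)
    wt(rep$candidates, "candidates_report.tsv")
    if (!is.null(rep$validation)) wt(rep$validation, "validation_report.tsv")
  }
  if (!is.null(result$validation)) {
    wt(result$validation$records, "validation_records.tsv")
    wt(result$validation$summary, "validation_summary.tsv")
  }
  if (!is.null(result$network)) {
    wt(result$network$hubs, "hub_genes.tsv")
    paths <- c(paths,
               network = write_network(result$network$filtered,
                                       file.path(outdir,
                                                 "network_filtered"))[1])
  }
  wt(result$summary, "summary.tsv")

  log <- list(
    package_version = as.character(utils::packageVersion("mirdrift")),
    r_version = R.version.string,
    seed = result$config$seed,
    params = result$config$params,
    covariates = result$config$covariates,
    counts = list(
      features_in = result$summary$n_input,
      features_after_expression_filter = result$summary$n_filtered,
      constant_features_dropped =
        attr(result$stages$expr_results, "n_constant"),
      nonconverged_features =
        attr(result$stages$expr_results, "n_nonconverged"),
      exploratory = result$summary$n_exploratory,
      final = result$summary$n_final,
      integrated = result$summary$n_integrated,
      concordant = result$summary$n_concordant,
      discordant = result$summary$n_discordant
    )
  )
  log_path <- file.path(outdir, "run_log.yaml")
  yaml::write_yaml(log, log_path)
  paths[["run_log"]] <- log_path
  paths
}
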