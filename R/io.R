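#' Read a feature-by-sample matrix from TSV
#'
#' Expects a header row of sample ids and feature ids in the first
#' column.
#'
#' @param path TSV file.
#' @return numeric matrix, features x samples.
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param mat matrix with feature row names and sample column names.
#' @param path output file.
#' @param id_column header name for the feature-id column.
#' @return invisibly, `path`.
#' @export
write_matrix_tsv <- function(mat, path, id_column = "feature_id") {
  d <- data.frame(rownames(mat), mat, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_column
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Requires `sample_id` and `age_years` columns; `gleason` and
#' `t_stage`, when present, are read as ordered factors.
#'
#' @param path TSV file.
#' @return clinical data.frame.
#' @export
read_clinical_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "age_years") %in% names(d)))
  if ("gleason" %in% names(d)) {
    d$gleason <- factor(d$gleason, levels = 6:10, ordered = TRUE)
  }
  if ("t_stage" %in% names(d)) {
    d$t_stage <- factor(d$t_stage,
                        levels = c("T2a", "T2b", "T2c", "T3a", "T3b", "T4"),
                        ordered = TRUE)
  }
  d
}

#' Read miRNA loci from GFF3, BED, or TSV
#'
#' GFF3 locus ids are taken from the `ID` (or `Name`) attribute; BED
#' from the name column; TSV files must carry `locus_id`, `chrom`,
#' `start`, `end`, `strand` columns.
#'
#' @param path annotation file; format chosen by extension
#'   (`.gff`/`.gff3`, `.bed`, else TSV).
#' @return data.frame: `locus_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_loci <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    id <- if (!is.null(gr$ID)) gr$ID else gr$Name
    grange_to_loci(gr, id)
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    grange_to_loci(gr, gr$name)
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("locus_id", "chrom", "start", "end", "strand") %in%
                    names(d)))
    d
  }
}

grange_to_loci <- function(gr, id) {
  data.frame(
    locus_id = as.character(id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

loci_to_granges <- function(loci) {
  GenomicRanges::GRanges(
    loci$chrom,
    IRanges::IRanges(loci$start, loci$end),
    strand = loci$strand,
    ID = loci$locus_id,
    Name = loci$locus_id
  )
}

#' Write miRNA loci as GFF3
#'
#' Features are exported with type `miRNA` and the locus id in the `ID`
#' attribute.
#'
#' @param loci locus data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_loci_gff3 <- function(loci, path) {
  gr <- loci_to_granges(loci)
  gr$type <- "miRNA"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write miRNA loci as 6-column BED
#'
#' @param loci locus data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_loci_bed <- function(loci, path) {
  gr <- loci_to_granges(loci)
  gr$name <- loci$locus_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read CpG probe annotation from a manifest-style TSV
#'
#' @param path TSV with `probe_id`, `chrom`, `position` columns
#'   (1-based positions).
#' @return probe data.frame.
#' @export
read_probes_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "chrom", "position") %in% names(d)))
  d
}

#' Write a complete synthetic study to disk
#'
#' Emits the generator's outputs in their interchange formats: count
#' and beta matrices as TSV, the clinical table, loci as both GFF3 and
#' BED, the probe annotation and truth table as TSV, and all generation
#' parameters as a YAML sidecar.
#'
#' @param study list from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    betas = file.path(dir, "betas.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    loci_gff3 = file.path(dir, "loci.gff3"),
    loci_bed = file.path(dir, "loci.bed"),
    probes = file.path(dir, "probes.tsv"),
    truth = file.path(dir, "truth.tsv"),
    params = file.path(dir, "params.yaml")
  )
  write_matrix_tsv(study$counts, paths["counts"], "mirna_id")
  write_matrix_tsv(study$betas, paths["betas"], "probe_id")
  utils::write.table(study$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_loci_gff3(study$loci, paths["loci_gff3"])
  write_loci_bed(study$loci, paths["loci_bed"])
  utils::write.table(study$probes, paths["probes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(study$params, paths["params"])
  invisible(paths)
}
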