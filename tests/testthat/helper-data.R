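# shared builders and independent oracles

# tiny clinical table with evenly spread ages
toy_clinical <- function(n = 10, ages = seq(50, 70, length.out = n)) {
  data.frame(sample_id = sprintf("S%04d", seq_len(n)),
             age_years = ages,
             stringsAsFactors = FALSE)
}

# exhaustive O(n * m) closed-interval overlap check; the oracle the
# GenomicRanges-based mapping must reproduce
brute_force_map <- function(probes, windows) {
  rows <- list()
  for (w in seq_len(nrow(windows))) {
    for (p in seq_len(nrow(probes))) {
      if (probes$chrom[p] == windows$chrom[w] &&
          probes$position[p] >= windows$window_start[w] &&
          probes$position[p] <= windows$window_end[w]) {
        rows[[length(rows) + 1L]] <-
          data.frame(base_id = windows$base_id[w],
                     probe_id = probes$probe_id[p],
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(base_id = character(0), probe_id = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# canonical ordering so mappings can be compared as sets
sort_mapping <- function(m) {
  m <- m[order(m$base_id, m$probe_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# canonical edge ordering for network comparisons
sort_net_edges <- function(net) {
  e <- net$edges[order(net$edges$base_id, net$edges$gene), ]
  rownames(e) <- NULL
  e
}

# primary-cohort direction calls (long format) from the bundled
# concordant reference table
reference_primary_calls <- function() {
  ref <- reference_concordant_mirnas()
  rbind(
    data.frame(base_id = ref$base_id, layer = "expression",
               call = ref$expr_direction, stringsAsFactors = FALSE),
    data.frame(base_id = ref$base_id, layer = "methylation",
               call = ref$meth_status, stringsAsFactors = FALSE)
  )
}

# external-cohort calls (long format) from the bundled direction table
reference_external_calls <- function() {
  ext <- reference_external_directions()
  rbind(
    data.frame(base_id = ext$base_id, layer = "expression",
               call = ifelse(ext$expr_direction %in% c("Up", "Down"),
                             ext$expr_direction, NA_character_),
               stringsAsFactors = FALSE),
    data.frame(base_id = ext$base_id, layer = "methylation",
               call = ifelse(ext$meth_status %in% c("Hyper", "Hypo"),
                             ext$meth_status, NA_character_),
               stringsAsFactors = FALSE)
  )
}
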