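#' Build a bipartite miRNA-target network from a validated edge list
#'
#' Nodes are harmonized miRNA base ids on one side and target gene
#' symbols on the other; edges are experimentally validated
#' interactions. Duplicate edges (including duplicates created by
#' identifier harmonization) are collapsed to set semantics. When the
#' edge list carries an `evidence` column and `evidence_filter` is
#' given, only edges whose evidence is in the filter set are kept —
#' supporting the convention of restricting to strong assay types
#' (reporter assay, Western blot, qPCR). Malformed rows (missing miRNA
#' or gene) are skipped with a counted warning.
#'
#' @param edge_list data.frame with columns `mirna_id`, `gene`, and
#'   optionally `evidence`.
#' @param evidence_filter optional character vector of admissible
#'   evidence labels.
#' @return object of class `bipartite_network`: list with `edges`
#'   (data.frame `base_id`, `gene`), `mirna_nodes`, `gene_nodes`,
#'   `mirna_degree`, `gene_degree` (named integer vectors).
#' @export
build_bipartite <- function(edge_list, evidence_filter = NULL) {
  if (nrow(edge_list) == 0L) {
    return(new_bipartite(data.frame(base_id = character(0),
                                    gene = character(0),
                                    stringsAsFactors = FALSE)))
  }
  stopifnot(all(c("mirna_id", "gene") %in% names(edge_list)))
  bad <- is.na(edge_list$mirna_id) | !nzchar(edge_list$mirna_id) |
    is.na(edge_list$gene) | !nzchar(edge_list$gene)
  if (any(bad)) {
    warning(sum(bad), " malformed edge row(s) skipped")
    edge_list <- edge_list[!bad, , drop = FALSE]
  }
  if (!is.null(evidence_filter) && "evidence" %in% names(edge_list)) {
    edge_list <- edge_list[edge_list$evidence %in% evidence_filter, ,
                           drop = FALSE]
  }
  edges <- unique(data.frame(
    base_id = harmonize_mirna_id(edge_list$mirna_id),
    gene = edge_list$gene,
    stringsAsFactors = FALSE
  ))
  new_bipartite(edges)
}

new_bipartite <- function(edges) {
  mirna_nodes <- sort(unique(edges$base_id))
  gene_nodes <- sort(unique(edges$gene))
  structure(list(
    edges = edges,
    mirna_nodes = mirna_nodes,
    gene_nodes = gene_nodes,
    mirna_degree = degree_of(edges$base_id, mirna_nodes),
    gene_degree = degree_of(edges$gene, gene_nodes)
  ), class = "bipartite_network")
}

degree_of <- function(endpoint, nodes) {
  d <- table(factor(endpoint, levels = nodes))
  stats::setNames(as.integer(d), nodes)
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("bipartite miRNA-target network:", length(x$mirna_nodes),
      "miRNAs,", length(x$gene_nodes), "genes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Degree-based hub filtering of a bipartite network
#'
#' Retains genes whose degree in the *input* network reaches
#' `min_gene_degree` (so reported hub degrees refer to the full
#' validated-interaction set, not the pruned one). With
#' `keep_neighbors`, miRNAs incident to a retained gene are kept along
#' with all their edges to retained genes, preserving the local network
#' structure around each hub; otherwise all miRNAs are dropped. Nodes
#' left without edges are removed when `prune_isolated`.
#'
#' @param net `bipartite_network`.
#' @param min_gene_degree minimum gene degree (>= 1; default 5).
#' @param keep_neighbors keep miRNA neighbors of retained genes
#'   (default `TRUE`).
#' @param prune_isolated drop nodes with no remaining edges (default
#'   `TRUE`).
#' @return filtered `bipartite_network`.
#' @export
degree_filter <- function(net, min_gene_degree = 5L,
                          keep_neighbors = TRUE, prune_isolated = TRUE) {
  stopifnot(inherits(net, "bipartite_network"), min_gene_degree >= 1)
  hubs <- names(net$gene_degree)[net$gene_degree >= min_gene_degree]
  edges <- net$edges[net$edges$gene %in% hubs, , drop = FALSE]
  if (!keep_neighbors) {
    edges <- edges[0L, , drop = FALSE]
  }
  out <- new_bipartite(edges)
  if (!prune_isolated) {
    # reinstate edge-less retained genes with degree 0
    iso <- setdiff(hubs, out$gene_nodes)
    if (length(iso)) {
      out$gene_nodes <- sort(c(out$gene_nodes, iso))
      out$gene_degree <- degree_of(out$edges$gene, out$gene_nodes)
    }
  }
  out
}

#' Rank genes by miRNA in-degree
#'
#' Total order over gene nodes: descending degree, lexicographic
#' tie-break. The top-ranked gene is the network's primary convergence
#' hub — the gene targeted by the most distinct age-associated miRNAs.
#'
#' @param net `bipartite_network`.
#' @return data.frame: `gene`, `degree`, `rank` (empty for an empty
#'   network).
#' @export
hub_genes <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  if (length(net$gene_nodes) == 0L) {
    return(data.frame(gene = character(0), degree = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  d <- net$gene_degree
  ord <- order(-d, names(d))
  data.frame(gene = names(d)[ord], degree = unname(d[ord]),
             rank = seq_along(d), stringsAsFactors = FALSE)
}

#' Convert a bipartite network to an igraph object
#'
#' Node attribute `type` is `FALSE` for miRNAs and `TRUE` for genes
#' (igraph's bipartite convention).
#'
#' @param net `bipartite_network`.
#' @return igraph graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  g <- igraph::graph_from_data_frame(
    net$edges,
    directed = FALSE,
    vertices = data.frame(
      name = c(net$mirna_nodes, net$gene_nodes),
      type = c(rep(FALSE, length(net$mirna_nodes)),
               rep(TRUE, length(net$gene_nodes))),
      stringsAsFactors = FALSE
    )
  )
  g
}

#' Export a bipartite network
#'
#' Writes GraphML (via igraph) plus a node table and an edge table as
#' TSV.
#'
#' @param net `bipartite_network`.
#' @param prefix output path prefix; files `<prefix>.graphml`,
#'   `<prefix>_nodes.tsv`, `<prefix>_edges.tsv` are written.
#' @return invisibly, the vector of written paths.
#' @export
write_network <- function(net, prefix) {
  g <- as_igraph(net)
  paths <- paste0(prefix, c(".graphml", "_nodes.tsv", "_edges.tsv"))
  igraph::write_graph(g, paths[1], format = "graphml")
  nodes <- data.frame(
    node = c(net$mirna_nodes, net$gene_nodes),
    class = c(rep("mirna", length(net$mirna_nodes)),
              rep("gene", length(net$gene_nodes))),
    degree = c(unname(net$mirna_degree), unname(net$gene_degree)),
    stringsAsFactors = FALSE
  )
  utils::write.table(nodes, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$edges, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
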