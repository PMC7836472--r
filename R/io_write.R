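#' Export a network in SIF format
#'
#' Writes Cytoscape's simple interaction format, one edge per line:
#' `nodeA<TAB>relation<TAB>nodeB`. Bipartite ingredient-target networks use
#' the relation `"targets"`; PPI networks use `"interacts"`.
#'
#' @param network A `bipartite_network` or `ppi_network`.
#' @param path Output path.
#' @param relation Relation label; defaults by network class.
#' @return Invisibly, the path.
#' @export
write_sif <- function(network, path, relation = NULL) {
  el <- network_edge_frame(network)
  relation <- relation %||%
    if (inherits(network, "bipartite_network")) "targets" else "interacts"
  lines <- if (nrow(el) == 0) character() else
    paste(el[[1]], relation, el[[2]], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Export a network as a delimited edge list
#'
#' @param network A `bipartite_network` or `ppi_network`.
#' @param path Output path (TSV).
#' @return Invisibly, the path.
#' @export
write_edge_list <- function(network, path) {
  el <- network_edge_frame(network, keep_score = TRUE)
  readr::write_tsv(el, path, progress = FALSE)
  invisible(path)
}

#' Export a network in GraphML format
#'
#' @param network A `bipartite_network` or `ppi_network`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Write an annotation collection in GMT format
#'
#' @param annotation An `annotation_collection`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(annotation, path) {
  lines <- vapply(
    names(annotation$terms),
    function(id) {
      t <- annotation$terms[[id]]
      paste(c(id, t$name, t$genes), collapse = "\t")
    },
    character(1)
  )
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write a gene set as a newline-delimited list
#'
#' @param genes A [gene_set()] or character vector.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as_members(genes), path)
  invisible(path)
}

#' Write the pipeline run report as JSON
#'
#' The report is the machine-readable "funnel": ordered per-stage counts
#' (ingredients, active ingredients, herb targets, disease genes, overlap,
#' network nodes/edges, enriched terms, integrated pathways) plus the exact
#' thresholds used.
#'
#' @param report Named list, typically from [run_pipeline()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

network_edge_frame <- function(network, keep_score = FALSE) {
  if (inherits(network, "bipartite_network")) {
    network$edges[, c("mol_id", "gene")]
  } else if (inherits(network, "ppi_network")) {
    if (keep_score) network$edges[, c("a", "b", "score")] else
      network$edges[, c("a", "b")]
  } else {
    stopf("netpharm_validation_error",
          "expected a bipartite_network or ppi_network")
  }
}
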