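#' Build the ingredient-target bipartite network
#'
#' Restricts the pair table to edges joining an active ingredient to a gene
#' in the therapeutic-target overlap set, and assembles the two-mode graph.
#' Ingredients or genes left without any edge are excluded from the node
#' sets (an ingredient whose every predicted target falls outside the
#' overlap does not appear).
#'
#' @param pairs Deduplicated pair tibble (`mol_id`, `gene`).
#' @param active_ids Active ingredient ids (character vector or the
#'   `retained` tibble of a screen result).
#' @param overlap_genes [gene_set()] (or character vector) of target genes
#'   to keep.
#' @return A `bipartite_network`: list with `ingredients`, `targets`
#'   (character vectors) and `edges` (tibble `mol_id`, `gene`).
#' @export
build_it_network <- function(pairs, active_ids, overlap_genes) {
  if (is.data.frame(active_ids)) active_ids <- active_ids$mol_id
  overlap <- as_members(overlap_genes)
  edges <- pairs |>
    filter(.data$mol_id %in% active_ids, .data$gene %in% overlap) |>
    distinct(.data$mol_id, .data$gene) |>
    arrange(.data$mol_id, .data$gene)
  if (nrow(edges) == 0) {
    stopf("netpharm_validation_error",
          "no ingredient-target edges survive the restriction; the network would be empty")
  }
  structure(
    list(
      ingredients = sort(unique(edges$mol_id)),
      targets = sort(unique(edges$gene)),
      edges = edges
    ),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "<bipartite_network> %d ingredients x %d targets, %d edges\n",
    length(x$ingredients), length(x$targets), nrow(x$edges)
  ))
  invisible(x)
}

#' Node degrees of a bipartite network
#'
#' @param net A `bipartite_network`.
#' @return A tibble `node`, `side` (`"ingredient"`/`"target"`), `degree`.
#'   Degrees on each side sum to the edge count.
#' @export
bipartite_degrees <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  ing <- net$edges |> count(node = .data$mol_id, name = "degree")
  tar <- net$edges |> count(node = .data$gene, name = "degree")
  bind_rows(
    mutate(ing, side = "ingredient"),
    mutate(tar, side = "target")
  ) |>
    select("node", "side", "degree") |>
    arrange(.data$side, desc(.data$degree), .data$node)
}

#' Degree histogram of one side of a centrality table
#'
#' Tabulates how many nodes on the chosen side have each degree (e.g. "14
#' genes had two degrees").
#'
#' @param degrees Tibble from [bipartite_degrees()] (or any tibble with
#'   `side` and `degree` columns).
#' @param side `"target"` or `"ingredient"`.
#' @return Tibble `degree`, `count`, ascending in degree; counts partition
#'   the side's nodes.
#' @export
degree_histogram <- function(degrees, side = c("target", "ingredient")) {
  side <- match.arg(side)
  sub <- degrees[degrees$side == side, ]
  if (nrow(sub) == 0) return(tibble(degree = integer(), count = integer()))
  sub |>
    count(degree = .data$degree, name = "count") |>
    arrange(.data$degree)
}

#' Build the confidence-filtered PPI network
#'
#' Restricts a scored interactome to edges whose both endpoints belong to
#' `member_genes` and whose confidence reaches `min_confidence` (inclusive,
#' mirroring the STRING "minimum required interaction score" convention),
#' then optionally removes proteins left without any interaction.
#'
#' @param edges Scored edge tibble (`a`, `b`, `score` in \[0,1\]) from
#'   [read_scored_edges()].
#' @param member_genes [gene_set()] or character vector of proteins to keep;
#'   `NULL` keeps all.
#' @param min_confidence Minimum combined score, default 0.4.
#' @param drop_isolated Remove degree-0 proteins (default `TRUE`).
#' @return A `ppi_network`: list with `nodes`, `edges`, `min_confidence`.
#'   Empty surviving edge set yields an empty network with a warning.
#' @export
build_ppi_network <- function(edges, member_genes = NULL, min_confidence = 0.4,
                              drop_isolated = TRUE) {
  stopifnot(min_confidence >= 0, min_confidence <= 1)
  if (any(edges$score < 0 | edges$score > 1)) {
    stopf("netpharm_validation_error", "edge scores must lie in [0,1]")
  }
  keep <- edges$score >= min_confidence
  if (!is.null(member_genes)) {
    members <- as_members(member_genes)
    keep <- keep & edges$a %in% members & edges$b %in% members
  }
  kept <- edges[keep, c("a", "b", "score")]
  kept <- arrange(distinct(kept, .data$a, .data$b, .keep_all = TRUE),
                  .data$a, .data$b)
  if (nrow(kept) == 0) {
    warn("no interaction survives the confidence filter; returning an empty network",
         class = "netpharm_warning")
  }
  nodes <- sort(unique(c(kept$a, kept$b)))
  if (!drop_isolated && !is.null(member_genes)) {
    nodes <- sort(unique(c(nodes, as_members(member_genes))))
  }
  structure(
    list(nodes = nodes, edges = kept, min_confidence = min_confidence),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "<ppi_network> %d proteins, %d interactions (confidence >= %g)\n",
    length(x$nodes), nrow(x$edges), x$min_confidence
  ))
  invisible(x)
}

#' Rank proteins by degree
#'
#' Orders the proteins of a PPI network by interaction count, descending,
#' breaking ties alphabetically so the ranking is deterministic.
#'
#' @param net A `ppi_network`.
#' @param top_n Number of leading rows to return (default 30).
#' @return Tibble `gene`, `degree` with `min(top_n, n_nodes)` rows.
#' @export
rank_by_degree <- function(net, top_n = 30) {
  stopifnot(inherits(net, "ppi_network"))
  if (length(net$nodes) == 0) {
    stopf("netpharm_validation_error", "cannot rank an empty network")
  }
  deg <- table(factor(c(net$edges$a, net$edges$b), levels = net$nodes))
  tibble(gene = names(deg), degree = as.integer(deg)) |>
    arrange(desc(.data$degree), .data$gene) |>
    head(top_n)
}

#' Convert a netpharm network to igraph
#'
#' Bipartite networks become a two-mode igraph (vertex attribute `type`);
#' PPI networks an undirected graph with a `score` edge attribute.
#'
#' @param network A `bipartite_network` or `ppi_network`.
#' @return An igraph object.
#' @export
as_igraph <- function(network) {
  if (inherits(network, "bipartite_network")) {
    g <- igraph::graph_from_data_frame(
      network$edges,
      directed = FALSE,
      vertices = data.frame(
        name = c(network$ingredients, network$targets),
        type = c(rep(TRUE, length(network$ingredients)),
                 rep(FALSE, length(network$targets))),
        stringsAsFactors = FALSE
      )
    )
  } else if (inherits(network, "ppi_network")) {
    g <- igraph::graph_from_data_frame(
      network$edges, directed = FALSE,
      vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE)
    )
  } else {
    stopf("netpharm_validation_error",
          "expected a bipartite_network or ppi_network")
  }
  g
}

#' Betweenness centrality
#'
#' Exact shortest-path betweenness on the undirected, unweighted graph. For
#' a two-mode ingredient-target network the metric is computed on the
#' combined graph (both node types together), matching how desktop network
#' tools treat such networks. By default values are unnormalized
#' shortest-path pair counts (each unordered pair counted once); the
#' normalized variant divides by `(n-1)(n-2)/2`.
#'
#' @param network A `bipartite_network`, `ppi_network` or igraph object.
#' @param normalized Report the normalized variant (default `FALSE`).
#' @return Tibble `node`, `betweenness`, sorted descending.
#' @export
betweenness_centrality <- function(network, normalized = FALSE) {
  g <- if (inherits(network, "igraph")) network else as_igraph(network)
  bc <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
  ids <- names(bc) %||% as.character(seq_along(bc))
  tibble(node = ids, betweenness = unname(bc)) |>
    arrange(desc(.data$betweenness), .data$node)
}
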