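#' Default disease-pathway whitelist
#'
#' The eight KEGG pathways retained in the integrated bladder-cancer
#' pathway model: bladder cancer, MAPK, HIF-1, TNF, apoptosis, PI3K-Akt,
#' p53 and NF-kappa B signaling. Used as the default whitelist of
#' [integrate_pathways()]; supply your own for other diseases.
#'
#' @return Named character vector: KEGG pathway id -> display name.
#' @export
bc_pathway_whitelist <- function() {
  c(
    hsa05219 = "Bladder cancer",
    hsa04010 = "MAPK signaling pathway",
    hsa04066 = "HIF-1 signaling pathway",
    hsa04668 = "TNF signaling pathway",
    hsa04210 = "Apoptosis",
    hsa04151 = "PI3K-Akt signaling pathway",
    hsa04115 = "p53 signaling pathway",
    hsa04064 = "NF-kappa B signaling pathway"
  )
}

#' Integrate enriched pathways into a disease pathway model
#'
#' Mimics the manual curation step of a network-pharmacology study: from
#' the significantly enriched pathways, keep those "directly related to the
#' disease" — operationalized as a whitelist of pathway ids or
#' case-insensitive name keywords — and record, for each retained pathway,
#' which therapeutic-target genes it contains. Output order follows the
#' whitelist, making the model deterministic and re-runnable.
#'
#' @param rows Enrichment tibble from [enrich()] run on `annotation`.
#' @param annotation The `annotation_collection` the rows came from.
#' @param overlap [gene_set()] of therapeutic targets (herb-disease
#'   overlap).
#' @param whitelist Character vector of pathway ids or name keywords;
#'   default [bc_pathway_whitelist()]. Entries matching nothing raise a
#'   warning.
#' @return A `pathway_model`: list with `pathways` (tibble `pathway_id`,
#'   `pathway_name`), `membership` (named list of gene vectors) and
#'   `provenance` (the matching enrichment rows).
#' @export
integrate_pathways <- function(rows, annotation, overlap,
                               whitelist = names(bc_pathway_whitelist())) {
  stopifnot(inherits(annotation, "annotation_collection"))
  overlap_members <- as_members(overlap)
  sig <- rows[rows$significant, , drop = FALSE]
  if (length(whitelist) == 0) {
    warn("empty pathway whitelist; the integrated model is empty",
         class = "netpharm_warning")
  }
  matched_ids <- character()
  for (entry in whitelist) {
    hit <- sig$term_id[
      tolower(sig$term_id) == tolower(entry) |
        grepl(tolower(entry), tolower(sig$term_name), fixed = TRUE)
    ]
    if (length(hit) == 0) {
      warn(sprintf("whitelist entry '%s' matched no significant pathway", entry),
           class = "netpharm_warning")
    }
    matched_ids <- c(matched_ids, setdiff(hit, matched_ids))
  }
  prov <- sig[match(matched_ids, sig$term_id), , drop = FALSE]
  membership <- lapply(matched_ids, function(id) {
    sort(intersect(annotation$terms[[id]]$genes, overlap_members))
  })
  names(membership) <- matched_ids
  structure(
    list(
      pathways = tibble(
        pathway_id = matched_ids,
        pathway_name = prov$term_name %||% character()
      ),
      membership = membership,
      provenance = prov
    ),
    class = "pathway_model"
  )
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf("<pathway_model> %d pathways\n", nrow(x$pathways)))
  for (i in seq_len(nrow(x$pathways))) {
    id <- x$pathways$pathway_id[[i]]
    cat(sprintf("  %s %s (%d target genes)\n", id,
                x$pathways$pathway_name[[i]], length(x$membership[[id]])))
  }
  invisible(x)
}

#' Binary gene-by-pathway membership matrix
#'
#' @param model A `pathway_model` from [integrate_pathways()].
#' @return Integer matrix, rows = union of member genes (sorted), columns =
#'   pathways in model order; cell 1 iff the gene belongs to the pathway's
#'   target membership.
#' @export
membership_matrix <- function(model) {
  stopifnot(inherits(model, "pathway_model"))
  if (nrow(model$pathways) == 0) {
    return(matrix(integer(), nrow = 0, ncol = 0))
  }
  genes <- sort(unique(unlist(model$membership, use.names = FALSE)))
  if (length(genes) == 0) {
    return(matrix(integer(), nrow = 0, ncol = nrow(model$pathways),
                  dimnames = list(character(), model$pathways$pathway_id)))
  }
  out <- vapply(
    model$pathways$pathway_id,
    function(id) as.integer(genes %in% model$membership[[id]]),
    integer(length(genes))
  )
  out <- matrix(out, nrow = length(genes),
                dimnames = list(genes, model$pathways$pathway_id))
  out
}

#' Serialize a pathway model to JSON
#'
#' @param model A `pathway_model`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_pathway_model <- function(model, path) {
  jsonlite::write_json(
    list(
      pathways = model$pathways,
      membership = model$membership
    ),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
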