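#' Union of targets over the active ingredients
#'
#' Collects the deduplicated set of genes targeted by any ingredient in
#' `active_ids`, the "herb target" set of a multi-compound preparation.
#' Active ids absent from the pair table are reported with a warning.
#'
#' @param pairs Pair tibble (`mol_id`, `gene`) from [read_pair_table()].
#' @param active_ids Character vector of active ingredient ids (or the
#'   `retained` tibble of a [screen_ingredients()] result).
#' @return A [gene_set()] with source `"herb"`.
#' @export
herb_target_union <- function(pairs, active_ids) {
  if (is.data.frame(active_ids)) active_ids <- active_ids$mol_id
  active_ids <- unique(as.character(active_ids))
  if (length(active_ids) == 0) {
    warn("no active ingredient ids supplied; herb target set is empty",
         class = "netpharm_warning")
    return(gene_set(character(), name = "herb_targets", source = "herb"))
  }
  stray <- setdiff(active_ids, unique(pairs$mol_id))
  if (length(stray) > 0) {
    warn(sprintf("active id(s) absent from the pair table: %s",
                 paste(stray, collapse = ", ")),
         class = "netpharm_warning")
  }
  genes <- pairs$gene[pairs$mol_id %in% active_ids]
  gene_set(genes, name = "herb_targets", source = "herb")
}

#' Merge disease gene sources
#'
#' Unions gene sets from several disease databases (GeneCards-style,
#' OMIM-style, ...) into one disease gene set, retaining per-source
#' cardinalities for the run report.
#'
#' @param sets List of [gene_set()] objects (at least one).
#' @param name Name for the merged set.
#' @return A [gene_set()] with attribute `source_counts`.
#' @export
merge_disease_sources <- function(sets, name = "disease_genes") {
  if (is_gene_set(sets)) sets <- list(sets)
  if (length(sets) == 0) {
    stopf("netpharm_validation_error",
          "at least one disease gene source is required")
  }
  stopifnot(all(vapply(sets, is_gene_set, logical(1))))
  members <- unlist(lapply(sets, `[[`, "members"), use.names = FALSE)
  out <- gene_set(members, name = name, source = "merged")
  counts <- vapply(sets, length, integer(1))
  names(counts) <- vapply(sets, `[[`, character(1), "source")
  attr(out, "source_counts") <- counts
  out
}

#' Intersect herb targets with disease genes
#'
#' The symmetric intersection of the herb target set and the disease gene
#' set: the putative therapeutic targets of the herb in this disease.
#'
#' @param herb,disease [gene_set()] objects (or character vectors).
#' @param name Name for the resulting set.
#' @return A [gene_set()] with source `"overlap"`.
#' @export
intersect_targets <- function(herb, disease, name = "overlap") {
  members <- intersect(as_members(herb), as_members(disease))
  gene_set(members, name = name, source = "overlap")
}

#' Assemble the full target universe
#'
#' Convenience wrapper running [herb_target_union()],
#' [merge_disease_sources()] and [intersect_targets()] in one step.
#'
#' @param pairs Pair tibble.
#' @param active_ids Active ingredient ids.
#' @param disease_sets List of disease [gene_set()]s.
#' @return List with `herb_targets`, `disease_genes`, `overlap`.
#' @export
target_universe <- function(pairs, active_ids, disease_sets) {
  herb <- herb_target_union(pairs, active_ids)
  disease <- merge_disease_sources(disease_sets)
  list(
    herb_targets = herb,
    disease_genes = disease,
    overlap = intersect_targets(herb, disease)
  )
}
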