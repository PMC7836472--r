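#' Pipeline configuration
#'
#' Collects the input paths and thresholds of a full pipeline run. All
#' thresholds default to the conventional values of single-herb network
#' pharmacology studies: OB >= 30%, DL >= 0.18, PPI confidence >= 0.4,
#' raw p <= 0.01, top 20 terms, top 30 proteins.
#'
#' @param ingredients Path to the ingredient table.
#' @param pairs Path to the ingredient-target pair table.
#' @param disease Character vector of disease gene list paths (>= 1).
#' @param ppi_edges Optional path to a scored interactome.
#' @param gmt Optional named character vector of GMT paths; names become
#'   the collection categories.
#' @param out_dir Output directory for every artifact.
#' @param ob_min,dl_min ADME screen thresholds.
#' @param ppi_min_confidence Minimum interaction confidence.
#' @param p_cutoff Raw p-value significance threshold.
#' @param top_terms_n,top_proteins_n Leading-row counts for the report.
#' @param whitelist Pathway whitelist for [integrate_pathways()].
#' @param score_scale Scale of the interactome scores (see
#'   [read_scored_edges()]).
#' @param aliases Optional symbol alias map used by every reader.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(ingredients, pairs, disease, out_dir,
                            ppi_edges = NULL, gmt = NULL,
                            ob_min = 30, dl_min = 0.18,
                            ppi_min_confidence = 0.4, p_cutoff = 0.01,
                            top_terms_n = 20, top_proteins_n = 30,
                            whitelist = names(bc_pathway_whitelist()),
                            score_scale = "auto", aliases = NULL) {
  cfg <- list(
    ingredients = ingredients, pairs = pairs, disease = disease,
    ppi_edges = ppi_edges, gmt = gmt, out_dir = out_dir,
    ob_min = ob_min, dl_min = dl_min,
    ppi_min_confidence = ppi_min_confidence, p_cutoff = p_cutoff,
    top_terms_n = top_terms_n, top_proteins_n = top_proteins_n,
    whitelist = whitelist, score_scale = score_scale, aliases = aliases
  )
  if (cfg$ppi_min_confidence < 0 || cfg$ppi_min_confidence > 1 ||
      cfg$p_cutoff <= 0 || cfg$p_cutoff > 1) {
    stopf("netpharm_validation_error",
          "thresholds outside their documented domains")
  }
  inputs <- c(cfg$ingredients, cfg$pairs, cfg$disease, cfg$ppi_edges,
              unname(cfg$gmt))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    stopf("netpharm_io_error", "input file(s) not found: %s",
          paste(missing, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a key-value YAML file whose keys mirror the arguments of
#' [pipeline_config()]; relative input paths are resolved against the YAML
#' file's directory.
#'
#' @param path Path to the YAML config.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    vapply(p, function(x) {
      if (file.exists(x)) x else file.path(base, x)
    }, character(1))
  }
  raw$ingredients <- unname(resolve(raw$ingredients))
  raw$pairs <- unname(resolve(raw$pairs))
  raw$disease <- unname(resolve(raw$disease))
  raw$ppi_edges <- unname(resolve(raw$ppi_edges))
  if (!is.null(raw$gmt)) raw$gmt <- resolve(raw$gmt)
  if (is.null(raw$out_dir)) raw$out_dir <- file.path(base, "netpharm_out")
  do.call(pipeline_config, raw)
}

#' Run the full inference chain
#'
#' Executes, in order: ADME screen, herb-target union, disease-source
#' merge, target intersection, ingredient-target network build and degree
#' analysis, confidence-filtered PPI build and degree ranking (when an
#' interactome is supplied), per-collection over-representation analysis
#' (when annotations are supplied), and pathway integration. Every
#' intermediate artifact is written under `cfg$out_dir`, and a JSON funnel
#' report records each stage's counts with the exact thresholds used. A
#' stage failure aborts with the stage name; artifacts written so far stay
#' on disk next to a `FAILED` marker naming the stage.
#'
#' @param cfg A `pipeline_config` (or path to a YAML config).
#' @return Invisibly, the report list (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(thresholds = list(
    ob_min = cfg$ob_min, dl_min = cfg$dl_min,
    ppi_min_confidence = cfg$ppi_min_confidence, p_cutoff = cfg$p_cutoff
  ))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      stopf("netpharm_stage_error", "stage '%s' failed: %s", name,
            conditionMessage(e))
    })
  }

  # -- screen ---------------------------------------------------------------
  screen <- stage("screen", {
    ing <- read_ingredient_table(cfg$ingredients)
    res <- screen_ingredients(ing, ob_min = cfg$ob_min, dl_min = cfg$dl_min)
    readr::write_tsv(res$retained, file.path(cfg$out_dir, "retained.tsv"),
                     progress = FALSE)
    res
  })
  report$ingredients <- nrow(screen$retained) + nrow(screen$rejected)
  report$active_ingredients <- nrow(screen$retained)

  # -- targets --------------------------------------------------------------
  targets <- stage("targets", {
    pairs <- read_pair_table(cfg$pairs, aliases = cfg$aliases)
    disease_sets <- lapply(seq_along(cfg$disease), function(i) {
      read_gene_list(cfg$disease[[i]], source = basename(cfg$disease[[i]]),
                     aliases = cfg$aliases)
    })
    tu <- target_universe(pairs, screen$retained$mol_id, disease_sets)
    write_gene_list(tu$herb_targets, file.path(cfg$out_dir, "herb_targets.txt"))
    write_gene_list(tu$disease_genes, file.path(cfg$out_dir, "disease_genes.txt"))
    write_gene_list(tu$overlap, file.path(cfg$out_dir, "overlap.txt"))
    c(tu, list(pairs = pairs))
  })
  report$pair_rows <- pair_report(targets$pairs)$raw_rows
  report$herb_targets <- length(targets$herb_targets)
  report$disease_genes <- length(targets$disease_genes)
  report$overlap_targets <- length(targets$overlap)

  # -- ingredient-target network -------------------------------------------
  itnet <- stage("itnet", {
    net <- build_it_network(targets$pairs, screen$retained$mol_id,
                            targets$overlap)
    write_sif(net, file.path(cfg$out_dir, "it_network.sif"))
    write_graphml(net, file.path(cfg$out_dir, "it_network.graphml"))
    deg <- bipartite_degrees(net)
    readr::write_tsv(deg, file.path(cfg$out_dir, "it_degrees.tsv"),
                     progress = FALSE)
    list(net = net, degrees = deg)
  })
  report$it_ingredient_nodes <- length(itnet$net$ingredients)
  report$it_target_nodes <- length(itnet$net$targets)
  report$it_edges <- nrow(itnet$net$edges)
  ing_deg <- itnet$degrees[itnet$degrees$side == "ingredient", ]
  report$it_degree_leaders <- setNames(
    as.list(head(ing_deg$degree, 3)), head(ing_deg$node, 3)
  )

  # -- PPI ------------------------------------------------------------------
  if (!is.null(cfg$ppi_edges)) {
    ppi <- stage("ppi", {
      edges <- read_scored_edges(cfg$ppi_edges, score_scale = cfg$score_scale,
                                 aliases = cfg$aliases)
      net <- build_ppi_network(edges, targets$overlap,
                               min_confidence = cfg$ppi_min_confidence)
      write_edge_list(net, file.path(cfg$out_dir, "ppi_filtered.tsv"))
      ranking <- rank_by_degree(net, top_n = cfg$top_proteins_n)
      readr::write_tsv(ranking, file.path(cfg$out_dir, "ppi_top_degrees.tsv"),
                       progress = FALSE)
      list(net = net, ranking = ranking)
    })
    report$ppi_nodes <- length(ppi$net$nodes)
    report$ppi_edges <- nrow(ppi$net$edges)
    report$ppi_top_degrees <- setNames(
      as.list(head(ppi$ranking$degree, 5)), head(ppi$ranking$gene, 5)
    )
  }

  # -- enrichment -----------------------------------------------------------
  enrichments <- list()
  if (!is.null(cfg$gmt)) {
    cats <- names(cfg$gmt) %||% basename(unname(cfg$gmt))
    enrichments <- stage("enrich", {
      out <- list()
      for (i in seq_along(cfg$gmt)) {
        annot <- read_gmt(cfg$gmt[[i]], category = cats[[i]],
                          aliases = cfg$aliases)
        rows <- enrich(targets$overlap, annot, p_cutoff = cfg$p_cutoff)
        readr::write_tsv(
          select(rows, -"genes"),
          file.path(cfg$out_dir, sprintf("enrichment_%s.tsv",
                                         gsub("[^A-Za-z0-9]+", "_", cats[[i]]))),
          progress = FALSE
        )
        out[[cats[[i]]]] <- list(annotation = annot, rows = rows)
      }
      out
    })
    report$significant_terms <- lapply(enrichments,
                                       function(e) sum(e$rows$significant))
  }

  # -- pathway integration --------------------------------------------------
  if (length(enrichments) > 0) {
    model <- stage("integrate", {
      last <- enrichments[[length(enrichments)]]
      m <- suppressWarnings(integrate_pathways(
        last$rows, last$annotation, targets$overlap, whitelist = cfg$whitelist
      ))
      write_pathway_model(m, file.path(cfg$out_dir, "pathway_model.json"))
      m
    })
    report$integrated_pathways <- nrow(model$pathways)
  }

  write_report(report, file.path(cfg$out_dir, "report.json"))
  invisible(report)
}
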