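#' Simulation configuration for synthetic pipeline inputs
#'
#' Bundles every knob of the synthetic-data generators with validation and
#' a master seed. Each generator derives its own sub-seed from the master
#' seed, so stages are reproducible in isolation, and an identical config
#' always yields byte-identical outputs.
#'
#' Defaults emulate the empirical shape of a single-herb network
#' pharmacology study: 39 screened components of which a ~7/39 fraction
#' passes the OB/DL screen, one near-universal hub ingredient covering the
#' whole 84-gene target universe (quercetin-like), a disease gene list of
#' 7,624 symbols overlapping ~92% of the herb targets, a dense scored
#' interactome with a planted degree-52 hub protein, and an 89-term
#' annotation collection with one planted over-represented term.
#'
#' @param seed Master integer seed.
#' @param n_ingredients Number of ingredient records.
#' @param active_fraction Expected fraction passing the default screen.
#' @param ob_meanlog,ob_sdlog Lognormal parameters of OB (percent scale,
#'   truncated at 100).
#' @param dl_shape1,dl_shape2 Beta parameters of DL.
#' @param n_target_universe Size of the herb target universe.
#' @param hub_fraction Fraction of targets hit by the planted hub
#'   ingredient (default 1).
#' @param other_degree_range Integer range of non-hub ingredient degrees.
#' @param n_disease_genes Disease gene list size.
#' @param overlap_fraction Fraction of herb targets shared with the disease
#'   list.
#' @param ppi_edge_prob Background edge probability of the interactome.
#' @param planted_hub_gene_degree Degree of the planted hub protein (all
#'   its edges score at least 0.4).
#' @param n_terms Number of annotation terms.
#' @param term_size_range Integer range of term sizes.
#' @param planted_term_size Size of the planted over-represented term.
#' @param planted_term_overlap Genes shared between the planted term and
#'   the designated query.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_ingredients = 39,
                       active_fraction = 7 / 39,
                       ob_meanlog = log(25), ob_sdlog = 0.6,
                       dl_shape1 = 1.5, dl_shape2 = 3,
                       n_target_universe = 84,
                       hub_fraction = 1.0,
                       other_degree_range = c(1L, 11L),
                       n_disease_genes = 7624,
                       overlap_fraction = 77 / 84,
                       ppi_edge_prob = 0.4,
                       planted_hub_gene_degree = 52,
                       n_terms = 89,
                       term_size_range = c(10L, 80L),
                       planted_term_size = 80,
                       planted_term_overlap = 40) {
  cfg <- list(
    seed = as.integer(seed), n_ingredients = n_ingredients,
    active_fraction = active_fraction,
    ob_meanlog = ob_meanlog, ob_sdlog = ob_sdlog,
    dl_shape1 = dl_shape1, dl_shape2 = dl_shape2,
    n_target_universe = n_target_universe, hub_fraction = hub_fraction,
    other_degree_range = as.integer(other_degree_range),
    n_disease_genes = n_disease_genes, overlap_fraction = overlap_fraction,
    ppi_edge_prob = ppi_edge_prob,
    planted_hub_gene_degree = planted_hub_gene_degree,
    n_terms = n_terms, term_size_range = as.integer(term_size_range),
    planted_term_size = planted_term_size,
    planted_term_overlap = planted_term_overlap
  )
  fracs <- c(cfg$active_fraction, cfg$hub_fraction, cfg$overlap_fraction,
             cfg$ppi_edge_prob)
  if (any(fracs < 0 | fracs > 1)) {
    stopf("netpharm_validation_error", "all fractions must lie in [0,1]")
  }
  counts <- c(cfg$n_ingredients, cfg$n_target_universe, cfg$n_disease_genes,
              cfg$n_terms)
  if (any(counts < 1)) {
    stopf("netpharm_validation_error", "all counts must be positive")
  }
  if (cfg$planted_term_overlap > cfg$planted_term_size) {
    stopf("netpharm_validation_error",
          "planted_term_overlap cannot exceed planted_term_size")
  }
  structure(cfg, class = "sim_config")
}

# uniform integer draw safe for single-value ranges
runif_int <- function(n, lo, hi) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# truncated draws via inverse-CDF
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  plo <- plnorm(lo, meanlog, sdlog)
  phi <- plnorm(hi, meanlog, sdlog)
  qlnorm(runif(n, plo, phi), meanlog, sdlog)
}

rbeta_trunc <- function(n, s1, s2, lo, hi) {
  plo <- pbeta(lo, s1, s2)
  phi <- pbeta(hi, s1, s2)
  qbeta(runif(n, plo, phi), s1, s2)
}

#' Generate a synthetic ingredient table
#'
#' Draws `n_ingredients` records whose OB (truncated lognormal on 0-100)
#' and DL (Beta on \[0,1\]) are sampled conditionally on a per-record
#' Bernoulli(active_fraction) "druggable" flag, so the expected pass-rate
#' of the default OB >= 30 / DL >= 0.18 screen equals `active_fraction`
#' exactly while keeping the marginal distribution families.
#'
#' @param cfg A [sim_config()].
#' @return Ingredient tibble (`mol_id`, `name`, `mw`, `ob`, `dl`, `part`).
#' @export
gen_ingredients <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, 11L), {
    n <- cfg$n_ingredients
    active <- runif(n) < cfg$active_fraction
    ob <- numeric(n)
    dl <- numeric(n)
    n_act <- sum(active)
    # pass region: OB in [30,100] and DL in [0.18,1]
    ob[active] <- rlnorm_trunc(n_act, cfg$ob_meanlog, cfg$ob_sdlog, 30, 100)
    dl[active] <- rbeta_trunc(n_act, cfg$dl_shape1, cfg$dl_shape2, 0.18, 1)
    # fail region: rejection-sample the complement of the pass region
    idx <- which(!active)
    while (length(idx) > 0) {
      ob[idx] <- pmin(rlnorm_trunc(length(idx), cfg$ob_meanlog, cfg$ob_sdlog,
                                   0, 100), 100)
      dl[idx] <- rbeta_trunc(length(idx), cfg$dl_shape1, cfg$dl_shape2, 0, 1)
      idx <- idx[ob[idx] >= 30 & dl[idx] >= 0.18]
    }
    tibble(
      mol_id = sprintf("SIM%05d", seq_len(n)),
      name = sprintf("simulated compound %d", seq_len(n)),
      mw = round(stats::rlnorm(n, log(350), 0.3), 2),
      ob = round(ob, 2),
      dl = round(dl, 2),
      part = sample(c("leaves", "stems", "fruits", "roots"), n, replace = TRUE)
    )
  })
}

sim_gene_symbols <- function(n, prefix = "GEN") {
  sprintf("%s%05d", prefix, seq_len(n))
}

#' Generate a synthetic ingredient-target pair table
#'
#' Emulates the heavy-tailed, hub-dominated shape of herb target maps: one
#' designated hub ingredient (the first active id) is linked to
#' `ceiling(hub_fraction * n_target_universe)` targets; every other active
#' ingredient receives a degree drawn uniformly from
#' `other_degree_range`, sampling its targets from the universe so genes
#' shared by several ingredients (degree >= 2) arise.
#'
#' @param cfg A [sim_config()].
#' @param active_ids Character vector of active ingredient ids (>= 1).
#' @return Pair tibble (`mol_id`, `gene`), deduplicated.
#' @export
gen_target_map <- function(cfg, active_ids) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(active_ids) < 1) {
    stopf("netpharm_validation_error", "at least one active id is required")
  }
  with_seed(derive_seed(cfg$seed, 23L), {
    targets <- sim_gene_symbols(cfg$n_target_universe)
    hub <- active_ids[[1]]
    hub_deg <- ceiling(cfg$hub_fraction * cfg$n_target_universe)
    rows <- list(tibble(mol_id = hub, gene = targets[seq_len(hub_deg)]))
    for (id in setdiff(active_ids, hub)) {
      d <- runif_int(1, cfg$other_degree_range[1], cfg$other_degree_range[2])
      d <- min(d, length(targets))
      rows[[length(rows) + 1]] <- tibble(
        mol_id = id, gene = sample(targets, d)
      )
    }
    distinct(bind_rows(rows), .data$mol_id, .data$gene)
  })
}

#' Generate a synthetic disease gene list
#'
#' Builds a disease gene set of size `n_disease_genes` sharing exactly
#' `ceiling(overlap_fraction * |herb_targets|)` symbols with the herb
#' target set; the remainder are novel disease-only symbols.
#'
#' @param cfg A [sim_config()].
#' @param herb_targets [gene_set()] or character vector of herb targets.
#' @return A [gene_set()] with source `"simulated"`.
#' @export
gen_disease_genes <- function(cfg, herb_targets) {
  stopifnot(inherits(cfg, "sim_config"))
  herb <- as_members(herb_targets)
  with_seed(derive_seed(cfg$seed, 37L), {
    n_shared <- ceiling(cfg$overlap_fraction * length(herb))
    shared <- if (n_shared > 0) sample(herb, n_shared) else character()
    n_novel <- max(0, cfg$n_disease_genes - n_shared)
    novel <- sim_gene_symbols(n_novel, prefix = "DIS")
    gene_set(c(shared, novel), name = "simulated_disease", source = "simulated")
  })
}

#' Generate a synthetic scored interactome
#'
#' An Erdos-Renyi interactome over the supplied genes (edge probability
#' `ppi_edge_prob`, scores uniform on \[0,1\]) with one planted hub: the
#' first gene is wired to `planted_hub_gene_degree` partners with scores
#' drawn from \[0.4, 1\], so the hub survives the default confidence filter
#' with its full planted degree.
#'
#' @param cfg A [sim_config()].
#' @param genes Character vector or [gene_set()] of proteins.
#' @return Scored edge tibble (`a`, `b`, `score`).
#' @export
gen_ppi <- function(cfg, genes) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- as_members(genes)
  n <- length(genes)
  if (cfg$planted_hub_gene_degree > n - 1) {
    stopf("netpharm_validation_error",
          "planted hub degree %d exceeds the %d available partners",
          cfg$planted_hub_gene_degree, n - 1)
  }
  with_seed(derive_seed(cfg$seed, 53L), {
    hub <- genes[[1]]
    partners <- sample(genes[-1], cfg$planted_hub_gene_degree)
    hub_edges <- tibble(
      a = pmin(hub, partners), b = pmax(hub, partners),
      score = round(runif(length(partners), 0.4, 1), 3)
    )
    others <- setdiff(genes, hub)
    pairs <- utils::combn(others, 2)
    take <- runif(ncol(pairs)) < cfg$ppi_edge_prob
    bg_edges <- tibble(
      a = pmin(pairs[1, take], pairs[2, take]),
      b = pmax(pairs[1, take], pairs[2, take]),
      score = round(runif(sum(take)), 3)
    )
    arrange(bind_rows(hub_edges, bg_edges), .data$a, .data$b)
  })
}

#' Generate a synthetic annotation collection
#'
#' Draws `n_terms` gene-set terms from the background with sizes uniform in
#' `term_size_range`. When a `query` is supplied, one additional planted
#' term of `planted_term_size` genes shares exactly
#' `planted_term_overlap` genes with the query, giving a known
#' over-represented term for recovery tests.
#'
#' @param cfg A [sim_config()].
#' @param background Character vector or [gene_set()] of background genes.
#' @param query Optional character vector/[gene_set()]; enables the planted
#'   term (id `"SIM:PLANTED"`).
#' @return An `annotation_collection` with category `"SIM"`.
#' @export
gen_annotation <- function(cfg, background, query = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  bg <- as_members(background)
  with_seed(derive_seed(cfg$seed, 71L), {
    terms <- list()
    sizes <- runif_int(cfg$n_terms, cfg$term_size_range[1],
                       cfg$term_size_range[2])
    sizes <- pmin(sizes, length(bg))
    for (i in seq_len(cfg$n_terms)) {
      terms[[sprintf("SIM:%04d", i)]] <- list(
        name = sprintf("simulated term %d", i),
        genes = sort(sample(bg, sizes[[i]]))
      )
    }
    if (!is.null(query)) {
      q <- intersect(as_members(query), bg)
      n_in <- min(cfg$planted_term_overlap, length(q))
      n_out <- min(cfg$planted_term_size - n_in, length(setdiff(bg, q)))
      planted <- c(sample(q, n_in), sample(setdiff(bg, q), n_out))
      terms[["SIM:PLANTED"]] <- list(
        name = "planted over-represented term",
        genes = sort(planted)
      )
    }
    annotation_collection(terms, category = "SIM")
  })
}

#' Generate and write a complete synthetic input bundle
#'
#' Runs every generator in dependency order and writes each artifact in the
#' format the pipeline readers consume: ingredient TSV, pair TSV, disease
#' gene list, scored edge TSV, annotation GMT and a config echo
#' (`sim_config.yaml`).
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the written paths.
#' @export
gen_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ing <- gen_ingredients(cfg)
  active <- screen_ingredients(ing)$retained$mol_id
  # the planted structures need at least one active ingredient
  if (length(active) == 0) active <- ing$mol_id[[1]]
  pairs <- gen_target_map(cfg, active)
  herb <- herb_target_union(pairs, active)
  disease <- gen_disease_genes(cfg, herb)
  overlap <- intersect_targets(herb, disease)
  ppi_genes <- if (length(overlap) >= 3) overlap$members else herb$members
  cfg_ppi <- cfg
  cfg_ppi$planted_hub_gene_degree <-
    min(cfg$planted_hub_gene_degree, length(ppi_genes) - 1)
  ppi <- gen_ppi(cfg_ppi, ppi_genes)
  annot <- gen_annotation(cfg, background = disease$members,
                          query = overlap$members)
  paths <- list(
    ingredients = file.path(dir, "ingredients.tsv"),
    pairs = file.path(dir, "pairs.tsv"),
    disease = file.path(dir, "disease_genes.txt"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    gmt = file.path(dir, "annotation.gmt"),
    config = file.path(dir, "sim_config.yaml")
  )
  readr::write_tsv(ing, paths$ingredients, progress = FALSE)
  readr::write_tsv(pairs, paths$pairs, progress = FALSE)
  write_gene_list(disease, paths$disease)
  readr::write_tsv(
    setNames(ppi, c("protein1", "protein2", "combined_score")),
    paths$ppi, progress = FALSE
  )
  write_gmt(annot, paths$gmt)
  yaml::write_yaml(unclass(cfg), paths$config)
  invisible(paths)
}
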