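test_that("identical configs reproduce identical artifacts; seeds differ", {
  cfg <- sim_config(seed = 123, n_disease_genes = 200)
  expect_identical(gen_ingredients(cfg), gen_ingredients(cfg))
  ing <- gen_ingredients(cfg)
  pairs <- gen_target_map(cfg, ing$mol_id[1:5])
  expect_identical(pairs, gen_target_map(cfg, ing$mol_id[1:5]))
  other <- sim_config(seed = 124, n_disease_genes = 200)
  expect_false(identical(gen_ingredients(other), ing))
  d1 <- tempfile(); d2 <- tempfile()
  gen_bundle(cfg, d1); gen_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("screen pass-rate tracks active_fraction within binomial bounds", {
  # pooled over seeds: retained ~ Binomial(n_total, 7/39)
  retained <- 0
  n_per <- 39
  seeds <- 1:40
  for (s in seeds) {
    cfg <- sim_config(seed = s)
    retained <- retained + nrow(screen_ingredients(gen_ingredients(cfg))$retained)
  }
  n_total <- n_per * length(seeds)
  bounds <- qbinom(c(0.005, 0.995), n_total, 7 / 39)
  expect_gte(retained, bounds[1])
  expect_lte(retained, bounds[2])
  none <- sim_config(seed = 2, active_fraction = 0)
  expect_equal(nrow(screen_ingredients(gen_ingredients(none))$retained), 0)
})

test_that("target map plants a full-coverage hub and shared targets", {
  cfg <- sim_config(seed = 9, n_target_universe = 60)
  pairs <- gen_target_map(cfg, c("hub", "i2", "i3", "i4"))
  deg <- table(pairs$mol_id)
  expect_equal(unname(deg[["hub"]]), 60) # hub_fraction = 1
  expect_true(all(deg[c("i2", "i3", "i4")] >= cfg$other_degree_range[1]))
  expect_true(all(deg[c("i2", "i3", "i4")] <= cfg$other_degree_range[2]))
  # bipartite conservation on the generated map
  net <- build_it_network(pairs, c("hub", "i2", "i3", "i4"),
                          gene_set(unique(pairs$gene)))
  d <- bipartite_degrees(net)
  expect_equal(sum(d$degree[d$side == "ingredient"]), nrow(net$edges))
  expect_equal(sum(d$degree[d$side == "target"]), nrow(net$edges))
  # sharing: with a full hub, every other ingredient's target has degree >= 2
  hist <- degree_histogram(d, "target")
  expect_true(any(hist$degree >= 2))
  half <- sim_config(seed = 9, n_target_universe = 60, hub_fraction = 0.5)
  hp <- gen_target_map(half, c("hub", "i2"))
  expect_equal(sum(hp$mol_id == "hub"), 30)
})

test_that("disease list hits the configured overlap exactly", {
  herb <- gene_set(sprintf("H%03d", 1:50))
  cfg <- sim_config(seed = 4, n_disease_genes = 120, overlap_fraction = 0.6)
  dis <- gen_disease_genes(cfg, herb)
  expect_equal(length(dis), 120)
  expect_equal(length(intersect_targets(herb, dis)), ceiling(0.6 * 50))
  full <- gen_disease_genes(
    sim_config(seed = 4, n_disease_genes = 120, overlap_fraction = 1), herb
  )
  expect_true(all(herb$members %in% full$members))
  none <- gen_disease_genes(
    sim_config(seed = 4, n_disease_genes = 120, overlap_fraction = 0), herb
  )
  expect_equal(length(intersect_targets(herb, none)), 0)
})

test_that("interactome generator plants a dominant hub with filter-proof scores", {
  genes <- sprintf("P%03d", 1:50)
  cfg <- sim_config(seed = 77, planted_hub_gene_degree = 30,
                    ppi_edge_prob = 0.15)
  edges <- gen_ppi(cfg, genes)
  net <- build_ppi_network(edges, min_confidence = 0.4)
  expect_equal(rank_by_degree(net)$gene[[1]], "P001")
  expect_equal(rank_by_degree(net)$degree[[1]], 30)
  only_hub <- gen_ppi(sim_config(seed = 77, planted_hub_gene_degree = 10,
                                 ppi_edge_prob = 0), genes)
  expect_equal(nrow(only_hub), 10)
  expect_true(all(only_hub$a == "P001" | only_hub$b == "P001"))
  expect_error(
    gen_ppi(sim_config(seed = 1, planted_hub_gene_degree = 60), genes),
    class = "netpharm_validation_error"
  )
})

test_that("interactome edge count concentrates around its binomial mean", {
  genes <- sprintf("P%03d", 1:40)
  p <- 0.2
  counts <- vapply(1:30, function(s) {
    cfg <- sim_config(seed = s, planted_hub_gene_degree = 0, ppi_edge_prob = p)
    nrow(gen_ppi(cfg, genes))
  }, numeric(1))
  m <- choose(39, 2) * p # hub excluded from the background graph
  sd3 <- 3 * sqrt(choose(39, 2) * p * (1 - p) / 30)
  expect_lt(abs(mean(counts) - m), sd3)
})

test_that("annotation generator respects sizes and plants a recoverable term", {
  withr::local_seed(61)
  bg <- sprintf("B%04d", 1:500)
  query <- sample(bg, 60)
  cfg <- sim_config(seed = 6, n_terms = 30, term_size_range = c(5, 25),
                    planted_term_size = 40, planted_term_overlap = 30)
  annot <- gen_annotation(cfg, bg, query = query)
  sizes <- lengths(lapply(annot$terms, `[[`, "genes"))
  null_sizes <- sizes[names(sizes) != "SIM:PLANTED"]
  expect_true(all(null_sizes >= 5 & null_sizes <= 25))
  rows <- enrich(gene_set(query), annot, background = bg)
  expect_equal(rows$term_id[[1]], "SIM:PLANTED")
  expect_equal(rows$k[rows$term_id == "SIM:PLANTED"], 30)
})

test_that("every generated artifact passes its reader cleanly", {
  cfg <- sim_config(seed = 31, n_disease_genes = 150,
                    n_target_universe = 40, planted_hub_gene_degree = 15)
  dir <- tempfile()
  paths <- gen_bundle(cfg, dir)
  expect_no_warning(ing <- read_ingredient_table(paths$ingredients))
  expect_equal(nrow(ing), 39)
  expect_no_warning(pairs <- read_pair_table(paths$pairs))
  expect_no_warning(dis <- read_gene_list(paths$disease))
  expect_equal(length(dis), 150)
  expect_no_warning(edges <- read_scored_edges(paths$ppi, "unit"))
  expect_true(all(edges$score >= 0 & edges$score <= 1))
  expect_no_warning(annot <- read_gmt(paths$gmt))
  expect_gt(length(annot$terms), 0)
})
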