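test_that("bipartite build restricts edges to active ingredients and overlap genes", {
  pairs <- tibble::tibble(
    mol_id = c("i1", "i1", "i2", "i3"),
    gene = c("A", "B", "B", "C")
  )
  net <- build_it_network(pairs, c("i1", "i2"), gene_set(c("A", "B")))
  expect_equal(net$ingredients, c("i1", "i2"))
  expect_equal(net$targets, c("A", "B"))
  expect_equal(nrow(net$edges), 3)
  single <- build_it_network(tibble::tibble(mol_id = "i", gene = "G"),
                             "i", gene_set("G"))
  expect_equal(length(single$ingredients) + length(single$targets), 2)
  expect_error(build_it_network(pairs, "i3", gene_set("A")),
               class = "netpharm_validation_error")
})

test_that("restricted edge count matches a brute-force filter oracle", {
  withr::local_seed(11)
  for (rep in 1:25) {
    pairs <- dplyr::distinct(tibble::tibble(
      mol_id = sample(paste0("i", 1:5), 30, replace = TRUE),
      gene = sample(LETTERS[1:12], 30, replace = TRUE)
    ))
    active <- sample(paste0("i", 1:5), 3)
    overlap <- sample(LETTERS[1:12], 6)
    want <- sum(pairs$mol_id %in% active & pairs$gene %in% overlap)
    if (want == 0) next
    net <- build_it_network(pairs, active, gene_set(overlap))
    expect_equal(nrow(net$edges), want)
  }
})

test_that("degrees sum to the edge count on both sides and histogram partitions nodes", {
  pairs <- tibble::tibble(
    mol_id = c("c", "c", "c", "c", "c"),
    gene = paste0("T", 1:5)
  )
  net <- build_it_network(pairs, "c", gene_set(paste0("T", 1:5)))
  deg <- bipartite_degrees(net)
  expect_equal(deg$degree[deg$node == "c"], 5)
  expect_true(all(deg$degree[deg$side == "target"] == 1))
  expect_equal(sum(deg$degree[deg$side == "ingredient"]), nrow(net$edges))
  expect_equal(sum(deg$degree[deg$side == "target"]), nrow(net$edges))
  hist <- degree_histogram(deg, "target")
  expect_equal(sum(hist$count), length(net$targets))
  expect_equal(degree_histogram(deg[0, ], "target"),
               tibble::tibble(degree = integer(), count = integer()))
})

test_that("betweenness matches hand-derived values on canonical graphs", {
  path3 <- matrix(0L, 3, 3); path3[1, 2] <- path3[2, 3] <- 1L
  path3[lower.tri(path3)] <- t(path3)[lower.tri(path3)]
  bc <- betweenness_centrality(adj_to_graph(path3))
  expect_equal(bc$betweenness[bc$node == "2"], 1)
  expect_equal(sort(bc$betweenness), c(0, 0, 1))
  star <- matrix(0L, 4, 4); star[1, 2:4] <- 1L
  star[lower.tri(star)] <- t(star)[lower.tri(star)]
  bs <- betweenness_centrality(adj_to_graph(star))
  expect_equal(bs$betweenness[bs$node == "1"], 3) # choose(3, 2) leaf pairs
  expect_true(all(bs$betweenness[bs$node != "1"] == 0))
})

test_that("betweenness equals the all-pairs shortest-path enumeration oracle", {
  # exhaustive over every labelled graph on 4 nodes
  pairs4 <- which(upper.tri(matrix(0, 4, 4)))
  for (mask in 0:(2^6 - 1)) {
    adj <- matrix(0L, 4, 4)
    adj[pairs4] <- as.integer(bitwAnd(mask, 2^(0:5)) > 0)
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    got <- betweenness_centrality(adj_to_graph(adj))
    got <- got$betweenness[order(as.integer(got$node))]
    expect_equal(got, brute_betweenness(adj), tolerance = 1e-10)
  }
  # seeded random graphs on 5-8 nodes
  withr::local_seed(7)
  for (rep in 1:40) {
    n <- sample(5:8, 1)
    adj <- random_adj(n, runif(1, 0.2, 0.7))
    got <- betweenness_centrality(adj_to_graph(adj))
    got <- got$betweenness[order(as.integer(got$node))]
    expect_equal(got, brute_betweenness(adj), tolerance = 1e-10)
  }
})

test_that("tree leaves have zero betweenness", {
  withr::local_seed(3)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    g <- igraph::sample_tree(n)
    igraph::V(g)$name <- as.character(seq_len(n))
    bc <- betweenness_centrality(g)
    leaves <- as.character(which(igraph::degree(g) == 1))
    expect_true(all(bc$betweenness[bc$node %in% leaves] == 0))
  }
})

test_that("PPI build filters by confidence inclusively and drops isolated nodes", {
  edges <- tibble::tibble(
    a = c("A", "A", "B", "D"),
    b = c("B", "C", "C", "E"),
    score = c(0.39, 0.40, 0.95, 0.2)
  )
  net <- build_ppi_network(edges, min_confidence = 0.4)
  expect_equal(nrow(net$edges), 2)
  expect_true(all(net$edges$score >= 0.4))
  expect_false("D" %in% net$nodes) # every edge below cutoff
  expect_true(all(c("A", "B", "C") %in% net$nodes))
  expect_warning(empty <- build_ppi_network(edges, min_confidence = 0.99),
                 class = "netpharm_warning")
  expect_equal(length(empty$nodes), 0)
})

test_that("confidence thresholds are monotone: higher cutoff keeps a subset", {
  withr::local_seed(21)
  edges <- tibble::tibble(
    a = sprintf("G%02d", sample(1:30, 200, replace = TRUE)),
    b = sprintf("G%02d", sample(31:60, 200, replace = TRUE)),
    score = round(runif(200), 3)
  )
  edges <- dplyr::distinct(edges, a, b, .keep_all = TRUE)
  cutoffs <- c(0.0, 0.4, 0.7, 0.9)
  nets <- lapply(cutoffs, function(cc) {
    suppressWarnings(build_ppi_network(edges, min_confidence = cc))
  })
  for (i in seq_len(length(cutoffs) - 1)) {
    lo <- paste(nets[[i]]$edges$a, nets[[i]]$edges$b)
    hi <- paste(nets[[i + 1]]$edges$a, nets[[i + 1]]$edges$b)
    expect_true(all(hi %in% lo))
  }
})

test_that("degree ranking is deterministic, tie-broken alphabetically, and a permutation", {
  single <- build_ppi_network(
    tibble::tibble(a = "A", b = "B", score = 0.9), min_confidence = 0.4
  )
  rk <- rank_by_degree(single)
  expect_equal(rk$gene, c("A", "B")) # tie broken alphabetically
  expect_equal(rk$degree, c(1L, 1L))
  cfg <- sim_config(seed = 5, planted_hub_gene_degree = 15, ppi_edge_prob = 0.1)
  genes <- sprintf("G%03d", 1:40)
  net <- build_ppi_network(gen_ppi(cfg, genes), min_confidence = 0.4)
  rk <- rank_by_degree(net, top_n = 100)
  expect_equal(rk$gene[[1]], "G001") # planted hub first
  expect_equal(anyDuplicated(rk$gene), 0)
  expect_equal(nrow(rk), length(net$nodes)) # top_n larger than node count
  deg <- table(c(net$edges$a, net$edges$b))
  expect_equal(rk$degree, as.integer(deg[rk$gene]))
})
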