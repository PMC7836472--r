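make_pathway_inputs <- function() {
  bg <- sprintf("G%03d", 1:300)
  overlap <- bg[1:40]
  terms <- list(
    hsa05219 = list(name = "Bladder cancer", genes = bg[1:20]),
    hsa04010 = list(name = "MAPK signaling pathway", genes = bg[10:40]),
    hsa99999 = list(name = "Ribosome", genes = bg[200:260]),
    hsa04066 = list(name = "HIF-1 signaling pathway", genes = bg[5:25])
  )
  annot <- annotation_collection(terms, category = "KEGG")
  rows <- enrich(gene_set(overlap), annot, background = bg, p_cutoff = 0.05)
  list(annot = annot, rows = rows, overlap = gene_set(overlap), bg = bg)
}

test_that("integration keeps whitelisted significant pathways in whitelist order", {
  x <- make_pathway_inputs()
  model <- integrate_pathways(x$rows, x$annot, x$overlap,
                              whitelist = c("hsa04010", "hsa05219"))
  expect_equal(model$pathways$pathway_id, c("hsa04010", "hsa05219"))
  expect_true(all(model$provenance$significant))
  # name-keyword matching, case-insensitive
  byname <- integrate_pathways(x$rows, x$annot, x$overlap,
                               whitelist = c("mapk"))
  expect_equal(byname$pathways$pathway_id, "hsa04010")
  expect_warning(
    integrate_pathways(x$rows, x$annot, x$overlap, whitelist = "hsa00000"),
    class = "netpharm_warning"
  )
  expect_warning(
    empty <- integrate_pathways(x$rows, x$annot, x$overlap,
                                whitelist = character()),
    class = "netpharm_warning"
  )
  expect_equal(nrow(empty$pathways), 0)
})

test_that("membership equals brute-force intersection and integration is idempotent", {
  x <- make_pathway_inputs()
  wl <- c("hsa05219", "hsa04010", "hsa04066")
  model <- integrate_pathways(x$rows, x$annot, x$overlap, whitelist = wl)
  for (id in model$pathways$pathway_id) {
    expect_equal(model$membership[[id]],
                 sort(intersect(x$annot$terms[[id]]$genes, x$overlap$members)))
    expect_true(all(model$membership[[id]] %in% x$overlap$members))
  }
  again <- integrate_pathways(x$rows, x$annot, x$overlap, whitelist = wl)
  expect_identical(model$pathways, again$pathways)
  expect_identical(model$membership, again$membership)
})

test_that("membership matrix is binary with faithful marginals", {
  x <- make_pathway_inputs()
  model <- integrate_pathways(x$rows, x$annot, x$overlap,
                              whitelist = c("hsa05219", "hsa04010", "hsa04066"))
  m <- membership_matrix(model)
  expect_true(all(m %in% c(0L, 1L)))
  expect_equal(sum(m), sum(lengths(model$membership)))
  expect_equal(unname(colSums(m)), unname(lengths(model$membership)))
  # a gene in two pathways has row sum 2
  two <- intersect(model$membership$hsa05219, model$membership$hsa04010)
  if (length(two) > 0) expect_true(all(rowSums(m)[two] >= 2))
  tiny <- integrate_pathways(x$rows, x$annot, gene_set(x$bg[1:2]),
                             whitelist = "hsa05219")
  mt <- membership_matrix(tiny)
  expect_equal(dim(mt), c(2L, 1L))
  expect_true(all(mt == 1L))
})
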