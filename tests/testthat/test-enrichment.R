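test_that("hypergeometric tail matches closed-form anchors", {
  expect_equal(hypergeom_sf(5, K = 5, n = 5, N = 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_sf(0, K = 3, n = 4, N = 20), 1)
  expect_equal(hypergeom_sf(2, K = 2, n = 2, N = 4), 1 / choose(4, 2),
               tolerance = 1e-12)
  expect_error(hypergeom_sf(6, K = 5, n = 5, N = 10),
               class = "netpharm_validation_error")
  expect_error(hypergeom_sf(1, K = 5, n = 11, N = 10),
               class = "netpharm_validation_error")
})

test_that("hypergeometric tail equals draw enumeration for every small case", {
  for (N in 2:9) {
    for (n in 1:N) {
      for (K in 1:N) {
        want <- enum_hypergeom_tail(K, n, N)
        got <- hypergeom_sf(0:min(n, K), K = K, n = n, N = N)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("hypergeometric tail is non-increasing in k and agrees with phyper", {
  withr::local_seed(8)
  for (rep in 1:50) {
    N <- sample(20:2000, 1)
    n <- sample(1:N, 1)
    K <- sample(1:N, 1)
    ks <- 0:min(n, K)
    if (length(ks) > 25) ks <- sort(sample(ks, 25))
    got <- hypergeom_sf(ks, K = K, n = n, N = N)
    expect_true(all(diff(got) <= 1e-12))
    want <- phyper(ks - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the hand-stepped oracle and p.adjust", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 0)), class = "netpharm_validation_error")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "netpharm_validation_error")
  withr::local_seed(15)
  for (rep in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    p <- pmax(p, 1e-12)
    got <- bh_fdr(p)
    expect_equal(got, naive_bh(p), tolerance = 1e-12)
    expect_equal(got, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(got >= p - 1e-15) && all(got <= 1))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), got[perm], tolerance = 1e-15)
  }
})

test_that("enrichment recovers a planted term and orders rows by p", {
  withr::local_seed(33)
  bg <- sprintf("G%04d", 1:1000)
  planted <- sample(bg, 10)
  terms <- list(PLANTED = list(name = "planted", genes = planted))
  for (i in 1:30) {
    terms[[sprintf("N%02d", i)]] <- list(
      name = sprintf("null %d", i), genes = sample(bg, 25)
    )
  }
  annot <- annotation_collection(terms, category = "TEST")
  rows <- enrich(gene_set(planted), annot, background = bg)
  expect_equal(rows$term_id[[1]], "PLANTED")
  expect_equal(rows$k[[1]], 10)
  expect_true(all(diff(rows$p_value) >= 0))
  expect_true(all(rows$fdr >= rows$p_value - 1e-15))
  expect_true(all(rows$k <= pmin(rows$n, rows$K)))
})

test_that("enrichment handles degenerate queries and backgrounds", {
  annot <- mini_annotation()
  # query disjoint from every term but inside the background
  rows <- enrich(gene_set(c("H", "I")), annot)
  expect_equal(rows$term_id, "T3")
  none <- enrich(gene_set("A"), annot, background = c("A", "H", "I"),
                 min_term_size = 2)
  expect_equal(nrow(none), 0)
  expect_error(enrich(gene_set("ZZZ"), annot),
               class = "netpharm_validation_error")
  # genes outside the background shrink n, with a message
  expect_message(rows2 <- enrich(gene_set(c("A", "B", "ZZZ")), annot),
                 "absent from the background")
  expect_equal(rows2$n[[1]], 2)
  # p_cutoff = 1 flags every returned row
  all_sig <- enrich(gene_set(c("A", "B")), annot, p_cutoff = 1)
  expect_true(all(all_sig$significant))
})

test_that("top_terms truncates stably and breaks p ties by term id", {
  annot <- annotation_collection(
    list(
      B_term = list(name = "b", genes = c("X", "Y")),
      A_term = list(name = "a", genes = c("X", "Y"))
    ),
    category = "TIE"
  )
  rows <- enrich(gene_set(c("X", "Y")), annot,
                 background = c("X", "Y", "Z", "W"))
  expect_equal(rows$term_id, c("A_term", "B_term")) # identical p, id ascending
  expect_equal(nrow(top_terms(rows, 20)), 2)
  expect_equal(top_terms(rows, 1)$term_id, "A_term")
})

test_that("plot data mirrors counts and round-trips through TSV", {
  annot <- mini_annotation()
  rows <- enrich(gene_set(c("A", "B", "C")), annot)
  pd <- enrichment_plot_data(rows)
  expect_equal(pd$count, rows$k)
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(pd, path, progress = FALSE)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$count, pd$count)
  expect_equal(back$p_value, pd$p_value, tolerance = 1e-12)
  expect_equal(nrow(enrichment_plot_data(rows[0, ])), 0)
})
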