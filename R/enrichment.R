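#' Hypergeometric upper-tail probability
#'
#' The exact over-representation p-value: the probability of observing `k`
#' or more annotated genes in a query of size `n` drawn without replacement
#' from a background of `N` genes of which `K` carry the annotation,
#'
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(n,K)}
#'   \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}.}
#'
#' The sum is accumulated in log-space (via `lchoose` and a log-sum-exp
#' reduction), so small tail probabilities are computed without underflow.
#' Arguments are recycled to a common length.
#'
#' @param k Observed overlap count(s).
#' @param K Annotated genes in the background (term size).
#' @param n Query size.
#' @param N Background size.
#' @return Numeric vector of tail probabilities in (0, 1].
#' @examples
#' hypergeom_sf(5, K = 5, n = 5, N = 10)  # 1 / choose(10, 5)
#' @export
hypergeom_sf <- function(k, K, n, N) {
  args <- vctrs_recycle(k = k, K = K, n = n, N = N)
  k <- args$k; K <- args$K; n <- args$n; N <- args$N
  ok <- k == floor(k) & K == floor(K) & n == floor(n) & N == floor(N) &
    k >= 0 & K >= 0 & n >= 0 & N >= 1 & n <= N & K <= N & k <= pmin(n, K)
  if (any(!ok)) {
    stopf("netpharm_validation_error",
          "invalid hypergeometric arguments at position(s) %s (need 0 <= k <= min(n,K), n <= N, K <= N)",
          paste(which(!ok), collapse = ", "))
  }
  vapply(seq_along(k), function(j) {
    hi <- min(n[j], K[j])
    i <- k[j]:hi
    lg <- lchoose(K[j], i) + lchoose(N[j] - K[j], n[j] - i) -
      lchoose(N[j], n[j])
    m <- max(lg)
    min(1, exp(m + log(sum(exp(lg - m)))))
  }, numeric(1))
}

vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(vapply(args, length, integer(1)))
  lapply(args, rep_len, length.out = len)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' The step-up adjustment: with `m` p-values sorted ascending, the adjusted
#' value at rank `i` is `min over j >= i of p_(j) * m / j`, clipped at 1,
#' and values are returned in the input order. Output never falls below the
#' input and is invariant (up to the same permutation) to permuting the
#' input.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of FDR-adjusted values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stopf("netpharm_validation_error", "p-values must lie in (0, 1]")
  }
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Over-representation analysis of a gene set
#'
#' Tests each term of an annotation collection for over-representation in
#' the query using the hypergeometric upper tail ([hypergeom_sf()]), with
#' Benjamini-Hochberg FDR across the tested terms of the collection. The
#' background defaults to the union of all genes annotated anywhere in the
#' collection; query genes outside the background are dropped from the
#' effective query size (their count is reported via a message). The
#' significance flag applies to the raw p-value (`p <= p_cutoff`), with the
#' FDR reported alongside.
#'
#' @param query [gene_set()] (or character vector) of genes of interest.
#' @param annotation An `annotation_collection`.
#' @param background A [gene_set()]/character vector, or
#'   `"annotation-universe"` (default) for the union of all annotated genes.
#' @param p_cutoff Raw p-value threshold for the significance flag
#'   (default 0.01).
#' @param min_term_size,max_term_size Term-size filter applied to `K` (the
#'   term restricted to the background).
#' @return Tibble of one row per term with `k >= 1`: `term_id`,
#'   `term_name`, `category`, `k`, `n`, `K`, `N`, `p_value`, `fdr`,
#'   `significant`, `genes` (list column of overlapping symbols); sorted by
#'   p ascending, term id ascending on ties.
#' @export
enrich <- function(query, annotation, background = "annotation-universe",
                   p_cutoff = 0.01, min_term_size = 1, max_term_size = Inf) {
  stopifnot(inherits(annotation, "annotation_collection"))
  bg <- if (identical(background, "annotation-universe")) {
    annotation_universe(annotation)
  } else {
    as_members(background)
  }
  q_all <- as_members(query)
  q <- intersect(q_all, bg)
  dropped <- length(q_all) - length(q)
  if (length(q) == 0) {
    stopf("netpharm_validation_error",
          "no query gene is present in the background; check that query and background use the same symbol universe")
  }
  if (dropped > 0) {
    inform(sprintf("%d query gene(s) absent from the background were dropped",
                   dropped))
  }
  N <- length(bg)
  n <- length(q)
  rows <- purrr::map(names(annotation$terms), function(id) {
    term <- annotation$terms[[id]]
    tg <- intersect(term$genes, bg)
    K <- length(tg)
    if (K < min_term_size || K > max_term_size) return(NULL)
    hits <- intersect(q, tg)
    if (length(hits) == 0) return(NULL)
    tibble(
      term_id = id, term_name = term$name, category = annotation$category,
      k = length(hits), n = n, K = K, N = N,
      p_value = hypergeom_sf(length(hits), K, n, N),
      genes = list(sort(hits))
    )
  })
  rows <- bind_rows(rows)
  if (nrow(rows) == 0) {
    return(tibble(
      term_id = character(), term_name = character(), category = character(),
      k = integer(), n = integer(), K = integer(), N = integer(),
      p_value = numeric(), fdr = numeric(), significant = logical(),
      genes = list()
    ))
  }
  rows$fdr <- bh_fdr(rows$p_value)
  rows$significant <- rows$p_value <= p_cutoff
  rows |>
    arrange(.data$p_value, .data$term_id) |>
    select("term_id", "term_name", "category", "k", "n", "K", "N",
           "p_value", "fdr", "significant", "genes")
}

#' Leading rows of an enrichment result
#'
#' @param rows Tibble from [enrich()] (already sorted by p).
#' @param n Number of terms to keep (default 20).
#' @return The first `min(n, nrow(rows))` rows, order preserved.
#' @export
top_terms <- function(rows, n = 20) {
  head(rows, n)
}

#' Tabular plot data for enrichment results
#'
#' Extracts the columns a bar or dot plot of enriched terms needs: the term
#' name, the overlap count on the x-axis, and the raw and adjusted
#' significance.
#'
#' @param rows Tibble from [enrich()].
#' @return Tibble `term_name`, `count`, `p_value`, `fdr`.
#' @export
enrichment_plot_data <- function(rows) {
  if (nrow(rows) == 0) {
    return(tibble(term_name = character(), count = integer(),
                  p_value = numeric(), fdr = numeric()))
  }
  tibble(
    term_name = rows$term_name,
    count = rows$k,
    p_value = rows$p_value,
    fdr = rows$fdr
  )
}
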