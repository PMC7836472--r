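#' Study-shaped fixture: Solanum nigrum / bladder cancer
#'
#' A packaged desk-scale input bundle reproducing the published numerical
#' shape of a single-herb network-pharmacology study of *Solanum nigrum* in
#' bladder cancer. It contains:
#'
#' * `table1`: the seven active ingredients with their published molecule
#'   ids, molecular weights, OB and DL values and plant parts. These values
#'   are as printed.
#' * `ingredients`: a 39-row ingredient table — the seven published records
#'   plus 32 **synthetic** records constructed to fail the OB/DL screen
#'   (the published study screened 39 components but printed only the
#'   seven passing rows).
#' * `pairs`: a 100-row ingredient-target pair table over 77 unique genes,
#'   reconstructed from the published degree facts: quercetin linked to
#'   all 77 targets, beta-carotene to 11, diosgenin to 9; NCOA2 targeted by
#'   four ingredients (quercetin, sitosterol, medioresinol, cholesterol);
#'   14 genes of degree 2 and 3 of degree 3. The 23 gene symbols named in
#'   the study appear verbatim; the remaining 54 degree-1 symbols are
#'   **synthetic** stand-ins (real human symbols typical of quercetin
#'   target lists). Note the published degree arithmetic leaves
#'   solanocapsine without an edge among the 77 overlap genes.
#' * `disease_genes`: a 7,624-symbol disease gene set containing the 77
#'   targets plus **synthetic** padding symbols, matching the published
#'   disease-list scale.
#' * `ppi_edges`: the archived interactome snapshot from
#'   [synthetic_string_snapshot()].
#'
#' Everything beyond the printed values is a deterministic synthetic
#' reconstruction; the bundle exists so the pipeline's desk-scale numbers
#' (7 active of 39; 100 edges over 77 genes; the degree table; 77 proteins
#' with 697 interactions, hub degree 52) are reproducible offline.
#'
#' @return Named list with elements `table1`, `ingredients`, `pairs`,
#'   `disease_genes`, `ppi_edges`.
#' @examples
#' fx <- snigrum_fixture()
#' screen_ingredients(fx$ingredients)
#' @export
snigrum_fixture <- function() {
  list(
    table1 = snigrum_table1(),
    ingredients = snigrum_ingredients(),
    pairs = snigrum_pairs(),
    disease_genes = snigrum_disease_genes(),
    ppi_edges = synthetic_string_snapshot()
  )
}

# The seven published active ingredients (values as printed).
snigrum_table1 <- function() {
  tibble(
    mol_id = c("MOL000546", "MOL002058", "MOL007356", "MOL000098",
               "MOL000953", "MOL002773", "MOL000359"),
    name = c("Diosgenin", "Medioresinol", "Solanocapsine", "Quercetin",
             "Cholesterol", "beta-Carotene", "Sitosterol"),
    mw = c(414.69, 388.45, 430.75, 302.35, 386.73, 536.96, 414.79),
    ob = c(80.88, 57.20, 52.94, 46.43, 37.87, 37.18, 36.91),
    dl = c(0.81, 0.62, 0.67, 0.28, 0.68, 0.58, 0.75),
    part = c("leaves stems", "fruits", "fruits", "leaves stems", "fruits",
             "fruits", "fruits")
  )
}

# 39-row table: the seven published records plus 32 synthetic records, each
# constructed to fail at least one screening criterion.
snigrum_ingredients <- function() {
  i <- seq_len(32)
  fail_mode <- i %% 3 # 0: dl only, 1: ob only, 2: both
  ob <- ifelse(fail_mode == 0, 31 + i * 1.7, 4 + (i * 2.3) %% 24)
  dl <- ifelse(fail_mode == 1, 0.19 + (i %% 9) * 0.06, 0.02 + (i %% 8) * 0.018)
  synthetic <- tibble(
    mol_id = sprintf("SYN%03d", i),
    name = sprintf("synthetic component %d", i),
    mw = round(180 + i * 13.7, 2),
    ob = round(ob, 2),
    dl = round(dl, 2),
    part = rep(c("leaves", "fruits", "stems", "roots"), length.out = 32)
  )
  bind_rows(snigrum_table1(), synthetic)
}

# Gene symbols by ingredient-target degree, as published (degree >= 2) or
# synthetic stand-ins (degree 1 beyond the five named hub proteins).
snigrum_gene_groups <- function() {
  list(
    degree4 = "NCOA2",
    degree3 = c("PGR", "NR3C2", "VEGFA"),
    degree2 = c("MYC", "HIF1A", "F7", "CYP3A4", "CAV1", "RELA", "CASP3",
                "CASP8", "CASP9", "BCL2", "AR", "TP63", "PTGS1", "PPARG"),
    degree1 = c(
      "IL6", "EGFR", "CCND1", "ERBB2", "MTOR",
      "AKT1", "AHR", "ALOX5", "BAX", "BIRC5", "CAT", "CCL2", "CDKN1A",
      "CHEK2", "COL1A1", "CRP", "CXCL10", "CXCL11", "CXCL8", "CYP1A1",
      "CYP1A2", "CYP1B1", "E2F1", "EGF", "ERBB3", "ESR1", "ESR2", "FOS",
      "GSTM1", "GSTP1", "HMOX1", "ICAM1", "IGF2", "IGFBP3", "IL10", "IL1B",
      "IL2", "JUN", "MMP1", "MMP2", "MMP3", "MMP9", "NFE2L2", "NOS2",
      "NOS3", "NQO1", "ODC1", "PARP1", "PLAU", "PON1", "PRKCA", "RAF1",
      "RB1", "SELE", "SOD1", "SPP1", "TNF", "TOP2A", "XDH"
    )
  )
}

# 100-row pair table over 77 genes, consistent with the published degrees.
snigrum_pairs <- function() {
  g <- snigrum_gene_groups()
  all_genes <- c(g$degree4, g$degree3, g$degree2, g$degree1)
  stopifnot(length(all_genes) == 77)
  rows <- bind_rows(
    tibble(mol_id = "MOL000098", gene = all_genes),              # quercetin
    tibble(mol_id = "MOL002773", gene = c(g$degree3, g$degree2[1:8])),  # beta-carotene
    tibble(mol_id = "MOL000546", gene = c(g$degree3, g$degree2[9:14])), # diosgenin
    tibble(mol_id = "MOL002058", gene = "NCOA2"),                # medioresinol
    tibble(mol_id = "MOL000953", gene = "NCOA2"),                # cholesterol
    tibble(mol_id = "MOL000359", gene = "NCOA2")                 # sitosterol
  )
  stopifnot(nrow(rows) == 100)
  rows
}

# 7,624-gene disease set: the 77 targets plus synthetic padding symbols.
snigrum_disease_genes <- function() {
  g <- snigrum_gene_groups()
  targets <- c(g$degree4, g$degree3, g$degree2, g$degree1)
  padding <- sprintf("BCG%05d", seq_len(7624 - length(targets)))
  gene_set(c(targets, padding), name = "bladder_cancer_genes",
           source = "synthetic")
}

#' Synthetic archived interactome snapshot
#'
#' A deterministic **synthetic** stand-in for the confidence-filtered
#' STRING snapshot of the 77 therapeutic-target proteins: 697 scored edges
#' (every score >= 0.4) realizing a frozen graphical degree sequence in
#' which the nine hub proteins carry the published degrees (IL6 52, CASP3
#' and EGFR 47, MYC and VEGFA 45, CCND1 40, ERBB2 37, MTOR 34, PPARG 33)
#' and the remaining 68 proteins a smoothly decreasing tail (27 down to 2).
#' The graph is built with a deterministic Havel-Hakimi-style realization
#' (`igraph::realize_degseq`), so repeated calls are identical. Such a
#' snapshot cannot be re-derived from a live database offline; this object
#' exists as a regression fixture for the PPI stage.
#'
#' @return Scored edge tibble (`a`, `b`, `score`), 697 rows.
#' @export
synthetic_string_snapshot <- function() {
  g <- snigrum_gene_groups()
  planted <- c(
    IL6 = 52L, CASP3 = 47L, EGFR = 47L, MYC = 45L, VEGFA = 45L,
    CCND1 = 40L, ERBB2 = 37L, MTOR = 34L, PPARG = 33L
  )
  others <- sort(setdiff(c(g$degree4, g$degree3, g$degree2, g$degree1),
                         names(planted)))
  # frozen tail: 68 degrees <= 27 summing to 1014 (total 2 * 697)
  tail_deg <- round(seq(28, 2, length.out = length(others)))
  excess <- sum(tail_deg) - (2L * 697L - sum(planted))
  stopifnot(excess >= 0)
  if (excess > 0) tail_deg[seq_len(excess)] <- tail_deg[seq_len(excess)] - 1L
  nodes <- c(names(planted), others)
  degs <- c(unname(planted), tail_deg)
  graph <- igraph::realize_degseq(degs, method = "smallest")
  el <- igraph::as_edgelist(graph)
  a <- nodes[el[, 1]]
  b <- nodes[el[, 2]]
  scores <- with_seed(20210125L, round(runif(nrow(el), 0.4, 0.999), 3))
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  arrange(tibble(a = lo, b = hi, score = scores), .data$a, .data$b)
}
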