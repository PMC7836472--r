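#' Read a herb ingredient table
#'
#' Reads a delimited snapshot of a TCMSP-style ingredient table: one row per
#' herb component with its molecule identifier, display name, molecular
#' weight (g/mol), predicted oral bioavailability (OB, percent on the 0-100
#' scale) and drug-likeness (DL, unitless on \[0,1\]), plus an optional
#' plant-part column. TSV and CSV are both accepted; the dialect is detected
#' from the file extension unless given explicitly.
#'
#' @param path Path to the delimited file.
#' @param dialect One of `"auto"`, `"tsv"`, `"csv"`.
#' @return A tibble with columns `mol_id`, `name`, `mw`, `ob`, `dl`, `part`
#'   in file order.
#' @export
read_ingredient_table <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  raw <- read_delim_auto(path, dialect)
  cols <- match_columns(
    names(raw),
    required = list(
      mol_id = c("mol_id", "molecule_id", "molecule id", "id", "molid"),
      name   = c("name", "molecule_name", "molecule name", "molecule"),
      mw     = c("mw", "molecular_weight", "molecular weight"),
      ob     = c("ob", "ob_percent", "oral_bioavailability"),
      dl     = c("dl", "drug_likeness", "drug likeness")
    ),
    optional = list(part = c("part", "parts", "plant_part", "plant part")),
    what = "ingredient table"
  )
  out <- tibble(
    mol_id = as.character(raw[[cols$mol_id]]),
    name = as.character(raw[[cols$name]]),
    mw = parse_numeric_column(raw[[cols$mw]], "mw"),
    ob = parse_numeric_column(raw[[cols$ob]], "ob"),
    dl = parse_numeric_column(raw[[cols$dl]], "dl"),
    part = if (is.na(cols$part)) NA_character_ else as.character(raw[[cols$part]])
  )
  validate_ingredients(out)
  out
}

validate_ingredients <- function(x) {
  dup <- unique(x$mol_id[duplicated(x$mol_id)])
  if (length(dup) > 0) {
    stopf(
      "netpharm_validation_error",
      "duplicated mol_id in ingredient table: %s", paste(dup, collapse = ", ")
    )
  }
  check_range <- function(ok, what) {
    if (!all(ok)) {
      stopf(
        "netpharm_validation_error", "%s at row(s) %s",
        what, paste(which(!ok), collapse = ", ")
      )
    }
  }
  check_range(x$mw > 0, "molecular weight must be positive")
  check_range(x$ob >= 0, "OB must be non-negative")
  check_range(x$dl >= 0 & x$dl <= 1, "DL must lie in [0,1]")
  invisible(x)
}

#' Read an ingredient-target pair table
#'
#' Reads a two-or-more-column delimited table of ingredient-to-gene edges
#' (the shape of an herb-target supplementary table). Gene symbols are
#' normalized via [normalize_symbol()], duplicate pairs collapse to one, and
#' the raw/deduplicated bookkeeping is attached for the funnel report:
#' `raw_rows = unique_pairs + duplicate_rows` always holds, and
#' `duplicate_genes = raw_rows - unique_genes` counts repeated gene entries
#' across ingredients.
#'
#' @param path Path to the delimited file.
#' @param dialect One of `"auto"`, `"tsv"`, `"csv"`.
#' @param aliases Optional alias map forwarded to [normalize_symbol()].
#' @return A tibble with columns `mol_id`, `gene` (deduplicated); the
#'   counting report is available via [pair_report()].
#' @export
read_pair_table <- function(path, dialect = c("auto", "tsv", "csv"),
                            aliases = NULL) {
  dialect <- match.arg(dialect)
  raw <- read_delim_auto(path, dialect)
  cols <- match_columns(
    names(raw),
    required = list(
      mol_id = c("mol_id", "molecule_id", "id", "ingredient", "ingredient_id",
                 "molecule", "molid"),
      gene = c("gene", "gene_symbol", "symbol", "target", "target_gene",
               "genesymbol")
    ),
    optional = list(),
    what = "pair table"
  )
  mol <- as.character(raw[[cols$mol_id]])
  gen <- as.character(raw[[cols$gene]])
  blank <- is.na(gen) | trimws(gen) == ""
  if (any(blank)) {
    warn(sprintf("skipped %d row(s) with blank gene field", sum(blank)),
         class = "netpharm_warning")
    mol <- mol[!blank]
    gen <- gen[!blank]
  }
  pairs <- tibble(mol_id = mol, gene = normalize_symbol(gen, aliases = aliases))
  raw_rows <- nrow(pairs)
  dedup <- distinct(pairs, .data$mol_id, .data$gene)
  report <- list(
    raw_rows = raw_rows,
    unique_pairs = nrow(dedup),
    duplicate_rows = raw_rows - nrow(dedup),
    unique_genes = length(unique(dedup$gene)),
    duplicate_genes = raw_rows - length(unique(dedup$gene))
  )
  attr(dedup, "pair_report") <- report
  dedup
}

#' Counting report of a pair table
#'
#' @param pairs A tibble returned by [read_pair_table()].
#' @return Named list with `raw_rows`, `unique_pairs`, `duplicate_rows`,
#'   `unique_genes`, `duplicate_genes`.
#' @export
pair_report <- function(pairs) {
  rep <- attr(pairs, "pair_report")
  if (is.null(rep)) {
    dedup <- distinct(pairs, .data$mol_id, .data$gene)
    rep <- list(
      raw_rows = nrow(pairs), unique_pairs = nrow(dedup),
      duplicate_rows = nrow(pairs) - nrow(dedup),
      unique_genes = length(unique(dedup$gene)),
      duplicate_genes = nrow(pairs) - length(unique(dedup$gene))
    )
  }
  rep
}

#' Read a disease gene list
#'
#' Reads a GeneCards/OMIM-style gene list: either one symbol per line or a
#' delimited table with a recognizable symbol column. Symbols are normalized
#' and deduplicated into a [gene_set()] tagged with its source.
#'
#' @param path Path to the file.
#' @param source Provenance tag stored on the returned set.
#' @param aliases Optional alias map.
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, source = "unknown", aliases = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) {
    warn(sprintf("gene list '%s' is empty", path), class = "netpharm_warning")
    return(gene_set(character(), name = basename(path), source = source))
  }
  first <- lines[[1]]
  symbols <- if (grepl("[\t,]", first)) {
    raw <- read_delim_auto(path, "auto")
    cols <- match_columns(
      names(raw),
      required = list(gene = c("gene", "gene_symbol", "symbol", "target",
                               "genesymbol")),
      optional = list(), what = "gene list"
    )
    as.character(raw[[cols$gene]])
  } else {
    header_like <- tolower(trimws(first)) %in%
      c("gene", "genes", "symbol", "gene_symbol", "target")
    if (header_like) lines[-1] else lines
  }
  gs <- gene_set(symbols, name = basename(path), source = source,
                 aliases = aliases)
  if (length(gs) == 0) {
    warn(sprintf("gene list '%s' yielded no symbols", path),
         class = "netpharm_warning")
  }
  gs
}

#' Read a GMT gene-set collection
#'
#' Parses the tab-delimited GMT format (one term per line:
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`) into an annotation
#' collection. Gene symbols are normalized; duplicate genes within a line
#' count once; terms left empty after normalization are dropped with a
#' warning.
#'
#' @param path Path to the GMT file.
#' @param category Label for the collection (e.g. `"GO:BP"`, `"KEGG"`).
#' @param aliases Optional alias map.
#' @return An `annotation_collection`: list with `category` and `terms`, the
#'   latter a named list of `list(name =, genes =)`.
#' @export
read_gmt <- function(path, category = "custom", aliases = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- trimws(lines) != ""
  terms <- list()
  for (i in seq_along(lines)) {
    if (!keep[[i]]) next
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stopf("netpharm_parse_error",
            "GMT line %d has fewer than 3 tab-separated fields", i)
    }
    id <- trimws(fields[[1]])
    if (id %in% names(terms)) {
      stopf("netpharm_validation_error", "duplicate GMT term id '%s'", id)
    }
    genes <- fields[-(1:2)]
    genes <- genes[trimws(genes) != ""]
    if (length(genes) == 0) {
      warn(sprintf("GMT term '%s' has no genes; dropped", id),
           class = "netpharm_warning")
      next
    }
    terms[[id]] <- list(
      name = trimws(fields[[2]]),
      genes = sort(unique(normalize_symbol(genes, aliases = aliases)))
    )
  }
  annotation_collection(terms, category = category)
}

#' Construct an annotation collection
#'
#' @param terms Named list mapping term id to `list(name =, genes =)`.
#' @param category Collection label.
#' @return An `annotation_collection`.
#' @export
annotation_collection <- function(terms, category = "custom") {
  if (length(terms) > 0 && (is.null(names(terms)) || anyDuplicated(names(terms)))) {
    stopf("netpharm_validation_error",
          "annotation terms must have unique names")
  }
  empty <- vapply(terms, function(t) length(t$genes) == 0, logical(1))
  if (any(empty)) {
    stopf("netpharm_validation_error", "annotation term(s) with no genes: %s",
          paste(names(terms)[empty], collapse = ", "))
  }
  structure(list(category = category, terms = terms),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  sizes <- vapply(x$terms, function(t) length(t$genes), integer(1))
  cat(sprintf("<annotation_collection> %s: %d terms, %d distinct genes\n",
              x$category, length(x$terms),
              length(annotation_universe(x))))
  if (length(sizes) > 0) {
    cat(sprintf("  term sizes: %d-%d (median %g)\n",
                min(sizes), max(sizes), stats::median(sizes)))
  }
  invisible(x)
}

#' Union of all genes annotated in a collection
#'
#' @param annotation An `annotation_collection`.
#' @return Sorted character vector of all annotated symbols.
#' @export
annotation_universe <- function(annotation) {
  sort(unique(unlist(lapply(annotation$terms, `[[`, "genes"), use.names = FALSE)))
}

#' Read a scored interaction edge list
#'
#' Reads a STRING-style edge table (`protein1 protein2 combined_score`;
#' space-, tab- or comma-delimited). STRING publishes combined scores on the
#' 0-1000 scale; these are divided by 1000 so every retained edge carries a
#' confidence in \[0,1\]. Self-loops are dropped (with a warning), and when
#' the same unordered pair appears twice (e.g. both orientations) the
#' maximum score is kept.
#'
#' @param path Path to the edge file.
#' @param score_scale `"unit"` (scores already in \[0,1\]),
#'   `"string1000"` (0-1000, divided by 1000), or `"auto"` (string1000 when
#'   any score exceeds 1).
#' @param aliases Optional alias map.
#' @return A tibble with columns `a`, `b`, `score` (`a < b` lexically, one
#'   row per unordered pair).
#' @export
read_scored_edges <- function(path,
                              score_scale = c("auto", "unit", "string1000"),
                              aliases = NULL) {
  score_scale <- match.arg(score_scale)
  raw <- read_delim_auto(path, "auto", allow_whitespace = TRUE)
  cols <- match_columns(
    names(raw),
    required = list(
      a = c("protein1", "node1", "a", "gene1", "source"),
      b = c("protein2", "node2", "b", "gene2", "target"),
      score = c("combined_score", "score", "weight", "confidence")
    ),
    optional = list(), what = "scored edge list",
    positional_fallback = TRUE
  )
  a <- as.character(raw[[cols$a]])
  b <- as.character(raw[[cols$b]])
  score <- parse_numeric_column(raw[[cols$score]], "score")
  if (score_scale == "auto") {
    score_scale <- if (any(score > 1)) "string1000" else "unit"
  }
  hi <- if (score_scale == "string1000") 1000 else 1
  bad <- score < 0 | score > hi
  if (any(bad)) {
    stopf("netpharm_validation_error",
          "score outside the declared %s scale [0,%g] at row(s) %s",
          score_scale, hi, paste(which(bad), collapse = ", "))
  }
  if (score_scale == "string1000") score <- score / 1000
  a <- normalize_symbol(a, aliases = aliases)
  b <- normalize_symbol(b, aliases = aliases)
  loops <- a == b
  if (any(loops)) {
    warn(sprintf("dropped %d self-loop(s)", sum(loops)),
         class = "netpharm_warning")
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  edges <- tibble(a = lo, b = hi, score = score)[!loops, ]
  n_before <- nrow(edges)
  edges <- edges |>
    group_by(.data$a, .data$b) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    arrange(.data$a, .data$b)
  attr(edges, "edge_report") <- list(
    raw_rows = length(loops),
    self_loops_dropped = sum(loops),
    duplicates_merged = n_before - nrow(edges)
  )
  edges
}

# ---- shared helpers ---------------------------------------------------------

read_delim_auto <- function(path, dialect, allow_whitespace = FALSE) {
  if (!file.exists(path)) {
    stopf("netpharm_io_error", "file not found: %s", path)
  }
  delim <- switch(dialect,
    tsv = "\t", csv = ",",
    auto = {
      first <- readLines(path, n = 1L, warn = FALSE)
      if (length(first) == 0) {
        if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
      } else if (grepl("\t", first)) {
        "\t"
      } else if (grepl(",", first)) {
        ","
      } else if (allow_whitespace && grepl(" ", trimws(first))) {
        " "
      } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
        ","
      } else {
        "\t"
      }
    }
  )
  if (delim == " ") {
    tbl <- utils::read.table(path, header = TRUE, colClasses = "character",
                             check.names = FALSE, comment.char = "")
    return(as_tibble(tbl))
  }
  readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
}

match_columns <- function(have, required, optional = list(), what = "table",
                          positional_fallback = FALSE) {
  key <- function(x) gsub("[ ._-]+", "_", tolower(trimws(x)))
  have_key <- key(have)
  out <- list()
  misses <- character()
  for (nm in names(required)) {
    idx <- match(key(required[[nm]]), have_key)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) misses <- c(misses, nm) else out[[nm]] <- have[idx[[1]]]
  }
  if (length(misses) > 0) {
    if (positional_fallback && length(have) >= length(required)) {
      # STRING-style files without canonical headers: take columns in order
      for (i in seq_along(required)) out[[names(required)[i]]] <- have[[i]]
    } else {
      stopf("netpharm_schema_error",
            "%s is missing required column(s): %s", what,
            paste(misses, collapse = ", "))
    }
  }
  for (nm in names(optional)) {
    idx <- match(key(optional[[nm]]), have_key)
    idx <- idx[!is.na(idx)]
    out[[nm]] <- if (length(idx) == 0) NA_character_ else have[idx[[1]]]
  }
  out
}

parse_numeric_column <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x) & trimws(x) != ""
  bad <- bad | is.na(x)
  if (any(bad)) {
    stopf("netpharm_parse_error",
          "column '%s' has unparseable numeric value(s) at data row(s) %s",
          col, paste(which(bad), collapse = ", "))
  }
  out
}
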