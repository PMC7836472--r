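#' Construct a gene set
#'
#' A `gene_set` is a named, deduplicated, normalized collection of gene
#' symbols carrying a provenance tag ("genecards", "omim", "herb", ...). All
#' set operations in the pipeline (union over ingredients, multi-source
#' disease merges, therapeutic-target intersection) consume and return
#' `gene_set` objects.
#'
#' @param members Character vector of (possibly raw) gene symbols.
#' @param name Display name of the set.
#' @param source Provenance tag.
#' @param aliases Optional alias map forwarded to [normalize_symbol()].
#' @return A `gene_set`: list with `name`, `source` and sorted unique
#'   `members`.
#' @examples
#' gene_set(c("tp53", "TP53", "EGFR"), name = "demo", source = "manual")
#' @export
gene_set <- function(members = character(), name = "gene_set",
                     source = "unknown", aliases = NULL) {
  members <- as.character(members)
  members <- members[!is.na(members) & trimws(members) != ""]
  if (length(members) > 0) {
    members <- sort(unique(normalize_symbol(members, aliases = aliases)))
  }
  structure(
    list(name = name, source = source, members = members),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf(
    "<gene_set> %s [%s]: %d symbols\n", x$name, x$source, length(x$members)
  ))
  if (length(x$members) > 0) {
    shown <- head(x$members, 8)
    cat(" ", paste(shown, collapse = ", "),
        if (length(x$members) > 8) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' @export
as.character.gene_set <- function(x, ...) x$members

is_gene_set <- function(x) inherits(x, "gene_set")

as_members <- function(x) {
  if (is_gene_set(x)) x$members else normalize_symbol(as.character(x))
}
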