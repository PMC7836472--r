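#' Normalize gene symbols
#'
#' Gene symbols arriving from herb-target databases, disease-gene portals and
#' interaction downloads mix case ("il6"), carry stray whitespace, use Greek
#' letters ("HIF1α") or historical aliases ("TIF2"). `normalize_symbol()`
#' maps each raw string to a canonical symbol: trim, transliterate Greek
#' letters to their Latin equivalents, apply an optional user-supplied alias
#' map, then uppercase. The function is deterministic and fully offline; no
#' nomenclature service is consulted.
#'
#' Normalization is idempotent: applying it twice gives the same result as
#' applying it once.
#'
#' @param x Character vector of raw symbols.
#' @param aliases Optional named character vector mapping alias to canonical
#'   symbol (e.g. `c(TIF2 = "NCOA2")`). Matched against the trimmed,
#'   transliterated string, case-insensitively, before uppercasing.
#' @return Character vector of normalized symbols, same length as `x`.
#' @examples
#' normalize_symbol(c("il6 ", "HIF1α"))
#' normalize_symbol("TIF2", aliases = c(TIF2 = "NCOA2"))
#' @export
normalize_symbol <- function(x, aliases = NULL) {
  if (!is.character(x)) {
    stopf("netpharm_validation_error", "symbols must be a character vector")
  }
  out <- trimws(x)
  bad <- is.na(out) | out == ""
  if (any(bad)) {
    stopf(
      "netpharm_validation_error",
      "empty or missing gene symbol at position(s) %s",
      paste(which(bad), collapse = ", ")
    )
  }
  out <- transliterate_greek(out)
  if (!is.null(aliases)) {
    if (is.null(names(aliases)) || any(names(aliases) == "")) {
      stopf("netpharm_validation_error", "alias map must be a named character vector")
    }
    idx <- match(toupper(out), toupper(names(aliases)))
    hit <- !is.na(idx)
    out[hit] <- unname(aliases[idx[hit]])
  }
  toupper(out)
}

# Greek letters seen in gene names in print (HIF1a, TNFa, NFkB, ...).
.greek_map <- c(
  "α" = "A", "Α" = "A", # alpha
  "β" = "B", "Β" = "B", # beta
  "γ" = "G", "Γ" = "G", # gamma
  "δ" = "D", "Δ" = "D", # delta
  "ε" = "E", "Ε" = "E", # epsilon
  "κ" = "K", "Κ" = "K", # kappa
  "λ" = "L", "Λ" = "L", # lambda
  "μ" = "M", # mu
  "σ" = "S", "Σ" = "S", # sigma
  "ω" = "O", "Ω" = "O"  # omega
)

transliterate_greek <- function(x) {
  for (i in seq_along(.greek_map)) {
    x <- gsub(names(.greek_map)[i], .greek_map[[i]], x, fixed = TRUE)
  }
  x
}
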