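#' Screen herb ingredients by ADME druggability criteria
#'
#' Applies the standard TCMSP-style druggability filter: an ingredient is
#' retained when its predicted oral bioavailability and drug-likeness both
#' reach their thresholds (`ob >= ob_min` and `dl >= dl_min`, inclusive on
#' both sides). OB is on the percent scale (30 means 30%); DL is unitless on
#' \[0,1\]. Rejected ingredients are annotated with which criterion failed.
#'
#' @param records Ingredient tibble as returned by
#'   [read_ingredient_table()].
#' @param ob_min Minimum oral bioavailability, percent. Default 30.
#' @param dl_min Minimum drug-likeness. Default 0.18.
#' @return A `screen_result`: list with `retained` (tibble, input order),
#'   `rejected` (tibble with a `failed_criteria` column: `"ob"`, `"dl"` or
#'   `"ob+dl"`), and `thresholds`.
#' @examples
#' fx <- snigrum_fixture()
#' res <- screen_ingredients(fx$ingredients)
#' res$retained$mol_id
#' @export
screen_ingredients <- function(records, ob_min = 30, dl_min = 0.18) {
  stopifnot(is.finite(ob_min), is.finite(dl_min))
  if (nrow(records) == 0) {
    return(new_screen_result(records, records[0, ], character(), ob_min, dl_min))
  }
  validate_ingredients(records)
  ob_ok <- records$ob >= ob_min
  dl_ok <- records$dl >= dl_min
  pass <- ob_ok & dl_ok
  failed <- dplyr::case_when(
    !ob_ok & !dl_ok ~ "ob+dl",
    !ob_ok ~ "ob",
    !dl_ok ~ "dl",
    TRUE ~ NA_character_
  )
  new_screen_result(records[pass, ], records[!pass, ], failed[!pass],
                    ob_min, dl_min)
}

new_screen_result <- function(retained, rejected, failed, ob_min, dl_min) {
  rejected$failed_criteria <- failed
  structure(
    list(
      retained = retained,
      rejected = rejected,
      thresholds = c(ob_min = ob_min, dl_min = dl_min)
    ),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "<screen_result> OB >= %g%%, DL >= %g: %d retained / %d rejected\n",
    x$thresholds[["ob_min"]], x$thresholds[["dl_min"]],
    nrow(x$retained), nrow(x$rejected)
  ))
  invisible(x)
}

#' Summarize an ADME screen for the funnel report
#'
#' @param result A `screen_result` from [screen_ingredients()].
#' @return Named list of counts: `input`, `retained`, `rejected_by_ob`,
#'   `rejected_by_dl`, `rejected_by_both`.
#' @export
screen_summary <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  fc <- result$rejected$failed_criteria
  list(
    input = nrow(result$retained) + nrow(result$rejected),
    retained = nrow(result$retained),
    rejected_by_ob = sum(fc == "ob"),
    rejected_by_dl = sum(fc == "dl"),
    rejected_by_both = sum(fc == "ob+dl")
  )
}
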