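.reportedCache <- new.env(parent = emptyenv())

#' Previously reported values for the built-in polymers
#'
#' Loads the bundled transcription of the published closed forms, numeric
#' tables (n = 1..10) and logarithmic-model statistics for polyester and
#' polycarbonate. These are data, not code: [auditClosedForms()] and
#' [reproduceTables()] compare recomputed quantities against them. The
#' \code{verified} element lists the columns whose published values agree
#' with recomputation from the edge partitions (the remainder are the
#' documented internal inconsistencies the audit flags).
#'
#' @return nested list mirroring the JSON fixture: \code{closed_forms},
#'   \code{tables}, \code{regressions}, \code{verified}.
#' @examples
#' reportedValues()$closed_forms$polyester$index$M1
#' @export
reportedValues <- function() {
  if (is.null(.reportedCache$values)) {
    path <- system.file("extdata", "reported_values.json",
                        package = "polyentropy", mustWork = TRUE)
    .reportedCache$values <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  .reportedCache$values
}
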