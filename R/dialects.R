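#' File dialects for assay metadata and outcome tables
#'
#' A dialect describes how a delimited text file maps onto the package's
#' domain model: the field separator, which source columns hold which fields,
#' and how source outcome labels (text or numeric codes) map onto the closed
#' outcome vocabulary \code{active, inactive, inconclusive, unspecified,
#' probe}. Exports from different sources vary, so the mapping is data, not
#' code.
#'
#' \code{default_dialect()} expects columns named after the model fields and
#' accepts both text outcome labels (case-insensitive) and the conventional
#' PubChem numeric outcome codes (1 = inactive, 2 = active, 3 = inconclusive,
#' 4 = unspecified, 5 = probe). \code{pubchem_dialect()} additionally expects
#' PubChem-style column headers (\code{AID}, \code{CID}, \code{Outcome}).
#'
#' @param sep field separator, default tab.
#' @return a list with elements \code{sep}, \code{assay_columns},
#'   \code{outcome_columns} (named character vectors mapping model field ->
#'   source column name) and \code{outcome_map} (named character vector
#'   mapping lowercased source label -> outcome level).
#' @export
#' @examples
#' d <- default_dialect(sep = ",")
#' d$outcome_map[["2"]]   # PubChem numeric code for an active outcome
default_dialect <- function(sep = "\t") {
  fields <- c("assay_id", "category", "substance_type", "screening_stage",
              "on_hold", "target_ids", "target_type", "activity_specified",
              "has_active_outcome")
  list(
    sep = sep,
    assay_columns   = stats::setNames(fields, fields),
    outcome_columns = c(cid = "cid", assay_id = "assay_id", outcome = "outcome"),
    outcome_map = c(
      active = "active", inactive = "inactive", inconclusive = "inconclusive",
      unspecified = "unspecified", probe = "probe",
      # PubChem activity outcome codes
      "1" = "inactive", "2" = "active", "3" = "inconclusive",
      "4" = "unspecified", "5" = "probe"
    )
  )
}

#' @rdname default_dialect
#' @export
pubchem_dialect <- function(sep = "\t") {
  d <- default_dialect(sep)
  d$outcome_columns <- c(cid = "CID", assay_id = "AID", outcome = "Outcome")
  d$assay_columns[["assay_id"]] <- "AID"
  d
}
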