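## internal helpers shared across modules

# closed vocabularies
.assay_categories <- c("primary", "confirmatory")
.substance_types  <- c("chemical", "rnai", "other")
.screening_stages <- c("primary_screening", "confirmatory_dose_response", "other")
.target_types     <- c("protein", "cell_based", "other", "none")
.outcome_levels   <- c("active", "inactive", "inconclusive", "unspecified", "probe")
.profile_cols <- c("cid",
                   "n_tested_primary", "n_tested_confirmatory",
                   "n_active_primary", "n_active_confirmatory",
                   "n_targets_primary", "n_targets_confirmatory")

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; printed percentages and degree
#' means here follow the half-away-from-zero convention (27.27 -> 27.3).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(27.27, 1)
#' round_half_up(c(0.25, -0.25), 1)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values stored just below .5 (e.g. 4.7-3.4)
  # still round up as their printed form would
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# TRUE/FALSE from common text encodings; NA for anything else
.parse_logical <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

# lowercase, collapse separators to "_": "confirmatory, dose-response" ->
# "confirmatory_dose_response", "primary screening" -> "primary_screening"
.normalize_token <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("_+", "_", gsub("[ ,;/-]+", "_", x))
}

# map free-text enum values onto a closed vocabulary; unknowns -> fallback
# (with one warning listing them) unless fallback is NULL (then error)
.map_enum <- function(x, levels, synonyms = character(), fallback = "other",
                      what = "value") {
  v <- .normalize_token(x)
  hit <- v %in% levels
  syn <- !hit & v %in% names(synonyms)
  v[syn] <- synonyms[v[syn]]
  unknown <- !(v %in% levels)
  if (any(unknown)) {
    bad <- unique(v[unknown])
    if (is.null(fallback)) {
      stop(sprintf("unmapped %s value(s): %s", what,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    warning(sprintf("unknown %s value(s) mapped to '%s': %s", what, fallback,
                    paste(bad, collapse = ", ")), call. = FALSE)
    v[unknown] <- fallback
  }
  v
}

# split ";"-separated target id strings into a list of character vectors
.split_targets <- function(target_ids) {
  v <- as.character(target_ids)
  v[is.na(v)] <- ""
  out <- strsplit(v, ";", fixed = TRUE)
  lapply(out, function(x) x[nzchar(trimws(x))])
}

# number of annotated targets per assay
.n_target_ids <- function(target_ids) lengths(.split_targets(target_ids))

.stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}
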