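#' Build per-compound profiles from filtered outcome records
#'
#' Aggregates one record per (compound, assay) into the seven-field compound
#' profile: per assay category, the number of assays the compound was tested
#' in, the number with an active outcome (its assay promiscuity), and the
#' number of unique targets over single-target assays with an active outcome
#' (its target promiscuity). Cell-based or otherwise targetless assays count
#' toward tested/active but never toward targets; assays annotating more than
#' one target likewise contribute no target count, since a per-target
#' activity cannot be attributed.
#'
#' @param records filtered outcome records (see [filter_outcomes()]).
#' @param assays the qualified assay metadata covering every assay referenced
#'   by \code{records}; a record pointing at an unknown assay is an error.
#' @return a validated profile \code{data.table}, one row per compound,
#'   sorted by \code{cid}.
#' @export
build_profiles <- function(records, assays) {
  rec <- as.data.table(records)
  am <- validate_assay_meta(assays)
  unknown <- setdiff(unique(rec$assay_id), am$assay_id)
  if (length(unknown))
    stop("records reference unknown assay_id(s): ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  if (nrow(rec) == 0)
    return(validate_profiles(data.table(
      cid = character(),
      n_tested_primary = integer(), n_tested_confirmatory = integer(),
      n_active_primary = integer(), n_active_confirmatory = integer(),
      n_targets_primary = integer(), n_targets_confirmatory = integer())))
  ntid <- .n_target_ids(am$target_ids)
  lut <- data.table(assay_id = am$assay_id, category = am$category,
                    tgt = ifelse(ntid == 1L, am$target_ids, NA_character_))
  x <- lut[rec, on = "assay_id"]
  per <- x[, .(
    n_tested = uniqueN(assay_id),
    n_active = uniqueN(assay_id[outcome == "active"]),
    n_targets = uniqueN(tgt[outcome == "active" & !is.na(tgt)])
  ), by = .(cid, category)]
  wide <- dcast(per, cid ~ category,
                value.var = c("n_tested", "n_active", "n_targets"),
                fill = 0L)
  for (col in setdiff(.profile_cols, "cid"))
    if (!col %in% names(wide)) wide[, (col) := 0L]
  setorder(wide, cid)
  validate_profiles(wide)
}

#' Partition compounds by assay-category coverage
#'
#' Splits profiled compounds into three disjoint sets: tested in both
#' categories, in primary assays only, and in confirmatory assays only.
#' The union identities \code{both + primary_only = compounds with >= 1
#' primary record} (and symmetrically for confirmatory) hold by construction
#' and are what large-scale analyses use to focus on the extensively tested
#' both-category subset.
#'
#' @param profiles a profile table from [build_profiles()].
#' @return an object of class \code{compound_partition}: a list with
#'   character-vector elements \code{both}, \code{primary_only},
#'   \code{confirmatory_only}.
#' @export
partition_compounds <- function(profiles) {
  dt <- validate_profiles(profiles)
  if (any(dt$n_tested_primary == 0 & dt$n_tested_confirmatory == 0))
    stop("profile with zero tested assays in both categories", call. = FALSE)
  out <- structure(list(
    both = dt$cid[dt$n_tested_primary > 0 & dt$n_tested_confirmatory > 0],
    primary_only = dt$cid[dt$n_tested_primary > 0 &
                            dt$n_tested_confirmatory == 0],
    confirmatory_only = dt$cid[dt$n_tested_primary == 0 &
                                 dt$n_tested_confirmatory > 0]
  ), class = "compound_partition")
  out
}

#' @export
print.compound_partition <- function(x, ...) {
  cat("Compound partition by assay-category coverage\n")
  cat(sprintf("  both:              %d\n", length(x$both)))
  cat(sprintf("  primary only:      %d\n", length(x$primary_only)))
  cat(sprintf("  confirmatory only: %d\n", length(x$confirmatory_only)))
  invisible(x)
}

#' Summarize assay frequency across compounds
#'
#' Computes, over the supplied profiles, the distribution of the number of
#' assays each compound was tested in — for one assay category or for both
#' combined — as a histogram over half-open bins \code{[k*w, (k+1)*w)}
#' together with the arithmetic mean and the median (central-pair average
#' for even counts). Subset the profiles first to restrict the denominator
#' (e.g. to the both-category partition).
#'
#' @param profiles a profile table.
#' @param scope \code{"primary"}, \code{"confirmatory"} or \code{"combined"}.
#' @param bin_width positive integer histogram bin width (default 50).
#' @return an object of class \code{frequency_summary}: list with
#'   \code{histogram} (data.table: lower, upper, count), \code{mean},
#'   \code{median}, \code{scope}, \code{bin_width}, \code{n}.
#' @export
assay_frequency <- function(profiles,
                            scope = c("primary", "confirmatory", "combined"),
                            bin_width = 50L) {
  scope <- match.arg(scope)
  dt <- validate_profiles(profiles)
  if (nrow(dt) == 0)
    stop("no compounds in scope: empty profile table", call. = FALSE)
  if (!(is.numeric(bin_width) && length(bin_width) == 1 && bin_width >= 1 &&
        bin_width == as.integer(bin_width)))
    stop("bin_width must be a positive integer", call. = FALSE)
  freq <- switch(scope,
                 primary = dt$n_tested_primary,
                 confirmatory = dt$n_tested_confirmatory,
                 combined = dt$n_tested_primary + dt$n_tested_confirmatory)
  breaks <- seq(0L, (max(freq) %/% bin_width + 1L) * bin_width, by = bin_width)
  idx <- findInterval(freq, breaks)      # half-open [lower, upper)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  hist <- data.table(lower = breaks[-length(breaks)], upper = breaks[-1],
                     count = counts)
  structure(list(histogram = hist,
                 mean = mean(freq),
                 median = stats::median(freq),
                 scope = scope, bin_width = as.integer(bin_width),
                 n = length(freq)),
            class = "frequency_summary")
}

#' @export
print.frequency_summary <- function(x, ...) {
  cat(sprintf("Assay frequency (%s), %d compounds, bin width %d\n",
              x$scope, x$n, x$bin_width))
  cat(sprintf("  mean %.1f, median %.1f\n",
              round_half_up(x$mean, 1), round_half_up(x$median, 1)))
  print(x$histogram[count > 0])
  invisible(x)
}

#' Census consistently inactive ("dark") compounds
#'
#' Returns the compound identifiers that were tested but never active within
#' the requested scope. For \code{"primary"}/\code{"confirmatory"}: tested in
#' at least one assay of that category with zero active outcomes. For
#' \code{"both_categories"}: tested in both categories and active in neither
#' — the dark-chemical-matter census of the extensively tested subset.
#'
#' @param profiles a profile table.
#' @param scope \code{"primary"}, \code{"confirmatory"} or
#'   \code{"both_categories"}.
#' @return character vector of compound identifiers.
#' @export
consistently_inactive <- function(profiles,
                                  scope = c("primary", "confirmatory",
                                            "both_categories")) {
  scope <- match.arg(scope)
  dt <- validate_profiles(profiles)
  switch(scope,
         primary = dt$cid[dt$n_tested_primary > 0 & dt$n_active_primary == 0],
         confirmatory = dt$cid[dt$n_tested_confirmatory > 0 &
                                 dt$n_active_confirmatory == 0],
         both_categories = dt$cid[dt$n_tested_primary > 0 &
                                    dt$n_tested_confirmatory > 0 &
                                    dt$n_active_primary == 0 &
                                    dt$n_active_confirmatory == 0])
}
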