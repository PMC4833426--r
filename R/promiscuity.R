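#' Per-compound promiscuity degrees
#'
#' \code{assay_promiscuity} is the number of qualified assays of the given
#' category in which a compound was active; assays probing the same target
#' count individually. \code{target_promiscuity} is the number of unique
#' annotated targets over those active assays and can never exceed assay
#' promiscuity. Never-active compounds have degree 0.
#'
#' @param profiles a profile table (one or more rows).
#' @param category \code{"primary"} or \code{"confirmatory"}.
#' @return named integer vector of degrees (names are compound ids).
#' @export
#' @examples
#' # a compound tested in assays 1-5 (target T1) and 6-10 (target T2),
#' # active in assays 1, 2, 3, 8 and 10: assay promiscuity 5, target 2
#' rec <- outcome_records(cid = rep("C", 10), assay_id = paste0("A", 1:10),
#'                        outcome = ifelse(1:10 %in% c(1, 2, 3, 8, 10),
#'                                         "active", "inactive"))
#' am <- assay_meta(assay_id = paste0("A", 1:10),
#'                  target_ids = rep(c("T1", "T2"), each = 5))
#' p <- build_profiles(rec, am)
#' assay_promiscuity(p, "primary")   # 5
#' target_promiscuity(p, "primary")  # 2
assay_promiscuity <- function(profiles, category = c("primary", "confirmatory")) {
  category <- match.arg(category)
  dt <- validate_profiles(profiles)
  stats::setNames(dt[[paste0("n_active_", category)]], dt$cid)
}

#' @rdname assay_promiscuity
#' @export
target_promiscuity <- function(profiles, category = c("primary", "confirmatory")) {
  category <- match.arg(category)
  dt <- validate_profiles(profiles)
  stats::setNames(dt[[paste0("n_targets_", category)]], dt$cid)
}

#' Summarize promiscuity degrees over active compounds
#'
#' Restricts to compounds with degree >= 1 (the active test compounds; dark
#' compounds are censused separately by [consistently_inactive()]) and
#' reports their count, the mean and median degree, and the degree histogram
#' with percentages of actives.
#'
#' @param profiles a profile table.
#' @param category \code{"primary"} or \code{"confirmatory"}.
#' @param kind \code{"assay"} or \code{"target"} promiscuity.
#' @return an object of class \code{promiscuity_summary}: list with
#'   \code{category}, \code{kind}, \code{n_active_compounds}, \code{mean},
#'   \code{median} and \code{degree_histogram} (data.table: degree, count,
#'   pct).
#' @export
summarize_promiscuity <- function(profiles,
                                  category = c("primary", "confirmatory"),
                                  kind = c("assay", "target")) {
  category <- match.arg(category)
  kind <- match.arg(kind)
  deg <- switch(kind,
                assay = assay_promiscuity(profiles, category),
                target = target_promiscuity(profiles, category))
  deg <- deg[deg >= 1]
  if (!length(deg))
    stop(sprintf("no compounds with %s %s promiscuity >= 1", category, kind),
         call. = FALSE)
  hist <- data.table(degree = as.integer(names(table(deg))),
                     count = as.integer(table(deg)))
  hist[, pct := 100 * count / length(deg)]
  structure(list(category = category, kind = kind,
                 n_active_compounds = length(deg),
                 mean = mean(deg), median = stats::median(deg),
                 degree_histogram = hist),
            class = "promiscuity_summary")
}

#' @export
print.promiscuity_summary <- function(x, ...) {
  cat(sprintf("%s %s promiscuity over %d active compounds\n",
              x$category, x$kind, x$n_active_compounds))
  cat(sprintf("  mean %.1f, median %.1f\n",
              round_half_up(x$mean, 1), round_half_up(x$median, 1)))
  invisible(x)
}

#' Default assay-count bins for box-plot summaries
#'
#' Half-open bins \code{[k*w, (k+1)*w)} covering 1..max_tested; width 50 for
#' primary and 25 for confirmatory by default (figure granularity is a
#' display choice, so widths are configurable).
#'
#' @param max_tested largest tested-assay count to cover.
#' @param width bin width.
#' @return data.table with columns \code{lower}, \code{upper}.
#' @export
make_bins <- function(max_tested, width = 50L) {
  breaks <- seq(0L, (max_tested %/% width + 1L) * width, by = width)
  data.table(lower = breaks[-length(breaks)], upper = breaks[-1])
}

#' Five-number promiscuity summaries per assay-frequency bin
#'
#' Assigns compounds to half-open bins \code{[lower, upper)} by the number of
#' category assays they were tested in, and per bin computes the five-number
#' summary (minimum, first quartile, median, third quartile, maximum) of the
#' promiscuity degree over compounds with degree >= 1 — the box-plot view of
#' promiscuity versus assay frequency. Quartiles interpolate linearly
#' between order statistics at ranks \code{(n-1) * q} (stats::quantile type
#' 7); the method is recorded in the result so alternates can be compared.
#' Bins with no active compounds are omitted with a log note.
#'
#' @inheritParams summarize_promiscuity
#' @param bins a two-column (lower, upper) data.frame of ordered,
#'   non-overlapping half-open bins; default [make_bins()] with width 50
#'   (primary) or 25 (confirmatory).
#' @return a \code{data.table} with columns lower, upper, n, min, q1, median,
#'   q3, max; attribute \code{quartile_method = "type7"}.
#' @export
binned_box_stats <- function(profiles,
                             category = c("primary", "confirmatory"),
                             kind = c("assay", "target"),
                             bins = NULL) {
  category <- match.arg(category)
  kind <- match.arg(kind)
  dt <- validate_profiles(profiles)
  tested <- dt[[paste0("n_tested_", category)]]
  if (is.null(bins))
    bins <- make_bins(max(tested, 1L),
                      width = if (category == "primary") 50L else 25L)
  b <- as.data.table(bins)
  if (!all(c("lower", "upper") %in% names(b)))
    stop("bins must have columns lower and upper", call. = FALSE)
  if (any(b$upper <= b$lower))
    stop("each bin must satisfy lower < upper", call. = FALSE)
  if (is.unsorted(b$lower, strictly = TRUE) ||
      any(b$lower[-1] < b$upper[-nrow(b)]))
    stop("bins must be ordered and non-overlapping", call. = FALSE)
  deg <- switch(kind,
                assay = dt[[paste0("n_active_", category)]],
                target = dt[[paste0("n_targets_", category)]])
  rows <- vector("list", nrow(b))
  for (i in seq_len(nrow(b))) {
    sel <- tested >= b$lower[i] & tested < b$upper[i] & deg >= 1
    if (!any(sel)) {
      .stage_log("binned_box_stats", "bin [%d,%d) empty, omitted",
                 b$lower[i], b$upper[i])
      next
    }
    q <- stats::quantile(deg[sel], probs = c(0, .25, .5, .75, 1),
                         type = 7, names = FALSE)
    rows[[i]] <- data.table(lower = b$lower[i], upper = b$upper[i],
                            n = sum(sel), min = q[1], q1 = q[2],
                            median = q[3], q3 = q[4], max = q[5])
  }
  out <- rbindlist(rows)
  setattr(out, "quartile_method", "type7")
  out[]
}
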