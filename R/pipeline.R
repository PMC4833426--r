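#' Difference between two reported statistics
#'
#' The gap rows of the consolidated report — e.g. mean assay promiscuity
#' minus mean target promiscuity within a category — are reported to one
#' decimal, half away from zero, matching how the underlying means are
#' printed.
#'
#' @param first,second finite numbers (e.g. two means, or a mean and median).
#' @param digits decimals for the returned value (default 1).
#' @return \code{first - second} rounded to \code{digits}.
#' @export
#' @examples
#' report_gap(4.7, 3.4)  # 1.3
#' report_gap(3.0, 2.6)  # 0.4
report_gap <- function(first, second, digits = 1) {
  stopifnot(is.finite(first), is.finite(second))
  round_half_up(first - second, digits)
}

# Table-1-style census for one qualified category
.category_census <- function(qualified, filtered) {
  rec <- filtered[assay_id %in% qualified$assay_id]
  tgts <- unique(unlist(.split_targets(qualified$target_ids)))
  list(assays = nrow(qualified),
       targets = length(tgts),
       compounds = uniqueN(rec$cid),
       records_all = nrow(rec),
       records_active = sum(rec$outcome == "active"),
       records_inactive = sum(rec$outcome == "inactive"))
}

#' Run the full promiscuity-analysis pipeline
#'
#' Chains qualification, outcome filtering, profile building, compound
#' partitioning, dark-compound censuses, the four promiscuity summaries
#' (category x assay/target), the assay-vs-target gap rows, and optional
#' PAINS triage, into one consolidated report. Input is either a synthetic
#' generator configuration or paths to metadata/outcome (and optionally
#' structure and pattern) files. Every filter logs its in/out counts; every
#' number in the report is re-derivable from the returned tables.
#'
#' @param config a named list (or path to a YAML/JSON file holding one) with
#'   either \itemize{
#'   \item \code{synthetic}: arguments for [synthetic_config()] (seed
#'     mandatory), or
#'   \item \code{inputs}: \code{assay_meta}, \code{outcomes}, optionally
#'     \code{structures} file paths and \code{dialect} (\code{"default"} or
#'     \code{"pubchem"}).
#'   } plus optional \code{bin_width} (assay-frequency histograms, default
#'   50), \code{pains}: list(\code{patterns} = path, \code{threshold}).
#' @param out_dir optional directory: writes \code{profiles.tsv} and
#'   \code{report.json} there.
#' @return list of class \code{promprof_report}; notable elements:
#'   \code{census} (per category), \code{partition_sizes} (with union
#'   identities), \code{dark} (counts and both-category percentage),
#'   \code{summaries}, \code{gaps}, \code{frequency}, \code{triage},
#'   \code{tables} (qualified assays, filtered records, profiles).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  structures <- NULL
  truth <- NULL
  if (!is.null(config$synthetic)) {
    gen <- stage("simulate",
                 generate_screening_data(
                   do.call(synthetic_config, config$synthetic)))
    assays <- gen$assays; records <- gen$records
    structures <- gen$structures; truth <- gen$truth
  } else if (!is.null(config$inputs)) {
    dia <- switch(config$inputs$dialect %||% "default",
                  default = default_dialect(), pubchem = pubchem_dialect(),
                  stop("unknown dialect", call. = FALSE))
    assays <- stage("read_assay_meta",
                    read_assay_meta(config$inputs$assay_meta, dia))
    records <- stage("read_outcomes",
                     read_outcomes(config$inputs$outcomes, dia))
    if (!is.null(config$inputs$structures))
      structures <- stage("read_structures",
                          read_structures(config$inputs$structures))
  } else stop("config needs a 'synthetic' or 'inputs' section", call. = FALSE)

  qp <- stage("qualify_primary", qualify_primary(assays))
  qc <- stage("qualify_confirmatory", qualify_confirmatory(assays))
  qualified <- rbindlist(list(qp, qc))
  filtered <- stage("filter_outcomes", filter_outcomes(records, qualified))
  profiles <- stage("build_profiles", build_profiles(filtered, qualified))
  partition <- stage("partition", partition_compounds(profiles))

  census <- list(primary = .category_census(qp, filtered),
                 confirmatory = .category_census(qc, filtered))
  for (cat in names(census)) {
    cc <- census[[cat]]
    stopifnot(cc$records_active + cc$records_inactive == cc$records_all)
    .stage_log("census", "%s: %d assays, %d targets, %d compounds, %d records (%d active + %d inactive)",
               cat, cc$assays, cc$targets, cc$compounds, cc$records_all,
               cc$records_active, cc$records_inactive)
  }

  n_prim <- sum(profiles$n_tested_primary > 0)
  n_conf <- sum(profiles$n_tested_confirmatory > 0)
  partition_sizes <- list(
    both = length(partition$both),
    primary_only = length(partition$primary_only),
    confirmatory_only = length(partition$confirmatory_only),
    identity_primary = length(partition$both) +
      length(partition$primary_only) == n_prim,
    identity_confirmatory = length(partition$both) +
      length(partition$confirmatory_only) == n_conf)

  both_prof <- profiles[cid %in% partition$both]
  dark_both <- consistently_inactive(profiles, "both_categories")
  dark <- list(
    primary = length(consistently_inactive(profiles, "primary")),
    confirmatory = length(consistently_inactive(profiles, "confirmatory")),
    both_categories = length(dark_both),
    both_pct = if (length(partition$both))
      round_half_up(100 * length(dark_both) / length(partition$both), 1)
      else NA_real_)

  bw <- config$bin_width %||% 50L
  frequency <- lapply(
    stats::setNames(nm = c("primary", "confirmatory", "combined")),
    function(sc) if (nrow(both_prof))
      assay_frequency(both_prof, sc, bin_width = bw) else NULL)

  summaries <- list()
  gaps <- list()
  for (cat in .assay_categories) {
    for (kind in c("assay", "target")) {
      key <- paste(cat, kind, sep = "_")
      summaries[[key]] <- tryCatch(
        summarize_promiscuity(profiles, cat, kind),
        error = function(e) { .stage_log("summarize", "%s: %s", key,
                                         conditionMessage(e)); NULL })
    }
    sa <- summaries[[paste0(cat, "_assay")]]
    st <- summaries[[paste0(cat, "_target")]]
    if (!is.null(sa) && !is.null(st))
      gaps[[cat]] <- list(
        mean_assay_minus_mean_target = report_gap(sa$mean, st$mean),
        mean_minus_median_assay = report_gap(sa$mean, sa$median))
  }

  triage <- NULL
  if (!is.null(config$pains) && !is.null(structures)) {
    pats <- if (!is.null(config$pains$patterns))
      stage("load_pains_patterns",
            load_pains_patterns(config$pains$patterns))
    else data.table(name = character(), smarts = character())
    triage <- stage("triage",
                    triage_promiscuous(profiles, structures, pats,
                                       config$pains$threshold %||% 100L))
  }

  report <- structure(list(
    config = config, census = census, partition_sizes = partition_sizes,
    dark = dark, frequency = frequency, summaries = summaries, gaps = gaps,
    triage = triage, recovery = if (!is.null(truth))
      recovery_report(truth, profiles) else NULL,
    tables = list(qualified_assays = qualified, filtered_records = filtered,
                  profiles = profiles, partition = partition)),
    class = "promprof_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_profiles(profiles, file.path(out_dir, "profiles.tsv"))
    jsonlite::write_json(.report_as_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# machine-readable view: scalars only, tables dropped
.report_as_json <- function(report) {
  s <- lapply(report$summaries, function(x) if (is.null(x)) NULL else
    list(n_active_compounds = x$n_active_compounds,
         mean = x$mean, median = x$median))
  list(census = report$census,
       partition_sizes = report$partition_sizes,
       dark = report$dark,
       summaries = s, gaps = report$gaps)
}

#' @export
print.promprof_report <- function(x, ...) {
  cat("== Promiscuity analysis report ==\n\nCensus\n")
  for (cat_ in names(x$census)) {
    cc <- x$census[[cat_]]
    cat(sprintf("  %-12s assays %d | targets %d | compounds %d | records %d (%d active + %d inactive)\n",
                cat_, cc$assays, cc$targets, cc$compounds, cc$records_all,
                cc$records_active, cc$records_inactive))
  }
  ps <- x$partition_sizes
  cat(sprintf("\nPartition: both %d | primary only %d | confirmatory only %d (identities: %s, %s)\n",
              ps$both, ps$primary_only, ps$confirmatory_only,
              ps$identity_primary, ps$identity_confirmatory))
  cat(sprintf("Dark: primary %d | confirmatory %d | both %d (%.1f%% of both-subset)\n",
              x$dark$primary, x$dark$confirmatory, x$dark$both_categories,
              x$dark$both_pct))
  cat("\nPromiscuity (actives only)\n")
  for (key in names(x$summaries)) {
    s <- x$summaries[[key]]
    if (!is.null(s))
      cat(sprintf("  %-22s n %d, mean %.1f, median %.1f\n", key,
                  s$n_active_compounds, round_half_up(s$mean, 1),
                  round_half_up(s$median, 1)))
  }
  for (cat_ in names(x$gaps))
    cat(sprintf("  gap(%s): mean assay - mean target = %.1f\n",
                cat_, x$gaps[[cat_]]$mean_assay_minus_mean_target))
  if (!is.null(x$triage))
    cat(sprintf("\nPAINS triage: %d compound(s) at threshold\n",
                nrow(x$triage)))
  invisible(x)
}
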