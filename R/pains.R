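## PAINS flagging: substructure matching via the OpenBabel SMARTS engine
## (ChemmineR/ChemmineOB). Flags are annotation only and never remove a
## compound from any statistic.

# one-molecule SDF used to probe whether a SMARTS string parses
.smarts_probe_sdf <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- ChemmineR::smiles2sdf(c(probe = "CCO"))
    cache
  }
})

.smarts_is_valid <- function(smarts) {
  if (!nzchar(trimws(smarts))) return(FALSE)
  ok <- TRUE
  tryCatch(
    ChemmineR::smartsSearchOB(.smarts_probe_sdf(), smarts,
                              uniqueMatches = FALSE),
    error = function(e) ok <<- FALSE)
  ok
}

#' Load a PAINS SMARTS pattern list
#'
#' Reads substructure patterns from plain text, one pattern per line, in
#' either layout: \code{name<TAB>SMARTS} or \code{SMARTS name} (pattern
#' first, whitespace, then the name — the pattern-checker layout). Lines
#' starting with \code{#} and blank lines are ignored. Every SMARTS is
#' checked against the substructure engine; unparseable lines are an error
#' listing their line numbers, or are dropped with a warning when
#' \code{skip_bad = TRUE}. Pattern names must be unique. The pattern list is
#' deliberately an input file, never embedded: published PAINS translations
#' differ, so which list was used is part of the analysis record.
#'
#' @param path path to the pattern file.
#' @param skip_bad drop unparseable lines with a warning instead of erroring.
#' @return a \code{data.table} with columns \code{name}, \code{smarts}.
#' @export
load_pains_patterns <- function(path, skip_bad = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) stop("no patterns in ", path, call. = FALSE)
  parse_line <- function(ln) {
    if (grepl("\t", ln)) {
      f <- strsplit(ln, "\t")[[1]]
      c(name = trimws(f[1]), smarts = trimws(f[2]))
    } else {
      # SMARTS first, optional trailing name
      sm <- regmatches(ln, regexpr("\\S+", ln))
      nm <- trimws(sub("^\\S+\\s*", "", ln))
      c(name = if (nzchar(nm)) nm else sm, smarts = sm)
    }
  }
  parsed <- do.call(rbind, lapply(trimws(lines[keep]), parse_line))
  pats <- data.table(name = parsed[, "name"], smarts = parsed[, "smarts"],
                     line = keep)
  bad <- !vapply(pats$smarts, .smarts_is_valid, logical(1))
  if (any(bad)) {
    msg <- sprintf("unparseable SMARTS at line(s): %s",
                   paste(pats$line[bad], collapse = ", "))
    if (!skip_bad) stop(msg, call. = FALSE)
    warning(msg, "; skipped", call. = FALSE)
    pats <- pats[!bad]
  }
  if (nrow(pats) == 0)
    stop("no parseable patterns in ", path, call. = FALSE)
  if (anyDuplicated(pats$name))
    stop("duplicate pattern name(s): ",
         paste(unique(pats$name[duplicated(pats$name)]), collapse = ", "),
         call. = FALSE)
  .stage_log("load_pains_patterns", "%d pattern(s) loaded from %s",
             nrow(pats), path)
  pats[, .(name, smarts)][]
}

# parse SMILES one compound at a time so a single bad structure cannot abort
# the batch; returns list(sdf = SDFset of parseable molecules or NULL,
# ok = names parsed, failed = names not parseable)
.parse_structures <- function(structures) {
  stopifnot(is.character(structures))
  if (is.null(names(structures)) || any(!nzchar(names(structures))))
    names(structures) <- paste0("S", seq_along(structures))
  parses <- function(smi) {
    !inherits(tryCatch(ChemmineR::smiles2sdf(smi), error = identity),
              "condition")
  }
  ok <- vapply(unname(structures), parses, logical(1))
  sdf <- NULL
  if (any(ok)) {
    sdf <- ChemmineR::smiles2sdf(structures[ok])
    ChemmineR::cid(sdf) <- names(structures)[ok]
  }
  list(sdf = sdf, ok = names(structures)[ok],
       failed = names(structures)[!ok])
}

#' Match PAINS patterns against compound structures
#'
#' Runs every pattern against every structure and reports, per compound, the
#' names of matching patterns in pattern-list order (an empty vector means
#' clean). Matching is deterministic; permuting the pattern list permutes
#' only the reported order. A structure that cannot be parsed does not abort
#' the run: the compound is recorded under the \code{"unevaluated"}
#' attribute and excluded from the result list.
#'
#' @param structures named character vector of SMILES (names = compound ids),
#'   e.g. from [read_structures()].
#' @param patterns a pattern table from [load_pains_patterns()] (columns
#'   \code{name}, \code{smarts}); may have zero rows.
#' @return named list (one element per parseable compound) of character
#'   vectors of matched pattern names; attribute \code{unevaluated} holds
#'   the ids of unparseable structures.
#' @export
match_pains <- function(structures, patterns) {
  pats <- as.data.table(patterns)
  if (nrow(pats) && !all(c("name", "smarts") %in% names(pats)))
    stop("patterns must have columns name and smarts", call. = FALSE)
  ps <- .parse_structures(structures)
  if (length(ps$failed))
    .stage_log("match_pains", "%d structure(s) unevaluated (parse failure)",
               length(ps$failed))
  res <- stats::setNames(
    rep(list(character()), length(ps$ok)), ps$ok)
  if (!is.null(ps$sdf) && nrow(pats)) {
    for (j in seq_len(nrow(pats))) {
      hits <- ChemmineR::smartsSearchOB(ps$sdf, pats$smarts[j],
                                        uniqueMatches = FALSE) > 0
      for (i in which(hits))
        res[[i]] <- c(res[[i]], pats$name[j])
    }
  }
  attr(res, "unevaluated") <- ps$failed
  res
}

#' Triage highly promiscuous compounds with PAINS annotation
#'
#' Selects compounds whose assay promiscuity reaches \code{degree_threshold}
#' in either assay category, and annotates each with the PAINS patterns its
#' structure contains. Rows are sorted by assay promiscuity (the larger of
#' the two category degrees) descending, compound id ascending for ties.
#' Compounds without a structure record, or whose structure cannot be
#' parsed, appear with \code{pains = "unevaluated"}. Flags never feed back
#' into any promiscuity statistic.
#'
#' @param profiles a profile table.
#' @param structures named character vector of SMILES keyed by compound id;
#'   may omit compounds.
#' @param patterns a PAINS pattern table (see [load_pains_patterns()]).
#' @param degree_threshold minimum assay promiscuity (>= 1) for inclusion.
#' @return a \code{data.table} with columns \code{cid},
#'   \code{assay_promiscuity}, \code{target_promiscuity},
#'   \code{n_active_primary}, \code{n_active_confirmatory}, \code{pains}
#'   (\code{";"}-joined matched names, \code{""} if clean,
#'   \code{"unevaluated"} if no parseable structure).
#' @export
triage_promiscuous <- function(profiles, structures, patterns,
                               degree_threshold = 100L) {
  if (!(length(degree_threshold) == 1 && degree_threshold >= 1))
    stop("degree_threshold must be >= 1", call. = FALSE)
  dt <- validate_profiles(profiles)
  sel <- dt[pmax(n_active_primary, n_active_confirmatory) >= degree_threshold]
  sel[, assay_promiscuity := pmax(n_active_primary, n_active_confirmatory)]
  sel[, target_promiscuity := pmax(n_targets_primary, n_targets_confirmatory)]
  setorder(sel, -assay_promiscuity, cid)
  have <- intersect(sel$cid, names(structures))
  matches <- if (length(have)) match_pains(structures[have], patterns)
             else structure(list(), unevaluated = character())
  flag <- function(cid) {
    if (!cid %in% have || cid %in% attr(matches, "unevaluated"))
      return("unevaluated")
    paste(matches[[cid]], collapse = ";")
  }
  sel[, pains := vapply(cid, flag, character(1))]
  sel[, .(cid, assay_promiscuity, target_promiscuity,
          n_active_primary, n_active_confirmatory, pains)][]
}
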