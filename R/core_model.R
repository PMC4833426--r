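#' Construct an assay metadata table
#'
#' Builds and validates the per-assay metadata table consumed by the
#' qualification rules. One row per assay. \code{target_ids} holds zero or
#' more annotated target identifiers per assay as a \code{";"}-separated
#' string (\code{""} for targetless assays); identifiers are treated as
#' opaque, with no synonym reconciliation.
#'
#' @param assay_id character, unique non-empty assay identifiers.
#' @param category \code{"primary"} or \code{"confirmatory"}.
#' @param substance_type \code{"chemical"}, \code{"rnai"} or \code{"other"}.
#' @param screening_stage \code{"primary_screening"},
#'   \code{"confirmatory_dose_response"} or \code{"other"}.
#' @param on_hold logical; assay deposited on hold.
#' @param target_ids \code{";"}-separated target identifiers, \code{""} if none.
#' @param target_type \code{"protein"}, \code{"cell_based"}, \code{"other"} or
#'   \code{"none"}; cell-based and none imply empty \code{target_ids}.
#' @param activity_specified logical; a quantitative readout (e.g. IC50) is
#'   reported.
#' @param has_active_outcome logical; the assay reports at least one active
#'   outcome (a deposition-level facet, not recomputed from records).
#' @return a \code{data.table} with one validated row per assay.
#' @export
#' @examples
#' assay_meta(assay_id = c("A1", "A2"),
#'            category = c("primary", "confirmatory"),
#'            target_ids = c("", "T1"),
#'            target_type = c("cell_based", "protein"))
assay_meta <- function(assay_id,
                       category = "primary",
                       substance_type = "chemical",
                       screening_stage = ifelse(category == "primary",
                                                "primary_screening",
                                                "confirmatory_dose_response"),
                       on_hold = FALSE,
                       target_ids = "",
                       target_type = ifelse(.n_target_ids(target_ids) > 0,
                                            "protein", "none"),
                       activity_specified = category == "confirmatory",
                       has_active_outcome = TRUE) {
  dt <- data.table(
    assay_id = as.character(assay_id),
    category = as.character(category),
    substance_type = as.character(substance_type),
    screening_stage = as.character(screening_stage),
    on_hold = as.logical(on_hold),
    target_ids = ifelse(is.na(target_ids), "", as.character(target_ids)),
    target_type = as.character(target_type),
    activity_specified = as.logical(activity_specified),
    has_active_outcome = as.logical(has_active_outcome)
  )
  validate_assay_meta(dt)
}

#' Validate an assay metadata table
#'
#' Checks the structural invariants: all nine fields present, identifiers
#' non-empty and unique, enumerations drawn from their closed vocabularies,
#' and targetless assay types (\code{cell_based}, \code{none}) carrying no
#' target identifiers.
#'
#' @param assays a data.frame-like assay metadata table.
#' @return the validated table as a \code{data.table} (invisibly usable).
#' @export
validate_assay_meta <- function(assays) {
  dt <- as.data.table(assays)
  need <- c("assay_id", "category", "substance_type", "screening_stage",
            "on_hold", "target_ids", "target_type", "activity_specified",
            "has_active_outcome")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("assay metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(dt$assay_id) || any(!nzchar(dt$assay_id)))
    stop("assay_id must be non-empty", call. = FALSE)
  if (anyDuplicated(dt$assay_id))
    stop("duplicate assay_id: ",
         paste(unique(dt$assay_id[duplicated(dt$assay_id)]), collapse = ", "),
         call. = FALSE)
  chk <- function(col, levels) {
    bad <- setdiff(unique(dt[[col]]), levels)
    if (length(bad))
      stop(sprintf("invalid %s value(s): %s", col, paste(bad, collapse = ", ")),
           call. = FALSE)
  }
  chk("category", .assay_categories)
  chk("substance_type", .substance_types)
  chk("screening_stage", .screening_stages)
  chk("target_type", .target_types)
  for (col in c("on_hold", "activity_specified", "has_active_outcome"))
    if (anyNA(dt[[col]]))
      stop("column ", col, " must be TRUE/FALSE with no missing values",
           call. = FALSE)
  targetless <- dt$target_type %in% c("cell_based", "none")
  if (any(targetless & .n_target_ids(dt$target_ids) > 0))
    stop("cell_based/none assays must have empty target_ids: ",
         paste(dt$assay_id[targetless & .n_target_ids(dt$target_ids) > 0],
               collapse = ", "), call. = FALSE)
  dt[]
}

#' Read assay metadata from a delimited text file
#'
#' Columns are located via the dialect's \code{assay_columns} mapping.
#' Enumeration values are normalized case-insensitively (so \code{"RNAi"}
#' becomes \code{rnai}, \code{"confirmatory, dose-response"} becomes
#' \code{confirmatory_dose_response}); values outside the vocabulary are
#' mapped to \code{"other"} with a warning. A duplicated assay identifier is
#' an error.
#'
#' @param path path to the metadata file.
#' @param dialect a dialect list, see [default_dialect()].
#' @return a validated assay metadata \code{data.table}.
#' @export
read_assay_meta <- function(path, dialect = default_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- fread(path, sep = dialect$sep, colClasses = "character",
               header = TRUE)
  cols <- dialect$assay_columns
  miss <- cols[!(cols %in% names(raw))]
  if (length(miss))
    stop("assay metadata file lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  syn_target <- c(protein_target = "protein", cell = "cell_based",
                  cellbased = "cell_based")
  syn_target <- c(syn_target, stats::setNames("none", ""))
  syn_stage <- c(confirmatory = "confirmatory_dose_response",
                 dose_response = "confirmatory_dose_response",
                 primary = "primary_screening",
                 screening = "primary_screening")
  dt <- data.table(
    assay_id = raw[[cols[["assay_id"]]]],
    category = .map_enum(raw[[cols[["category"]]]], .assay_categories,
                         fallback = NULL, what = "category"),
    substance_type = .map_enum(raw[[cols[["substance_type"]]]],
                               .substance_types, what = "substance_type"),
    screening_stage = .map_enum(raw[[cols[["screening_stage"]]]],
                                .screening_stages, synonyms = syn_stage,
                                what = "screening_stage"),
    on_hold = .parse_logical(raw[[cols[["on_hold"]]]]),
    target_ids = ifelse(is.na(raw[[cols[["target_ids"]]]]), "",
                        raw[[cols[["target_ids"]]]]),
    target_type = .map_enum(raw[[cols[["target_type"]]]], .target_types,
                            synonyms = syn_target, what = "target_type"),
    activity_specified = .parse_logical(raw[[cols[["activity_specified"]]]]),
    has_active_outcome = .parse_logical(raw[[cols[["has_active_outcome"]]]])
  )
  validate_assay_meta(dt)
}

#' Construct an outcome record table
#'
#' One row per (compound, assay) observation. Duplicate pairs are permitted
#' on input and resolved later by [filter_outcomes()].
#'
#' @param cid compound identifiers (coerced to character).
#' @param assay_id assay identifiers.
#' @param outcome outcome labels from the closed vocabulary
#'   \code{active, inactive, inconclusive, unspecified, probe}.
#' @return a \code{data.table} of outcome records.
#' @export
outcome_records <- function(cid, assay_id, outcome) {
  dt <- data.table(cid = as.character(cid),
                   assay_id = as.character(assay_id),
                   outcome = as.character(outcome))
  bad <- setdiff(unique(dt$outcome), .outcome_levels)
  if (length(bad))
    stop("invalid outcome value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyNA(dt$cid) || any(!nzchar(dt$cid)) ||
      anyNA(dt$assay_id) || any(!nzchar(dt$assay_id)))
    stop("cid and assay_id must be non-empty", call. = FALSE)
  dt[]
}

#' Read outcome records from a delimited text file
#'
#' Outcome labels are mapped through the dialect's \code{outcome_map}, which
#' covers both text labels (case-insensitive) and numeric codes. Values with
#' no mapping are an error that lists the offending labels; missing compound
#' or assay identifiers are an error.
#'
#' @inheritParams read_assay_meta
#' @return a \code{data.table} of outcome records.
#' @export
read_outcomes <- function(path, dialect = default_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- fread(path, sep = dialect$sep, colClasses = "character",
               header = TRUE)
  cols <- dialect$outcome_columns
  miss <- cols[!(cols %in% names(raw))]
  if (length(miss))
    stop("outcome file lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0)
    return(outcome_records(character(), character(), character()))
  lab <- tolower(trimws(raw[[cols[["outcome"]]]]))
  unmapped <- setdiff(unique(lab), names(dialect$outcome_map))
  if (length(unmapped))
    stop("unmapped outcome label(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  outcome_records(cid = raw[[cols[["cid"]]]],
                  assay_id = raw[[cols[["assay_id"]]]],
                  outcome = unname(dialect$outcome_map[lab]))
}

#' Validate a compound profile table
#'
#' Every profile must satisfy, within each assay category,
#' \eqn{0 \le n_{targets} \le n_{active} \le n_{tested}} with integer counts.
#'
#' @param profiles a data.frame-like table with the seven profile columns.
#' @return the validated \code{data.table}.
#' @export
validate_profiles <- function(profiles) {
  dt <- as.data.table(profiles)
  miss <- setdiff(.profile_cols, names(dt))
  if (length(miss))
    stop("profile table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dt <- dt[, .SD, .SDcols = .profile_cols]
  dt[, cid := as.character(cid)]
  if (anyDuplicated(dt$cid))
    stop("duplicate cid in profiles", call. = FALSE)
  for (col in setdiff(.profile_cols, "cid")) {
    v <- dt[[col]]
    if (anyNA(v) || any(v < 0) || any(v != as.integer(v)))
      stop("profile column ", col, " must hold non-negative integers",
           call. = FALSE)
    dt[, (col) := as.integer(get(col))]
  }
  for (cat in .assay_categories) {
    nt <- dt[[paste0("n_tested_", cat)]]
    na <- dt[[paste0("n_active_", cat)]]
    ng <- dt[[paste0("n_targets_", cat)]]
    bad <- which(ng > na | na > nt)
    if (length(bad))
      stop(sprintf(
        "profile invariant n_targets <= n_active <= n_tested violated (%s) for cid: %s",
        cat, paste(head(dt$cid[bad], 5), collapse = ", ")), call. = FALSE)
  }
  dt[]
}

#' Write and read compound profile tables
#'
#' Profiles are persisted as tab-separated text with exactly the seven
#' profile columns, one row per compound, sorted by compound identifier so
#' output is stable. Writing refuses tables that violate the count
#' invariants; \code{read_profiles(write_profiles(x))} reproduces \code{x}
#' up to row order.
#'
#' @param profiles a validated profile table.
#' @param path output (input) file path.
#' @return \code{write_profiles} returns \code{path} invisibly;
#'   \code{read_profiles} returns the validated \code{data.table}.
#' @export
write_profiles <- function(profiles, path) {
  dt <- validate_profiles(profiles)
  setorder(dt, cid)
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = "cid"))
  validate_profiles(dt)
}

#' Read structures from a SMILES or SDF file
#'
#' SMILES files hold one structure per line, optionally followed by a
#' whitespace-separated name; unnamed structures are numbered. SDF input is
#' parsed with ChemmineR and converted back to SMILES. Returns the named
#' character vector of SMILES used by the PAINS module.
#'
#' @param path path to a \code{.smi}/plain SMILES file or an \code{.sdf} file.
#' @param format \code{"auto"} (by extension), \code{"smiles"} or \code{"sdf"}.
#' @return named character vector of SMILES strings (names are compound ids).
#' @export
read_structures <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smiles"
  if (format == "sdf") {
    sdf <- ChemmineR::read.SDFset(path)
    smi <- ChemmineR::sdf2smiles(sdf)
    out <- as.character(smi)
    names(out) <- ChemmineR::sdfid(sdf)
    return(out)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(stats::setNames(character(), character()))
  toks <- regmatches(lines, regexpr("\\S+", lines))
  rest <- trimws(sub("^\\S+\\s*", "", lines))
  nm <- ifelse(nzchar(rest), rest, paste0("S", seq_along(lines)))
  stats::setNames(toks, nm)
}
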