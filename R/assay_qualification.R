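#' Qualify primary assays
#'
#' From the primary assay pool only RNA-interference screens are removed:
#' every chemical primary screen is retained, including cell-based assays for
#' which no individual target is specified (those later contribute to assay
#' promiscuity but never to target promiscuity). Idempotent.
#'
#' @param assays an assay metadata table ([assay_meta()]/[read_assay_meta()]).
#' @return the qualifying rows as a \code{data.table}.
#' @export
qualify_primary <- function(assays) {
  dt <- validate_assay_meta(assays)
  out <- dt[category == "primary" & substance_type != "rnai"]
  .stage_log("qualify_primary", "%d of %d primary assays retained",
             nrow(out), sum(dt$category == "primary"))
  out[]
}

#' Qualify confirmatory assays
#'
#' Retains confirmatory assays in which chemical compounds were tested
#' against a single protein target with dose-response measurements: not on
#' hold, substance type chemical, screening stage confirmatory dose-response,
#' exactly one annotated target of type protein, a quantitative activity
#' readout specified, and at least one active outcome reported. Idempotent.
#'
#' @inheritParams qualify_primary
#' @return the qualifying rows as a \code{data.table}.
#' @export
qualify_confirmatory <- function(assays) {
  dt <- validate_assay_meta(assays)
  out <- dt[category == "confirmatory" &
              on_hold == FALSE &
              substance_type == "chemical" &
              screening_stage == "confirmatory_dose_response" &
              .n_target_ids(target_ids) == 1L &
              target_type == "protein" &
              activity_specified == TRUE &
              has_active_outcome == TRUE]
  .stage_log("qualify_confirmatory", "%d of %d confirmatory assays retained",
             nrow(out), sum(dt$category == "confirmatory"))
  out[]
}

#' Filter outcome records against a qualified assay set
#'
#' Keeps records whose assay is in the qualified set and whose outcome is an
#' unambiguous \code{active} or \code{inactive} call; \code{inconclusive},
#' \code{unspecified} and \code{probe} designations are discarded. Duplicate
#' (compound, assay) observations are collapsed to a single record, active if
#' any duplicate was active. The numbers of records dropped by assay
#' qualification, dropped by outcome vocabulary, and collapsed as duplicates
#' are logged and attached as attributes (\code{n_dropped_assay},
#' \code{n_dropped_outcome}, \code{n_collapsed}).
#'
#' @param records an outcome record table ([outcome_records()]/[read_outcomes()]).
#' @param qualified qualified assay metadata (unique \code{assay_id}).
#' @return a \code{data.table} with at most one record per (cid, assay_id)
#'   and outcomes restricted to \code{active}/\code{inactive}.
#' @export
filter_outcomes <- function(records, qualified) {
  rec <- as.data.table(records)
  qids <- unique(as.data.table(qualified)$assay_id)
  if (anyDuplicated(as.data.table(qualified)$assay_id))
    stop("qualified assay_ids must be unique", call. = FALSE)
  n0 <- nrow(rec)
  rec <- rec[assay_id %in% qids]
  n_assay_drop <- n0 - nrow(rec)
  n1 <- nrow(rec)
  rec <- rec[outcome %in% c("active", "inactive")]
  n_outcome_drop <- n1 - nrow(rec)
  n2 <- nrow(rec)
  out <- rec[, .(outcome = if (any(outcome == "active")) "active"
                           else "inactive"),
             by = .(cid, assay_id)]
  n_collapsed <- n2 - nrow(out)
  .stage_log("filter_outcomes",
             "%d in; %d dropped (unqualified assay), %d dropped (outcome), %d duplicate pairs collapsed; %d out",
             n0, n_assay_drop, n_outcome_drop, n_collapsed, nrow(out))
  setattr(out, "n_dropped_assay", n_assay_drop)
  setattr(out, "n_dropped_outcome", n_outcome_drop)
  setattr(out, "n_collapsed", n_collapsed)
  out[]
}
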