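## Synthetic screening corpus with recorded ground truth. The generator
## emulates the statistical shape of a large public screening collection at
## desk scale: per-compound assay counts driven by per-category coverage,
## overwhelmingly inactive records, a sizeable never-active (dark) fraction,
## and a small frequent-hitter tail carrying interference substructures.

# clean structures cycled over ordinary compounds
.clean_smiles_pool <- c(
  "CCO", "CCCO", "CCNC", "c1ccccc1", "CC(C)O", "CCOCC", "CCCCC",
  "CCN(CC)CC", "c1ccncc1", "CC(=O)NC", "COc1ccccc1", "CC(C)CC(C)C"
)

# interference-substructure carriers for injected frequent hitters
# (rhodanine, quinone, catechol cores embedded in small molecules)
.pains_smiles_pool <- c(
  "CC1SC(=S)NC1=O", "O=C1C=CC(=O)C=C1", "Cc1ccc(O)c(O)c1"
)

#' Configure the synthetic screening-data generator
#'
#' Defaults are scaled-down analogues of a large public screening corpus:
#' roughly 500 assays over a couple of hundred targets, 2-5 assays per
#' target (so assay promiscuity can exceed target promiscuity), per-pair
#' testing coverage 0.24 primary / 0.047 confirmatory (the tested-assays
#' to available-assays ratio of the corpus being emulated, putting each
#' compound in on the order of a hundred assays here), a ~1% per-tested-
#' assay activity rate so records are overwhelmingly inactive, 27% of
#' compounds forced dark, and a 0.2% frequent-hitter tail with a 50% hit
#' rate. A few RNAi primary screens and disqualified confirmatory assays
#' are included so that assay qualification has work to do; their records
#' never enter the ground-truth counts.
#'
#' @param seed integer seed; mandatory, all generation is reproducible.
#' @param n_compounds number of compounds.
#' @param n_targets_primary,n_targets_confirmatory number of targets with
#'   targeted assays per category.
#' @param assays_per_target integer constant or length-2 range (inclusive)
#'   of assays per target.
#' @param n_cell_based_primary number of targetless cell-based primary
#'   assays (assay promiscuity only).
#' @param n_rnai_primary number of RNAi primary screens (disqualified).
#' @param n_unqualified_confirmatory number of confirmatory assays each
#'   violating one qualification rule.
#' @param coverage_primary,coverage_confirmatory either a probability that a
#'   compound is tested in a given assay (independent per pair), or a
#'   length-2 integer range: each compound is tested in a uniformly drawn
#'   number of distinct assays of that category (per-compound count mode).
#' @param p_active per-tested-assay activity probability for ordinary
#'   compounds.
#' @param dark_fraction fraction of compounds forced inactive everywhere.
#' @param hitter_fraction fraction of compounds drawn as frequent hitters.
#' @param p_hitter per-tested-assay activity probability for hitters.
#' @param pains_inject SMILES pool assigned to hitter compounds (each
#'   carries a known interference substructure by default).
#' @return a validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(seed,
                             n_compounds = 2000L,
                             n_targets_primary = 100L,
                             n_targets_confirmatory = 120L,
                             assays_per_target = c(2L, 5L),
                             n_cell_based_primary = 50L,
                             n_rnai_primary = 5L,
                             n_unqualified_confirmatory = 5L,
                             coverage_primary = 0.24,
                             coverage_confirmatory = 0.047,
                             p_active = 0.01,
                             dark_fraction = 0.27,
                             hitter_fraction = 0.002,
                             p_hitter = 0.5,
                             pains_inject = .pains_smiles_pool) {
  if (missing(seed) || length(seed) != 1 || is.na(seed) ||
      seed != as.integer(seed))
    stop("an integer seed is mandatory", call. = FALSE)
  cfg <- list(seed = as.integer(seed),
              n_compounds = as.integer(n_compounds),
              n_targets_primary = as.integer(n_targets_primary),
              n_targets_confirmatory = as.integer(n_targets_confirmatory),
              assays_per_target = as.integer(assays_per_target),
              n_cell_based_primary = as.integer(n_cell_based_primary),
              n_rnai_primary = as.integer(n_rnai_primary),
              n_unqualified_confirmatory = as.integer(n_unqualified_confirmatory),
              coverage_primary = coverage_primary,
              coverage_confirmatory = coverage_confirmatory,
              p_active = p_active, dark_fraction = dark_fraction,
              hitter_fraction = hitter_fraction, p_hitter = p_hitter,
              pains_inject = pains_inject)
  chk_frac <- function(x, nm) {
    if (!(length(x) == 1 && is.finite(x) && x >= 0 && x <= 1))
      stop(nm, " must be a fraction in [0, 1]", call. = FALSE)
  }
  for (nm in c("p_active", "dark_fraction", "hitter_fraction", "p_hitter"))
    chk_frac(cfg[[nm]], nm)
  if (cfg$dark_fraction + cfg$hitter_fraction > 1)
    stop("dark_fraction + hitter_fraction must be <= 1", call. = FALSE)
  for (nm in c("coverage_primary", "coverage_confirmatory")) {
    cv <- cfg[[nm]]
    if (length(cv) == 1) chk_frac(cv, nm)
    else if (!(length(cv) == 2 && all(cv == as.integer(cv)) &&
               cv[1] >= 0 && cv[1] <= cv[2]))
      stop(nm, " must be a probability or an integer count range",
           call. = FALSE)
  }
  if (!(length(cfg$assays_per_target) %in% 1:2) ||
      any(cfg$assays_per_target < 1))
    stop("assays_per_target must be a positive constant or range",
         call. = FALSE)
  if (cfg$n_compounds < 1) stop("n_compounds must be >= 1", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

# sample() treats a length-1 x as 1:x; guard against that
.sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(seq(lo, hi), n, replace = TRUE)
}

# draw assays-per-target counts for n targets
.apt_draw <- function(spec, n) {
  if (length(spec) == 1) rep(spec, n)
  else .sample_range(spec[1], spec[2], n)
}

# which compounds (of n) are tested in one assay / how many assays each
.draw_tested <- function(coverage, n_compounds, assay_ids) {
  # returns list per assay of tested compound indices
  if (length(coverage) == 1) {
    lapply(seq_along(assay_ids),
           function(j) which(runif(n_compounds) < coverage))
  } else {
    # per-compound count mode: each compound picks its assay set
    k <- .sample_range(coverage[1], coverage[2], n_compounds)
    k <- pmin(k, length(assay_ids))
    per_assay <- vector("list", length(assay_ids))
    picks <- lapply(seq_len(n_compounds),
                    function(i) sample.int(length(assay_ids), k[i]))
    for (i in seq_len(n_compounds))
      for (j in picks[[i]])
        per_assay[[j]] <- c(per_assay[[j]], i)
    per_assay
  }
}

#' Generate a synthetic screening corpus with ground truth
#'
#' Produces assay metadata, outcome records, compound structures and a
#' ground-truth object, all deterministic for a fixed seed. Each targeted
#' assay annotates exactly one target; cell-based primaries are targetless.
#' Dark compounds never yield an active record; hitters hit with
#' \code{p_hitter}; everyone else with \code{p_active}. The truth object
#' records each compound's designed class and its realized tested/active/
#' target counts over the qualifying assays, tabulated with base-R code
#' independent of [build_profiles()] so end-to-end recovery is a genuine
#' cross-check.
#'
#' @param config a [synthetic_config()].
#' @return list of class \code{synthetic_screen} with elements
#'   \code{assays} (metadata table), \code{records} (outcome records over
#'   all assays, active/inactive only), \code{structures} (named SMILES),
#'   and \code{truth} (list: \code{config}, \code{classes} data.table
#'   (cid, class), \code{counts} profile-shaped data.table).
#' @export
generate_screening_data <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)

  ## --- assays -----------------------------------------------------------
  apt_p <- .apt_draw(cfg$assays_per_target, cfg$n_targets_primary)
  prim_tgt <- assay_meta(
    assay_id = sprintf("PA%04d", seq_len(sum(apt_p))),
    category = "primary",
    target_ids = rep(sprintf("PT%03d", seq_len(cfg$n_targets_primary)), apt_p),
    target_type = "protein", activity_specified = FALSE)
  prim_cell <- if (cfg$n_cell_based_primary > 0) assay_meta(
    assay_id = sprintf("PC%04d", seq_len(cfg$n_cell_based_primary)),
    category = "primary", target_ids = "", target_type = "cell_based",
    activity_specified = FALSE) else NULL
  prim_rnai <- if (cfg$n_rnai_primary > 0) assay_meta(
    assay_id = sprintf("PR%04d", seq_len(cfg$n_rnai_primary)),
    category = "primary", substance_type = "rnai", target_ids = "",
    target_type = "other", activity_specified = FALSE) else NULL
  apt_c <- .apt_draw(cfg$assays_per_target, cfg$n_targets_confirmatory)
  conf_ok <- assay_meta(
    assay_id = sprintf("CA%04d", seq_len(sum(apt_c))),
    category = "confirmatory",
    target_ids = rep(sprintf("CT%03d", seq_len(cfg$n_targets_confirmatory)),
                     apt_c),
    target_type = "protein")
  conf_bad <- if (cfg$n_unqualified_confirmatory > 0) {
    n <- cfg$n_unqualified_confirmatory
    flaw <- rep_len(c("hold", "two_targets", "cell", "stage", "no_activity"), n)
    assay_meta(
      assay_id = sprintf("CX%04d", seq_len(n)),
      category = "confirmatory",
      on_hold = flaw == "hold",
      target_ids = ifelse(flaw == "two_targets", "CT001;CT002",
                          ifelse(flaw == "cell", "", "CT001")),
      target_type = ifelse(flaw == "cell", "cell_based", "protein"),
      screening_stage = ifelse(flaw == "stage", "other",
                               "confirmatory_dose_response"),
      activity_specified = flaw != "no_activity")
  } else NULL
  assays <- rbindlist(list(prim_tgt, prim_cell, prim_rnai, conf_ok, conf_bad))
  qualified_ids <- c(prim_tgt$assay_id,
                     if (!is.null(prim_cell)) prim_cell$assay_id,
                     conf_ok$assay_id)

  ## --- compounds --------------------------------------------------------
  n <- cfg$n_compounds
  cids <- sprintf("CID%06d", seq_len(n))
  n_dark <- round(n * cfg$dark_fraction)
  n_hit <- round(n * cfg$hitter_fraction)
  cls <- rep("normal", n)
  perm <- sample.int(n)
  cls[perm[seq_len(n_dark)]] <- "dark"
  if (n_hit > 0) cls[perm[n_dark + seq_len(n_hit)]] <- "hitter"
  p_act <- c(dark = 0, normal = cfg$p_active, hitter = cfg$p_hitter)[cls]

  ## --- records ----------------------------------------------------------
  gen_records <- function(assay_tbl, coverage) {
    if (is.null(assay_tbl) || nrow(assay_tbl) == 0) return(NULL)
    tested <- .draw_tested(coverage, n, assay_tbl$assay_id)
    parts <- vector("list", nrow(assay_tbl))
    for (j in seq_len(nrow(assay_tbl))) {
      idx <- tested[[j]]
      if (!length(idx)) next
      act <- runif(length(idx)) < p_act[idx]
      parts[[j]] <- data.table(cid = cids[idx],
                               assay_id = assay_tbl$assay_id[j],
                               outcome = ifelse(act, "active", "inactive"))
    }
    rbindlist(parts)
  }
  prim_all <- rbindlist(list(prim_tgt, prim_cell, prim_rnai))
  records <- rbindlist(list(gen_records(prim_all, cfg$coverage_primary),
                            gen_records(rbindlist(list(conf_ok, conf_bad)),
                                        cfg$coverage_confirmatory)))

  ## --- structures -------------------------------------------------------
  structures <- .clean_smiles_pool[(seq_len(n) - 1L) %%
                                     length(.clean_smiles_pool) + 1L]
  if (n_hit > 0 && length(cfg$pains_inject)) {
    hit_idx <- which(cls == "hitter")
    structures[hit_idx] <- cfg$pains_inject[(seq_along(hit_idx) - 1L) %%
                                              length(cfg$pains_inject) + 1L]
  }
  names(structures) <- cids

  ## --- ground truth (base-R tabulation, independent of build_profiles) --
  q <- records[records$assay_id %in% qualified_ids, ]
  acat <- stats::setNames(assays$category, assays$assay_id)
  ntid <- .n_target_ids(assays$target_ids)
  atgt <- stats::setNames(ifelse(ntid == 1L, assays$target_ids, NA_character_),
                          assays$assay_id)
  rcat <- unname(acat[q$assay_id])
  cnt <- function(sel) {
    t <- table(factor(q$cid[sel], levels = cids))
    as.integer(t)
  }
  uniq_tgt <- function(sel) {
    sub_cid <- q$cid[sel]
    sub_tgt <- unname(atgt[q$assay_id[sel]])
    ok <- !is.na(sub_tgt)
    key <- paste(sub_cid[ok], sub_tgt[ok], sep = "\r")
    first <- !duplicated(key)
    t <- table(factor(sub_cid[ok][first], levels = cids))
    as.integer(t)
  }
  is_act <- q$outcome == "active"
  counts <- data.table(
    cid = cids,
    n_tested_primary = cnt(rcat == "primary"),
    n_tested_confirmatory = cnt(rcat == "confirmatory"),
    n_active_primary = cnt(rcat == "primary" & is_act),
    n_active_confirmatory = cnt(rcat == "confirmatory" & is_act),
    n_targets_primary = uniq_tgt(rcat == "primary" & is_act),
    n_targets_confirmatory = uniq_tgt(rcat == "confirmatory" & is_act))

  structure(list(
    assays = assays, records = records, structures = structures,
    truth = list(config = cfg,
                 classes = data.table(cid = cids, class = cls),
                 counts = counts)),
    class = "synthetic_screen")
}

#' Recovery report: pipeline outputs versus generator ground truth
#'
#' Compares the profiles computed by the pipeline with the counts the
#' generator recorded while producing the data. Reports the exact-match rate
#' of the six per-compound counts (1.0 means the pipeline reproduced every
#' ground-truth count), dark-set precision and recall per scope against the
#' compounds whose ground-truth active counts are zero, and the recall of
#' designed frequent hitters at the given assay-promiscuity threshold.
#'
#' @param truth the \code{truth} element of [generate_screening_data()]
#'   output (or the whole \code{synthetic_screen}).
#' @param profiles profiles computed by [build_profiles()] on the generated
#'   records after qualification/filtering.
#' @param hitter_threshold assay-promiscuity threshold for hitter detection;
#'   default is the smallest realized hitter degree, so recall 1.0 is the
#'   correct-pipeline expectation.
#' @return list of class \code{recovery_report}: \code{profile_match_rate},
#'   \code{dark} (per-scope precision/recall table), \code{hitter_recall},
#'   \code{hitter_threshold}.
#' @export
recovery_report <- function(truth, profiles, hitter_threshold = NULL) {
  if (inherits(truth, "synthetic_screen")) truth <- truth$truth
  prof <- validate_profiles(profiles)
  tc <- validate_profiles(truth$counts)
  # profiles omit compounds with no qualified records; truth keeps them
  tested <- tc[n_tested_primary + n_tested_confirmatory > 0]
  m <- merge(tested, prof, by = "cid", all = TRUE, suffixes = c(".t", ".p"))
  cols <- setdiff(.profile_cols, "cid")
  same <- rep(TRUE, nrow(m))
  for (col in cols) {
    a <- m[[paste0(col, ".t")]]
    b <- m[[paste0(col, ".p")]]
    same <- same & !is.na(a) & !is.na(b) & a == b
  }
  match_rate <- mean(same)

  dark_pr <- rbindlist(lapply(
    c("primary", "confirmatory", "both_categories"), function(sc) {
      pred <- consistently_inactive(prof, sc)
      truthset <- consistently_inactive(tested, sc)
      tp <- length(intersect(pred, truthset))
      data.table(scope = sc,
                 n_true = length(truthset), n_pred = length(pred),
                 precision = if (length(pred)) tp / length(pred) else NA_real_,
                 recall = if (length(truthset)) tp / length(truthset)
                          else NA_real_)
    }))

  hit_cids <- truth$classes$cid[truth$classes$class == "hitter"]
  hitter_recall <- NA_real_
  if (length(hit_cids)) {
    tdeg <- pmax(tc$n_active_primary,
                 tc$n_active_confirmatory)[match(hit_cids, tc$cid)]
    if (is.null(hitter_threshold))
      hitter_threshold <- max(1L, min(tdeg))
    pdeg <- pmax(prof$n_active_primary,
                 prof$n_active_confirmatory)[match(hit_cids, prof$cid)]
    pdeg[is.na(pdeg)] <- 0L
    hitter_recall <- mean(pdeg >= hitter_threshold)
  }
  structure(list(profile_match_rate = match_rate, dark = dark_pr,
                 hitter_recall = hitter_recall,
                 hitter_threshold = hitter_threshold),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("profile exact-match rate: %.4f\n", x$profile_match_rate))
  print(x$dark)
  cat(sprintf("hitter recall at threshold %s: %s\n",
              format(x$hitter_threshold), format(x$hitter_recall)))
  invisible(x)
}
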