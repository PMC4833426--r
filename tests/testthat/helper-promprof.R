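## shared builders and independent oracles

# the hypothetical compound C: tested in assays 1-5 (target T1) and 6-10
# (target T2), active in assays 1, 2, 3, 8 and 10
worked_example <- function(cid = "C", category = "primary") {
  active <- c(1, 2, 3, 8, 10)
  list(
    assays = assay_meta(
      assay_id = paste0("A", 1:10),
      category = category,
      target_ids = rep(c("T1", "T2"), each = 5),
      target_type = "protein",
      activity_specified = category == "confirmatory"),
    records = outcome_records(
      cid = rep(cid, 10),
      assay_id = paste0("A", 1:10),
      outcome = ifelse(1:10 %in% active, "active", "inactive"))
  )
}

# explicit linear interpolation at ranks (n-1)*q, independent of
# stats::quantile
quartile_oracle <- function(x, probs = c(0, .25, .5, .75, 1)) {
  s <- sort(x)
  n <- length(s)
  vapply(probs, function(q) {
    h <- (n - 1) * q
    lo <- floor(h)
    if (lo + 1 >= n) return(s[n])
    s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
  }, numeric(1))
}

# brute-force per-compound counting from raw tables, independent of
# build_profiles' grouped aggregation
profile_oracle <- function(records, assays) {
  cat_of <- setNames(assays$category, assays$assay_id)
  tgt_of <- setNames(
    ifelse(!grepl(";", assays$target_ids) & nzchar(assays$target_ids),
           assays$target_ids, NA_character_),
    assays$assay_id)
  out <- list()
  for (cc in sort(unique(records$cid))) {
    r <- records[records$cid == cc, ]
    row <- list(cid = cc)
    for (cat in c("primary", "confirmatory")) {
      rc <- r[cat_of[r$assay_id] == cat, ]
      act <- rc[rc$outcome == "active", ]
      row[[paste0("n_tested_", cat)]] <- length(unique(rc$assay_id))
      row[[paste0("n_active_", cat)]] <- length(unique(act$assay_id))
      tg <- tgt_of[act$assay_id]
      row[[paste0("n_targets_", cat)]] <- length(unique(tg[!is.na(tg)]))
    }
    out[[cc]] <- as.data.frame(row)
  }
  res <- do.call(rbind, out)
  res[, c("cid", "n_tested_primary", "n_tested_confirmatory",
          "n_active_primary", "n_active_confirmatory",
          "n_targets_primary", "n_targets_confirmatory")]
}

# independent substructure oracle: RDKit through the system python
rdkit_available <- local({
  ans <- NULL
  function() {
    if (is.null(ans)) {
      ans <<- tryCatch(
        system2("python", c("-c", shQuote("import rdkit")),
                stdout = FALSE, stderr = FALSE) == 0,
        error = function(e) FALSE)
    }
    ans
  }
})

rdkit_matches <- function(smiles, smarts) {
  stopifnot(length(smiles) == length(smarts))
  inp <- paste(smiles, smarts, sep = "\t", collapse = "\n")
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit import RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "for line in sys.stdin.read().splitlines():",
    "    smi, sma = line.split('\\t')",
    "    m = Chem.MolFromSmiles(smi)",
    "    p = Chem.MolFromSmarts(sma)",
    "    print(int(m is not None and p is not None and m.HasSubstructMatch(p)))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script)), input = inp,
                 stdout = TRUE, stderr = FALSE)
  as.logical(as.integer(out))
}

# a small qualified corpus plus its profiles, reused across tests
small_screen <- function(seed = 11, n = 400, ...) {
  cfg <- synthetic_config(seed = seed, n_compounds = n,
                          n_targets_primary = 15L,
                          n_targets_confirmatory = 20L,
                          n_cell_based_primary = 8L, ...)
  gen <- generate_screening_data(cfg)
  q <- rbind(qualify_primary(gen$assays), qualify_confirmatory(gen$assays))
  filtered <- filter_outcomes(gen$records, q)
  profiles <- build_profiles(filtered, q)
  list(gen = gen, qualified = q, filtered = filtered, profiles = profiles)
}

quiet <- function(expr) suppressMessages(expr)
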