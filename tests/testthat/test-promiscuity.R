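test_that("worked example: assay promiscuity five, target promiscuity two", {
  w <- worked_example()
  p <- build_profiles(w$records, w$assays)
  expect_equal(unname(assay_promiscuity(p, "primary")), 5L)
  expect_equal(unname(target_promiscuity(p, "primary")), 2L)
})

test_that("14 actives over two targets give assay 14, target still two", {
  am <- assay_meta(assay_id = sprintf("B%02d", 1:50),
                   target_ids = rep(c("T1", "T2"), each = 25))
  active_in <- c(1:7, 26:32)   # 14 assays split across the two targets
  rec <- outcome_records(cid = rep("K", 50), assay_id = sprintf("B%02d", 1:50),
                         outcome = ifelse(1:50 %in% active_in,
                                          "active", "inactive"))
  p <- build_profiles(rec, am)
  expect_equal(unname(assay_promiscuity(p, "primary")), 14L)
  expect_equal(unname(target_promiscuity(p, "primary")), 2L)
})

test_that("target promiscuity matches a brute-force active-pair oracle", {
  set.seed(91)
  for (rep_i in 1:50) {
    n_assay <- sample(3:12, 1)
    am <- assay_meta(assay_id = paste0("A", seq_len(n_assay)),
                     target_ids = paste0("T", sample(1:4, n_assay,
                                                     replace = TRUE)))
    rec <- outcome_records(
      cid = "C1", assay_id = am$assay_id,
      outcome = sample(c("active", "inactive"), n_assay, replace = TRUE))
    p <- build_profiles(rec, am)
    # oracle: materialize active (assay -> target) pairs, count targets
    act <- rec$assay_id[rec$outcome == "active"]
    tgts <- am$target_ids[match(act, am$assay_id)]
    expect_equal(unname(target_promiscuity(p, "primary")),
                 length(unique(tgts)))
    expect_equal(unname(assay_promiscuity(p, "primary")), length(act))
  }
})

test_that("promiscuity chain target <= assay <= tested holds universally", {
  s <- small_screen(seed = 92, hitter_fraction = 0.01)
  for (cat in c("primary", "confirmatory")) {
    ap <- assay_promiscuity(s$profiles, cat)
    tp <- target_promiscuity(s$profiles, cat)
    tested <- s$profiles[[paste0("n_tested_", cat)]]
    expect_true(all(tp <= ap))
    expect_true(all(ap <= tested))
  }
})

test_that("summaries cover actives only with exact small-sample statistics", {
  prof <- data.frame(cid = paste0("C", 1:5),
                     n_tested_primary = 10L,
                     n_tested_confirmatory = 0L,
                     n_active_primary = c(1L, 1L, 2L, 4L, 0L),
                     n_active_confirmatory = 0L,
                     n_targets_primary = c(1L, 1L, 1L, 1L, 0L),
                     n_targets_confirmatory = 0L)
  s <- summarize_promiscuity(prof, "primary", "assay")
  expect_equal(s$n_active_compounds, 4)   # the degree-0 compound is excluded
  expect_equal(s$mean, 2.0)
  expect_equal(s$median, 1.5)
  expect_equal(sum(s$degree_histogram$count), s$n_active_compounds)
  expect_equal(sum(s$degree_histogram$pct), 100)
  # degenerate cohort: every active compound hits exactly one target
  st <- summarize_promiscuity(prof, "primary", "target")
  expect_equal(st$mean, 1.0)
  expect_equal(st$median, 1.0)
  # no actives at all -> error
  prof0 <- prof
  prof0$n_active_primary <- 0L
  prof0$n_targets_primary <- 0L
  expect_error(summarize_promiscuity(prof0, "primary", "assay"), "no compounds")
})

test_that("shifted-Poisson degrees are recovered within 3 standard errors", {
  set.seed(93)
  lambda <- 2.5
  n <- 4000
  deg <- stats::rpois(n, lambda) + 1L
  prof <- data.frame(cid = sprintf("C%05d", 1:n),
                     n_tested_primary = max(deg) + 1L,
                     n_tested_confirmatory = 0L,
                     n_active_primary = deg,
                     n_active_confirmatory = 0L,
                     n_targets_primary = 0L,
                     n_targets_confirmatory = 0L)
  s <- summarize_promiscuity(prof, "primary", "assay")
  se <- sqrt(lambda / n)
  expect_lt(abs(s$mean - (lambda + 1)), 3 * se)
})

test_that("an injected frequent-hitter tail pulls the mean above the median", {
  s <- small_screen(seed = 94, n = 800, hitter_fraction = 0.01)
  sm <- summarize_promiscuity(s$profiles, "primary", "assay")
  expect_gt(sm$mean, sm$median)
})

test_that("box statistics give exact five-number summaries on odd samples", {
  prof <- data.frame(cid = paste0("C", 1:5),
                     n_tested_primary = 10L, n_tested_confirmatory = 0L,
                     n_active_primary = c(1L, 2L, 3L, 4L, 5L),
                     n_active_confirmatory = 0L,
                     n_targets_primary = 0L, n_targets_confirmatory = 0L)
  b <- binned_box_stats(prof, "primary", "assay",
                        bins = data.frame(lower = 0, upper = 20))
  expect_equal(unlist(b[, c("min", "q1", "median", "q3", "max")]),
               c(min = 1, q1 = 2, median = 3, q3 = 4, max = 5))
  expect_equal(b$n, 5L)
})

test_that("box statistics agree with the interpolation oracle on random bins", {
  set.seed(95)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    deg <- sample(1:30, n, replace = TRUE)
    prof <- data.frame(cid = sprintf("C%03d", seq_len(n)),
                       n_tested_primary = 50L, n_tested_confirmatory = 0L,
                       n_active_primary = as.integer(deg),
                       n_active_confirmatory = 0L,
                       n_targets_primary = 0L, n_targets_confirmatory = 0L)
    b <- binned_box_stats(prof, "primary", "assay",
                          bins = data.frame(lower = 0, upper = 100))
    expect_equal(unname(unlist(b[, c("min", "q1", "median", "q3", "max")])),
                 quartile_oracle(deg))
    # five-number ordering chain
    expect_true(b$min <= b$q1 && b$q1 <= b$median &&
                  b$median <= b$q3 && b$q3 <= b$max)
  }
})

test_that("box bins validate ordering and omit empty bins", {
  prof <- data.frame(cid = "C1",
                     n_tested_primary = 10L, n_tested_confirmatory = 0L,
                     n_active_primary = 2L, n_active_confirmatory = 0L,
                     n_targets_primary = 0L, n_targets_confirmatory = 0L)
  expect_error(binned_box_stats(prof, "primary", "assay",
                                bins = data.frame(lower = c(0, 5),
                                                  upper = c(10, 15))),
               "non-overlapping")
  expect_error(binned_box_stats(prof, "primary", "assay",
                                bins = data.frame(lower = 5, upper = 5)),
               "lower < upper")
  b <- quiet(binned_box_stats(prof, "primary", "assay",
                              bins = data.frame(lower = c(0, 20),
                                                upper = c(20, 40))))
  expect_equal(nrow(b), 1)   # the empty [20,40) bin is omitted
})
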