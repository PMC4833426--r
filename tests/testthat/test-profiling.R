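test_that("profiles reproduce the two-target worked example", {
  w <- worked_example()
  p <- build_profiles(w$records, w$assays)
  expect_equal(nrow(p), 1)
  expect_equal(p$n_tested_primary, 10L)
  expect_equal(p$n_active_primary, 5L)
  expect_equal(p$n_targets_primary, 2L)
  expect_equal(p$n_tested_confirmatory, 0L)
})

test_that("cell-based assays count as tested/active but never as targets", {
  am <- rbind(assay_meta("P1", category = "primary", target_ids = "",
                         target_type = "cell_based"),
              assay_meta("P2", category = "primary", target_ids = "T1"))
  rec <- outcome_records(cid = c("C1", "C1"), assay_id = c("P1", "P2"),
                         outcome = c("active", "inactive"))
  p <- build_profiles(rec, am)
  expect_equal(p$n_active_primary, 1L)
  expect_equal(p$n_targets_primary, 0L)
  # multi-target assays likewise contribute no target count
  am2 <- assay_meta("P3", category = "primary", target_ids = "T1;T2")
  rec2 <- outcome_records("C1", "P3", "active")
  p2 <- build_profiles(rec2, am2)
  expect_equal(p2$n_active_primary, 1L)
  expect_equal(p2$n_targets_primary, 0L)
})

test_that("all-inactive compounds profile to zero actives and targets", {
  w <- worked_example()
  rec <- outcome_records("D", paste0("A", 1:10), "inactive")
  p <- build_profiles(rec, w$assays)
  expect_equal(p$n_active_primary, 0L)
  expect_equal(p$n_targets_primary, 0L)
})

test_that("a record referencing an unknown assay is an error", {
  w <- worked_example()
  rec <- outcome_records("C", "A99", "active")
  expect_error(build_profiles(rec, w$assays), "unknown assay")
})

test_that("profiles match a brute-force oracle on a random small corpus", {
  s <- small_screen(seed = 33, n = 60)
  oracle <- profile_oracle(as.data.frame(s$filtered),
                           as.data.frame(s$qualified))
  got <- as.data.frame(s$profiles)
  rownames(oracle) <- NULL
  expect_equal(got, oracle, ignore_attr = TRUE)
})

test_that("partition sets are disjoint and satisfy the union identities", {
  prof <- data.frame(cid = c("X1", "X2", "X3"),
                     n_tested_primary = c(3L, 4L, 0L),
                     n_tested_confirmatory = c(2L, 0L, 1L),
                     n_active_primary = 0L, n_active_confirmatory = 0L,
                     n_targets_primary = 0L, n_targets_confirmatory = 0L)
  part <- partition_compounds(prof)
  expect_equal(part$both, "X1")
  expect_equal(part$primary_only, "X2")
  expect_equal(part$confirmatory_only, "X3")

  s <- small_screen(seed = 44)
  part <- partition_compounds(s$profiles)
  expect_length(intersect(part$both, part$primary_only), 0)
  expect_length(intersect(part$both, part$confirmatory_only), 0)
  expect_equal(length(part$both) + length(part$primary_only),
               sum(s$profiles$n_tested_primary > 0))
  expect_equal(length(part$both) + length(part$confirmatory_only),
               sum(s$profiles$n_tested_confirmatory > 0))
})

test_that("partition recovers one-only counts by set algebra", {
  # |primary_only| = |primary total| - |both|, as in the full-scale census
  # 836,585 - 437,257 = 399,328 (and 457,842 - 437,257 = 20,585)
  expect_equal(836585 - 437257, 399328)
  expect_equal(457842 - 437257, 20585)
  s <- small_screen(seed = 45)
  part <- partition_compounds(s$profiles)
  expect_equal(length(part$primary_only),
               sum(s$profiles$n_tested_primary > 0) - length(part$both))
})

test_that("assay frequency summarizes mean, median and a conserving histogram", {
  prof <- data.frame(cid = c("X1", "X2", "X3"),
                     n_tested_primary = c(10L, 20L, 30L),
                     n_tested_confirmatory = c(0L, 0L, 0L),
                     n_active_primary = 0L, n_active_confirmatory = 0L,
                     n_targets_primary = 0L, n_targets_confirmatory = 0L)
  fs <- assay_frequency(prof, "primary", bin_width = 10L)
  expect_equal(fs$mean, 20)
  expect_equal(fs$median, 20)
  expect_equal(sum(fs$histogram$count), 3)
  # median of an even count averages the central pair
  prof2 <- rbind(prof, within(prof[1, ], { cid <- "X4"
                                           n_tested_primary <- 40L }))
  expect_equal(assay_frequency(prof2, "primary")$median, 25)
  expect_error(assay_frequency(prof[0, ], "primary"), "empty")
  expect_error(assay_frequency(prof, "primary", bin_width = 0), "positive")
})

test_that("combined mean equals primary mean plus confirmatory mean", {
  s <- small_screen(seed = 46)
  fp <- assay_frequency(s$profiles, "primary")
  fc <- assay_frequency(s$profiles, "confirmatory")
  fb <- assay_frequency(s$profiles, "combined")
  expect_equal(fb$mean, fp$mean + fc$mean)
  # histogram conservation at a larger simulated size
  expect_equal(sum(fb$histogram$count), nrow(s$profiles))
})

test_that("dark censuses contain exactly the tested-but-never-active compounds", {
  prof <- data.frame(
    cid = c("D1", "A1", "B1", "N1"),
    n_tested_primary = c(700L, 10L, 5L, 0L),
    n_tested_confirmatory = c(3L, 2L, 0L, 4L),
    n_active_primary = c(0L, 1L, 0L, 0L),
    n_active_confirmatory = c(0L, 0L, 0L, 2L),
    n_targets_primary = c(0L, 1L, 0L, 0L),
    n_targets_confirmatory = c(0L, 0L, 0L, 1L))
  expect_setequal(consistently_inactive(prof, "primary"), c("D1", "B1"))
  expect_setequal(consistently_inactive(prof, "confirmatory"), c("D1", "A1"))
  expect_setequal(consistently_inactive(prof, "both_categories"), "D1")
  # any compound with an active outcome in scope is excluded
  s <- small_screen(seed = 47)
  for (sc in c("primary", "confirmatory", "both_categories")) {
    dark <- consistently_inactive(s$profiles, sc)
    active_any <- s$profiles$cid[s$profiles$n_active_primary > 0 |
                                   s$profiles$n_active_confirmatory > 0]
    if (sc != "both_categories") {
      col <- paste0("n_active_", sc)
      active_any <- s$profiles$cid[s$profiles[[col]] > 0]
    }
    expect_length(intersect(dark, active_any), 0)
  }
})

test_that("dark percentage of the both-subset rounds half away from zero", {
  expect_equal(round_half_up(100 * 119256 / 437257, 1), 27.3)
  expect_equal(round_half_up(27.25, 1), 27.3)
})
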