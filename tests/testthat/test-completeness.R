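test_that("coverage hits 100% and 0% in the two degenerate layouts", {
  p <- as_partition(c(a1 = "m1", a2 = "m1", b1 = "m2", b2 = "m2"))
  # every batch-2 specimen shares its MOTU with a batch-1 specimen
  cov <- coverage_stats(p, c(a1 = "1", a2 = "2", b1 = "1", b2 = "2"))
  expect_equal(cov$motu_coverage_pct, 100)
  expect_equal(cov$specimen_coverage_pct, 100)
  expect_equal(cov$n_new, 0L)
  # batch 2 entirely in MOTUs with no batch-1 members
  cov0 <- coverage_stats(p, c(a1 = "1", a2 = "1", b1 = "2", b2 = "2"))
  expect_equal(cov0$motu_coverage_pct, 0)
  expect_equal(cov0$specimen_coverage_pct, 0)
  expect_equal(cov0$new_motus, "m2")
  expect_equal(cov0$new_motu_specimen_count, 2L)
  expect_error(coverage_stats(p, c(a1 = "1", a2 = "1", b1 = "1", b2 = "1")),
               "empty")
  expect_error(coverage_stats(p, c(a1 = "1", a2 = "1", b1 = "1")), "without")
})

test_that("shared + new MOTUs always partition the batch-2-occupied set", {
  set.seed(61)
  for (trial in 1:10) {
    sim <- simulate_community(community_spec(
      n_species = sample(5:12, 1), total = 70, seed = 600 + trial))
    pd <- distance_matrix(sim$records, min_overlap = 100)
    p <- objective_cluster(pd, 0.05)
    b <- setNames(sim$records$batch, sim$records$specimen_id)
    cov <- coverage_stats(p, b)
    expect_equal(cov$n_shared + cov$n_new, cov$n_motus_occupied_by_batch2)
    expect_true(cov$motu_coverage_pct >= 0 && cov$motu_coverage_pct <= 100)
    expect_true(cov$specimen_coverage_pct >= 0 &&
                cov$specimen_coverage_pct <= 100)
    # new MOTUs contain only batch-2 specimens
    for (m in cov$new_motus)
      expect_true(all(b[names(p$assignment)[p$assignment == m]] == "2"))
  }
})

test_that("singleton and doubleton accounting matches cluster sizes", {
  p <- as_partition(c(a = "m1", b = "m2", c = "m3", d = "m3",
                      e = "m4", f = "m4", g = "m4", h = "m4", i = "m4"))
  ab <- abundance_classes(p)
  expect_equal(ab$n_singletons, 2L)
  expect_equal(ab$n_doubletons, 1L)
  expect_equal(ab$singleton_prop, 0.5)
  b <- setNames(c("1", "1", "1", "2", "2", "2", "2", "2", "2"), letters[1:9])
  ab2 <- abundance_classes(p, b)
  expect_equal(ab2$scope, c("combined", "batch1", "batch2"))
  # batch-1 restriction: {a},{b},{c} -> 3 singletons
  expect_equal(ab2$n_singletons[ab2$scope == "batch1"], 3L)
})

test_that("rarer sampling inflates the singleton proportion", {
  # subsampling a simulated log-series community leaves more species as
  # singletons: monotone trend over decreasing sampling fractions
  sim <- simulate_community(community_spec(
    n_species = 20, total = 400, abundance = "logseries", seed = 62))
  pd <- distance_matrix(sim$records, min_overlap = 100)
  set.seed(62)
  props <- vapply(c(1, 0.25, 0.05), function(f) {
    keep <- sort(sample.int(nrow(sim$records), max(20, round(
      f * nrow(sim$records)))))
    p <- objective_cluster(subset_pd <- distance_matrix(
      sim$records[keep, ], min_overlap = 100), 0.03)
    ab <- abundance_classes(p)
    ab$singleton_prop
  }, numeric(1))
  expect_true(props[3] > props[1])
})

test_that("randomization is seed-reproducible and demands >= 2 reps", {
  sim <- simulate_community(community_spec(n_species = 8, total = 80,
                                           seed = 63))
  pd <- distance_matrix(sim$records, min_overlap = 100)
  p <- objective_cluster(pd, 0.05)
  r1 <- randomization_test(p, sizes = c(40, 40), n_reps = 25, seed = 5)
  r2 <- randomization_test(p, sizes = c(40, 40), n_reps = 25, seed = 5)
  expect_identical(r1$motu_coverage, r2$motu_coverage)
  expect_identical(r1$specimen_coverage, r2$specimen_coverage)
  r3 <- randomization_test(p, sizes = c(40, 40), n_reps = 25, seed = 6)
  expect_false(identical(r1$motu_coverage, r3$motu_coverage))
  expect_gte(r1$motu_coverage_sd, 0)
  expect_error(randomization_test(p, sizes = c(40, 40), n_reps = 1, seed = 1),
               "n_reps")
  expect_error(randomization_test(p, sizes = c(10, 40), n_reps = 5, seed = 1),
               "sum")
  # pdist entry point clusters once and matches the partition route
  r4 <- randomization_test(pd, sizes = c(40, 40), n_reps = 25, seed = 5,
                           threshold = 0.05)
  expect_identical(r1$motu_coverage, r4$motu_coverage)
})

test_that("observed coverage lies within the support of the null", {
  sim <- simulate_community(community_spec(n_species = 10, total = 120,
                                           seed = 64))
  pd <- distance_matrix(sim$records, min_overlap = 100)
  p <- objective_cluster(pd, 0.05)
  b <- setNames(sim$records$batch, sim$records$specimen_id)
  obs <- coverage_stats(p, b)
  rt <- randomization_test(p, sizes = c(sum(b == "1"), sum(b == "2")),
                           n_reps = 200, seed = 17)
  rng <- range(rt$motu_coverage)
  slack <- 2 * rt$motu_coverage_sd
  expect_gte(obs$motu_coverage_pct, rng[1] - slack)
  expect_lte(obs$motu_coverage_pct, rng[2] + slack)
})
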