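toy_partition <- function(...) {
  as_partition(unlist(list(...)))
}

test_that("match ratio handles identity, total disagreement and the formula", {
  a <- toy_partition(s1 = "m1", s2 = "m1", s3 = "m2", s4 = "m3")
  expect_equal(match_ratio(a, a)$match_ratio, 1)
  # one cluster of n vs n singletons: nothing congruent
  one <- toy_partition(s1 = "m", s2 = "m", s3 = "m")
  singl <- toy_partition(s1 = "x1", s2 = "x2", s3 = "x3")
  expect_equal(match_ratio(one, singl)$match_ratio, 0)
  # published-style counts: 113 congruent of 115 MOTUs vs 117 morphospecies
  expect_equal(round(match_ratio_from_counts(115, 117, 113), 2), 0.97)
  expect_error(match_ratio(a, toy_partition(z9 = "m")), "share no specimens")
})

test_that("match ratio is symmetric and 1 only for identical partitions", {
  set.seed(99)
  for (trial in 1:20) {
    n <- sample(4:12, 1)
    ids <- sprintf("s%02d", 1:n)
    a <- as_partition(setNames(sample(letters[1:4], n, TRUE), ids))
    b <- as_partition(setNames(sample(LETTERS[1:4], n, TRUE), ids))
    ra <- match_ratio(a, b)
    rb <- match_ratio(b, a)
    expect_equal(ra$match_ratio, rb$match_ratio)
    expect_equal(ra$n_congruent, rb$n_congruent)
    identical_parts <- setequal(partition_sets(a), partition_sets(b))
    expect_equal(ra$match_ratio == 1, identical_parts)
  }
})

test_that("restriction to the shared specimen set precedes comparison", {
  # morphospecies cover only examined specimens; unexamined ones drop out
  motu <- toy_partition(s1 = "m1", s2 = "m1", s3 = "m1", s4 = "m2")
  morph <- data.frame(specimen_id = c("s1", "s2"),
                      morphospecies = c("X", "X"))
  r <- match_ratio(motu, morph)
  expect_equal(r$n_shared_specimens, 2L)
  expect_equal(r$n_congruent, 1L)  # {s1,s2} = X on the shared set
  expect_equal(r$match_ratio, 1)
})

test_that("species statuses implement congruence rules (i) and (ii)", {
  p <- toy_partition(a = "M1", b = "M1", c = "M2", d = "M2",
                     e = "M3", f = "M3", g = "M4")
  morph <- data.frame(
    specimen_id = c("a", "b", "c", "d", "e", "f"),
    morphospecies = c("X", "X", "Y", "Z", "W", "W"))
  out <- classify_species(p, morph)
  st <- setNames(out$species$status, out$species$morphospecies)
  expect_equal(unname(st["X"]), "congruent")   # own MOTU, no admixture
  expect_equal(unname(st["Y"]), "fused")       # shares M2 with Z
  expect_equal(unname(st["Z"]), "fused")
  expect_equal(unname(st["W"]), "congruent")
  expect_equal(out$untested_motus, "M4")       # no examined specimen

  morph2 <- data.frame(specimen_id = c("a", "c"),
                       morphospecies = c("X", "X"))
  out2 <- classify_species(p, morph2)
  expect_equal(out2$species$status, "split")   # X spans M1 and M2
  expect_error(classify_species(p, data.frame(specimen_id = "zz",
                                              morphospecies = "Q")),
               "outside")
})

test_that("fused MOTUs are resolved by splitting at a finer threshold", {
  # simulated cryptic pair: two true species ~1.6% apart merge at 3% and
  # separate cleanly at a finer grid threshold
  sim <- simulate_community(community_spec(
    n_species = 6, total = 60, n_cryptic_pairs = 1, seed = 73))
  pd <- distance_matrix(sim$records, min_overlap = 100)
  grid <- cluster_grid(pd, c(0.01, 0.015, 0.02, 0.025, 0.03, 0.04, 0.05))
  base <- grid[["0.03"]]
  expect_equal(length(unique(base$assignment)), 5L)  # 6 species - 1 merge
  res <- resolve_conflicts(grid, sim$morph, base)
  expect_true(any(res$log$action == "split"))
  expect_true(all(res$log$threshold[res$log$action == "split"] < 0.03))
  # accepted species = truth
  acc <- as_partition(res$species[!is.na(res$species)])
  expect_equal(partition_sets(acc),
               partition_sets(as_partition(sim$morph)))
})

test_that("split morphospecies are resolved by fusing at a coarser threshold", {
  sim <- simulate_community(community_spec(
    n_species = 6, total = 60, n_divergent_conspecifics = 1, seed = 74))
  pd <- distance_matrix(sim$records, min_overlap = 100)
  grid <- cluster_grid(pd, c(0.01, 0.015, 0.02, 0.025, 0.03, 0.04, 0.05))
  base <- grid[["0.03"]]
  expect_equal(length(unique(base$assignment)), 7L)  # 6 species + 1 split
  res <- resolve_conflicts(grid, sim$morph, base)
  expect_true(any(res$log$action == "fuse"))
  expect_true(all(res$log$threshold[res$log$action == "fuse"] > 0.03))
  acc <- as_partition(res$species[!is.na(res$species)])
  expect_equal(partition_sets(acc),
               partition_sets(as_partition(sim$morph)))
})

test_that("irreconcilable label interleaving is a conflict, not a species", {
  # two morphospecies interleaved inside one tight cluster at every
  # threshold: specimens identical or 1 site apart, labels crosswise
  s <- function(edits = integer(0)) {
    x <- rep("A", 100); if (length(edits)) x[edits] <- "G"
    paste(x, collapse = "")
  }
  rec <- toy_records(c(a = s(), b = s(1), c = s(), d = s(1),
                       far = paste(rep("T", 100), collapse = "")))
  pd <- distance_matrix(rec, min_overlap = 50)
  grid <- cluster_grid(pd, c(0.005, 0.01, 0.02, 0.03, 0.05))
  base <- grid[["0.03"]]
  morph <- data.frame(specimen_id = c("a", "b", "c", "d"),
                      morphospecies = c("X", "X", "Y", "Y"))
  res <- resolve_conflicts(grid, morph, base)
  expect_true(any(res$log$action == "conflict"))
  expect_true(all(is.na(res$species[c("a", "b", "c", "d")])))
  # locality: the unrelated cluster keeps its assignment
  expect_equal(unname(res$species["far"]), "far")
})

test_that("resolution is local and clean communities are fully congruent", {
  sim <- simulate_community(community_spec(
    n_species = 8, total = 70, n_cryptic_pairs = 1, seed = 75))
  pd <- distance_matrix(sim$records, min_overlap = 100)
  grid <- cluster_grid(pd, c(0.01, 0.015, 0.02, 0.025, 0.03, 0.04, 0.05))
  base <- grid[["0.03"]]
  res <- resolve_conflicts(grid, sim$morph, base)
  # specimens outside the affected (cryptic) MOTU keep their base MOTU
  affected_species <- sim$truth$species[sim$truth$anomaly == "cryptic_pair"]
  untouched <- sim$truth$specimen_id[!sim$truth$species %in% affected_species]
  expect_identical(res$species[untouched], base$assignment[untouched])

  clean <- clean_sim(seed = 76, n_species = 9, total = 80)
  p3 <- objective_cluster(clean$pd, 0.03)
  out <- classify_species(p3, clean$sim$morph)
  expect_true(all(out$species$status == "congruent"))
  expect_equal(match_ratio(p3, clean$sim$morph)$match_ratio, 1)
})
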