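# helpers building controlled MOTUs from explicit sequence edits
seq_of <- function(base, edits = integer(0), to = "G") {
  s <- rep(base, 100)
  if (length(edits)) s[edits] <- to
  paste(s, collapse = "")
}

test_that("haplotype collapse groups identical-on-compared-sites sequences", {
  rec <- toy_records(c(a = "AAAA", b = "AAAT", c = "AAAT"))
  pd <- distance_matrix(rec, min_overlap = 3)
  h <- collapse_haplotypes(c("a", "b", "c"), pd)
  expect_equal(h, list(c("b", "c"), "a"))
  rec <- toy_records(c(x = "AAAA", y = "AAAA", z = "AAAA"))
  pd <- distance_matrix(rec, min_overlap = 3)
  expect_equal(collapse_haplotypes(c("x", "y", "z"), pd),
               list(c("x", "y", "z")))
})

test_that("haplotype groups recover the simulator's haplotype truth", {
  cs <- clean_sim(seed = 31, n_species = 4, total = 40)
  p <- objective_cluster(cs$pd, 0.03)
  for (m in unique(p$assignment)) {
    mem <- names(p$assignment)[p$assignment == m]
    haps <- collapse_haplotypes(mem, cs$pd)
    truth <- cs$sim$truth[cs$sim$truth$specimen_id %in% mem, ]
    # distinct realized sequences = distinct truth haplotype sequences
    n_true <- length(unique(cs$sim$records$sequence[
      match(mem, cs$sim$records$specimen_id)]))
    expect_equal(length(haps), n_true)
  }
})

test_that("stability classes follow the composition and 1.5% rules", {
  # three well-separated groups: g (tight, 5 members), h (max intra 2%),
  # plus a singleton
  seqs <- c(
    g1 = seq_of("A"), g2 = seq_of("A", 1), g3 = seq_of("A", 1),
    g4 = seq_of("A"), g5 = seq_of("A", 1),
    h1 = seq_of("C"), h2 = seq_of("C", 1:2),   # 2% apart -> instable
    s1 = seq_of("T"))
  pd <- distance_matrix(toy_records(seqs), min_overlap = 50)
  grid <- cluster_grid(pd, c(0.01, 0.015, 0.02, 0.025, 0.03))
  cls <- classify_stability(grid, 0.03, pd)
  cls <- setNames(cls$class, cls$motu_id)
  expect_equal(unname(cls["g1"]), "stable")
  expect_equal(unname(cls["h1"]), "instable")   # max intra 2% > 1.5%
  expect_equal(unname(cls["s1"]), "singleton")
  full <- classify_stability(grid, 0.03, pd)
  expect_equal(sum(table(full$class)), length(unique(grid[[5]]$assignment)))
  expect_true(all(full$stability_index >= 0 & full$stability_index <= 1))

  # composition change across the grid makes a MOTU instable even when its
  # max intra distance stays below 1.5%: subgroups 1% apart separate at the
  # 0.5% grid threshold but merge at 3%
  seqs2 <- c(p1 = seq_of("A"), p2 = seq_of("A"), q1 = seq_of("A", 1))
  pd2 <- distance_matrix(toy_records(seqs2), min_overlap = 50)
  grid2 <- cluster_grid(pd2, c(0.005, 0.03))
  cls2 <- classify_stability(grid2, 0.03, pd2)
  expect_equal(cls2$class, "instable")          # {p1,p2} vs {q1} at 0.5%
  expect_equal(cls2$stability_index, 0.5)
  expect_true(cls2$max_intra_dist <= 0.015)
})

test_that("classification rejects foreign (non-nested) partitions", {
  cs <- clean_sim(seed = 41, n_species = 5, total = 30)
  grid <- cluster_grid(cs$pd, c(0.01, 0.02, 0.03))
  foreign <- grid[[1]]
  # merge members of two different base MOTUs at the finest threshold: a
  # fine cluster now straddles two coarse clusters
  base_motus <- unique(grid[[3]]$assignment)
  m1 <- names(grid[[3]]$assignment)[grid[[3]]$assignment == base_motus[1]][1]
  m2 <- names(grid[[3]]$assignment)[grid[[3]]$assignment == base_motus[2]][1]
  foreign$assignment[c(m1, m2)] <- "ZZZ"
  grid[[1]] <- foreign
  expect_error(classify_stability(grid, 0.03, cs$pd), "nested")
})

test_that("examination plans follow the LIT selection rules", {
  # stable MOTU, single haplotype, 7 specimens -> 1 specimen
  seqs <- setNames(rep(seq_of("A"), 7), paste0("m", 1:7))
  seqs <- c(seqs, far = seq_of("T"))
  pd <- distance_matrix(toy_records(seqs), min_overlap = 50)
  grid <- cluster_grid(pd, c(0.01, 0.015, 0.02, 0.025, 0.03))
  cls <- classify_stability(grid, 0.03, pd)
  plan <- examination_plan(cls, grid[[5]], pd)
  expect_equal(plan$specimen_id[plan$motu_id == "m1"], "m1")
  expect_equal(plan$reason[plan$motu_id == "m1"], "main-haplotype")

  # stable MOTU with two haplotypes 1% apart -> one specimen from each
  seqs <- c(a1 = seq_of("A"), a2 = seq_of("A"), a3 = seq_of("A", 1),
            far = seq_of("T"))
  pd <- distance_matrix(toy_records(seqs), min_overlap = 50)
  grid <- cluster_grid(pd, c(0.015, 0.02, 0.025, 0.03))
  cls <- classify_stability(grid, 0.03, pd)
  expect_equal(cls$class[cls$motu_id == "a1"], "stable")
  plan <- examination_plan(cls, grid[[4]], pd)
  sel <- plan[plan$motu_id == "a1", ]
  expect_equal(nrow(sel), 2L)
  expect_setequal(sel$specimen_id, c("a1", "a3"))
  expect_equal(unique(sel$reason), "most-distant-pair")

  # instable MOTU with haplotype sizes {10, 6, 1}: most-distant pair plus
  # representatives of the size-10 and size-6 haplotypes, <= 4, no dupes
  h1 <- setNames(rep(seq_of("A"), 10), sprintf("x%02d", 1:10))
  h2 <- setNames(rep(seq_of("A", 1:2), 6), sprintf("y%02d", 1:6))
  h3 <- c(z1 = seq_of("A", 1:3))
  pd <- distance_matrix(toy_records(c(h1, h2, h3)), min_overlap = 50)
  grid <- cluster_grid(pd, c(0.01, 0.015, 0.02, 0.025, 0.03))
  cls <- classify_stability(grid, 0.03, pd)
  expect_equal(cls$class, "instable")   # max intra 3% > 1.5%
  plan <- examination_plan(cls, grid[[5]], pd, main_min_count = 2L)
  expect_lte(nrow(plan), 4L)
  expect_false(anyDuplicated(plan$specimen_id) > 0)
  # the most distant pair is x.. vs z1 (3%)
  expect_true("z1" %in% plan$specimen_id)
  # both main haplotypes represented
  expect_true(any(plan$specimen_id %in% names(h1)))
  expect_true(any(plan$specimen_id %in% names(h2)))
  # determinism
  plan2 <- examination_plan(cls, grid[[5]], pd, main_min_count = 2L)
  expect_identical(plan, plan2)
})

test_that("clean simulated communities have only singleton or stable MOTUs", {
  cs <- clean_sim(seed = 51, n_species = 12, total = 90)
  grid <- cluster_grid(cs$pd, c(0.01, 0.015, 0.02, 0.025, 0.03))
  cls <- classify_stability(grid, 0.03, cs$pd)
  expect_true(all(cls$class[cls$n_specimens > 1] == "stable"))
  expect_true(all(cls$class[cls$n_specimens == 1] == "singleton"))
  plan <- examination_plan(cls, grid[[5]], cs$pd)
  # plan size bounds: singleton 1, stable 1-2
  sizes <- table(plan$motu_id)
  expect_true(all(sizes[cls$motu_id[cls$class == "singleton"]] == 1))
  expect_true(all(sizes[cls$motu_id[cls$class == "stable"]] <= 2))
  expect_lte(nrow(plan), nrow(cs$sim$records))
})
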