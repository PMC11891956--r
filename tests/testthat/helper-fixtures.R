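# In-code fixtures and independent oracles used across the test files.

# quick specimen table from a named character vector of sequences
toy_records <- function(seqs) {
  data.frame(specimen_id = names(seqs), sequence = unname(seqs),
             batch = NA_character_, site = NA_character_,
             habitat = NA_character_, stringsAsFactors = FALSE)
}

# independent naive p-distance: per-pair character loop, no matrix algebra
naive_pdist <- function(records, min_overlap = 1L) {
  n <- nrow(records)
  chars <- strsplit(records$sequence, "")
  d <- matrix(NA_real_, n, n,
              dimnames = list(records$specimen_id, records$specimen_id))
  for (i in seq_len(n)) {
    d[i, i] <- 0
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- chars[[i]]
      b <- chars[[j]]
      mism <- 0L
      comp <- 0L
      for (k in seq_along(a)) {
        if (a[k] %in% c("A", "C", "G", "T") &&
            b[k] %in% c("A", "C", "G", "T")) {
          comp <- comp + 1L
          if (a[k] != b[k]) mism <- mism + 1L
        }
      }
      if (comp >= min_overlap) d[i, j] <- d[j, i] <- mism / comp
    }
  }
  d
}

# independent clustering oracle: transitive closure of the link relation by
# boolean matrix powering (no union-find)
brute_force_components <- function(d, threshold, tol = 1e-12) {
  n <- nrow(d)
  adj <- !is.na(d) & d <= threshold + tol
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  # component key per specimen: sorted member ids
  apply(reach, 1L, function(r) paste(sort(colnames(d)[r]), collapse = "|"))
}

# canonical set-of-sets representation of any partition-like object
partition_sets <- function(p) {
  a <- if (inherits(p, "motu_partition")) p$assignment else p
  sets <- vapply(split(names(a), a),
                 function(m) paste(sort(m), collapse = "|"), character(1))
  sort(unname(sets))
}

# random equal-length sequence set over ACGT (optionally with some N sites)
random_records <- function(n, len, n_rate = 0) {
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (n_rate > 0) {
      k <- rbinom(1L, len, n_rate)
      if (k > 0) s[sample.int(len, k)] <- "N"
    }
    paste(s, collapse = "")
  }, character(1))
  toy_records(setNames(seqs, sprintf("r%03d", seq_len(n))))
}

# small clean community + distance matrix used by several files
clean_sim <- function(seed = 11, n_species = 10, total = 120, ...) {
  sim <- simulate_community(community_spec(
    n_species = n_species, total = total, seed = seed, ...))
  pd <- distance_matrix(sim$records, min_overlap = 100)
  list(sim = sim, pd = pd)
}
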