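# Faunal completeness between specimen batches: coverage of a second batch
# by the MOTUs of the first, and a randomized-reassignment null.

# batches: named character vector specimen_id -> batch label
check_batches <- function(partition, batches) {
  ids <- names(partition$assignment)
  stopifnot(!is.null(names(batches)))
  missing <- setdiff(ids, names(batches))
  if (length(missing) > 0L)
    stop("specimen(s) without batch label: ", paste(missing, collapse = ", "))
  b <- as.character(batches[ids])
  if (!all(b %in% c("1", "2")))
    stop("batch labels must be \"1\" or \"2\"")
  if (!all(c("1", "2") %in% b)) stop("a batch is empty")
  setNames(b, ids)
}

#' Batch-2 coverage by batch-1 MOTUs
#'
#' Given a partition of the combined (batch 1 + batch 2) data, measures how
#' completely the first batch covered the fauna found in the second:
#' which MOTUs occupied by batch-2 specimens also contain at least one
#' batch-1 specimen (shared) versus contain only batch-2 specimens (new),
#' and what fraction of batch-2 specimens fall in shared MOTUs.
#'
#' @param partition `motu_partition` of the combined data.
#' @param batches Named character vector specimen_id -> batch (`"1"`/`"2"`).
#' @return A list of class `coverage_report`: `threshold`,
#'   `n_motus_combined`, `n_motus_occupied_by_batch2`, `n_shared`, `n_new`,
#'   `new_motus` (character), `new_motu_specimen_count`,
#'   `motu_coverage_pct`, `specimen_coverage_pct`, `n_batch2_specimens`,
#'   `abundance` (the [abundance_classes()] table).
#' @export
coverage_stats <- function(partition, batches) {
  b <- check_batches(partition, batches)
  a <- partition$assignment
  motus <- sort(unique(a))
  has1 <- tapply(b == "1", a, any)[motus]
  has2 <- tapply(b == "2", a, any)[motus]
  occupied2 <- motus[has2]
  shared <- motus[has2 & has1]
  new <- motus[has2 & !has1]
  n2 <- sum(b == "2")
  n2_shared <- sum(b == "2" & a %in% shared)
  structure(list(
    threshold = partition$threshold,
    n_motus_combined = length(motus),
    n_motus_occupied_by_batch2 = length(occupied2),
    n_shared = length(shared),
    n_new = length(new),
    new_motus = new,
    new_motu_specimen_count = sum(b == "2" & a %in% new),
    motu_coverage_pct = 100 * length(shared) / length(occupied2),
    specimen_coverage_pct = 100 * n2_shared / n2,
    n_batch2_specimens = n2,
    abundance = abundance_classes(partition, batches)
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Batch-2 coverage", if (!is.na(x$threshold))
    sprintf(" (threshold %.3g)", x$threshold), ":\n", sep = "")
  cat(sprintf("  combined MOTUs: %d; occupied by batch 2: %d (shared %d, new %d)\n",
              x$n_motus_combined, x$n_motus_occupied_by_batch2,
              x$n_shared, x$n_new))
  cat(sprintf("  MOTU coverage: %.1f%%; specimen coverage: %.1f%% (%d new-MOTU specimens of %d)\n",
              x$motu_coverage_pct, x$specimen_coverage_pct,
              x$new_motu_specimen_count, x$n_batch2_specimens))
  invisible(x)
}

#' Singleton and doubleton accounting
#'
#' Counts MOTUs of size 1 and 2 in the combined partition and in each
#' batch-restricted partition (the combined clusters intersected with one
#' batch's specimens).
#'
#' @param partition `motu_partition`.
#' @param batches Optional named batch vector; if `NULL` only the combined
#'   scope is reported.
#' @return A `data.frame`: `scope`, `n_specimens`, `n_motus`,
#'   `n_singletons`, `n_doubletons`, `singleton_prop`, `doubleton_prop`
#'   (proportions of MOTUs).
#' @export
abundance_classes <- function(partition, batches = NULL) {
  a <- partition$assignment
  one_scope <- function(scope, keep) {
    sizes <- table(a[keep])
    data.frame(scope = scope, n_specimens = sum(keep),
               n_motus = length(sizes),
               n_singletons = sum(sizes == 1L),
               n_doubletons = sum(sizes == 2L),
               singleton_prop = sum(sizes == 1L) / length(sizes),
               doubleton_prop = sum(sizes == 2L) / length(sizes),
               stringsAsFactors = FALSE)
  }
  out <- one_scope("combined", rep(TRUE, length(a)))
  if (!is.null(batches)) {
    b <- check_batches(partition, batches)
    out <- rbind(out,
                 one_scope("batch1", b == "1"),
                 one_scope("batch2", b == "2"))
  }
  rownames(out) <- NULL
  out
}

#' Randomized batch-reassignment null for coverage
#'
#' Tests whether the observed batch-2 coverage could reflect the haphazard
#' assignment of specimens to batches: each replicate draws a uniform random
#' subset of the given size as pseudo-batch 1 (sampling specimens without
#' replacement), relabels the rest pseudo-batch 2, and recomputes coverage
#' on the fixed combined partition (batch labels do not affect distances, so
#' the partition is reused). Reported as per-replicate values with mean and
#' sample standard deviation (n-1).
#'
#' @param x A `motu_partition` of the combined data, or a `pdist` matrix
#'   (then `threshold` must be given and clustering is run once).
#' @param sizes Integer vector `c(n1, n2)`; must sum to the specimen count.
#' @param n_reps Number of randomizations (default 100; must be >= 2 for the
#'   standard deviation to exist).
#' @param seed Integer seed; the full per-replicate vectors are reproducible
#'   for a fixed seed.
#' @param threshold Clustering threshold, only used when `x` is a `pdist`.
#' @return A list of class `randomization_result`: `n_reps`, `seed`,
#'   `motu_coverage` and `specimen_coverage` (numeric vectors, percent),
#'   `motu_coverage_mean`, `motu_coverage_sd`, `specimen_coverage_mean`,
#'   `specimen_coverage_sd`.
#' @export
randomization_test <- function(x, sizes, n_reps = 100L, seed,
                               threshold = NULL) {
  if (inherits(x, "pdist")) {
    stopifnot(!is.null(threshold))
    partition <- objective_cluster(x, threshold)
  } else {
    stopifnot(inherits(x, "motu_partition"))
    partition <- x
  }
  ids <- names(partition$assignment)
  n <- length(ids)
  stopifnot(length(sizes) == 2L)
  if (sum(sizes) != n)
    stop("sizes must sum to the total specimen count (", n, ")")
  if (n_reps < 2L) stop("n_reps must be >= 2 (sd undefined otherwise)")
  if (missing(seed)) stop("seed is required")
  a <- partition$assignment
  motus <- sort(unique(a))
  motu_idx <- match(a, motus)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  mc <- numeric(n_reps)
  sc <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    in1 <- logical(n)
    in1[sample.int(n, sizes[1L])] <- TRUE
    has1 <- tabulate(motu_idx[in1], nbins = length(motus)) > 0L
    n2_per_motu <- tabulate(motu_idx[!in1], nbins = length(motus))
    occ2 <- n2_per_motu > 0L
    mc[r] <- 100 * sum(occ2 & has1) / sum(occ2)
    sc[r] <- 100 * sum(n2_per_motu[has1]) / sizes[2L]
  }
  structure(list(n_reps = as.integer(n_reps), seed = as.integer(seed),
                 motu_coverage = mc, specimen_coverage = sc,
                 motu_coverage_mean = mean(mc), motu_coverage_sd = sd(mc),
                 specimen_coverage_mean = mean(sc),
                 specimen_coverage_sd = sd(sc)),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("Randomized batch reassignment (%d reps, seed %d):\n",
              x$n_reps, x$seed))
  cat(sprintf("  MOTU coverage: %.1f +/- %.1f%%\n",
              x$motu_coverage_mean, x$motu_coverage_sd))
  cat(sprintf("  specimen coverage: %.1f +/- %.1f%%\n",
              x$specimen_coverage_mean, x$specimen_coverage_sd))
  invisible(x)
}
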