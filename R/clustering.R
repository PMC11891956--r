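# Objective clustering: single-linkage MOTUs at p-distance thresholds.

new_partition <- function(assignment, method, threshold) {
  assignment <- assignment[order(names(assignment))]
  structure(list(assignment = assignment, method = method,
                 threshold = threshold),
            class = "motu_partition")
}

#' @export
print.motu_partition <- function(x, ...) {
  sizes <- table(x$assignment)
  cat("MOTU partition (", x$method,
      if (!is.na(x$threshold)) sprintf(", threshold %.3g", x$threshold),
      "): ", length(x$assignment), " specimens in ", length(sizes),
      " MOTUs\n", sep = "")
  cat("  singletons: ", sum(sizes == 1L), ", largest MOTU: ", max(sizes),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.motu_partition <- function(x, ...) {
  data.frame(specimen_id = names(x$assignment),
             motu_id = unname(x$assignment),
             stringsAsFactors = FALSE)
}

# list of member-id vectors, one per MOTU, names = motu ids,
# ordered by motu id; members sorted
motu_members <- function(partition) {
  out <- split(names(partition$assignment), partition$assignment)
  out <- lapply(out, sort)
  out[order(names(out))]
}

#' Construct a partition from a specimen/cluster table
#'
#' Turns a data frame with columns `specimen_id` and `motu_id` (or
#' `morphospecies`), or a named character vector, into a `motu_partition`.
#' Useful for hand-built partitions and for treating a morphospecies table
#' as a partition.
#'
#' @param x Data frame or named character vector (names = specimen ids).
#' @param method Method tag (default `"manual"`).
#' @param threshold Optional threshold tag.
#' @return A `motu_partition`.
#' @export
as_partition <- function(x, method = "manual", threshold = NA_real_) {
  a <- if (is.character(x) && !is.null(names(x))) x else as_assignment(x)
  if (anyDuplicated(names(a)))
    stop("specimen(s) assigned more than once: ",
         paste(unique(names(a)[duplicated(names(a))]), collapse = ", "))
  new_partition(a, method = method, threshold = threshold)
}

#' Cluster barcodes into MOTUs at a p-distance threshold
#'
#' MOTUs are the connected components of the graph that links every specimen
#' pair whose p-distance is less than or equal to the threshold
#' (single-linkage closure, so clusters can chain). Pairs flagged invalid in
#' the distance matrix never create links. Threshold comparison uses `<=`
#' with a small tolerance so pairs at exactly the threshold link. MOTU ids
#' are canonical: each MOTU is named after its lexicographically smallest
#' member id, which makes the partition invariant to input order.
#'
#' @param pd A `pdist` distance matrix.
#' @param threshold Distance threshold as a fraction in `[0, 1)`.
#' @return A `motu_partition` with method `"objective_clustering"`.
#' @examples
#' rec <- data.frame(specimen_id = c("a", "b", "c"),
#'                   sequence = c("AAAA", "AAAT", "ATTT"))
#' pd <- distance_matrix(rec, min_overlap = 4)
#' objective_cluster(pd, 0.3)
#' @export
objective_cluster <- function(pd, threshold) {
  stopifnot(inherits(pd, "pdist"))
  n <- length(pd$ids)
  if (n == 0L) stop("empty distance matrix")
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  adj <- !is.na(pd$d) & pd$d <= threshold + .tol
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1L])
      rj <- find(edges[k, 2L])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  # canonical label: smallest member id per component
  labels <- stats::ave(pd$ids, root, FUN = min)
  new_partition(setNames(labels, pd$ids),
                method = "objective_clustering", threshold = threshold)
}

#' MOTU counts across a threshold series
#'
#' Runs [objective_cluster()] at each threshold and tabulates MOTU,
#' singleton and doubleton counts. Because single-linkage partitions are
#' nested in the threshold, the MOTU count is non-increasing.
#'
#' @param pd A `pdist` distance matrix.
#' @param thresholds Numeric vector of thresholds, sorted ascending.
#' @return A `data.frame` with columns `threshold`, `n_motus`,
#'   `n_singletons`, `n_doubletons`.
#' @export
threshold_profile <- function(pd, thresholds) {
  stopifnot(!is.unsorted(thresholds))
  rows <- lapply(thresholds, function(t) {
    sizes <- table(objective_cluster(pd, t)$assignment)
    data.frame(threshold = t, n_motus = length(sizes),
               n_singletons = sum(sizes == 1L),
               n_doubletons = sum(sizes == 2L))
  })
  do.call(rbind, rows)
}

#' Cluster at several thresholds at once
#'
#' @param pd A `pdist` distance matrix.
#' @param thresholds Numeric vector of thresholds.
#' @return Named list of `motu_partition` objects (names = threshold values).
#' @export
cluster_grid <- function(pd, thresholds) {
  out <- lapply(thresholds, function(t) objective_cluster(pd, t))
  names(out) <- fmt_threshold(thresholds)
  out
}

# per-element formatting so 0.03 is always named "0.03", never "0.030"
fmt_threshold <- function(t) vapply(t, format, character(1), trim = TRUE)

# TRUE iff partitions (list, ascending thresholds) are nested: any two
# specimens together at a finer threshold stay together at every coarser one
partitions_nested <- function(partitions) {
  if (length(partitions) < 2L) return(TRUE)
  ids <- names(partitions[[1L]]$assignment)
  for (k in seq_len(length(partitions) - 1L)) {
    a <- partitions[[k]]$assignment[ids]
    b <- partitions[[k + 1L]]$assignment[ids]
    # each fine cluster must map into exactly one coarse cluster
    n_coarse_per_fine <- tapply(b, a, function(z) length(unique(z)))
    if (any(n_coarse_per_fine > 1L)) return(FALSE)
  }
  TRUE
}
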