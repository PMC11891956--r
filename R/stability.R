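# LIT stages 2-3: MOTU stability classes and the specimen-examination plan.

#' Collapse the members of a MOTU into haplotype groups
#'
#' A haplotype is an equivalence class of sequences identical on all mutually
#' compared sites (p-distance zero under pairwise deletion). With missing
#' data "identical on compared sites" is not transitive, so groups are the
#' connected components of the zero-distance graph, which keeps the grouping
#' deterministic. Groups are ordered by decreasing size, ties broken by the
#' lexicographically smallest member id; members within a group are sorted.
#'
#' @param member_ids Character vector of specimen ids (one MOTU).
#' @param pd A `pdist` covering the ids.
#' @return List of character vectors, one per haplotype group.
#' @export
collapse_haplotypes <- function(member_ids, pd) {
  member_ids <- sort(member_ids)
  if (length(member_ids) == 1L) return(list(member_ids))
  sub <- subset_pdist(pd, member_ids)
  part <- objective_cluster(sub, 0)
  groups <- motu_members(part)
  ord <- order(-lengths(groups), vapply(groups, `[[`, character(1), 1L))
  unname(groups[ord])
}

#' Classify MOTUs as singleton, stable or instable
#'
#' Applies the LIT stability rules to the MOTUs of the base-threshold
#' partition. A MOTU is a singleton if it holds one specimen. It is instable
#' if its specimen set does not occur as one whole cluster at every threshold
#' of the grid (its composition changes as the threshold is varied), or if
#' the maximum pairwise distance between any two of its members exceeds
#' `max_intra_limit` (default 1.5%). Otherwise it is stable. The stability
#' index is the fraction of grid thresholds at which the composition is
#' unchanged, reported as a diagnostic alongside the binary class.
#'
#' @param partitions List of `motu_partition` objects over the stability
#'   grid, in ascending threshold order. Must be nested (all from
#'   [objective_cluster()] on one matrix) and include the base threshold as
#'   their maximum.
#' @param base_threshold The threshold whose MOTUs are being classified
#'   (default: the largest threshold in the grid).
#' @param pd The `pdist` the partitions were clustered from.
#' @param max_intra_limit Maximum within-MOTU pairwise distance tolerated for
#'   a stable MOTU (default 0.015).
#' @return A `data.frame`: `motu_id`, `class`, `n_specimens`, `n_haplotypes`,
#'   `max_intra_dist`, `composition_stable`, `stability_index`.
#' @export
classify_stability <- function(partitions, base_threshold = NULL, pd,
                               max_intra_limit = 0.015) {
  stopifnot(length(partitions) >= 1L,
            all(vapply(partitions, inherits, logical(1), "motu_partition")))
  th <- vapply(partitions, function(p) p$threshold, numeric(1))
  partitions <- partitions[order(th)]
  th <- sort(th)
  base_threshold <- base_threshold %||% th[length(th)]
  if (abs(th[length(th)] - base_threshold) > .tol)
    stop("grid must include the base threshold as its maximum")
  ids <- names(partitions[[1L]]$assignment)
  if (!all(vapply(partitions, function(p)
    identical(names(p$assignment), ids), logical(1))))
    stop("partitions cover different specimen sets")
  if (!partitions_nested(partitions))
    stop("partitions are not nested; stability requires single-linkage ",
         "partitions from one distance matrix")
  base <- partitions[[length(partitions)]]
  members <- motu_members(base)
  # at each grid threshold, the set of cluster-size lookups per specimen
  grid_assign <- lapply(partitions, function(p) p$assignment[ids])
  grid_sizes <- lapply(grid_assign, function(a) table(a))
  rows <- lapply(names(members), function(m) {
    mem <- members[[m]]
    n <- length(mem)
    # composition unchanged at threshold k iff all members share one cluster
    # of exactly size n there
    occurs <- vapply(seq_along(partitions), function(k) {
      a <- grid_assign[[k]][mem]
      length(unique(a)) == 1L &&
        as.integer(grid_sizes[[k]][a[1L]]) == n
    }, logical(1))
    d_sub <- pd$d[mem, mem, drop = FALSE]
    off <- d_sub[upper.tri(d_sub)]
    max_intra <- if (length(off) == 0L || all(is.na(off))) 0
                 else max(off, na.rm = TRUE)
    comp_stable <- all(occurs)
    class <- if (n == 1L) "singleton"
             else if (!comp_stable || max_intra > max_intra_limit + .tol)
               "instable"
             else "stable"
    data.frame(motu_id = m, class = class, n_specimens = n,
               n_haplotypes = length(collapse_haplotypes(mem, pd)),
               max_intra_dist = max_intra,
               composition_stable = comp_stable,
               stability_index = mean(occurs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$motu_id), ]
}

# most distant specimen pair within a member set; ties broken by the
# lexicographically smallest sorted id pair; returns sorted pair
most_distant_pair <- function(member_ids, pd) {
  member_ids <- sort(member_ids)
  d <- pd$d[member_ids, member_ids, drop = FALSE]
  iu <- which(upper.tri(d), arr.ind = TRUE)
  dd <- d[iu]
  if (all(is.na(dd))) return(member_ids[1:2])
  best <- max(dd, na.rm = TRUE)
  cand <- iu[!is.na(dd) & dd >= best - .tol, , drop = FALSE]
  pairs <- cbind(member_ids[cand[, 1L]], member_ids[cand[, 2L]])
  pairs <- t(apply(pairs, 1L, sort))
  key <- paste(pairs[, 1L], pairs[, 2L])
  pairs[order(key)[1L], ]
}

#' Build the LIT specimen-examination plan
#'
#' Decides which specimens must be studied morphologically to test each
#' MOTU's boundary: a singleton contributes its only specimen; a stable MOTU
#' is tested with a pair of specimens representing its two most distant
#' haplotypes (one specimen if it holds a single haplotype); an instable
#' MOTU is tested with its most distant specimen pair plus one specimen
#' representing each "main" haplotype not already covered by that pair. Main
#' haplotypes default to those with at least `min_count` members, with the
#' largest haplotype always included. All tie-breaks are lexicographic on
#' specimen id, so the plan is deterministic.
#'
#' @param classes Output of [classify_stability()].
#' @param partition The base `motu_partition` the classes were computed on.
#' @param pd The `pdist` matrix.
#' @param main_min_count Minimum haplotype size to count as a main haplotype
#'   in instable MOTUs (default 2).
#' @return A `data.frame` with columns `motu_id`, `specimen_id`, `reason`
#'   (`singleton`, `most-distant-pair` or `main-haplotype`).
#' @export
examination_plan <- function(classes, partition, pd, main_min_count = 2L) {
  members <- motu_members(partition)
  rows <- lapply(classes$motu_id, function(m) {
    mem <- members[[m]]
    cls <- classes$class[classes$motu_id == m]
    if (cls == "singleton") {
      return(data.frame(motu_id = m, specimen_id = mem,
                        reason = "singleton", stringsAsFactors = FALSE))
    }
    haps <- collapse_haplotypes(mem, pd)
    if (cls == "stable") {
      if (length(haps) == 1L) {
        return(data.frame(motu_id = m, specimen_id = haps[[1L]][1L],
                          reason = "main-haplotype", stringsAsFactors = FALSE))
      }
      pair <- most_distant_pair(mem, pd)
      return(data.frame(motu_id = m, specimen_id = pair,
                        reason = "most-distant-pair", stringsAsFactors = FALSE))
    }
    # instable: most distant pair, then main-haplotype representatives
    pair <- most_distant_pair(mem, pd)
    out <- data.frame(motu_id = m, specimen_id = pair,
                      reason = "most-distant-pair", stringsAsFactors = FALSE)
    main <- haps[lengths(haps) >= main_min_count]
    if (length(main) == 0L) main <- haps[1L]  # largest haplotype always counts
    covered <- vapply(main, function(h) any(pair %in% h), logical(1))
    for (h in main[!covered]) {
      out <- rbind(out, data.frame(motu_id = m, specimen_id = h[1L],
                                   reason = "main-haplotype",
                                   stringsAsFactors = FALSE))
    }
    out
  })
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(paste(out$motu_id, out$specimen_id)))
  rownames(out) <- NULL
  out
}
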