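# LIT stages 4-5: morphospecies/MOTU congruence, match ratio, and split/fuse
# conflict resolution across the threshold grid.

# coerce a morphospecies table (specimen_id, morphospecies) or a
# motu_partition to a named assignment vector
as_assignment <- function(x) {
  if (inherits(x, "motu_partition")) return(x$assignment)
  if (is.data.frame(x)) {
    lab_col <- intersect(c("morphospecies", "motu_id"), names(x))[1L]
    stopifnot(!is.na(lab_col), "specimen_id" %in% names(x))
    return(setNames(as.character(x[[lab_col]]), x$specimen_id))
  }
  stop("cannot interpret object as a partition")
}

# canonical set keys of the clusters of an assignment vector
cluster_keys <- function(assignment) {
  vapply(split(names(assignment), assignment),
         function(m) paste(sort(m), collapse = "\r"), character(1))
}

#' Match ratio between two partitions
#'
#' Quantifies agreement between a MOTU partition and a second partition
#' (typically morphospecies) as
#' `2 * N_congruent / (N_MOTU + N_morph)`, where `N_congruent` is the number
#' of clusters that form identical specimen sets in both partitions. Both
#' partitions are first restricted to their shared specimen set, so the
#' morphospecies side may cover only examined specimens. The statistic is
#' symmetric in its arguments and equals 1 exactly when the partitions are
#' identical on the shared set.
#'
#' @param partition_a,partition_b `motu_partition` objects or data frames
#'   with columns `specimen_id` and `morphospecies` (or `motu_id`).
#' @return A list with `n_a`, `n_b`, `n_congruent`, `match_ratio`,
#'   `n_shared_specimens`.
#' @examples
#' a <- data.frame(specimen_id = c("s1", "s2"), motu_id = c("m1", "m2"))
#' b <- data.frame(specimen_id = c("s1", "s2"), morphospecies = c("X", "Y"))
#' match_ratio(a, b)$match_ratio # 1
#' @export
match_ratio <- function(partition_a, partition_b) {
  a <- as_assignment(partition_a)
  b <- as_assignment(partition_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) stop("partitions share no specimens")
  a <- a[shared]
  b <- b[shared]
  ka <- cluster_keys(a)
  kb <- cluster_keys(b)
  n_congruent <- length(intersect(ka, kb))
  list(n_a = length(ka), n_b = length(kb), n_congruent = n_congruent,
       match_ratio = 2 * n_congruent / (length(ka) + length(kb)),
       n_shared_specimens = length(shared))
}

#' Match ratio from summary counts
#'
#' The same statistic as [match_ratio()] computed directly from the three
#' counts, for use with published congruence tables where only the cluster
#' counts are available.
#'
#' @param n_motu,n_morph,n_congruent Cluster counts (vectorized).
#' @return `2 * n_congruent / (n_motu + n_morph)`.
#' @export
match_ratio_from_counts <- function(n_motu, n_morph, n_congruent) {
  stopifnot(all(n_congruent <= pmin(n_motu, n_morph)))
  2 * n_congruent / (n_motu + n_morph)
}

#' Classify morphospecies against a MOTU partition
#'
#' Applies the LIT congruence rules on the examined specimens only: a
#' morphospecies is congruent iff (i) its examined specimens fall in exactly
#' one MOTU and (ii) that MOTU's examined specimens carry no other
#' morphospecies label. A morphospecies spanning several MOTUs is `split`; a
#' morphospecies sharing its single MOTU with another label is `fused`; one
#' that both spans and shares is `conflict`. MOTUs containing no examined
#' specimen are reported separately as untested.
#'
#' @param partition The base `motu_partition`.
#' @param morph Morphospecies table (`specimen_id`, `morphospecies`) covering
#'   the examined specimens.
#' @return A list with `species` (data.frame: `morphospecies`, `status`,
#'   `n_examined`, `motus`) and `untested_motus` (character vector).
#' @export
classify_species <- function(partition, morph) {
  stopifnot(inherits(partition, "motu_partition"))
  m <- as_assignment(morph)
  unknown <- setdiff(names(m), names(partition$assignment))
  if (length(unknown) > 0L)
    stop("morphospecies table refers to specimens outside the partition: ",
         paste(unknown, collapse = ", "))
  if (length(m) == 0L) stop("no examined specimens")
  motu_of <- partition$assignment[names(m)]
  labels_in_motu <- tapply(m, motu_of, function(z) unique(z))
  rows <- lapply(sort(unique(m)), function(sp) {
    ids <- names(m)[m == sp]
    motus <- sort(unique(motu_of[ids]))
    spans <- length(motus) > 1L
    shares <- any(vapply(motus, function(mo)
      length(labels_in_motu[[mo]]) > 1L, logical(1)))
    status <- if (spans && shares) "conflict"
              else if (spans) "split"
              else if (shares) "fused"
              else "congruent"
    data.frame(morphospecies = sp, status = status, n_examined = length(ids),
               motus = paste(motus, collapse = ","), stringsAsFactors = FALSE)
  })
  untested <- setdiff(unique(partition$assignment), unique(motu_of))
  list(species = do.call(rbind, rows), untested_motus = sort(untested))
}

#' Resolve morphology/barcode conflict across the threshold grid
#'
#' Implements LIT's split/fuse resolution. Starting from the base-threshold
#' MOTUs: where one MOTU holds several morphospecies (rule (i) violated),
#' finer thresholds are searched — nearest first — for a sub-clustering of
#' that MOTU in which every morphospecies occupies its own sub-cluster; if
#' found, the MOTU is split accordingly. Where one morphospecies spans
#' several MOTUs (rule (ii) violated), coarser thresholds are searched —
#' nearest first — for a cluster that unites all its examined specimens
#' without admitting any other morphospecies; if found, those MOTUs are
#' fused. If no grid threshold restores congruence the case is a genuine
#' conflict and its specimens are left unassigned to species (`NA`): no
#' species delimitation is performed for them. Resolution is local — only
#' the affected clusters change. Unexamined specimens inherit the species of
#' their (possibly re-cut) cluster.
#'
#' @param grid_partitions List of nested `motu_partition` objects spanning
#'   thresholds below and above the base.
#' @param morph Morphospecies table of examined specimens.
#' @param base The base `motu_partition` (its threshold must be in the grid).
#' @return A list with `species` (named character vector specimen -> species
#'   id, `NA` for unresolved), `log` (data.frame of resolution actions:
#'   `morphospecies`, `action`, `threshold`, `clusters`), and `statuses`
#'   (the [classify_species()] table on the base partition).
#' @export
resolve_conflicts <- function(grid_partitions, morph, base) {
  stopifnot(inherits(base, "motu_partition"))
  th <- vapply(grid_partitions, function(p) p$threshold, numeric(1))
  grid_partitions <- grid_partitions[order(th)]
  th <- sort(th)
  ids <- names(base$assignment)
  if (!all(vapply(grid_partitions, function(p)
    identical(names(p$assignment), ids), logical(1))))
    stop("grid partitions cover different specimen sets than the base")
  if (!partitions_nested(grid_partitions))
    stop("grid partitions are not nested")
  base_pos <- which(abs(th - base$threshold) <= .tol)
  if (length(base_pos) != 1L)
    stop("base threshold not found in the grid")

  cls <- classify_species(base, morph)
  m <- as_assignment(morph)
  motu_of <- base$assignment[names(m)]
  species <- base$assignment  # start from base MOTUs
  log <- data.frame(morphospecies = character(0), action = character(0),
                    threshold = numeric(0), clusters = character(0),
                    stringsAsFactors = FALSE)
  add_log <- function(sp, action, threshold, clusters) {
    log <<- rbind(log, data.frame(
      morphospecies = sp, action = action, threshold = threshold,
      clusters = paste(sort(unique(clusters)), collapse = ","),
      stringsAsFactors = FALSE))
  }

  # --- rule (i) violations: fused/conflicted MOTUs -> try splitting finer
  fused_motus <- unique(motu_of[names(m)[m %in% cls$species$morphospecies[
    cls$species$status %in% c("fused", "conflict")]]])
  members <- motu_members(base)
  for (mo in sort(fused_motus)) {
    mem <- members[[mo]]
    examined <- intersect(mem, names(m))
    labels <- m[examined]
    resolved <- FALSE
    for (k in rev(seq_len(base_pos - 1L))) {   # nearest finer first
      sub <- grid_partitions[[k]]$assignment[mem]
      # congruent sub-partition: each sub-cluster's examined specimens carry
      # one label and each label occupies one sub-cluster
      lab_per_sub <- tapply(labels, sub[examined], function(z)
        length(unique(z)))
      sub_per_lab <- tapply(sub[examined], labels, function(z)
        length(unique(z)))
      if (all(lab_per_sub == 1L) && all(sub_per_lab == 1L)) {
        species[mem] <- sub           # adopt the finer cut, locally
        add_log(paste(sort(unique(labels)), collapse = "+"), "split",
                th[k], unique(sub))
        resolved <- TRUE
        break
      }
    }
    if (!resolved) {
      species[mem] <- NA_character_
      add_log(paste(sort(unique(labels)), collapse = "+"), "conflict",
              base$threshold, mo)
    }
  }

  # --- rule (ii) violations: split morphospecies -> try fusing coarser
  split_species <- cls$species$morphospecies[cls$species$status == "split"]
  for (sp in split_species) {
    sp_ids <- names(m)[m == sp]
    base_motus <- sort(unique(motu_of[sp_ids]))
    resolved <- FALSE
    for (k in seq(base_pos + 1L, length.out = length(th) - base_pos)) {
      a <- grid_partitions[[k]]$assignment
      cl <- unique(a[sp_ids])
      if (length(cl) != 1L) next     # still split at this threshold
      cl_mem <- ids[a == cl]
      other <- setdiff(intersect(cl_mem, names(m)), sp_ids)
      if (length(other) > 0L) next   # fusing would admit another label
      species[cl_mem] <- min(cl_mem) # fuse: one species named canonically
      add_log(sp, "fuse", th[k], base_motus)
      resolved <- TRUE
      break
    }
    if (!resolved) {
      affected <- ids[base$assignment %in% base_motus]
      species[affected] <- NA_character_
      add_log(sp, "conflict", base$threshold, base_motus)
    }
  }

  list(species = species, log = log, statuses = cls$species)
}

#' Congruence summary across methods and thresholds
#'
#' Convenience wrapper: computes [match_ratio()] of each partition in a list
#' against one morphospecies table.
#'
#' @param partitions Named list of partitions.
#' @param morph Morphospecies table.
#' @return A `data.frame`: `partition`, `threshold`, `n_motu`, `n_morph`,
#'   `n_congruent`, `match_ratio`.
#' @export
congruence_summary <- function(partitions, morph) {
  rows <- lapply(seq_along(partitions), function(i) {
    p <- partitions[[i]]
    mr <- match_ratio(p, morph)
    data.frame(partition = names(partitions)[i] %||% as.character(i),
               threshold = p$threshold, n_motu = mr$n_a, n_morph = mr$n_b,
               n_congruent = mr$n_congruent, match_ratio = mr$match_ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
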