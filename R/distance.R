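# Uncorrected p-distances with pairwise deletion.

#' Uncorrected p-distance between two equal-length sequences
#'
#' Positions where either sequence carries a gap or any non-ACGT code are
#' excluded pair by pair (pairwise deletion); the distance is the fraction of
#' mismatches among the remaining compared positions. If fewer than
#' `min_overlap` positions can be compared the pair carries no usable signal
#' and the distance is flagged invalid (`NA`).
#'
#' @param seq_a,seq_b DNA strings of equal length.
#' @param min_overlap Minimum number of compared sites for a valid distance.
#' @return A list with `distance` (fraction, `NA` if invalid),
#'   `compared_sites` (integer) and `valid` (logical).
#' @examples
#' pdistance("ACGT", "ACGA", min_overlap = 1) # 0.25 over 4 sites
#' pdistance("ACNT", "ACGA", min_overlap = 1) # 1/3 over 3 sites
#' @export
pdistance <- function(seq_a, seq_b, min_overlap = 100L) {
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences have unequal lengths (", nchar(seq_a), " vs ",
         nchar(seq_b), ")")
  stopifnot(min_overlap >= 1L)
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  compared <- sum(ok)
  valid <- compared >= min_overlap
  d <- if (compared == 0L) NA_real_ else sum(a[ok] != b[ok]) / compared
  list(distance = if (valid) d else NA_real_,
       compared_sites = as.integer(compared),
       valid = valid)
}

#' Pairwise p-distance matrix for a specimen set
#'
#' Computes all n(n-1)/2 uncorrected p-distances under pairwise deletion,
#' together with the per-pair compared-site counts. Pairs with fewer than
#' `min_overlap` compared sites are flagged invalid (`NA` distance); such
#' pairs carry no information and never link clusters downstream.
#'
#' Implemented with indicator-matrix cross-products so the full matrix for a
#' few thousand 313-bp minibarcodes is computed in seconds.
#'
#' @param records Specimen table (validated, equal-length sequences).
#' @param min_overlap Minimum compared sites for a valid pair (default 100).
#' @param strict If `TRUE`, any invalid pair is a hard error listing the
#'   offending pairs.
#' @return An object of class `pdist`: list with `ids`, `d` (symmetric
#'   numeric matrix, zero diagonal, `NA` where invalid), `sites` (integer
#'   matrix of compared-site counts), `min_overlap`, `seq_length`.
#' @export
distance_matrix <- function(records, min_overlap = 100L, strict = FALSE) {
  validate_records(records)
  if (nrow(records) < 2L) stop("need at least 2 records")
  stopifnot(min_overlap >= 1L)
  ids <- records$specimen_id
  M <- do.call(rbind, strsplit(records$sequence, ""))
  L <- ncol(M)
  valid <- matrix(M %in% c("A", "C", "G", "T"), nrow = nrow(M))
  Vi <- valid * 1
  compared <- tcrossprod(Vi)
  matches <- matrix(0, nrow(M), nrow(M))
  for (b in c("A", "C", "G", "T")) {
    Ib <- (M == b & valid) * 1
    matches <- matches + tcrossprod(Ib)
  }
  compared <- round(compared)
  matches <- round(matches)
  d <- ifelse(compared > 0, (compared - matches) / compared, NA_real_)
  invalid <- compared < min_overlap
  d[invalid] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  sites <- matrix(as.integer(compared), nrow(M), dimnames = dimnames(d))
  if (strict) {
    bad <- which(invalid & upper.tri(invalid), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("pair(s) below min_overlap: ",
           paste(ids[bad[, 1]], ids[bad[, 2]], sep = "/", collapse = ", "))
  }
  structure(list(ids = ids, d = d, sites = sites,
                 min_overlap = as.integer(min_overlap),
                 seq_length = L),
            class = "pdist")
}

#' @export
print.pdist <- function(x, ...) {
  n <- length(x$ids)
  off <- x$d[upper.tri(x$d)]
  cat("p-distance matrix: ", n, " specimens, ", x$seq_length, " sites\n",
      sep = "")
  cat("  invalid pairs (< ", x$min_overlap, " compared sites): ",
      sum(is.na(off)), "\n", sep = "")
  if (any(!is.na(off)))
    cat(sprintf("  distance range: %.4f-%.4f\n",
                min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  invisible(x)
}

#' Export a distance matrix
#'
#' Writes either a square TSV (ids as header row and first column) or a
#' long-format TSV (`id_a`, `id_b`, `distance`, `compared_sites`, upper
#' triangle only).
#'
#' @param pd A `pdist` object.
#' @param path Output path.
#' @param format `"square"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(pd, path, format = c("square", "long")) {
  format <- match.arg(format)
  if (format == "square") {
    df <- data.frame(specimen_id = pd$ids, pd$d, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    iu <- which(upper.tri(pd$d), arr.ind = TRUE)
    df <- data.frame(id_a = pd$ids[iu[, 1]], id_b = pd$ids[iu[, 2]],
                     distance = pd$d[iu], compared_sites = pd$sites[iu])
    df <- df[order(df$id_a, df$id_b), ]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# restrict a pdist to a subset of ids, preserving order of `ids`
subset_pdist <- function(pd, ids) {
  idx <- match(ids, pd$ids)
  stopifnot(!anyNA(idx))
  structure(list(ids = ids, d = pd$d[idx, idx, drop = FALSE],
                 sites = pd$sites[idx, idx, drop = FALSE],
                 min_overlap = pd$min_overlap, seq_length = pd$seq_length),
            class = "pdist")
}
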