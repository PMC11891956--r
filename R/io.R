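# Input/output: FASTA barcodes, specimen metadata, morphospecies tables,
# external partitions, and the stop-codon quality filter.

.IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N", "-")

#' Read a set of barcode sequences from FASTA
#'
#' Reads aligned (or equal-length by construction) DNA minibarcodes into a
#' specimen table. Sequences are uppercased and validated against the IUPAC
#' alphabet (plus `-` for alignment gaps); all sequences must share one
#' length. Metadata (batch, site, habitat) is joined separately with
#' [join_metadata()] because FASTA headers are not guaranteed to be
#' structured.
#'
#' @param path Path to a FASTA file (plain, single-line or wrapped).
#' @param expected_length Optional positive integer; if given, every sequence
#'   must have exactly this length (default for COI minibarcodes: 313).
#' @return A `data.frame` with columns `specimen_id`, `sequence`, `batch`,
#'   `site`, `habitat` (the last three `NA` until joined).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGTACGT", ">s2", "ACGTACGA"), fa)
#' read_barcode_fasta(fa)
#' @export
read_barcode_fasta <- function(path, expected_length = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file is empty: ", path)
  ids <- names(seqs)
  # headers may carry descriptions after whitespace; the id is the first token
  ids <- vapply(strsplit(ids, "[ \t]+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate specimen id(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  sq <- toupper(as.character(seqs))
  records <- data.frame(
    specimen_id = ids, sequence = unname(sq),
    batch = NA_character_, site = NA_character_, habitat = NA_character_,
    stringsAsFactors = FALSE
  )
  validate_records(records, expected_length = expected_length)
  records
}

#' Validate a specimen record table
#'
#' Checks the invariants every downstream stage relies on: unique non-empty
#' ids, non-empty sequences of one common length, characters restricted to
#' IUPAC codes and `-`.
#'
#' @param records Specimen table as returned by [read_barcode_fasta()].
#' @param expected_length Optional required sequence length.
#' @return The validated table, invisibly.
#' @export
validate_records <- function(records, expected_length = NULL) {
  stopifnot(is.data.frame(records),
            all(c("specimen_id", "sequence") %in% names(records)))
  if (nrow(records) == 0L) stop("no specimen records")
  if (anyNA(records$specimen_id) || any(!nzchar(records$specimen_id)))
    stop("empty specimen id")
  dup <- unique(records$specimen_id[duplicated(records$specimen_id)])
  if (length(dup) > 0L)
    stop("duplicate specimen id(s): ", paste(dup, collapse = ", "))
  len <- nchar(records$sequence)
  if (any(len == 0L)) stop("empty sequence(s)")
  if (!is.null(expected_length)) {
    bad <- records$specimen_id[len != expected_length]
    if (length(bad) > 0L) {
      stop("sequence length != ", expected_length, " for: ",
           paste(bad, collapse = ", "))
    }
  } else if (length(unique(len)) > 1L) {
    stop("sequences are not all the same length (lengths: ",
         paste(sort(unique(len)), collapse = ", "),
         "); align or trim before import")
  }
  chars <- unique(strsplit(paste(records$sequence, collapse = ""), "")[[1]])
  bad <- setdiff(chars, .IUPAC)
  if (length(bad) > 0L)
    stop("invalid sequence character(s): ", paste(bad, collapse = " "))
  invisible(records)
}

#' Write barcode records to FASTA
#'
#' @param records Specimen table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(setNames(records$sequence, records$specimen_id))
  Biostrings::writeXStringSet(x, path, width = 20000L)
  invisible(path)
}

#' Join specimen metadata onto barcode records
#'
#' The metadata table is a tab-delimited file (header row required) with
#' columns `specimen_id`, `batch`, `site`, `habitat`; `site`/`habitat` may be
#' blank. Records absent from the table get `batch = "unassigned"` with a
#' warning; table rows whose id matches no record are ignored with a warning.
#'
#' @param records Specimen table.
#' @param table Path to the metadata TSV, or a data.frame with the same
#'   columns.
#' @return The annotated specimen table.
#' @export
join_metadata <- function(records, table) {
  meta <- if (is.data.frame(table)) table else read_tsv_checked(
    table, c("specimen_id", "batch", "site", "habitat"))
  meta$specimen_id <- as.character(meta$specimen_id)
  unknown <- setdiff(meta$specimen_id, records$specimen_id)
  if (length(unknown) > 0L) {
    warning("metadata row(s) for unknown specimen id(s) ignored: ",
            paste(unknown, collapse = ", "))
    meta <- meta[!meta$specimen_id %in% unknown, , drop = FALSE]
  }
  if (anyDuplicated(meta$specimen_id))
    stop("metadata lists a specimen more than once: ",
         paste(unique(meta$specimen_id[duplicated(meta$specimen_id)]),
               collapse = ", "))
  idx <- match(records$specimen_id, meta$specimen_id)
  records$batch <- as.character(meta$batch[idx])
  records$site <- as.character(meta$site[idx])
  records$habitat <- as.character(meta$habitat[idx])
  missing <- is.na(idx)
  if (any(missing)) {
    warning(sum(missing), " record(s) absent from metadata; batch set to ",
            '"unassigned": ',
            paste(records$specimen_id[missing], collapse = ", "))
    records$batch[missing] <- "unassigned"
  }
  records
}

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
               check.names = FALSE, quote = "", comment.char = ""),
    error = function(e) stop("malformed TSV ", path, ": ", conditionMessage(e))
  )
  miss <- setdiff(required_cols, names(tab))
  if (length(miss) > 0L)
    stop("TSV ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' Read a morphospecies table
#'
#' Tab-delimited, header row required, columns `specimen_id` and
#' `morphospecies`; restricted to the specimens actually examined. Labels
#' must be non-empty and each specimen may carry at most one label.
#'
#' @param path TSV path.
#' @param specimen_ids Optional character vector of known dataset ids; if
#'   given, morphospecies rows must all refer to these ids.
#' @return A `data.frame` with columns `specimen_id`, `morphospecies`.
#' @export
read_morphospecies <- function(path, specimen_ids = NULL) {
  tab <- read_tsv_checked(path, c("specimen_id", "morphospecies"))
  tab <- tab[, c("specimen_id", "morphospecies")]
  if (any(!nzchar(tab$morphospecies)) || anyNA(tab$morphospecies))
    stop("empty morphospecies label(s)")
  if (anyDuplicated(tab$specimen_id))
    stop("specimen(s) with more than one morphospecies label: ",
         paste(unique(tab$specimen_id[duplicated(tab$specimen_id)]),
               collapse = ", "))
  if (!is.null(specimen_ids)) {
    unknown <- setdiff(tab$specimen_id, specimen_ids)
    if (length(unknown) > 0L)
      stop("morphospecies table refers to unknown specimen id(s): ",
           paste(unknown, collapse = ", "))
  }
  tab
}

#' Import an externally produced partition
#'
#' Reads a specimen-to-cluster table as produced by third-party species
#' delimitation tools (ABGD, PTP, ...). The file must assign every specimen
#' of the dataset to exactly one cluster.
#'
#' @param path TSV with columns `specimen_id`, `motu_id`.
#' @param specimen_ids Optional character vector of the dataset's ids; if
#'   given, totality is enforced (a specimen missing from the file is a hard
#'   error).
#' @param method Method tag recorded on the partition; default `"imported"`.
#' @return A [motu_partition] object.
#' @export
import_partition <- function(path, specimen_ids = NULL, method = "imported") {
  tab <- read_tsv_checked(path, c("specimen_id", "motu_id"))
  # a specimen listed twice with the same motu_id is tolerated, different ids
  # are a contradiction
  tab <- unique(tab[, c("specimen_id", "motu_id")])
  dup <- unique(tab$specimen_id[duplicated(tab$specimen_id)])
  if (length(dup) > 0L)
    stop("specimen(s) assigned to more than one cluster: ",
         paste(dup, collapse = ", "))
  if (!is.null(specimen_ids)) {
    missing <- setdiff(specimen_ids, tab$specimen_id)
    if (length(missing) > 0L)
      stop("partition does not cover specimen(s): ",
           paste(missing, collapse = ", "))
    extra <- setdiff(tab$specimen_id, specimen_ids)
    if (length(extra) > 0L)
      stop("partition lists unknown specimen(s): ",
           paste(extra, collapse = ", "))
  }
  new_partition(setNames(as.character(tab$motu_id), tab$specimen_id),
                method = method, threshold = NA_real_)
}

#' Write a partition to TSV
#'
#' @param partition A [motu_partition].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- as.data.frame(partition)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter barcodes by stop codons
#'
#' Putative pseudogenes (NUMTs) and other artefactual barcodes are flagged by
#' translating each sequence and looking for stop codons. The minibarcode
#' sits inside the COI open reading frame, so any stop codon in the true
#' frame indicates a non-functional copy. Because the reading frame after
#' primer trimming is not always known, the default policy passes a sequence
#' if at least one of the three forward frames is stop-free. Codons
#' containing gaps or ambiguity codes are not counted as stops. A trailing
#' partial codon is ignored.
#'
#' @param records Specimen table.
#' @param genetic_code NCBI genetic code identifier as understood by
#'   [Biostrings::getGeneticCode()]; default `"5"`, invertebrate
#'   mitochondrial.
#' @param frame_policy `"any"` (default) or a fixed frame `"0"`, `"1"`, `"2"`
#'   (offset in bases from the 5' end).
#' @return A list with elements `pass` and `fail` (record tables); `fail`
#'   additionally has a column `stop_frames` listing the offending frame(s).
#' @export
qc_stop_codons <- function(records, genetic_code = "5",
                           frame_policy = c("any", "0", "1", "2")) {
  frame_policy <- match.arg(frame_policy)
  code <- tryCatch(Biostrings::getGeneticCode(genetic_code),
                   error = function(e) stop("unknown genetic code identifier: ",
                                            genetic_code))
  stops <- names(code)[code == "*"]
  validate_records(records)
  frame_has_stop <- function(seq, frame) {
    s <- substring(seq, frame + 1L, nchar(seq))
    n_codon <- nchar(s) %/% 3L
    if (n_codon == 0L) return(FALSE)
    starts <- seq.int(1L, by = 3L, length.out = n_codon)
    codons <- substring(s, starts, starts + 2L)
    any(codons %in% stops)
  }
  stop_mat <- t(vapply(records$sequence, function(s)
    vapply(0:2, function(f) frame_has_stop(s, f), logical(1)),
    logical(3)))
  pass <- if (frame_policy == "any") {
    !apply(stop_mat, 1L, all)
  } else {
    !stop_mat[, as.integer(frame_policy) + 1L]
  }
  fail <- records[!pass, , drop = FALSE]
  if (nrow(fail) > 0L) {
    fail$stop_frames <- apply(stop_mat[!pass, , drop = FALSE], 1L, function(z)
      paste(which(z) - 1L, collapse = ","))
  } else {
    fail$stop_frames <- character(0)
  }
  rownames(fail) <- NULL
  list(pass = `rownames<-`(records[pass, , drop = FALSE], NULL), fail = fail)
}
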