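# Synthetic barcode communities with known species truth.
#
# The generator emulates the structure of a Malaise-trap minibarcode data
# set: a species-abundance distribution with many rare species, tight
# intraspecific haplotype clouds, a wide barcode gap to other species, and
# optionally injected anomalies (cryptic species pairs below 2% divergence,
# deep conspecific lineages above 3%, pseudogene-like stop-bearing copies).
# Sequences are stop-free protein-coding in frame 0 by construction;
# mutations are substitutions only, so sequences stay aligned.

#' Specify a synthetic barcode community
#'
#' Validates and freezes the parameters of one simulated community. All
#' divergences are fractions of the sequence length.
#'
#' @param n_species Number of true species.
#' @param total Total number of specimens (>= `n_species`; every species
#'   gets at least one).
#' @param abundance Abundance model: `"geometric"` (rank-abundance weights
#'   `(1-p)^(k-1)`), `"logseries"` or `"uniform"`.
#' @param p Geometric parameter; the default 0.18 yields roughly 20%
#'   singleton species at the default community size.
#' @param alpha Log-series diversity parameter.
#' @param seq_length Barcode length in bp (default 313, a COI minibarcode).
#' @param max_intra Maximum intraspecific divergence (default 0.01).
#' @param min_inter Minimum interspecific divergence for non-cryptic species
#'   (default 0.05).
#' @param n_cryptic_pairs Species pairs injected at `cryptic_divergence`,
#'   which must lie in (`max_intra`, 0.02].
#' @param cryptic_divergence Divergence of injected cryptic pairs (default
#'   0.015). Cryptic species carry a single haplotype so the realized
#'   divergence is exact.
#' @param n_divergent_conspecifics Species injected with a second
#'   conspecific lineage at `divergent_divergence`.
#' @param divergent_divergence Divergence of the injected deep lineage
#'   (default 0.04; must exceed 0.03 and stay below `min_inter`).
#' @param batch_fraction Fraction of specimens assigned (at random) to
#'   batch 1; the rest are batch 2.
#' @param morph_error_rate Fraction of specimens whose morphospecies label
#'   is deliberately wrong in the emitted morphospecies table.
#' @param n_pseudogenes Specimens whose sequence receives in-frame stop
#'   codons, for testing the stop-codon filter.
#' @param genetic_code Genetic code used to keep frame 0 stop-free (default
#'   `"5"`, invertebrate mitochondrial).
#' @param seed Mandatory integer seed; the same spec yields byte-identical
#'   output.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(n_species = 30L, total = 300L,
                           abundance = c("geometric", "logseries", "uniform"),
                           p = 0.18, alpha = 10,
                           seq_length = 313L,
                           max_intra = 0.01, min_inter = 0.05,
                           n_cryptic_pairs = 0L, cryptic_divergence = 0.015,
                           n_divergent_conspecifics = 0L,
                           divergent_divergence = 0.04,
                           batch_fraction = 0.5,
                           morph_error_rate = 0,
                           n_pseudogenes = 0L,
                           genetic_code = "5", seed) {
  abundance <- match.arg(abundance)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_species >= 1L, total >= n_species, seq_length >= 30L,
            max_intra >= 0, min_inter > max_intra,
            p > 0, p < 1, alpha > 0,
            batch_fraction > 0, batch_fraction < 1,
            morph_error_rate >= 0, morph_error_rate < 1,
            n_pseudogenes >= 0L)
  if (n_cryptic_pairs > 0L) {
    if (!(cryptic_divergence > max_intra && cryptic_divergence <= 0.02))
      stop("cryptic_divergence must lie in (max_intra, 0.02]")
    if (2L * n_cryptic_pairs > n_species)
      stop("not enough species for the requested cryptic pairs")
  }
  if (n_divergent_conspecifics > 0L &&
      !(divergent_divergence > 0.03 && divergent_divergence < min_inter))
    stop("divergent_divergence must lie in (0.03, min_inter)")
  structure(list(
    n_species = as.integer(n_species), total = as.integer(total),
    abundance = abundance, p = p, alpha = alpha,
    seq_length = as.integer(seq_length),
    max_intra = max_intra, min_inter = min_inter,
    n_cryptic_pairs = as.integer(n_cryptic_pairs),
    cryptic_divergence = cryptic_divergence,
    n_divergent_conspecifics = as.integer(n_divergent_conspecifics),
    divergent_divergence = divergent_divergence,
    batch_fraction = batch_fraction,
    morph_error_rate = morph_error_rate,
    n_pseudogenes = as.integer(n_pseudogenes),
    genetic_code = genetic_code, seed = as.integer(seed)
  ), class = "community_spec")
}

# sense codons of a genetic code
sense_codons <- function(genetic_code) {
  code <- Biostrings::getGeneticCode(genetic_code)
  names(code)[code != "*"]
}

random_coding_seq <- function(length, sense) {
  n_codons <- ceiling(length / 3)
  substr(paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
         1L, length)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# substitute exactly n_sub sites, codon-aware so frame 0 stays stop-free;
# each codon is touched at most once
mutate_coding <- function(seq, n_sub, sense) {
  if (n_sub == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n_codons <- length(chars) %/% 3L
  remaining <- n_sub
  for (idx in sample.int(n_codons)) {
    if (remaining <= 0L) break
    pos <- (idx - 1L) * 3L + 1:3
    cur <- paste(chars[pos], collapse = "")
    cand <- setdiff(sense, cur)
    diffs <- vapply(cand, hamming, numeric(1), a = cur)
    usable <- cand[diffs <= remaining]
    if (length(usable) == 0L) next
    want <- max(diffs[diffs <= remaining])
    pick <- sample(cand[diffs == want], 1L)
    chars[pos] <- strsplit(pick, "")[[1]]
    remaining <- remaining - want
  }
  if (remaining > 0L)
    stop("could not place ", n_sub, " substitutions")
  paste(chars, collapse = "")
}

# deterministic largest-remainder allocation of `total` specimens to ranked
# species, one guaranteed each
allocate_abundances <- function(spec) {
  k <- seq_len(spec$n_species)
  w <- switch(spec$abundance,
    geometric = (1 - spec$p)^(k - 1),
    logseries = { x <- spec$total / (spec$total + spec$alpha); x^k / k },
    uniform = rep(1, spec$n_species))
  extra <- spec$total - spec$n_species
  e <- extra * w / sum(w)
  a <- floor(e)
  rem <- extra - sum(a)
  if (rem > 0) {
    ord <- order(e - a, k, decreasing = c(TRUE, FALSE), method = "radix")
    a[ord[seq_len(rem)]] <- a[ord[seq_len(rem)]] + 1
  }
  as.integer(a) + 1L
}

#' Simulate a barcode community with known truth
#'
#' Generates specimen barcodes under the model described in
#' [community_spec()]: species ancestors are random stop-free coding
#' sequences, redrawn until all pairs satisfy the minimum interspecific
#' divergence (bounded retries; an infeasible spec is an error); specimens
#' sample haplotypes within the intraspecific bound (each haplotype differs
#' from the species ancestor at no more than `floor(max_intra*L/2)` sites,
#' so the maximum intraspecific distance respects `max_intra`); cryptic
#' pairs and divergent conspecific lineages are injected with an exact
#' substitution count; batches are assigned at random with the configured
#' split. Species involved in cryptic pairs carry a single haplotype so
#' their pairwise divergence is exactly the configured value.
#'
#' @param spec A [community_spec()].
#' @return A list of class `community_sim`: `records` (specimen table with
#'   batch labels), `truth` (`specimen_id`, `species`, `lineage`,
#'   `haplotype`, `anomaly`), `morph` (`specimen_id`, `morphospecies`),
#'   `spec`.
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)
  sense <- sense_codons(spec$genetic_code)
  L <- spec$seq_length

  # --- species ancestors with a guaranteed barcode gap
  ancestors <- character(spec$n_species)
  far_enough <- function(cand, others) {
    all(vapply(others, function(o)
      hamming(cand, o) / L >= spec$min_inter, logical(1)))
  }
  for (i in seq_len(spec$n_species)) {
    ok <- FALSE
    for (try in 1:100) {
      cand <- random_coding_seq(L, sense)
      if (far_enough(cand, ancestors[seq_len(i - 1L)])) { ok <- TRUE; break }
    }
    if (!ok) stop("infeasible spec: could not draw ancestor ", i,
                  " at min_inter = ", spec$min_inter)
    ancestors[i] <- cand
  }

  species_ids <- sprintf("sp%03d", seq_len(spec$n_species))
  anomaly <- setNames(rep("none", spec$n_species), species_ids)

  # --- cryptic pairs: species 2k overwritten as a near neighbour of 2k-1
  if (spec$n_cryptic_pairs > 0L) {
    for (k in seq_len(spec$n_cryptic_pairs)) {
      a <- 2L * k - 1L
      b <- 2L * k
      ancestors[b] <- mutate_coding(ancestors[a],
                                    round(spec$cryptic_divergence * L), sense)
      anomaly[c(a, b)] <- "cryptic_pair"
    }
  }

  abund <- allocate_abundances(spec)

  # --- divergent conspecific lineages: most abundant unanomalous species
  lineage_b <- setNames(rep(NA_character_, spec$n_species), species_ids)
  if (spec$n_divergent_conspecifics > 0L) {
    eligible <- which(anomaly == "none" & abund >= 4L)
    if (length(eligible) < spec$n_divergent_conspecifics)
      stop("infeasible spec: not enough abundant species for divergent ",
           "conspecific lineages")
    chosen <- eligible[order(-abund[eligible])][
      seq_len(spec$n_divergent_conspecifics)]
    for (i in chosen) {
      lineage_b[i] <- mutate_coding(ancestors[i],
                                    round(spec$divergent_divergence * L),
                                    sense)
      anomaly[i] <- "divergent_conspecific"
    }
  }

  # --- haplotype clouds and specimens
  hap_max_sub <- floor(spec$max_intra * L / 2)
  make_haplotypes <- function(ancestor, n, single_hap) {
    if (single_hap || hap_max_sub == 0L) return(ancestor)
    n_hap <- min(3L, n)
    haps <- ancestor
    for (j in seq_len(n_hap - 1L))
      haps <- c(haps, mutate_coding(ancestor, hap_max_sub, sense))
    haps
  }
  rows <- vector("list", spec$n_species)
  for (i in seq_len(spec$n_species)) {
    n_i <- abund[i]
    single_hap <- anomaly[i] == "cryptic_pair"
    if (!is.na(lineage_b[i])) {
      n_b <- max(1L, n_i %/% 2L)
      n_a <- n_i - n_b
      haps_a <- make_haplotypes(ancestors[i], n_a, single_hap)
      haps_b <- make_haplotypes(lineage_b[i], n_b, single_hap)
      hap_of <- c(sample(seq_along(haps_a), n_a, replace = TRUE,
                         prob = 0.6^(seq_along(haps_a) - 1L)),
                  length(haps_a) + sample(seq_along(haps_b), n_b,
                                          replace = TRUE,
                                          prob = 0.6^(seq_along(haps_b) - 1L)))
      seqs <- c(haps_a, haps_b)[hap_of]
      lin <- rep(c("A", "B"), c(n_a, n_b))
    } else {
      haps <- make_haplotypes(ancestors[i], n_i, single_hap)
      hap_of <- sample(seq_along(haps), n_i, replace = TRUE,
                       prob = 0.6^(seq_along(haps) - 1L))
      # the ancestor haplotype is always realized so the "main haplotype"
      # is well defined
      hap_of[1L] <- 1L
      seqs <- haps[hap_of]
      lin <- rep("A", n_i)
    }
    rows[[i]] <- data.frame(species = species_ids[i], lineage = lin,
                            haplotype = sprintf("%s_%s_h%d", species_ids[i],
                                                lin, hap_of),
                            sequence = unname(seqs),
                            anomaly = unname(anomaly[i]),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  tab$specimen_id <- sprintf("SP%04d", seq_len(n))

  # --- pseudogene-like copies: in-frame stops for QC testing
  if (spec$n_pseudogenes > 0L) {
    idx <- sample.int(n, min(spec$n_pseudogenes, n))
    for (j in idx) {
      chars <- strsplit(tab$sequence[j], "")[[1]]
      chars[28:30] <- c("T", "A", "A")
      chars[58:60] <- c("T", "A", "A")
      tab$sequence[j] <- paste(chars, collapse = "")
      tab$anomaly[j] <- "pseudogene"
    }
  }

  # --- batches
  n1 <- round(spec$batch_fraction * n)
  batch <- rep("2", n)
  batch[sample.int(n, n1)] <- "1"

  records <- data.frame(specimen_id = tab$specimen_id,
                        sequence = tab$sequence, batch = batch,
                        site = "simulated", habitat = "simulated",
                        stringsAsFactors = FALSE)
  truth <- data.frame(specimen_id = tab$specimen_id, species = tab$species,
                      lineage = tab$lineage, haplotype = tab$haplotype,
                      anomaly = tab$anomaly, stringsAsFactors = FALSE)

  # --- morphospecies = truth, with optional label error
  morph <- data.frame(specimen_id = truth$specimen_id,
                      morphospecies = truth$species,
                      stringsAsFactors = FALSE)
  n_err <- floor(spec$morph_error_rate * n)
  if (n_err > 0L && spec$n_species > 1L) {
    idx <- sample.int(n, n_err)
    for (j in idx) {
      morph$morphospecies[j] <- sample(
        setdiff(species_ids, morph$morphospecies[j]), 1L)
    }
  }
  structure(list(records = records, truth = truth, morph = morph,
                 spec = spec),
            class = "community_sim")
}

#' @export
print.community_sim <- function(x, ...) {
  cat("Simulated community: ", nrow(x$records), " specimens, ",
      x$spec$n_species, " species (seed ", x$spec$seed, ")\n", sep = "")
  anom <- table(x$truth$anomaly[!duplicated(x$truth$species)])
  cat("  species anomalies:",
      paste(names(anom), anom, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated community to disk
#'
#' Emits the exact formats the pipeline consumes: `barcodes.fasta`,
#' `metadata.tsv` (specimen_id, batch, site, habitat), `morphospecies.tsv`
#' and `truth.tsv`.
#'
#' @param sim A `community_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_barcode_fasta(sim$records, file.path(dir, "barcodes.fasta"))
  write.table(sim$records[, c("specimen_id", "batch", "site", "habitat")],
              file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$morph, file.path(dir, "morphospecies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
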