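# Pseudo-reference construction: substitute each sample's called alleles
# into the reference, resolve heterozygous sites to one random allele, mask
# repeats / low-support / indel sites as N, and stack samples into a
# complete-column site matrix.

#' Build a per-sample pseudo-reference sequence
#'
#' Homozygous calls are substituted into the reference; heterozygous calls
#' are resolved to one allele chosen uniformly at random, with the draw
#' determined by `(seed, chromosome, position, sample)` so the resolution is
#' independent of processing order. Positions inside mask intervals or whose
#' support metric (per-sample GQ, falling back to site QUAL, treated as
#' passing when both are absent) falls below `quality_threshold` are set to
#' N, as are indel and non-SNV calls. Positions with no call keep the
#' reference base.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param variants Genotype table as from [read_vcf_genotypes()].
#' @param sample Sample name (a column of `variants$gt`).
#' @param seed Integer master seed for heterozygote resolution.
#' @param quality_threshold Minimum support score (default 20).
#' @param mask Optional data.frame of mask intervals with `chrom`, `start`,
#'   `end` (0-based half-open), e.g. from [read_bed()].
#' @return An object of class `masked_sequence`: list with `sample`, `seq`
#'   (named list of character vectors over A/C/G/T/N), and `flags` counting
#'   masked positions by provenance (`repeat_mask`, `low_support`,
#'   `non_snv`) plus `n_het_resolved`, `n_skipped_non_snv`.
#' @export
build_pseudoreference <- function(reference, variants, sample, seed,
                                  quality_threshold = 20, mask = NULL) {
  stopifnot(is.character(reference), !is.null(names(reference)))
  seqs <- lapply(reference, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  flags <- c(repeat_mask = 0L, low_support = 0L, non_snv = 0L)
  n_het <- 0L; n_skip <- 0L
  if (length(variants$pos)) {
    if (!sample %in% variants$samples) stop("unknown sample: ", sample)
    gt <- variants$gt[, sample]
    gq <- if (!is.null(variants$gq)) variants$gq[, sample] else rep(NA_real_, length(gt))
    for (i in seq_along(variants$pos)) {
      chrom <- variants$chrom[i]
      if (!chrom %in% names(reference)) stop("variant on unknown chromosome: ", chrom)
      pos <- variants$pos[i]                      # 1-based
      if (pos > length(seqs[[chrom]])) stop("variant position beyond reference length")
      alleles <- c(variants$ref[i], variants$alt[[i]])
      g <- gt[i]
      if (is.na(g) || g %in% c("./.", ".")) next  # no call: keep reference base
      ai <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]])) + 1L
      if (any(is.na(ai))) next
      called <- alleles[ai]
      if (any(nchar(called) != 1L) || any(!called %in% c("A", "C", "G", "T"))) {
        # indels / symbolic alleles are masked, keeping samples length-aligned
        seqs[[chrom]][pos] <- "N"
        flags["non_snv"] <- flags["non_snv"] + 1L
        n_skip <- n_skip + 1L
        next
      }
      support <- if (!is.na(gq[i])) gq[i] else variants$qual[i]
      if (!is.na(support) && support < quality_threshold) {
        seqs[[chrom]][pos] <- "N"
        flags["low_support"] <- flags["low_support"] + 1L
        next
      }
      if (length(unique(called)) == 1L) {
        seqs[[chrom]][pos] <- called[1]
      } else {
        # random draw among the called genotype's alleles only
        u <- unit_runif(seed, list("het", chrom, pos, sample))
        seqs[[chrom]][pos] <- called[1L + (u >= 0.5)]
        n_het <- n_het + 1L
      }
    }
  }
  if (!is.null(mask) && nrow(mask)) {
    for (i in seq_len(nrow(mask))) {
      chrom <- mask$chrom[i]
      if (!chrom %in% names(seqs)) next
      lo <- max(mask$start[i] + 1L, 1L)           # to 1-based inclusive
      hi <- min(mask$end[i], length(seqs[[chrom]]))
      if (hi >= lo) {
        flags["repeat_mask"] <- flags["repeat_mask"] +
          sum(seqs[[chrom]][lo:hi] != "N")
        seqs[[chrom]][lo:hi] <- "N"
      }
    }
  }
  structure(list(sample = sample, seq = seqs, flags = flags,
                 n_het_resolved = n_het, n_skipped_non_snv = n_skip),
            class = "masked_sequence")
}

#' Stack pseudo-references into a complete-column site matrix
#'
#' Retains exactly the columns where no sample has an N; positions are
#' recorded in 0-based reference coordinates.
#'
#' @param sequences List of `masked_sequence` objects (or named list of
#'   per-chromosome character vectors per sample).
#' @param groups Optional named character vector, sample -> group label.
#' @param chrom_lengths Optional named vector of chromosome lengths;
#'   inferred from the sequences when NULL.
#' @return An object of class `site_matrix`; see [site_matrix()].
#' @export
build_site_matrix <- function(sequences, groups = NULL, chrom_lengths = NULL) {
  if (!length(sequences)) stop("no sequences")
  getseq <- function(x) if (inherits(x, "masked_sequence")) x$seq else x
  getname <- function(x, i) if (inherits(x, "masked_sequence")) x$sample else names(sequences)[i]
  samples <- vapply(seq_along(sequences), function(i) getname(sequences[[i]], i), character(1))
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  chroms <- names(getseq(sequences[[1]]))
  lens <- vapply(getseq(sequences[[1]]), length, integer(1))
  for (x in sequences) {
    s <- getseq(x)
    if (!identical(names(s), chroms) || !identical(vapply(s, length, integer(1)), lens))
      stop("sequences differ in length or chromosome set")
  }
  if (is.null(chrom_lengths)) chrom_lengths <- lens
  base_list <- list(); pos_list <- list(); chr_list <- list()
  for (chrom in chroms) {
    m <- do.call(rbind, lapply(sequences, function(x) getseq(x)[[chrom]]))
    keep <- colSums(m == "N") == 0L
    base_list[[chrom]] <- m[, keep, drop = FALSE]
    pos_list[[chrom]] <- which(keep) - 1L        # 0-based
    chr_list[[chrom]] <- rep(chrom, sum(keep))
  }
  bases <- do.call(cbind, base_list)
  rownames(bases) <- samples
  site_matrix(samples = samples, chrom = unlist(chr_list, use.names = FALSE),
              pos = unlist(pos_list, use.names = FALSE), bases = bases,
              groups = groups, chrom_lengths = chrom_lengths)
}

#' Construct a site matrix
#'
#' The substrate of all downstream popgen and phylogenomic statistics: one
#' base per sample per retained reference position, complete columns only.
#' A compact form stores only variable columns and records the number of
#' retained invariant columns in `n_invariant` (used by the simulator path,
#' where every position is retained).
#'
#' @param samples Character vector of sample ids (matrix row order).
#' @param chrom Character vector, chromosome of each stored column.
#' @param pos Integer vector, 0-based reference position of each column
#'   (strictly increasing within a chromosome).
#' @param bases Character matrix, samples x stored columns, over A/C/G/T.
#' @param groups Optional named character vector sample -> group.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_invariant Count of retained invariant columns not stored
#'   explicitly (0 for fully materialized matrices).
#' @param compact Logical: TRUE when only variable columns are stored and
#'   every reference position is retained.
#' @return Object of class `site_matrix`.
#' @export
site_matrix <- function(samples, chrom, pos, bases, groups = NULL,
                        chrom_lengths = NULL, n_invariant = 0L,
                        compact = FALSE) {
  stopifnot(is.matrix(bases), nrow(bases) == length(samples),
            ncol(bases) == length(pos), length(chrom) == length(pos))
  if (any(bases == "N")) stop("site matrix must have complete columns (no N)")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) stop("positions must be strictly increasing")
  }
  if (!is.null(groups)) {
    if (!all(samples %in% names(groups))) stop("groups must cover all samples")
    groups <- groups[samples]
  }
  structure(list(samples = samples, chrom = chrom, pos = pos, bases = bases,
                 groups = groups, chrom_lengths = chrom_lengths,
                 n_invariant = as.numeric(n_invariant), compact = compact),
            class = "site_matrix")
}

#' @export
print.site_matrix <- function(x, ...) {
  cat("Site matrix:", length(x$samples), "samples x",
      format(n_sites(x), big.mark = " "), "retained sites (",
      ncol(x$bases), "stored columns )\n")
  invisible(x)
}

#' Total retained sites of a site matrix (stored + unstored invariant)
#' @param x A `site_matrix`.
#' @return Numeric count.
#' @export
n_sites <- function(x) ncol(x$bases) + x$n_invariant

#' Site matrix of true simulated haplotypes
#'
#' Builds the compact matrix of one row per haplotype (or, with
#' `one_per_sample`, a random haplotype per individual, emulating the
#' pseudo-reference convention of one sequence per sample) at all variant
#' columns, with all invariant positions counted as retained.
#'
#' @param ds A [simulate_dataset()] result.
#' @param groups Optional named character vector (haplotype or sample ->
#'   group); by default the species name parsed from the label.
#' @return A `site_matrix`.
#' @export
site_matrix_from_sim <- function(ds, groups = NULL) {
  stopifnot(inherits(ds, "sim_dataset"))
  hap <- ds$hap_gt
  m <- length(ds$variants$pos)
  bases <- matrix(rep(ds$variants$ref, each = nrow(hap)), nrow(hap), m,
                  dimnames = list(rownames(hap), NULL))
  if (m) {
    alt <- unlist(ds$variants$alt, use.names = FALSE)
    for (j in seq_len(m)) bases[hap[, j], j] <- alt[j]
  }
  if (is.null(groups)) {
    sp <- sub("_[0-9]+_[12]$", "", rownames(hap))
    groups <- stats::setNames(sp, rownames(hap))
  }
  total <- ds$model$n_windows * ds$model$window_length
  site_matrix(samples = rownames(hap),
              chrom = rep(ds$chrom, m),
              pos = ds$variants$pos - 1L,
              bases = bases, groups = groups,
              chrom_lengths = stats::setNames(total, ds$chrom),
              n_invariant = total - m, compact = TRUE)
}
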