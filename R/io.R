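# Format boundaries. Internal conventions used everywhere in the package:
#   * coordinates 0-based half-open; VCF (1-based) and GFF3 (1-based closed)
#     are converted exactly once, here;
#   * a "reference" is a named character vector, one string per chromosome;
#   * trees are ape "phylo" objects.

#' Read a FASTA file into a named character vector
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read a multi-sample VCF into a genotype table
#'
#' Keeps the fields the pipeline uses: CHROM, POS, REF, ALT, QUAL, per-sample
#' GT and (when present) GQ.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @return A list with elements `chrom`, `pos` (1-based integer), `ref`,
#'   `alt` (list of character vectors), `qual` (numeric, NA when missing),
#'   `gt` (character matrix sites x samples, e.g. "0/1"), `gq` (numeric
#'   matrix or NULL) and `samples`.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  gq <- NULL
  if ("GQ" %in% unlist(strsplit(v@gt[1, "FORMAT"], ":"))) {
    gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
    if (is.null(dim(gq))) gq <- matrix(gq, nrow = nrow(fix), dimnames = dimnames(gt))
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  list(chrom = as.character(fix[, "CHROM"]),
       pos = as.integer(fix[, "POS"]),
       ref = as.character(fix[, "REF"]),
       alt = strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE),
       qual = qual,
       gt = gt, gq = gq,
       samples = colnames(gt))
}

#' Write a genotype table as VCF v4.2
#' @param vt A genotype table as returned by [read_vcf_genotypes()].
#' @param path Output path; written gzipped, use a `.vcf.gz` suffix.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(vt, path) {
  n <- length(vt$pos)
  fix <- cbind(CHROM = vt$chrom,
               POS = as.character(vt$pos),
               ID = rep(".", n),
               REF = vt$ref,
               ALT = vapply(vt$alt, paste, character(1), collapse = ","),
               QUAL = ifelse(is.na(vt$qual), ".", format(vt$qual, trim = TRUE, scientific = FALSE)),
               FILTER = rep("PASS", n),
               INFO = rep(".", n))
  fmt <- if (is.null(vt$gq)) "GT" else "GT:GQ"
  gt <- vt$gt
  if (!is.null(vt$gq)) {
    gt <- matrix(paste(vt$gt, ifelse(is.na(vt$gq), ".", format(vt$gq, trim = TRUE)), sep = ":"),
                 nrow = n, dimnames = dimnames(vt$gt))
  }
  gtm <- cbind(FORMAT = rep(fmt, n), gt)
  meta <- c("##fileformat=VCFv4.2",
            "##source=oakdiv",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            if (!is.null(vt$gq))
              "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
  obj <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                      meta = meta, fix = fix, gt = gtm)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path Path to a BED file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write intervals to BED
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  lines <- paste(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                 format(df$end, scientific = FALSE, trim = TRUE), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene and exon features from a GFF3 file
#'
#' @param path Path to a GFF3 file.
#' @param types Feature types to keep (column 3), e.g. `c("gene", "exon")`.
#' @return data.frame with `id`, `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `type`, `parent`.
#' @export
read_gff3_features <- function(path, types = c("gene", "exon")) {
  gr <- rtracklayer::import.gff3(path)
  gr <- gr[as.character(gr$type) %in% types]
  md <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(md))
    vapply(md$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_, character(1))
  else rep(NA_character_, length(gr))
  data.frame(id = id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             type = as.character(gr$type),
             parent = parent,
             stringsAsFactors = FALSE)
}

#' Read newick trees
#' @param path Path to a newick file (one or more trees).
#' @return An ape `phylo` or `multiPhylo` object.
#' @export
read_trees <- function(path) ape::read.tree(path)

#' Write trees to newick
#' @param trees `phylo` or `multiPhylo` (or list of `phylo`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) {
    class(trees) <- "phylo"              # drop subclasses for dispatch
    trees <- list(trees)
  }
  if (!inherits(trees, "multiPhylo")) trees <- structure(trees, class = "multiPhylo")
  if (length(trees) == 0L) writeLines(character(0), path)
  else ape::write.tree(trees, file = path)
  invisible(path)
}

#' Write a data frame as TSV with a fixed column order
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with header
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
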