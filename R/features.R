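# Interval accounting: R-gene cluster aggregation, per-chromosome density
# bins, structural-variant size classes, and gene/exon/repeat overlap
# reports. All coordinates are 0-based half-open; IRanges does the interval
# algebra.

.sv_types <- c("inversion", "translocation", "insertion", "deletion",
               "duplicated region", "inverted duplicate", "tandem repeat",
               "copy gain", "copy loss")

.size_breaks <- c(100, 1e3, 1e4, 1e5, 1e6, Inf)
.size_labels <- c("100 to <1 kb", "1 to <10 kb", "10 to <100 kb",
                  "100 kb to <1 Mb", ">=1 Mb")

.check_intervals <- function(df, what = "feature") {
  if (!all(c("chrom", "start", "end") %in% names(df)))
    stop(what, " table needs chrom/start/end columns")
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("malformed ", what, " interval: need 0 <= start < end")
  invisible(df)
}

.as_iranges <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)

#' Aggregate same-category features into positional clusters
#'
#' Per chromosome and category, features sorted by start are chained into a
#' cluster while the gap to the running end of the chain (the maximum end
#' seen so far) is at most `max_gap`; maximal chains with at least
#' `min_size` members are clusters. This equals the transitive closure of
#' the pairwise "within `max_gap`" relation.
#'
#' @param features data.frame with `id`, `chrom`, `start`, `end`,
#'   `category` (0-based half-open coordinates).
#' @param max_gap Maximum gap in bases between chained features
#'   (default 200 kb).
#' @param min_size Minimum members per cluster (default 2; a lone gene is
#'   not a cluster).
#' @return Object of class `feature_clusters`: list with `members`
#'   (features plus a `cluster` id, NA for unclustered) and `summary`
#'   (per category: `n_features`, `n_clusters`, `pct_in_clusters`,
#'   `largest_cluster`).
#' @export
cluster_features <- function(features, max_gap = 200000, min_size = 2L) {
  .check_intervals(features)
  if (!"category" %in% names(features) || any(!nzchar(features$category)))
    stop("features need a non-empty category")
  features$cluster <- NA_character_
  cl_id <- 0L
  for (cat in unique(features$category)) {
    for (ch in unique(features$chrom[features$category == cat])) {
      idx <- which(features$category == cat & features$chrom == ch)
      idx <- idx[order(features$start[idx], features$end[idx])]
      run <- idx[1]; run_end <- features$end[idx[1]]
      flush <- function(run) {
        if (length(run) >= min_size) {
          cl_id <<- cl_id + 1L
          features$cluster[run] <<- sprintf("c%04d", cl_id)
        }
      }
      for (i in idx[-1]) {
        if (features$start[i] - run_end <= max_gap) {
          run <- c(run, i)
          run_end <- max(run_end, features$end[i])
        } else {
          flush(run)
          run <- i; run_end <- features$end[i]
        }
      }
      flush(run)
    }
  }
  summ <- do.call(rbind, lapply(unique(features$category), function(cat) {
    f <- features[features$category == cat, ]
    sizes <- table(f$cluster)
    data.frame(category = cat, n_features = nrow(f),
               n_clusters = length(sizes),
               pct_in_clusters = round(100 * sum(!is.na(f$cluster)) / nrow(f), 1),
               largest_cluster = if (length(sizes)) max(sizes) else 0L)
  }))
  structure(list(members = features, summary = summ), class = "feature_clusters")
}

#' @export
print.feature_clusters <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Feature counts in fixed-size genomic bins
#'
#' Counts feature starts per half-open bin `[k*bin, (k+1)*bin)`; the last
#' (possibly partial) bin is included, so each vector has
#' `ceiling(length/bin)` entries.
#'
#' @param features data.frame with `chrom`, `start`, `end`.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param bin Bin width in bases (default 2 Mb).
#' @return Named list of integer count vectors, one per chromosome.
#' @export
density_bins <- function(features, chrom_lengths, bin = 2e6) {
  .check_intervals(features)
  bad <- !features$chrom %in% names(chrom_lengths) |
    features$start >= chrom_lengths[features$chrom]
  if (any(bad)) stop("feature beyond chromosome length")
  out <- lapply(names(chrom_lengths), function(ch) {
    nb <- ceiling(chrom_lengths[[ch]] / bin)
    v <- integer(nb)
    st <- features$start[features$chrom == ch]
    if (length(st)) {
      t <- table(floor(st / bin))
      v[as.integer(names(t)) + 1L] <- as.integer(t)
    }
    v
  })
  names(out) <- names(chrom_lengths)
  out
}

#' Tabulate structural variants into size classes
#'
#' Records shorter than 100 bases are excluded (count attached as
#' attribute `"n_excluded"`); each remaining record falls in exactly one
#' left-closed, right-open class.
#'
#' @param records data.frame with `type` and either `length` or
#'   `start`/`end` (0-based half-open).
#' @return Object of class `sv_size_table`: list with `counts` (types x
#'   classes matrix), `row_totals`, `col_totals`, `grand_total`.
#' @export
classify_sv_sizes <- function(records) {
  if (!"length" %in% names(records)) {
    .check_intervals(records, "SV")
    records$length <- records$end - records$start
  }
  bad <- setdiff(unique(records$type), .sv_types)
  if (length(bad)) stop("unknown SV type: ", paste(bad, collapse = ", "))
  n_excluded <- sum(records$length < 100)
  records <- records[records$length >= 100, , drop = FALSE]
  cls <- cut(records$length, breaks = .size_breaks, labels = .size_labels,
             right = FALSE)
  counts <- table(factor(records$type, levels = .sv_types), cls)
  counts <- matrix(as.integer(counts), nrow = length(.sv_types),
                   dimnames = list(.sv_types, .size_labels))
  row_totals <- rowSums(counts); storage.mode(row_totals) <- "integer"
  col_totals <- colSums(counts); storage.mode(col_totals) <- "integer"
  structure(list(counts = counts,
                 row_totals = row_totals,
                 col_totals = col_totals,
                 grand_total = sum(counts)),
            class = "sv_size_table", n_excluded = n_excluded)
}

#' @export
print.sv_size_table <- function(x, ...) {
  m <- cbind(x$counts, Total = x$row_totals)
  m <- rbind(m, All = c(x$col_totals, x$grand_total))
  print(m)
  invisible(x)
}

#' Overlap accounting between genes, exons and structural variants
#'
#' A gene counts as overlapped when any SV intersects its body by at least
#' one base; exonic overlap likewise against the gene's exons. Intervals
#' are half-open, so adjacency is not overlap.
#'
#' @param genes data.frame with `id`, `chrom`, `start`, `end`.
#' @param exons data.frame with `chrom`, `start`, `end` and `parent`
#'   (gene id). An exon outside its parent gene raises a warning but is
#'   still used.
#' @param svs data.frame with `type`, `chrom`, `start`, `end`.
#' @return Object of class `overlap_report`: `n_genes`,
#'   `n_gene_body_overlap`, `n_exonic_overlap`, fractions of the gene
#'   universe, and `by_sv_type` (distinct overlapped genes per SV type).
#' @export
gene_sv_overlap <- function(genes, exons, svs) {
  .check_intervals(genes, "gene"); .check_intervals(svs, "SV")
  if (nrow(exons)) {
    .check_intervals(exons, "exon")
    g <- genes[match(exons$parent, genes$id), ]
    outside <- !is.na(g$id) & (exons$start < g$start | exons$end > g$end |
                                 exons$chrom != g$chrom)
    if (any(outside)) warning(sum(outside), " exon(s) extend outside their gene")
  }
  body_hit <- rep(FALSE, nrow(genes))
  exon_hit <- rep(FALSE, nrow(genes))
  by_type <- stats::setNames(integer(length(unique(svs$type))), unique(svs$type))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    si <- which(svs$chrom == ch)
    ei <- which(exons$chrom == ch)
    if (!length(gi) || !length(si)) next
    gr <- .as_iranges(genes[gi, ]); sr <- .as_iranges(svs[si, ])
    ov <- IRanges::findOverlaps(gr, sr)
    body_hit[gi[unique(S4Vectors::queryHits(ov))]] <- TRUE
    for (ty in unique(svs$type[si])) {
      hits <- S4Vectors::queryHits(ov)[svs$type[si][S4Vectors::subjectHits(ov)] == ty]
      by_type[ty] <- by_type[ty] + length(unique(genes$id[gi[unique(hits)]]))
    }
    if (length(ei)) {
      er <- .as_iranges(exons[ei, ])
      ove <- IRanges::findOverlaps(er, sr)
      hit_parents <- unique(exons$parent[ei[unique(S4Vectors::queryHits(ove))]])
      exon_hit[genes$id %in% hit_parents & genes$chrom == ch] <- TRUE
    }
  }
  structure(list(n_genes = nrow(genes),
                 n_gene_body_overlap = sum(body_hit),
                 n_exonic_overlap = sum(exon_hit),
                 frac_gene_body = sum(body_hit) / nrow(genes),
                 frac_exonic = sum(exon_hit) / nrow(genes),
                 by_sv_type = sort(by_type, decreasing = TRUE),
                 gene_body_overlap = genes$id[body_hit],
                 exonic_overlap = genes$id[exon_hit]),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("%d of %d genes (%.1f%%) overlap an SV; %d (%.1f%%) in exons\n",
              x$n_gene_body_overlap, x$n_genes, 100 * x$frac_gene_body,
              x$n_exonic_overlap, 100 * x$frac_exonic))
  invisible(x)
}

#' Features overlapped by repeats for at least a fraction of their length
#'
#' Repeat intervals are unioned before computing each feature's overlap, so
#' overlapping repeats are never double-counted; the threshold is
#' inclusive.
#'
#' @param features data.frame with `chrom`, `start`, `end`.
#' @param repeats data.frame with `chrom`, `start`, `end`.
#' @param min_frac Minimum fractional overlap (default 0.10).
#' @return List with `n` (features at/above threshold), `fraction` (of all
#'   features), and `per_feature` (data.frame with `overlap_bases`,
#'   `overlap_frac`, `counted`).
#' @export
fractional_repeat_overlap <- function(features, repeats, min_frac = 0.10) {
  .check_intervals(features)
  if (nrow(repeats)) .check_intervals(repeats, "repeat")
  ovl <- numeric(nrow(features))
  for (ch in unique(features$chrom)) {
    fi <- which(features$chrom == ch)
    ri <- which(repeats$chrom == ch)
    if (!length(ri)) next
    fr <- .as_iranges(features[fi, ])
    rr <- IRanges::reduce(.as_iranges(repeats[ri, ]))
    ov <- IRanges::findOverlaps(fr, rr)
    if (length(ov)) {
      inter <- IRanges::pintersect(fr[S4Vectors::queryHits(ov)],
                                   rr[S4Vectors::subjectHits(ov)])
      w <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
      ovl[fi[as.integer(names(w))]] <- as.numeric(w)
    }
  }
  frac <- ovl / (features$end - features$start)
  counted <- frac >= min_frac
  list(n = sum(counted), fraction = sum(counted) / nrow(features),
       per_feature = data.frame(overlap_bases = ovl, overlap_frac = frac,
                                counted = counted))
}

#' Structural-variant size-class counts between the two white-oak haplotype
#' assemblies
#'
#' The per-(type, size-class) counts of SVs of at least 100 bases called
#' between the hapA and hapB assemblies of the Quercus alba reference
#' individual, shipped as package data.
#'
#' @return data.frame with `type`, `size_class`, `count`.
#' @export
oak_sv_class_counts <- function() {
  read_tsv(system.file("extdata", "sv_size_class_counts_hapA_hapB.tsv",
                       package = "oakdiv", mustWork = TRUE))
}

#' Expand per-class SV counts into synthetic records
#'
#' Builds one record per counted SV with a representative length inside its
#' size class, so class tabulations of the synthesized records reproduce
#' the input counts.
#'
#' @param counts data.frame with `type`, `size_class`, `count` (size
#'   classes as in [classify_sv_sizes()]).
#' @return data.frame with `type` and `length`.
#' @export
sv_records_from_class_counts <- function(counts) {
  rep_len <- stats::setNames(c(500, 5e3, 5e4, 5e5, 1.5e6), .size_labels)
  if (!all(counts$size_class %in% .size_labels))
    stop("unknown size class label")
  data.frame(type = rep(counts$type, counts$count),
             length = rep(unname(rep_len[counts$size_class]), counts$count))
}
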