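# Window trees and concordance accounting: JC69 distances, neighbor
# joining with a fixed tie-break, nonoverlapping genomic windows, and
# per-branch gene/site concordance factors against a reference species
# tree.

#' Jukes-Cantor (JC69) distance between two aligned sequences
#'
#' Comparison is restricted to positions where both sequences are unmasked
#' (neither is N); `d = -(3/4) log(1 - (4/3) p)` for mismatch fraction `p`.
#'
#' @param a,b Character vectors of single bases (equal length).
#' @return Distance in expected substitutions per site.
#' @export
jc69_distance <- function(a, b) {
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- a != "N" & b != "N"
  if (!any(ok)) stop("no comparable positions")
  jc69_from_p(mean(a[ok] != b[ok]))
}

#' JC69 distance from a mismatch proportion
#' @param p Mismatch proportion.
#' @return Distance in expected substitutions per site.
#' @export
jc69_from_p <- function(p) {
  if (any(p >= 0.75)) stop("saturated pair: p >= 0.75 is outside the JC69 domain")
  -0.75 * log(1 - 4 * p / 3)
}

#' Neighbor joining with deterministic tie-breaking
#'
#' Standard NJ agglomeration; ties in the Q criterion are broken by the
#' lowest (row, column) index pair in the current matrix ordering, and
#' negative estimated branch lengths are clamped to zero.
#'
#' @param D Symmetric numeric distance matrix with row/column names.
#' @return Unrooted ape `phylo` (basal trifurcation).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n0 <- nrow(D)
  if (n0 < 3) stop("neighbor joining needs >= 3 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n0))
  stopifnot(all(abs(D - t(D)) < 1e-12), all(is.finite(D)))
  labels <- rownames(D)
  # node bookkeeping: tips 1..n0, internals appended
  kids <- vector("list", 2L * n0)
  klen <- vector("list", 2L * n0)
  next_id <- n0 + 1L
  active <- seq_len(n0)              # node id per current matrix row
  d <- unname(D)
  while (length(active) > 3L) {
    n <- length(active)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    # lowest (row, column) pair among minima
    qmin <- min(q)
    hits <- which(q - qmin <= qmin * 0 + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    u <- next_id; next_id <- next_id + 1L
    kids[[u]] <- c(active[i], active[j])
    klen[[u]] <- c(max(li, 0), max(lj, 0))
    duk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], duk[keep]), c(duk[keep], 0))
    active <- c(active[keep], u)
  }
  # final three-point configuration
  x1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  x2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  x3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  u <- next_id
  kids[[u]] <- active
  klen[[u]] <- pmax(c(x1, x2, x3), 0)
  .build_phylo(u, kids, klen, n0, labels)
}

# assemble an ape phylo from children/edge-length lists rooted at `root`
.build_phylo <- function(root, kids, klen, ntips, labels) {
  ninternal <- 0L
  map <- integer(length(kids))
  map[seq_len(ntips)] <- seq_len(ntips)
  # count internals and assign preorder numbers
  stack <- root
  order_nodes <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v > ntips) {
      ninternal <- ninternal + 1L
      order_nodes <- c(order_nodes, v)
      stack <- c(stack, rev(kids[[v]]))
    }
  }
  map[order_nodes] <- ntips + seq_len(ninternal)
  edges <- NULL; elen <- NULL
  for (v in order_nodes) {
    for (k in seq_along(kids[[v]])) {
      edges <- rbind(edges, c(map[v], map[kids[[v]][k]]))
      elen <- c(elen, klen[[v]][k])
    }
  }
  structure(list(edge = edges, edge.length = elen, tip.label = labels,
                 Nnode = ninternal), class = "phylo")
}

#' JC69 distance matrix from rows of a site matrix
#'
#' @param sm A [site_matrix()].
#' @param cols Integer indices of stored columns to use (default all).
#' @param n_compared Number of compared positions per pair. Defaults to
#'   `length(cols)` for fully materialized matrices; for compact matrices
#'   the retained invariant positions are added.
#' @return Symmetric distance matrix (taxa x taxa), or NULL with a
#'   `"saturated"` attribute when some pair is JC-saturated.
#' @export
jc69_matrix <- function(sm, cols = seq_len(ncol(sm$bases)), n_compared = NULL) {
  nt <- length(sm$samples)
  sub <- sm$bases[, cols, drop = FALSE]
  if (is.null(n_compared)) n_compared <- length(cols) + if (sm$compact) sm$n_invariant else 0
  d <- matrix(0, nt, nt, dimnames = list(sm$samples, sm$samples))
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    p <- sum(sub[i, ] != sub[j, ]) / n_compared
    if (p >= 0.75) return(structure(NA, saturated = c(i, j)))
    d[i, j] <- d[j, i] <- jc69_from_p(p)
  }
  d
}

# parsimony-informative columns: >= 2 distinct bases each carried >= 2 times
.informative_cols <- function(bases) {
  cnt <- rbind(colSums(bases == "A"), colSums(bases == "C"),
               colSums(bases == "G"), colSums(bases == "T"))
  colSums(cnt >= 2) >= 2
}

#' Neighbor-joining trees from nonoverlapping genomic windows
#'
#' Windows are laid on reference coordinates (`[k w, (k+1) w)`), trailing
#' partial windows dropped. A window is retained when at least
#' `min_fraction` of its positions are retained matrix columns and it has
#' at least `min_informative` parsimony-informative sites; JC-saturated
#' windows are skipped with a logged count.
#'
#' @param sm A [site_matrix()] with `chrom_lengths`.
#' @param window_size Window size in bases (default 5000).
#' @param min_fraction Minimum fraction of retained positions (default 0.5).
#' @param min_informative Minimum parsimony-informative sites (default 1).
#' @return List with `trees` (`multiPhylo`), `windows` (data.frame of
#'   provenance: chrom, start, end, n_sites, n_informative), and counts of
#'   windows excluded by each filter.
#' @export
window_trees <- function(sm, window_size = 5000L, min_fraction = 0.5,
                         min_informative = 1L) {
  if (is.null(sm$chrom_lengths)) stop("site matrix carries no chromosome lengths")
  trees <- list(); prov <- NULL
  n_sparse <- 0L; n_uninformative <- 0L; n_saturated <- 0L
  for (ch in names(sm$chrom_lengths)) {
    nwin <- floor(sm$chrom_lengths[[ch]] / window_size)
    on_ch <- sm$chrom == ch
    for (w in seq_len(nwin) - 1L) {
      lo <- w * window_size; hi <- lo + window_size
      cols <- which(on_ch & sm$pos >= lo & sm$pos < hi)
      n_retained <- if (sm$compact) window_size else length(cols)
      if (n_retained < min_fraction * window_size) { n_sparse <- n_sparse + 1L; next }
      ninf <- sum(.informative_cols(sm$bases[, cols, drop = FALSE]))
      if (ninf < min_informative) { n_uninformative <- n_uninformative + 1L; next }
      d <- jc69_matrix(sm, cols, n_compared = n_retained)
      if (!is.matrix(d)) { n_saturated <- n_saturated + 1L; next }
      trees[[length(trees) + 1L]] <- neighbor_joining(d)
      prov <- rbind(prov, data.frame(chrom = ch, start = lo, end = hi,
                                     n_sites = n_retained, n_informative = ninf))
    }
  }
  class(trees) <- "multiPhylo"
  list(trees = trees, windows = prov, n_sparse = n_sparse,
       n_uninformative = n_uninformative, n_saturated = n_saturated)
}

# For each internal branch of the (unrooted) reference tree, the four
# surrounding taxon blocks (lists of tip labels) and the bipartition.
.branch_blocks <- function(ref) {
  tr <- if (ape::is.rooted(ref)) ape::unroot(ref) else ref
  ntips <- ape::Ntip(tr)
  desc <- .tip_descendants(tr)
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  parent <- rep(NA_integer_, ntips + tr$Nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  out <- list()
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; c <- tr$edge[e, 2]
    if (c <= ntips) next                       # terminal branch
    ckids <- kids[[as.character(c)]]
    blocksA <- lapply(ckids, function(k) tr$tip.label[desc[[k]]])
    pkids <- setdiff(kids[[as.character(p)]], c)
    blocksB <- lapply(pkids, function(k) tr$tip.label[desc[[k]]])
    if (!is.na(parent[p])) {
      above <- setdiff(tr$tip.label, tr$tip.label[desc[[p]]])
      blocksB <- c(blocksB, list(above))
    }
    A <- sort(unlist(blocksA)); B <- sort(setdiff(tr$tip.label, A))
    out[[length(out) + 1L]] <- list(branch = c, blocks = c(blocksA, blocksB),
                                    A = A, B = B,
                                    split = paste(A, collapse = ","))
  }
  out
}

#' Gene concordance factors from window trees
#'
#' For each internal branch of the reference tree, a window tree is
#' decisive if it contains at least one taxon from each of the branch's
#' four surrounding taxon blocks; among decisive trees it is concordant
#' when the branch's bipartition, restricted to the shared taxa, occurs in
#' the window tree. gCF = 100 * concordant / decisive.
#'
#' @param ref Reference species tree (`phylo`, rooted or unrooted).
#' @param trees Window trees (`multiPhylo` or list of `phylo`), on subsets
#'   of the reference taxa.
#' @return data.frame, one row per internal reference branch: `split`,
#'   `gCF`, `n_concordant`, `n_conflicting`, `n_uninformative`.
#' @export
gene_concordance <- function(ref, trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  branches <- .branch_blocks(ref)
  # pre-extract window tree split sets
  wsets <- lapply(trees, function(tw) {
    extra <- setdiff(tw$tip.label, ref$tip.label)
    if (length(extra)) stop("window tree taxa absent from reference: ",
                            paste(extra, collapse = ", "))
    desc <- .tip_descendants(tw)
    ntips <- ape::Ntip(tw)
    ids <- (ntips + 1L):(ntips + tw$Nnode)
    sets <- lapply(ids, function(v) sort(tw$tip.label[desc[[v]]]))
    list(taxa = tw$tip.label, sets = sets)
  })
  out <- NULL
  for (br in branches) {
    conc <- 0L; dec <- 0L
    for (wt in wsets) {
      S <- wt$taxa
      if (!all(vapply(br$blocks, function(b) any(b %in% S), logical(1)))) next
      dec <- dec + 1L
      As <- sort(intersect(br$A, S)); Bs <- sort(intersect(br$B, S))
      hit <- any(vapply(wt$sets, function(s) identical(s, As) || identical(s, Bs),
                        logical(1)))
      if (hit) conc <- conc + 1L
    }
    out <- rbind(out, data.frame(split = br$split,
                                 gCF = if (dec) 100 * conc / dec else NA_real_,
                                 n_concordant = conc,
                                 n_conflicting = dec - conc,
                                 n_uninformative = length(trees) - dec))
  }
  out
}

#' Site concordance factors by quartet sampling
#'
#' For each internal reference branch, `n_quartets` quartets are sampled
#' (one taxon uniformly per surrounding block, with replacement, from a
#' per-branch substream of `seed`). Each complete alignment column with a
#' two-versus-two base pattern on the quartet supports one of the three
#' quartet topologies; a quartet's support is supporting / decisive
#' columns, and sCF is 100 times the mean over quartets with at least one
#' decisive column.
#'
#' @param ref Reference species tree.
#' @param sm A [site_matrix()] whose samples are (a subset of) the
#'   reference taxa.
#' @param n_quartets Quartet replicates per branch (default 1000).
#' @param seed Integer master seed.
#' @return data.frame: `split`, `sCF`, `n_quartets_used`.
#' @export
site_concordance <- function(ref, sm, n_quartets = 1000L, seed) {
  branches <- .branch_blocks(ref)
  row_of <- stats::setNames(seq_along(sm$samples), sm$samples)
  out <- NULL
  for (bi in seq_along(branches)) {
    br <- branches[[bi]]
    blocks <- lapply(br$blocks, function(b) unname(row_of[b[b %in% sm$samples]]))
    if (any(!vapply(blocks, length, integer(1)))) {
      out <- rbind(out, data.frame(split = br$split, sCF = NA_real_,
                                   n_quartets_used = 0L))
      next
    }
    vals <- with_substream(seed, list("scf", br$split), {
      v <- numeric(0)
      for (q in seq_len(n_quartets)) {
        pick <- vapply(blocks, function(b) b[sample.int(length(b), 1L)], numeric(1))
        b1 <- sm$bases[pick[1], ]; b2 <- sm$bases[pick[2], ]
        b3 <- sm$bases[pick[3], ]; b4 <- sm$bases[pick[4], ]
        sAB <- sum(b1 == b2 & b3 == b4 & b1 != b3)
        sAC <- sum(b1 == b3 & b2 == b4 & b1 != b2)
        sAD <- sum(b1 == b4 & b2 == b3 & b1 != b2)
        ndec <- sAB + sAC + sAD
        if (ndec > 0) v <- c(v, sAB / ndec)
      }
      v
    })
    out <- rbind(out, data.frame(split = br$split,
                                 sCF = if (length(vals)) 100 * mean(vals) else NA_real_,
                                 n_quartets_used = length(vals)))
  }
  out
}
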