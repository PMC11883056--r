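# Shared fixtures and independent brute-force oracles used across tests.

# quick site-matrix builder from a samples x sites base matrix
mk_sm <- function(bases, groups = NULL, chrom = "c1") {
  if (is.null(rownames(bases))) rownames(bases) <- paste0("s", seq_len(nrow(bases)))
  site_matrix(samples = rownames(bases),
              chrom = rep(chrom, ncol(bases)),
              pos = seq_len(ncol(bases)) - 1L,
              bases = bases, groups = groups,
              chrom_lengths = stats::setNames(ncol(bases), chrom))
}

# two-species model helper (sample only species A when nB = 0)
mk_model <- function(Ne, mu, nA, nB = 0, split_gen = NULL, window_length = 1000,
                     n_windows = 100, ploidy = 2) {
  if (is.null(split_gen)) split_gen <- 100 * Ne
  tr <- ape::read.tree(text = sprintf("(A:%.1f,B:%.1f);", split_gen, split_gen))
  species_tree_model(tr, Ne = Ne, mu = mu, sample_plan = c(A = nA, B = nB),
                     window_length = window_length, n_windows = n_windows,
                     ploidy = ploidy)
}

# ---- exhaustive least-squares tree oracle (NJ correctness) ----------------

# indicator matrix: rows = unordered tip pairs (i<j), cols = edges;
# entry 1 iff the edge lies on the path between the pair
path_design <- function(tree) {
  ntips <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  clade <- vector("list", ntips + tree$Nnode)
  walk <- function(v) {
    if (v <= ntips) clade[[v]] <<- v
    else {
      for (k in kids[[as.character(v)]]) walk(k)
      clade[[v]] <<- unlist(clade[kids[[as.character(v)]]])
    }
  }
  walk(root)
  pairs <- t(utils::combn(ntips, 2))
  P <- matrix(0, nrow(pairs), nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    inset <- pairs[, 1] %in% clade[[tree$edge[e, 2]]]
    jnset <- pairs[, 2] %in% clade[[tree$edge[e, 2]]]
    P[, e] <- as.numeric(xor(inset, jnset))
  }
  list(P = P, pairs = pairs)
}

# fit every unrooted topology by least squares; return the exact-fit tree
exhaustive_tree_oracle <- function(D) {
  labels <- rownames(D)
  topos <- ape::.uncompressTipLabel(
    phangorn::allTrees(length(labels), rooted = FALSE, tip.label = labels))
  best <- NULL
  for (tp in topos) {
    pd <- path_design(tp)
    d <- D[cbind(labels[pd$pairs[, 1]], labels[pd$pairs[, 2]])]
    fit <- stats::lm.fit(pd$P, d)
    res <- max(abs(pd$P %*% fit$coefficients - d))
    if (res < 1e-8) {
      tp$edge.length <- as.numeric(fit$coefficients)
      best <- tp
      break
    }
  }
  best
}

# ---- brute-force interval oracles -----------------------------------------

# transitive closure of the pairwise "within max_gap" relation, per
# chromosome and category; returns a list of member index sets (size >= 2)
closure_cluster_oracle <- function(features, max_gap) {
  n <- nrow(features)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (features$chrom[i] != features$chrom[j]) next
    if (features$category[i] != features$category[j]) next
    gap <- max(features$start[i], features$start[j]) -
      min(features$end[i], features$end[j])
    adj[i, j] <- gap <= max_gap
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  sets <- split(seq_len(n), comp)
  Filter(function(s) length(s) >= 2, unname(sets))
}

# all-pairs gene/SV overlap oracle on half-open intervals
overlap_oracle <- function(genes, exons, svs) {
  hit <- function(a1, a2, b1, b2) a1 < b2 & b1 < a2
  body <- vapply(seq_len(nrow(genes)), function(i) {
    any(genes$chrom[i] == svs$chrom &
          hit(genes$start[i], genes$end[i], svs$start, svs$end))
  }, logical(1))
  exonic <- vapply(seq_len(nrow(genes)), function(i) {
    e <- exons[exons$parent == genes$id[i], , drop = FALSE]
    if (!nrow(e)) return(FALSE)
    any(vapply(seq_len(nrow(e)), function(k) {
      any(e$chrom[k] == svs$chrom & hit(e$start[k], e$end[k], svs$start, svs$end))
    }, logical(1)))
  }, logical(1))
  by_type <- vapply(unique(svs$type), function(ty) {
    s <- svs[svs$type == ty, , drop = FALSE]
    sum(vapply(seq_len(nrow(genes)), function(i) {
      any(genes$chrom[i] == s$chrom & hit(genes$start[i], genes$end[i], s$start, s$end))
    }, logical(1)))
  }, integer(1))
  list(n_body = sum(body), n_exonic = sum(exonic), by_type = by_type)
}

# random feature tables for the interval property tests
random_features <- function(n, n_chrom = 2, n_cat = 2, span = 1e6, maxlen = 5e4) {
  start <- floor(stats::runif(n, 0, span))
  len <- 1 + floor(stats::runif(n, 0, maxlen))
  data.frame(id = paste0("f", seq_len(n)),
             chrom = paste0("c", sample.int(n_chrom, n, replace = TRUE)),
             start = start, end = start + len,
             category = paste0("cat", sample.int(n_cat, n, replace = TRUE)))
}
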