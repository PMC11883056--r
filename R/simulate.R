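# Multispecies-coalescent simulator: gene trees inside a species tree with
# per-branch effective sizes, infinite-sites mutations, and diploid VCF
# assembly. Windows are unlinked loci; time is measured in generations and
# the diploid pairwise coalescent has E[T2] = 2*Ne.

#' Define a multispecies coalescent model on a species tree
#'
#' @param tree Rooted, ultrametric ape `phylo`; branch lengths in
#'   generations; tip labels are species names.
#' @param Ne Diploid effective population size. Either a single value used
#'   for every branch (including the root stem), or a numeric vector indexed
#'   by node id (`1..Ntip+Nnode`) giving the size of the branch above each
#'   node, with the root entry giving the root-stem size.
#' @param mu Mutation rate per site per generation.
#' @param sample_plan Named integer vector, species -> number of sampled
#'   individuals.
#' @param window_length Window (locus) length in bases.
#' @param n_windows Number of unlinked windows.
#' @param ploidy 2 for diploid individuals (default); 1 for haploid
#'   lineages (simulation experiments only; such models cannot be assembled
#'   into diploid VCFs).
#' @return An object of class `species_tree_model`.
#' @export
species_tree_model <- function(tree, Ne, mu, sample_plan,
                               window_length = 5000L, n_windows = 100L,
                               ploidy = 2L) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("species tree needs branch lengths (generations)")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  ntot <- ape::Ntip(tree) + tree$Nnode
  node_time <- ape::node.depth.edgelength(tree)
  node_time <- max(node_time) - node_time     # time before present per node
  node_time[seq_len(ape::Ntip(tree))] <- 0    # tips at the present
  parent <- rep(NA_integer_, ntot)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # tips are set to exactly time 0; internal ordering must hold
  ok <- all(node_time[tree$edge[, 1]] > node_time[tree$edge[, 2]] - 1e-9)
  if (!ok) stop("parent node times must exceed child node times")
  if (length(Ne) == 1L) Ne <- rep(Ne, ntot)
  if (length(Ne) != ntot) stop("Ne must be length 1 or one value per node")
  if (any(!is.finite(Ne)) || any(Ne <= 0)) stop("Ne must be positive and finite on every branch")
  if (!is.finite(mu) || mu < 0) stop("mu must be >= 0")
  if (is.null(names(sample_plan)) || !all(names(sample_plan) %in% tree$tip.label))
    stop("sample_plan must be named by species tip labels")
  if (any(sample_plan < 0)) stop("sample counts must be >= 0")
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  theta <- 4 * Ne * mu
  if (any(!is.finite(theta))) stop("theta = 4*Ne*mu must be finite")
  structure(list(tree = tree, node_time = node_time, parent = parent,
                 Ne = Ne, mu = mu, sample_plan = sample_plan,
                 window_length = as.integer(window_length),
                 n_windows = as.integer(n_windows),
                 ploidy = as.integer(ploidy), theta = theta),
            class = "species_tree_model")
}

#' @export
print.species_tree_model <- function(x, ...) {
  cat("Multispecies coalescent model\n")
  cat("  species:", paste(x$tree$tip.label, collapse = ", "), "\n")
  cat("  samples:", sum(x$sample_plan), "individuals (ploidy", x$ploidy, ")\n")
  cat("  mu =", x$mu, "per site per generation;",
      x$n_windows, "windows x", x$window_length, "bp\n")
  invisible(x)
}

# Coalesce lineages within one species-tree branch [t0, t1) of size Ne.
# `lin` is an integer vector of gene-tree node ids; `st` is the mutable
# gene-tree state (environment with time, child1, child2, next_id).
.coalesce_arena <- function(st, lin, t0, t1, Ne) {
  t <- t0
  k <- length(lin)
  while (k >= 2) {
    dt <- stats::rexp(1, rate = k * (k - 1) / (4 * Ne))
    if (t + dt > t1) break
    t <- t + dt
    pair <- sample.int(k, 2L)
    id <- st$next_id
    st$next_id <- id + 1L
    st$time[id] <- t
    st$child1[id] <- lin[pair[1]]
    st$child2[id] <- lin[pair[2]]
    lin <- c(lin[-pair], id)
    k <- k - 1L
  }
  lin
}

# Simulate one gene tree under the censored coalescent; returns ape phylo
# with branch lengths in generations and tips labelled species_ind_hap.
.sim_one_gene_tree <- function(model) {
  tr <- model$tree
  ntip_sp <- ape::Ntip(tr)
  labels <- character(0)
  tip_species <- character(0)
  for (sp in names(model$sample_plan)) {
    n <- model$sample_plan[[sp]]
    if (n > 0) {
      for (i in seq_len(n)) for (h in seq_len(model$ploidy)) {
        labels <- c(labels, paste(sp, i, h, sep = "_"))
        tip_species <- c(tip_species, sp)
      }
    }
  }
  if (length(labels) == 0L) stop("empty sample plan")
  ntips <- length(labels)
  maxn <- 2L * ntips
  st <- new.env(parent = emptyenv())
  st$time <- numeric(maxn); st$child1 <- integer(maxn); st$child2 <- integer(maxn)
  st$next_id <- ntips + 1L
  # lineages entering the branch above each species-tree node
  pool <- vector("list", ntip_sp + tr$Nnode)
  for (v in seq_len(ntip_sp)) {
    sp <- tr$tip.label[v]
    pool[[v]] <- which(tip_species == sp)
  }
  ord <- order(model$node_time[(ntip_sp + 1L):(ntip_sp + tr$Nnode)])
  internal <- (ntip_sp + 1L):(ntip_sp + tr$Nnode)
  root <- internal[which.max(model$node_time[internal])]
  # run every non-root arena: branch above node v from time(v) to time(parent(v))
  events <- c(seq_len(ntip_sp), internal[ord])
  for (v in events) {
    if (v == root) next
    lin <- pool[[v]]
    if (is.null(lin)) lin <- integer(0)
    p <- model$parent[v]
    surv <- .coalesce_arena(st, lin, model$node_time[v], model$node_time[p], model$Ne[v])
    pool[[p]] <- c(pool[[p]], surv)
  }
  # root stem: unbounded duration
  lin <- pool[[root]]
  lin <- .coalesce_arena(st, lin, model$node_time[root], Inf, model$Ne[root])
  stopifnot(length(lin) == 1L)
  .gene_tree_phylo(st, lin, ntips, labels)
}

# Convert the array-based gene-tree state to an ape phylo.
.gene_tree_phylo <- function(st, root, ntips, labels) {
  if (root <= ntips) {  # single lineage, nothing coalesced
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          edge.length = 0,
                          tip.label = labels[root], Nnode = 1L),
                     class = "phylo"))
  }
  ninternal <- st$next_id - 1L - ntips
  map <- integer(ntips + ninternal)
  map[seq_len(ntips)] <- seq_len(ntips)
  # preorder numbering of internal nodes, root first (ape convention)
  nxt <- ntips + 1L
  stack <- root
  order_int <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v > ntips) {
      map[v] <- nxt; nxt <- nxt + 1L
      stack <- c(stack, st$child2[v], st$child1[v])
    }
  }
  edge <- matrix(0L, ntips + ninternal - 1L, 2)
  elen <- numeric(nrow(edge))
  i <- 0L
  for (v in (ntips + 1L):(ntips + ninternal)) {
    for (ch in c(st$child1[v], st$child2[v])) {
      i <- i + 1L
      edge[i, ] <- c(map[v], map[ch])
      elen[i] <- st$time[v] - st$time[ch]
    }
  }
  node_time <- numeric(ntips + ninternal)
  node_time[map] <- st$time[seq_len(ntips + ninternal)]
  structure(list(edge = edge, edge.length = elen, tip.label = labels,
                 Nnode = ninternal, node.time = node_time),
            class = "phylo")
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One censored-coalescent gene tree per window. Within a branch holding
#' `k` lineages and diploid size `Ne`, successive coalescence waiting times
#' are exponential with rate `k(k-1)/(4 Ne)` per generation, censored at the
#' top of the branch; survivors merge into the parent branch and all
#' remaining lineages coalesce in the root stem.
#'
#' @param model A [species_tree_model()].
#' @param seed Integer master seed; window `w` uses the substream
#'   `(seed, "gene_tree", w)`.
#' @return A `multiPhylo` list of gene trees (branch lengths in
#'   generations; each tree also carries a `node.time` vector).
#' @export
simulate_gene_trees <- function(model, seed) {
  stopifnot(inherits(model, "species_tree_model"))
  if (sum(model$sample_plan) * model$ploidy == 0) stop("empty sample plan")
  out <- vector("list", model$n_windows)
  for (w in seq_len(model$n_windows)) {
    out[[w]] <- with_substream(seed, list("gene_tree", w), .sim_one_gene_tree(model))
  }
  class(out) <- "multiPhylo"
  out
}

#' Drop infinite-sites mutations on a gene tree
#'
#' Mutation counts per branch are Poisson with mean
#' `mu * window_length * branch_duration`; each mutation gets a distinct
#' uniformly drawn position and a derived base distinct from the ancestral
#' base, and derived states propagate to all descendant tips.
#'
#' @param tree A gene tree from [simulate_gene_trees()] (branch lengths in
#'   generations).
#' @param mu Mutation rate per site per generation.
#' @param window_length Number of sites in the window.
#' @param seed Integer seed for this window's mutation substream.
#' @param ancestral Optional ancestral sequence (character vector of
#'   `window_length` single bases). Random ACGT when NULL.
#' @param return_haplotypes Also return full haplotype sequences
#'   (tips x window_length character matrix).
#' @return List with `positions` (1-based, sorted), `ancestral_base`,
#'   `derived_base`, `carriers` (tips x variants logical matrix, TRUE where
#'   the tip carries the derived base), `ancestral` (full ancestral
#'   sequence) and optionally `haplotypes`.
#' @export
drop_mutations <- function(tree, mu, window_length, seed, ancestral = NULL,
                           return_haplotypes = TRUE) {
  if (mu < 0) stop("mu must be >= 0")
  if (window_length < 1) stop("window_length must be >= 1")
  bases <- c("A", "C", "G", "T")
  ntips <- length(tree$tip.label)
  with_substream(seed, list("mutations"), {
    if (is.null(ancestral)) ancestral <- sample(bases, window_length, replace = TRUE)
    nedge <- if (is.null(tree$edge)) 0L else nrow(tree$edge)
    nmut_per_edge <- if (nedge)
      stats::rpois(nedge, mu * window_length * tree$edge.length) else integer(0)
    m <- sum(nmut_per_edge)
    if (m > window_length) stop("infinite-sites overflow: lower mu * window_length")
    pos <- if (m) sort(sample.int(window_length, m)) else integer(0)
    # assign sorted positions to edges in a seeded random order
    edge_of <- if (m) sample(rep.int(seq_len(nedge), nmut_per_edge)) else integer(0)
    carriers <- matrix(FALSE, ntips, m, dimnames = list(tree$tip.label, NULL))
    if (m) {
      desc <- .tip_descendants(tree)
      for (j in seq_len(m)) carriers[desc[[tree$edge[edge_of[j], 2]]], j] <- TRUE
    }
    anc_b <- ancestral[pos]
    der_b <- character(m)
    for (j in seq_len(m)) der_b[j] <- sample(setdiff(bases, anc_b[j]), 1L)
    out <- list(positions = pos, ancestral_base = anc_b, derived_base = der_b,
                carriers = carriers, ancestral = ancestral)
    if (return_haplotypes) {
      hap <- matrix(rep(ancestral, each = ntips), ntips, window_length,
                    dimnames = list(tree$tip.label, NULL))
      if (m) for (j in seq_len(m)) hap[carriers[, j], pos[j]] <- der_b[j]
      out$haplotypes <- hap
    }
    out
  })
}

# list: for each node, integer vector of descendant tip indices.
# Robust to edge ordering (works for both simulator-built and read trees).
.tip_descendants <- function(tree) {
  ntips <- length(tree$tip.label)
  ntot <- ntips + tree$Nnode
  kids <- vector("list", ntot)
  if (!is.null(tree$edge) && nrow(tree$edge)) {
    for (e in seq_len(nrow(tree$edge)))
      kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  }
  desc <- vector("list", ntot)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  stack <- root
  pre <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    pre <- c(pre, v)
    stack <- c(stack, kids[[v]])
  }
  for (v in rev(pre))
    desc[[v]] <- if (v <= ntips) v else unlist(desc[kids[[v]]], use.names = FALSE)
  desc
}

#' Simulate and assemble a complete diploid resequencing dataset
#'
#' Runs the gene-tree and mutation stages for every window, lays the windows
#' end to end on one reference chromosome, pairs haplotypes into diploid
#' individuals (deterministically, by sorted lineage label), and returns the
#' reference, variant records and per-window true gene trees.
#'
#' @param model A [species_tree_model()] with `ploidy = 2`.
#' @param seed Integer master seed.
#' @param chrom Chromosome name for the assembled reference.
#' @return An object of class `sim_dataset` with elements `reference`
#'   (named character vector), `variants` (genotype table as in
#'   [read_vcf_genotypes()], plus a `hap_gt` haplotype matrix), `trees`
#'   (`multiPhylo`), `windows` (data.frame of per-window truth), `model`,
#'   `samples`, `seed`.
#' @export
simulate_dataset <- function(model, seed, chrom = "chr1") {
  stopifnot(inherits(model, "species_tree_model"))
  if (model$ploidy != 2L) stop("diploid assembly requires ploidy = 2 (odd haplotype count per individual)")
  trees <- simulate_gene_trees(model, seed)
  L <- model$window_length
  refs <- character(model$n_windows)
  vt_chrom <- character(0); vt_pos <- integer(0); vt_ref <- character(0); vt_alt <- character(0)
  hap_rows <- NULL
  win_info <- data.frame(window = seq_len(model$n_windows),
                         start = (seq_len(model$n_windows) - 1L) * L,
                         end = seq_len(model$n_windows) * L,
                         n_variants = 0L, tmrca = NA_real_)
  hap_gt_list <- vector("list", model$n_windows)
  for (w in seq_len(model$n_windows)) {
    mut <- drop_mutations(trees[[w]], model$mu, L,
                          seed = substream_seed(seed, "mut", w),
                          return_haplotypes = FALSE)
    refs[w] <- paste(mut$ancestral, collapse = "")
    m <- length(mut$positions)
    win_info$n_variants[w] <- m
    win_info$tmrca[w] <- if (!is.null(trees[[w]]$node.time)) max(trees[[w]]$node.time) else NA_real_
    if (m) {
      vt_chrom <- c(vt_chrom, rep(chrom, m))
      vt_pos <- c(vt_pos, (w - 1L) * L + mut$positions)   # 1-based global
      vt_ref <- c(vt_ref, mut$ancestral_base)
      vt_alt <- c(vt_alt, mut$derived_base)
      hap_gt_list[[w]] <- mut$carriers[sort(rownames(mut$carriers)), , drop = FALSE]
    }
  }
  haps <- sort(trees[[1]]$tip.label)
  hap_gt <- do.call(cbind, c(list(matrix(FALSE, length(haps), 0,
                                         dimnames = list(haps, NULL))),
                             hap_gt_list[!vapply(hap_gt_list, is.null, logical(1))]))
  # diploid pairing: haplotypes sp_i_1 / sp_i_2 -> individual sp_i
  ind_of <- sub("_[12]$", "", haps)
  if (any(table(ind_of) != 2L)) stop("odd haplotype count for an individual slot")
  samples <- unique(ind_of)
  gt <- matrix("0/0", length(vt_pos), length(samples),
               dimnames = list(NULL, samples))
  for (s in samples) {
    pair <- hap_gt[ind_of == s, , drop = FALSE]
    g <- colSums(pair)
    gt[, s] <- c("0/0", "0/1", "1/1")[g + 1L]
  }
  reference <- stats::setNames(paste(refs, collapse = ""), chrom)
  variants <- list(chrom = vt_chrom, pos = vt_pos, ref = vt_ref,
                   alt = as.list(vt_alt), qual = rep(NA_real_, length(vt_pos)),
                   gt = gt, gq = NULL, samples = samples)
  structure(list(reference = reference, variants = variants, hap_gt = hap_gt,
                 trees = trees, windows = win_info, model = model,
                 samples = samples, seed = seed, chrom = chrom),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated diploid dataset:", length(x$samples), "individuals,",
      x$model$n_windows, "windows x", x$model$window_length, "bp,",
      length(x$variants$pos), "variant sites\n")
  invisible(x)
}

#' Simulate straight to a haplotype site matrix
#'
#' The fast path for simulation experiments: runs the gene-tree and
#' mutation stages with the same substreams as [simulate_dataset()] but
#' assembles the true haplotypes directly into a compact [site_matrix()]
#' (one row per haplotype, variant columns stored, all positions retained),
#' skipping the VCF/pseudo-reference stages. Works for either ploidy.
#'
#' @param model A [species_tree_model()].
#' @param seed Integer master seed.
#' @param chrom Chromosome name.
#' @return A `site_matrix` with groups set to the species labels and the
#'   true gene trees in attribute `"trees"`.
#' @export
simulate_site_matrix <- function(model, seed, chrom = "chr1") {
  stopifnot(inherits(model, "species_tree_model"))
  trees <- simulate_gene_trees(model, seed)
  L <- model$window_length
  haps <- sort(trees[[1]]$tip.label)
  pos_list <- vector("list", model$n_windows)
  base_list <- vector("list", model$n_windows)
  for (w in seq_len(model$n_windows)) {
    mut <- drop_mutations(trees[[w]], model$mu, L,
                          seed = substream_seed(seed, "mut", w),
                          return_haplotypes = FALSE)
    m <- length(mut$positions)
    if (!m) next
    b <- matrix(rep(mut$ancestral_base, each = length(haps)), length(haps), m,
                dimnames = list(haps, NULL))
    carriers <- mut$carriers[haps, , drop = FALSE]
    for (j in seq_len(m)) b[carriers[, j], j] <- mut$derived_base[j]
    base_list[[w]] <- b
    pos_list[[w]] <- (w - 1L) * L + mut$positions - 1L   # 0-based global
  }
  keep <- !vapply(base_list, is.null, logical(1))
  bases <- do.call(cbind, c(list(matrix(character(0), length(haps), 0,
                                        dimnames = list(haps, NULL))),
                            base_list[keep]))
  pos <- unlist(pos_list[keep], use.names = FALSE)
  if (is.null(pos)) pos <- integer(0)
  total <- model$n_windows * L
  sp <- if (model$ploidy == 2L) sub("_[0-9]+_[12]$", "", haps) else sub("_[0-9]+_1$", "", haps)
  sm <- site_matrix(samples = haps, chrom = rep(chrom, length(pos)),
                    pos = as.integer(pos), bases = bases,
                    groups = stats::setNames(sp, haps),
                    chrom_lengths = stats::setNames(total, chrom),
                    n_invariant = total - length(pos), compact = TRUE)
  attr(sm, "trees") <- trees
  sm
}

#' Write a simulated dataset as reference FASTA + VCF + true trees
#'
#' @param ds A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of written file paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(dir, "reference.fa"),
             vcf = file.path(dir, "variants.vcf.gz"),
             trees = file.path(dir, "true_trees.nwk"),
             windows = file.path(dir, "windows.tsv"))
  write_fasta(ds$reference, paths[["reference"]])
  write_vcf_genotypes(ds$variants, paths[["vcf"]])
  write_trees(ds$trees, paths[["trees"]])
  write_tsv(ds$windows, paths[["windows"]])
  invisible(paths)
}

#' Read back a dataset written by [write_dataset()]
#' @param dir Directory written by [write_dataset()].
#' @return List with `reference`, `variants`, `trees`, `windows`.
#' @export
read_dataset <- function(dir) {
  list(reference = read_fasta(file.path(dir, "reference.fa")),
       variants = read_vcf_genotypes(file.path(dir, "variants.vcf.gz")),
       trees = read_trees(file.path(dir, "true_trees.nwk")),
       windows = read_tsv(file.path(dir, "windows.tsv")))
}
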