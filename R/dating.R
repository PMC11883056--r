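# Time calibration by penalized likelihood: a Poisson likelihood on
# per-branch substitution counts plus a smoothness penalty on rate changes
# between adjacent branches, with the root-children rates tied through a
# variance term (so a very large penalty drives all branches to a single
# clock rate). Ancestral polymorphism inflates terminal branch lengths by
# pi/2 per tip under a uniform ancestral theta; correcting the terminals
# before dating removes that bias.

#' Correct branch lengths for ancestral polymorphism
#'
#' Subtracts `pi/2` (half the nucleotide diversity, in substitutions per
#' site) from every terminal branch, clamping at `floor`; internal branches
#' are unchanged. On a (near-)ultrametric tree this is equivalent to
#' shifting every node height down by `pi/2`, the expected coalescent
#' contribution of shared ancestral variation to each tip lineage.
#'
#' @param tree Rooted ape `phylo` with branch lengths in substitutions per
#'   site.
#' @param pi Nucleotide diversity (proportion), `pi >= 0`.
#' @param floor Minimum terminal branch length after correction.
#' @return The corrected tree; attribute `"n_clamped"` counts terminal
#'   branches clamped at the floor.
#' @export
correct_ancestral_polymorphism <- function(tree, pi, floor = 0) {
  if (pi < 0) stop("pi must be >= 0")
  ntips <- ape::Ntip(tree)
  term <- tree$edge[, 2] <= ntips
  adj <- tree$edge.length[term] - pi / 2
  n_clamped <- sum(adj < floor)
  tree$edge.length[term] <- pmax(adj, floor)
  attr(tree, "n_clamped") <- n_clamped
  tree
}

# index structure for the penalized-likelihood optimization
.pl_prepare <- function(tree, calibration_node) {
  ntips <- ape::Ntip(tree)
  ntot <- ntips + tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  parent <- rep(NA_integer_, ntot)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  if (is.null(calibration_node)) calibration_node <- root
  # strict ancestors of the calibration node, nearest first
  anc <- integer(0); v <- calibration_node
  while (!is.na(parent[v])) { anc <- c(anc, parent[v]); v <- parent[v] }
  internal <- setdiff((ntips + 1L):ntot, c(calibration_node, anc))
  # preorder so parents are assigned before children
  ord <- integer(0); stack <- root
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    if (v > ntips) stack <- c(stack, kids[[as.character(v)]])
  }
  free_nodes <- ord[ord %in% internal]
  # parent edge of each edge (NA for root children)
  edge_above <- rep(NA_integer_, ntot)
  edge_above[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  parent_edge <- edge_above[tree$edge[, 1]]
  list(ntips = ntips, ntot = ntot, root = root, parent = parent,
       calib = calibration_node, anc = anc, free_nodes = free_nodes,
       parent_edge = parent_edge,
       root_edges = which(is.na(parent_edge)),
       nonroot_edges = which(!is.na(parent_edge)))
}

# node ages from the unconstrained parameter vector
.pl_ages <- function(par, prep, calibration_age) {
  nfree <- length(prep$free_nodes); nanc <- length(prep$anc)
  s <- par[seq_len(nfree)]
  u <- par[nfree + seq_len(nanc)]
  ages <- numeric(prep$ntot)
  ages[prep$calib] <- calibration_age
  if (nanc) {
    a <- calibration_age
    for (i in seq_len(nanc)) { a <- a + exp(u[i]); ages[prep$anc[i]] <- a }
  }
  if (nfree) {
    fr <- stats::plogis(s)
    for (i in seq_len(nfree)) {
      v <- prep$free_nodes[i]
      ages[v] <- ages[prep$parent[v]] * fr[i]
    }
  }
  ages
}

#' Date a tree by penalized likelihood with an age calibration
#'
#' Minimizes, over node ages and per-branch rates,
#' `sum_b [ r_b d_b L - x_b ln(r_b d_b L) ] + lambda * P(r)` where `x_b` is
#' the branch length times `L_effective` (a Poisson substitution count),
#' `d_b` the branch duration, and `P(r)` sums squared rate differences
#' between each branch and its parent branch plus the variance of the
#' root-children rates. Node ordering constraints and the calibration are
#' enforced by construction of the parameterization. Optimization starts
#' from a root-to-tip-mean clock solution and takes seeded random restarts.
#'
#' @param tree Rooted ape `phylo`, branch lengths in substitutions per
#'   site.
#' @param calibration_age Age assigned to the calibration node (default 56,
#'   in Myr).
#' @param calibration_node Internal node id to calibrate (default: root).
#' @param lambda Rate-smoothness penalty weight (>= 0), default 1.
#' @param L_effective Alignment length used to convert branch lengths to
#'   Poisson counts.
#' @param n_restarts Random restarts after the clock start (default 3).
#' @param seed Integer seed for the restarts.
#' @return Object of class `chronogram`: the input tree with
#'   `edge.length` in time units, plus `ages` (per-node), `rates` (per
#'   edge, substitutions per site per time unit), `objective`,
#'   `convergence` (0 = converged).
#' @export
penalized_likelihood_date <- function(tree, calibration_age = 56,
                                      calibration_node = NULL, lambda = 1,
                                      L_effective = 1e4, n_restarts = 3,
                                      seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (any(tree$edge.length < 0)) stop("branch lengths must be nonnegative")
  if (lambda < 0) stop("lambda must be >= 0")
  if (calibration_age <= 0) stop("calibration age must be positive")
  if (L_effective < 1) stop("L_effective must be >= 1")
  prep <- .pl_prepare(tree, calibration_node)
  funs <- .pl_funs(tree, prep, calibration_age, lambda, L_effective)
  objective <- funs$fn
  gradient <- funs$gr
  child <- tree$edge[, 2]; parnode <- tree$edge[, 1]
  nfree <- length(prep$free_nodes); nanc <- length(prep$anc)
  nedge <- nrow(tree$edge)
  .pl_run(tree, prep, objective, gradient, calibration_age, n_restarts, seed)
}

# objective and analytic gradient closures for the PL problem
.pl_funs <- function(tree, prep, calibration_age, lambda, L_effective) {
  x <- tree$edge.length * L_effective
  child <- tree$edge[, 2]; parnode <- tree$edge[, 1]
  pe <- prep$parent_edge; nre <- prep$nonroot_edges; re <- prep$root_edges
  nfree <- length(prep$free_nodes); nanc <- length(prep$anc)
  nedge <- nrow(tree$edge)

  objective <- function(par) {
    ages <- .pl_ages(par[seq_len(nfree + nanc)], prep, calibration_age)
    r <- exp(par[nfree + nanc + seq_len(nedge)])
    d <- ages[parnode] - ages[child]
    ex <- r * d * L_effective
    if (any(!is.finite(ex)) || any(ex <= 0)) return(1e12)
    ll <- sum(ex - x * log(ex))
    pen <- sum((r[nre] - r[pe[nre]])^2)
    if (length(re) > 1) pen <- pen + sum((r[re] - mean(r[re]))^2)
    ll + lambda * pen
  }

  gradient <- function(par) {
    ages <- .pl_ages(par[seq_len(nfree + nanc)], prep, calibration_age)
    r <- exp(par[nfree + nanc + seq_len(nedge)])
    d <- ages[parnode] - ages[child]
    if (any(d <= 0) || any(!is.finite(r))) return(rep(0, length(par)))
    # d(pen)/dr
    dpen <- numeric(nedge)
    dpen[nre] <- dpen[nre] + 2 * (r[nre] - r[pe[nre]])
    for (e in nre) dpen[pe[e]] <- dpen[pe[e]] - 2 * (r[e] - r[pe[e]])
    if (length(re) > 1) dpen[re] <- dpen[re] + 2 * (r[re] - mean(r[re]))
    g_rho <- r * d * L_effective - x + lambda * r * dpen
    # direct df/dt per node: +(rL - x/d) for edges below, -(rL - x/d) above
    w <- r * L_effective - x / d
    g_node <- numeric(prep$ntot)
    for (e in seq_len(nedge)) {
      g_node[parnode[e]] <- g_node[parnode[e]] + w[e]
      g_node[child[e]] <- g_node[child[e]] - w[e]
    }
    # backprop through the age parameterization (reverse assignment order)
    s <- par[seq_len(nfree)]
    fr <- stats::plogis(s)
    G <- g_node
    for (v in rev(prep$free_nodes)) {
      G[prep$parent[v]] <- G[prep$parent[v]] +
        G[v] * fr[match(v, prep$free_nodes)]
    }
    if (nanc) for (i in rev(seq_len(nanc))) {
      prev <- if (i == 1) prep$calib else prep$anc[i - 1]
      G[prev] <- G[prev] + G[prep$anc[i]]
    }
    g_s <- if (nfree) vapply(seq_len(nfree), function(i) {
      v <- prep$free_nodes[i]
      G[v] * ages[prep$parent[v]] * fr[i] * (1 - fr[i])
    }, numeric(1)) else numeric(0)
    g_u <- if (nanc) vapply(seq_len(nanc), function(i) {
      u <- par[nfree + i]
      G[prep$anc[i]] * exp(u)
    }, numeric(1)) else numeric(0)
    c(g_s, g_u, g_rho)
  }

  list(fn = objective, gr = gradient)
}

# clock initialization, seeded restarts, and chronogram assembly
.pl_run <- function(tree, prep, objective, gradient, calibration_age,
                    n_restarts, seed) {
  child <- tree$edge[, 2]; parnode <- tree$edge[, 1]
  nfree <- length(prep$free_nodes); nanc <- length(prep$anc)
  nedge <- nrow(tree$edge)
  # clock initialization: node ages proportional to mean subtree depth
  depth <- .mean_tip_distance(tree)
  rel <- depth / max(depth[prep$calib], 1e-12)
  ages0 <- pmax(rel, 0) * calibration_age
  par0 <- numeric(nfree + nanc + nedge)
  if (nanc) par0[nfree + seq_len(nanc)] <- log(pmax(diff(c(calibration_age,
    ages0[prep$anc])), calibration_age * 0.05))
  if (nfree) {
    fr <- vapply(seq_len(nfree), function(i) {
      v <- prep$free_nodes[i]; p <- prep$parent[v]
      f <- if (ages0[p] > 0) ages0[v] / ages0[p] else 0.5
      min(max(f, 0.02), 0.98)
    }, numeric(1))
    par0[seq_len(nfree)] <- stats::qlogis(fr)
  }
  # make ages0 consistent with the (clamped) parameterization
  ages0 <- .pl_ages(par0[seq_len(nfree + nanc)], prep, calibration_age)
  r0 <- sum(tree$edge.length) / max(sum(ages0[parnode] - ages0[child]), 1e-12)
  par0[nfree + nanc + seq_len(nedge)] <- log(max(r0, 1e-12))

  starts <- list(par0)
  for (k in seq_len(n_restarts)) {
    starts[[k + 1L]] <- with_substream(seed, list("date_restart", k),
                                       par0 + stats::rnorm(length(par0), sd = 0.3))
  }
  best <- NULL
  for (st in starts) {
    fit <- try(stats::optim(st, objective, gradient, method = "BFGS",
                            control = list(maxit = 5000, reltol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    # polish along the near-flat likelihood ridge, where only the rate
    # penalty separates solutions
    pol <- try(stats::nlminb(fit$par, objective, gradient,
                             control = list(rel.tol = 1e-15, abs.tol = 0,
                                            iter.max = 2000, eval.max = 4000)),
               silent = TRUE)
    if (!inherits(pol, "try-error") && pol$objective <= fit$value)
      fit <- list(par = pol$par, value = pol$objective, convergence = 0)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("dating optimizer failed on all starts")
  if (best$convergence != 0) {
    cond <- structure(class = c("oakdiv_dating_error", "error", "condition"),
                      list(message = "dating optimizer did not converge after restarts",
                           call = sys.call(), best = best))
    stop(cond)
  }
  ages <- .pl_ages(best$par[seq_len(nfree + nanc)], prep, calibration_age)
  rates <- exp(best$par[nfree + nanc + seq_len(nedge)])
  out <- tree
  out$edge.length <- ages[parnode] - ages[child]
  out$ages <- ages
  out$rates <- rates
  out$objective <- best$value
  out$convergence <- best$convergence
  class(out) <- c("chronogram", "phylo")
  out
}

# mean root-to-tip path length below every node (0 at tips)
.mean_tip_distance <- function(tree) {
  ntips <- ape::Ntip(tree)
  ntot <- ntips + tree$Nnode
  sumd <- numeric(ntot); cnt <- numeric(ntot)
  cnt[seq_len(ntips)] <- 1
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  post <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    post <- c(post, v)
    if (v > ntips) stack <- c(stack, tree$edge[kids[[as.character(v)]], 2])
  }
  for (v in rev(post)) {
    if (v <= ntips) next
    for (e in kids[[as.character(v)]]) {
      ch <- tree$edge[e, 2]
      sumd[v] <- sumd[v] + sumd[ch] + tree$edge.length[e] * cnt[ch]
      cnt[v] <- cnt[v] + cnt[ch]
    }
  }
  sumd / cnt
}

#' @export
print.chronogram <- function(x, ...) {
  ntips <- ape::Ntip(x)
  cat("Chronogram:", ntips, "tips; root age",
      format(max(x$ages), digits = 4), "\n")
  invisible(x)
}

#' Node ages of a chronogram, keyed by descendant tip sets
#' @param x A `chronogram` (or any `phylo` with an `ages` element).
#' @return Named numeric vector; names are comma-joined sorted tip labels
#'   of each internal node's clade.
#' @export
node_ages <- function(x) {
  ntips <- ape::Ntip(x)
  desc <- .tip_descendants(x)
  ids <- (ntips + 1L):(ntips + x$Nnode)
  stats::setNames(x$ages[ids],
                  vapply(ids, function(v) paste(sort(x$tip.label[desc[[v]]]),
                                                collapse = ","), character(1)))
}

#' Per-node age differences between two chronograms
#'
#' @param chronoA,chronoB Chronograms on identical topologies.
#' @return data.frame with `clade`, `age_a`, `age_b`, `shift`
#'   (`age_a - age_b`), and the maximum absolute shift in attribute
#'   `"max_abs_shift"`.
#' @export
age_shift_report <- function(chronoA, chronoB) {
  a <- node_ages(chronoA); b <- node_ages(chronoB)
  if (!setequal(names(a), names(b))) stop("topology mismatch between chronograms")
  b <- b[names(a)]
  out <- data.frame(clade = names(a), age_a = unname(a), age_b = unname(b),
                    shift = unname(a - b))
  attr(out, "max_abs_shift") <- max(abs(out$shift))
  out
}
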