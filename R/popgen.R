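# Nucleotide diversity and the Reich-Patterson F_ST estimator, computed on
# complete-column site matrices. Both estimators work from per-site allele
# counts; pi handles any number of alleles, Reich-Patterson is defined for
# biallelic sites and skips others with a logged count.

# per-base count matrix (4 x sites) for a set of rows of a site matrix
.base_counts <- function(bases, rows) {
  sub <- bases[rows, , drop = FALSE]
  rbind(A = colSums(sub == "A"), C = colSums(sub == "C"),
        G = colSums(sub == "G"), T = colSums(sub == "T"))
}

.group_rows <- function(sm, group) {
  if (is.null(group)) return(seq_along(sm$samples))
  if (is.null(sm$groups)) stop("site matrix carries no group assignment")
  which(sm$groups == group)
}

#' Nucleotide diversity (pi) from a site matrix
#'
#' Per site with haploid sample size `n` and allele counts `c_k`,
#' `pi_i = sum_{k<l} 2 c_k c_l / (n (n-1))` (the unbiased average pairwise
#' difference). Genome-wide pi divides the summed per-site values by the
#' total number of retained sites, monomorphic sites included.
#'
#' @param sm A [site_matrix()].
#' @param group Group label (NULL = all samples).
#' @param window_size Optional window size (bases) for per-window values.
#' @return Object of class `pi_result`: list with `pi`, `sites_used`,
#'   `n_segregating` and optionally `windows` (data.frame with per-window
#'   pi).
#' @export
nucleotide_diversity <- function(sm, group = NULL, window_size = NULL) {
  rows <- .group_rows(sm, group)
  n <- length(rows)
  if (n < 2) stop("pi undefined: group has fewer than 2 sequences")
  cnt <- .base_counts(sm$bases, rows)
  # pi_i = 1 - sum_k c_k (c_k - 1) / (n (n-1)); identical to the pair sum
  same <- colSums(cnt * (cnt - 1))
  pi_site <- 1 - same / (n * (n - 1))
  total <- n_sites(sm)
  out <- list(pi = sum(pi_site) / total, sites_used = total,
              n_segregating = sum(pi_site > 0))
  if (!is.null(window_size)) {
    win <- floor(sm$pos / window_size)
    key <- paste(sm$chrom, win, sep = ":")
    sums <- tapply(pi_site, key, sum)
    denom <- if (sm$compact) window_size else as.vector(table(key)[names(sums)])
    out$windows <- data.frame(window = names(sums),
                              pi = as.vector(sums) / denom,
                              row.names = NULL)
  }
  structure(out, class = "pi_result")
}

#' @export
print.pi_result <- function(x, ...) {
  cat(sprintf("pi = %.6g over %s sites (%s segregating)\n", x$pi,
              format(x$sites_used, big.mark = " "),
              format(x$n_segregating, big.mark = " ")))
  invisible(x)
}

#' Reich-Patterson F_ST from per-site allele counts
#'
#' Per biallelic site with derived/minor counts `(a1, n1)` and `(a2, n2)`:
#' `h_j = a_j (n_j - a_j) / (n_j (n_j - 1))`,
#' `N = (a1/n1 - a2/n2)^2 - h1/n1 - h2/n2`, `D = N + h1 + h2`, and the
#' estimate is the ratio of sums `sum(N) / sum(D)` across sites.
#'
#' @param a1,n1,a2,n2 Numeric vectors of per-site allele counts (`a`) and
#'   haploid sample sizes (`n`) for the two groups.
#' @return Object of class `fst_result` with `fst`, `sum_num`, `sum_den`,
#'   `sites_used`, `sites_skipped`.
#' @export
rp_fst_from_counts <- function(a1, n1, a2, n2) {
  usable <- n1 >= 2 & n2 >= 2
  skipped <- sum(!usable)
  a1 <- a1[usable]; n1 <- n1[usable]; a2 <- a2[usable]; n2 <- n2[usable]
  h1 <- a1 * (n1 - a1) / (n1 * (n1 - 1))
  h2 <- a2 * (n2 - a2) / (n2 * (n2 - 1))
  num <- (a1 / n1 - a2 / n2)^2 - h1 / n1 - h2 / n2
  den <- num + h1 + h2
  ok <- is.finite(den)
  if (sum(den[ok]) == 0) stop("no informative sites: sum of denominators is zero")
  structure(list(fst = sum(num[ok]) / sum(den[ok]),
                 sum_num = sum(num[ok]), sum_den = sum(den[ok]),
                 sites_used = sum(ok), sites_skipped = skipped + sum(!ok)),
            class = "fst_result")
}

#' Reich-Patterson F_ST between two groups of a site matrix
#'
#' Uses biallelic sites only (sites with three or more alleles across the
#' two groups are skipped and counted); monomorphic sites contribute zero
#' to both sums and are omitted from the accumulation.
#'
#' @param sm A [site_matrix()].
#' @param group1,group2 Group labels.
#' @param stride Optional thinning stride (use every stride-th variable
#'   site; default 1 = all sites).
#' @return An `fst_result`; see [rp_fst_from_counts()].
#' @export
reich_patterson_fst <- function(sm, group1, group2, stride = 1L) {
  r1 <- .group_rows(sm, group1); r2 <- .group_rows(sm, group2)
  if (length(r1) < 2 || length(r2) < 2) stop("each group needs >= 2 sequences")
  c1 <- .base_counts(sm$bases, r1); c2 <- .base_counts(sm$bases, r2)
  tot <- c1 + c2
  nalleles <- colSums(tot > 0)
  poly <- nalleles == 2L
  multi <- sum(nalleles > 2L)
  idx <- which(poly)
  if (stride > 1L) idx <- idx[seq(1L, length(idx), by = stride)]
  if (!length(idx)) stop("no informative sites: no biallelic site between the groups")
  # count the alphabetically later of the two segregating bases; the
  # estimator is symmetric under allele relabeling
  sel <- apply(tot[, idx, drop = FALSE] > 0, 2, which)
  hi <- vapply(seq_along(idx), function(j) max(sel[, j]), integer(1))
  a1 <- c1[cbind(hi, idx)]
  a2 <- c2[cbind(hi, idx)]
  res <- rp_fst_from_counts(a1, rep(length(r1), length(idx)),
                            a2, rep(length(r2), length(idx)))
  res$sites_skipped <- res$sites_skipped + multi
  res$n_multiallelic <- multi
  res
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Reich-Patterson F_ST = %.4f (%d sites used, %d skipped)\n",
              x$fst, x$sites_used, x$sites_skipped))
  invisible(x)
}

#' Pairwise Reich-Patterson F_ST matrix over all groups
#'
#' @param sm A [site_matrix()] with a group assignment.
#' @param groups Character vector of group labels (default: all groups in
#'   the matrix).
#' @return A symmetric numeric matrix of F_ST estimates (zero diagonal),
#'   with the full `fst_result` objects in attribute `"results"`.
#' @export
pairwise_fst_matrix <- function(sm, groups = NULL) {
  if (is.null(groups)) groups <- unique(unname(sm$groups))
  k <- length(groups)
  m <- matrix(0, k, k, dimnames = list(groups, groups))
  results <- list()
  if (k >= 2) for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- reich_patterson_fst(sm, groups[i], groups[j])
    m[i, j] <- m[j, i] <- r$fst
    results[[paste(groups[i], groups[j], sep = "|")]] <- r
  }
  attr(m, "results") <- results
  m
}
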