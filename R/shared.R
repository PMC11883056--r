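# Shared ancestral variation: of the sites variable within a focal species,
# what fraction is also variable among a comparison set of species? Deep
# coalescence across rapid radiations leaves polymorphisms segregating on
# both sides of a species split, so this fraction stays high long after
# divergence.

#' Shared variable sites between a focal group and a comparison group
#'
#' A site is focal-variable if at least two distinct bases occur among the
#' focal sequences; a focal singleton is a focal-variable site whose
#' variation is carried by exactly one focal sequence (haploid count of the
#' non-majority bases equals one), and is removed from the focal tally when
#' `exclude_singletons` is set. A focal-variable site is shared when at
#' least two distinct bases occur among the comparison sequences. A
#' stricter allele-matching tally (`n_shared_same_allele`) additionally
#' requires that at least two of the bases segregating in the comparison
#' group also occur in the focal group.
#'
#' @param sm A [site_matrix()].
#' @param focal_group,comparison_group Disjoint group labels (each with at
#'   least 2 sequences).
#' @param exclude_singletons Drop focal singletons from the focal-variable
#'   set (default TRUE).
#' @return Object of class `shared_variation`: `n_focal_variable`,
#'   `n_shared`, `fraction` (NA when no focal-variable sites),
#'   `n_shared_same_allele`, `fraction_same_allele`, `singleton_mode`,
#'   `n_singletons_excluded`.
#' @export
shared_variable_sites <- function(sm, focal_group, comparison_group,
                                  exclude_singletons = TRUE) {
  rf <- .group_rows(sm, focal_group)
  rc <- .group_rows(sm, comparison_group)
  if (length(intersect(rf, rc))) stop("focal and comparison groups overlap")
  if (!length(rc)) stop("empty comparison group")
  if (length(rf) < 2 || length(rc) < 2) stop("each group needs >= 2 sequences")
  cf <- .base_counts(sm$bases, rf)
  cc <- .base_counts(sm$bases, rc)
  focal_var <- colSums(cf > 0) >= 2L
  nf <- length(rf)
  singleton <- focal_var & (nf - apply(cf, 2, max)) == 1L
  n_singletons <- sum(singleton)
  keep <- if (exclude_singletons) focal_var & !singleton else focal_var
  comp_var <- colSums(cc > 0) >= 2L
  shared <- keep & comp_var
  # allele-matching variant: >= 2 of the comparison group's segregating
  # bases also segregate (occur) in the focal group
  both <- colSums(cc > 0 & cf > 0) >= 2L
  shared_same <- keep & comp_var & both
  n_focal <- sum(keep)
  structure(list(n_focal_variable = n_focal,
                 n_shared = sum(shared),
                 fraction = if (n_focal) sum(shared) / n_focal else NA_real_,
                 n_shared_same_allele = sum(shared_same),
                 fraction_same_allele = if (n_focal) sum(shared_same) / n_focal else NA_real_,
                 singleton_mode = if (exclude_singletons) "excluded" else "included",
                 n_singletons_excluded = if (exclude_singletons) n_singletons else 0L),
            class = "shared_variation")
}

#' @export
print.shared_variation <- function(x, ...) {
  cat(sprintf("Shared variation: %d of %d focal-variable sites (%s) also variable in comparison group",
              x$n_shared, x$n_focal_variable,
              ifelse(is.na(x$fraction), "NA", sprintf("%.1f%%", 100 * x$fraction))),
      sprintf("[singletons %s]\n", x$singleton_mode))
  invisible(x)
}
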