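# Interval accounting: clusters, density bins, SV size classes, overlaps.

test_that("cluster chaining follows the 200-kb gap rule", {
  f <- data.frame(id = paste0("g", 1:3), chrom = "c1",
                  start = c(0, 150000, 400000),
                  end = c(1000, 151000, 401000), category = "RxNL")
  cf <- cluster_features(f)
  expect_equal(cf$summary$n_clusters, 1)
  expect_equal(cf$summary$pct_in_clusters, 66.7)
  expect_equal(cf$summary$largest_cluster, 2)
  expect_equal(is.na(cf$members$cluster), c(FALSE, FALSE, TRUE))
  # all gaps > 200 kb: no clusters at all
  f2 <- transform(f, start = c(0, 300000, 600000),
                  end = c(100, 300100, 600100))
  cf2 <- cluster_features(f2)
  expect_equal(cf2$summary$n_clusters, 0)
  expect_equal(cf2$summary$pct_in_clusters, 0)
  expect_error(cluster_features(transform(f, end = start)), "malformed")
})

test_that("clusters equal the brute-force transitive closure on random inputs", {
  set.seed(99)
  for (i in 1:200) {
    f <- random_features(sample(4:14, 1), span = 2e6, maxlen = 3e5)
    gap <- 2e5
    cf <- cluster_features(f, max_gap = gap)
    got <- split(seq_len(nrow(f)), cf$members$cluster)
    want <- closure_cluster_oracle(f, gap)
    norm <- function(x) sort(unname(vapply(x, function(s)
      paste(sort(s), collapse = "-"), character(1))))
    expect_identical(norm(got), norm(want))
    expect_true(all(cf$summary$pct_in_clusters >= 0 &
                      cf$summary$pct_in_clusters <= 100))
    expect_true(all(cf$summary$largest_cluster <= cf$summary$n_features))
  }
})

test_that("density bins use half-open 2-Mb segments and conserve totals", {
  lens <- c(c1 = 5e6, c2 = 3e6)
  none <- density_bins(data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0)), lens)
  expect_equal(none$c1, rep(0L, 3))
  f <- data.frame(chrom = c("c1", "c1", "c2"), start = c(2e6, 1999999, 0),
                  end = c(2e6 + 10, 2e6, 100))
  b <- density_bins(f, lens)
  expect_equal(b$c1, c(1L, 1L, 0L))     # start at exactly 2 Mb -> bin 1
  expect_equal(sum(unlist(b)), nrow(f))
  expect_error(density_bins(data.frame(chrom = "c1", start = 6e6, end = 6e6 + 1),
                            lens), "beyond chromosome length")
})

test_that("SV size classes use half-open boundaries and the 100-b floor", {
  recs <- data.frame(type = c("inversion", "inversion", "deletion", "deletion",
                              "insertion"),
                     length = c(1100000, 99, 100, 10000, 999))
  tab <- classify_sv_sizes(recs)
  expect_equal(attr(tab, "n_excluded"), 1L)
  expect_equal(tab$counts["inversion", ">=1 Mb"], 1L)
  expect_equal(tab$counts["deletion", "100 to <1 kb"], 1L)
  expect_equal(tab$counts["deletion", "10 to <100 kb"], 1L)
  expect_equal(tab$counts["insertion", "100 to <1 kb"], 1L)
  expect_equal(tab$grand_total, 4L)
  expect_error(classify_sv_sizes(data.frame(type = "mystery", length = 500)),
               "unknown SV type")
})

test_that("size-class margins always equal interior sums", {
  set.seed(12)
  for (i in 1:20) {
    recs <- data.frame(type = sample(oakdiv:::.sv_types, 60, replace = TRUE),
                       length = floor(stats::rlnorm(60, log(2000), 2)) + 50)
    tab <- classify_sv_sizes(recs)
    expect_equal(unname(tab$row_totals), unname(rowSums(tab$counts)))
    expect_equal(unname(tab$col_totals), unname(colSums(tab$counts)))
    expect_equal(tab$grand_total, sum(tab$counts))
    expect_equal(tab$grand_total + attr(tab, "n_excluded"), 60L)
  }
})

test_that("the shipped hapA/hapB class counts reproduce the printed margins", {
  tab <- classify_sv_sizes(sv_records_from_class_counts(oak_sv_class_counts()))
  expect_equal(tab$grand_total, 12808L)
  expect_equal(unname(tab$row_totals),
               c(103L, 1331L, 4760L, 4858L, 803L, 652L, 15L, 134L, 152L))
  expect_equal(unname(tab$col_totals), c(8097L, 4232L, 454L, 23L, 2L))
})

test_that("gene/SV overlap respects half-open adjacency and counts exons", {
  genes <- data.frame(id = "g1", chrom = "c1", start = 100, end = 200)
  exons <- data.frame(parent = "g1", chrom = "c1", start = 180, end = 200)
  svs <- data.frame(type = "inversion", chrom = "c1", start = 150, end = 300)
  r <- gene_sv_overlap(genes, exons, svs)
  expect_equal(r$n_gene_body_overlap, 1)
  expect_equal(r$n_exonic_overlap, 1)
  # adjacent but not overlapping
  svs2 <- data.frame(type = "inversion", chrom = "c1", start = 200, end = 300)
  r2 <- gene_sv_overlap(genes, exons, svs2)
  expect_equal(r2$n_gene_body_overlap, 0)
  # exon outside its gene warns but is still used
  exons3 <- data.frame(parent = "g1", chrom = "c1", start = 250, end = 260)
  expect_warning(r3 <- gene_sv_overlap(genes, exons3, svs2), "outside")
  expect_equal(r3$n_exonic_overlap, 1)
})

test_that("overlap counts match the all-pairs oracle on random toy genomes", {
  set.seed(21)
  for (i in 1:25) {
    ng <- sample(5:15, 1)
    genes <- random_features(ng, n_cat = 1)
    genes$category <- NULL
    exons <- do.call(rbind, lapply(seq_len(ng), function(k) {
      g <- genes[k, ]
      n <- sample(1:3, 1)
      st <- sort(floor(stats::runif(n, g$start, g$end - 1)))
      data.frame(parent = g$id, chrom = g$chrom, start = st,
                 end = pmin(st + floor(stats::runif(n, 1, 2000)), g$end))
    }))
    svs <- random_features(sample(3:10, 1), n_cat = 1)
    svs$type <- sample(oakdiv:::.sv_types, nrow(svs), replace = TRUE)
    got <- gene_sv_overlap(genes, exons, svs)
    want <- overlap_oracle(genes, exons, svs)
    expect_equal(got$n_gene_body_overlap, want$n_body)
    expect_equal(got$n_exonic_overlap, want$n_exonic)
    expect_equal(got$by_sv_type[names(want$by_type)][want$by_type > 0],
                 want$by_type[want$by_type > 0])
    expect_lte(got$n_exonic_overlap, got$n_gene_body_overlap)
  }
})

test_that("fractional repeat overlap unions repeats and is inclusive at the threshold", {
  gene <- data.frame(chrom = "c1", start = 0, end = 1000)
  reps <- data.frame(chrom = "c1", start = c(0, 900), end = c(50, 1000))
  r <- fractional_repeat_overlap(gene, reps, min_frac = 0.10)
  expect_equal(r$per_feature$overlap_bases, 150)
  expect_equal(r$n, 1)
  # 99 / 1000 = 9.9% < 10%
  r2 <- fractional_repeat_overlap(gene, data.frame(chrom = "c1", start = 0,
                                                   end = 99), 0.10)
  expect_equal(r2$n, 0)
  # exactly 10% counts (inclusive)
  r3 <- fractional_repeat_overlap(gene, data.frame(chrom = "c1", start = 0,
                                                   end = 100), 0.10)
  expect_equal(r3$n, 1)
  # overlapping repeats are unioned, not double counted
  r4 <- fractional_repeat_overlap(gene, data.frame(chrom = "c1",
                                                   start = c(0, 25), end = c(50, 60)),
                                  0.10)
  expect_equal(r4$per_feature$overlap_bases, 60)
  # no repeats
  r5 <- fractional_repeat_overlap(gene, data.frame(chrom = character(0),
                                                   start = numeric(0),
                                                   end = numeric(0)))
  expect_equal(r5$n, 0)
})

test_that("interval results are invariant to input ordering", {
  set.seed(3)
  f <- random_features(12, span = 1e6, maxlen = 2e5)
  perm <- sample(nrow(f))
  a <- cluster_features(f)$summary
  b <- cluster_features(f[perm, ])$summary
  b <- b[match(a$category, b$category), ]
  expect_equal(a$n_clusters, b$n_clusters)
  expect_equal(a$pct_in_clusters, b$pct_in_clusters)
  expect_equal(a$largest_cluster, b$largest_cluster)
})
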