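# Coalescent simulator: closed-form checks of the censored MSC and the
# infinite-sites mutation model.

test_that("single sampled lineage yields a single-tip tree with no coalescence", {
  m <- mk_model(Ne = 1000, mu = 0, nA = 1, n_windows = 3, ploidy = 1)
  gt <- simulate_gene_trees(m, seed = 1)
  expect_length(gt, 3)
  for (t in gt) {
    expect_equal(ape::Ntip(t), 1)
    expect_equal(t$tip.label, "A_1_1")
  }
})

test_that("empty sample plan is refused", {
  m <- mk_model(Ne = 1000, mu = 0, nA = 0, nB = 0, n_windows = 2)
  expect_error(simulate_gene_trees(m, seed = 1), "empty sample plan")
})

test_that("pairwise TMRCA matches the diploid coalescent expectation 2Ne", {
  # E[T2] = 2Ne, SD = 2Ne for a single pair of lineages
  m <- mk_model(Ne = 1000, mu = 0, nA = 1, n_windows = 1000, ploidy = 2)
  gt <- simulate_gene_trees(m, seed = 42)
  tm <- vapply(gt, function(t) max(t$node.time), numeric(1))
  se <- 2000 / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2000), 3 * se)
})

test_that("coalescences across species never predate the species divergence", {
  tr <- ape::read.tree(text = "((A:2000,B:2000):2000,C:4000);")
  m <- species_tree_model(tr, Ne = 500, mu = 0,
                          sample_plan = c(A = 2, B = 2, C = 2), n_windows = 40)
  gt <- simulate_gene_trees(m, seed = 9)
  for (t in gt) {
    d <- ape::mrca(t)
    sp <- sub("_.*", "", t$tip.label)
    for (i in seq_len(ape::Ntip(t) - 1)) for (j in (i + 1):ape::Ntip(t)) {
      tm <- t$node.time[d[i, j]]
      if (sp[i] != sp[j]) {
        split_t <- if (all(c(sp[i], sp[j]) %in% c("A", "B"))) 2000 else 4000
        expect_gte(tm, split_t)
      }
      expect_gte(tm, 0)
    }
  }
})

test_that("triplet gene-tree concordance follows 1 - (2/3) exp(-tau)", {
  # tau = t / (2 Ne); checked across three internal branch lengths
  for (tau in c(0.5, 1, 2)) {
    Ne <- 1000; tint <- tau * 2 * Ne
    tr <- ape::read.tree(text = sprintf("((A:%f,B:%f):%f,C:%f);",
                                        2000, 2000, tint, 2000 + tint))
    m <- species_tree_model(tr, Ne = Ne, mu = 0,
                            sample_plan = c(A = 1, B = 1, C = 1),
                            ploidy = 1, n_windows = 600)
    gt <- simulate_gene_trees(m, seed = 100 + round(10 * tau))
    ab <- vapply(gt, function(t) {
      d <- ape::cophenetic.phylo(t)
      sp <- sub("_.*", "", rownames(d)); dimnames(d) <- list(sp, sp)
      d["A", "B"] < d["A", "C"] & d["A", "B"] < d["B", "C"]
    }, logical(1))
    p <- 1 - (2 / 3) * exp(-tau)
    se <- sqrt(p * (1 - p) / length(ab))
    expect_lt(abs(mean(ab) - p), 4 * se)
  }
})

test_that("zero mutation rate gives identical haplotypes and no variants", {
  m <- mk_model(Ne = 500, mu = 0, nA = 2, n_windows = 2)
  gt <- simulate_gene_trees(m, seed = 3)
  mut <- drop_mutations(gt[[1]], mu = 0, window_length = 100, seed = 5)
  expect_length(mut$positions, 0)
  expect_true(all(mut$haplotypes == matrix(mut$ancestral, 4, 100, byrow = TRUE)))
})

test_that("pairwise differences match the 2 t mu L Poisson expectation", {
  # fixed two-tip genealogy with TMRCA t: E[diffs] = 2 t mu L
  t2 <- 1500; mu <- 1e-5; L <- 1000
  tree <- ape::read.tree(text = sprintf("(A_1_1:%f,A_1_2:%f);", t2, t2))
  diffs <- vapply(1:500, function(i) {
    mut <- drop_mutations(tree, mu, L, seed = i, return_haplotypes = FALSE)
    sum(mut$carriers[1, ] != mut$carriers[2, ])
  }, numeric(1))
  expected <- 2 * t2 * mu * L
  se <- sqrt(expected / length(diffs))   # Poisson variance
  expect_lt(abs(mean(diffs) - expected), 3 * se)
})

test_that("total variant counts on a fixed genealogy are Poisson", {
  tree <- ape::read.tree(text = "((A_1_1:800,A_1_2:800):700,A_2_1:1500);")
  mu <- 2e-5; L <- 500
  lam <- mu * L * sum(tree$edge.length)
  counts <- vapply(1:400, function(i)
    length(drop_mutations(tree, mu, L, seed = 1000 + i,
                          return_haplotypes = FALSE)$positions), numeric(1))
  # chi-square goodness of fit against the Poisson pmf, tails pooled
  ks <- 0:max(counts)
  p <- stats::dpois(ks, lam); p[length(p)] <- 1 - sum(p[-length(p)])
  obs <- tabulate(counts + 1, nbins = length(ks))
  keep <- p * length(counts) >= 5
  obs2 <- c(sum(obs[!keep]), obs[keep]); p2 <- c(sum(p[!keep]), p[keep])
  gof <- suppressWarnings(stats::chisq.test(obs2, p = p2 / sum(p2)))
  expect_gt(gof$p.value, 0.01)
})

test_that("infinite-sites overflow is caught", {
  tree <- ape::read.tree(text = "(A_1_1:5e5,A_1_2:5e5);")
  expect_error(drop_mutations(tree, mu = 1, window_length = 10, seed = 1),
               "infinite-sites overflow")
})

test_that("same seed reproduces a dataset byte-identically; other seeds differ", {
  m <- mk_model(Ne = 800, mu = 1e-5, nA = 2, n_windows = 4, window_length = 300)
  d1 <- simulate_dataset(m, seed = 7)
  d2 <- simulate_dataset(m, seed = 7)
  d3 <- simulate_dataset(m, seed = 8)
  expect_identical(d1$reference, d2$reference)
  expect_identical(d1$variants, d2$variants)
  expect_identical(ape::write.tree(d1$trees), ape::write.tree(d2$trees))
  expect_false(identical(ape::write.tree(d1$trees), ape::write.tree(d3$trees)))
})

test_that("heterozygous genotypes occur exactly where the two haplotypes differ", {
  m <- mk_model(Ne = 800, mu = 2e-5, nA = 3, n_windows = 3, window_length = 400)
  ds <- simulate_dataset(m, seed = 21)
  for (s in ds$samples) {
    pair <- ds$hap_gt[paste(s, 1:2, sep = "_"), , drop = FALSE]
    het_truth <- pair[1, ] != pair[2, ]
    het_vcf <- ds$variants$gt[, s] == "0/1"
    expect_identical(unname(het_vcf), unname(het_truth))
  }
})

test_that("a mu = 0 dataset has no variant records and a written/read dataset round-trips", {
  m0 <- mk_model(Ne = 500, mu = 0, nA = 2, n_windows = 2, window_length = 200)
  ds0 <- simulate_dataset(m0, seed = 2)
  expect_length(ds0$variants$pos, 0)

  m <- mk_model(Ne = 800, mu = 2e-5, nA = 2, n_windows = 3, window_length = 300)
  ds <- simulate_dataset(m, seed = 13)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$reference, ds$reference)
  expect_identical(back$variants$pos, ds$variants$pos)
  expect_identical(back$variants$ref, ds$variants$ref)
  expect_identical(back$variants$alt, ds$variants$alt)
  expect_identical(unname(back$variants$gt), unname(ds$variants$gt))
  expect_equal(length(back$trees), length(ds$trees))
})

test_that("haploid models cannot be assembled into diploid VCFs", {
  m <- mk_model(Ne = 500, mu = 1e-5, nA = 3, n_windows = 2, ploidy = 1)
  expect_error(simulate_dataset(m, seed = 1), "odd haplotype")
})

test_that("simulated within-species pi is unbiased for theta = 4 Ne mu", {
  m <- mk_model(Ne = 1000, mu = 1.25e-6, nA = 3, n_windows = 250,
                window_length = 1000)
  sm <- simulate_site_matrix(m, seed = 77)
  pr <- nucleotide_diversity(sm, "A", window_size = 1000)
  w <- numeric(250)                      # windows without variants have pi = 0
  idx <- as.integer(sub("chr1:", "", pr$windows$window)) + 1L
  w[idx] <- pr$windows$pi
  se <- stats::sd(w) / sqrt(length(w))
  expect_lt(abs(mean(w) - 0.005), 3 * se)
  expect_equal(pr$pi, mean(w), tolerance = 1e-10)
})

test_that("between-species divergence approaches 2 mu T + 4 N_anc mu", {
  T_split <- 20000; Ne <- 1000; mu <- 1e-6
  tr <- ape::read.tree(text = sprintf("(A:%d,B:%d);", T_split, T_split))
  m <- species_tree_model(tr, Ne = Ne, mu = mu, sample_plan = c(A = 1, B = 1),
                          ploidy = 1, window_length = 1000, n_windows = 300)
  sm <- simulate_site_matrix(m, seed = 55)
  win <- floor(sm$pos / 1000)
  mis <- sm$bases[1, ] != sm$bases[2, ]
  per_win <- vapply(0:299, function(w) sum(mis[win == w]) / 1000, numeric(1))
  expected <- 2 * mu * T_split + 4 * Ne * mu
  se <- stats::sd(per_win) / sqrt(length(per_win))
  expect_lt(abs(mean(per_win) - expected), 3 * se)
})
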