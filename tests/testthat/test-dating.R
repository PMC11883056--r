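# Ancestral-polymorphism correction and penalized-likelihood dating.

test_that("pi correction subtracts pi/2 from terminals only", {
  tr <- ape::read.tree(text = "((A:0.02,B:0.03):0.01,C:0.04);")
  same <- correct_ancestral_polymorphism(tr, 0)
  expect_equal(same$edge.length, tr$edge.length)
  corr <- correct_ancestral_polymorphism(tr, 0.012)
  term <- corr$edge[, 2] <= 3
  lens <- stats::setNames(corr$edge.length, c("int", "A", "B", "C")[
    ifelse(term, corr$edge[, 2] + 1, 1)])
  expect_equal(unname(lens[c("A", "B")]), c(0.014, 0.024))
  expect_equal(sum(corr$edge.length[!term]), sum(tr$edge.length[!term]))
  # tip-to-tip path shrinks by exactly pi
  expect_equal(ape::cophenetic.phylo(tr)["A", "B"] -
                 ape::cophenetic.phylo(corr)["A", "B"], 0.012)
  # clamping at the floor is logged
  tr2 <- ape::read.tree(text = "((A:0.004,B:0.03):0.01,C:0.04);")
  c2 <- correct_ancestral_polymorphism(tr2, 0.012, floor = 0)
  expect_equal(min(c2$edge.length), 0)
  expect_equal(attr(c2, "n_clamped"), 1L)
  expect_error(correct_ancestral_polymorphism(tr, -0.1), "pi must be")
})

test_that("clocklike input is recovered exactly for any penalty weight", {
  tr <- ape::read.tree(text = "(((A:0.01,B:0.01):0.02,C:0.03):0.02,D:0.05);")
  true_rel <- c(1, 0.6, 0.2)          # root, ABC, AB relative heights
  for (lam in c(0.1, 1, 100)) {
    ch <- penalized_likelihood_date(tr, calibration_age = 56, lambda = lam,
                                    L_effective = 1e4, seed = 2)
    ages <- node_ages(ch)
    expect_equal(unname(ages["A,B,C,D"]), 56)   # calibration exact
    expect_equal(unname(ages[c("A,B,C,D", "A,B,C", "A,B")]) / 56, true_rel,
                 tolerance = 1e-3)
    # ultrametric output
    depth <- ape::node.depth.edgelength(ch)
    tips <- depth[1:ape::Ntip(ch)]
    expect_lt(diff(range(tips)) / max(tips), 1e-6)
  }
})

test_that("a dominant penalty drives all branch rates to a common value", {
  tr <- ape::read.tree(text = "(((A:0.012,B:0.009):0.021,C:0.035):0.018,D:0.047);")
  ch <- penalized_likelihood_date(tr, calibration_age = 10, lambda = 1e8,
                                  L_effective = 1e4, seed = 4)
  expect_lt(diff(range(ch$rates)), 1e-3)
})

test_that("the worked correction example dates to 26.88 vs 30.0 Ma", {
  tr <- ape::read.tree(text = "((A:0.030,B:0.030):0.026,C:0.056);")
  raw <- penalized_likelihood_date(tr, calibration_age = 56, seed = 1)
  expect_equal(unname(node_ages(raw)["A,B"]), 30.0, tolerance = 1e-3)
  corr <- penalized_likelihood_date(correct_ancestral_polymorphism(tr, 0.012),
                                    calibration_age = 56, seed = 1)
  expect_equal(unname(node_ages(corr)["A,B"]), 26.88, tolerance = 1e-3)
  shifts <- age_shift_report(corr, raw)
  expect_equal(attr(shifts, "max_abs_shift"), 3.12, tolerance = 1e-2)
  expect_equal(shifts$shift[shifts$clade == "A,B,C"], 0)
})

test_that("identical chronograms have zero shifts; mismatched topologies error", {
  tr <- ape::read.tree(text = "((A:0.01,B:0.01):0.01,C:0.02);")
  ch <- penalized_likelihood_date(tr, calibration_age = 5, seed = 1)
  s <- age_shift_report(ch, ch)
  expect_true(all(s$shift == 0))
  tr2 <- ape::read.tree(text = "((A:0.01,C:0.01):0.01,B:0.02);")
  ch2 <- penalized_likelihood_date(tr2, calibration_age = 5, seed = 1)
  expect_error(age_shift_report(ch, ch2), "topology mismatch")
})

test_that("dating a non-root calibration node holds it exactly", {
  tr <- ape::read.tree(text = "(((A:0.01,B:0.01):0.02,C:0.03):0.02,D:0.05);")
  # calibrate the ABC crown (node with tips A,B,C) at 20
  ntips <- 4
  lab <- function(v, tree) sort(tree$tip.label[
    oakdiv:::.tip_descendants(tree)[[v]]])
  abc <- which(vapply((ntips + 1):(ntips + tr$Nnode), function(v)
    identical(lab(v, tr), c("A", "B", "C")), logical(1))) + ntips
  ch <- penalized_likelihood_date(tr, calibration_age = 20,
                                  calibration_node = abc, seed = 3)
  ages <- node_ages(ch)
  expect_equal(unname(ages["A,B,C"]), 20)
  expect_gt(unname(ages["A,B,C,D"]), 20)
  expect_equal(unname(ages["A,B"]) / 20, 1 / 3, tolerance = 5e-3)
})

test_that("pi-corrected dating has smaller bias than uncorrected on MSC data", {
  # ((A,B),(C,D)) with deep ancestral polymorphism; distances -> NJ -> dating
  Ne <- 2000; mu <- 2e-6
  T_ab <- 10000; T_cd <- 14000; T_root <- 20000; T_out <- 60000
  nwk <- sprintf("(((A:%d,B:%d):%d,(C:%d,D:%d):%d):%d,O:%d);",
                 T_ab, T_ab, T_root - T_ab, T_cd, T_cd, T_root - T_cd,
                 T_out - T_root, T_out)
  m <- species_tree_model(ape::read.tree(text = nwk), Ne = Ne, mu = mu,
                          sample_plan = c(A = 2, B = 1, C = 1, D = 1, O = 1),
                          ploidy = 1, window_length = 2000, n_windows = 30)
  reps <- 12
  err_raw <- matrix(NA_real_, reps, 2); err_cor <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    sm <- simulate_site_matrix(m, seed = 4000 + r)
    pi_a <- nucleotide_diversity(sm, "A")$pi
    keep <- c("A_1_1", "B_1_1", "C_1_1", "D_1_1", "O_1_1")
    sm1 <- sm
    sm1$bases <- sm$bases[keep, , drop = FALSE]
    sm1$samples <- sub("_1_1$", "", keep)
    rownames(sm1$bases) <- sm1$samples
    sm1$groups <- NULL
    d <- jc69_matrix(sm1)
    nj <- neighbor_joining(d)
    rooted <- ape::drop.tip(ape::root(nj, outgroup = "O", resolve.root = TRUE), "O")
    raw <- penalized_likelihood_date(rooted, calibration_age = T_root,
                                     lambda = 1, seed = r)
    cor <- penalized_likelihood_date(
      correct_ancestral_polymorphism(rooted, pi_a),
      calibration_age = T_root, lambda = 1, seed = r)
    if (!all(c("A,B", "C,D") %in% names(node_ages(raw)))) next
    err_raw[r, ] <- node_ages(raw)[c("A,B", "C,D")] - c(T_ab, T_cd)
    err_cor[r, ] <- node_ages(cor)[c("A,B", "C,D")] - c(T_ab, T_cd)
  }
  ok <- stats::complete.cases(err_raw)
  expect_gt(sum(ok), reps / 2)
  # uncorrected ages systematically too old; corrected strictly less biased
  expect_true(all(colMeans(err_raw[ok, ]) > 0))
  expect_true(all(abs(colMeans(err_cor[ok, ])) < abs(colMeans(err_raw[ok, ]))))
})
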