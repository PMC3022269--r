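test_that("phi and psi corrections match closed-form evaluation and domain", {
  expect_identical(phi_correction(0), 0)
  expect_identical(psi_correction(0), 0)
  expect_equal(phi_correction(0.25), 0.0625 / 5.125)
  expect_equal(phi_correction(0.5), 0.1)
  expect_equal(psi_correction(0.25), 0.1)
  expect_equal(psi_correction(0.5), 0.25)
  expect_error(phi_correction(-0.01), "0, 0.5")
  expect_error(psi_correction(0.6), "0, 0.5")
  # monotone increasing on the domain
  r <- seq(0, 0.5, by = 0.005)
  expect_true(all(diff(phi_correction(r)) > 0))
  expect_true(all(diff(psi_correction(r)) > 0))
})

test_that("mode layout matches the hand-transcribed table and bookkeeping", {
  L <- mode_layout()
  expect_identical(unname(L$mode), oracle_mode_table)
  expect_identical(L$cells_per_mode, c(4L, 12L, 12L, 12L, 12L, 12L, 6L, 24L, 6L))
  # per mode, coefficients over its cells sum to exactly 1
  for (h in 1:9) {
    expect_identical(sum(L$coef[L$mode == h]), 1)
  }
  # the first four gametes, and only those, are double-reduction gametes
  expect_identical(is_double_reduction(1:10), c(rep(TRUE, 4), rep(FALSE, 6)))
})

test_that("joint table reproduces the layout cells and normalization", {
  g1 <- c(1, 0, 0, 0, 0, 0, 0, 0, 0)
  J <- build_joint_table(g1)
  expect_equal(J["M1M1", "Q1Q1"], 1 / 4)
  expect_equal(sum(J), 1)
  expect_equal(sum(J != 0), 4)

  g7 <- c(0, 0, 0, 0, 0, 0, 1, 0, 0)
  expect_equal(build_joint_table(g7)["M1M2", "Q1Q2"], 1 / 6)

  set.seed(1)
  for (k in 1:20) {
    g <- as.numeric(rmultinom(1, 60, rep(1 / 9, 9))) / 60
    J <- build_joint_table(g)
    expect_equal(sum(J), 1, tolerance = 1e-12)
    expect_equal(unname(J), oracle_joint_table(g), tolerance = 1e-15)
    # marker-DR rows carry exactly the marker double-reduction mode mass
    expect_equal(sum(J[1:4, ]), g[1] + g[2] + g[5] + g[6], tolerance = 1e-12)
    expect_equal(sum(J[5:10, ]), g[3] + g[4] + g[7] + g[8] + g[9],
                 tolerance = 1e-12)
  }
  expect_error(build_joint_table(c(0.5, 0.4, 0, 0, 0, 0, 0, 0, 0)), "sum to 1")
  expect_error(build_joint_table(rep(-1 / 9, 9)), "nonnegative|sum")
})

test_that("expected recombination-count table matches its structure", {
  C0 <- recomb_count_table(0)
  expect_equal(C0["M1M1", "Q1Q1"], 0)
  expect_equal(C0["M1M1", "Q2Q2"], 2)
  expect_equal(C0["M1M2", "Q1Q2"], 0)  # 2*phi(0)
  expect_equal(C0["M1M2", "Q1Q3"], 1)  # 1 + psi(0)
  r <- 0.31
  expect_equal(unname(recomb_count_table(r)), oracle_recomb_counts(r))
  expect_true(all(recomb_count_table(0.5) >= 0 & recomb_count_table(0.5) <= 2))
  # diagonal of the heterozygote block is the same-pair (2*phi) correction
  Cr <- recomb_count_table(0.2)
  expect_equal(unname(diag(Cr[5:10, 5:10])), rep(2 * phi_correction(0.2), 6))
})

test_that("marker marginals follow the double-reduction split", {
  expect_equal(unname(marker_marginals(0)), c(rep(0, 4), rep(1 / 6, 6)))
  m <- marker_marginals(0.3)
  expect_equal(unname(m), c(rep(0.075, 4), rep(0.7 / 6, 6)))
  expect_equal(sum(m), 1)
  expect_error(marker_marginals(1.2), "probability")
  # marginals equal the joint-table row sums for an admissible g
  g <- construct_g(0.3, 0.3, 0.1)
  expect_equal(unname(rowSums(build_joint_table(g))),
               unname(marker_marginals(0.3)), tolerance = 1e-10)
})

test_that("conditional QTL-given-marker rows are joint over marginal", {
  g <- construct_g(0.3, 0.3, 0.05)
  cond <- conditional_qtl_given_marker(g)
  expect_equal(unname(rowSums(cond)), rep(1, 10), tolerance = 1e-12)
  J <- oracle_joint_table(g)
  expect_equal(unname(cond), J / rowSums(J), tolerance = 1e-12)
  # degenerate: all mass in mode 1 gives a point mass on the matched genotype
  cond1 <- conditional_qtl_given_marker(c(1, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(cond1["M1M1", ]), c(1, rep(0, 9)))
  expect_identical(attr(cond1, "undefined_rows"), 5:10)
})

test_that("implied recombination fraction solves the count equation", {
  # no phi/psi mass: closed form
  g <- c(0.75, 0, 0, 0, 0, 0, 0, 0, 0.25)
  expect_equal(implied_r(g), 0.25, tolerance = 1e-10)
  g2 <- c(0.8, 0, 0.1, 0, 0.1, 0, 0, 0, 0)
  expect_equal(implied_r(g2), 0.1, tolerance = 1e-10)
  # all mass in the same-pair heterozygote mode: r = phi(r) has root 0
  expect_equal(implied_r(c(0, 0, 0, 0, 0, 0, 1, 0, 0)), 0)
  # inadmissible: all mass in 2-recombinant modes implies r = 1
  expect_warning(rhat <- implied_r(c(0, 1, 0, 0, 0, 0, 0, 0, 0)), "clamp")
  expect_equal(rhat, 0.5)
  expect_error(implied_r(c(0, 1, 0, 0, 0, 0, 0, 0, 0), strict = TRUE),
               "inadmissible")
})

test_that("modes_to_params recovers the double-reduction and linkage summaries", {
  p <- modes_to_params(c(1, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(p), c(1, 1, 0))
  g <- c(0.8, 0, 0.1, 0, 0.1, 0, 0, 0, 0)
  p <- modes_to_params(g)
  expect_equal(unname(p), c(0.9, 0.9, 0.1), tolerance = 1e-10)
  # the audit convention swaps the two double-reduction sums
  g2 <- construct_g(0.2, 0.4, 0.2)
  pt <- modes_to_params(g2, "table")
  pp <- modes_to_params(g2, "printed")
  expect_equal(pt[["alpha"]], pp[["beta"]])
  expect_equal(pt[["beta"]], pp[["alpha"]])
  expect_equal(pt[["alpha"]], 0.2, tolerance = 1e-8)
  expect_error(modes_to_params(c(0, 1, 0, 0, 0, 0, 0, 0, 0)), "inadmissible")
})
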