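test_that("construct_g hits the requested parameters across the study grid", {
  for (a in c(0.05, 0.15, 0.3)) {
    for (r in c(0.05, 0.25)) {
      g <- construct_g(a, a, r)
      expect_true(all(g >= 0))
      expect_equal(sum(g), 1, tolerance = 1e-12)
      p <- modes_to_params(g)
      expect_equal(unname(p), c(a, a, r), tolerance = 1e-8)
    }
  }
  # unequal double reduction is supported when r is attainable
  p <- modes_to_params(construct_g(0.1, 0.3, 0.2))
  expect_equal(unname(p), c(0.1, 0.3, 0.2), tolerance = 1e-8)
})

test_that("construct_g rejects unattainable recombination targets", {
  # |alpha - beta| mass must carry >= 1 recombination event each
  expect_error(construct_g(0.1, 0.5, 0.01), "feasible range")
  expect_error(construct_g(0.4, 0, 0.05), "feasible range")
  # r = 0 is attainable when alpha = beta (shared double reduction)
  g0 <- construct_g(0.3, 0.3, 0)
  expect_equal(implied_r(g0), 0, tolerance = 1e-12)
  expect_equal(g0[1], 0.3, tolerance = 1e-12)
  expect_equal(g0[7], 0.7, tolerance = 1e-12)
})

test_that("genetic variance enumerates the ten-genotype distribution", {
  expect_equal(genetic_variance(c(2, rep(0, 9)), 0.3), 0)
  # direct enumeration oracle at the default study setting
  m <- c(1.6, 1.6, 1.6, -0.8, 2.7, 2.7, 0.3, 2.7, 0.3, 0.3)
  p <- c(rep(0.3 / 4, 4), rep(0.7 / 6, 6))
  expect_equal(genetic_variance(study_effects, 0.3),
               sum(p * m^2) - sum(p * m)^2, tolerance = 1e-12)
  # beta = 1: only homozygote means contribute
  hom <- m[1:4]
  expect_equal(genetic_variance(study_effects, 1),
               mean(hom^2) - mean(hom)^2, tolerance = 1e-12)
})

test_that("error variance follows the heritability identity", {
  expect_equal(error_variance(1, 0.5), 1)
  expect_equal(error_variance(1, 0.1), 9)
  expect_equal(error_variance(2.5, 0.4), 2.5 * 1.5)
  expect_warning(v0 <- error_variance(0, 0.4), "degenerate")
  expect_equal(v0, 0)
  expect_error(error_variance(1, 0), "strictly inside")
  expect_error(error_variance(1, 1), "strictly inside")
})

test_that("simulated datasets are deterministic and match their config", {
  cfg <- sim_config(n = 200, alpha = 0.3, r = 0.05, h2 = 0.4, seed = 11)
  bc1 <- simulate_dataset(cfg)
  bc2 <- simulate_dataset(cfg)
  expect_identical(bc1$marker, bc2$marker)
  expect_identical(bc1$phenotype, bc2$phenotype)
  expect_identical(nrow(bc1), 200L)
  expect_true(all(bc1$marker %in% gamete_labels("M")))
  expect_true(all(bc1$qtl_true %in% gamete_labels("Q")))
  # noiseless trait: phenotype equals the genotypic value exactly
  cfg0 <- sim_config(n = 50, alpha = 0.3, r = 0.05, sigma2 = 0, seed = 2)
  bc0 <- simulate_dataset(cfg0)
  means <- effects_to_means(study_effects)
  expect_identical(bc0$phenotype,
                   unname(means[match(bc0$qtl_true, gamete_labels("Q"))]))
})

test_that("simulated gamete frequencies converge to the joint table", {
  cfg <- sim_config(n = 1e5, alpha = 0.3, r = 0.05, h2 = 0.4, seed = 31)
  bc <- simulate_dataset(cfg)
  midx <- match(bc$marker, gamete_labels("M"))
  qidx <- match(bc$qtl_true, gamete_labels("Q"))
  # marker double-reduction fraction within binomial sampling error
  expect_lt(abs(mean(midx <= 4) - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))
  # QTL double-reduction fraction likewise
  expect_lt(abs(mean(qidx <= 4) - 0.3), 4 * sqrt(0.3 * 0.7 / 1e5))
  # chi-square goodness of fit over the populated joint cells
  J <- build_joint_table(attr(bc, "g_true"))
  obs <- table(factor(midx, 1:10), factor(qidx, 1:10))
  keep <- J > 1e-12
  pval <- suppressWarnings(
    stats::chisq.test(as.vector(obs[keep]),
                      p = as.vector(J[keep]) / sum(J[keep]))$p.value)
  expect_gt(pval, 0.001)
})

test_that("phenotypic variance decomposes into genetic and residual parts", {
  cfg <- sim_config(n = 4e4, alpha = 0.3, r = 0.05, h2 = 0.4, seed = 17)
  bc <- simulate_dataset(cfg)
  sg2 <- genetic_variance(study_effects, 0.3)
  expect_equal(stats::var(bc$phenotype), sg2 + cfg$sigma2, tolerance = 0.05)
  # realized heritability near its nominal value
  means <- effects_to_means(study_effects)
  gvals <- means[match(bc$qtl_true, gamete_labels("Q"))]
  expect_equal(stats::var(gvals) / stats::var(bc$phenotype), 0.4,
               tolerance = 0.02)
})

test_that("replicate_study summarises per-replicate fits reproducibly", {
  cfg <- sim_config(n = 60, alpha = 0.3, r = 0.05, sigma2 = 0.05,
                    seed = 5, reps = 2)
  ctl <- tetra_em_control(n_starts = 1, tol = 1e-6, max_iter = 500, seed = 1)
  st <- replicate_study(cfg, ctl)
  expect_identical(nrow(st$estimates), 2L)
  s <- summary(st)
  expect_identical(attr(s, "reps"), 2L)
  # summary mean/sd equal hand-computed statistics of the replicate fits
  expect_equal(s["mean", "alpha"], mean(st$estimates$alpha))
  expect_equal(s["sd", "r"], stats::sd(st$estimates$r))
  # rerun is identical (master-seed-derived replicate seeds)
  st2 <- replicate_study(cfg, ctl)
  expect_equal(st$estimates$loglik, st2$estimates$loglik)
})
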