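test_that("E step equals the direct Bayes-rule oracle", {
  bc <- random_small_bc(15, seed = 21)
  g <- construct_g(0.3, 0.3, 0.05)
  means <- effects_to_means(study_effects)
  sigma2 <- 1.7
  theta <- e_step(bc, g, means, sigma2)
  expect_equal(unname(rowSums(theta)), rep(1, 15), tolerance = 1e-12)
  cond <- conditional_qtl_given_marker(g)
  midx <- match(bc$marker, gamete_labels("M"))
  for (i in seq_len(nrow(bc))) {
    expect_equal(unname(theta[i, ]),
                 oracle_posterior_row(cond[midx[i], ], bc$phenotype[i],
                                      means, sigma2),
                 tolerance = 1e-12)
  }
  # zero prior entries yield exactly zero responsibilities
  expect_true(all(theta[cbind(seq_len(15), midx)] > 0))
  expect_identical(unname(theta[cond[midx, ] == 0]),
                   rep(0, sum(cond[midx, ] == 0)))
  # equal component means: posterior equals the prior row
  theta_flat <- e_step(bc, g, rep(1, 10), sigma2)
  expect_equal(unname(theta_flat), unname(cond[midx, ]), tolerance = 1e-12)
})

test_that("M-step updates match brute-force oracles on random instances", {
  for (seed in c(3, 9, 27)) {
    bc <- random_small_bc(20, seed = seed)
    midx <- match(bc$marker, gamete_labels("M"))
    set.seed(seed + 1)
    theta <- matrix(stats::rexp(200), 20, 10)
    theta <- theta / rowSums(theta)
    ghat <- m_step_g(bc, theta)
    expect_equal(ghat, oracle_m_step_g(midx, theta), tolerance = 1e-12)
    expect_equal(sum(ghat), 1, tolerance = 1e-12)
    means <- m_step_means(bc, theta)
    expect_equal(unname(means), oracle_weighted_means(bc$phenotype, theta),
                 tolerance = 1e-12)
    v <- m_step_variance(bc, theta, unname(means))
    expect_equal(v, oracle_weighted_variance(bc$phenotype, theta,
                                             unname(means)),
                 tolerance = 1e-12)
  }
  # hard posteriors give per-group sample means
  bc <- random_small_bc(30, seed = 5)
  midx <- match(bc$marker, gamete_labels("M"))
  hard <- matrix(0, 30, 10)
  hard[cbind(1:30, midx)] <- 1
  mh <- m_step_means(bc, hard)
  for (j in unique(midx)) {
    expect_equal(mh[[j]], mean(bc$phenotype[midx == j]))
  }
  # equal responsibilities: every mean is the grand mean
  flat <- matrix(0.1, 30, 10)
  expect_equal(unname(m_step_means(bc, flat)), rep(mean(bc$phenotype), 10))
})

test_that("rate summaries follow the mode-frequency functionals", {
  expect_equal(unname(m_step_rates(c(1, 0, 0, 0, 0, 0, 0, 0, 0))),
               c(1, 1, 0))
  g <- construct_g(0.15, 0.15, 0.25)
  expect_equal(unname(m_step_rates(g)), c(0.15, 0.15, 0.25),
               tolerance = 1e-8)
  # one-step variant evaluates the corrections at the previous iterate
  r1 <- m_step_rates(g, r_prev = 0.25, r_update = "onestep")[["r"]]
  expect_equal(r1, 0.25, tolerance = 1e-8)
})

test_that("mixture log-likelihood matches brute force and scales additively", {
  bc <- random_small_bc(12, seed = 8)
  g <- construct_g(0.3, 0.3, 0.1)
  means <- effects_to_means(study_effects)
  ll <- tetra_loglik(bc, g, means, 2)
  cond <- conditional_qtl_given_marker(g)
  midx <- match(bc$marker, gamete_labels("M"))
  expect_equal(ll, oracle_loglik(bc$phenotype, midx, cond, means, 2),
               tolerance = 1e-10)
  # doubling every individual doubles the log-likelihood
  bc2 <- rbind(bc, bc)
  class(bc2) <- class(bc)
  expect_equal(tetra_loglik(bc2, g, means, 2), 2 * ll, tolerance = 1e-10)
  # a point-mass prior reduces to a single normal density
  bc1 <- bc[1, , drop = FALSE]
  class(bc1) <- class(bc)
  bc1$marker <- "M1M1"
  ll1 <- tetra_loglik(bc1, c(1, 0, 0, 0, 0, 0, 0, 0, 0), means, 2)
  expect_equal(ll1, stats::dnorm(bc1$phenotype, means[1], sqrt(2), log = TRUE))
})

test_that("EM recovers parameters exactly in the near-complete-data limit", {
  # distinct genotype means and tiny noise: the posterior reveals the QTL
  # genotype, so the EM must agree with the closed-form complete-data fit
  eff <- means_to_effects(seq(1, 10))
  cfg <- sim_config(n = 500, alpha = 0.3, r = 0.05, effects = eff,
                    sigma2 = 1e-4, seed = 5)
  bc <- simulate_dataset(cfg)
  fit <- tetra_fit(bc, tetra_em_control(n_starts = 1, seed = 1))
  midx <- match(bc$marker, gamete_labels("M"))
  qidx <- match(bc$qtl_true, gamete_labels("Q"))
  g_complete <- tabulate(mode_layout()$mode[cbind(midx, qidx)], 9) / nrow(bc)
  expect_equal(unname(fit$g_hat), g_complete, tolerance = 1e-6)
  expect_equal(fit$r_hat, implied_r(g_complete), tolerance = 1e-6)
  expect_equal(fit$alpha_hat, mean(midx <= 4), tolerance = 1e-12)
  for (j in 1:10) {
    expect_equal(fit$means_hat[[j]], mean(bc$phenotype[qidx == j]),
                 tolerance = 1e-3)
  }
  expect_true(fit$converged)
})

test_that("log-likelihood is monotone and the marker-DR identity holds", {
  cfg <- sim_config(n = 150, alpha = 0.3, r = 0.05, h2 = 0.4, seed = 23)
  bc <- simulate_dataset(cfg)
  fit <- tetra_fit(bc, tetra_em_control(seed = 2))
  expect_true(all(diff(fit$ll_trace) > -1e-9))
  dr_frac <- mean(match(bc$marker, gamete_labels("M")) <= 4)
  # the marker double-reduction estimate equals the observed fraction after
  # every M step, not just at convergence
  expect_true(all(abs(fit$alpha_trace - dr_frac) < 1e-12))
  expect_equal(fit$alpha_hat, dr_frac, tolerance = 1e-12)
  # plain (non-accelerated) EM satisfies the same invariants
  fitp <- tetra_fit(bc, tetra_em_control(n_starts = 1, accelerate = FALSE,
                                         max_iter = 400, tol = 1e-6))
  expect_true(all(diff(fitp$ll_trace) > -1e-9))
  expect_true(all(abs(fitp$alpha_trace - dr_frac) < 1e-12))
})

test_that("no-double-reduction mode drops DR markers and pins DR modes to 0", {
  cfg <- sim_config(n = 200, alpha = 0.3, r = 0.05, h2 = 0.4, seed = 29)
  bc <- simulate_dataset(cfg)
  expect_warning(
    fit <- tetra_fit(bc, tetra_em_control(n_starts = 1, seed = 1,
                                          force_no_double_reduction = TRUE)),
    "zero prior mass")
  expect_identical(unname(fit$g_hat[1:6]), rep(0, 6))
  expect_equal(fit$alpha_hat, 0)
  expect_equal(fit$beta_hat, 0)
  expect_identical(fit$n_dropped,
                   sum(match(bc$marker, gamete_labels("M")) <= 4))
})

test_that("constrained fits stay in the constraint space and nest", {
  cfg <- sim_config(n = 150, alpha = 0.3, r = 0.1, h2 = 0.4, seed = 37)
  bc <- simulate_dataset(cfg)
  ctl <- tetra_em_control(n_starts = 1, seed = 1)
  fit <- tetra_fit(bc, ctl)
  add <- tetra_fit_constrained(bc, constraint_design("additive_null"), ctl,
                               start_from = fit)
  expect_equal(add$means_hat[[1]], add$means_hat[[2]], tolerance = 1e-9)
  expect_equal(add$means_hat[[1]], add$means_hat[[4]], tolerance = 1e-9)
  expect_lte(add$loglik_cond, fit$loglik_cond + 1e-6)
  dom <- tetra_fit_constrained(bc, constraint_design("dominance_null"), ctl,
                               start_from = fit)
  expect_equal(unname(dom$effects_hat[5:10]), rep(0, 6), tolerance = 1e-8)
  expect_lte(dom$loglik_cond, fit$loglik_cond + 1e-6)
  # the saturated design reproduces the unconstrained fit
  sat <- tetra_fit_constrained(bc, constraint_design("saturated"), ctl,
                               start_from = fit)
  expect_equal(sat$loglik_cond, fit$loglik_cond, tolerance = 1e-6)
  expect_equal(unname(sat$means_hat), unname(fit$means_hat), tolerance = 1e-4)
})
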