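# Independent oracles for the gamete-mode model and the EM updates.
# The mode table below is transcribed by hand, row by row, from the joint
# frequency table of the quadrivalent gamete classification (rows = marker
# gametes, columns = QTL gametes, canonical order 11,22,33,44,12,13,14,23,
# 24,34). It is deliberately independent of the package's rule-based layout
# builder.
oracle_mode_table <- matrix(as.integer(c(
  1, 2, 2, 2, 5, 5, 5, 6, 6, 6,   # M1M1
  2, 1, 2, 2, 5, 6, 6, 5, 5, 6,   # M2M2
  2, 2, 1, 2, 6, 5, 6, 5, 6, 5,   # M3M3
  2, 2, 2, 1, 6, 6, 5, 6, 5, 5,   # M4M4
  3, 3, 4, 4, 7, 8, 8, 8, 8, 9,   # M1M2
  3, 4, 3, 4, 8, 7, 8, 8, 9, 8,   # M1M3
  3, 4, 4, 3, 8, 8, 7, 9, 8, 8,   # M1M4
  4, 3, 3, 4, 8, 8, 9, 7, 8, 8,   # M2M3
  4, 3, 4, 3, 8, 9, 8, 8, 7, 8,   # M2M4
  4, 4, 3, 3, 9, 8, 8, 8, 8, 7    # M3M4
)), nrow = 10, byrow = TRUE)

# within-mode coefficients: 1/4 (mode 1), 1/12 (modes 2-6), 1/6 (7, 9),
# 1/24 (8)
oracle_mode_coef <- c(1 / 4, rep(1 / 12, 5), 1 / 6, 1 / 24, 1 / 6)

oracle_joint_table <- function(g) {
  matrix(oracle_mode_coef[oracle_mode_table] * g[oracle_mode_table], 10, 10)
}

# per-cell expected recombination counts: 0 (mode 1), 2 (2,4,6,9),
# 1 (3,5), 2*phi (7), 1+psi (8)
oracle_recomb_counts <- function(r) {
  phi <- r^2 / (10 * r^2 - 18 * r + 9)
  psi <- r / (3 - 2 * r)
  cnt <- c(0, 2, 1, 2, 1, 2, 2 * phi, 1 + psi, 2)
  matrix(cnt[oracle_mode_table], 10, 10)
}

# direct Bayes-rule posterior for one individual
oracle_posterior_row <- function(prior_row, y, means, sigma2) {
  w <- unname(prior_row) * stats::dnorm(y, unname(means), sqrt(sigma2))
  w / sum(w)
}

# brute-force accumulation of mode masses over the explicit 100-cell layout
oracle_m_step_g <- function(midx, posteriors) {
  acc <- numeric(9)
  for (i in seq_along(midx)) {
    for (j in 1:10) {
      h <- oracle_mode_table[midx[i], j]
      acc[h] <- acc[h] + posteriors[i, j]
    }
  }
  acc / length(midx)
}

oracle_weighted_means <- function(y, posteriors) {
  vapply(1:10, function(j) sum(posteriors[, j] * y) / sum(posteriors[, j]), 0)
}

oracle_weighted_variance <- function(y, posteriors, means) {
  tot <- 0
  for (i in seq_along(y)) {
    tot <- tot + sum(posteriors[i, ] * (y[i] - means)^2)
  }
  tot / length(y)
}

# brute-force mixture log-likelihood
oracle_loglik <- function(y, midx, cond, means, sigma2) {
  sum(vapply(seq_along(y), function(i) {
    log(sum(cond[midx[i], ] * stats::dnorm(y[i], means, sqrt(sigma2))))
  }, 0))
}

# small random dataset with a valid tetra_bc shape
random_small_bc <- function(n, seed) {
  set.seed(seed)
  midx <- sample.int(10L, n, replace = TRUE)
  structure(
    data.frame(id = seq_len(n),
               marker = gamete_labels("M")[midx],
               phenotype = stats::rnorm(n, 1, 1.5),
               stringsAsFactors = FALSE),
    class = c("tetra_bc", "data.frame"))
}

study_effects <- c(mu = 1, a1 = 0.6, a2 = 0.6, a3 = 0.6,
                   d12 = 0.5, d13 = 0.5, d14 = 0.5,
                   d23 = 0.5, d24 = 0.5, d34 = 0.5)
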