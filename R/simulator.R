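# Simulation of pseudo-testcross datasets under tetrasomic co-inheritance.
#
# The scientific parameters are (alpha, beta, r): double-reduction
# frequencies at the marker and QTL and the marker-QTL recombination
# fraction. The estimator works on the nine observable mode frequencies g,
# of which (alpha, beta, r) are functionals, so the simulator needs a forward
# map (alpha, beta, r) -> g. Fisher's mechanism-level frequencies are not
# used; instead the mass of the four double-reduction classes and the
# within-class splits over recombinant counts are driven by one latent
# linkage parameter rho in [0, 1]:
#   * the both-loci-DR mass interpolates from min(alpha, beta) at rho = 0
#     (tight linkage: a DR event at one locus drags the other along) to
#     alpha * beta at rho = 1 (independent DR at unlinked loci); the
#     single-locus-DR and no-DR classes take the remaining mass consistent
#     with the alpha and beta marginals;
#   * within each class, mass is split over member modes by recombinant
#     count with binomial(2, rho) weights (the single-DR classes contain
#     only 1- and 2-recombinant modes, so their weights reduce to the ratio
#     2(1 - rho) : rho).
# rho is solved by 1-D root finding so the implied recombination fraction of
# the resulting g equals the target r. The coupling of class mass to rho is
# required for feasibility: with independent class masses the single-DR
# classes (whose modes all carry at least one recombination event) would
# bound r away from 0, contradicting tightly linked configurations such as
# alpha = beta = 0.3 with r = 0.05. The map is exact with respect to
# everything the estimator identifies (alpha, beta, r and the cell structure
# of the joint table).

# g as a function of the latent linkage parameter rho
.tq_g_of_rho <- function(alpha, beta, rho) {
  m_max <- min(alpha, beta)
  w_both <- m_max + (alpha * beta - m_max) * rho
  w_qtl  <- beta - w_both    # modes g3 (1 rec), g4 (2 rec)
  w_mrk  <- alpha - w_both   # modes g5 (1 rec), g6 (2 rec)
  w_none <- 1 - alpha - beta + w_both
  # both-DR class: members with 0 (g1) and 2 (g2) recombinants
  s12 <- (1 - rho)^2 + rho^2
  g1 <- w_both * (1 - rho)^2 / s12
  g2 <- w_both * rho^2 / s12
  # single-DR classes: members with 1 and 2 recombinants; binomial weights
  # 2*rho*(1-rho) : rho^2 reduce to 2*(1-rho) : rho (well defined at rho = 0)
  s34 <- 2 * (1 - rho) + rho
  g3 <- w_qtl * 2 * (1 - rho) / s34
  g4 <- w_qtl * rho / s34
  g5 <- w_mrk * 2 * (1 - rho) / s34
  g6 <- w_mrk * rho / s34
  # no-DR class: full binomial over 0/1/2-recombinant members g7/g8/g9
  g7 <- w_none * (1 - rho)^2
  g8 <- w_none * 2 * rho * (1 - rho)
  g9 <- w_none * rho^2
  c(g1, g2, g3, g4, g5, g6, g7, g8, g9)
}

# implied r extended to the whole admissible range (may exceed 0.5); the
# constructor brackets over it
.tq_implied_r_ext <- function(g) {
  base <- g[3] + g[5] + 2 * (g[2] + g[4] + g[6] + g[9])
  f <- function(r) r - 0.5 * (base + 2 * .tq_phi(r) * g[7] + (1 + .tq_psi(r)) * g[8])
  if (f(0) >= 0) return(0)
  # beyond the representable range (2-recombinant mass too large): return a
  # continuous monotone surrogate > 1, used only for bracketing
  if (f(1) <= 0) return(1 - f(1))
  stats::uniroot(f, c(0, 1), tol = 1e-12)$root
}

#' Construct a mode-frequency vector with given (alpha, beta, r)
#'
#' Inverts the parameter map: returns a valid mode-frequency vector `g` whose
#' marker and QTL double-reduction frequencies equal `alpha` and `beta` and
#' whose implied recombination fraction ([implied_r()]) equals `r`. The four
#' double-reduction classes receive independent mass; within each class, mass
#' is split over member modes by recombinant count using binomial weights in a
#' latent parameter `rho`, solved by 1-D root finding.
#'
#' The both-loci class mass is itself coupled to `rho`, interpolating from
#' `min(alpha, beta)` under tight linkage to `alpha * beta` under
#' independence, so that tightly linked loci share their double-reduction
#' events. Not every `r` is attainable: when `alpha != beta`, at least
#' `|alpha - beta|` of mass must sit in a single-locus double-reduction
#' class, whose modes all carry at least one recombination event, so the
#' implied recombination fraction is bounded away from 0. An error reporting
#' the feasible range is raised for unattainable targets.
#'
#' @param alpha Marker double-reduction frequency in `[0, 1]`.
#' @param beta QTL double-reduction frequency in `[0, 1]`.
#' @param r Target recombination fraction in `[0, 0.5]`.
#' @return Numeric vector of 9 mode frequencies with
#'   `modes_to_params(g) = (alpha, beta, r)`.
#' @examples
#' g <- construct_g(0.3, 0.3, 0.05)
#' modes_to_params(g)
#' @export
construct_g <- function(alpha, beta, r) {
  stopifnot(length(alpha) == 1L, length(beta) == 1L, length(r) == 1L,
            is.finite(alpha), is.finite(beta), is.finite(r))
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1) {
    stop("'alpha' and 'beta' must be probabilities in [0, 1]", call. = FALSE)
  }
  .tq_check_r(r)
  h <- function(rho) .tq_implied_r_ext(.tq_g_of_rho(alpha, beta, rho))
  r_min <- h(0)
  r_max <- h(1)
  tol <- 1e-10
  if (r < r_min - tol || r > min(r_max, 0.5) + tol) {
    stop(sprintf(paste0("recombination fraction %.4g is not attainable for ",
                        "alpha = %.4g, beta = %.4g; feasible range is ",
                        "[%.4g, %.4g]"),
                 r, alpha, beta, r_min, min(r_max, 0.5)), call. = FALSE)
  }
  if (r <= r_min) {
    rho <- 0
  } else {
    rho <- stats::uniroot(function(rho) h(rho) - r, c(0, 1), tol = 1e-13)$root
  }
  g <- .tq_g_of_rho(alpha, beta, rho)
  g / sum(g)
}

#' Genetic variance of the QTL genotypic values
#'
#' Variance of the 10 genotypic values under the QTL gamete frequencies
#' implied by the QTL double-reduction frequency `beta` (`beta/4` for each
#' double-reduction genotype, `(1 - beta)/6` for each heterozygous genotype).
#'
#' @param effects Numeric vector of 10 effects (see [effects_to_means()]).
#' @param beta QTL double-reduction frequency in `[0, 1]`.
#' @return The genetic variance, in squared trait units.
#' @export
genetic_variance <- function(effects, beta) {
  if (beta < 0 || beta > 1) {
    stop("'beta' must be a probability in [0, 1]", call. = FALSE)
  }
  means <- effects_to_means(effects)
  p <- c(rep(beta / 4, 4L), rep((1 - beta) / 6, 6L))
  m <- sum(p * means)
  sum(p * (means - m)^2)
}

#' Residual variance from heritability
#'
#' Solves `H2 = sigma_g2 / (sigma_g2 + sigma2)` for the residual variance:
#' `sigma2 = sigma_g2 * (1 - H2) / H2`.
#'
#' @param sigma_g2 Genetic variance (squared trait units).
#' @param h2 Heritability, strictly inside `(0, 1)`.
#' @return Residual variance in squared trait units.
#' @export
error_variance <- function(sigma_g2, h2) {
  if (!is.numeric(h2) || length(h2) != 1L || is.na(h2) || h2 <= 0 || h2 >= 1) {
    stop("'h2' must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (sigma_g2 < 0) stop("'sigma_g2' must be nonnegative", call. = FALSE)
  if (sigma_g2 == 0) {
    warning("genetic variance is 0: the trait is degenerate", call. = FALSE)
  }
  sigma_g2 * (1 - h2) / h2
}

#' Simulation configuration
#'
#' Bundles the parameters of one simulated pseudo-testcross study: sample
#' size, double-reduction frequencies at the marker and QTL, marker-QTL
#' recombination fraction, QTL effects, heritability, seed and replicate
#' count. The residual variance is derived from the heritability against the
#' genetic variance at the simulated `beta` (see [genetic_variance()]);
#' `sigma2` may instead be given directly (e.g. `sigma2 = 0` for a noiseless
#' trait), in which case `h2` is ignored.
#'
#' @param n Number of pseudo-testcross individuals (at least 10).
#' @param alpha Marker double-reduction frequency.
#' @param beta QTL double-reduction frequency; defaults to `alpha` (the same
#'   degree of double reduction at both loci).
#' @param r Recombination fraction in `[0, 0.5]`.
#' @param effects QTL effects vector (default: overall mean 1, additive
#'   effects 0.6, dominance effects 0.5).
#' @param h2 Heritability in `(0, 1)`.
#' @param sigma2 Optional residual variance overriding `h2`.
#' @param seed Integer RNG seed, or `NULL`.
#' @param reps Replicate count for [replicate_study()].
#' @return An object of class `"tetra_sim_config"`.
#' @export
sim_config <- function(n = 400, alpha = 0.3, beta = alpha, r = 0.05,
                       effects = c(mu = 1, a1 = 0.6, a2 = 0.6, a3 = 0.6,
                                   d12 = 0.5, d13 = 0.5, d14 = 0.5,
                                   d23 = 0.5, d24 = 0.5, d34 = 0.5),
                       h2 = 0.4, sigma2 = NULL, seed = NULL, reps = 1000L) {
  stopifnot(n >= 10, reps >= 1)
  effects <- .tq_check_effects(effects)
  if (is.null(sigma2)) {
    sigma2 <- error_variance(genetic_variance(effects, beta), h2)
  } else {
    stopifnot(sigma2 >= 0)
  }
  structure(list(n = as.integer(n), alpha = alpha, beta = beta, r = r,
                 effects = effects, h2 = h2, sigma2 = sigma2,
                 seed = if (!is.null(seed)) as.integer(seed),
                 reps = as.integer(reps)),
            class = "tetra_sim_config")
}

#' @export
print.tetra_sim_config <- function(x, ...) {
  cat("Pseudo-testcross simulation configuration\n")
  cat(sprintf("  n = %d, alpha = %.3g, beta = %.3g, r = %.3g\n",
              x$n, x$alpha, x$beta, x$r))
  cat(sprintf("  h2 = %.3g (residual variance %.4g), reps = %d, seed = %s\n",
              x$h2, x$sigma2, x$reps,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Simulate a pseudo-testcross dataset
#'
#' Draws `n` (marker gamete, QTL gamete) pairs from the joint frequency table
#' implied by `(alpha, beta, r)` and generates phenotypes as the QTL genotypic
#' value plus normal residual noise. The latent QTL genotype is retained for
#' oracle checks. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A data frame of class `"tetra_bc"` with columns `id`, `marker`
#'   (e.g. `"M1M3"`), `qtl_true` (e.g. `"Q2Q2"`) and `phenotype`; attributes
#'   `config` and `g_true` record the generating parameters.
#' @examples
#' bc <- simulate_dataset(sim_config(n = 50, alpha = 0.3, r = 0.05,
#'                                   h2 = 0.4, seed = 1))
#' head(bc)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "tetra_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  g <- construct_g(config$alpha, config$beta, config$r)
  joint <- build_joint_table(g)
  means <- effects_to_means(config$effects)
  idx <- sample.int(100L, config$n, replace = TRUE, prob = as.vector(joint))
  marker <- (idx - 1L) %% 10L + 1L
  qtl <- (idx - 1L) %/% 10L + 1L
  y <- means[qtl] + stats::rnorm(config$n, 0, sqrt(config$sigma2))
  out <- data.frame(
    id = seq_len(config$n),
    marker = gamete_labels("M")[marker],
    qtl_true = gamete_labels("Q")[qtl],
    phenotype = as.numeric(y),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("tetra_bc", "data.frame"),
            config = config, g_true = g)
}

# integer gamete indices for a tetra_bc marker column
.tq_marker_index <- function(data) {
  m <- match(data$marker, gamete_labels("M"))
  if (anyNA(m)) {
    stop("unknown marker genotypes: ",
         paste(unique(data$marker[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  m
}

#' Replicated simulation study
#'
#' Runs `config$reps` independent simulate-and-fit replicates and summarises
#' the maximum-likelihood estimates. Per-replicate seeds are derived
#' deterministically from `config$seed`; fit failures are recorded per
#' replicate and never abort the study.
#'
#' @param config A [sim_config()] object (its `reps` and `seed` fields drive
#'   the study).
#' @param control EM options from [tetra_em_control()].
#' @param align_labels If `TRUE`, allele labels of each fitted mean vector are
#'   aligned to the generating values by the best of the 24 allele
#'   permutations before effects are summarised; the number of replicates
#'   changed by alignment is reported.
#' @return An object of class `"tetra_repstudy"`: a list with `estimates`
#'   (data frame of per-replicate estimates and convergence flags), `config`,
#'   and `n_aligned`. See [summary.tetra_repstudy()].
#' @export
replicate_study <- function(config, control = tetra_em_control(),
                            align_labels = FALSE) {
  stopifnot(inherits(config, "tetra_sim_config"), config$reps >= 2)
  master <- if (is.null(config$seed)) 0L else config$seed
  true_means <- effects_to_means(config$effects)
  perms <- if (align_labels) .tq_allele_perms() else NULL
  rows <- vector("list", config$reps)
  n_aligned <- 0L
  for (b in seq_len(config$reps)) {
    seed_b <- (master %% 1000003L) * 2011L + b  # < 2^31 always
    cfg_b <- config
    cfg_b$seed <- as.integer(seed_b)
    cfg_b$reps <- 1L
    dat <- simulate_dataset(cfg_b)
    ctl <- control
    ctl$seed <- as.integer(seed_b + 1L)
    fit <- tryCatch(tetra_fit(dat, ctl), error = function(e) NULL)
    if (is.null(fit)) {
      rows[[b]] <- NULL
      next
    }
    means <- fit$means_hat
    if (align_labels) {
      aligned <- .tq_align_means(means, true_means, perms)
      if (aligned$changed) n_aligned <- n_aligned + 1L
      means <- aligned$means
    }
    eff <- means_to_effects(means)
    rows[[b]] <- data.frame(
      rep = b, failed = FALSE, converged = fit$converged,
      n_iter = fit$n_iter,
      alpha = fit$alpha_hat, beta = fit$beta_hat, r = fit$r_hat,
      sigma2 = fit$sigma2_hat, loglik = fit$loglik,
      as.list(eff)
    )
  }
  ok_rows <- !vapply(rows, is.null, TRUE)
  if (!any(ok_rows)) stop("every replicate fit failed", call. = FALSE)
  estimates <- do.call(rbind, rows[ok_rows])
  if (any(!ok_rows)) {
    pad <- estimates[rep(1L, sum(!ok_rows)), ]
    pad[] <- NA
    pad$rep <- which(!ok_rows)
    pad$failed <- TRUE
    pad$converged <- FALSE
    estimates <- rbind(estimates, pad)
    estimates <- estimates[order(estimates$rep), ]
  }
  rownames(estimates) <- NULL
  structure(list(estimates = estimates, config = config,
                 n_aligned = if (align_labels) n_aligned else NA_integer_,
                 align_labels = align_labels),
            class = "tetra_repstudy")
}

# all 24 permutations of the 4 allele labels, as reorderings of the 10
# canonical genotype indices
.tq_allele_perms <- function() {
  perms4 <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms4 <- perms4[apply(perms4, 1L, function(p) length(unique(p)) == 4L), ]
  key <- paste(.tq_pairs[, 1L], .tq_pairs[, 2L])
  lapply(seq_len(nrow(perms4)), function(i) {
    p <- perms4[i, ]
    newpair <- cbind(pmin(p[.tq_pairs[, 1L]], p[.tq_pairs[, 2L]]),
                     pmax(p[.tq_pairs[, 1L]], p[.tq_pairs[, 2L]]))
    match(paste(newpair[, 1L], newpair[, 2L]), key)
  })
}

.tq_align_means <- function(means, true_means, perms) {
  sse <- vapply(perms, function(pm) {
    permuted <- means
    permuted[pm] <- means
    sum((permuted - true_means)^2)
  }, 0)
  best <- which.min(sse)
  pm <- perms[[best]]
  out <- means
  out[pm] <- means
  list(means = stats::setNames(out, names(means)),
       changed = !identical(pm, 1:10))
}

#' Summarise a replicated simulation study
#'
#' Monte-Carlo means and standard deviations of each estimate over the
#' converged replicates, alongside the generating values.
#'
#' @param object A [replicate_study()] result.
#' @param ... Unused.
#' @return A data frame with rows `truth`, `mean`, `sd`, columns
#'   `alpha, beta, r, mu, a1..a3, d12..d34, sigma2`; attributes
#'   `n_converged`, `n_failed`, `reps`.
#' @export
summary.tetra_repstudy <- function(object, ...) {
  est <- object$estimates
  ok <- !is.na(est$converged) & est$converged
  cols <- c("alpha", "beta", "r", .tq_effect_names, "sigma2")
  truth <- c(object$config$alpha, object$config$beta, object$config$r,
             object$config$effects, object$config$sigma2)
  m <- vapply(cols, function(cn) mean(est[[cn]][ok]), 0)
  s <- vapply(cols, function(cn) stats::sd(est[[cn]][ok]), 0)
  out <- rbind(truth = truth, mean = m, sd = s)
  colnames(out) <- cols
  out <- as.data.frame(out)
  attr(out, "n_converged") <- sum(ok)
  attr(out, "n_failed") <- sum(is.na(est$converged) | (!est$converged))
  attr(out, "reps") <- nrow(est)
  out
}

#' @export
print.tetra_repstudy <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Replicated simulation study: %d replicates (%d converged)\n",
              attr(s, "reps"), attr(s, "n_converged")))
  print(round(as.matrix(s), 4))
  if (isTRUE(x$align_labels)) {
    cat("label alignment changed", x$n_aligned, "replicate(s)\n")
  }
  invisible(x)
}
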