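# EM estimation for the marker-QTL normal mixture under tetrasomic
# inheritance. The free parameters are the nine observable gamete-mode
# frequencies g (a multinomial over the 100 joint cells, tied within modes),
# the 10 QTL genotype means and the residual variance. (alpha, beta, r) are
# derived functionals of g. EM ascends the joint log-likelihood of the
# observed marker genotypes and phenotypes:
#   l(g, mu, sigma2) = sum_i log( sum_j P_g(marker_i, QTL_j) N(y_i; mu_j, sigma2) )
# The E step computes posterior QTL-genotype responsibilities given each
# individual's marker; the M steps are closed-form (mode counts, weighted
# means, weighted mean squared error), with the recombination fraction
# recovered from g by an inner 1-D solve at each iteration.

#' EM fitting options
#'
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence threshold on the change in joint log-likelihood.
#' @param n_starts Number of starting points: starts 1-3 combine
#'   marker-anchored means (each genotype mean initialised from the
#'   phenotypes of individuals carrying the same-labelled marker) with
#'   initial recombination fractions 0.25, 0.05 and 0.45; start 4 uses a
#'   prior-weighted phenotype-quantile spread of the means; further starts
#'   are random jitters of the anchored means.
#' @param variance_floor Lower bound for the residual variance, as a fraction
#'   of the phenotypic variance; prevents component collapse.
#' @param force_no_double_reduction If `TRUE`, fit the "traditional" model
#'   that ignores double reduction: all g-mass restricted to the three
#'   non-double-reduction modes. Individuals carrying double-reduction marker
#'   genotypes then have zero prior mass and are dropped with a warning.
#' @param accelerate Use SQUAREM-type extrapolation between EM sweeps
#'   (monotonicity-safeguarded); `FALSE` runs plain EM.
#' @param fix_r Optional fixed recombination value. The mixture likelihood is
#'   parameterised by the mode frequencies, of which `r` is a derived
#'   functional, so fixing `r` does not constrain the fit; the reported
#'   `r_hat` is overridden (diagnostic use).
#' @param r_update `"solve"` (default): recover `r` from the mode frequencies
#'   by the inner root solve at every M step; `"onestep"`: evaluate the
#'   phi/psi corrections at the previous iterate instead.
#' @param seed Integer seed for the random restarts, or `NULL`.
#' @return A list of class `"tetra_em_control"`.
#' @export
tetra_em_control <- function(max_iter = 5000L, tol = 1e-8, n_starts = 4L,
                             variance_floor = 1e-8,
                             force_no_double_reduction = FALSE,
                             accelerate = TRUE,
                             fix_r = NULL, r_update = c("solve", "onestep"),
                             seed = NULL) {
  stopifnot(max_iter >= 1, tol > 0, n_starts >= 1, variance_floor > 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 n_starts = as.integer(n_starts),
                 variance_floor = variance_floor,
                 force_no_double_reduction = isTRUE(force_no_double_reduction),
                 accelerate = isTRUE(accelerate),
                 fix_r = fix_r, r_update = match.arg(r_update),
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "tetra_em_control")
}

# run a block of code under a temporary RNG state
.tq_with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Mixture log-likelihood of a pseudo-testcross dataset
#'
#' The marker-conditional mixture log-likelihood: for each individual, the log
#' of the prior-weighted sum of normal densities over the ten QTL genotypes,
#' with prior weights the conditional QTL distribution given that
#' individual's marker genotype.
#'
#' @param data A `tetra_bc` data frame (see [simulate_dataset()] /
#'   [read_backcross()]).
#' @param g Mode-frequency vector.
#' @param means The 10 genotype means, canonical order.
#' @param sigma2 Residual variance (> 0).
#' @return The log-likelihood (a scalar).
#' @export
tetra_loglik <- function(data, g, means, sigma2) {
  stopifnot(sigma2 > 0)
  midx <- .tq_marker_index(data)
  cond <- conditional_qtl_given_marker(g)
  bad <- attr(cond, "undefined_rows")
  if (length(bad) && any(midx %in% bad)) {
    stop("data contain marker genotypes with zero marginal frequency under 'g'",
         call. = FALSE)
  }
  A <- .tq_logmix(data$phenotype, midx, log(cond), means, sigma2)
  sum(A$ll)
}

# log-space E quantities: per-individual log mixture density and
# responsibilities. logcond is the 10x10 log conditional table.
.tq_logmix <- function(y, midx, logcond, means, sigma2) {
  n <- length(y)
  dev2 <- (matrix(y, n, 10L) - matrix(means, n, 10L, byrow = TRUE))^2
  logf <- -0.5 * (log(2 * pi * sigma2) + dev2 / sigma2)
  A <- logcond[midx, , drop = FALSE] + logf
  mx <- A[cbind(seq_len(n), max.col(A, ties.method = "first"))]
  if (any(!is.finite(mx))) {
    stop("zero mixture density for some individuals (variance underflow); ",
         "raise 'variance_floor'", call. = FALSE)
  }
  W <- exp(A - mx)
  rs <- rowSums(W)
  list(ll = mx + log(rs), theta = W / rs, dev2 = dev2)
}

#' E step: posterior QTL-genotype responsibilities
#'
#' Bayes responsibilities of each of the 10 QTL genotypes for every
#' individual, combining the marker-conditional prior row with the normal
#' phenotype density. Computed in log space.
#'
#' @inheritParams tetra_loglik
#' @return n x 10 matrix with rows summing to 1; entries are zero wherever
#'   the prior conditional is zero.
#' @export
e_step <- function(data, g, means, sigma2) {
  stopifnot(sigma2 > 0)
  midx <- .tq_marker_index(data)
  cond <- conditional_qtl_given_marker(g)
  bad <- attr(cond, "undefined_rows")
  if (length(bad) && any(midx %in% bad)) {
    stop("data contain marker genotypes with zero marginal frequency under 'g'",
         call. = FALSE)
  }
  .tq_logmix(data$phenotype, midx, log(cond), means, sigma2)$theta
}

#' M step: gamete-mode frequencies
#'
#' The expected proportion of individuals in each observable gamete mode:
#' each (marker, QTL) cell of the joint table belongs to exactly one mode, so
#' the update sums, over individuals and QTL genotypes, the posterior
#' responsibility falling in each mode's cells and divides by n.
#'
#' @param data A `tetra_bc` data frame.
#' @param posteriors n x 10 responsibility matrix from [e_step()].
#' @return Mode-frequency vector of length 9 summing to 1.
#' @export
m_step_g <- function(data, posteriors) {
  midx <- .tq_marker_index(data)
  .tq_m_step_g(midx, posteriors)
}

.tq_m_step_g <- function(midx, posteriors) {
  n <- length(midx)
  S <- matrix(0, 10L, 10L)
  agg <- rowsum(posteriors, group = midx)
  S[as.integer(rownames(agg)), ] <- agg
  vapply(.tq_layout$cells, function(ii) sum(S[ii]), 0) / n
}

#' M step: double-reduction frequencies and recombination fraction
#'
#' Derived parameter update: the marker double-reduction frequency is the
#' total updated mass of the marker-DR modes (and always equals the observed
#' fraction of double-reduction marker genotypes), the QTL double-reduction
#' frequency the mass of the QTL-DR modes, and the recombination fraction is
#' recovered from the mode frequencies by the inner root solve (or a one-step
#' evaluation of phi/psi at `r_prev`).
#'
#' @param g_hat Updated mode-frequency vector.
#' @param r_prev Previous recombination value (used by the one-step variant).
#' @param r_update `"solve"` or `"onestep"`.
#' @return Named vector `c(alpha, beta, r)`; `r` clamped to `[0, 0.5]` with a
#'   warning if the mode vector is inadmissible.
#' @export
m_step_rates <- function(g_hat, r_prev = 0.25,
                         r_update = c("solve", "onestep")) {
  r_update <- match.arg(r_update)
  alpha <- g_hat[1] + g_hat[2] + g_hat[5] + g_hat[6]
  beta <- g_hat[1] + g_hat[2] + g_hat[3] + g_hat[4]
  if (r_update == "solve") {
    r <- min(.tq_implied_r_ext(g_hat), 0.5)
  } else {
    r <- 0.5 * (g_hat[3] + g_hat[5] +
                  2 * (g_hat[2] + g_hat[4] + g_hat[6] + g_hat[9]) +
                  2 * .tq_phi(r_prev) * g_hat[7] +
                  (1 + .tq_psi(r_prev)) * g_hat[8])
    r <- min(max(r, 0), 0.5)
  }
  c(alpha = unname(alpha), beta = unname(beta), r = unname(r))
}

#' M step: genotype means
#'
#' Responsibility-weighted phenotype mean for each QTL genotype. Genotypes
#' with (numerically) zero total responsibility keep their previous value and
#' are flagged via the `"held"` attribute.
#'
#' @inheritParams m_step_g
#' @param prev Previous means (fallback for empty genotypes).
#' @return Numeric vector of 10 genotype means.
#' @export
m_step_means <- function(data, posteriors, prev = NULL) {
  y <- data$phenotype
  den <- colSums(posteriors)
  num <- colSums(posteriors * y)
  out <- num / den
  empty <- den < 1e-12
  if (any(empty)) {
    out[empty] <- if (is.null(prev)) mean(y) else prev[empty]
    attr(out, "held") <- which(empty)
  }
  stats::setNames(out, gamete_labels("Q"))
}

#' M step: residual variance
#'
#' Responsibility-weighted mean squared deviation of phenotypes from their
#' genotype means, floored at `floor_value` to prevent component collapse.
#'
#' @inheritParams m_step_means
#' @param means Current genotype means.
#' @param floor_value Lower bound for the returned variance.
#' @return The updated residual variance.
#' @export
m_step_variance <- function(data, posteriors, means, floor_value = 0) {
  y <- data$phenotype
  dev2 <- outer(y, means, `-`)^2
  v <- sum(posteriors * dev2) / length(y)
  max(v, floor_value)
}

# weighted least-squares mean update under a linear constraint design:
# minimise sum_ij Theta_ij (y_i - (X theta)_j)^2
.tq_m_step_means_constrained <- function(y, posteriors, X, prev = NULL) {
  w <- colSums(posteriors)            # per-genotype total responsibility
  cvec <- colSums(posteriors * y)     # per-genotype weighted phenotype sum
  XtWX <- crossprod(X, X * w)
  if (rcond(XtWX) < 1e-12) {
    stop("weighted constraint design is rank deficient", call. = FALSE)
  }
  theta <- solve(XtWX, crossprod(X, cvec))
  stats::setNames(drop(X %*% theta), gamete_labels("Q"))
}

# starting points for the EM. The recombination fraction is weakly
# identified through the mode frequencies, so starts vary the initial r over
# a coarse grid as well as the initial means: starts 1-3 use marker-anchored
# means (each genotype mean taken from the phenotypes of individuals whose
# marker carries the same allele pair) with r0 = 0.25, 0.05, 0.45; start 4
# uses a prior-weighted phenotype-quantile spread; further starts jitter the
# anchored means at random.
.tq_start_r0 <- c(0.25, 0.05, 0.45)

.tq_start_means <- function(y, midx, start, qtl_marginal, sd_y) {
  anchored <- vapply(1:10, function(j) {
    yj <- y[midx == j]
    if (length(yj)) mean(yj) else mean(y)
  }, 0)
  if (start <= 3L) {
    anchored
  } else if (start == 4L) {
    # prior-weighted quantile spread: genotype j sits at the midpoint of its
    # prior mass along the phenotype distribution
    p <- qtl_marginal / sum(qtl_marginal)
    mid <- cumsum(p) - p / 2
    as.numeric(stats::quantile(y, probs = mid, names = FALSE, type = 7))
  } else {
    anchored + stats::rnorm(10L, 0, sd_y / 2)
  }
}

# single EM run from one start; returns fit list.
#
# Plain EM on this mixture can need thousands of iterations because the
# likelihood is nearly flat along a ridge in the mode frequencies, so the
# iteration is wrapped in a SQUAREM-type extrapolation (Varadhan & Roland's
# squared iterative scheme): after two base EM steps the parameter vector is
# extrapolated along the secant directions, projected back onto the valid
# region, and stabilised with one further EM step. An extrapolated cycle is
# accepted only when its log-likelihood does not fall below the plain
# two-step EM value, so the recorded log-likelihood trace stays monotone.
.tq_em_run <- function(y, midx, g0, means0, sigma20, control, design = NULL) {
  n <- length(y)
  floor_value <- control$variance_floor * max(stats::var(y), .Machine$double.eps)
  state <- new.env(parent = emptyenv())
  state$floored <- FALSE
  state$held <- FALSE
  state$rates <- m_step_rates(g0, r_update = "solve")
  state$alpha_trace <- numeric(0)

  pack <- function(g, means, sigma2) c(g, means, sigma2)
  project <- function(p) {
    g <- pmax(p[1:9], 0)
    if (control$force_no_double_reduction) g[1:6] <- 0
    s <- sum(g)
    g <- if (s > 0) g / s else c(rep(0, 6), 1 / 3, 1 / 3, 1 / 3)
    c(g, p[10:19], max(p[20], floor_value))
  }

  # one EM iteration; returns updated parameters and the joint log-likelihood
  # at the *input* parameters
  em_step <- function(p, trace_alpha = FALSE) {
    g <- p[1:9]
    means <- p[10:19]
    sigma2 <- p[20]
    joint <- build_joint_table(g)
    marg <- rowSums(joint)
    logcond <- log(joint) - log(marg)[row(joint)]
    em <- .tq_logmix(y, midx, logcond, means, sigma2)
    ll <- sum(em$ll) + sum(log(marg[midx]))
    theta <- em$theta
    g_new <- .tq_m_step_g(midx, theta)
    if (control$force_no_double_reduction) {
      g_new[1:6] <- 0
      s <- sum(g_new[7:9])
      if (s > 0) g_new[7:9] <- g_new[7:9] / s
    }
    if (trace_alpha) {
      state$alpha_trace <- c(state$alpha_trace,
                             g_new[1] + g_new[2] + g_new[5] + g_new[6])
    }
    if (is.null(design)) {
      means_new <- m_step_means(list(phenotype = y), theta, prev = means)
      if (!is.null(attr(means_new, "held"))) state$held <- TRUE
    } else {
      means_new <- .tq_m_step_means_constrained(y, theta, design, prev = means)
    }
    v <- m_step_variance(list(phenotype = y), theta, means_new, floor_value)
    if (v <= floor_value) state$floored <- TRUE
    list(par = pack(g_new, as.numeric(means_new), v), ll = ll)
  }

  p <- project(pack(g0, means0, max(sigma20, floor_value)))
  ll_trace <- numeric(0)
  ll_mark <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    s1 <- em_step(p, trace_alpha = TRUE)
    p1 <- s1$par
    if (!control$accelerate) {
      iter <- iter + 1L
      ll_new <- s1$ll
      p <- p1
      ll_trace <- c(ll_trace, ll_new)
      if (is.finite(ll_mark) && abs(ll_new - ll_mark) < control$tol) {
        converged <- TRUE
        break
      }
      if (iter >= control$max_iter) break
      ll_mark <- ll_new
      next
    }
    s2 <- em_step(p1, trace_alpha = TRUE)
    p2 <- s2$par
    iter <- iter + 2L
    ll_new <- s2$ll  # = ll(p1) >= ll(p)
    rr <- p1 - p
    v2 <- (p2 - p1) - rr
    nv <- sqrt(sum(v2^2))
    if (nv > 1e-14) {
      a <- -sqrt(sum(rr^2)) / nv
      if (a > -1) a <- -1
      pe <- project(p - 2 * a * rr + a^2 * v2)
      s3 <- em_step(pe, trace_alpha = TRUE)
      iter <- iter + 1L
      if (s3$ll >= ll_new) {  # accept extrapolated cycle
        p <- s3$par
        ll_new <- s3$ll
      } else {
        p <- p2
      }
    } else {
      p <- p2
    }
    ll_trace <- c(ll_trace, ll_new)
    if (is.finite(ll_mark) && abs(ll_new - ll_mark) < control$tol) {
      converged <- TRUE
      break
    }
    if (iter >= control$max_iter) break
    ll_mark <- ll_new
  }
  g <- p[1:9]
  means <- p[10:19]
  sigma2 <- p[20]
  rates <- m_step_rates(g, r_prev = state$rates[["r"]],
                        r_update = control$r_update)
  # final log-likelihoods at the returned parameter values
  joint <- build_joint_table(g)
  marg <- rowSums(joint)
  logcond <- log(joint) - log(marg)[row(joint)]
  em <- .tq_logmix(y, midx, logcond, means, sigma2)
  ll_cond <- sum(em$ll)
  ll_joint <- ll_cond + sum(log(marg[midx]))
  list(g = g, means = means, sigma2 = sigma2, rates = rates,
       loglik = ll_joint, loglik_cond = ll_cond, n_iter = iter,
       converged = converged, ll_trace = ll_trace,
       alpha_trace = state$alpha_trace, floored = state$floored,
       held_any = state$held)
}

.tq_prepare_fit <- function(data, control) {
  midx <- .tq_marker_index(data)
  y <- data$phenotype
  dropped <- 0L
  if (control$force_no_double_reduction) {
    dr <- midx <= 4L
    if (any(dr)) {
      warning(sum(dr), " individual(s) carry double-reduction marker ",
              "genotypes, which have zero prior mass under the ",
              "no-double-reduction model; they are excluded from the fit",
              call. = FALSE)
      y <- y[!dr]
      midx <- midx[!dr]
      dropped <- sum(dr)
    }
  }
  if (length(y) < 2L) stop("too few usable individuals", call. = FALSE)
  list(y = y, midx = midx, dropped = dropped)
}

.tq_fit_engine <- function(data, control, design = NULL, start_params = NULL) {
  prep <- .tq_prepare_fit(data, control)
  y <- prep$y
  midx <- prep$midx
  alpha0 <- mean(midx <= 4L)
  if (control$force_no_double_reduction) alpha0 <- 0
  g0_of_r <- function(r0) {
    tryCatch(construct_g(alpha0, alpha0, r0),
             error = function(e) construct_g(alpha0, alpha0, 0.25))
  }
  g0 <- g0_of_r(0.25)
  qtl_marginal <- colSums(build_joint_table(g0))
  sd_y <- stats::sd(y)
  sigma20 <- stats::var(y) / 2
  best <- NULL
  .tq_with_seed(control$seed, {
    for (s in seq_len(control$n_starts)) {
      if (!is.null(start_params) && s == 1L) {
        g_s <- start_params$g
        means_s <- start_params$means
        sig_s <- start_params$sigma2
      } else {
        g_s <- if (s <= 3L) g0_of_r(.tq_start_r0[s]) else g0
        means_s <- .tq_start_means(y, midx, s, qtl_marginal, sd_y)
        sig_s <- sigma20
      }
      run <- .tq_em_run(y, midx, g_s, means_s, sig_s, control, design = design)
      run$start_used <- s
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
  })
  best$dropped <- prep$dropped
  best
}

.tq_as_fit_result <- function(run, control, constraint = NULL) {
  rates <- run$rates
  r_hat <- if (!is.null(control$fix_r)) control$fix_r else rates[["r"]]
  means <- stats::setNames(run$means, gamete_labels("Q"))
  structure(list(
    g_hat = stats::setNames(run$g, paste0("g", 1:9)),
    alpha_hat = rates[["alpha"]], beta_hat = rates[["beta"]], r_hat = r_hat,
    means_hat = means, effects_hat = means_to_effects(means),
    sigma2_hat = run$sigma2,
    loglik = run$loglik, loglik_cond = run$loglik_cond,
    n_iter = run$n_iter, converged = run$converged,
    start_used = run$start_used, ll_trace = run$ll_trace,
    alpha_trace = run$alpha_trace,
    variance_floored = run$floored, means_held = run$held_any,
    n_dropped = run$dropped,
    constraint = if (!is.null(constraint)) constraint$kind,
    control = control
  ), class = "tetra_fit")
}

#' Fit the marker-QTL mixture model by EM
#'
#' Maximum-likelihood estimation of the gamete-mode frequencies (hence the
#' marker and QTL double-reduction frequencies and the recombination
#' fraction), the 10 QTL genotype means (hence the additive and dominance
#' effects) and the residual variance, by EM on the marker-conditional normal
#' mixture. Multiple starting points guard against local optima; the best
#' final likelihood wins.
#'
#' @param data A `tetra_bc` data frame with columns `marker` and `phenotype`
#'   (see [simulate_dataset()] and [read_backcross()]).
#' @param control Options from [tetra_em_control()].
#' @return An object of class `"tetra_fit"` with elements `g_hat`,
#'   `alpha_hat`, `beta_hat`, `r_hat`, `means_hat`, `effects_hat`,
#'   `sigma2_hat`, `loglik` (joint marker+phenotype), `loglik_cond`
#'   (marker-conditional mixture), `n_iter`, `converged`, `ll_trace`,
#'   `alpha_trace` and convergence diagnostics.
#' @examples
#' bc <- simulate_dataset(sim_config(n = 100, alpha = 0.3, r = 0.05,
#'                                   h2 = 0.4, seed = 7))
#' fit <- tetra_fit(bc, tetra_em_control(n_starts = 1, seed = 1))
#' fit$alpha_hat
#' @export
tetra_fit <- function(data, control = tetra_em_control()) {
  run <- .tq_fit_engine(data, control)
  .tq_as_fit_result(run, control)
}

#' Fit the mixture model under a linear genotype-mean constraint
#'
#' Identical EM except that the genotype-mean update solves a
#' responsibility-weighted least-squares problem over the constraint's linear
#' design (so the fitted means always lie in the constrained subspace). Used
#' for the null models of the likelihood-ratio tests.
#'
#' @inheritParams tetra_fit
#' @param constraint A [constraint_design()] object.
#' @param start_from Optional `tetra_fit` result; its fitted parameters
#'   (means projected onto the constraint space) seed the first start, which
#'   keeps null fits nested within the full fit.
#' @return A `"tetra_fit"` object; the `constraint` element records the kind.
#' @export
tetra_fit_constrained <- function(data, constraint,
                                  control = tetra_em_control(),
                                  start_from = NULL) {
  stopifnot(inherits(constraint, "tetra_constraint"))
  X <- constraint$design
  start_params <- NULL
  if (!is.null(start_from)) {
    proj <- X %*% qr.solve(X, start_from$means_hat)
    start_params <- list(g = unname(start_from$g_hat),
                         means = drop(proj),
                         sigma2 = start_from$sigma2_hat)
  }
  run <- .tq_fit_engine(data, control, design = X, start_params = start_params)
  .tq_as_fit_result(run, control, constraint = constraint)
}

#' @export
print.tetra_fit <- function(x, digits = 4, ...) {
  cat("Tetrasomic marker-QTL mixture fit",
      if (!is.null(x$constraint)) paste0("(constrained: ", x$constraint, ")"),
      "\n")
  cat(sprintf("  alpha = %.*f  beta = %.*f  r = %.*f  sigma2 = %.*f\n",
              digits, x$alpha_hat, digits, x$beta_hat,
              digits, x$r_hat, digits, x$sigma2_hat))
  cat("  effects:\n")
  print(round(x$effects_hat, digits))
  cat(sprintf("  loglik = %.4f (%d iterations, %s)\n", x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  if (x$n_dropped > 0) cat("  ", x$n_dropped, "individuals dropped\n")
  invisible(x)
}
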