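# Likelihood-ratio tests for QTL presence and for additive/dominance effects.
# The presence test compares the full mixture fit against a single-normal
# null (all genotype means equal); because the mixture violates the
# regularity conditions for a chi-square reference, its threshold is the
# empirical quantile of statistics from datasets with phenotypes permuted
# against markers. Effect sub-tests compare the full fit against constrained
# EM fits; no finite-sample reference distribution is established for
# these, so a chi-square with df = number of constraints is used by default
# (a documented convention), with a permutation option.

.tq_lr_stat <- function(ll1, ll0) {
  stat <- 2 * (ll1 - ll0)
  if (stat < 0) {
    if (stat < -1e-6) {
      warning("negative LR statistic (", format(stat),
              ") clamped to 0; optimization noise exceeded tolerance",
              call. = FALSE)
    }
    stat <- 0
  }
  stat
}

.tq_permute_data <- function(data) {
  data$phenotype <- sample(data$phenotype)
  data
}

#' Likelihood-ratio test for QTL presence
#'
#' Tests the null of no segregating QTL (all nine additive and dominance
#' effects zero, i.e. one common mean) against the full mixture model. The
#' null maximum likelihood has closed form (sample mean and maximum-likelihood
#' variance of the phenotypes). The critical threshold is the empirical
#' `1 - level` quantile of statistics recomputed on datasets whose phenotypes
#' are reshuffled against the marker genotypes, taken as the order statistic
#' of rank `ceiling((1 - level) * (n_perm + 1))` so the test is exactly
#' calibrated under exchangeability; the reported p-value is
#' `(1 + #permutations >= observed) / (n_perm + 1)`. Permuted-data fits reuse
#' the data-driven initialisation with a single start (pass a control with
#' `n_starts = 1` if exact observed/permuted symmetry is wanted).
#'
#' @param data A `tetra_bc` data frame.
#' @param control EM options for the full fit ([tetra_em_control()]).
#' @param n_perm Number of permutations (at least 20).
#' @param level Significance level for the threshold.
#' @param seed Integer seed for the permutations, or `NULL`.
#' @param keep_perms Keep the per-permutation statistics in the result.
#' @return An object of class `"tetra_test"` with elements `statistic`,
#'   `threshold`, `reject`, `n_perm`, `level`, `fit` (the full fit) and
#'   optionally `perm_stats`.
#' @export
lr_presence <- function(data, control = tetra_em_control(), n_perm = 1000L,
                        level = 0.05, seed = NULL, keep_perms = TRUE) {
  if (n_perm < 20L) {
    stop("'n_perm' must be at least 20 for a meaningful quantile", call. = FALSE)
  }
  fit1 <- tetra_fit(data, control)
  stat <- .tq_lr_stat(fit1$loglik_cond, .tq_null_normal_loglik(data$phenotype))
  perm_control <- control
  perm_control$n_starts <- 1L
  perm_stats <- numeric(n_perm)
  .tq_with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pd <- .tq_permute_data(data)
      pfit <- tetra_fit(pd, perm_control)
      perm_stats[b] <- .tq_lr_stat(pfit$loglik_cond,
                                   .tq_null_normal_loglik(pd$phenotype))
    }
  })
  k <- min(ceiling((1 - level) * (n_perm + 1)), n_perm)
  threshold <- sort(perm_stats)[k]
  p <- (1 + sum(perm_stats >= stat)) / (n_perm + 1)
  structure(list(test = "presence", statistic = stat, threshold = threshold,
                 reject = stat > threshold, n_perm = n_perm, level = level,
                 df = 9L, p_value = p,
                 perm_stats = if (keep_perms) perm_stats, fit = fit1),
            class = "tetra_test")
}

# closed-form single-normal null log-likelihood (MLE mean and variance)
.tq_null_normal_loglik <- function(y) {
  n <- length(y)
  v <- mean((y - mean(y))^2)
  sum(stats::dnorm(y, mean(y), sqrt(v), log = TRUE))
}

.tq_lr_constrained <- function(data, constraint, control, n_perm, level,
                               seed, test_name) {
  fit1 <- tetra_fit(data, control)
  fit0 <- tetra_fit_constrained(data, constraint, control, start_from = fit1)
  stat <- .tq_lr_stat(fit1$loglik_cond, fit0$loglik_cond)
  df <- constraint$df
  if (is.null(n_perm)) {
    threshold <- stats::qchisq(1 - level, df)
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    perm_stats <- NULL
    n_perm_out <- 0L
  } else {
    if (n_perm < 20L) {
      stop("'n_perm' must be at least 20 for a meaningful quantile",
           call. = FALSE)
    }
    perm_control <- control
    perm_control$n_starts <- 1L
    perm_stats <- numeric(n_perm)
    .tq_with_seed(seed, {
      for (b in seq_len(n_perm)) {
        pd <- .tq_permute_data(data)
        p1 <- tetra_fit(pd, perm_control)
        p0 <- tetra_fit_constrained(pd, constraint, perm_control,
                                    start_from = p1)
        perm_stats[b] <- .tq_lr_stat(p1$loglik_cond, p0$loglik_cond)
      }
    })
    k <- min(ceiling((1 - level) * (n_perm + 1)), n_perm)
    threshold <- sort(perm_stats)[k]
    p <- (1 + sum(perm_stats >= stat)) / (n_perm + 1)
    n_perm_out <- n_perm
  }
  structure(list(test = test_name, statistic = stat, threshold = threshold,
                 reject = stat > threshold, n_perm = n_perm_out,
                 level = level, df = df, p_value = p,
                 perm_stats = perm_stats, fit = fit1, null_fit = fit0),
            class = "tetra_test")
}

#' Likelihood-ratio test for additive QTL effects
#'
#' Tests `a1 = a2 = a3 = 0` (all four homozygote genotypic values equal)
#' against the full model, via a constrained EM fit. By default the statistic
#' is referred to a chi-square with 3 degrees of freedom; set `n_perm` for a
#' permutation threshold instead.
#'
#' @inheritParams lr_presence
#' @param n_perm `NULL` for the chi-square reference (default), or a
#'   permutation count (at least 20).
#' @return A `"tetra_test"` object (see [lr_presence()]); `null_fit` holds
#'   the constrained fit.
#' @export
lr_additive <- function(data, control = tetra_em_control(), n_perm = NULL,
                        level = 0.05, seed = NULL) {
  .tq_lr_constrained(data, constraint_design("additive_null"), control,
                     n_perm, level, seed, "additive")
}

#' Likelihood-ratio test for dominance QTL effects
#'
#' Tests `d12 = d13 = d14 = d23 = d24 = d34 = 0` (heterozygote genotypic
#' values equal their additive predictions) against the full model.
#' Chi-square with 6 degrees of freedom by default; permutation optional.
#'
#' @inheritParams lr_additive
#' @return A `"tetra_test"` object.
#' @export
lr_dominance <- function(data, control = tetra_em_control(), n_perm = NULL,
                         level = 0.05, seed = NULL) {
  .tq_lr_constrained(data, constraint_design("dominance_null"), control,
                     n_perm, level, seed, "dominance")
}

#' Likelihood-ratio test for a single genetic effect
#'
#' Pins one named additive or dominance effect to zero and compares the
#' constrained fit against the full model (1 degree of freedom by default).
#'
#' @inheritParams lr_additive
#' @param which_effect Effect to test: one of `"a1"`, `"a2"`, `"a3"`,
#'   `"d12"`, `"d13"`, `"d14"`, `"d23"`, `"d24"`, `"d34"`.
#' @return A `"tetra_test"` object.
#' @export
lr_single_effect <- function(data, which_effect,
                             control = tetra_em_control(), n_perm = NULL,
                             level = 0.05, seed = NULL) {
  .tq_lr_constrained(data,
                     constraint_design("single_effect",
                                       which_effect = which_effect),
                     control, n_perm, level, seed,
                     paste0("single:", which_effect))
}

#' @export
print.tetra_test <- function(x, digits = 4, ...) {
  cat("Likelihood-ratio test:", x$test, "\n")
  cat(sprintf("  LR = %.*f, threshold = %.*f (%s), %s at level %.3g\n",
              digits, x$statistic, digits, x$threshold,
              if (x$n_perm > 0) paste0(x$n_perm, " permutations")
              else paste0("chi-square df = ", x$df),
              if (x$reject) "REJECT null" else "do not reject null",
              x$level))
  cat(sprintf("  p-value: %.4g\n", x$p_value))
  invisible(x)
}
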