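# Quantitative-genetic parameterization of the 10 QTL genotypic values.
# With QTL alleles Q1..Q4, the genotypic value of genotype QjQk is
#   mu_jj = mu + a_j                    (j = 1..3),   mu_44 = mu - a1 - a2 - a3
#   mu_jk = mu + a_j + a_k + d_jk       (with a_4 = -a1 - a2 - a3)
# giving 10 parameters (mu, a1..a3, d12, d13, d14, d23, d24, d34) in
# one-to-one linear correspondence with the 10 genotype means.

.tq_effect_names <- c("mu", "a1", "a2", "a3",
                      "d12", "d13", "d14", "d23", "d24", "d34")

# 10 x 10 design matrix mapping (mu, a1..a3, d12..d34) -> genotype means,
# rows in canonical genotype order (11,22,33,44,12,13,14,23,24,34)
.tq_build_effect_design <- function() {
  X <- matrix(0, 10L, 10L,
              dimnames = list(gamete_labels("Q"), .tq_effect_names))
  a <- function(k) {  # contribution of allele k to (a1, a2, a3)
    if (k < 4L) {
      v <- numeric(3); v[k] <- 1; v
    } else {
      c(-1, -1, -1)
    }
  }
  for (idx in 1:10) {
    j <- .tq_pairs[idx, 1L]
    k <- .tq_pairs[idx, 2L]
    X[idx, 1L] <- 1
    if (j == k) {
      X[idx, 2:4] <- a(j)
    } else {
      X[idx, 2:4] <- a(j) + a(k)
      X[idx, paste0("d", j, k)] <- 1
    }
  }
  X
}

.tq_effect_design <- .tq_build_effect_design()
.tq_effect_design_inv <- solve(.tq_effect_design)

#' Design matrix from QTL effects to genotype means
#'
#' The invertible 10 x 10 linear map from the effect parameterization
#' `(mu, a1, a2, a3, d12, d13, d14, d23, d24, d34)` to the 10 genotypic values
#' in canonical genotype order. The additive effect of allele Q4 is implicitly
#' `-a1 - a2 - a3`.
#'
#' @return 10 x 10 numeric matrix with genotype row names and effect column
#'   names.
#' @export
effect_design <- function() .tq_effect_design

.tq_check_effects <- function(effects) {
  if (is.list(effects)) effects <- unlist(effects)
  if (length(effects) != 10L || anyNA(effects) || !is.numeric(effects)) {
    stop("'effects' must be 10 finite values (mu, a1..a3, d12..d34)",
         call. = FALSE)
  }
  if (!is.null(names(effects)) && all(.tq_effect_names %in% names(effects))) {
    effects <- effects[.tq_effect_names]
  }
  stats::setNames(as.numeric(effects), .tq_effect_names)
}

#' Convert QTL effects to genotype means
#'
#' @param effects Numeric vector of 10 effects in the order
#'   `(mu, a1, a2, a3, d12, d13, d14, d23, d24, d34)` (names, if present, are
#'   honoured).
#' @return Named numeric vector of the 10 genotypic values in canonical
#'   genotype order.
#' @examples
#' effects_to_means(c(mu = 1, a1 = 0.6, a2 = 0.6, a3 = 0.6,
#'                    d12 = 0.5, d13 = 0.5, d14 = 0.5,
#'                    d23 = 0.5, d24 = 0.5, d34 = 0.5))
#' @export
effects_to_means <- function(effects) {
  effects <- .tq_check_effects(effects)
  drop(.tq_effect_design %*% effects)
}

#' Convert genotype means to QTL effects
#'
#' Exact inverse of [effects_to_means()] (the effect design matrix is
#' invertible, so the two maps are mutual inverses for arbitrary real input).
#' The overall mean is the average of the four homozygote values; additive
#' effects are contrasts of homozygote values; each dominance effect is the
#' deviation of a heterozygote mean from its additive prediction.
#'
#' @param means Numeric vector of the 10 genotypic values in canonical
#'   genotype order.
#' @return Named numeric vector of 10 effects.
#' @export
means_to_effects <- function(means) {
  if (length(means) != 10L || anyNA(means) || !is.numeric(means)) {
    stop("'means' must be 10 finite genotypic values", call. = FALSE)
  }
  drop(.tq_effect_design_inv %*% as.numeric(means))
}

#' Linear constraint systems for null-hypothesis fits
#'
#' Builds the design matrix from free parameters to the 10 genotype means for
#' a constrained (null-hypothesis) model:
#' \describe{
#'   \item{`additive_null`}{`a1 = a2 = a3 = 0`, equivalently all four
#'     homozygote means equal; 7 free parameters (the common homozygote value
#'     plus the six heterozygote means).}
#'   \item{`dominance_null`}{all six dominance effects zero; heterozygote
#'     means are their additive predictions; 4 free parameters
#'     `(mu, a1, a2, a3)`.}
#'   \item{`single_effect`}{one named effect pinned to zero; 9 free
#'     parameters (the effect design with that column dropped).}
#'   \item{`intercept_only`}{all genotype means equal (no QTL); 1 free
#'     parameter.}
#'   \item{`saturated`}{the full 10-parameter effect design (no constraint);
#'     a constrained fit with this design reproduces the unconstrained fit.}
#' }
#'
#' @param kind Constraint kind (see above).
#' @param which_effect For `single_effect`: name of the effect to pin, one of
#'   `"a1"`, `"a2"`, `"a3"`, `"d12"`, `"d13"`, `"d14"`, `"d23"`, `"d24"`,
#'   `"d34"`.
#' @return An object of class `"tetra_constraint"`: a list with elements
#'   `kind`, `design` (10 x p full-column-rank matrix) and `df` (number of
#'   constraints, i.e. `10 - p`).
#' @export
constraint_design <- function(kind = c("additive_null", "dominance_null",
                                       "single_effect", "intercept_only",
                                       "saturated"),
                              which_effect = NULL) {
  kind <- match.arg(kind)
  X <- switch(kind,
    additive_null = {
      D <- matrix(0, 10L, 7L,
                  dimnames = list(gamete_labels("Q"),
                                  c("hom", gamete_labels("Q")[5:10])))
      D[1:4, 1L] <- 1
      D[cbind(5:10, 2:7)] <- 1
      D
    },
    dominance_null = .tq_effect_design[, 1:4],
    single_effect = {
      if (is.null(which_effect) ||
          !which_effect %in% .tq_effect_names[-1L]) {
        stop("'which_effect' must be one of: ",
             paste(.tq_effect_names[-1L], collapse = ", "), call. = FALSE)
      }
      .tq_effect_design[, setdiff(.tq_effect_names, which_effect)]
    },
    intercept_only = matrix(1, 10L, 1L,
                            dimnames = list(gamete_labels("Q"), "mu")),
    saturated = .tq_effect_design
  )
  structure(list(kind = kind, design = X, df = 10L - ncol(X),
                 which_effect = which_effect),
            class = "tetra_constraint")
}

#' @export
print.tetra_constraint <- function(x, ...) {
  cat("Genotype-mean constraint:", x$kind,
      if (!is.null(x$which_effect)) paste0("(", x$which_effect, " = 0)"), "\n")
  cat("  free parameters:", ncol(x$design), " constraints:", x$df, "\n")
  invisible(x)
}
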