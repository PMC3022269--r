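# Fisher's observable gamete-mode model for a quadrivalent (multivalent)
# tetraploid. A heterozygous parent with marker alleles M1..M4 and QTL alleles
# Q1..Q4 produces 10 observable diploid gametes per locus; the 100 two-locus
# gamete genotypes fall into 9 observable formation modes g1..g9 classified by
# the double-reduction pattern (marker, QTL, both, neither) and the number of
# recombination events.

# Canonical unordered allele pairs, in fixed order. The first four are the
# double-reduction (DR) gametes.
.tq_pairs <- cbind(
  first  = c(1L, 2L, 3L, 4L, 1L, 1L, 1L, 2L, 2L, 3L),
  second = c(1L, 2L, 3L, 4L, 2L, 3L, 4L, 3L, 4L, 4L)
)

#' Canonical gamete labels
#'
#' The 10 unordered allele-pair gametes of a tetrasomic locus, in the canonical
#' order `(11, 22, 33, 44, 12, 13, 14, 23, 24, 34)`. The first four are
#' double-reduction gametes (two copies of one parental allele in the same
#' gamete); the last six arise from ordinary chromosome pairing.
#'
#' @param prefix Single-character allele prefix, e.g. `"M"` for marker gametes
#'   or `"Q"` for QTL gametes.
#' @return Character vector of length 10, e.g. `"M1M1", ..., "M3M4"`.
#' @examples
#' gamete_labels("Q")
#' @export
gamete_labels <- function(prefix = "M") {
  paste0(prefix, .tq_pairs[, 1L], prefix, .tq_pairs[, 2L])
}

#' Is a gamete a double-reduction gamete?
#'
#' @param index Integer vector of canonical gamete indices (1..10).
#' @return Logical vector; `TRUE` for the four homozygous (double-reduction)
#'   gametes.
#' @export
is_double_reduction <- function(index) {
  stopifnot(all(index %in% 1:10))
  index <= 4L
}

# Mode of one (marker gamete, QTL gamete) cell, per the structure of the joint
# frequency table:
#   both DR:   same allele -> g1 (0 rec), different -> g2 (2 rec)
#   QTL DR only (marker het): QTL allele in marker pair -> g3 (1), else g4 (2)
#   marker DR only (QTL het): marker allele in QTL pair -> g5 (1), else g6 (2)
#   neither DR: same pair -> g7, share one allele -> g8, disjoint -> g9
.tq_cell_mode <- function(l, j) {
  lp <- .tq_pairs[l, ]
  jp <- .tq_pairs[j, ]
  ldr <- l <= 4L
  jdr <- j <= 4L
  if (ldr && jdr) {
    if (lp[1L] == jp[1L]) 1L else 2L
  } else if (!ldr && jdr) {
    if (jp[1L] %in% lp) 3L else 4L
  } else if (ldr && !jdr) {
    if (lp[1L] %in% jp) 5L else 6L
  } else {
    shared <- length(intersect(lp, jp))
    c(9L, 8L, 7L)[shared + 1L]
  }
}

#' Gamete-mode layout of the joint marker-QTL table
#'
#' Static layout of the 100 (marker gamete, QTL gamete) cells: which of the
#' nine observable modes each cell belongs to, and the within-mode coefficient
#' (each mode's frequency is split uniformly over its cells, so the coefficient
#' is 1/4 for mode 1, 1/12 for modes 2-6, 1/6 for modes 7 and 9, and 1/24 for
#' mode 8).
#'
#' @return A list with components
#'   \describe{
#'     \item{mode}{10 x 10 integer matrix; `mode[l, j]` is the mode index
#'       (1..9) of marker gamete `l` and QTL gamete `j`.}
#'     \item{coef}{10 x 10 numeric matrix of within-mode coefficients.}
#'     \item{cells_per_mode}{integer vector of length 9: number of cells in
#'       each mode (`c(4, 12, 12, 12, 12, 12, 6, 24, 6)`).}
#'     \item{cells}{list of 9 integer vectors: linear (column-major) indices of
#'       the cells of each mode.}
#'   }
#' @export
mode_layout <- function() .tq_layout

.tq_build_layout <- function() {
  mode <- matrix(0L, 10L, 10L,
                 dimnames = list(gamete_labels("M"), gamete_labels("Q")))
  for (l in 1:10) {
    for (j in 1:10) {
      mode[l, j] <- .tq_cell_mode(l, j)
    }
  }
  m <- tabulate(mode, nbins = 9L)
  list(
    mode = mode,
    coef = matrix(1 / m[mode], 10L, 10L, dimnames = dimnames(mode)),
    cells_per_mode = m,
    cells = lapply(1:9, function(h) which(mode == h))
  )
}

.tq_layout <- .tq_build_layout()

.tq_check_g <- function(g, tol = 1e-8) {
  if (!is.numeric(g) || length(g) != 9L || anyNA(g)) {
    stop("'g' must be a numeric vector of 9 gamete-mode frequencies", call. = FALSE)
  }
  if (any(g < -tol)) {
    stop("gamete-mode frequencies must be nonnegative", call. = FALSE)
  }
  if (abs(sum(g) - 1) > tol) {
    stop("gamete-mode frequencies must sum to 1 (got ", format(sum(g)), ")",
         call. = FALSE)
  }
  pmax(g, 0)
}

.tq_check_r <- function(r) {
  if (!is.numeric(r) || anyNA(r) || any(r < 0) || any(r > 0.5)) {
    stop("recombination fraction must lie in [0, 0.5]", call. = FALSE)
  }
  r
}

#' Recombination-count corrections for mixed-configuration modes
#'
#' Two of the nine observable gamete modes (the same-pair and one-shared-allele
#' heterozygote x heterozygote modes) are each a mixture of two underlying
#' formation configurations carrying different numbers of recombination
#' events. Their expected recombination counts are `2 * phi(r)` and
#' `1 + psi(r)`, with
#' \deqn{\phi(r) = r^2 / (10 r^2 - 18 r + 9), \qquad \psi(r) = r / (3 - 2 r).}
#' Both vanish at r = 0 and increase monotonically on `[0, 0.5]`.
#'
#' @param r Recombination fraction(s) in `[0, 0.5]`.
#' @return Numeric vector of the same length as `r`.
#' @examples
#' phi_correction(c(0, 0.25, 0.5))
#' psi_correction(0.25)
#' @export
phi_correction <- function(r) {
  .tq_check_r(r)
  r^2 / (10 * r^2 - 18 * r + 9)
}

#' @rdname phi_correction
#' @export
psi_correction <- function(r) {
  .tq_check_r(r)
  r / (3 - 2 * r)
}

# unchecked versions, defined on [0, 1] (denominators positive there); used by
# the inner root solves which may probe r above 0.5 transiently
.tq_phi <- function(r) r^2 / (10 * r^2 - 18 * r + 9)
.tq_psi <- function(r) r / (3 - 2 * r)

#' Joint marker-QTL gamete frequency table
#'
#' Builds the 10 x 10 table of joint (marker gamete, QTL gamete) frequencies
#' from the nine observable mode frequencies: each cell equals its mode's
#' frequency times the within-mode coefficient (see [mode_layout()]). Rows are
#' marker gametes, columns QTL gametes, both in canonical order.
#'
#' @param g Numeric vector of 9 mode frequencies (nonnegative, summing to 1).
#' @return 10 x 10 numeric matrix summing to 1.
#' @examples
#' g <- c(1, 0, 0, 0, 0, 0, 0, 0, 0)
#' build_joint_table(g)["M1M1", "Q1Q1"]  # 1/4
#' @export
build_joint_table <- function(g) {
  g <- .tq_check_g(g)
  .tq_layout$coef * g[.tq_layout$mode]
}

#' Expected recombination-event counts per observable gamete genotype
#'
#' The 10 x 10 table of expected numbers of recombination events for each
#' observable (marker gamete, QTL gamete) genotype. Single-configuration modes
#' carry integer counts 0, 1 or 2; the two mixed-configuration heterozygote
#' modes carry the expected counts `2 * phi(r)` and `1 + psi(r)`
#' (see [phi_correction()]).
#'
#' @param r Recombination fraction in `[0, 0.5]`.
#' @return 10 x 10 numeric matrix with entries in `[0, 2]`.
#' @export
recomb_count_table <- function(r) {
  .tq_check_r(r)
  counts <- c(0, 2, 1, 2, 1, 2, 2 * phi_correction(r), 1 + psi_correction(r), 2)
  matrix(counts[.tq_layout$mode], 10L, 10L, dimnames = dimnames(.tq_layout$mode))
}


#' Marker gamete marginal frequencies
#'
#' Marginal frequency of each marker gamete given the marker double-reduction
#' frequency `alpha`: `alpha/4` for each of the four double-reduction gametes
#' and `(1 - alpha)/6` for each of the six heterozygous gametes.
#'
#' @param alpha Marker double-reduction frequency in `[0, 1]`.
#' @return Named numeric vector of length 10 summing to 1.
#' @export
marker_marginals <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("'alpha' must be a probability in [0, 1]", call. = FALSE)
  }
  stats::setNames(c(rep(alpha / 4, 4L), rep((1 - alpha) / 6, 6L)),
                  gamete_labels("M"))
}

#' Conditional QTL-gamete distribution given the marker gamete
#'
#' Each row is the conditional distribution of the QTL gamete given the marker
#' gamete: the joint cell frequency divided by the marker row marginal. Rows
#' whose marker marginal is zero are returned as `NA` and flagged.
#'
#' @param g Numeric vector of 9 mode frequencies.
#' @return 10 x 10 matrix; each defined row sums to 1. Attribute
#'   `"undefined_rows"` holds the indices of zero-marginal marker rows (if any).
#' @export
conditional_qtl_given_marker <- function(g) {
  joint <- build_joint_table(g)
  marg <- rowSums(joint)
  cond <- joint / marg
  bad <- unname(which(marg <= 0))
  if (length(bad)) {
    cond[bad, ] <- NA_real_
    attr(cond, "undefined_rows") <- bad
  }
  cond
}

#' Recombination fraction implied by a mode-frequency vector
#'
#' The recombination fraction is defined implicitly through the expected
#' recombination counts: `r` solves
#' \deqn{r = \tfrac12\left[g_3 + g_5 + 2 (g_2 + g_4 + g_6 + g_9)
#'   + 2\phi(r) g_7 + (1 + \psi(r)) g_8\right].}
#' The root is located by bisection (via [stats::uniroot()]) to tolerance
#' 1e-12. Vectors whose implied fixed point falls above 0.5 are inadmissible:
#' by default the value is clamped to 0.5 with a warning; with
#' `strict = TRUE` an error is raised instead.
#'
#' @param g Numeric vector of 9 mode frequencies.
#' @param strict Error (rather than clamp with warning) on inadmissible `g`.
#' @return The implied recombination fraction in `[0, 0.5]`.
#' @export
implied_r <- function(g, strict = FALSE) {
  g <- .tq_check_g(g)
  base <- g[3] + g[5] + 2 * (g[2] + g[4] + g[6] + g[9])
  f <- function(r) r - 0.5 * (base + 2 * .tq_phi(r) * g[7] + (1 + .tq_psi(r)) * g[8])
  # f(0) <= 0 and f(1) >= 0 always, so a root exists in [0, 1]
  if (f(0) >= 0) return(0)
  root <- stats::uniroot(f, c(0, 1), tol = 1e-12)$root
  if (root > 0.5 + 1e-9) {
    if (strict) {
      stop("mode-frequency vector is inadmissible: implied recombination ",
           "fraction ", format(root, digits = 4), " exceeds 0.5", call. = FALSE)
    }
    warning("mode-frequency vector implies r = ", format(root, digits = 4),
            " > 0.5; clamping to 0.5", call. = FALSE)
    return(0.5)
  }
  min(root, 0.5)
}

#' Map mode frequencies to (alpha, beta, r)
#'
#' Double-reduction frequencies and the recombination fraction as functionals
#' of the nine observable mode frequencies. Under the table convention
#' (default) the marker double-reduction frequency is the total mass of the
#' marker-DR rows, `alpha = g1 + g2 + g5 + g6`, and the QTL double-reduction
#' frequency is the total mass of the QTL-DR columns,
#' `beta = g1 + g2 + g3 + g4`; `convention = "printed"` swaps the two sums to
#' match an alternative published convention (for audit only). `r` is computed
#' by [implied_r()].
#'
#' @param g Numeric vector of 9 mode frequencies.
#' @param convention `"table"` (default) or `"printed"`.
#' @return Named numeric vector `c(alpha, beta, r)`.
#' @export
modes_to_params <- function(g, convention = c("table", "printed")) {
  convention <- match.arg(convention)
  g <- .tq_check_g(g)
  marker_dr <- g[1] + g[2] + g[5] + g[6]
  qtl_dr <- g[1] + g[2] + g[3] + g[4]
  r <- implied_r(g, strict = TRUE)
  if (convention == "table") {
    c(alpha = marker_dr, beta = qtl_dr, r = r)
  } else {
    c(alpha = qtl_dr, beta = marker_dr, r = r)
  }
}
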