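# Simplex machinery for 21-part isotope compositions: the first 20 aggregated
# isotope probabilities plus a closure term (pseudo-isotope) absorbing the
# leftover probability, the additive log-ratio (ALR) transform with the
# monoisotopic variant as reference, and its modified-softmax inverse.

# Floor for an exactly-zero (or float-negative) closure term: low-mass
# molecules are fully covered by 20 peaks, but the ALR of the closure must
# stay finite for the regression to be well-posed.
.CLOSURE_FLOOR <- 1e-30

#' Append the closure term to a truncated isotope distribution
#'
#' Turns the first `n_peaks` aggregated isotope probabilities into a true
#' composition by appending a pseudo-isotope that absorbs the probability not
#' covered by the listed peaks, then renormalising to unit sum. An exactly
#' zero (or negative, from float slop) leftover is floored at a tiny positive
#' constant so downstream log-ratios stay finite.
#'
#' @param q Numeric vector of the first `n_peaks` probabilities (default
#'   length 20), each in `[0, 1]`.
#' @param floor_eps Positive floor for the closure term.
#' @return Numeric vector of length `length(q) + 1` summing to 1.
#' @examples
#' x <- add_closure(isotope_distribution("C45H62N15O31P5", 20)$prob)
#' sum(x)
#' @export
add_closure <- function(q, floor_eps = .CLOSURE_FLOOR) {
  stopifnot(is.numeric(q), length(q) >= 1, floor_eps > 0)
  if (any(q < 0) || any(q > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(q)
  if (s > 1 + 1e-6) {
    stop("probabilities sum to more than 1 (", format(s), ")", call. = FALSE)
  }
  x <- c(q, max(1 - s, floor_eps))
  x / sum(x)
}

# Matrix variant: rows are molecules, 20 columns of probabilities in, 21 out.
.add_closure_matrix <- function(Q, floor_eps = .CLOSURE_FLOOR) {
  cl <- pmax(1 - rowSums(Q), floor_eps)
  X <- cbind(Q, cl, deparse.level = 0)
  X / rowSums(X)
}

#' Additive log-ratio transform
#'
#' Maps a D-part composition to D-1 real coordinates, `z[j] =
#' ln(x[j+1] / x[ref])`, with the monoisotopic variant (component 1) as the
#' fixed reference. With the 21-part isotope composition this yields the 20
#' ALR isotopes that the regression models.
#'
#' @param x Composition vector (nonnegative, summing to 1) or a matrix with
#'   compositions in rows.
#' @param reference_index Index of the reference component (default 1).
#' @return Vector of length `length(x) - 1` (or matrix with one fewer
#'   column).
#' @export
alr <- function(x, reference_index = 1L) {
  if (is.matrix(x)) {
    ref <- x[, reference_index]
    if (any(ref <= 0)) stop("reference component must be positive",
                            call. = FALSE)
    return(log(x[, -reference_index, drop = FALSE] / ref))
  }
  ref <- x[reference_index]
  if (is.na(ref) || ref <= 0) {
    stop("reference component must be positive", call. = FALSE)
  }
  log(x[-reference_index] / ref)
}

#' Modified softmax: inverse of the additive log-ratio transform
#'
#' Back-transforms ALR coordinates to the simplex with an implicit unit term
#' for the reference component: `x = (1, e^z1, ..., e^zd) / (1 + sum e^z)`,
#' so the output always sums to exactly 1. Exponentials are max-shifted
#' (algebraically identical) to avoid overflow.
#'
#' @param z Real vector of ALR coordinates, or a matrix with one row per
#'   observation.
#' @return Composition vector of length `length(z) + 1` (reference first), or
#'   the corresponding matrix.
#' @examples
#' inverse_alr(alr(c(0.5, 0.3, 0.2)))
#' @export
inverse_alr <- function(z) {
  if (is.matrix(z)) {
    m <- pmax(apply(z, 1L, max), 0)
    e <- cbind(exp(-m), exp(z - m), deparse.level = 0)
    return(e / rowSums(e))
  }
  stopifnot(all(is.finite(z)))
  m <- max(z, 0)
  e <- c(exp(-m), exp(z - m))
  e / sum(e)
}

#' ALR transform of an observed isotope envelope
#'
#' Log-ratios of observed peak intensities against the observed monoisotopic
#' intensity: `t[i] = ln(o[i+1] / o[1])`. Intensities are relative, so the
#' result is invariant to rescaling all peaks by a common factor. Requires
#' the monoisotopic peak; without it the log-ratio reference is undefined and
#' the intensity-space statistic must be used instead.
#'
#' @param intensities Observed intensities, ordered by isotope index.
#' @param indices Isotope indices (1 = monoisotopic) of the intensities;
#'   defaults to `1:length(intensities)`.
#' @return Tibble with columns `index` (the non-reference isotope indices)
#'   and `t` (observed log-ratios).
#' @export
observed_alr <- function(intensities, indices = seq_along(intensities)) {
  stopifnot(length(intensities) == length(indices))
  if (length(intensities) < 2L) {
    stop("need at least two observed peaks", call. = FALSE)
  }
  ref <- which(indices == 1L)
  if (length(ref) != 1L || !(intensities[ref] > 0)) {
    stop("reference unobserved: the monoisotopic peak (index 1) must be ",
         "present with positive intensity", call. = FALSE)
  }
  tibble::tibble(
    index = indices[-ref],
    t = log(intensities[-ref] / intensities[ref])
  )
}
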