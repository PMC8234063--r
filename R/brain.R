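# Aggregated isotope distributions via the Newton-Girard power-sum recursion
# (BRAIN). Each element e contributes a generating polynomial
#   Q_e(I) = sum_i p_{e,i} I^{d_{e,i}}
# over extra-nucleon counts d, and a molecule with n_e atoms of element e has
#   U(I) = prod_e Q_e(I)^{n_e},
# whose coefficient q_j is the probability of carrying exactly j extra
# nucleons. Writing psi_l for the power sums of the inverse roots of U,
# Newton's identities give the recursion
#   q_j = -(1/j) * sum_{l=1..j} psi_l q_{j-l},  q_0 = prod_e p_{e,0}^{n_e},
# and psi_l is additive over atoms: psi_l(U) = sum_e n_e psi_l(Q_e). Centroid
# masses come from the parallel mass-moment series C(I) = U(I) * A(I) with
# A(I) = sum_e n_e Qtilde_e(I)/Q_e(I), where Qtilde_e is Q_e with each term
# weighted by its isotope mass; then m_j = c_j / q_j.

# Per-element constants: abundance polynomial p (dense over nucleon offsets),
# inverse-root power sums to order L, and the Qtilde/Q series to order L.
.element_poly <- function(element) {
  iso <- .isotope_entry(element)
  d <- max(iso$nucleons)
  p <- numeric(d + 1L)
  pm <- numeric(d + 1L)
  p[iso$nucleons + 1L] <- iso$abundance
  pm[iso$nucleons + 1L] <- iso$abundance * iso$mass
  list(p = p, pm = pm, degree = d)
}

# Power sums of the inverse roots of Q via Newton's identities on the
# reversed monic polynomial x^d + a_1 x^{d-1} + ... + a_d, a_i = p_i / p_0.
.element_power_sums <- function(element, L) {
  ep <- .element_poly(element)
  d <- ep$degree
  psi <- numeric(L)
  if (d == 0L || L == 0L) return(psi)
  a <- ep$p[-1L] / ep$p[1L]           # a_1 .. a_d
  for (k in seq_len(L)) {
    acc <- if (k <= d) -k * a[k] else 0
    for (j in seq_len(min(k - 1L, d))) acc <- acc - a[j] * psi[k - j]
    psi[k] <- acc
  }
  psi
}

# Series coefficients b_0..b_L of Qtilde(I)/Q(I).
.element_mass_series <- function(element, L) {
  ep <- .element_poly(element)
  d <- ep$degree
  b <- numeric(L + 1L)
  b[1L] <- ep$pm[1L] / ep$p[1L]
  if (L >= 1L) {
    for (l in seq_len(L)) {
      acc <- if (l <= d) ep$pm[l + 1L] else 0
      for (j in seq_len(min(l, d))) acc <- acc - ep$p[j + 1L] * b[l - j + 1L]
      b[l + 1L] <- acc / ep$p[1L]
    }
  }
  b
}

#' Aggregated isotope distribution of a molecular formula
#'
#' Computes the first `K` aggregated isotope variants (probabilities and
#' centroid masses) of an elemental formula with the Newton-Girard power-sum
#' recursion. Variant `j` collects all isotopologues carrying exactly `j - 1`
#' extra nucleons relative to the all-lightest-isotope species, so peak 1 is
#' the monoisotopic variant and its centroid equals the monoisotopic mass.
#'
#' @param formula Formula string or named count vector; see [parse_formula()].
#' @param K Number of aggregated variants to return (>= 1).
#' @return A tibble of class `isotope_distribution` with columns `peak`
#'   (1-based variant index), `prob` and `centroid_mass` (Da; `NA` where the
#'   probability underflows to zero), plus attributes `formula`, `mono_mass`
#'   and `snapshot`.
#' @examples
#' isotope_distribution("C45H62N15O31P5", K = 8) # d(C)5, 5'-phosphate
#' @export
isotope_distribution <- function(formula, K = 20L) {
  counts <- parse_formula(formula)
  if (length(counts) == 0L) stop("empty formula", call. = FALSE)
  if (!(is.numeric(K) && length(K) == 1L && K >= 1)) {
    stop("K must be a positive integer", call. = FALSE)
  }
  K <- as.integer(K)
  els <- names(counts)
  L <- K - 1L

  psi <- numeric(L)
  eta <- numeric(K)
  lq0 <- 0
  for (i in seq_along(els)) {
    n <- counts[[i]]
    psi <- psi + n * .element_power_sums(els[i], L)
    eta <- eta + n * .element_mass_series(els[i], L)
    lq0 <- lq0 + n * log(.element_poly(els[i])$p[1L])
  }

  q <- numeric(K)
  q[1L] <- exp(lq0)
  if (K > 1L) {
    for (j in seq_len(L)) {
      q[j + 1L] <- -sum(psi[seq_len(j)] * q[j:1L]) / j
    }
  }
  q <- pmax(q, 0)

  # mass moments c_j = sum_l eta_l q_{j-l}; centroid m_j = c_j / q_j
  cm <- numeric(K)
  for (j in seq_len(K)) {
    cm[j] <- sum(eta[seq_len(j)] * q[j:1L])
  }
  centroid <- ifelse(q > 0, cm / q, NA_real_)

  out <- tibble::tibble(peak = seq_len(K), prob = q, centroid_mass = centroid)
  class(out) <- c("isotope_distribution", class(out))
  attr(out, "formula") <- formula_to_string(counts)
  attr(out, "mono_mass") <- monoisotopic_mass(counts)
  attr(out, "snapshot") <- .ISOTOPE_SNAPSHOT
  out
}

#' Summed probability of a distribution's peaks
#'
#' The coverage of a truncated aggregated isotope distribution: the total
#' probability captured by its first `K` variants. Low-mass oligonucleotides
#' are fully covered by a handful of peaks; for the heaviest database records
#' 20 peaks capture roughly 95%.
#'
#' @param dist An [isotope_distribution()] result (or any tibble with `prob`).
#' @return Coverage probability in `[0, 1]` (up to float slop).
#' @export
coverage <- function(dist) {
  sum(dist$prob)
}

#' Batch aggregated isotope distributions
#'
#' Vectorised Newton-Girard recursion for many molecules sharing an element
#' set: takes a matrix of element counts (rows = molecules) and returns the
#' probability and centroid-mass matrices for the first `K` variants. Used to
#' process the multi-million-record composition database; work is chunked to
#' bound memory.
#'
#' @param counts Numeric matrix of element counts with colnames naming the
#'   elements (e.g. from [element_counts()]).
#' @param K Number of aggregated variants.
#' @param centroids Also compute centroid masses (default `TRUE`).
#' @param chunk_size Rows per processing chunk.
#' @return List with matrices `prob` (n x K) and, if requested, `centroid`
#'   (n x K).
#' @export
batch_isotope <- function(counts, K = 20L, centroids = TRUE,
                          chunk_size = 250000L) {
  stopifnot(is.matrix(counts), !is.null(colnames(counts)))
  K <- as.integer(K)
  els <- colnames(counts)
  L <- K - 1L
  S <- matrix(vapply(els, .element_power_sums, numeric(L), L = L),
              nrow = L, ncol = length(els))                   # L x n_el
  B <- matrix(vapply(els, .element_mass_series, numeric(K), L = L),
              nrow = K, ncol = length(els))                   # K x n_el
  lp0 <- vapply(els, function(e) log(.element_poly(e)$p[1L]), numeric(1))

  n <- nrow(counts)
  prob <- matrix(NA_real_, n, K)
  cent <- if (centroids) matrix(NA_real_, n, K) else NULL
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, n)
    Nc <- counts[idx, , drop = FALSE]
    Psi <- if (L > 0L) Nc %*% t(S) else NULL                  # n_c x L
    Eta <- Nc %*% t(B)                                        # n_c x K
    Q <- matrix(0, length(idx), K)
    Q[, 1L] <- exp(drop(Nc %*% lp0))
    if (K > 1L) {
      for (j in seq_len(L)) {
        acc <- 0
        for (l in seq_len(j)) acc <- acc - Psi[, l] * Q[, j - l + 1L]
        Q[, j + 1L] <- acc / j
      }
    }
    Q[Q < 0] <- 0
    prob[idx, ] <- Q
    if (centroids) {
      Cm <- matrix(0, length(idx), K)
      for (j in seq_len(K)) {
        acc <- 0
        for (l in seq_len(j)) acc <- acc + Eta[, l] * Q[, j - l + 1L]
        Cm[, j] <- acc
      }
      cent[idx, ] <- ifelse(Q > 0, Cm / Q, NA_real_)
    }
  }
  c(list(prob = prob), if (centroids) list(centroid = cent))
}

#' Exact convolution oracle for aggregated isotope distributions
#'
#' Reference implementation by direct polynomial convolution: each element's
#' abundance polynomial (over extra-nucleon counts) is raised to its atom
#' count by binary exponentiation, carrying a parallel mass-moment
#' accumulator, and the per-element results are convolved. Mathematically
#' exact (up to float rounding) and independent of the power-sum recursion;
#' intended for verification on small molecules.
#'
#' @inheritParams isotope_distribution
#' @param max_atoms Guard on total atom count (convolution is quadratic).
#' @return Same shape as [isotope_distribution()].
#' @export
convolution_oracle <- function(formula, K = 20L, max_atoms = 10000L) {
  counts <- parse_formula(formula)
  if (length(counts) == 0L) stop("empty formula", call. = FALSE)
  if (sum(counts) > max_atoms) {
    stop("formula too large for the convolution oracle", call. = FALSE)
  }
  K <- as.integer(K)

  conv_pair <- function(x, y) {
    # x, y: lists (q = prob poly, u = mass-moment poly), truncated at K terms
    nx <- length(x$q); ny <- length(y$q)
    n <- min(nx + ny - 1L, K)
    q <- numeric(n); u <- numeric(n)
    for (a in seq_len(nx)) {
      jmax <- min(ny, n - a + 1L)
      if (jmax < 1L) next
      j <- seq_len(jmax)
      tgt <- a + j - 1L
      q[tgt] <- q[tgt] + x$q[a] * y$q[j]
      u[tgt] <- u[tgt] + x$u[a] * y$q[j] + x$q[a] * y$u[j]
    }
    list(q = q, u = u)
  }
  unit <- list(q = 1, u = 0)
  pow <- function(base, n) {
    out <- unit
    while (n > 0L) {
      if (n %% 2L == 1L) out <- conv_pair(out, base)
      base <- conv_pair(base, base)
      n <- n %/% 2L
    }
    out
  }

  acc <- unit
  for (el in names(counts)) {
    ep <- .element_poly(el)
    base <- list(q = ep$p, u = ep$pm)
    acc <- conv_pair(acc, pow(base, counts[[el]]))
  }
  q <- acc$q; u <- acc$u
  length(q) <- K; length(u) <- K        # pad with NA then zero-fill
  q[is.na(q)] <- 0; u[is.na(u)] <- 0
  centroid <- ifelse(q > 0, u / q, NA_real_)

  out <- tibble::tibble(peak = seq_len(K), prob = q, centroid_mass = centroid)
  class(out) <- c("isotope_distribution", class(out))
  attr(out, "formula") <- formula_to_string(counts)
  attr(out, "mono_mass") <- monoisotopic_mass(counts)
  attr(out, "snapshot") <- .ISOTOPE_SNAPSHOT
  out
}
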