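# Embedded elemental isotope data (NIST/CIAAW atomic masses and representative
# isotopic abundances). Masses in Da; abundances sum to 1 per element. The
# lightest isotope of C, H, N, O, P, S and F is also the most abundant, so the
# all-lightest species is the monoisotopic variant. `nucleons` is the extra
# nucleon count relative to the lightest isotope of that element.
.ISOTOPE_SNAPSHOT <- "NIST-CIAAW-2021"

.ISOTOPES <- list(
  C = list(mass = c(12.0, 13.00335483521),
           abundance = c(0.9893, 0.0107),
           nucleons = c(0L, 1L)),
  H = list(mass = c(1.00782503224, 2.01410177811),
           abundance = c(0.999885, 0.000115),
           nucleons = c(0L, 1L)),
  N = list(mass = c(14.00307400446, 15.00010889894),
           abundance = c(0.99636, 0.00364),
           nucleons = c(0L, 1L)),
  O = list(mass = c(15.99491461960, 16.99913175664, 17.99915961284),
           abundance = c(0.99757, 0.00038, 0.00205),
           nucleons = c(0L, 1L, 2L)),
  P = list(mass = 30.97376199850,
           abundance = 1.0,
           nucleons = 0L),
  S = list(mass = c(31.97207117443, 32.97145890985, 33.967867011, 35.96708069),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001),
           nucleons = c(0L, 1L, 2L, 4L)),
  F = list(mass = 18.99840316288,
           abundance = 1.0,
           nucleons = 0L)
)

#' Elemental isotope table
#'
#' Returns the embedded isotope table used throughout the package: one row per
#' isotope with its exact mass, abundance and extra-nucleon count relative to
#' the element's lightest isotope. The snapshot identifier records which
#' NIST/CIAAW release the constants were taken from and is propagated into
#' model bundles so predictions are traceable to an isotope definition.
#'
#' @return A tibble with columns `element`, `mass` (Da), `abundance`
#'   (probability) and `nucleons` (integer offset), plus a `snapshot`
#'   attribute.
#' @examples
#' isotope_table()
#' @export
isotope_table <- function() {
  tbl <- purrr::imap_dfr(.ISOTOPES, function(iso, el) {
    tibble::tibble(element = el, mass = iso$mass,
                   abundance = iso$abundance, nucleons = iso$nucleons)
  })
  attr(tbl, "snapshot") <- .ISOTOPE_SNAPSHOT
  tbl
}

.isotope_entry <- function(element) {
  entry <- .ISOTOPES[[element]]
  if (is.null(entry)) {
    stop("unknown element symbol: '", element, "'", call. = FALSE)
  }
  entry
}

#' Parse a molecular formula string
#'
#' Parses Hill-like notation such as `"C266H334N100O162P26"` into a named
#' integer vector of element counts. Element symbols are one uppercase letter
#' optionally followed by a lowercase letter; a missing count means 1. The
#' inverse operation is [formula_to_string()], and the round trip is stable.
#'
#' @param x A formula string, or an already-parsed named numeric vector (which
#'   is validated and returned as integer counts).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("H2O")
#' parse_formula("C266H334N100O162P26")
#' @export
parse_formula <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    counts <- x
  } else {
    if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
      stop("formula must be a single non-empty string or named count vector",
           call. = FALSE)
    }
    s <- gsub("[[:space:]]", "", x)
    m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
    parts <- regmatches(s, list(m))[[1]]
    if (length(parts) == 0L || sum(attr(m, "match.length")) != nchar(s)) {
      stop("cannot parse formula string: '", x, "'", call. = FALSE)
    }
    els <- sub("[0-9]*$", "", parts)
    ns <- sub("^[A-Za-z]+", "", parts)
    counts <- ifelse(nzchar(ns), as.numeric(ns), 1)
    names(counts) <- els
    if (anyDuplicated(els)) counts <- tapply(counts, els, sum)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be nonnegative integers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  out <- as.integer(round(counts))
  names(out) <- names(counts)
  out
}

#' Write a formula as a string
#'
#' @param counts Named vector of element counts.
#' @param order Element ordering; defaults to Hill-like C, H, then the
#'   remaining elements alphabetically.
#' @return A single string such as `"C9H14N3O7P"` (count 1 is omitted).
#' @examples
#' formula_to_string(c(H = 2, O = 1))
#' @export
formula_to_string <- function(counts, order = NULL) {
  counts <- parse_formula(counts)
  if (is.null(order)) {
    rest <- sort(setdiff(names(counts), c("C", "H")))
    order <- c(intersect(c("C", "H"), names(counts)), rest)
  }
  counts <- counts[order]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum over elements of count times the mass of the element's lightest
#' isotope. For the elements covered here (C, H, N, O, P, S, F) the lightest
#' isotope is also the most abundant, so this is the monoisotopic mass in the
#' usual mass-spectrometric sense.
#'
#' @param formula Formula string or named count vector; see [parse_formula()].
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass("C266H334N100O162P26")
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(vapply(names(counts), function(el) .isotope_entry(el)$mass[1L],
             numeric(1)) * counts)
}

#' m/z of a deprotonated species (negative ion mode)
#'
#' Display helper for negative-mode oligonucleotide spectra: computes
#' (M - z * m(H)) / z for charge state z.
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge state (number of protons removed).
#' @return m/z value(s).
#' @export
mz_negative <- function(mass, charge) {
  stopifnot(all(charge >= 1), all(charge == round(charge)))
  (mass - charge * .ISOTOPES$H$mass[1L]) / charge
}

# Sum/subtract formulas elementwise; negative results are an error.
.formula_add <- function(a, b, mult_b = 1L) {
  a <- parse_formula(a); b <- parse_formula(b)
  els <- union(names(a), names(b))
  out <- numeric(length(els)); names(out) <- els
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + mult_b * b
  if (any(out < 0)) stop("formula subtraction yields negative counts",
                         call. = FALSE)
  parse_formula(out)
}
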