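# Exhaustive composition database for phosphodiester DNA/RNA oligonucleotides.
# Records are compositions (multisets of the four monomers), not sequences:
# within one backbone a composition uniquely determines the elemental formula
# and hence the monoisotopic mass.

# Monomer formulas: nucleoside 5'-monophosphate free acids. A strand of
# length l condenses (l - 1) waters; the database convention carries a
# 5'-terminal phosphate (l phosphates), while synthesis-style 5'-OH strands
# additionally lose HPO3.
.MONOMERS <- list(
  DNA = list(A = c(C = 10, H = 14, N = 5, O = 6, P = 1),
             C = c(C = 9,  H = 14, N = 3, O = 7, P = 1),
             G = c(C = 10, H = 14, N = 5, O = 7, P = 1),
             TU = c(C = 10, H = 15, N = 2, O = 8, P = 1)),
  RNA = list(A = c(C = 10, H = 14, N = 5, O = 7, P = 1),
             C = c(C = 9,  H = 14, N = 3, O = 8, P = 1),
             G = c(C = 10, H = 14, N = 5, O = 8, P = 1),
             TU = c(C = 9,  H = 13, N = 2, O = 9, P = 1))
)
.H2O <- c(C = 0, H = 2, N = 0, O = 1, P = 0)
.HPO3 <- c(C = 0, H = 1, N = 0, O = 3, P = 1)
.ELEMENTS_DB <- c("C", "H", "N", "O", "P")

.check_backbone <- function(backbone) {
  backbone <- toupper(backbone)
  if (!backbone %in% c("DNA", "RNA")) {
    stop("backbone must be \"DNA\" or \"RNA\"", call. = FALSE)
  }
  backbone
}

#' Monomer elemental composition matrix
#'
#' One row per monomer (A, C, G, and T or U), one column per element
#' (C, H, N, O, P), for the nucleoside 5'-monophosphate free acids that the
#' database is built from.
#'
#' @param backbone `"DNA"` or `"RNA"`.
#' @return A 4 x 5 integer matrix with rownames `A`, `C`, `G`, `TU`.
#' @export
monomer_matrix <- function(backbone) {
  backbone <- .check_backbone(backbone)
  t(vapply(.MONOMERS[[backbone]], function(f) f[.ELEMENTS_DB], numeric(5)))
}

.monomer_masses <- function(backbone) {
  vapply(.MONOMERS[[.check_backbone(backbone)]], monoisotopic_mass, numeric(1))
}

#' Closed-form composition count
#'
#' Number of 4-part nucleotide compositions with length in
#' `[min_len, max_len]`: the multiset count sum of C(l+3, 3), which telescopes
#' to C(max_len+4, 4) - C(min_len+3, 4).
#'
#' @param min_len,max_len Length range (inclusive).
#' @return Number of compositions.
#' @export
count_compositions <- function(min_len, max_len) {
  stopifnot(min_len >= 1, min_len <= max_len)
  choose(max_len + 4, 4) - choose(min_len + 3, 4)
}

#' Enumerate all nucleotide compositions in a length range
#'
#' Yields every multiset (n_A, n_C, n_G, n_TU) with total length between
#' `min_len` and `max_len` exactly once, in lexicographic order of
#' (length, n_A, n_C, n_G). The order is deterministic so that seeded
#' operations on the database are reproducible across platforms.
#'
#' @param backbone `"DNA"` or `"RNA"` (recorded; the combinatorics are
#'   identical, only masses differ).
#' @param min_len,max_len Inclusive length range; `1 <= min_len <= max_len`.
#' @return A tibble with columns `n_A`, `n_C`, `n_G`, `n_TU` (integer) and
#'   `length`, plus a `backbone` attribute.
#' @examples
#' enumerate_compositions("DNA", 1, 1)
#' nrow(enumerate_compositions("DNA", 5, 5)) # choose(8, 3) = 56
#' @export
enumerate_compositions <- function(backbone, min_len, max_len) {
  backbone <- .check_backbone(backbone)
  if (!(is.numeric(min_len) && is.numeric(max_len) &&
        min_len >= 1 && min_len <= max_len)) {
    stop("invalid length range: need 1 <= min_len <= max_len", call. = FALSE)
  }
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)

  # memoised (n_C, n_G) blocks for a given remainder m, nC-major ascending
  pair_nC <- vector("list", max_len + 1L)
  pair_nG <- vector("list", max_len + 1L)
  for (m in 0:max_len) {
    reps <- (m:0) + 1L
    pair_nC[[m + 1L]] <- rep.int(0:m, reps)
    pair_nG[[m + 1L]] <- sequence(reps) - 1L
  }

  total <- count_compositions(min_len, max_len)
  n_A <- integer(total); n_C <- integer(total); n_G <- integer(total)
  len <- integer(total)
  pos <- 0L
  for (l in min_len:max_len) {
    for (a in 0:l) {
      m <- l - a
      k <- m + 1L
      blk <- length(pair_nC[[k]])
      idx <- pos + seq_len(blk)
      n_A[idx] <- a
      n_C[idx] <- pair_nC[[k]]
      n_G[idx] <- pair_nG[[k]]
      len[idx] <- l
      pos <- pos + blk
    }
  }
  out <- tibble::tibble(n_A = n_A, n_C = n_C, n_G = n_G,
                        n_TU = len - n_A - n_C - n_G, length = len)
  attr(out, "backbone") <- backbone
  out
}

#' Elemental formula of a nucleotide composition
#'
#' Sums the monomer formulas and removes `length - 1` waters (one per
#' phosphodiester condensation). With `terminus = "five_prime_OH"` an
#' additional HPO3 is removed, matching synthetic strands without a
#' 5'-terminal phosphate.
#'
#' @param counts Numeric vector `c(n_A, n_C, n_G, n_TU)`, or a data frame /
#'   tibble with those columns (one row).
#' @param backbone `"DNA"` or `"RNA"`.
#' @param terminus `"five_prime_phosphate"` (database convention) or
#'   `"five_prime_OH"`.
#' @return Named integer vector of element counts.
#' @examples
#' composition_formula(c(0, 5, 0, 0), "DNA") # d(C)5, 5'-phosphate
#' @export
composition_formula <- function(counts, backbone,
                                terminus = c("five_prime_phosphate",
                                             "five_prime_OH")) {
  terminus <- match.arg(terminus)
  backbone <- .check_backbone(backbone)
  if (is.data.frame(counts)) {
    stopifnot(nrow(counts) == 1L)
    counts <- c(counts$n_A, counts$n_C, counts$n_G, counts$n_TU)
  }
  stopifnot(length(counts) == 4L, all(counts >= 0))
  l <- sum(counts)
  if (l < 1) stop("composition length must be at least 1", call. = FALSE)
  M <- monomer_matrix(backbone)
  f <- drop(counts %*% M) - (l - 1) * .H2O[.ELEMENTS_DB]
  if (terminus == "five_prime_OH") f <- f - .HPO3[.ELEMENTS_DB]
  if (any(f < 0)) stop("terminus removal yields negative counts",
                       call. = FALSE)
  parse_formula(f)
}

# Vectorised masses for a composition tibble (database convention terminus).
.composition_masses <- function(comp, backbone) {
  mm <- .monomer_masses(backbone)
  h2o <- monoisotopic_mass("H2O")
  comp$n_A * mm[["A"]] + comp$n_C * mm[["C"]] + comp$n_G * mm[["G"]] +
    comp$n_TU * mm[["TU"]] - (comp$length - 1) * h2o
}

#' Restricted-range mass limit
#'
#' The database enumerates compositions up to `max_len`; beyond the mass of
#' the lightest possible (`max_len` + 1)-mer — a homopolymer of the lightest
#' monomer (dCMP or CMP) — heavier length classes are missing and the mass
#' axis is no longer exhaustively covered. Records at or above this limit are
#' excluded from the restricted view used for model deployment.
#'
#' @param backbone `"DNA"` or `"RNA"`.
#' @param max_len Maximum enumerated length.
#' @return Mass limit in Da (exclusive upper bound).
#' @export
restricted_mass_limit <- function(backbone, max_len) {
  mm <- .monomer_masses(backbone)
  n <- max_len + 1
  n * mm[["C"]] - (n - 1) * monoisotopic_mass("H2O")
}

#' Build the theoretical oligonucleotide database
#'
#' Enumerates all compositions in the length range, attaches monoisotopic
#' masses (5'-phosphate terminus), and optionally keeps only the restricted
#' mass range where the database exhaustively covers the mass axis (see
#' [restricted_mass_limit()]).
#'
#' @param backbone `"DNA"` or `"RNA"`.
#' @param min_len,max_len Length range; defaults are 5 to 92 for DNA and 5 to
#'   90 for RNA.
#' @param restrict Keep only records strictly below the restricted mass limit.
#' @return A tibble of class `oligo_db` with columns `n_A`, `n_C`, `n_G`,
#'   `n_TU`, `length`, `mono_mass`, and attributes `backbone`, `min_len`,
#'   `max_len`, `restricted`, `mass_limit`.
#' @examples
#' db <- build_oligo_db("DNA", 5, 12)
#' dplyr::summarise(db, n = dplyr::n(), min = min(mono_mass))
#' @export
build_oligo_db <- function(backbone,
                           min_len = 5,
                           max_len = if (.check_backbone(backbone) == "DNA")
                             92 else 90,
                           restrict = FALSE) {
  backbone <- .check_backbone(backbone)
  db <- enumerate_compositions(backbone, min_len, max_len)
  db$mono_mass <- .composition_masses(db, backbone)
  limit <- restricted_mass_limit(backbone, max_len)
  if (restrict) db <- db[db$mono_mass < limit, ]
  attr(db, "backbone") <- backbone
  attr(db, "min_len") <- min_len
  attr(db, "max_len") <- max_len
  attr(db, "restricted") <- restrict
  attr(db, "mass_limit") <- limit
  class(db) <- c("oligo_db", class(db))
  db
}

#' Elemental count matrix for a database
#'
#' Converts composition counts to per-molecule element counts (columns C, H,
#' N, O, P) under the 5'-phosphate database convention; input to the batch
#' isotope-distribution engine.
#'
#' @param db A composition tibble (with `n_A` .. `n_TU`, `length`).
#' @param backbone Backbone; defaults to the tibble's attribute.
#' @return Numeric matrix, one row per record.
#' @export
element_counts <- function(db, backbone = attr(db, "backbone")) {
  M <- monomer_matrix(backbone)
  cnt <- cbind(db$n_A, db$n_C, db$n_G, db$n_TU) %*% M
  cnt - outer(db$length - 1, .H2O[.ELEMENTS_DB])
}

#' Train/test split of the database
#'
#' The test set is drawn uniformly without replacement from the records in the
#' restricted mass range (where the model will operate); the training set is
#' every remaining record across the entire mass range, so the polynomial is
#' anchored beyond the deployment range and boundary artefacts are pushed
#' outside it. The test-set size is round-half-up of `fraction` times the
#' number of records in `size_basis` ("full" reproduces the published split
#' sizes).
#'
#' @param db Full-range database from [build_oligo_db()].
#' @param fraction Test fraction in (0, 1); default 0.05.
#' @param seed Integer seed; the split is reproducible given the seed.
#' @param size_basis Count the test size against the `"full"` database
#'   (default) or only the `"restricted"` records.
#' @return List with integer index vectors `train` and `test` (row indices
#'   into `db`).
#' @export
train_test_split <- function(db, fraction = 0.05, seed = 1L,
                             size_basis = c("full", "restricted")) {
  size_basis <- match.arg(size_basis)
  if (nrow(db) == 0L) stop("empty database", call. = FALSE)
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  limit <- attr(db, "mass_limit")
  eligible <- if (is.null(limit)) seq_len(nrow(db)) else
    which(db$mono_mass < limit)
  basis_n <- if (size_basis == "full") nrow(db) else length(eligible)
  n_test <- floor(fraction * basis_n + 0.5)  # round half up
  n_test <- min(n_test, length(eligible))
  test <- withr::with_seed(as.integer(seed),
                           sort(sample(eligible, n_test, replace = FALSE)))
  list(train = setdiff(seq_len(nrow(db)), test), test = test)
}

#' Parse a nucleotide sequence into a composition
#'
#' Accepts A/C/G/T/U strings, case-insensitive and whitespace/dash tolerant.
#' `T` and `U` both count towards `n_TU`; the backbone decides whether that
#' slot is thymidine or uridine.
#'
#' @param sequence Sequence string, e.g. `"GCC ACA TAT"`.
#' @param backbone `"DNA"` or `"RNA"`.
#' @return One-row tibble with columns `n_A`, `n_C`, `n_G`, `n_TU`, `length`.
#' @examples
#' parse_sequence("GCC ACA TAT GAG AGT GGA TTT GTC ATT", "DNA")
#' @export
parse_sequence <- function(sequence, backbone) {
  backbone <- .check_backbone(backbone)
  s <- toupper(gsub("[[:space:]-]", "", sequence))
  if (!nzchar(s)) stop("empty sequence", call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "U"))
  if (length(bad) > 0) {
    stop("invalid residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    n_A = sum(chars == "A"), n_C = sum(chars == "C"),
    n_G = sum(chars == "G"), n_TU = sum(chars %in% c("T", "U"))
  )
  out$length <- out$n_A + out$n_C + out$n_G + out$n_TU
  attr(out, "backbone") <- backbone
  out
}
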