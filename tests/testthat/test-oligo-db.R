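# Composition enumeration, elemental formulas and masses, database filtering
# and splitting.

brute_force_count <- function(min_len, max_len) {
  # independent oracle: explicit quadruple nested loop
  n <- 0L
  for (a in 0:max_len) for (c in 0:(max_len - a)) {
    for (g in 0:(max_len - a - c)) for (t in 0:(max_len - a - c - g)) {
      l <- a + c + g + t
      if (l >= min_len && l <= max_len) n <- n + 1L
    }
  }
  n
}

test_that("enumeration matches the closed-form and brute-force counts", {
  for (rng in list(c(1, 1), c(5, 5), c(2, 7), c(5, 12))) {
    comp <- enumerate_compositions("DNA", rng[1], rng[2])
    expect_identical(nrow(comp), as.integer(count_compositions(rng[1],
                                                               rng[2])))
    expect_identical(nrow(comp), brute_force_count(rng[1], rng[2]))
  }
  expect_identical(nrow(enumerate_compositions("DNA", 1, 1)), 4L)
  expect_identical(nrow(enumerate_compositions("DNA", 5, 5)), 56L)
  expect_error(enumerate_compositions("DNA", 0, 5), "length range")
  expect_error(enumerate_compositions("DNA", 6, 5), "length range")
})

test_that("enumeration yields each multiset once, in deterministic order", {
  comp <- enumerate_compositions("RNA", 2, 9)
  key <- paste(comp$length, comp$n_A, comp$n_C, comp$n_G)
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(comp$n_TU >= 0))
  expect_identical(comp, enumerate_compositions("RNA", 2, 9))
  # lexicographic in (length, n_A, n_C, n_G)
  ord <- order(comp$length, comp$n_A, comp$n_C, comp$n_G)
  expect_identical(ord, seq_len(nrow(comp)))
})

test_that("composition formulas follow the condensation and terminus rules", {
  # d(C)5 with 5'-phosphate: 5 x dCMP - 4 x H2O
  expect_identical(formula_to_string(composition_formula(c(0, 5, 0, 0),
                                                         "DNA")),
                   "C45H62N15O31P5")
  # single dA, no water lost
  expect_identical(formula_to_string(composition_formula(c(1, 0, 0, 0),
                                                         "DNA")),
                   "C10H14N5O6P")
  # published strands use the 5'-OH convention
  s1 <- parse_sequence("GCC ACA TAT GAG AGT GGA TTT GTC ATT", "DNA")
  expect_identical(
    formula_to_string(composition_formula(s1, "DNA", "five_prime_OH")),
    "C266H334N100O162P26")
  s2 <- parse_sequence("GGT GCC CCA GAA TCT CTC AGC CT", "DNA")
  expect_identical(
    formula_to_string(composition_formula(s2, "DNA", "five_prime_OH")),
    "C221H282N82O137P22")
  expect_error(composition_formula(c(0, 0, 0, 0), "DNA"), "at least 1")
})

test_that("terminus offset is exactly one HPO3 for every composition", {
  hpo3 <- monoisotopic_mass(c(H = 1, P = 1, O = 3))
  comp <- enumerate_compositions("RNA", 1, 4)
  for (i in seq_len(nrow(comp))) {
    mp <- monoisotopic_mass(composition_formula(comp[i, ], "RNA"))
    mo <- monoisotopic_mass(composition_formula(comp[i, ], "RNA",
                                                "five_prime_OH"))
    expect_equal(mp - mo, hpo3, tolerance = 1e-12)
  }
})

test_that("monoisotopic masses are additive in the monomer masses", {
  h2o <- monoisotopic_mass("H2O")
  expect_equal(h2o, 18.01056, tolerance = 1e-5)
  db <- small_db("DNA")
  idx <- c(1L, 57L, nrow(db))
  mono <- diag(4)
  for (i in idx) {
    row <- db[i, ]
    monomers <- sum(vapply(1:4, function(j) {
      n <- c(row$n_A, row$n_C, row$n_G, row$n_TU)[j]
      if (n == 0) return(0)
      n * monoisotopic_mass(composition_formula(mono[j, ], "DNA"))
    }, numeric(1)))
    expect_equal(row$mono_mass, monomers - (row$length - 1) * h2o,
                 tolerance = 1e-9)
  }
  expect_error(monoisotopic_mass("Xx3"), "unknown element")
})

test_that("no two compositions of one backbone share a formula (len <= 10)", {
  for (bb in c("DNA", "RNA")) {
    comp <- enumerate_compositions(bb, 1, 10)
    fml <- vapply(seq_len(nrow(comp)), function(i) {
      formula_to_string(composition_formula(comp[i, ], bb))
    }, character(1))
    expect_false(anyDuplicated(fml) > 0)
  }
})

test_that("restricted view keeps only masses strictly below the limit", {
  db <- build_oligo_db("DNA", 5, 12, restrict = TRUE)
  limit <- restricted_mass_limit("DNA", 12)
  expect_equal(limit,
               monoisotopic_mass(composition_formula(c(0, 13, 0, 0),
                                                     "DNA")),
               tolerance = 1e-12)
  expect_true(all(db$mono_mass < limit))
  full <- build_oligo_db("DNA", 5, 12)
  expect_identical(nrow(db), sum(full$mono_mass < limit))
  expect_true(all(full$mono_mass > 0))
})

test_that("train/test split is seeded, restricted-sourced and round-half-up", {
  db <- small_db("DNA")
  s1 <- train_test_split(db, 0.05, seed = 7)
  s2 <- train_test_split(db, 0.05, seed = 7)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_identical(sort(c(s1$train, s1$test)), seq_len(nrow(db)))
  # test indices only from the restricted mass region
  expect_true(all(db$mono_mass[s1$test] < attr(db, "mass_limit")))
  # size: round-half-up of fraction x full count
  expect_length(s1$test, floor(0.05 * nrow(db) + 0.5))
  # the published sizes imply half-up rounding on the full count
  expect_identical(floor(0.05 * 3321890 + 0.5), 166095)
  expect_identical(floor(0.05 * 3049431 + 0.5), 152472)
  expect_error(train_test_split(db[0, ], 0.05), "empty")
  expect_error(train_test_split(db, 1.5), "fraction")
})

test_that("sequence parsing is whitespace- and case-tolerant", {
  a <- parse_sequence("gcc aca", "DNA")
  b <- parse_sequence("GCCACA", "DNA")
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(a$n_C, 3L + 0L)
  u <- parse_sequence("AUGC", "RNA")
  expect_identical(u$n_TU, 1L)
  expect_error(parse_sequence("ACGX", "DNA"), "invalid residue")
  expect_error(parse_sequence("  ", "DNA"), "empty")
})
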