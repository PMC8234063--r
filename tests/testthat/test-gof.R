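# Envelope scoring statistics and the label-free backbone classifier.

# envelope exactly proportional to a model's predicted probabilities
perfect_envelope <- function(model, mass, scale = 1e4, n_peaks = 12) {
  env <- predict_envelope(mass, model)
  observed_envelope(index = 1:n_peaks,
                    intensity = scale * env$prob[1:n_peaks],
                    mono_mass = mass)
}

test_that("both statistics vanish on a perfect envelope", {
  model <- small_model("DNA")
  mass <- mean(model$mass_range)
  env <- perfect_envelope(model, mass)
  expect_equal(mse_alr(env, model), 0, tolerance = 1e-18)
  chi <- chi2_simplex(env, model)
  expect_equal(chi$score, 0, tolerance = 1e-12)
  expect_equal(chi$N, 1e4, tolerance = 1e-6)
})

test_that("ALR error matches the hand-computed value and ignores scale", {
  # observed log-ratios equal the prediction except the first, off by 0.1
  z <- c(log(0.5), log(0.25)) # predicted log-ratios for peaks 2 and 3
  o <- c(100, 100 * exp(z[1] + 0.1), 100 * exp(z[2]))
  env <- observed_envelope(1:3, o, mono_mass = 5000)
  expect_equal(mse_alr(env, c(z, rep(0, 18))), 0.1^2 / 2,
               tolerance = 1e-12)
  env_scaled <- observed_envelope(1:3, 7.3 * o, mono_mass = 5000)
  expect_equal(mse_alr(env_scaled, c(z, rep(0, 18))), 0.1^2 / 2,
               tolerance = 1e-12)
  # reference peak is mandatory for the ALR statistic
  env_nomono <- observed_envelope(2:4, o, mono_mass = 5000)
  expect_error(mse_alr(env_nomono, c(z, rep(0, 18))),
               "reference unobserved")
})

test_that("chi-squared error scales linearly with total intensity", {
  x <- add_closure(isotope_distribution("C100H140N40O60P10", 20)$prob)
  o <- 1e4 * x[1:10] * c(1.1, rep(0.98, 9)) # fixed relative misfit
  env1 <- observed_envelope(1:10, o, mono_mass = 1)
  env2 <- observed_envelope(1:10, 2 * o, mono_mass = 1)
  s1 <- chi2_simplex(env1, x)
  s2 <- chi2_simplex(env2, x)
  expect_equal(s2$score, 2 * s1$score, tolerance = 1e-10)
  expect_equal(s2$N, 2 * s1$N, tolerance = 1e-10)
  # works without the monoisotopic peak
  env3 <- observed_envelope(2:10, 1e4 * x[2:10], mono_mass = 1)
  expect_equal(chi2_simplex(env3, x)$score, 0, tolerance = 1e-10)
  expect_error(chi2_simplex(observed_envelope(2:3, c(1, 1), 1),
                            c(1, rep(0, 20))), "zero on every observed")
})

test_that("per-peak contributions are unchanged when support shrinks", {
  x <- add_closure(isotope_distribution("C80H100N30O50P8", 20)$prob)
  z <- alr(x)
  o <- withr::with_seed(31, 1e4 * x[1:8] * exp(rnorm(8, sd = 0.1)))
  full <- observed_envelope(1:8, o, mono_mass = 1)
  reduced <- observed_envelope(1:7, o[1:7], mono_mass = 1)
  t_full <- (observed_alr(full$intensity, full$index)$t - z[1:7])^2
  t_red <- (observed_alr(reduced$intensity, reduced$index)$t - z[1:6])^2
  expect_equal(t_full[1:6], t_red, tolerance = 1e-12)
  expect_equal(mse_alr(full, z), mean(t_full), tolerance = 1e-12)
  expect_equal(mse_alr(reduced, z), mean(t_red), tolerance = 1e-12)
})

test_that("backbone classification picks the lower-error model", {
  dna <- small_model("DNA")
  rna <- small_model("RNA")
  lo <- max(dna$mass_range[1], rna$mass_range[1])
  hi <- min(dna$mass_range[2], rna$mass_range[2])
  db <- small_db("DNA")
  pool <- db[db$mono_mass > lo & db$mono_mass < hi, ]
  idx <- withr::with_seed(32, sample(nrow(pool), 50))
  cls <- purrr::map_dfr(idx, function(i) {
    env <- synth_envelope(pool[i, ], "DNA", noise = noise_spec(), seed = i)
    classify_backbone(env, dna, rna)
  })
  # discrimination strengthens with mass (the full-scale check lives in the
  # acceptance suite); on these short oligos expect a clear aggregate signal
  expect_gt(mean(cls$label == "DNA"), 0.6)
  expect_lt(mean(cls$score_dna), mean(cls$score_rna))
  # degenerate tie: scoring a model against itself twice
  env <- synth_envelope(pool[idx[1], ], "DNA", seed = 1)
  tie <- classify_backbone(env, dna, dna)
  expect_identical(tie$label, "ambiguous")
  # without the monoisotopic peak the chi-squared statistic decides
  env2 <- synth_envelope(pool[idx[2], ], "DNA",
                         noise = noise_spec(drop_monoisotopic = TRUE),
                         seed = 2)
  cls <- classify_backbone(env2, dna, rna)
  expect_identical(cls$statistic, "chi2_simplex")
})

test_that("envelope files round-trip through the index-assigning reader", {
  model <- small_model("DNA")
  db <- small_db("DNA")
  comp <- db[db$mono_mass > model$mass_range[1] + 500 &
               db$mono_mass < model$mass_range[2], ][13, ]
  env <- synth_envelope(comp, "DNA", noise = noise_spec(sigma = 0.05),
                        seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  f <- readLines(write_envelope(env, path))
  writeLines(f[-1], path) # body only; reader gets the mass separately
  back <- read_envelope(path, attr(env, "mono_mass"))
  expect_identical(back$index, env$index)
  expect_equal(back$intensity, env$intensity, tolerance = 1e-6)
})
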