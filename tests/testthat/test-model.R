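# Weighted polynomial fit, order selection, envelope prediction and the
# bundle round trip.

test_that("standardization is the plain affine map", {
  expect_equal(standardize_mass(10, 10, 2), 0)
  expect_equal(standardize_mass(12, 10, 2), 1)
  expect_error(standardize_mass(1, 0, 0))
})

test_that("noise-free polynomial data is recovered exactly", {
  withr::with_seed(21, {
    m <- runif(200, 2000, 25000)
    mu <- mean(m); sigma <- sd(m)
    beta_true <- matrix(rnorm(20 * 4), 20, 4)
    X <- outer(standardize_mass(m, mu, sigma), 0:3, `^`)
    Z <- X %*% t(beta_true)
    fit <- fit_wls_poly(m, Z, order = 3, mu = mu, sigma = sigma)
    expect_equal(fit$beta, beta_true, tolerance = 1e-8)
    # constant response: intercept only, regardless of requested order
    Zc <- matrix(rep(seq_len(20) / 10, each = 200), 200)
    fitc <- fit_wls_poly(m, Zc, order = 4, mu = mu, sigma = sigma)
    expect_equal(fitc$beta[, 1], seq_len(20) / 10, tolerance = 1e-8)
    expect_equal(fitc$beta[, -1], matrix(0, 20, 4), tolerance = 1e-8)
  })
  expect_error(fit_wls_poly(1:3, matrix(0, 3, 20), order = 3, mu = 0,
                            sigma = 1), "distinct masses")
})

test_that("order selection recovers a cubic and honours a singleton list", {
  withr::with_seed(22, {
    m <- runif(3000, 2000, 25000)
    mu <- mean(m); sigma <- sd(m)
    ms <- standardize_mass(m, mu, sigma)
    beta_true <- matrix(rnorm(20 * 4, sd = 0.5), 20, 4)
    Z <- outer(ms, 0:3, `^`) %*% t(beta_true) +
      matrix(rnorm(3000 * 20, sd = 0.05), 3000)
    test <- sample(3000, 300)
    train <- setdiff(seq_len(3000), test)
    sel <- select_order(m, Z, train, test, orders = 1:8, mu = mu,
                        sigma = sigma)
    expect_true(sel$order %in% c(3, 4))
    sel1 <- select_order(m, Z, train, test, orders = 5, mu = mu,
                         sigma = sigma)
    expect_identical(sel1$order, 5L)
    expect_error(select_order(m, Z, 1:100, 50:60, orders = 2, mu = mu,
                              sigma = sigma))
  })
})

test_that("predicted envelopes are valid compositions with offset centroids", {
  model <- small_model("DNA")
  grid <- seq(model$mass_range[1], model$mass_range[2], length.out = 40)
  env <- predict_envelope(grid, model)
  sums <- tapply(env$prob, env$mono_mass, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(env$prob >= 0))
  one <- predict_envelope(grid[3], model)
  expect_equal(one$centroid_mass[1], grid[3], tolerance = 1e-12)
  expect_equal(one$centroid_mass[2] - grid[3], model$mass_diffs[2],
               tolerance = 1e-12)
  expect_true(is.na(one$centroid_mass[21]))
  expect_error(predict_envelope(model$mass_range[2] + 1, model),
               "outside the model's valid range")
  expect_error(predict_envelope(model$mass_range[1] - 1, model),
               "outside the model's valid range")
})

test_that("average mass offsets start at zero and step by ~1.0025 Da", {
  db <- small_db("DNA")
  md <- compute_mass_diffs(db[db$mono_mass < attr(db, "mass_limit"), ][
    seq(1, 20000, by = 7), ])
  expect_identical(md[1], 0)
  expect_true(all(diff(md) > 0.99 & diff(md) < 1.01))
})

test_that("model bundles round-trip losslessly through disk", {
  model <- small_model("DNA")
  path <- withr::local_tempdir()
  export_bundle(model, path)
  back <- import_bundle(path)
  expect_identical(back$beta, model$beta)          # binary-identical
  expect_identical(back$mass_diffs, model$mass_diffs)
  expect_equal(back$mu, model$mu)
  expect_equal(back$sigma, model$sigma)
  expect_equal(back$mass_range, model$mass_range)
  expect_identical(back$order, model$order)
  expect_identical(back$backbone, model$backbone)
  # coefficient table is (order + 1) rows x 20 isotope columns
  tbl <- readr::read_csv(file.path(path, "coefficients.csv"),
                         show_col_types = FALSE)
  expect_identical(dim(tbl), c(model$order + 1L, 21L)) # + degree column
  # a bundle with a missing field is rejected by name
  meta <- jsonlite::read_json(file.path(path, "model.json"))
  meta$sigma <- NULL
  jsonlite::write_json(meta, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(import_bundle(path), "sigma")
  expect_error(import_bundle(withr::local_tempdir()), "model.json")
})

test_that("tidy and glance summarise the fitted model", {
  model <- small_model("DNA")
  td <- tidy(model)
  expect_identical(nrow(td), 20L * (model$order + 1L))
  expect_identical(td$estimate[1:(model$order + 1)], model$beta[1, ])
  gl <- glance(model)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$order, model$order)
  expect_gt(gl$mean_train_mse_alr, 0)
})
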