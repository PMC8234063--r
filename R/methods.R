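#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
print.oligo_model <- function(x, ...) {
  cat("<oligo_model> average", x$backbone,
      "isotope model (order", paste0(x$order, ")"), "\n")
  cat("  fitted on", format(x$n_fit, big.mark = ","),
      "compositions; isotope table", x$snapshot, "\n")
  cat(sprintf("  valid mass range: [%.4f, %.4f] Da\n",
              x$mass_range[1], x$mass_range[2]))
  cat(sprintf("  standardization: mu = %.4f, sigma = %.4f Da\n",
              x$mu, x$sigma))
  invisible(x)
}

#' Tidy the coefficients of a fitted isotope model
#'
#' @param x An `oligo_model`.
#' @param ... Unused.
#' @return Tibble with one row per (isotope, degree): columns `isotope`
#'   (1..20, ALR index), `degree` (power of standardized mass) and
#'   `estimate`.
#' @method tidy oligo_model
#' @export
tidy.oligo_model <- function(x, ...) {
  tibble::tibble(
    isotope = rep(seq_len(nrow(x$beta)), each = ncol(x$beta)),
    degree = rep(0:(ncol(x$beta) - 1L), nrow(x$beta)),
    estimate = as.vector(t(x$beta))
  )
}

#' One-row summary of a fitted isotope model
#'
#' @param x An `oligo_model`.
#' @param ... Unused.
#' @return One-row tibble: backbone, order, fitting-set size,
#'   standardization constants, valid mass range and mean training MSE in
#'   ALR space (`NA` for imported bundles without diagnostics).
#' @method glance oligo_model
#' @export
glance.oligo_model <- function(x, ...) {
  tibble::tibble(
    backbone = x$backbone,
    order = x$order,
    n_fit = x$n_fit,
    mu = x$mu,
    sigma = x$sigma,
    mass_lo = x$mass_range[1],
    mass_hi = x$mass_range[2],
    mean_train_mse_alr = if (is.null(x$diagnostics)) NA_real_ else
      mean(x$diagnostics$train_mse_alr, na.rm = TRUE)
  )
}
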