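# Lossless export/import of a fitted model as a documented plain-text bundle:
# model.json (scalars), coefficients.csv ((k+1) x 20, rows = coefficient
# degree 0..k, columns = isotope — the published layout), mass_diffs.csv.

#' Export a fitted model bundle
#'
#' Writes three files into `path`: `model.json` with the polynomial order,
#' backbone, standardization constants, valid mass range and isotope-table
#' snapshot; `coefficients.csv` with the coefficient table laid out as
#' (order + 1) rows by 20 isotope columns; and `mass_diffs.csv` with the
#' average centroid-mass offsets. Numbers are written at full double
#' precision ('.' decimal separator) so the round trip through
#' [import_bundle()] is exact.
#'
#' @param model An `oligo_model`.
#' @param path Directory to write into (created if missing).
#' @return `path`, invisibly.
#' @export
export_bundle <- function(model, path) {
  stopifnot(inherits(model, "oligo_model"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format = "oligoisotope-bundle-1",
    order = model$order,
    backbone = model$backbone,
    mu = model$mu,
    sigma = model$sigma,
    mass_range = model$mass_range,
    snapshot = model$snapshot,
    n_fit = model$n_fit
  )
  jsonlite::write_json(meta, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # numbers are serialised as %.17g strings: 17 significant digits are the
  # shortest representation guaranteed to round-trip a double exactly
  coef_tbl <- as.data.frame(apply(t(model$beta), 2, sprintf,
                                  fmt = "%.17g"))
  names(coef_tbl) <- paste0("isotope_", seq_len(nrow(model$beta)))
  coef_tbl <- cbind(degree = 0:model$order, coef_tbl)
  readr::write_csv(coef_tbl, file.path(path, "coefficients.csv"))
  readr::write_csv(
    tibble::tibble(isotope = seq_along(model$mass_diffs),
                   mass_diff = sprintf("%.17g", model$mass_diffs)),
    file.path(path, "mass_diffs.csv"))
  invisible(path)
}

#' Import a model bundle
#'
#' Reads a bundle written by [export_bundle()] back into an `oligo_model`.
#' Missing files or fields raise an error naming the offender.
#'
#' @param path Bundle directory.
#' @return An `oligo_model`.
#' @export
import_bundle <- function(path) {
  meta_path <- file.path(path, "model.json")
  if (!file.exists(meta_path)) stop("missing model.json in ", path,
                                    call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("order", "backbone", "mu", "sigma", "mass_range",
                  "snapshot")) {
    if (is.null(meta[[field]])) {
      stop("model.json is missing required field '", field, "'",
           call. = FALSE)
    }
  }
  # base read.csv parses doubles with correctly rounded strtod, which the
  # exact round-trip contract relies on
  coef_tbl <- utils::read.csv(file.path(path, "coefficients.csv"))
  if (!isTRUE(all.equal(as.numeric(coef_tbl$degree),
                        as.numeric(0:meta$order)))) {
    stop("coefficients.csv degree column does not match the stated order",
         call. = FALSE)
  }
  beta <- t(as.matrix(coef_tbl[, -1L, drop = FALSE]))
  dimnames(beta) <- NULL
  md <- utils::read.csv(file.path(path, "mass_diffs.csv"))
  structure(
    list(beta = beta, order = as.integer(meta$order),
         backbone = meta$backbone, mu = meta$mu, sigma = meta$sigma,
         mass_range = as.numeric(meta$mass_range),
         mass_diffs = md$mass_diff, snapshot = meta$snapshot,
         n_fit = meta$n_fit, selection = NULL, diagnostics = NULL),
    class = "oligo_model"
  )
}
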