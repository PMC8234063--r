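# ggplot2 figures for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stem plot of an aggregated isotope distribution
#'
#' @param object An `isotope_distribution` from [isotope_distribution()] or
#'   [convolution_oracle()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot isotope_distribution
#' @export
autoplot.isotope_distribution <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$centroid_mass, y = .data$prob)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$centroid_mass,
                                       yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "centroid mass (Da)", y = "probability",
                  title = attr(object, "formula")) +
    ggplot2::theme_minimal()
}

#' Stem plot of a predicted envelope
#'
#' Shows the 20 predicted isotope probabilities at their reconstructed
#' centroid masses (the closure term, which has no centroid, is omitted).
#'
#' @param object An `oligo_envelope` from [predict_envelope()].
#' @param ... Unused.
#' @return A ggplot (facetted by input mass when several were predicted).
#' @method autoplot oligo_envelope
#' @export
autoplot.oligo_envelope <- function(object, ...) {
  dat <- object[!is.na(object$centroid_mass), ]
  p <- ggplot2::ggplot(dat,
                       ggplot2::aes(x = .data$centroid_mass,
                                    y = .data$prob)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$centroid_mass,
                                       yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "centroid mass (Da)", y = "predicted probability",
                  title = paste("average", attr(object, "backbone"),
                                "isotope envelope")) +
    ggplot2::theme_minimal()
  if (length(unique(dat$mono_mass)) > 1L) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$mono_mass),
                                 scales = "free_x")
  }
  p
}

#' Predicted isotope probabilities across the mass range
#'
#' Plots each isotope's predicted probability as a function of monoisotopic
#' mass over the model's valid range: the low-mass region is dominated by
#' the fast-declining monoisotopic variant, and successive variants peak at
#' increasing masses.
#'
#' @param model An `oligo_model`.
#' @param n_grid Number of mass grid points.
#' @return A ggplot.
#' @export
plot_model_curves <- function(model, n_grid = 200L) {
  grid <- seq(model$mass_range[1], model$mass_range[2],
              length.out = n_grid)
  X <- inverse_alr(.predict_alr(model$beta, grid, model$mu, model$sigma))
  dat <- tibble::tibble(
    mono_mass = rep(grid, times = ncol(X)),
    peak = factor(rep(seq_len(ncol(X)), each = length(grid))),
    prob = as.vector(X)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mono_mass, y = .data$prob,
                                    colour = .data$peak)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "monoisotopic mass (Da)",
                  y = "predicted probability", colour = "isotope",
                  title = paste("average", model$backbone, "model, order",
                                model$order)) +
    ggplot2::theme_minimal()
}

#' Test-MSE order-selection curve
#'
#' @param selection The `mse` tibble returned by [select_order()] (or stored
#'   on a model fitted with `order = "auto"`).
#' @return A ggplot of mean test MSE (across isotopes) versus order.
#' @export
plot_order_selection <- function(selection) {
  dat <- selection |>
    dplyr::group_by(.data$order) |>
    dplyr::summarise(mean_mse = mean(.data$test_mse_alr), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$order, y = .data$mean_mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "polynomial order", y = "mean test MSE (ALR space)") +
    ggplot2::theme_minimal()
}
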