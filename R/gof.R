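# Goodness-of-fit statistics for observed isotope envelopes against model
# predictions, and the label-free DNA-vs-RNA backbone classifier built on
# them. Envelopes may be partially observed (gapped index sets are allowed);
# each statistic averages over the peaks actually used.

#' Construct an observed envelope
#'
#' @param index Isotope indices present (1 = monoisotopic), strictly
#'   increasing, subset of 1..20.
#' @param intensity Nonnegative intensities (arbitrary units).
#' @param mono_mass Monoisotopic mass in Da (known even when peak 1 is not
#'   observed).
#' @param mass Optional observed peak masses (Da).
#' @param charge Optional charge state.
#' @return An `observed_envelope` tibble.
#' @export
observed_envelope <- function(index, intensity, mono_mass, mass = NULL,
                              charge = NULL) {
  stopifnot(length(index) == length(intensity), length(index) >= 2,
            all(diff(index) > 0), all(is.finite(intensity)),
            all(intensity >= 0))
  out <- tibble::tibble(index = as.integer(index),
                        mass = if (is.null(mass)) NA_real_ else mass,
                        intensity = intensity)
  class(out) <- c("observed_envelope", class(out))
  attr(out, "mono_mass") <- mono_mass
  attr(out, "charge") <- charge
  out
}

#' Read an observed envelope from a two-column table
#'
#' Reads a CSV/TSV of (mass, intensity) centroids and assigns isotope indices
#' by rounding `(mass - mono_mass) / spacing` to the nearest integer; peaks
#' further than `window` Da from their assigned slot are dropped with a
#' warning.
#'
#' @param path File with columns mass, intensity (header optional).
#' @param mono_mass Known monoisotopic mass in Da.
#' @param spacing Average per-nucleon mass spacing used for index assignment.
#' @param window Acceptance half-window in Da.
#' @return An `observed_envelope` tibble.
#' @export
read_envelope <- function(path, mono_mass, spacing = 1.00235, window = 0.3) {
  tbl <- utils::read.csv(path, header = FALSE,
                         sep = if (grepl("\\.tsv$", path)) "\t" else ",",
                         strip.white = TRUE)
  if (is.character(tbl[[1]]) || is.character(tbl[[2]])) {
    tbl <- tbl[-1L, , drop = FALSE]  # header row
    tbl[] <- lapply(tbl, as.numeric)
  }
  names(tbl)[1:2] <- c("mass", "intensity")
  off <- (tbl$mass - mono_mass) / spacing
  idx <- as.integer(round(off)) + 1L
  dev <- abs(tbl$mass - (mono_mass + (idx - 1L) * spacing))
  ok <- dev <= window & idx >= 1L
  if (any(!ok)) {
    warning(sum(!ok), " peak(s) outside the +/-", window,
            " Da index-assignment window were dropped", call. = FALSE)
  }
  o <- order(idx[ok])
  observed_envelope(idx[ok][o], tbl$intensity[ok][o], mono_mass,
                    mass = tbl$mass[ok][o])
}

# Predicted ALR vector / 21-composition for one mass under a model.
.model_alr <- function(model, mono_mass) {
  drop(.predict_alr(model$beta, mono_mass, model$mu, model$sigma))
}

#' Mean squared error in ALR space
#'
#' Transforms the observed intensities to log-ratios against the observed
#' monoisotopic peak and averages the squared differences to the predicted
#' log-ratios over the observed (non-reference) isotope indices. Invariant to
#' rescaling all intensities; requires the monoisotopic peak to be observed.
#'
#' @param envelope An `observed_envelope`.
#' @param predicted Either a numeric ALR vector (length 20, entry j =
#'   predicted log-ratio of isotope j+1) or an `oligo_model` (the prediction
#'   is made at the envelope's monoisotopic mass).
#' @return Nonnegative score (0 for a perfect match up to scale).
#' @export
mse_alr <- function(envelope, predicted) {
  if (inherits(predicted, "oligo_model")) {
    predicted <- .model_alr(predicted, attr(envelope, "mono_mass"))
  }
  obs <- observed_alr(envelope$intensity, envelope$index)
  z <- predicted[obs$index - 1L]
  if (anyNA(z)) stop("observed isotope index beyond the predicted range",
                     call. = FALSE)
  mean((obs$t - z)^2)
}

#' Mean Pearson chi-squared error in intensity space
#'
#' Estimates the total intensity as the ratio of summed observed intensities
#' to summed predicted probabilities over the observed indices, forms
#' expected intensities `E = N * x`, and averages `(O - E)^2 / E` over the
#' observed peaks. Applicable when the monoisotopic peak is missing; scales
#' linearly with total intensity at fixed relative misfit, so scores are
#' comparable only within one acquisition.
#'
#' @param envelope An `observed_envelope`.
#' @param predicted Either a 21-part probability vector (peaks 1..20 plus
#'   closure) or an `oligo_model`.
#' @return List with `score` (mean chi-squared error) and `N` (estimated
#'   total intensity).
#' @export
chi2_simplex <- function(envelope, predicted) {
  if (inherits(predicted, "oligo_model")) {
    env_mass <- attr(envelope, "mono_mass")
    predicted <- drop(inverse_alr(.model_alr(predicted, env_mass)))
  }
  x <- predicted[envelope$index]
  if (anyNA(x) || all(x == 0)) {
    stop("predicted probabilities are zero on every observed index",
         call. = FALSE)
  }
  N <- sum(envelope$intensity) / sum(x)
  E <- N * x
  pos <- E > 0
  list(score = mean((envelope$intensity[pos] - E[pos])^2 / E[pos]), N = N)
}

#' Score an envelope and classify its backbone
#'
#' Scores the envelope against the predicted envelopes of a DNA and an RNA
#' model at the same monoisotopic mass and returns the backbone with the
#' lower ALR mean squared error (falling back to the chi-squared statistic
#' when the monoisotopic peak is unobserved). Exactly equal scores give
#' `"ambiguous"`.
#'
#' @param envelope An `observed_envelope` (with its `mono_mass` attribute).
#' @param dna_model,rna_model Fitted `oligo_model` objects.
#' @return One-row tibble: `label`, `statistic` (which score decided),
#'   `score_dna`, `score_rna`.
#' @export
classify_backbone <- function(envelope, dna_model, rna_model) {
  has_mono <- 1L %in% envelope$index &&
    envelope$intensity[match(1L, envelope$index)] > 0
  if (has_mono) {
    statistic <- "mse_alr"
    s_dna <- mse_alr(envelope, dna_model)
    s_rna <- mse_alr(envelope, rna_model)
  } else {
    statistic <- "chi2_simplex"
    s_dna <- chi2_simplex(envelope, dna_model)$score
    s_rna <- chi2_simplex(envelope, rna_model)$score
  }
  label <- if (s_dna < s_rna) "DNA" else if (s_rna < s_dna) "RNA" else
    "ambiguous"
  tibble::tibble(label = label, statistic = statistic,
                 score_dna = s_dna, score_rna = s_rna)
}

#' Score a set of envelopes against both backbone models
#'
#' @param envelopes List of `observed_envelope` objects (optionally named).
#' @param dna_model,rna_model Fitted `oligo_model` objects.
#' @return Tibble with one row per envelope: `id`, `n_peaks`,
#'   `sum_intensity`, `mse_alr` (`NA` when the monoisotopic peak is
#'   unobserved), `mpcse`, `N`, `label`.
#' @export
score_envelopes <- function(envelopes, dna_model, rna_model) {
  ids <- names(envelopes)
  if (is.null(ids)) ids <- as.character(seq_along(envelopes))
  purrr::map2_dfr(envelopes, ids, function(env, id) {
    cls <- classify_backbone(env, dna_model, rna_model)
    m <- if (cls$statistic == "mse_alr") cls$score_dna else NA_real_
    chi <- chi2_simplex(env, dna_model)
    tibble::tibble(id = id, n_peaks = nrow(env),
                   sum_intensity = sum(env$intensity),
                   mse_alr = m, mpcse = chi$score, N = chi$N,
                   label = cls$label)
  })
}
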