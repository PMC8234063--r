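# Synthetic inputs: seeded composition samples from the database and
# theoretical isotope envelopes with controllable multiplicative noise,
# detection thresholding and monoisotopic-peak dropout — emulating the
# structure of centroided TOF envelope traces without modelling raw spectra.

#' Noise specification for synthetic envelopes
#'
#' @param sigma Standard deviation of the per-peak multiplicative log-normal
#'   perturbation (0 = noiseless).
#' @param threshold Detection threshold as a fraction of the most intense
#'   peak; peaks below it are dropped (emulating a baseline intensity
#'   filter). In `[0, 1)`.
#' @param drop_monoisotopic Remove the monoisotopic peak regardless of
#'   intensity (it is not always retrievable in practice).
#' @param total_intensity Total ion count the theoretical probabilities are
#'   scaled to before perturbation.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, threshold = 0, drop_monoisotopic = FALSE,
                       total_intensity = 1e4) {
  stopifnot(sigma >= 0, threshold >= 0, threshold < 1, total_intensity > 0)
  structure(list(sigma = sigma, threshold = threshold,
                 drop_monoisotopic = drop_monoisotopic,
                 total_intensity = total_intensity),
            class = "noise_spec")
}

#' Sample nucleotide compositions from the restricted database
#'
#' Uniform or mass-stratified (equal counts per mass decile) seeded sampling.
#' Stratified sampling keeps sparse mass regions represented in desk-scale
#' model fits.
#'
#' @param backbone `"DNA"` or `"RNA"`.
#' @param n Number of compositions.
#' @param mass_stratified Equal counts per mass decile (default `FALSE`).
#' @param seed Integer seed.
#' @param db Optional prebuilt database tibble to sample from (avoids
#'   re-enumeration); built on demand otherwise.
#' @param restrict Sample only records below the restricted mass limit
#'   (default `TRUE`).
#' @return Tibble of sampled compositions (same columns as the database).
#' @export
sample_compositions <- function(backbone, n, mass_stratified = FALSE,
                                seed = 1L, db = NULL, restrict = TRUE) {
  stopifnot(n >= 1)
  if (is.null(db)) db <- build_oligo_db(backbone)
  limit <- attr(db, "mass_limit")
  pool <- if (restrict && !is.null(limit)) which(db$mono_mass < limit) else
    seq_len(nrow(db))
  idx <- withr::with_seed(as.integer(seed), {
    if (mass_stratified) {
      dec <- cut(db$mono_mass[pool],
                 breaks = stats::quantile(db$mono_mass[pool],
                                          probs = seq(0, 1, 0.1)),
                 include.lowest = TRUE, labels = FALSE)
      per <- diff(round(seq(0, n, length.out = 11L)))
      unlist(purrr::map(1:10, function(d) {
        cand <- pool[dec == d]
        sample(cand, min(per[d], length(cand)), replace = FALSE)
      }))
    } else {
      sample(pool, min(n, length(pool)), replace = FALSE)
    }
  })
  out <- db[sort(idx), ]
  attr(out, "backbone") <- attr(db, "backbone")
  attr(out, "mass_limit") <- limit
  out
}

#' Generate a synthetic observed isotope envelope
#'
#' Computes the theoretical aggregated isotope distribution of a composition,
#' scales it to a total intensity, perturbs each peak with multiplicative
#' log-normal noise, and removes peaks below the detection threshold (and
#' optionally the monoisotopic peak). With `sigma = 0` and `threshold = 0`
#' the envelope is exactly proportional to theory and both goodness-of-fit
#' statistics are zero against it.
#'
#' @param composition One-row composition tibble or count vector
#'   `c(n_A, n_C, n_G, n_TU)`.
#' @param backbone `"DNA"` or `"RNA"`.
#' @param charge Optional charge state recorded on the envelope (display
#'   only; intensities are charge-independent here).
#' @param noise A [noise_spec()].
#' @param K Number of theoretical peaks generated before thresholding.
#' @param seed Integer seed; envelopes are reproducible given the seed.
#' @return An `observed_envelope` tibble with columns `index`, `mass`,
#'   `intensity`, and attributes `mono_mass`, `charge`, `backbone`.
#' @export
synth_envelope <- function(composition, backbone, charge = NULL,
                           noise = noise_spec(), K = 20L, seed = 1L) {
  if (is.data.frame(composition)) {
    stopifnot(nrow(composition) == 1L)
  }
  fml <- composition_formula(composition, backbone)
  dist <- isotope_distribution(fml, K = K)
  intensity <- withr::with_seed(as.integer(seed), {
    dist$prob * noise$total_intensity *
      exp(stats::rnorm(K, mean = 0, sd = noise$sigma))
  })
  keep <- intensity >= noise$threshold * max(intensity)
  if (noise$drop_monoisotopic) keep[1L] <- FALSE
  if (!any(keep)) stop("all peaks fell below the detection threshold",
                       call. = FALSE)
  out <- tibble::tibble(index = dist$peak[keep],
                        mass = dist$centroid_mass[keep],
                        intensity = intensity[keep])
  class(out) <- c("observed_envelope", class(out))
  attr(out, "mono_mass") <- attr(dist, "mono_mass")
  attr(out, "charge") <- charge
  attr(out, "backbone") <- .check_backbone(backbone)
  out
}

#' Write an envelope trace to a CSV file
#'
#' File format consumed by [cmd_score()]: a first comment line
#' `# mono_mass=<value>` followed by headerless `mass,intensity` rows at full
#' double precision.
#'
#' @param envelope An `observed_envelope` with non-missing peak masses.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(envelope, path) {
  stopifnot(inherits(envelope, "observed_envelope"),
            !anyNA(envelope$mass))
  lines <- c(
    sprintf("# mono_mass=%.15g", attr(envelope, "mono_mass")),
    sprintf("%.15g,%.15g", envelope$mass, envelope$intensity)
  )
  writeLines(lines, path)
  invisible(path)
}
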