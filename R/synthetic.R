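#' Configuration for the synthetic NIR spectra generator
#'
#' Describes a caricature of a multi-grade NIR absorbance study: smooth
#' class-specific spectra built from Gaussian absorption bands on a
#' polynomial baseline, degraded by per-sample multiplicative scatter
#' and additive noise. The defaults emulate a 6-grade tea-leaf infusion
#' study: 6 classes x 60 samples x 1557 channels spanning 10000 down to
#' 4000 cm^-1, a dominant absorption band at 7200 cm^-1 (the
#' O-H / N-H stretching region), and an extra-noisy window between 5500
#' and 5100 cm^-1.
#'
#' Class identity enters only through small (few percent) amplitude
#' offsets on selected bands: one band increases with grade, one
#' decreases, and one alternates, so classes are neither identical nor
#' collinear. Raw spectra of different classes overlap heavily because
#' the +-20% scatter factor dwarfs the class signal; SNV removes the
#' scatter exactly, which is what makes the downstream pipeline able to
#' separate the classes.
#'
#' @param classes number of classes c.
#' @param samples_per_class samples per class.
#' @param channels number of wavelength channels d.
#' @param wavenumber_range length-2 vector, first to last channel
#'   position in cm^-1 (default descending 10000 -> 4000).
#' @param peaks data frame with columns `center` (cm^-1), `width`
#'   (Gaussian sd, cm^-1), `amplitude` (absorbance units).
#' @param class_offsets c x nrow(peaks) matrix; entry (g, p) is the
#'   relative amplitude offset of peak p in class g (amplitude scaled by
#'   1 + offset). Default: +-5% graded on the dominant band, -+4% graded
#'   on a second band, alternating +-3% on a third.
#' @param baseline polynomial coefficients (constant first) in the
#'   normalized channel position 0..1.
#' @param scatter_range positive length-2 range; each sample's
#'   multiplicative scatter factor is log-uniform in it.
#' @param noise_sd additive Gaussian noise sd (absorbance units), all
#'   channels.
#' @param noise_band length-2 wavenumber window receiving extra noise.
#' @param noise_band_sd sd of the extra noise inside `noise_band`.
#' @param seed default RNG seed used by [synthetic_spectra()].
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(classes = 6L, samples_per_class = 60L,
                             channels = 1557L,
                             wavenumber_range = c(10000, 4000),
                             peaks = NULL, class_offsets = NULL,
                             baseline = c(0.2, 0.1),
                             scatter_range = c(0.8, 1.25),
                             noise_sd = 0.005,
                             noise_band = c(5500, 5100),
                             noise_band_sd = 0.015,
                             seed = 20230126L) {
  if (is.null(peaks))
    peaks <- data.frame(
      center    = c(8700, 7200, 6900, 5800, 5200, 4400),
      width     = c(350, 120, 200, 180, 250, 150),
      amplitude = c(0.25, 1.00, 0.45, 0.35, 0.50, 0.60))
  stopifnot(classes >= 1, samples_per_class >= 1, channels >= 2,
            all(c("center", "width", "amplitude") %in% names(peaks)),
            length(scatter_range) == 2, all(scatter_range > 0),
            noise_sd >= 0, noise_band_sd >= 0)
  if (is.null(class_offsets)) {
    grade <- if (classes > 1) (seq_len(classes) - (classes + 1) / 2) /
      ((classes - 1) / 2) else 0  # centered grade in [-1, 1]
    class_offsets <- matrix(0, classes, nrow(peaks))
    np <- nrow(peaks)
    class_offsets[, min(2L, np)] <- 0.05 * grade
    if (np >= 3) class_offsets[, 3L] <- -0.04 * grade
    if (np >= 6) class_offsets[, 6L] <- 0.03 * rep_len(c(1, -1), classes)
  }
  class_offsets <- as.matrix(class_offsets)
  if (nrow(class_offsets) != classes || ncol(class_offsets) != nrow(peaks))
    stop("class_offsets must be ", classes, " x ", nrow(peaks))
  structure(list(classes = as.integer(classes),
                 samples_per_class = as.integer(samples_per_class),
                 channels = as.integer(channels),
                 wavenumber_range = as.numeric(wavenumber_range),
                 peaks = peaks, class_offsets = class_offsets,
                 baseline = baseline, scatter_range = scatter_range,
                 noise_sd = noise_sd, noise_band = noise_band,
                 noise_band_sd = noise_band_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Noise-free class template spectra
#'
#' @param config a [synthetic_config()].
#' @return c x d matrix of class template spectra (baseline plus
#'   class-offset Gaussian bands), with the wavenumber grid as the
#'   `"wavenumbers"` attribute.
#' @export
synthetic_templates <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  wn <- seq(config$wavenumber_range[1], config$wavenumber_range[2],
            length.out = config$channels)
  pos <- seq(0, 1, length.out = config$channels)
  base <- rep(0, config$channels)
  for (k in seq_along(config$baseline))
    base <- base + config$baseline[k] * pos^(k - 1)
  tmpl <- matrix(0, config$classes, config$channels)
  for (g in seq_len(config$classes)) {
    s <- base
    for (p in seq_len(nrow(config$peaks))) {
      amp <- config$peaks$amplitude[p] * (1 + config$class_offsets[g, p])
      s <- s + amp * exp(-(wn - config$peaks$center[p])^2 /
                           (2 * config$peaks$width[p]^2))
    }
    tmpl[g, ] <- s
  }
  attr(tmpl, "wavenumbers") <- wn
  tmpl
}

#' Generate a synthetic labelled NIR spectra set
#'
#' Each sample is `scatter_factor * template(class) + noise`, with the
#' per-sample scatter factor log-uniform in `config$scatter_range`,
#' i.i.d. Gaussian channel noise of sd `config$noise_sd`, and extra
#' noise of sd `config$noise_band_sd` inside `config$noise_band`.
#' Bitwise deterministic given `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (default `config$seed`).
#' @return A [spectra_set()] with `classes * samples_per_class` samples,
#'   labels `"grade1" ... "gradec"`.
#' @export
synthetic_spectra <- function(config = synthetic_config(), seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  tmpl <- synthetic_templates(config)
  wn <- attr(tmpl, "wavenumbers")
  n <- config$classes * config$samples_per_class
  d <- config$channels
  in_band <- wn <= max(config$noise_band) & wn >= min(config$noise_band)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(as.integer(seed))
  scatter <- exp(stats::runif(n, log(config$scatter_range[1]),
                              log(config$scatter_range[2])))
  labels <- rep(seq_len(config$classes), each = config$samples_per_class)
  X <- tmpl[labels, , drop = FALSE] * scatter
  if (config$noise_sd > 0)
    X <- X + matrix(stats::rnorm(n * d, sd = config$noise_sd), n, d)
  if (config$noise_band_sd > 0 && any(in_band))
    X[, in_band] <- X[, in_band] +
      matrix(stats::rnorm(n * sum(in_band), sd = config$noise_band_sd),
             n, sum(in_band))
  spectra_set(X, wn, paste0("grade", labels),
              sample_ids = sprintf("g%d_s%02d", labels,
                                   rep(seq_len(config$samples_per_class),
                                       times = config$classes)))
}
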