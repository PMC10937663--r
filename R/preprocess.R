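#' Reconstruct a log-intensity volume from raw spectra
#'
#' Standard spectral-domain OCT reconstruction: per A-scan the background
#' spectrum is subtracted, the spectrum is linearly resampled onto a uniform
#' wavenumber grid (k = 2 pi / lambda), apodized, and inverse Fourier
#' transformed; the output is `10*log10` of the squared magnitude of the
#' positive-depth half. The result is not yet noise-normalized.
#'
#' @param raw A [raw_spectra()] object (>= 8 spectral pixels).
#' @param window Apodization window: `"hann"` (default), `"hamming"` or
#'   `"none"`.
#' @param refractive_index Refractive index stored on the output volume for
#'   later optical-to-physical conversion.
#' @return An [oct_volume()]; depth pixels are uniform in optical path, with
#'   axial pitch implied by the sampled wavenumber span.
#' @export
reconstruct <- function(raw, window = c("hann", "hamming", "none"),
                        refractive_index = 1.4) {
  stopifnot(inherits(raw, "raw_spectra"))
  window <- match.arg(window)
  n <- length(raw$wavelength_nm)
  if (n < 8L) stop("reconstruct: need at least 8 spectral pixels")
  lambda_um <- raw$wavelength_nm / 1000
  k <- 2 * pi / lambda_um
  ord <- order(k)
  k_uniform <- seq(min(k), max(k), length.out = n)
  w <- switch(window,
    hann = 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)),
    hamming = 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1)),
    none = rep(1, n)
  )
  d <- dim(raw$spectra)
  nz <- n %/% 2L
  out <- array(NA_real_, dim = c(d[1], d[2], nz))
  flat <- matrix(raw$spectra, nrow = d[1] * d[2], ncol = n)
  bg <- raw$background
  all_zero <- FALSE
  for (i in seq_len(nrow(flat))) {
    s <- flat[i, ]
    if (all(s == 0)) all_zero <- TRUE
    s <- s - bg
    s_k <- approx(k[ord], s[ord], xout = k_uniform, rule = 2)$y
    a <- fft(s_k * w, inverse = TRUE) / n
    out[(i - 1L) %% d[1] + 1L, (i - 1L) %/% d[1] + 1L, ] <-
      10 * log10(Mod(a[seq_len(nz)])^2 + 1e-30)
  }
  if (all_zero) warning("reconstruct: all-zero spectrum encountered; returning noise-only A-scan(s)")
  oct_volume(
    out,
    axial_pitch_um = axial_pitch_from_grid(raw$wavelength_nm),
    lateral_pitch_um = raw$lateral_pitch_um,
    refractive_index = refractive_index
  )
}

#' Normalize the noise floor to 0 dB
#'
#' Estimates the noise intensity as the mean dB level over a deep region
#' where the OCT signal is fully attenuated, and subtracts it from the whole
#' logarithmic scan, so that signal-free voxels average 0 dB.
#'
#' @param vol An [oct_volume()].
#' @param noise_region Integer depth-index range (vector whose `range()` is
#'   used) over which to measure the noise; default: the deepest 10% of
#'   samples.
#' @return The normalized [oct_volume()] with `noise_normalized = TRUE`.
#' @export
normalize_noise <- function(vol, noise_region = NULL) {
  stopifnot(inherits(vol, "oct_volume"))
  nz <- dim(vol$data)[3]
  if (is.null(noise_region)) {
    noise_region <- seq.int(max(1L, nz - ceiling(nz / 10) + 1L), nz)
  }
  noise_region <- seq.int(min(noise_region), max(noise_region))
  if (length(noise_region) == 0L || any(noise_region < 1) ||
      any(noise_region > nz)) {
    stop("normalize_noise: empty or out-of-range noise region")
  }
  region <- vol$data[, , noise_region, drop = FALSE]
  level <- mean(region)
  # a region still carrying signal is a user error worth flagging: compare
  # against the volume-wide median as a crude tissue level
  if (level > median(vol$data) + 3) {
    warning("normalize_noise: noise region mean exceeds the volume median; region may overlap tissue")
  }
  vol$data <- vol$data - level
  vol$noise_normalized <- TRUE
  vol
}

#' Convert optical path length to physical length
#'
#' OCT measures optical path; dividing by the refractive index gives the
#' physical (geometric) length in tissue.
#'
#' @param length_optical Length in optical path units (any unit).
#' @param n Refractive index (>= 1); default 1.4.
#' @return Physical length in the same unit.
#' @examples
#' optical_to_physical(5.5, 1.4) # axial resolution: ~3.9 um in tissue
#' optical_to_physical(3.6, 1.4) # depth range: ~2.6 mm physical
#' @export
optical_to_physical <- function(length_optical, n = 1.4) {
  if (any(n < 1)) stop("optical_to_physical: refractive index must be >= 1")
  length_optical / n
}
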