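#' OCT log-intensity volume
#'
#' The substrate of the whole pipeline: a 3-D array of log intensity in dB
#' (`10 * log10(I)`), indexed `[x, y, z]` with `z = 1` the shallowest sample.
#' Depth is stored in optical path length; physical (tissue) depth is the
#' optical depth divided by the refractive index.
#'
#' @param data 3-D numeric array `[x, y, z]` of log intensity (dB).
#' @param axial_pitch_um Optical path length per depth pixel (micrometres).
#' @param lateral_pitch_um Length-2 numeric, micrometres per pixel along x
#'   and y.
#' @param refractive_index Group refractive index used to convert optical to
#'   physical depth (default 1.4, typical for tissue at 1300 nm).
#' @param noise_normalized Logical; `TRUE` once the noise floor has been
#'   subtracted so that signal-free regions average 0 dB.
#' @param seed Optional integer recording the random seed that generated the
#'   volume (synthetic data provenance).
#'
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(data, axial_pitch_um, lateral_pitch_um,
                       refractive_index = 1.4, noise_normalized = FALSE,
                       seed = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!all(is.finite(data))) {
    stop("oct_volume: data must be finite")
  }
  if (axial_pitch_um <= 0 || any(lateral_pitch_um <= 0)) {
    stop("oct_volume: pitches must be positive")
  }
  if (refractive_index < 1) {
    stop("oct_volume: refractive index must be >= 1")
  }
  structure(
    list(
      data = data,
      axial_pitch_um = axial_pitch_um,
      lateral_pitch_um = rep_len(as.numeric(lateral_pitch_um), 2L),
      refractive_index = refractive_index,
      noise_normalized = isTRUE(noise_normalized),
      seed = seed
    ),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<oct_volume> %d x %d x %d voxels, axial %.3g um (optical), lateral %.3g x %.3g um\n",
    d[1], d[2], d[3], x$axial_pitch_um,
    x$lateral_pitch_um[1], x$lateral_pitch_um[2]
  ))
  cat(sprintf(
    "  n = %.2f; noise-normalized: %s; dB range [%.1f, %.1f]\n",
    x$refractive_index, x$noise_normalized,
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$data)

# physical depth per pixel, micrometres
physical_pitch_um <- function(vol) vol$axial_pitch_um / vol$refractive_index

#' Binary 3-D vessel mask
#'
#' @param mask 3-D logical array on the same lateral grid as its source
#'   volume.
#' @param frame Coordinate frame: `"native"` (scanner depth axis) or
#'   `"flattened"` (depth 0 = tissue surface after alignment).
#' @param crop_um Depth extent retained below the surface (micrometres of
#'   tissue), or `NA` when uncropped.
#' @param provenance Which method produced the mask: `"conventional"`
#'   (attenuation-compensated thresholding), `"dl"` (U-Net), or
#'   `"ground_truth"` (synthetic geometry).
#'
#' @return An object of class `vessel_mask`.
#' @export
vessel_mask <- function(mask, frame = c("native", "flattened"),
                        crop_um = NA_real_,
                        provenance = c("conventional", "dl", "ground_truth")) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  structure(
    list(
      mask = mask,
      frame = match.arg(frame),
      crop_um = crop_um,
      provenance = match.arg(provenance)
    ),
    class = "vessel_mask"
  )
}

#' @export
print.vessel_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<vessel_mask> %d x %d x %d, frame %s, provenance %s, %.2f%% vessel\n",
    d[1], d[2], d[3], x$frame, x$provenance, 100 * mean(x$mask)
  ))
  invisible(x)
}

#' @export
dim.vessel_mask <- function(x) dim(x$mask)

#' Raw spectral-domain OCT frames
#'
#' Wavelength-sampled interferograms prior to reconstruction, plus the
#' background (reference-arm) spectrum.
#'
#' @param spectra 3-D numeric array `[x, y, spectral pixel]` of detector
#'   counts.
#' @param wavelength_nm Strictly monotonic wavelength grid (nanometres), one
#'   entry per spectral pixel.
#' @param background Background spectrum, same length as `wavelength_nm`.
#' @param lateral_pitch_um Length-2 numeric, micrometres per pixel (x, y).
#'
#' @return An object of class `raw_spectra`.
#' @export
raw_spectra <- function(spectra, wavelength_nm, background,
                        lateral_pitch_um = c(12, 12)) {
  stopifnot(is.array(spectra), length(dim(spectra)) == 3L)
  dl <- diff(wavelength_nm)
  if (length(wavelength_nm) != dim(spectra)[3] ||
      !(all(dl > 0) || all(dl < 0))) {
    stop("raw_spectra: wavelength grid must be strictly monotonic and match the spectral dimension")
  }
  if (length(background) != dim(spectra)[3]) {
    stop("raw_spectra: background length must equal the spectral dimension")
  }
  structure(
    list(
      spectra = spectra,
      wavelength_nm = as.numeric(wavelength_nm),
      background = as.numeric(background),
      lateral_pitch_um = rep_len(as.numeric(lateral_pitch_um), 2L)
    ),
    class = "raw_spectra"
  )
}

# axial pitch (optical um per depth pixel) implied by a wavelength grid:
# pi over the uniform-k span sampled by the reconstruction.
axial_pitch_from_grid <- function(wavelength_nm) {
  lambda_um <- wavelength_nm / 1000
  k <- 2 * pi / lambda_um
  n <- length(k)
  dk <- (max(k) - min(k)) / (n - 1)
  pi / (n * dk)
}
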