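#' Estimate the axial system response from a calibration scan
#'
#' The confocal collection function and the spectrometer sensitivity
#' roll-off jointly impose a depth-dependent response `H(z)` on every
#' A-scan. Scanning a homogeneous, low-scattering phantom of known
#' attenuation isolates `H(z)`: the lateral mean dB profile, with the
#' phantom's own round-trip decay added back, equals `H(z)` up to a
#' constant, which is fixed by re-zeroing at the profile maximum.
#'
#' The estimate is restricted to depths where the mean signal is at least
#' `min_signal_db` above the (normalized) noise floor and held flat beyond.
#'
#' @param cal Noise-normalized [oct_volume()] of the homogeneous phantom.
#' @param mu_cal Attenuation coefficient of the calibration phantom,
#'   1/mm of physical depth.
#' @param min_signal_db Depth validity cutoff, dB above the noise floor
#'   (default 3).
#' @param homogeneity_db Maximum allowed lateral standard deviation of the
#'   per-A-scan mean dB (default 3); larger values indicate the scan is not
#'   of a homogeneous phantom.
#' @return A `calibration_profile`: list with `h_db` (length-nz response,
#'   0 dB at its peak), `mu_cal`, `axial_pitch_um`, `valid` (logical per
#'   depth).
#' @export
estimate_system_response <- function(cal, mu_cal, min_signal_db = 3,
                                     homogeneity_db = 3) {
  stopifnot(inherits(cal, "oct_volume"))
  if (!cal$noise_normalized) {
    warning("estimate_system_response: calibration volume is not noise-normalized")
  }
  ascan_means <- apply(cal$data, c(1, 2), mean)
  if (sd(ascan_means) > homogeneity_db) {
    stop("calibration not homogeneous: lateral dB variability exceeds bound")
  }
  prof <- apply(cal$data, 3, mean)
  valid <- prof >= min_signal_db
  if (!any(valid)) stop("calibration scan has no depths above the noise floor")
  z_mm <- (seq_along(prof) - 1) * physical_pitch_um(cal) / 1000
  h <- prof + db_per_mm(mu_cal) * z_mm
  # hold flat outside the valid depth range; re-zero at the valid-range peak
  first_valid <- min(which(valid))
  last_valid <- max(which(valid))
  if (first_valid > 1) h[seq_len(first_valid - 1)] <- h[first_valid]
  if (last_valid < length(h)) h[(last_valid + 1):length(h)] <- h[last_valid]
  h <- h - max(h[first_valid:last_valid])
  structure(
    list(
      h_db = h, mu_cal = mu_cal,
      axial_pitch_um = cal$axial_pitch_um, valid = valid
    ),
    class = "calibration_profile"
  )
}

#' Remove the axial system response from a volume
#'
#' Subtracts the calibrated response `H(z)` from every A-scan, leaving only
#' sample-induced depth decay.
#'
#' @param vol An [oct_volume()].
#' @param prof A `calibration_profile` from [estimate_system_response()] on
#'   a matching depth grid.
#' @return The corrected [oct_volume()].
#' @export
correct_system <- function(vol, prof) {
  stopifnot(inherits(vol, "oct_volume"), inherits(prof, "calibration_profile"))
  nz <- dim(vol$data)[3]
  if (length(prof$h_db) != nz) {
    stop("correct_system: calibration profile depth length does not match the volume")
  }
  d <- dim(vol$data)
  vol$data <- vol$data - rep(prof$h_db, each = d[1] * d[2])
  vol
}

#' Fit the attenuation coefficient of every A-scan
#'
#' Fits the system-corrected, noise-normalized log signal of each A-scan to
#' the single-scattering model `I(z) = I0 * exp(-2 * mu * z)`, i.e. an
#' ordinary least-squares line of dB against physical depth; the attenuation
#' coefficient is `mu = -slope * ln(10) / 20` per mm. The fit window runs
#' from the detected surface plus a guard band to the last depth still above
#' a noise margin; A-scans whose window is shorter than a minimum length are
#' flagged invalid (never silently zeroed).
#'
#' @param vol System-corrected, noise-normalized [oct_volume()].
#' @param surface Integer `[nx, ny]` surface map (depth indices), e.g. from
#'   [detect_surface()].
#' @param guard_px Pixels skipped below the surface before fitting
#'   (default 5).
#' @param noise_margin_db Window ends at the last depth with signal at least
#'   this many dB above the noise floor (default 3).
#' @param min_window_px Minimum usable window length in pixels (default 20).
#' @return An `attenuation_map`: list with `mu` (`[nx, ny]`, 1/mm),
#'   `window` (array `[nx, ny, 2]` of start/end depth pixels),
#'   `r_squared` (`[nx, ny]`), `valid` (logical `[nx, ny]`).
#' @export
fit_attenuation <- function(vol, surface, guard_px = 5, noise_margin_db = 3,
                            min_window_px = 20) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$data)
  stopifnot(all(dim(surface) == d[1:2]))
  pz_mm <- physical_pitch_um(vol) / 1000
  mu <- matrix(NA_real_, d[1], d[2])
  r2 <- matrix(NA_real_, d[1], d[2])
  win <- array(NA_integer_, dim = c(d[1], d[2], 2))
  valid <- matrix(FALSE, d[1], d[2])
  for (j in seq_len(d[2])) {
    for (i in seq_len(d[1])) {
      a <- vol$data[i, j, ]
      z0 <- surface[i, j] + guard_px
      above <- which(a >= noise_margin_db)
      z1 <- if (length(above)) max(above) else 0L
      if (z0 < 1 || z1 - z0 + 1 < min_window_px) next
      zz <- z0:z1
      y <- a[zz]
      x <- (zz - 1) * pz_mm
      sx <- sum(x)
      sy <- sum(y)
      n <- length(x)
      sxx <- sum(x * x)
      sxy <- sum(x * y)
      denom <- n * sxx - sx * sx
      if (denom <= 0) next
      slope <- (n * sxy - sx * sy) / denom
      icpt <- (sy - slope * sx) / n
      ss_res <- sum((y - icpt - slope * x)^2)
      ss_tot <- sum((y - sy / n)^2)
      mu[i, j] <- -slope * log(10) / 20
      r2[i, j] <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
      win[i, j, ] <- c(z0, z1)
      valid[i, j] <- TRUE
    }
  }
  structure(
    list(mu = mu, window = win, r_squared = r2, valid = valid),
    class = "attenuation_map"
  )
}

#' Compensate attenuation in a corrected volume
#'
#' Adds back the fitted round-trip decay below the surface of each valid
#' A-scan, `dB(z) + 2 * mu * (z - surface) * 10/ln(10)` with depth in
#' physical mm, so that homogeneous tissue becomes depth-constant while
#' transparent vessels keep their signal deficit. Invalid A-scans pass
#' through unchanged.
#'
#' @param vol The system-corrected [oct_volume()] the fit was computed from.
#' @param att An `attenuation_map` from [fit_attenuation()].
#' @param surface Integer `[nx, ny]` surface map.
#' @return The compensated [oct_volume()].
#' @export
compensate <- function(vol, att, surface) {
  stopifnot(inherits(vol, "oct_volume"), inherits(att, "attenuation_map"))
  d <- dim(vol$data)
  if (!all(dim(att$mu) == d[1:2]) || !all(dim(surface) == d[1:2])) {
    stop("compensate: shape mismatch between volume, attenuation map and surface")
  }
  pz_mm <- physical_pitch_um(vol) / 1000
  zidx <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  surf3 <- array(surface, dim = d) # recycles [nx, ny] along z
  mu3 <- array(ifelse(att$valid, att$mu, 0), dim = d)
  depth_mm <- pmax(0, zidx - surf3 + 1) * pz_mm
  vol$data <- vol$data + db_per_mm(mu3) * depth_mm * (zidx >= surf3 - 1)
  vol
}

#' Threshold a compensated volume into a vessel mask
#'
#' Vessels keep a markedly low signal after compensation while surrounding
#' tissue is nearly depth-constant, so a single constant threshold separates
#' them: voxels below `theta_db` and below the tissue surface are vessel.
#'
#' @param vol Compensated [oct_volume()].
#' @param theta_db Threshold in dB. The default `NULL` places it
#'   `rel_db` below the tissue mode (the most common compensated
#'   below-surface level).
#' @param surface Integer `[nx, ny]` surface map.
#' @param rel_db Offset below the tissue mode used when `theta_db` is `NULL`
#'   (default 8).
#' @return A native-frame [vessel_mask()] (provenance `"conventional"`).
#' @export
threshold_vessels <- function(vol, theta_db = NULL, surface, rel_db = 8) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$data)
  zidx <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  below <- zidx > array(surface, dim = d)
  if (is.null(theta_db)) {
    theta_db <- tissue_mode_db(vol$data[below]) - rel_db
  }
  m <- (vol$data < theta_db) & below
  out <- vessel_mask(m, frame = "native", provenance = "conventional")
  attr(out, "theta_db") <- theta_db
  out
}

# mode of a dB sample via kernel density
tissue_mode_db <- function(x) {
  dd <- density(x, n = 512)
  dd$x[which.max(dd$y)]
}

#' Detect the tissue surface with a Canny edge detector
#'
#' Per B-scan, Canny edges of the dB image are computed (Gaussian smoothing,
#' Sobel gradients, non-maximum suppression, hysteresis on the per-scan
#' dynamic range); per A-scan the shallowest edge pixel is taken as the
#' surface. Gaps are filled by lateral interpolation and the map is
#' median-filtered laterally.
#'
#' @param vol Noise-normalized [oct_volume()].
#' @param sigma Gaussian smoothing scale in pixels (default 2).
#' @param low,high Hysteresis thresholds as fractions of the per-scan
#'   maximum gradient magnitude (defaults 0.1 and 0.3).
#' @param median_width Lateral median filter width in pixels, odd
#'   (default 15).
#' @return A `surface_map`: list with `surface` (integer `[nx, ny]` depth
#'   indices) and `reliable` (logical; `FALSE` when a B-scan had no edges
#'   and was filled entirely by interpolation).
#' @export
detect_surface <- function(vol, sigma = 2, low = 0.1, high = 0.3,
                           median_width = 15) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$data)
  surf <- matrix(NA_real_, d[1], d[2])
  reliable <- rep(TRUE, d[2])
  for (j in seq_len(d[2])) {
    bscan <- vol$data[, j, ] # [x, z]
    edges <- canny_edges(bscan, sigma = sigma, low = low, high = high)
    first_edge <- apply(edges, 1, function(e) if (any(e)) which(e)[1] else NA_integer_)
    if (all(is.na(first_edge))) {
      reliable[j] <- FALSE
      next
    }
    if (anyNA(first_edge)) {
      idx <- seq_along(first_edge)
      first_edge <- approx(idx[!is.na(first_edge)], first_edge[!is.na(first_edge)],
        xout = idx, rule = 2
      )$y
    }
    # refine each A-scan to the steepest 1-D depth rise near the Canny edge:
    # the 2-D blur inside Canny can bias the edge by a fraction of a pixel
    # along a tilted surface; this 1-D step is orientation-independent
    for (i in seq_len(d[1])) {
      s0 <- round(first_edge[i])
      zz <- max(2L, s0 - 3L):min(d[3], s0 + 3L)
      a <- bscan[i, ]
      first_edge[i] <- zz[which.max(a[zz] - a[zz - 1L])]
    }
    if (d[1] > median_width) {
      first_edge <- runmed(first_edge, k = median_width, endrule = "median")
    }
    surf[, j] <- first_edge
    # sanity: the surface must separate dark (noise) from bright (tissue)
    above <- mean(vapply(seq_len(d[1]), function(i) {
      s <- round(first_edge[i])
      if (s <= 3) return(NA_real_)
      mean(bscan[i, seq_len(s - 2L)])
    }, numeric(1)), na.rm = TRUE)
    below <- mean(vapply(seq_len(d[1]), function(i) {
      s <- round(first_edge[i])
      mean(bscan[i, min(d[3], s + 1L):min(d[3], s + 20L)])
    }, numeric(1)))
    if (is.finite(above) && below - above < 5) reliable[j] <- FALSE
  }
  if (any(!reliable)) {
    surf[, !reliable] <- NA_real_
    warning("detect_surface: unreliable B-scan(s) (no edges or no surface contrast); surface filled from neighbors")
    if (all(!reliable)) {
      surf[] <- 1
    } else {
      for (i in seq_len(d[1])) {
        ok <- which(!is.na(surf[i, ]))
        surf[i, ] <- approx(ok, surf[i, ok], xout = seq_len(d[2]), rule = 2)$y
      }
    }
  }
  structure(
    list(
      surface = matrix(
        as.integer(pmin(pmax(round(surf), 1), d[3])),
        d[1], d[2]
      ),
      reliable = reliable
    ),
    class = "surface_map"
  )
}

#' Flatten A-scans to the tissue surface and crop in depth
#'
#' Shifts each A-scan up by its (integer) surface index so the tissue
#' surface lies at depth 1, then keeps only the first
#' `round(crop_um / physical pitch)` depth pixels. Vacated deep samples are
#' zero-padded (volumes) or `FALSE`-padded (masks); integer shifts keep
#' masks binary.
#'
#' @param data An [oct_volume()] or [vessel_mask()].
#' @param surface Integer `[nx, ny]` surface map (or a `surface_map`).
#' @param crop_um Depth to retain below the surface, micrometres of tissue
#'   (default 500).
#' @return Same type as `data`, in the flattened frame.
#' @export
flatten_and_crop <- function(data, surface, crop_um = 500) {
  if (inherits(surface, "surface_map")) surface <- surface$surface
  is_vol <- inherits(data, "oct_volume")
  arr <- if (is_vol) data$data else data$mask
  d <- dim(arr)
  pitch <- if (is_vol) {
    physical_pitch_um(data)
  } else {
    attr(data, "physical_pitch_um") %||% NA_real_
  }
  if (is.na(pitch)) {
    stop("flatten_and_crop: physical pitch unknown; supply an oct_volume or a mask with a physical_pitch_um attribute")
  }
  crop_px <- round(crop_um / pitch)
  if (crop_px > d[3]) stop("flatten_and_crop: crop exceeds the volume depth")
  fill <- if (is_vol) 0 else FALSE
  out <- array(fill, dim = c(d[1], d[2], crop_px))
  for (j in seq_len(d[2])) {
    for (i in seq_len(d[1])) {
      s <- surface[i, j]
      take <- s:min(d[3], s + crop_px - 1L)
      out[i, j, seq_along(take)] <- arr[i, j, take]
    }
  }
  if (is_vol) {
    data$data <- out
    attr(data, "frame") <- "flattened"
    attr(data, "crop_um") <- crop_um
    data
  } else {
    m <- vessel_mask(out,
      frame = "flattened", crop_um = crop_um,
      provenance = data$provenance
    )
    attr(m, "physical_pitch_um") <- pitch
    m
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the conventional attenuation-compensated OCTL pipeline
#'
#' The complete conventional label generator: system-response correction,
#' per-A-scan attenuation fitting and compensation, constant-threshold
#' segmentation, Canny surface detection on the original volume, and
#' flattening/cropping of both the mask and the pre-processed volume.
#'
#' @param vol Noise-normalized [oct_volume()] (pre-processed scan).
#' @param prof `calibration_profile` from [estimate_system_response()].
#' @param theta_db Absolute threshold in dB, or `NULL` for the
#'   mode-relative default (see [threshold_vessels()]).
#' @param crop_um Depth crop below the surface, micrometres of tissue.
#' @param rel_db Mode-relative threshold offset used when `theta_db` is
#'   `NULL`.
#' @param guard_px,noise_margin_db,min_window_px Fit-window policy, see
#'   [fit_attenuation()].
#' @param sigma,low,high,median_width Surface detection parameters, see
#'   [detect_surface()].
#' @return List: `mask` (flattened, cropped [vessel_mask()]), `volume`
#'   (flattened, cropped [oct_volume()] of the input scan, for training),
#'   `surface` (`surface_map`), `attenuation` (`attenuation_map`),
#'   `theta_db` (threshold actually applied), `compensated`
#'   (native-frame compensated volume).
#' @export
run_conventional <- function(vol, prof, theta_db = NULL, crop_um = 500,
                             rel_db = 8, guard_px = 5, noise_margin_db = 3,
                             min_window_px = 20, sigma = 2, low = 0.1,
                             high = 0.3, median_width = 15) {
  stopifnot(inherits(vol, "oct_volume"))
  sm <- detect_surface(vol,
    sigma = sigma, low = low, high = high,
    median_width = median_width
  )
  corrected <- correct_system(vol, prof)
  att <- fit_attenuation(corrected, sm$surface,
    guard_px = guard_px,
    noise_margin_db = noise_margin_db, min_window_px = min_window_px
  )
  comp <- compensate(corrected, att, sm$surface)
  mask <- threshold_vessels(comp, theta_db, sm$surface, rel_db = rel_db)
  theta_db <- attr(mask, "theta_db")
  attr(mask, "physical_pitch_um") <- physical_pitch_um(vol)
  list(
    mask = flatten_and_crop(mask, sm, crop_um = crop_um),
    volume = flatten_and_crop(vol, sm, crop_um = crop_um),
    surface = sm,
    attenuation = att,
    theta_db = theta_db,
    compensated = comp
  )
}
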