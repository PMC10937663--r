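#' Specify a synthetic OCT phantom
#'
#' Defines a speckled single-scattering phantom: a tilted tissue slab with
#' exponential depth decay, an optional confocal/roll-off axial system
#' response, an additive noise floor, embedded low-signal tubular vessels and
#' an optional low-signal superficial layer. Rendered volumes follow
#' `I(z) = I0 * H(z) * exp(-2 * mu * z)` in linear intensity (displayed as
#' `10*log10`), with fully or partially developed multiplicative speckle.
#'
#' @param nx,ny,nz Grid size in voxels (x, y lateral; z depth).
#' @param axial_pitch_um Optical path length per depth pixel (micrometres).
#' @param lateral_pitch_um Micrometres per lateral pixel (recycled to x, y).
#' @param refractive_index Tissue refractive index (default 1.4).
#' @param mu_t Tissue attenuation coefficient, 1/mm of physical depth.
#' @param signal_db Tissue backscatter level at the surface, dB above 1.
#' @param noise_floor_db Additive noise-floor intensity level in dB
#'   (pre-normalization); `-Inf` renders a noise-free phantom.
#' @param speckle_contrast Speckle contrast in `[0, 1]`: 0 is noiseless, 1 is
#'   fully developed speckle (unit-mean exponential intensity).
#' @param surface_tilt_um Length-2: micrometres of optical depth added to the
#'   surface per lateral pixel along x and y.
#' @param surface_offset_px Depth index (pixels) of the surface at the
#'   (1, 1) corner.
#' @param vessels List of vessels from [phantom_vessel()].
#' @param layer Optional superficial layer,
#'   `list(thickness_um =, deficit_db =)`: a band of tissue of the given
#'   physical thickness below the surface, uniformly darker by the deficit.
#'   This breaks depth homogeneity and is the artifact source for
#'   attenuation-compensated thresholding.
#' @param confocal Optional `list(focus_um =, rayleigh_um =)`: Lorentzian-like
#'   confocal collection efficiency `1 / (1 + ((z - focus)/rayleigh)^2)`
#'   (depths in optical micrometres). `NULL` = flat.
#' @param rolloff_db_per_mm Sensitivity roll-off decay, dB per optical mm
#'   (0 = none).
#' @param n_spectral_px,center_wavelength_nm,bandwidth_nm Spectral sampling
#'   used by [make_raw_spectra()].
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(nx = 64, ny = 16, nz = 320,
                         axial_pitch_um = 5.6, lateral_pitch_um = 12,
                         refractive_index = 1.4,
                         mu_t = 3, signal_db = 45, noise_floor_db = 20,
                         speckle_contrast = 0.2,
                         surface_tilt_um = c(0, 0), surface_offset_px = 10,
                         vessels = list(), layer = NULL, confocal = NULL,
                         rolloff_db_per_mm = 0,
                         n_spectral_px = 512, center_wavelength_nm = 1300,
                         bandwidth_nm = 100,
                         seed = 1L) {
  stopifnot(
    nx >= 1, ny >= 1, nz >= 1,
    axial_pitch_um > 0, all(lateral_pitch_um > 0),
    refractive_index >= 1, mu_t >= 0,
    speckle_contrast >= 0, speckle_contrast <= 1
  )
  for (v in vessels) {
    if (!inherits(v, "phantom_vessel")) {
      stop("vessels must be created with phantom_vessel()")
    }
    if (any(v$radius_um <= 0)) stop("vessel radii must be positive")
    if (v$deficit_db <= 0) stop("vessel signal deficits must be positive (dB)")
  }
  if (!is.null(layer)) {
    stopifnot(layer$thickness_um > 0, layer$deficit_db > 0)
  }
  structure(
    list(
      nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
      axial_pitch_um = axial_pitch_um,
      lateral_pitch_um = rep_len(as.numeric(lateral_pitch_um), 2L),
      refractive_index = refractive_index,
      mu_t = mu_t, signal_db = signal_db, noise_floor_db = noise_floor_db,
      speckle_contrast = speckle_contrast,
      surface_tilt_um = rep_len(as.numeric(surface_tilt_um), 2L),
      surface_offset_px = surface_offset_px,
      vessels = vessels, layer = layer,
      confocal = confocal, rolloff_db_per_mm = rolloff_db_per_mm,
      n_spectral_px = as.integer(n_spectral_px),
      center_wavelength_nm = center_wavelength_nm,
      bandwidth_nm = bandwidth_nm,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' Define a tubular vessel for a phantom
#'
#' A vessel is a polyline centerline in voxel coordinates with a radius
#' profile; its interior backscatter is lower than the surrounding tissue by
#' a fixed dB deficit (lymph and aqueous humor are nearly transparent).
#' Ground truth is geometric: a voxel is vessel iff its physical distance to
#' the centerline is at most the local radius.
#'
#' @param centerline Numeric matrix with columns (x, y, z), voxel
#'   coordinates; at least 2 rows.
#' @param radius_um Radius in micrometres: a scalar or one value per vertex
#'   (linearly interpolated along the polyline). Irregular profiles emulate
#'   lymphatics; constant profiles emulate aqueous veins.
#' @param type `"lymphatic"` or `"vein"` (annotation only; both render the
#'   same way).
#' @param deficit_db Interior signal deficit in dB (> 0).
#'
#' @return An object of class `phantom_vessel`.
#' @export
phantom_vessel <- function(centerline, radius_um, type = c("lymphatic", "vein"),
                           deficit_db = 15) {
  centerline <- as.matrix(centerline)
  stopifnot(ncol(centerline) == 3L, nrow(centerline) >= 2L)
  if (!(length(radius_um) %in% c(1L, nrow(centerline)))) {
    stop("radius_um must be scalar or one value per centerline vertex")
  }
  structure(
    list(
      centerline = centerline,
      radius_um = rep_len(as.numeric(radius_um), nrow(centerline)),
      type = match.arg(type),
      deficit_db = deficit_db
    ),
    class = "phantom_vessel"
  )
}

# surface depth index (fractional pixels) per A-scan: [nx, ny]
surface_px <- function(spec) {
  tx <- spec$surface_tilt_um[1] / spec$axial_pitch_um
  ty <- spec$surface_tilt_um[2] / spec$axial_pitch_um
  outer(
    spec$surface_offset_px + tx * (seq_len(spec$nx) - 1),
    ty * (seq_len(spec$ny) - 1),
    "+"
  )
}

# combined confocal x roll-off system response in dB, re-zeroed at its peak
system_response_db <- function(spec, nz = spec$nz) {
  z_um <- (seq_len(nz) - 1) * spec$axial_pitch_um
  h <- -spec$rolloff_db_per_mm * z_um / 1000
  if (!is.null(spec$confocal)) {
    h <- h - 10 * log10(1 + ((z_um - spec$confocal$focus_um) /
                               spec$confocal$rayleigh_um)^2)
  }
  h - max(h)
}

# voxelize one vessel: logical [nx, ny, nz]; distances in physical um
voxelize_one <- function(spec, v) {
  mask <- array(FALSE, dim = c(spec$nx, spec$ny, spec$nz))
  px <- spec$lateral_pitch_um[1]
  py <- spec$lateral_pitch_um[2]
  pz <- spec$axial_pitch_um / spec$refractive_index
  {
    cl <- v$centerline
    # voxel coords -> physical um
    cp <- cbind(cl[, 1] * px, cl[, 2] * py, cl[, 3] * pz)
    rmax <- max(v$radius_um)
    # bounding box (voxels) of the vessel, padded by the max radius
    lo <- pmax(1, floor(c(
      (min(cp[, 1]) - rmax) / px, (min(cp[, 2]) - rmax) / py,
      (min(cp[, 3]) - rmax) / pz
    )))
    hi <- pmin(c(spec$nx, spec$ny, spec$nz), ceiling(c(
      (max(cp[, 1]) + rmax) / px, (max(cp[, 2]) + rmax) / py,
      (max(cp[, 3]) + rmax) / pz
    )))
    if (any(hi < lo)) return(mask)
    xs <- seq.int(lo[1], hi[1])
    ys <- seq.int(lo[2], hi[2])
    zs <- seq.int(lo[3], hi[3])
    pts <- as.matrix(expand.grid(x = xs * px, y = ys * py, z = zs * pz))
    inside <- rep(FALSE, nrow(pts))
    for (s in seq_len(nrow(cp) - 1L)) {
      a <- cp[s, ]
      b <- cp[s + 1L, ]
      ab <- b - a
      len2 <- sum(ab^2)
      d <- sweep(pts, 2, a)
      t <- if (len2 > 0) pmin(1, pmax(0, drop(d %*% ab) / len2)) else 0
      dist2 <- rowSums((d - outer(t, ab))^2)
      r <- v$radius_um[s] + t * (v$radius_um[s + 1L] - v$radius_um[s])
      inside <- inside | (dist2 <= r^2)
    }
    sub <- mask[xs, ys, zs, drop = FALSE]
    mask[xs, ys, zs] <- sub | array(inside, dim = c(
      length(xs), length(ys),
      length(zs)
    ))
  }
  mask
}

# union mask over the vessel list
voxelize_vessels <- function(spec) {
  mask <- array(FALSE, dim = c(spec$nx, spec$ny, spec$nz))
  for (v in spec$vessels) mask <- mask | voxelize_one(spec, v)
  mask
}

# core renderer shared by calibration and eye phantoms
render_phantom <- function(spec, with_structures = TRUE) {
  nx <- spec$nx
  ny <- spec$ny
  nz <- spec$nz
  surf <- surface_px(spec) # [nx, ny], fractional pixels
  h_db <- system_response_db(spec) # [nz]
  pz_phys_mm <- spec$axial_pitch_um / spec$refractive_index / 1000

  # depth below surface in pixels (fractional), [nx, ny, nz]
  zidx <- array(rep(seq_len(nz) - 1, each = nx * ny), dim = c(nx, ny, nz))
  depth_px <- zidx - as.vector(surf)
  tissue <- depth_px >= 0

  db <- array(-Inf, dim = c(nx, ny, nz))
  db[tissue] <- spec$signal_db -
    db_per_mm(spec$mu_t) * depth_px[tissue] * pz_phys_mm
  db <- db + rep(h_db, each = nx * ny)

  mask <- array(FALSE, dim = c(nx, ny, nz))
  if (with_structures) {
    for (i in seq_along(spec$vessels)) {
      m1 <- voxelize_one(spec, spec$vessels[[i]])
      if (any(m1 & !tissue)) {
        stop(sprintf("vessel %d extends above the tissue surface", i))
      }
      newly <- m1 & !mask # overlapping vessels share one deficit, not two
      db[newly] <- db[newly] - spec$vessels[[i]]$deficit_db
      mask <- mask | m1
    }
    if (!is.null(spec$layer)) {
      thick_px <- spec$layer$thickness_um / (spec$axial_pitch_um / spec$refractive_index)
      in_layer <- tissue & depth_px < thick_px & !mask
      db[in_layer] <- db[in_layer] - spec$layer$deficit_db
    }
  }

  lin <- 10^(db / 10)
  lin[!tissue] <- 0
  n0 <- if (is.finite(spec$noise_floor_db)) 10^(spec$noise_floor_db / 10) else 0
  total <- lin + n0
  if (spec$speckle_contrast > 0) {
    m <- with_seed(spec$seed, {
      1 + spec$speckle_contrast * (rexp(length(total)) - 1)
    })
    total <- total * m
  }
  out_db <- 10 * log10(pmax(total, 1e-30))

  vol <- oct_volume(
    out_db,
    axial_pitch_um = spec$axial_pitch_um,
    lateral_pitch_um = spec$lateral_pitch_um,
    refractive_index = spec$refractive_index,
    seed = spec$seed
  )
  list(
    volume = vol,
    mask = mask,
    surface = round(surf),
    mu = matrix(spec$mu_t, nx, ny)
  )
}

#' Render a calibration phantom volume
#'
#' A homogeneous, low-scattering phantom scan used to estimate the combined
#' confocal and sensitivity-roll-off system response. The expected log signal
#' at depth z equals the source level plus the system response `H(z)` minus
#' the round-trip attenuation decay, on top of the additive noise floor; the
#' volume is laterally statistically homogeneous.
#'
#' @param spec A [phantom_spec()] with no vessels, no superficial layer, and
#'   small `mu_t` (<= 0.5 / mm).
#' @return An [oct_volume()] (not yet noise-normalized).
#' @export
make_calibration_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$vessels) > 0) {
    stop("calibration phantom must be homogeneous: spec contains vessels")
  }
  if (!is.null(spec$layer)) {
    stop("calibration phantom must be homogeneous: spec contains a superficial layer")
  }
  if (spec$mu_t > 0.5) {
    stop("calibration phantom must be low-scattering (mu_t <= 0.5 / mm)")
  }
  render_phantom(spec, with_structures = FALSE)$volume
}

#' Render an eye-like phantom with ground truth
#'
#' A tilted tissue slab containing low-signal tubular vessels and optionally
#' a low-signal superficial layer, emulating conjunctival/scleral scans with
#' lymphatic and aqueous-vein vessels. Returns the rendered volume together
#' with the geometric ground truth (vessel mask, surface map, per-A-scan true
#' attenuation).
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([oct_volume()]), and `truth`
#'   (list: `mask` logical array, `surface` integer `[nx, ny]` map,
#'   `mu` numeric `[nx, ny]` map).
#' @export
make_eye_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  r <- render_phantom(spec, with_structures = TRUE)
  list(
    volume = r$volume,
    truth = list(mask = r$mask, surface = r$surface, mu = r$mu)
  )
}

#' Simulate raw spectral-domain interferograms
#'
#' Generates wavelength-sampled (hence nonuniform-in-wavenumber) interference
#' spectra for a set of discrete reflectors, with a Gaussian source envelope
#' stored as the background spectrum. Reconstruction with [reconstruct()]
#' yields magnitude peaks at the specified optical depths.
#'
#' @param depth_reflectors Matrix or data.frame with columns
#'   `depth_um` (optical path depth) and `amplitude`, one row per reflector.
#' @param spec A [phantom_spec()] providing the spectral sampling
#'   (`n_spectral_px`, `center_wavelength_nm`, `bandwidth_nm`).
#' @param nx,ny Number of (identical) A-scans to emit laterally.
#' @return A [raw_spectra()] object.
#' @export
make_raw_spectra <- function(depth_reflectors, spec, nx = 1L, ny = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  dr <- as.matrix(depth_reflectors)
  if (ncol(dr) != 2L) stop("depth_reflectors must have columns (depth_um, amplitude)")
  n <- spec$n_spectral_px
  lambda <- seq(
    spec$center_wavelength_nm - spec$bandwidth_nm / 2,
    spec$center_wavelength_nm + spec$bandwidth_nm / 2,
    length.out = n
  )
  pitch <- axial_pitch_from_grid(lambda)
  zmax <- (n / 2 - 1) * pitch
  if (any(dr[, 1] < 0) || any(dr[, 1] > zmax)) {
    stop(sprintf(
      "reflector depth beyond the unambiguous range (%.0f um optical)", zmax
    ))
  }
  k <- 2 * pi / (lambda / 1000) # rad / um
  bg <- exp(-0.5 * ((lambda - spec$center_wavelength_nm) /
                      (spec$bandwidth_nm / 4))^2)
  s <- bg
  for (i in seq_len(nrow(dr))) {
    s <- s + bg * 2 * dr[i, 2] * cos(2 * k * dr[i, 1])
  }
  # dimension order [x, y, spectral]
  spectra <- aperm(array(s, dim = c(n, nx, ny)), c(2, 3, 1))
  raw_spectra(spectra, lambda, bg, spec$lateral_pitch_um)
}
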