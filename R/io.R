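#' Write an OCT volume as a multi-page TIFF with JSON sidecar
#'
#' One 32-bit page per B-scan (y slice). Samples are stored on a linear
#' 32-bit grid spanning the volume's dB range (offset and gain recorded in
#' the sidecar), so the round trip is exact to about 5e-10 of the dynamic
#' range -- sub-micro-dB for any practical scan. Metadata (pitches,
#' refractive index, flags, seed) goes to `<path>.json`.
#'
#' @param vol An [oct_volume()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$data)
  # TIFF stores samples in [0, 1]: rescale with an integer offset and a
  # power-of-two gain (recorded in the sidecar) so the trip stays exact
  off <- floor(min(vol$data))
  rng <- max(vol$data) - off
  k <- ceiling(log2(max(rng, 1e-12)))
  pages <- lapply(seq_len(d[2]), function(j) {
    matrix((vol$data[, j, ] - off) / 2^k, d[1], d[3])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    axial_pitch_um = vol$axial_pitch_um,
    lateral_pitch_um = vol$lateral_pitch_um,
    refractive_index = vol$refractive_index,
    noise_normalized = vol$noise_normalized,
    seed = vol$seed,
    db_offset = off,
    db_log2_gain = k
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE,
    digits = NA, null = "null"
  )
  invisible(path)
}

#' Read an OCT volume written by [write_volume()]
#'
#' @param path TIFF path; metadata is read from `<path>.json` when present,
#'   otherwise defaults are used with a warning.
#' @return An [oct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_volume: no such file '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[1], length(pages), d[2]))
  for (j in seq_along(pages)) arr[, j, ] <- pages[[j]]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    warning("read_volume: missing JSON sidecar; using default metadata")
    meta <- list()
  }
  arr <- arr * 2^(meta$db_log2_gain %||% 0) + (meta$db_offset %||% 0)
  oct_volume(
    arr,
    axial_pitch_um = meta$axial_pitch_um %||% 5.6,
    lateral_pitch_um = meta$lateral_pitch_um %||% c(12, 12),
    refractive_index = meta$refractive_index %||% 1.4,
    noise_normalized = meta$noise_normalized %||% FALSE,
    seed = meta$seed
  )
}

#' Write a vessel mask as an 8-bit 0/1 TIFF stack
#'
#' @param mask A [vessel_mask()].
#' @param path Output TIFF path (frame/crop/provenance go to a JSON
#'   sidecar).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "vessel_mask"))
  d <- dim(mask$mask)
  pages <- lapply(
    seq_len(d[2]),
    function(j) matrix(mask$mask[, j, ] * 1.0, d[1], d[3])
  )
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  meta <- list(
    frame = mask$frame, crop_um = mask$crop_um,
    provenance = mask$provenance,
    physical_pitch_um = attr(mask, "physical_pitch_um")
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE,
    digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a vessel mask written by [write_mask()]
#'
#' @param path TIFF path.
#' @return A [vessel_mask()] (values strictly 0/1 re-read as logical).
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_mask: no such file '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(FALSE, dim = c(d[1], length(pages), d[2]))
  for (j in seq_along(pages)) arr[, j, ] <- pages[[j]] > 0.5
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    warning("read_mask: missing JSON sidecar; using default metadata")
    list()
  }
  m <- vessel_mask(
    arr,
    frame = meta$frame %||% "native",
    crop_um = meta$crop_um %||% NA_real_,
    provenance = meta$provenance %||% "conventional"
  )
  attr(m, "physical_pitch_um") <- meta$physical_pitch_um
  m
}

#' Load a pipeline run configuration from YAML
#'
#' Unknown keys are rejected with their location so typos never silently
#' fall back to defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Named list overriding individual keys.
#' @return A validated named list of class `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 1L,
    phantom = list(
      nx = 96L, ny = 24L, nz = 320L, axial_pitch_um = 5.6,
      lateral_pitch_um = 12, refractive_index = 1.4, mu_t = 3,
      signal_db = 45, noise_floor_db = 20, speckle_contrast = 0.2,
      n_vessels = 3L, vessel_deficit_db = 20, layer = NULL
    ),
    conventional = list(
      theta_db = NULL, rel_db = 8, crop_um = 500, mu_cal = 0.1,
      canny = list(sigma = 2, low = 0.1, high = 0.3, median_width = 15),
      fit = list(guard_px = 5, noise_margin_db = 3, min_window_px = 20)
    ),
    unet = list(widths = c(8L, 16L, 32L, 64L)),
    train = list(
      lr = 1e-4, epochs = 60L, batch_size = 1L,
      fractions = c(0.5, 0.25, 0.25)
    ),
    projection = list(window_um = c(0, 300)),
    schema = 1L
  )
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  check_keys <- function(u, d, where) {
    bad <- setdiff(names(u), names(d))
    if (length(bad)) {
      stop(sprintf(
        "unknown config key(s) at %s: %s", where,
        paste(bad, collapse = ", ")
      ))
    }
    for (nm in names(u)) {
      if (is.list(d[[nm]]) && !is.null(names(d[[nm]])) && is.list(u[[nm]])) {
        check_keys(u[[nm]], d[[nm]], paste0(where, "$", nm))
      }
    }
  }
  check_keys(user, defaults, "config")
  check_keys(overrides, defaults, "overrides")
  cfg <- modifyList(defaults, user)
  cfg <- modifyList(cfg, overrides)
  class(cfg) <- c("run_config", "list")
  cfg
}

config_digest <- function(cfg) {
  # order-stable digest of the configuration for provenance stamping
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) * seq_len(nchar(s))) %% .Machine$integer.max)
}

#' Run the full pipeline end to end
#'
#' Simulates phantoms (calibration, training and held-out eye volumes),
#' pre-processes them, generates conventional labels, splits B-scans, trains
#' the U-Net, predicts on the held-out volume and reports agreement metrics.
#' All artifacts (masks, volumes, history, report) are written under
#' `out_dir`; the run is deterministic given the same configuration and
#' seed.
#'
#' @param config A `run_config` from [load_config()].
#' @param out_dir Output directory (created if missing).
#' @return The report list (also written as `report.json`), invisibly the
#'   full artifact list.
#' @export
run_pipeline <- function(config = load_config(), out_dir = tempfile("octl_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  ph <- config$phantom
  log_stage <- function(stage, ...) {
    message(sprintf(
      "[octl %s] %s (seed %d, config %s)",
      format(Sys.time(), "%H:%M:%S"), sprintf(stage, ...), seed,
      config_digest(config)
    ))
  }

  log_stage("simulate")
  cal_spec <- phantom_spec(
    nx = ph$nx, ny = ph$ny, nz = ph$nz,
    axial_pitch_um = ph$axial_pitch_um, lateral_pitch_um = ph$lateral_pitch_um,
    refractive_index = ph$refractive_index,
    mu_t = config$conventional$mu_cal, signal_db = ph$signal_db,
    noise_floor_db = ph$noise_floor_db,
    speckle_contrast = ph$speckle_contrast, surface_offset_px = 10,
    seed = seed + 101L
  )
  cal <- make_calibration_volume(cal_spec)
  train_spec <- eye_spec_from_config(ph, seed + 1L)
  test_spec <- eye_spec_from_config(ph, seed + 2L)
  train_ph <- make_eye_phantom(train_spec)
  test_ph <- make_eye_phantom(test_spec)

  log_stage("preprocess")
  # the low-scattering calibration phantom never attenuates into the floor,
  # so its noise level is measured in the signal-free region above its surface
  cal_n <- normalize_noise(cal, noise_region = 1:8)
  train_vol <- normalize_noise(train_ph$volume)
  test_vol <- normalize_noise(test_ph$volume)

  log_stage("conventional")
  prof <- estimate_system_response(cal_n, config$conventional$mu_cal)
  cv <- config$conventional
  conv_args <- function(v) {
    run_conventional(v, prof,
      theta_db = cv$theta_db, crop_um = cv$crop_um, rel_db = cv$rel_db,
      guard_px = cv$fit$guard_px, noise_margin_db = cv$fit$noise_margin_db,
      min_window_px = cv$fit$min_window_px, sigma = cv$canny$sigma,
      low = cv$canny$low, high = cv$canny$high,
      median_width = cv$canny$median_width
    )
  }
  conv_train <- conv_args(train_vol)
  conv_test <- conv_args(test_vol)
  write_mask(conv_test$mask, file.path(out_dir, "mask_conventional.tif"))

  log_stage("split + train")
  ds <- bscan_dataset(conv_train$volume, conv_train$mask)
  sp <- split_dataset(length(ds$images), config$train$fractions, seed = seed)
  model <- build_unet(unet_spec(config$unet$widths), seed = seed)
  model <- unet_train(
    model, ds$images[sp$train], ds$labels[sp$train],
    ds$images[sp$val], ds$labels[sp$val],
    train_config(
      lr = config$train$lr, epochs = config$train$epochs,
      batch_size = config$train$batch_size, seed = seed
    )
  )
  utils::write.csv(model$history, file.path(out_dir, "history.csv"),
    row.names = FALSE
  )
  saveRDS(model, file.path(out_dir, "model.rds")) # spec + weights + config + seed

  log_stage("predict + metrics")
  dl_mask <- unet_predict(model, conv_test$volume)
  attr(dl_mask, "physical_pitch_um") <- physical_pitch_um(conv_test$volume)
  write_mask(dl_mask, file.path(out_dir, "mask_dl.tif"))
  rep <- iou_summary(dl_mask, conv_test$mask)
  win <- config$projection$window_um
  win[2] <- min(win[2], cv$crop_um)
  report <- list(
    config_digest = config_digest(config),
    seed = seed,
    theta_db = conv_train$theta_db,
    mean_iou = rep$mean_iou,
    sd_iou = rep$sd_iou,
    n_bscans = rep$n_bscans,
    area_density_dl = area_density(project(dl_mask, win)),
    area_density_conventional = area_density(project(conv_test$mask, win)),
    volume_density_dl = volume_density(dl_mask, win),
    volume_density_conventional = volume_density(conv_test$mask, win),
    best_epoch = model$best_epoch,
    final_train_iou = tail(model$history$train_iou, 1)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(list(
    report = report, model = model, conventional = conv_test,
    dl_mask = dl_mask, out_dir = out_dir
  ))
}

# standard multi-vessel eye phantom from the pipeline configuration
eye_spec_from_config <- function(ph, seed) {
  spec0 <- phantom_spec(
    nx = ph$nx, ny = ph$ny, nz = ph$nz,
    axial_pitch_um = ph$axial_pitch_um,
    lateral_pitch_um = ph$lateral_pitch_um,
    refractive_index = ph$refractive_index, mu_t = ph$mu_t,
    signal_db = ph$signal_db, noise_floor_db = ph$noise_floor_db,
    speckle_contrast = ph$speckle_contrast, seed = seed
  )
  spec0$vessels <- random_vessels(spec0,
    n = ph$n_vessels, deficit_db = ph$vessel_deficit_db,
    seed = seed + 7L
  )
  spec0$layer <- ph$layer
  spec0
}

#' Draw random vessels for an eye phantom
#'
#' Vessels run along y with sinusoidal wander in x and depth, alternating
#' irregular (lymphatic-like, wavy radius profile) and regular (vein-like,
#' constant radius) tubes, placed within the cropped depth band below the
#' surface.
#'
#' @param spec A [phantom_spec()] (for grid geometry).
#' @param n Number of vessels.
#' @param deficit_db Interior signal deficit (dB).
#' @param radius_um_range Radius range sampled per vessel.
#' @param seed Integer seed.
#' @return List of [phantom_vessel()] objects.
#' @export
random_vessels <- function(spec, n = 3L, deficit_db = 20,
                           radius_um_range = c(25, 45), seed = 1L) {
  pz <- spec$axial_pitch_um / spec$refractive_index
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      yy <- seq(1, spec$ny, length.out = max(2L, min(spec$ny, 12L)))
      x0 <- runif(1, 0.15, 0.85) * spec$nx
      # keep centerlines inside the flattened 500 um band, below the surface
      zmin <- spec$surface_offset_px +
        (max(spec$surface_tilt_um) / spec$axial_pitch_um) *
          max(spec$nx, spec$ny) + 60 / pz
      zmax <- spec$surface_offset_px + 420 / pz
      z0 <- runif(1, zmin, zmax)
      amp_x <- runif(1, 0, 0.08) * spec$nx
      amp_z <- runif(1, 0, 25) / pz
      phase <- runif(2, 0, 2 * pi)
      cl <- cbind(
        x0 + amp_x * sin(2 * pi * yy / spec$ny + phase[1]),
        yy,
        pmin(z0 + amp_z * sin(2 * pi * yy / spec$ny + phase[2]), zmax)
      )
      r0 <- runif(1, radius_um_range[1], radius_um_range[2])
      if (i %% 2L == 1L) {
        # lymphatic-like: uneven diameter along the segment
        rr <- r0 * (1 + 0.3 * sin(seq(0, 3 * pi, length.out = nrow(cl)) + phase[1]))
        phantom_vessel(cl, rr, type = "lymphatic", deficit_db = deficit_db)
      } else {
        phantom_vessel(cl, r0, type = "vein", deficit_db = deficit_db)
      }
    })
  })
}

#' Slice a flattened volume/mask pair into U-Net-ready B-scans
#'
#' Converts each y slice to 8-bit grayscale on a single volume-wide scale,
#' rescales to `[0, 1]`, and zero-pads image and label to the next multiple
#' of 16.
#'
#' @param vol Flattened, cropped [oct_volume()].
#' @param mask Matching [vessel_mask()] (the labels).
#' @return List with `images` (list of matrices in `[0, 1]`), `labels`
#'   (list of logical matrices), `orig` (unpadded dimensions), `vmax`
#'   (dB scale used).
#' @export
bscan_dataset <- function(vol, mask) {
  stopifnot(inherits(vol, "oct_volume"))
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  d <- dim(vol$data)
  stopifnot(all(dim(m) == d))
  vmax <- quantile(vol$data, 0.999, names = FALSE)
  images <- vector("list", d[2])
  labels <- vector("list", d[2])
  for (j in seq_len(d[2])) {
    img <- to_uint8(vol$data[, j, ], vmax = vmax) / 255
    pd <- pad16(img)
    lab <- matrix(FALSE, nrow(pd$image), ncol(pd$image))
    lab[seq_len(d[1]), seq_len(d[3])] <- m[, j, ]
    images[[j]] <- pd$image
    labels[[j]] <- lab
  }
  list(images = images, labels = labels, orig = d[c(1, 3)], vmax = vmax)
}
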