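# Shared fixtures, built once per test run and cached in this environment.
# All fixtures are generated in code; sizes are chosen so the whole suite
# runs comfortably on one CPU.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# standard scleral-like phantom geometry used across tests
std_phantom_spec <- function(nx = 96, ny = 16, nz = 320, seed = 5, mu_t = 3,
                             signal_db = 45, noise_floor_db = 20,
                             speckle_contrast = 0.2, surface_offset_px = 15,
                             surface_tilt_um = c(1, 0), ...) {
  phantom_spec(
    nx = nx, ny = ny, nz = nz, mu_t = mu_t, signal_db = signal_db,
    noise_floor_db = noise_floor_db, speckle_contrast = speckle_contrast,
    surface_offset_px = surface_offset_px, surface_tilt_um = surface_tilt_um,
    seed = seed, ...
  )
}

# copy a spec with some fields replaced (NULL assignments kept, unlike
# utils::modifyList which drops them)
modifyList_keep <- function(spec, ...) {
  args <- list(...)
  for (nm in names(args)) spec[nm] <- list(args[[nm]])
  spec
}

# calibration profile matching the standard geometry
std_calibration <- function(nz = 320) {
  fixture(paste0("cal_", nz), function() {
    spec <- phantom_spec(
      nx = 96, ny = 16, nz = nz, mu_t = 0.1, signal_db = 45,
      noise_floor_db = 20, speckle_contrast = 0.2, surface_offset_px = 6,
      seed = 6
    )
    cal <- normalize_noise(make_calibration_volume(spec), noise_region = 1:5)
    estimate_system_response(cal, 0.1)
  })
}

# clean multi-vessel phantom + its conventional segmentation
clean_vessel_case <- function() {
  fixture("clean_vessel_case", function() {
    spec <- std_phantom_spec()
    spec$vessels <- random_vessels(spec, n = 3, deficit_db = 15, seed = 9)
    ph <- make_eye_phantom(spec)
    vol <- normalize_noise(ph$volume)
    res <- run_conventional(vol, std_calibration())
    gt <- vessel_mask(ph$truth$mask, frame = "native", provenance = "ground_truth")
    attr(gt, "physical_pitch_um") <- physical_pitch_um(ph$volume)
    gt_flat <- flatten_and_crop(gt, res$surface, crop_um = 500)
    list(spec = spec, phantom = ph, volume = vol, result = res, gt_flat = gt_flat)
  })
}

# the U-Net training fixture shared by the learning-related tests:
# one clean phantom provides 64 labelled 128x128 B-scans (32 train /
# 16 validation / 16 test after the random split); a second phantom with a
# different seed is the held-out volume; a third carries the dark
# superficial layer.
unet_fixture <- function() {
  fixture("unet_fixture", function() {
    mk_spec <- function(seed, layer = NULL, ny = 24) {
      spec <- phantom_spec(
        nx = 128, ny = ny, nz = 320, mu_t = 3, signal_db = 45,
        noise_floor_db = 20, speckle_contrast = 0.2, surface_offset_px = 15,
        surface_tilt_um = c(1, 0), seed = seed
      )
      spec$vessels <- random_vessels(spec,
        n = 4, deficit_db = 20,
        seed = seed + 7L
      )
      spec$layer <- layer
      spec
    }
    cal <- std_calibration()
    train_ph <- make_eye_phantom(mk_spec(21, ny = 64))
    conv_train <- run_conventional(normalize_noise(train_ph$volume), cal)
    ds <- bscan_dataset(conv_train$volume, conv_train$mask)
    sp <- split_dataset(length(ds$images), seed = 1)
    model <- build_unet(unet_spec(c(8, 16, 32, 64)), seed = 1)
    model <- unet_train(
      model, ds$images[sp$train], ds$labels[sp$train],
      ds$images[sp$val], ds$labels[sp$val],
      train_config(epochs = 100, seed = 1)
    )

    held_ph <- make_eye_phantom(mk_spec(22))
    conv_held <- run_conventional(normalize_noise(held_ph$volume), cal)
    dl_held <- unet_predict(model, conv_held$volume, vmax = ds$vmax)

    layer_ph <- make_eye_phantom(
      mk_spec(23, layer = list(thickness_um = 50, deficit_db = 10))
    )
    conv_layer <- run_conventional(normalize_noise(layer_ph$volume), cal)
    dl_layer <- unet_predict(model, conv_layer$volume, vmax = ds$vmax)
    gt_layer <- vessel_mask(layer_ph$truth$mask,
      frame = "native",
      provenance = "ground_truth"
    )
    attr(gt_layer, "physical_pitch_um") <- physical_pitch_um(layer_ph$volume)
    gt_layer_flat <- flatten_and_crop(gt_layer, conv_layer$surface, crop_um = 500)

    list(
      model = model, split = sp, dataset = ds,
      conv_train = conv_train,
      conv_held = conv_held, dl_held = dl_held,
      conv_layer = conv_layer, dl_layer = dl_layer,
      gt_layer_flat = gt_layer_flat,
      layer_thickness_um = 50
    )
  })
}
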