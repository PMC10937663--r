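# Conventional attenuation-compensated OCTL: system correction, per-A-scan
# fitting, compensation, thresholding, surface detection, flattening.

test_that("an injected system response is recovered from the calibration scan", {
  spec <- phantom_spec(
    nx = 16, ny = 8, nz = 256, mu_t = 0, signal_db = 45,
    noise_floor_db = -Inf, speckle_contrast = 0, surface_offset_px = 0,
    confocal = list(focus_um = 500, rayleigh_um = 400),
    rolloff_db_per_mm = 4
  )
  injected <- octlseg:::system_response_db(spec)
  cal <- make_calibration_volume(spec)
  cal$noise_normalized <- TRUE # noise-free render is already on a 0 dB floor
  prof <- estimate_system_response(cal, mu_cal = 0)
  ok <- prof$valid
  expect_gt(sum(ok), 200)
  expect_lt(max(abs(prof$h_db[ok] - injected[ok])), 0.1)

  # flat response with mu_cal matching the render: H identically 0
  spec2 <- phantom_spec(
    nx = 8, ny = 4, nz = 128, mu_t = 0.3, signal_db = 45,
    noise_floor_db = -Inf, speckle_contrast = 0, surface_offset_px = 0
  )
  cal2 <- make_calibration_volume(spec2)
  cal2$noise_normalized <- TRUE
  prof2 <- estimate_system_response(cal2, mu_cal = 0.3)
  expect_lt(max(abs(prof2$h_db[prof2$valid])), 1e-9)

  # doubling the source intensity leaves H unchanged (peak re-zeroing)
  cal3 <- cal2
  cal3$data <- cal3$data + 6.02
  prof3 <- estimate_system_response(cal3, mu_cal = 0.3)
  expect_equal(prof3$h_db, prof2$h_db, tolerance = 1e-9)

  # laterally inhomogeneous "calibration" data is rejected
  bad <- cal2
  bad$data[1:4, , ] <- bad$data[1:4, , ] + 12
  expect_error(estimate_system_response(bad, 0.3), "not homogeneous")
})

test_that("system correction subtracts H(z) exactly once", {
  spec <- phantom_spec(
    nx = 6, ny = 4, nz = 128, mu_t = 2, signal_db = 45,
    noise_floor_db = -Inf, speckle_contrast = 0, surface_offset_px = 0,
    confocal = list(focus_um = 300, rayleigh_um = 350), rolloff_db_per_mm = 3
  )
  vol <- make_eye_phantom(spec)$volume
  h <- octlseg:::system_response_db(spec)
  prof <- structure(
    list(h_db = h, mu_cal = 0, axial_pitch_um = 5.6, valid = rep(TRUE, 128)),
    class = "calibration_profile"
  )
  corr <- correct_system(vol, prof)
  # corrected noiseless homogeneous signal decays at exactly -2 mu 10/ln10
  z_mm <- (seq_len(128) - 1) * physical_pitch_um(vol) / 1000
  slope <- unname(coef(lm(corr$data[3, 2, ] ~ z_mm))[2])
  expect_equal(slope, -2 * 2 * 10 / log(10), tolerance = 1e-9)

  # H == 0 is the identity; correcting twice shifts by H again
  zero_prof <- structure(
    list(h_db = rep(0, 128), mu_cal = 0, axial_pitch_um = 5.6,
         valid = rep(TRUE, 128)),
    class = "calibration_profile"
  )
  expect_equal(correct_system(vol, zero_prof)$data, vol$data)
  twice <- correct_system(corr, prof)
  expect_equal(corr$data - twice$data, array(rep(h, each = 24), dim = dim(vol$data)),
    tolerance = 1e-12
  )
  short <- structure(
    list(h_db = rep(0, 64), mu_cal = 0, axial_pitch_um = 5.6,
         valid = rep(TRUE, 64)),
    class = "calibration_profile"
  )
  expect_error(correct_system(vol, short), "depth")
})

test_that("attenuation fitting recovers mu across the physiological range", {
  for (mu in c(0.5, 1, 2, 4)) {
    spec <- phantom_spec(
      nx = 4, ny = 2, nz = 256, mu_t = mu, signal_db = 45,
      noise_floor_db = -Inf, speckle_contrast = 0, surface_offset_px = 10
    )
    ph <- make_eye_phantom(spec)
    att <- fit_attenuation(ph$volume, ph$truth$surface)
    expect_true(all(att$valid))
    expect_lt(max(abs(att$mu - mu)) / mu, 1e-6)
    expect_gt(min(att$r_squared), 1 - 1e-9)
  }
  # a constant A-scan fits mu = 0
  flat <- oct_volume(array(10, dim = c(2, 2, 128)), 5.6, c(12, 12))
  att0 <- fit_attenuation(flat, matrix(1L, 2, 2))
  expect_equal(max(abs(att0$mu)), 0)
  # too-short windows are flagged invalid, not zeroed
  tiny <- oct_volume(array(10, dim = c(2, 2, 30)), 5.6, c(12, 12))
  att_inv <- fit_attenuation(tiny, matrix(20L, 2, 2))
  expect_false(any(att_inv$valid))
  expect_true(all(is.na(att_inv$mu)))
})

test_that("median fitted mu under full speckle is within 10%", {
  spec <- phantom_spec(
    nx = 64, ny = 64, nz = 256, mu_t = 2, signal_db = 45,
    noise_floor_db = -Inf, speckle_contrast = 1, surface_offset_px = 5,
    seed = 11
  )
  ph <- make_eye_phantom(spec)
  att <- fit_attenuation(ph$volume, ph$truth$surface)
  expect_lt(abs(median(att$mu[att$valid]) - 2) / 2, 0.1)
})

test_that("mu recovery bias stays below 10% over seeded speckled bundles", {
  # 100 bundles of 36 A-scans each, mu spanning the physiological range
  for (mu in c(0.5, 2, 4)) {
    meds <- vapply(1:10, function(s) {
      spec <- phantom_spec(
        nx = 60, ny = 6, nz = 256, mu_t = mu, signal_db = 45,
        noise_floor_db = -Inf, speckle_contrast = 1, surface_offset_px = 5,
        seed = 100 + s
      )
      ph <- make_eye_phantom(spec)
      att <- fit_attenuation(ph$volume, ph$truth$surface)
      median(att$mu[att$valid])
    }, numeric(1))
    expect_lt(abs(mean(meds) - mu) / mu, 0.1)
  }
})

test_that("compensation flattens homogeneous tissue and preserves vessel contrast", {
  spec <- phantom_spec(
    nx = 8, ny = 4, nz = 256, mu_t = 3, signal_db = 45,
    noise_floor_db = -Inf, speckle_contrast = 0, surface_offset_px = 10
  )
  ph <- make_eye_phantom(spec)
  att <- fit_attenuation(ph$volume, ph$truth$surface)
  comp <- compensate(ph$volume, att, ph$truth$surface)
  z_mm <- (seq_len(256) - 1) * physical_pitch_um(ph$volume) / 1000
  for (i in 1:8) {
    a <- comp$data[i, 2, 20:250]
    slope <- unname(coef(lm(a ~ z_mm[20:250]))[2])
    expect_lt(abs(slope), 0.01) # dB per mm
  }
  # zero attenuation map: identity
  att0 <- att
  att0$mu[] <- 0
  expect_equal(compensate(ph$volume, att0, ph$truth$surface)$data, ph$volume$data)

  # vessel interiors stay at least deficit/2 below compensated tissue
  case <- clean_vessel_case()
  compv <- case$result$compensated
  mask <- octlseg:::voxelize_vessels(case$spec)
  d <- dim(compv$data)
  zidx <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  below <- zidx > array(case$phantom$truth$surface, dim = d) &
    zidx < array(case$phantom$truth$surface + 100, dim = d)
  tissue_level <- median(compv$data[below & !mask])
  vessel_level <- median(compv$data[mask])
  expect_gte(tissue_level - vessel_level, 15 / 2)
})

test_that("threshold masks are monotone in theta and respect the surface", {
  case <- clean_vessel_case()
  comp <- case$result$compensated
  surf <- case$result$surface$surface
  thetas <- c(-20, 5, 10, 15, 40)
  masks <- lapply(thetas, function(t) threshold_vessels(comp, t, surf)$mask)
  for (k in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[k + 1]][masks[[k]]])) # subset relation
  }
  # theta below the minimum -> empty; above the maximum -> all below-surface
  expect_false(any(threshold_vessels(comp, min(comp$data) - 1, surf)$mask))
  full <- threshold_vessels(comp, max(comp$data) + 1, surf)$mask
  d <- dim(comp$data)
  zidx <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  below <- zidx > array(surf, dim = d)
  expect_identical(full, below)
})

test_that("surface detection follows flat and tilted phantoms", {
  spec_flat <- std_phantom_spec(nx = 64, ny = 8, surface_offset_px = 40,
    surface_tilt_um = c(0, 0), seed = 12)
  ph <- make_eye_phantom(spec_flat)
  sm <- detect_surface(normalize_noise(ph$volume))
  expect_true(all(abs(sm$surface - 40) <= 1))
  expect_true(all(sm$reliable))

  spec_tilt <- std_phantom_spec(nx = 96, ny = 8, surface_offset_px = 30,
    surface_tilt_um = c(2, 0), seed = 13)
  pht <- make_eye_phantom(spec_tilt)
  smt <- detect_surface(normalize_noise(pht$volume))
  plane <- octlseg:::surface_px(spec_tilt)
  expect_lt(sqrt(mean((smt$surface - plane)^2)), 2)

  # pure noise: every B-scan flagged unreliable
  set.seed(2)
  noise <- oct_volume(array(rnorm(32 * 4 * 64), dim = c(32, 4, 64)), 5.6, c(12, 12),
    noise_normalized = TRUE
  )
  expect_warning(smn <- detect_surface(noise), "unreliable|no edges")
  expect_false(any(smn$reliable))
})

test_that("flattening aligns the surface to depth 1 and commutes with masking", {
  case <- clean_vessel_case()
  res <- case$result
  flat_vol <- res$volume
  # the flattened volume's own surface re-detects at depth ~1 (some B-scans
  # legitimately warn: with the surface at depth 1 there is no "above" region)
  smf <- suppressWarnings(detect_surface(flat_vol))
  expect_lte(stats::quantile(smf$surface, 0.95), 2)

  # flat surface at z = 1: flatten_and_crop is a pure crop
  arr <- array(rnorm(8 * 4 * 64, 10), dim = c(8, 4, 64))
  vol <- oct_volume(arr, 5.6, c(12, 12))
  fc <- flatten_and_crop(vol, matrix(1L, 8, 4), crop_um = 100)
  expect_equal(fc$data, arr[, , 1:25])
  expect_error(flatten_and_crop(vol, matrix(1L, 8, 4), crop_um = 5000), "crop")

  # mask and volume flattened with the same surface stay in correspondence:
  # re-thresholding the flattened compensated volume reproduces the
  # flattened mask
  comp_flat <- flatten_and_crop(res$compensated, res$surface, crop_um = 500)
  rethr <- comp_flat$data < res$theta_db
  rethr[, , 1] <- FALSE # surface pixel itself is excluded in native frame
  agreement <- iou(rethr[, , -1], res$mask$mask[, , -1])
  expect_gte(agreement, 0.98)
})

test_that("the full conventional pipeline segments clean phantoms faithfully", {
  case <- clean_vessel_case()
  expect_gte(iou(case$result$mask$mask, case$gt_flat$mask), 0.8)

  ph0 <- make_eye_phantom(std_phantom_spec(seed = 5))
  res0 <- run_conventional(normalize_noise(ph0$volume), std_calibration())
  expect_lt(volume_density(res0$mask, c(0, 500)), 1)
})

test_that("the pipeline is insensitive to the B-scan orientation", {
  case <- clean_vessel_case()
  vol <- case$volume
  tvol <- oct_volume(
    aperm(vol$data, c(2, 1, 3)),
    vol$axial_pitch_um, rev(vol$lateral_pitch_um),
    vol$refractive_index, vol$noise_normalized
  )
  tres <- run_conventional(tvol, std_calibration())
  back <- aperm(tres$mask$mask, c(2, 1, 3))
  expect_gte(iou(back, case$result$mask$mask), 0.95)
})

test_that("a dark superficial layer creates the expected threshold artifact", {
  spec <- std_phantom_spec(seed = 5)
  spec$vessels <- random_vessels(spec, n = 3, deficit_db = 15, seed = 9)
  spec$layer <- list(thickness_um = 50, deficit_db = 10)
  ph <- make_eye_phantom(spec)
  res <- run_conventional(normalize_noise(ph$volume), std_calibration())
  gt <- vessel_mask(ph$truth$mask, frame = "native", provenance = "ground_truth")
  attr(gt, "physical_pitch_um") <- physical_pitch_um(ph$volume)
  gt_flat <- flatten_and_crop(gt, res$surface, crop_um = 500)
  fp <- res$mask$mask & !gt_flat$mask
  lay_px <- round(50 / physical_pitch_um(ph$volume))
  nz <- dim(fp)[3]
  fp_sup <- mean(fp[, , 1:lay_px])
  fp_deep <- mean(fp[, , (lay_px + 1):nz])
  expect_gte(fp_sup, 5 * fp_deep)
  expect_gt(fp_sup, 0.05)
})
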