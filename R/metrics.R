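#' Intersection over union of two binary masks
#'
#' `|a & b| / |a | b|`. When both masks are empty the IOU is defined as 1:
#' the two segmentations agree perfectly on the absence of vessels.
#'
#' @param a,b Logical (or 0/1) arrays of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
iou <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("iou: shape mismatch")
  a <- as.logical(a)
  b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) {
    return(1)
  }
  sum(a & b) / u
}

#' Per-B-scan IOU summary between two mask volumes
#'
#' Computes the IOU between corresponding B-scans (y slices) of the two 3-D
#' masks, and summarizes with the mean and the sample (n - 1) standard
#' deviation.
#'
#' @param mask_a,mask_b [vessel_mask()] objects (or 3-D logical arrays) on
#'   the same grid.
#' @return A `metrics_report`: list with `iou_per_bscan`, `mean_iou`,
#'   `sd_iou`, `n_bscans`.
#' @export
iou_summary <- function(mask_a, mask_b) {
  a <- if (inherits(mask_a, "vessel_mask")) mask_a$mask else mask_a
  b <- if (inherits(mask_b, "vessel_mask")) mask_b$mask else mask_b
  if (!all(dim(a) == dim(b))) stop("iou_summary: grids do not match")
  ny <- dim(a)[2]
  per <- vapply(
    seq_len(ny),
    function(j) iou(a[, j, ], b[, j, ]),
    numeric(1)
  )
  structure(
    list(
      iou_per_bscan = per,
      mean_iou = mean(per),
      sd_iou = if (ny > 1) sd(per) else 0,
      n_bscans = ny
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> mean IOU %.3f +/- %.3f over %d B-scans\n",
    x$mean_iou, x$sd_iou, x$n_bscans
  ))
  invisible(x)
}

# depth window (um from surface) -> 1-based z index range in a flattened
# array with the given physical pitch
window_to_idx <- function(window_um, pitch_um, nz) {
  lo <- max(1L, floor(window_um[1] / pitch_um) + 1L)
  hi <- min(nz, ceiling(window_um[2] / pitch_um))
  if (lo > hi) stop("depth window lies outside the cropped depth range")
  lo:hi
}

#' Binary en face projection of a vessel mask
#'
#' Collapses a depth window of a flattened mask along z: a lateral pixel is
#' vessel iff any voxel in the window is vessel.
#'
#' @param mask Flattened [vessel_mask()].
#' @param window_um Depth window below the surface, micrometres of tissue
#'   (length 2), e.g. `c(0, 300)` or `c(75, 400)`.
#' @param pitch_um Physical depth per pixel; taken from the mask attribute
#'   when present.
#' @return A `projection`: list with `image` (logical `[nx, ny]`),
#'   `kind = "binary"`, `window_um`.
#' @export
project <- function(mask, window_um = c(0, 300),
                    pitch_um = attr(mask, "physical_pitch_um")) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (mask$frame != "flattened") stop("project: mask must be flattened")
  if (is.null(pitch_um)) stop("project: physical pitch unknown")
  zz <- window_to_idx(window_um, pitch_um, dim(mask$mask)[3])
  img <- apply(mask$mask[, , zz, drop = FALSE], c(1, 2), any)
  structure(list(image = img, kind = "binary", window_um = window_um),
    class = "projection"
  )
}

#' Intensity-weighted en face projection
#'
#' Weights each vessel voxel by the reversed OCT signal
#' `w = (vmax - dB) / vmax` clipped to `[0, 1]` (vmax = the volume's 99.9th
#' percentile), so originally transparent vessel lumina project brightly;
#' each lateral pixel is the mean weight over the mask voxels in the window
#' (0 where the mask is empty).
#'
#' @param mask Flattened [vessel_mask()].
#' @param vol Flattened [oct_volume()] in the same frame.
#' @param window_um Depth window below the surface (micrometres, length 2).
#' @return A `projection` with `kind = "weighted"`, values in `[0, 1]`.
#' @export
weighted_project <- function(mask, vol, window_um = c(0, 300)) {
  stopifnot(inherits(mask, "vessel_mask"), inherits(vol, "oct_volume"))
  if (mask$frame != "flattened" ||
      !identical(attr(vol, "frame") %||% "flattened", "flattened")) {
    stop("weighted_project: mask and volume must be in the flattened frame")
  }
  if (!all(dim(mask$mask) == dim(vol$data))) {
    stop("weighted_project: mask and volume grids do not match")
  }
  pitch <- physical_pitch_um(vol)
  zz <- window_to_idx(window_um, pitch, dim(vol$data)[3])
  vmax <- quantile(vol$data, 0.999, names = FALSE)
  w <- pmin(pmax((vmax - vol$data[, , zz, drop = FALSE]) / vmax, 0), 1)
  m <- mask$mask[, , zz, drop = FALSE]
  num <- apply(w * m, c(1, 2), sum)
  den <- apply(m, c(1, 2), sum)
  img <- ifelse(den > 0, num / pmax(den, 1), 0)
  structure(list(image = img, kind = "weighted", window_um = window_um),
    class = "projection"
  )
}

#' Vessel area density of a binary projection
#'
#' Percentage of lateral pixels marked vessel in the en face projection.
#'
#' @param p A binary `projection` from [project()].
#' @return Percentage in `[0, 100]`.
#' @export
area_density <- function(p) {
  stopifnot(inherits(p, "projection"))
  if (p$kind != "binary") stop("area_density: needs a binary projection")
  100 * mean(p$image)
}

#' Vessel volume density within a depth window
#'
#' Percentage of voxels marked vessel among all voxels of the depth window.
#'
#' @param mask Flattened [vessel_mask()].
#' @param window_um Depth window below the surface (micrometres, length 2).
#' @param pitch_um Physical depth per pixel; taken from the mask attribute
#'   when present.
#' @return Percentage in `[0, 100]`.
#' @export
volume_density <- function(mask, window_um = c(0, 300),
                           pitch_um = attr(mask, "physical_pitch_um")) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (is.null(pitch_um)) stop("volume_density: physical pitch unknown")
  zz <- window_to_idx(window_um, pitch_um, dim(mask$mask)[3])
  100 * mean(mask$mask[, , zz])
}
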