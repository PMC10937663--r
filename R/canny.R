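# Canny edge detection on a single B-scan (matrix), used for tissue-surface
# detection. Gaussian smoothing, Sobel gradients, non-maximum suppression
# along the quantized gradient direction, and two-threshold hysteresis
# (weak edges kept only when connected to a strong edge).

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k / sum(k)
}

# separable same-size convolution with replicate padding
conv_sep <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  pad_rows <- function(m) rbind(
    m[rep(1L, r), , drop = FALSE], m,
    m[rep(nrow(m), r), , drop = FALSE]
  )
  conv_cols <- function(m) {
    p <- pad_rows(m)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * p[i:(i + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(img))))
}

shift_mat <- function(m, di, dj) {
  n <- nrow(m)
  p <- ncol(m)
  out <- matrix(FALSE, n, p)
  si <- seq_len(n) - di
  sj <- seq_len(p) - dj
  ok_i <- si >= 1 & si <= n
  ok_j <- sj >= 1 & sj <= p
  out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
  out
}

canny_edges <- function(img, sigma = 2, low = 0.1, high = 0.3) {
  sm <- conv_sep(img, gaussian_kernel1d(sigma))
  n <- nrow(sm)
  p <- ncol(sm)
  pad <- function(m) {
    m <- rbind(m[1, ], m, m[n, ])
    cbind(m[, 1], m, m[, p])
  }
  pm <- pad(sm)
  ctr <- function(di, dj) pm[(2 + di):(n + 1 + di), (2 + dj):(p + 1 + dj)]
  # Sobel
  gx <- (ctr(1, -1) + 2 * ctr(1, 0) + ctr(1, 1)) -
    (ctr(-1, -1) + 2 * ctr(-1, 0) + ctr(-1, 1))
  gy <- (ctr(-1, 1) + 2 * ctr(0, 1) + ctr(1, 1)) -
    (ctr(-1, -1) + 2 * ctr(0, -1) + ctr(1, -1))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) {
    return(matrix(FALSE, n, p))
  }
  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- (floor((ang + pi / 8) / (pi / 4)) %% 4) # 0:E-W 1:NE 2:N-S 3:NW
  pmag <- pad(mag)
  ctrm <- function(di, dj) pmag[(2 + di):(n + 1 + di), (2 + dj):(p + 1 + dj)]
  nb1 <- matrix(0, n, p)
  nb2 <- matrix(0, n, p)
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  for (s in 0:3) {
    o <- offs[[s + 1]]
    sel <- sector == s
    nb1[sel] <- ctrm(o[1], o[2])[sel]
    nb2[sel] <- ctrm(-o[1], -o[2])[sel]
  }
  keep <- mag >= nb1 & mag >= nb2
  hi_thr <- high * max(mag)
  lo_thr <- low * max(mag)
  strong <- keep & mag >= hi_thr
  weak <- keep & mag >= lo_thr
  # hysteresis: grow strong edges into connected weak pixels (8-connected)
  edges <- strong
  repeat {
    grown <- edges
    for (di in -1:1) {
      for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        grown <- grown | shift_mat(edges, di, dj)
      }
    }
    grown <- grown & weak
    if (all(grown == edges)) break
    edges <- grown
  }
  edges
}
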