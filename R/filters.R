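# Separable 3D filtering primitives on plain 3D arrays. Intensity filters
# (Sobel, Gaussian) use edge-replicate borders so uniform regions produce no
# spurious boundary response; morphological shifts use zero fill.

# Shift a 3D array by s voxels along one axis: out(i) = a(i + s), with
# out-of-range source indices either zero-filled or clamped to the edge.
shift3 <- function(a, s, axis, border = c("zero", "replicate")) {
  border <- match.arg(border)
  d <- dim(a)
  n <- d[axis]
  idx <- seq_len(n) + s
  if (border == "zero") {
    out <- array(0, d)
    keep <- idx >= 1L & idx <= n
    if (!any(keep)) return(out)
    if (axis == 1L) out[keep, , ] <- a[idx[keep], , , drop = FALSE]
    else if (axis == 2L) out[, keep, ] <- a[, idx[keep], , drop = FALSE]
    else out[, , keep] <- a[, , idx[keep], drop = FALSE]
    out
  } else {
    idx <- pmin(pmax(idx, 1L), n)
    if (axis == 1L) a[idx, , , drop = FALSE]
    else if (axis == 2L) a[, idx, , drop = FALSE]
    else a[, , idx, drop = FALSE]
  }
}

# 1D correlation along an axis with an odd-length kernel:
# out(i) = sum_j k[j] * a(i + j - r - 1).
axis_correlate <- function(a, k, axis, border = "replicate") {
  r <- (length(k) - 1L) %/% 2L
  out <- array(0, dim(a))
  for (j in seq_along(k)) {
    if (k[j] != 0) out <- out + k[j] * shift3(a, j - r - 1L, axis, border)
  }
  out
}

# Reverse a 3D array along one axis (the z-flip used in augmentation).
flip3 <- function(a, axis = 3L) {
  n <- dim(a)[axis]
  if (axis == 1L) a[n:1, , , drop = FALSE]
  else if (axis == 2L) a[, n:1, , drop = FALSE]
  else a[, , n:1, drop = FALSE]
}

# Separable discrete Gaussian on a 3D array; sigma given per axis in voxels.
gaussian_smooth3 <- function(a, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    a <- axis_correlate(a, k, axis)
  }
  a
}

#' Sobel contour image of a vessel volume
#'
#' Applies the separable 3x3x3 Sobel operator along each axis (derivative
#' kernel (-1, 0, 1) combined with (1, 2, 1) smoothing on the two transverse
#' axes, edge-replicate borders) and returns the Euclidean gradient magnitude rescaled to
#' \[0, 1\] by its maximum. A uniform input yields an all-zero contour. The
#' contour image is the second input channel of the fine network: it
#' emphasizes the vessel wall and the neck of an attached aneurysm, which is
#' exactly where segmentation errors concentrate.
#'
#' @param vessel A `volume_image`.
#' @return A `volume_image` with values in \[0, 1\] on the same geometry.
#' @export
sobel_contour <- function(vessel) {
  stopifnot(inherits(vessel, "volume_image"))
  a <- vessel$data
  d <- c(-1, 0, 1)
  s <- c(1, 2, 1)
  gx <- axis_correlate(axis_correlate(axis_correlate(a, d, 1L), s, 2L), s, 3L)
  gy <- axis_correlate(axis_correlate(axis_correlate(a, s, 1L), d, 2L), s, 3L)
  gz <- axis_correlate(axis_correlate(axis_correlate(a, s, 1L), s, 2L), d, 3L)
  mag <- sqrt(gx^2 + gy^2 + gz^2)
  m <- max(mag)
  if (m > 0) mag <- mag / m
  volume_image(mag, spacing = vessel$spacing, origin = vessel$origin)
}

#' Gaussian filtering at a physical scale
#'
#' Discrete Gaussian smoothing with the standard deviation specified in mm
#' and converted to voxels through the volume's spacing, so the amount of
#' smoothing is consistent across acquisitions with different resolutions.
#'
#' @param vol A `volume_image`.
#' @param sigma_mm Standard deviation of the Gaussian in mm.
#' @return A smoothed `volume_image`.
#' @export
gaussian_filter <- function(vol, sigma_mm = 0.5) {
  stopifnot(inherits(vol, "volume_image"), sigma_mm > 0)
  out <- gaussian_smooth3(vol$data, sigma_mm / vol$spacing)
  volume_image(out, spacing = vol$spacing, origin = vol$origin)
}

#' Histogram equalization of a volume
#'
#' Classic global histogram equalization over `bins` equal-width bins of the
#' volume's intensity range; the output is mapped back onto the original
#' \[min, max\] range so equalized copies remain comparable to their sources.
#' Constant volumes are returned unchanged.
#'
#' @param vol A `volume_image`.
#' @param bins Number of histogram bins.
#' @return An equalized `volume_image`.
#' @export
hist_equalize <- function(vol, bins = 256L) {
  stopifnot(inherits(vol, "volume_image"), bins >= 2)
  a <- vol$data
  rng <- range(a)
  if (diff(rng) == 0) return(vol)
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  bin <- findInterval(a, br, rightmost.closed = TRUE, all.inside = TRUE)
  cdf <- cumsum(tabulate(bin, nbins = bins)) / length(a)
  c0 <- cdf[min(bin)]   # anchor the smallest occupied bin at the range minimum
  if (1 - c0 <= 0) return(vol)
  out <- array(rng[1] + diff(rng) * (cdf[bin] - c0) / (1 - c0), dim(a))
  volume_image(out, spacing = vol$spacing, origin = vol$origin)
}
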