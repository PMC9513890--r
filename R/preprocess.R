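#' Z-score intensity normalization
#'
#' Standardizes a volume to zero mean and unit standard deviation (population
#' moments) with the statistics computed over the whole volume (the phantom
#' generator and extracted-vessel inputs have controlled background, so no
#' masking is applied).
#'
#' @param vol A `volume_image` with more than one distinct value.
#' @return A normalized `volume_image`.
#' @export
zscore <- function(vol) {
  stopifnot(inherits(vol, "volume_image"))
  mu <- mean(vol$data)
  sig <- sqrt(mean((vol$data - mu)^2))
  if (!is.finite(sig) || sig == 0) {
    stop("cannot z-score a constant volume", call. = FALSE)
  }
  volume_image((vol$data - mu) / sig, spacing = vol$spacing, origin = vol$origin)
}

#' 26-connected components of a binary mask
#'
#' @param mask A `binary_mask` (or 3D 0/1 array).
#' @return A list with `labels` (integer array, 0 background, components
#'   numbered from 1) and `n` (component count).
#' @export
label_components <- function(mask) {
  arr <- if (inherits(mask, "binary_mask")) mask$data else mask
  stopifnot(length(dim(arr)) == 3L)
  storage.mode(arr) <- "integer"
  lab <- cpp_label_components26(arr, dim(arr))
  list(labels = lab, n = if (length(lab)) max(lab) else 0L)
}

# Euclidean-ball dilation of a logical/0-1 3D array by r voxels,
# restricted to the bounding box of the foreground for speed.
dilate_ball <- function(arr, r) {
  idx <- which(arr != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(arr)
  d <- dim(arr)
  lo <- pmax(apply(idx, 2, min) - r, 1L)
  hi <- pmin(apply(idx, 2, max) + r, d)
  sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out <- sub
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    if (dx * dx + dy * dy + dz * dz > r * r) next
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- pmax(out, shift3(sub, dx, 1L) |> shift3(dy, 2L) |> shift3(dz, 3L))
  }
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- out
  arr
}

#' Size-adaptive dilation of aneurysm labels
#'
#' Before coarse training each labelled aneurysm is dilated in proportion to
#' its own size, so small lesions gain enough foreground voxels to be
#' detectable at low resolution. Per 26-connected component the equivalent
#' sphere diameter \eqn{d_{eq} = 2 (3V / 4\pi)^{1/3}} (V = voxel count times
#' voxel volume, mm^3) sets a ball dilation radius of
#' \code{max(1, round(coef * d_eq / mean(spacing)))} voxels.
#'
#' @param label A nonempty `binary_mask`.
#' @param coef Proportionality coefficient between equivalent diameter and
#'   dilation radius (default 0.25).
#' @return The dilated `binary_mask` (always a superset of the input).
#' @export
adaptive_dilate_label <- function(label, coef = 0.25) {
  stopifnot(inherits(label, "binary_mask"))
  if (sum(label$data) == 0) stop("label mask is empty", call. = FALSE)
  comps <- label_components(label)
  vox_vol <- prod(label$spacing)
  out <- label$data
  for (i in seq_len(comps$n)) {
    comp <- array(as.integer(comps$labels == i), dim(out))
    d_eq <- 2 * (3 * sum(comp) * vox_vol / (4 * pi))^(1 / 3)
    r <- max(1L, as.integer(floor(coef * d_eq / mean(label$spacing) + 0.5)))
    out <- pmax(out, dilate_ball(comp, r))
  }
  binary_mask(out, spacing = label$spacing, origin = label$origin)
}

#' Augmentation policy
#'
#' The three transform families used for eightfold augmentation: flipping
#' along the z axis, discrete Gaussian filtering, and histogram equalization.
#'
#' @param flip_axis Axis to flip along (3 = z).
#' @param gaussian_sigma_mm Gaussian standard deviation in mm.
#' @param hist_eq_bins Histogram-equalization bin count.
#' @return An `augment_policy` list.
#' @export
augment_policy <- function(flip_axis = 3L, gaussian_sigma_mm = 0.5,
                           hist_eq_bins = 256L) {
  stopifnot(flip_axis %in% 1:3, gaussian_sigma_mm > 0, hist_eq_bins >= 2)
  structure(list(flip_axis = as.integer(flip_axis),
                 gaussian_sigma_mm = gaussian_sigma_mm,
                 hist_eq_bins = as.integer(hist_eq_bins)),
            class = "augment_policy")
}

# Apply an intensity or geometric transform to a bundle. The label only ever
# undergoes the geometric flip; contour channels are re-derived from the
# transformed vessel volume so the two channels stay consistent.
transform_bundle <- function(b, kind, policy) {
  v <- b$vessel
  lab <- b$label
  if (kind == "flip") {
    v <- volume_image(flip3(v$data, policy$flip_axis), v$spacing, v$origin)
    lab <- binary_mask(flip3(lab$data, policy$flip_axis), lab$spacing, lab$origin)
  } else if (kind == "gauss") {
    v <- gaussian_filter(v, policy$gaussian_sigma_mm)
  } else if (kind == "histeq") {
    v <- hist_equalize(v, policy$hist_eq_bins)
  }
  volume_bundle(v, sobel_contour(v), lab)
}

#' Eightfold data augmentation
#'
#' Cumulative augmentation of a training set: the originals (N) are joined by
#' their z-flips (2N); Gaussian-filtered copies of those 2N bundles bring the
#' total to 4N; histogram-equalized copies of those 4N bring it to 8N. Labels
#' undergo only the geometric flip, never intensity transforms, and every
#' derived bundle's contour channel is recomputed from its transformed vessel
#' volume.
#'
#' @param bundles Nonempty list of `volume_bundle` objects.
#' @param policy An [augment_policy()].
#' @return A list of `8 * length(bundles)` bundles (originals first).
#' @export
augment_eightfold <- function(bundles, policy = augment_policy()) {
  if (length(bundles) == 0L) stop("empty input list", call. = FALSE)
  stopifnot(all(vapply(bundles, inherits, logical(1), "volume_bundle")),
            inherits(policy, "augment_policy"))
  flips <- lapply(bundles, transform_bundle, kind = "flip", policy = policy)
  two_n <- c(bundles, flips)
  four_n <- c(two_n, lapply(two_n, transform_bundle, kind = "gauss",
                            policy = policy))
  c(four_n, lapply(four_n, transform_bundle, kind = "histeq", policy = policy))
}
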