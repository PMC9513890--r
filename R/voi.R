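#' Volume-of-interest cube
#'
#' An axis-aligned cube in voxel index space, described by its centre, side
#' length, the clipped in-volume bounds `lo`/`hi` (1-based, inclusive), and
#' the zero-padding applied on each side where the cube extends beyond the
#' volume. Invariant: `(hi - lo + 1) + pad_before + pad_after == side` on
#' every axis.
#'
#' @param center Integer length-3 voxel index (1-based) of the cube centre.
#' @param side Cube side length in voxels.
#' @param shape Shape of the host volume.
#' @return A `voi_box` list.
#' @export
voi_box <- function(center, side, shape) {
  center <- as.integer(center)
  side <- as.integer(side)
  shape <- as.integer(shape)
  stopifnot(length(center) == 3L, length(shape) == 3L, side >= 1L)
  if (any(center < 1L) || any(center > shape)) {
    stop("cube centre lies outside the volume", call. = FALSE)
  }
  half <- side %/% 2L
  lo_req <- center - half
  hi_req <- lo_req + side - 1L
  pad_before <- pmax(0L, 1L - lo_req)
  pad_after <- pmax(0L, hi_req - shape)
  structure(list(center = center, side = side,
                 lo = pmax(lo_req, 1L), hi = pmin(hi_req, shape),
                 pad_before = pad_before, pad_after = pad_after),
            class = "voi_box")
}

#' Centroid of a label mask
#'
#' Arithmetic mean of the foreground voxel indices, rounded half-up per axis.
#'
#' @param mask A nonempty `binary_mask`.
#' @return Integer length-3 voxel index (1-based).
#' @export
label_centroid <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  idx <- which(mask$data != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty", call. = FALSE)
  as.integer(floor(colMeans(idx) + 0.5))
}

#' Crop a cubic VOI from a volume
#'
#' Extracts a cube of exactly `side`^3 voxels centred on `center`; regions
#' falling outside the source volume are zero-filled and recorded in the
#' box's pad fields. Cropping a vessel volume and its contour volume with the
#' same box yields spatially aligned channels.
#'
#' @param vol A `volume_image` or `binary_mask`.
#' @param center Integer length-3 cube centre (must lie inside the volume).
#' @param side Cube side in voxels (default 64).
#' @return A list with `data` (a `side`^3 array) and `box` (the [voi_box()]).
#' @export
crop_cube <- function(vol, center, side = 64L) {
  stopifnot(inherits(vol, "volume_image") || inherits(vol, "binary_mask"))
  box <- voi_box(center, side, dim(vol$data))
  crop_with_box(vol$data, box)
}

crop_with_box <- function(arr, box) {
  side <- box$side
  out <- array(0, rep(side, 3L))
  dst <- lapply(1:3, function(ax) {
    (box$pad_before[ax] + 1L):(side - box$pad_after[ax])
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    arr[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]]
  list(data = out, box = box)
}

#' Propose VOIs from a coarse segmentation mask
#'
#' One cube per 26-connected component of the coarse mask, centred on the
#' component centroid. Near-duplicate boxes — centres within `side / 2`
#' voxels of one another in Chebyshev distance — are merged into a single box
#' at their voxel-count-weighted mean centroid, so one aneurysm never
#' receives two fine passes. An empty coarse mask yields an empty list.
#'
#' @param coarse_mask A `binary_mask` from the coarse network.
#' @param side Cube side in voxels.
#' @return List of [voi_box()] objects (possibly empty).
#' @export
propose_vois <- function(coarse_mask, side = 64L) {
  stopifnot(inherits(coarse_mask, "binary_mask"))
  comps <- label_components(coarse_mask)
  if (comps$n == 0L) return(list())
  idx <- which(coarse_mask$data != 0, arr.ind = TRUE)
  labs <- comps$labels[coarse_mask$data != 0]
  cent <- t(vapply(seq_len(comps$n),
                   function(i) colMeans(idx[labs == i, , drop = FALSE]),
                   numeric(3)))
  wt <- as.numeric(tabulate(labs, comps$n))
  # iterative merge of near-duplicate centres (Chebyshev < side/2)
  repeat {
    n <- nrow(cent)
    if (n <= 1L) break
    merged <- FALSE
    for (i in seq_len(n - 1L)) {
      dcheb <- apply(abs(cent[(i + 1L):n, , drop = FALSE] -
                           matrix(cent[i, ], n - i, 3, byrow = TRUE)), 1, max)
      j <- which(dcheb < side / 2)
      if (length(j) > 0L) {
        j <- i + j[1L]
        w <- wt[i] + wt[j]
        cent[i, ] <- (wt[i] * cent[i, ] + wt[j] * cent[j, ]) / w
        wt[i] <- w
        cent <- cent[-j, , drop = FALSE]
        wt <- wt[-j]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  shape <- dim(coarse_mask$data)
  lapply(seq_len(nrow(cent)), function(i) {
    ctr <- pmin(pmax(as.integer(floor(cent[i, ] + 0.5)), 1L), shape)
    voi_box(ctr, side, shape)
  })
}

#' Paste VOI predictions back into full-volume space
#'
#' The padded border of each cube is discarded; where cubes overlap the
#' predictions combine by logical OR; voxels outside every cube are 0.
#'
#' @param voi_masks List of `list(data = side^3 0/1 array, box = voi_box)`.
#' @param shape Integer length-3 full-volume shape.
#' @param spacing,origin Geometry for the returned mask.
#' @return A full-size `binary_mask`.
#' @export
paste_back <- function(voi_masks, shape, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  out <- array(0L, shape)
  for (vm in voi_masks) {
    box <- vm$box
    side <- box$side
    if (!identical(dim(vm$data), rep(side, 3L)) &&
        !all(dim(vm$data) == side)) {
      stop("VOI mask shape does not match its box side", call. = FALSE)
    }
    if (any(box$hi > shape) || any(box$lo < 1L)) {
      stop("box bounds inconsistent with the target shape", call. = FALSE)
    }
    src <- lapply(1:3, function(ax) {
      (box$pad_before[ax] + 1L):(side - box$pad_after[ax])
    })
    sub <- vm$data[src[[1]], src[[2]], src[[3]], drop = FALSE]
    tgt <- out[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]]
    out[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <-
      pmax(tgt, as.integer(sub != 0))
  }
  binary_mask(out, spacing = spacing, origin = origin)
}
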