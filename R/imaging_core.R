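#' Volumetric data model
#'
#' A `volume_image` carries a 3D array of scalar intensities together with its
#' voxel spacing (mm) and origin (mm); a `binary_mask` is the same geometry
#' restricted to values {0, 1} and is used for ground-truth labels and
#' predictions. A `volume_bundle` groups the three aligned channels the fine
#' network consumes: the vessel image, its contour image, and the label.
#'
#' Conventions: voxel indices are 1-based R array indices in (x, y, z) order;
#' the direction matrix is assumed identity, so geometry is fully described by
#' spacing and origin. Two objects share geometry when their shapes are equal
#' and spacings agree within 1e-6 mm.
#'
#' @param data 3D numeric array of intensities (for masks: values 0/1).
#' @param spacing Numeric length-3, voxel edge lengths in mm, all > 0.
#' @param origin Numeric length-3, position of the first voxel centre in mm.
#' @return `volume_image()` and `binary_mask()` return validated objects of
#'   the corresponding class; `volume_bundle()` a `volume_bundle` list.
#' @examples
#' v <- volume_image(array(rnorm(8 * 8 * 8), c(8, 8, 8)), spacing = c(0.5, 0.5, 0.5))
#' m <- binary_mask(array(0L, c(8, 8, 8)), spacing = c(0.5, 0.5, 0.5))
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- check_vol_array(data)
  spacing <- check_spacing(spacing)
  origin <- check_origin(origin)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @rdname volume_image
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- check_vol_array(data)
  if (!all(data %in% c(0, 1))) {
    stop("mask values must be exactly 0 or 1", call. = FALSE)
  }
  storage.mode(data) <- "integer"
  spacing <- check_spacing(spacing)
  origin <- check_origin(origin)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "binary_mask")
}

#' @rdname volume_image
#' @param vessel,contour `volume_image` channels (vessel intensities and the
#'   Sobel contour image; the contour may be all-zero until preprocessing
#'   fills it in).
#' @param label `binary_mask` of aneurysm voxels, aligned with `vessel`.
#' @export
volume_bundle <- function(vessel, contour, label) {
  stopifnot(inherits(vessel, "volume_image"), inherits(contour, "volume_image"),
            inherits(label, "binary_mask"))
  if (!same_geometry(vessel, contour) || !same_geometry(vessel, label)) {
    stop("vessel, contour and label must share shape and spacing", call. = FALSE)
  }
  structure(list(vessel = vessel, contour = contour, label = label),
            class = "volume_bundle")
}

check_vol_array <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    stop("data must be a 3D array", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all axes must have length >= 1", call. = FALSE)
  if (!is.numeric(data)) stop("data must be numeric", call. = FALSE)
  data
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive finite values (mm)", call. = FALSE)
  }
  spacing
}

check_origin <- function(origin) {
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin))) {
    stop("origin must be 3 finite values (mm)", call. = FALSE)
  }
  origin
}

#' Geometry agreement between two volumes
#'
#' Shapes must be identical and spacings agree within `tol` mm.
#'
#' @param a,b `volume_image` or `binary_mask` objects.
#' @param tol Spacing tolerance in mm.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) && all(abs(a$spacing - b$spacing) <= tol)
}

stop_if_geometry_differs <- function(a, b) {
  if (!same_geometry(a, b)) {
    stop("inputs do not share shape/spacing", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, spacing %s mm, %d foreground\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$data)))
  invisible(x)
}

#' Read a 3D volume or mask from NIfTI-1
#'
#' Spacing is taken from the file's pixdim and the origin from the qform
#' offset. The array axis order is the NIfTI on-disk order (x, y, z).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param mask If `TRUE`, validate and return a `binary_mask`.
#' @return A `volume_image` (or `binary_mask`).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D image, got ", length(dim(arr)), " dimensions",
         call. = FALSE)
  }
  hdr <- RNifti::niftiHeader(img)
  spacing <- abs(as.numeric(RNifti::pixdim(img)))[1:3]
  origin <- as.numeric(c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
  attributes(arr) <- list(dim = dim(arr))
  if (mask) {
    binary_mask(arr, spacing = spacing, origin = origin)
  } else {
    volume_image(arr, spacing = spacing, origin = origin)
  }
}

#' Write a volume or mask to NIfTI-1
#'
#' Masks are stored as unsigned 8-bit, intensity volumes as float64. The
#' spacing and origin are written into the qform (code 2).
#'
#' @param vol A `volume_image` or `binary_mask`.
#' @param path Output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image") || inherits(vol, "binary_mask"))
  if (!dir.exists(dirname(path))) {
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  }
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  xf <- diag(c(vol$spacing, 1))
  xf[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  dt <- if (inherits(vol, "binary_mask")) "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}
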