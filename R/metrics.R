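#' Weighted dice loss configuration
#'
#' @param beta Exponent of the `(1 - D)^beta` weight, in \[0, 1\]. At 0 the
#'   loss reduces to the plain negative soft dice ("initial loss").
#' @param smooth Smoothing constant S added to numerator (as S/2) and
#'   denominator of the soft dice; default 1e-4.
#' @param detach_weight If `TRUE` (default) the `(1 - D)^beta` factor is
#'   treated as a constant during backpropagation and contributes no
#'   gradient.
#' @return A `loss_config` list.
#' @export
loss_config <- function(beta = 0.1, smooth = 1e-4, detach_weight = TRUE) {
  if (!is.numeric(beta) || beta < 0 || beta > 1) {
    stop("beta must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(smooth > 0)
  structure(list(beta = beta, smooth = smooth,
                 detach_weight = isTRUE(detach_weight)),
            class = "loss_config")
}

as_mask_array <- function(m) {
  if (inherits(m, "binary_mask")) m$data else m
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("shape mismatch between prediction and ground truth", call. = FALSE)
  }
}

#' Soft dice overlap
#'
#' \eqn{D = 2 (\sum g p + S/2) / (\sum g + \sum p + S)} over all voxels,
#' where g is the binary ground truth and p the predicted foreground
#' probability. With both inputs empty the smoothing terms give D = 1.
#'
#' @param pred_prob Numeric array of foreground probabilities in \[0, 1\].
#' @param gt `binary_mask` or 0/1 array of the same shape.
#' @param smooth Smoothing constant S.
#' @return Scalar in (0, 1\].
#' @export
soft_dice <- function(pred_prob, gt, smooth = 1e-4) {
  g <- as_mask_array(gt)
  p <- if (inherits(pred_prob, "volume_image")) pred_prob$data else pred_prob
  check_same_shape(p, g)
  (2 * sum(g * p) + smooth) / (sum(g) + sum(p) + smooth)
}

#' Weighted dice loss
#'
#' \eqn{L = -(1 - D)^\beta D} with D the soft dice of the current
#' prediction. The weight `(1 - D)^beta` grows as the overlap worsens, so
#' poorly segmented cases incur relatively larger loss than under the plain
#' dice loss; for `beta` in \[0, 1\] the weight is strictly decreasing in D.
#' At `beta = 0` the loss is exactly the negative soft dice.
#'
#' @inheritParams soft_dice
#' @param cfg A [loss_config()].
#' @return Scalar in \[-1, 0\].
#' @export
weighted_dice_loss <- function(pred_prob, gt, cfg = loss_config()) {
  stopifnot(inherits(cfg, "loss_config"))
  d <- soft_dice(pred_prob, gt, cfg$smooth)
  -(1 - d)^cfg$beta * d
}

# Loss value and gradient wrt the foreground probability array. With
# detach_weight the (1-D)^beta factor is held constant; otherwise the chain
# rule through the weight is included.
weighted_dice_loss_grad <- function(pred_prob, gt, cfg = loss_config()) {
  g <- as_mask_array(gt)
  p <- pred_prob
  check_same_shape(p, g)
  s <- cfg$smooth
  num <- 2 * sum(g * p) + s
  den <- sum(g) + sum(p) + s
  d <- num / den
  w <- (1 - d)^cfg$beta
  dD_dp <- (2 * g * den - num) / den^2
  if (cfg$detach_weight || cfg$beta == 0) {
    dL_dD <- -w
  } else {
    dL_dD <- -w + cfg$beta * (1 - d)^(cfg$beta - 1) * d
  }
  list(loss = -w * d, grad = dL_dD * dD_dp)
}

#' Dice similarity coefficient of two binary masks
#'
#' \eqn{2 |GT \cap Pred| / (|GT| + |Pred|)}; defined as 1 when both masks
#' are empty.
#'
#' @param gt,pred `binary_mask` objects or 0/1 arrays of equal shape.
#' @return Scalar in \[0, 1\].
#' @export
dice_coefficient <- function(gt, pred) {
  g <- as_mask_array(gt)
  p <- as_mask_array(pred)
  check_same_shape(g, p)
  denom <- sum(g) + sum(p)
  if (denom == 0) return(1)
  2 * sum(g * p) / denom
}

#' Hausdorff distance between two masks, in mm
#'
#' Symmetric maximum of the two directed Hausdorff distances between the
#' foreground voxel-centre point sets, scaled to physical mm by the voxel
#' spacing (full maximum, not a percentile). If either mask is empty the
#' distance is undefined and `NA` is returned; evaluation summaries count
#' and exclude such cases.
#'
#' @param gt,pred `binary_mask` objects (or 0/1 arrays when `spacing` is
#'   given explicitly).
#' @param spacing Voxel spacing in mm; defaults to the masks' spacing.
#' @return Distance in mm, or `NA_real_` when undefined.
#' @export
hausdorff_mm <- function(gt, pred, spacing = NULL) {
  g <- as_mask_array(gt)
  p <- as_mask_array(pred)
  check_same_shape(g, p)
  if (is.null(spacing)) {
    if (!inherits(gt, "binary_mask")) {
      stop("spacing must be supplied for plain arrays", call. = FALSE)
    }
    stop_if_geometry_differs(gt, pred)
    spacing <- gt$spacing
  }
  ia <- which(g != 0, arr.ind = TRUE)
  ib <- which(p != 0, arr.ind = TRUE)
  if (nrow(ia) == 0L || nrow(ib) == 0L) return(NA_real_)
  A <- sweep(ia, 2, spacing, "*")
  B <- sweep(ib, 2, spacing, "*")
  cpp_hausdorff(A, B)
}

#' Volumetric similarity of two masks
#'
#' \eqn{1 - ||GT| - |Pred|| / (|GT| + |Pred|)}; defined as 1 when both masks
#' are empty.
#'
#' @inheritParams dice_coefficient
#' @return Scalar in \[0, 1\].
#' @export
volumetric_similarity <- function(gt, pred) {
  g <- as_mask_array(gt)
  p <- as_mask_array(pred)
  check_same_shape(g, p)
  denom <- sum(g) + sum(p)
  if (denom == 0) return(1)
  1 - abs(sum(g) - sum(p)) / denom
}

#' Per-case segmentation scores
#'
#' @param gt,pred Geometry-matched `binary_mask` objects.
#' @return A list with `dsc`, `hd_mm` (`NA` when undefined), `vs`.
#' @export
seg_scores <- function(gt, pred) {
  stop_if_geometry_differs(gt, pred)
  list(dsc = dice_coefficient(gt, pred),
       hd_mm = hausdorff_mm(gt, pred),
       vs = volumetric_similarity(gt, pred))
}
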