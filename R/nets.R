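# Network constructors: the dual-channel fine U-Net and the lightweight
# coarse encoder-decoder. Both are plain R objects (config + named list of
# parameter arrays) evaluated through the autodiff tape in nn_autodiff.R.

#' Fine-network configuration
#'
#' A four-level (by default) encoder-decoder: the input layer is a 3x3x3
#' stride-1 convolution; each deeper encoder stage is a 3x3x3 stride-2
#' convolution followed by a context block (two 3x3x3 stride-1 convolutions
#' with dropout in between) with a residual addition from the stage entry to
#' the context output. A squeeze-and-excitation (SE) channel-attention block
#' follows the penultimate context block, and another follows the first
#' (deepest) upsampling block of the decoder. Decoder stages upsample
#' (nearest-neighbour x2 then a 3x3x3 convolution), concatenate with the
#' matching encoder output, and apply a localization block (3x3x3 then 1x1x1
#' convolution). Segmentation heads at the coarsest decoder levels are
#' upsampled and summed into the final 3x3x3 output head (deep supervision)
#' before the voxelwise softmax.
#'
#' @param in_channels 2 for the dual-channel (vessel + contour) model, 1 for
#'   the single-channel ablation.
#' @param n_classes Number of output classes (2: background / aneurysm).
#' @param depth Number of resolution levels (input side must be divisible by
#'   `2^(depth - 1)`).
#' @param base_filters Filters at the finest level, doubled per level
#'   (paper-scale 16; the desk-scale preset is 4).
#' @param dropout_p Dropout probability inside context blocks.
#' @param se_reduction SE bottleneck reduction ratio.
#' @param deep_supervision_levels Number of auxiliary segmentation heads on
#'   the coarser decoder levels (clamped to `depth - 2`).
#' @param norm Use instance-style feature normalization inside blocks.
#' @return A `dunet_config` list.
#' @export
dunet_config <- function(in_channels = 2L, n_classes = 2L, depth = 4L,
                         base_filters = 16L, dropout_p = 0.3,
                         se_reduction = 8L, deep_supervision_levels = 2L,
                         norm = TRUE) {
  stopifnot(in_channels %in% c(1L, 2L), n_classes >= 2L, depth >= 2L,
            base_filters >= 1L, dropout_p >= 0, dropout_p < 1,
            se_reduction >= 1L)
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 dropout_p = dropout_p,
                 se_reduction = as.integer(se_reduction),
                 deep_supervision_levels =
                   max(0L, min(as.integer(deep_supervision_levels),
                               as.integer(depth) - 2L)),
                 norm = isTRUE(norm)),
            class = "dunet_config")
}

#' Coarse-network configuration
#'
#' A small three-level single-channel encoder-decoder used for whole-volume
#' candidate detection (the coarse stage of the cascade). Input sides must be
#' divisible by 4.
#'
#' @param in_channels Always 1 (vessel image only).
#' @param input_side Nominal input side in voxels (128 at clinical scale;
#'   any side divisible by 4 is accepted at run time).
#' @param base_filters Filters at the finest level.
#' @param n_classes Number of output classes.
#' @param norm Use instance-style feature normalization.
#' @return A `coarse_config` list.
#' @export
coarse_config <- function(in_channels = 1L, input_side = 128L,
                          base_filters = 8L, n_classes = 2L, norm = TRUE) {
  stopifnot(in_channels == 1L, base_filters >= 1L, n_classes >= 2L)
  structure(list(in_channels = 1L, input_side = as.integer(input_side),
                 base_filters = as.integer(base_filters),
                 n_classes = as.integer(n_classes), norm = isTRUE(norm)),
            class = "coarse_config")
}

# --- parameter initialization -------------------------------------------

param_builder <- function() {
  pb <- new.env(parent = emptyenv())
  pb$params <- list()
  pb$conv <- function(name, k, cin, cout, norm = TRUE) {
    sdev <- sqrt(2 / (k^3 * cin))
    pb$params[[paste0(name, ".w")]] <-
      array(stats::rnorm(k^3 * cin * cout, 0, sdev), c(k, k, k, cin, cout))
    pb$params[[paste0(name, ".b")]] <- numeric(cout)
    if (norm) {
      pb$params[[paste0(name, ".gamma")]] <- rep(1, cout)
      pb$params[[paste0(name, ".beta")]] <- numeric(cout)
    }
  }
  pb$dense <- function(name, cin, cout) {
    sdev <- sqrt(2 / cin)
    pb$params[[paste0(name, ".W")]] <-
      matrix(stats::rnorm(cin * cout, 0, sdev), cin, cout)
    pb$params[[paste0(name, ".b")]] <- numeric(cout)
  }
  pb
}

se_hidden <- function(C, reduction) max(1L, C %/% reduction)

#' Build the dual-channel fine network
#'
#' Initializes all parameters (He-normal convolution weights) from the
#' current RNG state; call `set.seed()` beforehand for reproducible builds.
#'
#' @param cfg A [dunet_config()].
#' @return A `cascseg_net` object.
#' @export
build_dunet <- function(cfg = dunet_config()) {
  stopifnot(inherits(cfg, "dunet_config"))
  f <- cfg$base_filters * 2L^(seq_len(cfg$depth) - 1L)
  pb <- param_builder()
  pb$conv("in", 3L, cfg$in_channels, f[1], cfg$norm)
  for (l in seq_len(cfg$depth)) {
    if (l > 1L) pb$conv(sprintf("down%d", l), 3L, f[l - 1], f[l], cfg$norm)
    pb$conv(sprintf("ctx%d.conv1", l), 3L, f[l], f[l], cfg$norm)
    pb$conv(sprintf("ctx%d.conv2", l), 3L, f[l], f[l], cfg$norm)
  }
  cse <- f[cfg$depth - 1L]
  pb$dense("se_enc.fc1", cse, se_hidden(cse, cfg$se_reduction))
  pb$dense("se_enc.fc2", se_hidden(cse, cfg$se_reduction), cse)
  for (l in seq.int(cfg$depth - 1L, 1L)) {
    pb$conv(sprintf("up%d", l), 3L, f[l + 1], f[l], cfg$norm)
    pb$conv(sprintf("loc%d.conv1", l), 3L, 2L * f[l], f[l], cfg$norm)
    pb$conv(sprintf("loc%d.conv2", l), 1L, f[l], f[l], cfg$norm)
  }
  pb$dense("se_dec.fc1", cse, se_hidden(cse, cfg$se_reduction))
  pb$dense("se_dec.fc2", se_hidden(cse, cfg$se_reduction), cse)
  pb$conv("seg1", 3L, f[1], cfg$n_classes, norm = FALSE)
  if (cfg$deep_supervision_levels > 0L) {
    for (l in 1L + seq_len(cfg$deep_supervision_levels)) {
      pb$conv(sprintf("seg%d", l), 1L, f[l], cfg$n_classes, norm = FALSE)
    }
  }
  structure(list(arch = "dunet", cfg = cfg, params = pb$params),
            class = "cascseg_net")
}

#' Build the coarse candidate-detection network
#'
#' @param cfg A [coarse_config()].
#' @return A `cascseg_net` object.
#' @export
build_coarse_cnn <- function(cfg = coarse_config()) {
  stopifnot(inherits(cfg, "coarse_config"))
  f <- cfg$base_filters * c(1L, 2L, 4L)
  pb <- param_builder()
  pb$conv("in", 3L, 1L, f[1], cfg$norm)
  pb$conv("down2", 3L, f[1], f[2], cfg$norm)
  pb$conv("ctx2", 3L, f[2], f[2], cfg$norm)
  pb$conv("down3", 3L, f[2], f[3], cfg$norm)
  pb$conv("ctx3", 3L, f[3], f[3], cfg$norm)
  pb$conv("up2", 3L, f[3], f[2], cfg$norm)
  pb$conv("loc2", 3L, 2L * f[2], f[2], cfg$norm)
  pb$conv("up1", 3L, f[2], f[1], cfg$norm)
  pb$conv("loc1", 3L, 2L * f[1], f[1], cfg$norm)
  pb$conv("seg", 1L, f[1], cfg$n_classes, norm = FALSE)
  structure(list(arch = "coarse", cfg = cfg, params = pb$params),
            class = "cascseg_net")
}

#' @export
print.cascseg_net <- function(x, ...) {
  cat(sprintf("<cascseg_net> %s, %d parameters\n", x$arch, net_num_params(x)))
  invisible(x)
}

#' Total trainable parameter count of a network
#'
#' @param net A `cascseg_net`.
#' @return Integer parameter count.
#' @export
net_num_params <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

# --- forward passes ------------------------------------------------------

# Wrap parameter arrays as tape leaves; returns the named list of leaf nodes.
wrap_params <- function(tp, params) {
  lapply(params, function(v) tape_leaf(tp, v))
}

conv_unit <- function(tp, P, name, x, stride = 1L, norm = TRUE, act = TRUE) {
  h <- op_conv3d(tp, x, P[[paste0(name, ".w")]], P[[paste0(name, ".b")]],
                 stride)
  if (norm && !is.null(P[[paste0(name, ".gamma")]])) {
    h <- op_instnorm(tp, h, P[[paste0(name, ".gamma")]],
                     P[[paste0(name, ".beta")]])
  }
  if (act) h <- op_lrelu(tp, h)
  h
}

se_unit <- function(tp, P, name, x) {
  s <- op_gap(tp, x)
  s <- op_dense(tp, s, P[[paste0(name, ".fc1.W")]], P[[paste0(name, ".fc1.b")]])
  s <- op_lrelu(tp, s, alpha = 0.01)
  s <- op_dense(tp, s, P[[paste0(name, ".fc2.W")]], P[[paste0(name, ".fc2.b")]])
  s <- op_sigmoid(tp, s)
  op_scale_channels(tp, x, s)
}

check_input_side <- function(x, in_channels, div) {
  d <- dim(x)
  if (length(d) != 4L || d[4] != in_channels) {
    stop(sprintf("input must be (s, s, s, %d)", in_channels), call. = FALSE)
  }
  if (any(d[1:3] %% div != 0L)) {
    stop(sprintf("input sides must be divisible by %d", div), call. = FALSE)
  }
}

dunet_forward <- function(net, tp, P, x, training) {
  cfg <- net$cfg
  check_input_side(x$value, cfg$in_channels, 2L^(cfg$depth - 1L))
  nrm <- cfg$norm
  enc <- vector("list", cfg$depth)
  h <- conv_unit(tp, P, "in", x, norm = nrm)
  for (l in seq_len(cfg$depth)) {
    if (l > 1L) h <- conv_unit(tp, P, sprintf("down%d", l), h, stride = 2L,
                               norm = nrm)
    c1 <- conv_unit(tp, P, sprintf("ctx%d.conv1", l), h, norm = nrm)
    c1 <- op_dropout(tp, c1, cfg$dropout_p, training)
    c2 <- conv_unit(tp, P, sprintf("ctx%d.conv2", l), c1, norm = nrm)
    h <- op_add(tp, h, c2)
    if (l == cfg$depth - 1L) h <- se_unit(tp, P, "se_enc", h)
    enc[[l]] <- h
  }
  u <- enc[[cfg$depth]]
  aux <- list()
  for (l in seq.int(cfg$depth - 1L, 1L)) {
    u <- op_upsample2(tp, u)
    u <- conv_unit(tp, P, sprintf("up%d", l), u, norm = nrm)
    if (l == cfg$depth - 1L) u <- se_unit(tp, P, "se_dec", u)
    u <- op_concat_channels(tp, u, enc[[l]])
    u <- conv_unit(tp, P, sprintf("loc%d.conv1", l), u, norm = nrm)
    u <- conv_unit(tp, P, sprintf("loc%d.conv2", l), u, norm = nrm)
    if (l >= 2L && l <= 1L + cfg$deep_supervision_levels) {
      aux[[sprintf("seg%d", l)]] <-
        list(level = l, node = op_conv3d(tp, u, P[[sprintf("seg%d.w", l)]],
                                         P[[sprintf("seg%d.b", l)]]))
    }
  }
  logits <- op_conv3d(tp, u, P[["seg1.w"]], P[["seg1.b"]])
  for (a in aux) {
    up <- a$node
    for (i in seq_len(a$level - 1L)) up <- op_upsample2(tp, up)
    logits <- op_add(tp, logits, up)
  }
  op_softmax_channels(tp, logits)
}

coarse_forward <- function(net, tp, P, x, training) {
  nrm <- net$cfg$norm
  check_input_side(x$value, 1L, 4L)
  e1 <- conv_unit(tp, P, "in", x, norm = nrm)
  h <- conv_unit(tp, P, "down2", e1, stride = 2L, norm = nrm)
  e2 <- op_add(tp, h, conv_unit(tp, P, "ctx2", h, norm = nrm))
  h <- conv_unit(tp, P, "down3", e2, stride = 2L, norm = nrm)
  e3 <- op_add(tp, h, conv_unit(tp, P, "ctx3", h, norm = nrm))
  u <- conv_unit(tp, P, "up2", op_upsample2(tp, e3), norm = nrm)
  u <- conv_unit(tp, P, "loc2", op_concat_channels(tp, u, e2), norm = nrm)
  u <- conv_unit(tp, P, "up1", op_upsample2(tp, u), norm = nrm)
  u <- conv_unit(tp, P, "loc1", op_concat_channels(tp, u, e1), norm = nrm)
  logits <- op_conv3d(tp, u, P[["seg.w"]], P[["seg.b"]])
  op_softmax_channels(tp, logits)
}

#' Forward pass of a network
#'
#' Runs one sample through the network and returns the per-voxel class
#' probabilities. With `training = FALSE` (dropout disabled) the pass is
#' deterministic for a fixed weight state.
#'
#' @param net A `cascseg_net`.
#' @param x Input array of shape `(s, s, s, in_channels)`.
#' @param training Enable dropout.
#' @return Probability array `(s, s, s, n_classes)` (rows sum to 1 per
#'   voxel).
#' @export
net_forward <- function(net, x, training = FALSE) {
  net_forward_tape(net, x, training)$prob$value
}

# Forward pass keeping tape handles, for the training loop.
net_forward_tape <- function(net, x, training = FALSE) {
  tp <- new_tape()
  P <- wrap_params(tp, net$params)
  xn <- tape_leaf(tp, x)
  prob <- switch(net$arch,
                 dunet = dunet_forward(net, tp, P, xn, training),
                 coarse = coarse_forward(net, tp, P, xn, training),
                 stop("unknown architecture: ", net$arch))
  list(tape = tp, pnodes = P, input = xn, prob = prob)
}

# Collect parameter gradients (zeros where a parameter received none).
collect_grads <- function(fw) {
  lapply(fw$pnodes, function(nd) {
    if (is.null(nd$grad)) {
      v <- nd$value
      v[] <- 0
      v
    } else nd$grad
  })
}

#' Save / load a network checkpoint
#'
#' Checkpoints are RDS files holding the architecture tag, configuration and
#' parameter arrays; a JSON sidecar with the configuration is written next to
#' the checkpoint for auditability.
#'
#' @param net A `cascseg_net`.
#' @param path Output `.rds` path.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` the restored `cascseg_net`.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "cascseg_net"))
  saveRDS(list(arch = net$arch, cfg = net$cfg, params = net$params), path)
  jsonlite::write_json(net$cfg[!vapply(net$cfg, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  obj <- readRDS(path)
  structure(list(arch = obj$arch, cfg = obj$cfg, params = obj$params),
            class = "cascseg_net")
}
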