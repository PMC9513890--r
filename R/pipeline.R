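#' Training plan for one cascade stage
#'
#' Defaults follow the published two-stage schedule: the coarse stage runs
#' 700 epochs with batch size 10, RMSProp at an initial rate of 1e-3 with L1
#' 1e-6 / L2 1e-4 penalties and a stepwise decay (x0.5 every
#' `ceiling(epochs / 3)` epochs, a concretization of the "gradually dropped"
#' rate); the fine stage runs 500 epochs with batch size 1, Adam at 5e-4,
#' halving on a 10-epoch validation plateau and stopping early after 50
#' epochs without improvement. Desk-scale runs shrink `epochs` (and the
#' network presets) but keep the schedule structure.
#'
#' @param stage `"coarse"` or `"fine"`.
#' @param epochs Training epochs.
#' @param batch_size Samples per optimizer step.
#' @param lr0 Initial learning rate.
#' @param l1,l2 Penalty coefficients (coarse stage).
#' @param lr_step_every Epochs between stepwise decays (coarse; default
#'   `ceiling(epochs / 3)`).
#' @param plateau_patience,lr_factor,early_stop_patience Fine-stage schedule.
#' @param val_frac Fraction of the cohort held out for validation (fine).
#' @param folds Cross-validation folds (used by callers that fold cohorts).
#' @param seed Integer seed for shuffling, dropout and initialization.
#' @param verbose Print per-epoch progress.
#' @return A `train_plan` list.
#' @export
train_plan <- function(stage = c("coarse", "fine"), epochs = NULL,
                       batch_size = NULL, lr0 = NULL,
                       l1 = 1e-6, l2 = 1e-4, lr_step_every = NULL,
                       plateau_patience = 10L, lr_factor = 0.5,
                       early_stop_patience = 50L, val_frac = 0.2,
                       folds = 5L, seed = 1L, verbose = FALSE) {
  stage <- match.arg(stage)
  if (is.null(epochs)) epochs <- if (stage == "coarse") 700L else 500L
  if (is.null(batch_size)) batch_size <- if (stage == "coarse") 10L else 1L
  if (is.null(lr0)) lr0 <- if (stage == "coarse") 1e-3 else 5e-4
  stopifnot(epochs >= 1, batch_size >= 1, lr0 > 0, plateau_patience >= 1,
            lr_factor > 0, early_stop_patience >= 1, folds >= 1,
            val_frac > 0, val_frac < 1)
  structure(list(stage = stage, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 l1 = l1, l2 = l2,
                 lr_step_every = if (is.null(lr_step_every))
                   as.integer(ceiling(epochs / 3)) else as.integer(lr_step_every),
                 plateau_patience = as.integer(plateau_patience),
                 lr_factor = lr_factor,
                 early_stop_patience = as.integer(early_stop_patience),
                 val_frac = val_frac, folds = as.integer(folds),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_plan")
}

prob_foreground_mask <- function(prob) {
  array(as.integer(prob[, , , 2] > prob[, , , 1]), dim(prob)[1:3])
}

#' Prepare a phantom cohort for coarse training
#'
#' Z-scores each vessel volume and adaptively dilates each label (the coarse
#' stage trains against dilated labels so small aneurysms survive the low
#' working resolution). With `crop_side` set, each case is a label-centred
#' crop (with optional random centre jitter) instead of the full volume —
#' the network is fully convolutional, so crop-trained weights apply
#' unchanged to whole volumes at inference while training on balanced
#' patches costs a fraction of full-volume passes.
#'
#' @param samples List of `phantom_sample` objects (or lists with `bundle`).
#' @param dilate_coef Coefficient of [adaptive_dilate_label()].
#' @param crop_side Optional patch side in voxels (divisible by 4).
#' @param jitter Max absolute uniform centre jitter in voxels (requires
#'   `crop_side`; draws from the current RNG).
#' @return List of training cases `list(x, y, spacing)` where `x` is the
#'   normalized single-channel input array and `y` the dilated label array.
#' @export
prepare_coarse_cohort <- function(samples, dilate_coef = 0.25,
                                  crop_side = NULL, jitter = 0L) {
  lapply(samples, function(s) {
    z <- zscore(s$bundle$vessel)
    y <- adaptive_dilate_label(s$bundle$label, coef = dilate_coef)
    if (is.null(crop_side)) {
      return(list(x = array(z$data, c(dim(z$data), 1L)), y = y$data,
                  spacing = z$spacing))
    }
    ctr <- label_centroid(s$bundle$label)
    if (jitter > 0) {
      ctr <- pmin(pmax(ctr + sample(seq.int(-jitter, jitter), 3L,
                                    replace = TRUE), 1L),
                  dim(z$data))
    }
    cz <- crop_cube(z, ctr, crop_side)
    cy <- crop_with_box(y$data, cz$box)
    list(x = array(cz$data, c(rep(crop_side, 3L), 1L)), y = cy$data,
         spacing = z$spacing)
  })
}

#' Prepare a phantom cohort for fine training
#'
#' For each sample the vessel volume is z-scored, the Sobel contour image is
#' derived from it, and a cube of `side` voxels is cropped around the label
#' centroid from the vessel, contour and label channels with one shared box.
#'
#' @param samples List of `phantom_sample` objects.
#' @param side VOI side in voxels (64 at clinical scale; desk presets use
#'   32).
#' @return List of cases `list(x, y, spacing, box)`; `x` has a trailing
#'   channel axis (vessel, contour).
#' @export
prepare_fine_cohort <- function(samples, side = 64L) {
  lapply(samples, function(s) {
    z <- zscore(s$bundle$vessel)
    ct <- sobel_contour(z)
    ctr <- label_centroid(s$bundle$label)
    vz <- crop_cube(z, ctr, side)
    vc <- crop_with_box(ct$data, vz$box)
    vy <- crop_with_box(s$bundle$label$data, vz$box)
    list(x = array(c(vz$data, vc$data), c(rep(side, 3L), 2L)),
         y = vy$data, spacing = z$spacing, box = vz$box)
  })
}

fine_case_input <- function(case, channels) {
  if (channels == 2L) case$x
  else case$x[, , , 1L, drop = FALSE]
}

# Mean loss and accumulated parameter gradients over a batch of cases.
batch_loss_grads <- function(net, cases, channels, loss_cfg, training) {
  total <- NULL
  loss <- 0
  for (case in cases) {
    x <- if (is.null(channels)) case$x else fine_case_input(case, channels)
    fw <- net_forward_tape(net, x, training = training)
    lg <- weighted_dice_loss_grad(fw$prob$value[, , , 2], case$y, loss_cfg)
    loss <- loss + lg$loss
    seedg <- array(0, dim(fw$prob$value))
    seedg[, , , 2] <- lg$grad / length(cases)
    tape_backward(fw$tape, fw$prob, seedg)
    g <- collect_grads(fw)
    total <- if (is.null(total)) g else mapply(`+`, total, g, SIMPLIFY = FALSE)
  }
  list(loss = loss / length(cases), grads = total)
}

cohort_loss <- function(net, cases, channels, loss_cfg) {
  mean(vapply(cases, function(case) {
    x <- if (is.null(channels)) case$x else fine_case_input(case, channels)
    prob <- net_forward(net, x, training = FALSE)
    weighted_dice_loss(prob[, , , 2], case$y, loss_cfg)
  }, numeric(1)))
}

#' Train the coarse candidate-detection network
#'
#' Plain soft-dice loss, RMSProp with L1/L2 penalties, and stepwise
#' learning-rate decay. Deterministic given `plan$seed`.
#'
#' @param cohort Output of [prepare_coarse_cohort()] (nonempty).
#' @param plan A [train_plan()] with stage `"coarse"`.
#' @param cfg A [coarse_config()]; the desk presets shrink `base_filters`.
#' @return A list with `net` (the trained `cascseg_net`) and `history`
#'   (per-epoch data frame of loss and learning rate).
#' @export
train_coarse <- function(cohort, plan = train_plan("coarse"),
                         cfg = coarse_config()) {
  if (length(cohort) == 0L) stop("empty cohort", call. = FALSE)
  stopifnot(inherits(plan, "train_plan"), plan$stage == "coarse")
  if (plan$batch_size > length(cohort)) {
    stop("batch_size exceeds cohort size", call. = FALSE)
  }
  set.seed(plan$seed)
  net <- build_coarse_cnn(cfg)
  opt <- optimizer_rmsprop(lr = plan$lr0, l1 = plan$l1, l2 = plan$l2)
  loss_cfg <- loss_config(beta = 0)
  hist <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  for (epoch in seq_len(plan$epochs)) {
    lr <- step_decay_lr(epoch, plan$lr0, plan$lr_factor, plan$lr_step_every)
    opt$set_lr(lr)
    ord <- sample.int(length(cohort))
    eloss <- 0
    nb <- 0L
    for (start in seq(1L, length(cohort), by = plan$batch_size)) {
      idx <- ord[start:min(start + plan$batch_size - 1L, length(cohort))]
      bl <- batch_loss_grads(net, cohort[idx], channels = NULL,
                             loss_cfg = loss_cfg, training = TRUE)
      net$params <- opt$step(net$params, bl$grads)
      eloss <- eloss + bl$loss
      nb <- nb + 1L
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = eloss / nb, lr = lr))
    if (plan$verbose) {
      message(sprintf("coarse epoch %d/%d loss %.4f lr %.2e",
                      epoch, plan$epochs, eloss / nb, lr))
    }
  }
  list(net = net, history = hist)
}

#' Train the fine segmentation network
#'
#' Adam with plateau halving and early stopping on a held-out validation
#' split of the cohort. The loss is the weighted dice loss of `loss_cfg`
#' (`beta = 0` gives the plain soft-dice "initial loss"); `channels = 1`
#' trains the single-channel ablation on the vessel channel only.
#'
#' @param cohort Output of [prepare_fine_cohort()] (or any list of cases
#'   with `x` of shape side^3 x 2 and `y`), at least 2 cases.
#' @param plan A [train_plan()] with stage `"fine"`.
#' @param loss_cfg A [loss_config()].
#' @param channels 2 (vessel + contour) or 1 (vessel only).
#' @param cfg A [dunet_config()]; its `in_channels` must equal `channels`.
#' @return A list with `net`, `history` (epoch, train/validation loss,
#'   learning rate) and `val_idx` (indices of the validation cases).
#' @export
train_fine <- function(cohort, plan = train_plan("fine"),
                       loss_cfg = loss_config(), channels = 2L,
                       cfg = NULL) {
  if (length(cohort) < 2L) stop("need at least 2 cases", call. = FALSE)
  stopifnot(inherits(plan, "train_plan"), plan$stage == "fine",
            channels %in% c(1L, 2L))
  if (dim(cohort[[1]]$x)[4] < channels) {
    stop("cohort does not carry the requested channel count", call. = FALSE)
  }
  if (is.null(cfg)) cfg <- dunet_config(in_channels = channels)
  if (cfg$in_channels != channels) {
    stop("cfg$in_channels must equal channels", call. = FALSE)
  }
  set.seed(plan$seed)
  net <- build_dunet(cfg)
  n <- length(cohort)
  n_val <- max(1L, round(plan$val_frac * n))
  val_idx <- sort(sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0L) stop("validation split left no training cases",
                                 call. = FALSE)
  if (plan$batch_size > length(tr_idx)) {
    stop("batch_size exceeds training-split size", call. = FALSE)
  }
  opt <- optimizer_adam(lr = plan$lr0)
  sched <- plateau_scheduler(plan$lr0, plan$plateau_patience, plan$lr_factor)
  stopper <- early_stopping(plan$early_stop_patience)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))
  for (epoch in seq_len(plan$epochs)) {
    ord <- sample(tr_idx)
    eloss <- 0
    nb <- 0L
    for (start in seq(1L, length(ord), by = plan$batch_size)) {
      idx <- ord[start:min(start + plan$batch_size - 1L, length(ord))]
      bl <- batch_loss_grads(net, cohort[idx], channels = channels,
                             loss_cfg = loss_cfg, training = TRUE)
      net$params <- opt$step(net$params, bl$grads)
      eloss <- eloss + bl$loss
      nb <- nb + 1L
    }
    val_loss <- cohort_loss(net, cohort[val_idx], channels, loss_cfg)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = eloss / nb,
                                   val_loss = val_loss, lr = opt$get_lr()))
    if (plan$verbose) {
      message(sprintf("fine epoch %d/%d train %.4f val %.4f lr %.2e",
                      epoch, plan$epochs, eloss / nb, val_loss, opt$get_lr()))
    }
    opt$set_lr(sched$observe(val_loss))
    if (stopper$observe(val_loss)) break
  }
  list(net = net, history = hist, val_idx = val_idx)
}

as_net <- function(x) {
  if (inherits(x, "cascseg_net")) return(x)
  if (is.character(x)) return(load_checkpoint(x))
  stop("expected a cascseg_net or a checkpoint path", call. = FALSE)
}

#' Cascade inference on one vessel volume
#'
#' Z-scores the input (idempotent on already-normalized volumes), runs the
#' coarse network on the whole volume, proposes one VOI per coarse component,
#' crops the vessel and its Sobel contour with each box, segments each VOI
#' with the fine network, and pastes the union of the fine masks back into
#' full-volume space. A volume with no coarse foreground (including a
#' constant/zero input) yields an empty prediction and an empty manifest.
#'
#' @param vessel A `volume_image`.
#' @param coarse A trained coarse `cascseg_net` or checkpoint path.
#' @param fine A trained fine `cascseg_net` or checkpoint path.
#' @param side VOI side in voxels (must suit the fine network's depth).
#' @return A list with `mask` (full-size `binary_mask`), `coarse_mask`,
#'   `vois` (list of [voi_box()]), and `manifest` (one row per VOI with its
#'   bounds and predicted voxel count).
#' @export
cascade_infer <- function(vessel, coarse, fine, side = 64L) {
  stopifnot(inherits(vessel, "volume_image"))
  coarse <- as_net(coarse)
  fine <- as_net(fine)
  shape <- dim(vessel$data)
  empty <- function() {
    list(mask = binary_mask(array(0L, shape), vessel$spacing, vessel$origin),
         coarse_mask = binary_mask(array(0L, shape), vessel$spacing,
                                   vessel$origin),
         vois = list(),
         manifest = data.frame(voi = integer(0), center_x = integer(0),
                               center_y = integer(0), center_z = integer(0),
                               pred_voxels = integer(0)))
  }
  if (stats::sd(as.vector(vessel$data)) == 0) return(empty())
  z <- zscore(vessel)

  pad_to <- 4L * ceiling(shape / 4)
  zin <- array(0, c(pad_to, 1L))
  zin[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]), 1L] <- z$data
  cprob <- net_forward(coarse, zin, training = FALSE)
  cmask_full <- prob_foreground_mask(cprob)
  cmask <- binary_mask(cmask_full[seq_len(shape[1]), seq_len(shape[2]),
                                  seq_len(shape[3]), drop = FALSE],
                       vessel$spacing, vessel$origin)
  vois <- propose_vois(cmask, side)
  if (length(vois) == 0L) {
    out <- empty()
    out$coarse_mask <- cmask
    return(out)
  }
  contour <- sobel_contour(z)
  preds <- lapply(vois, function(box) {
    vz <- crop_with_box(z$data, box)
    vc <- crop_with_box(contour$data, box)
    xin <- if (fine$cfg$in_channels == 2L) {
      array(c(vz$data, vc$data), c(rep(side, 3L), 2L))
    } else {
      array(vz$data, c(rep(side, 3L), 1L))
    }
    prob <- net_forward(fine, xin, training = FALSE)
    list(data = prob_foreground_mask(prob), box = box)
  })
  mask <- paste_back(preds, shape, vessel$spacing, vessel$origin)
  manifest <- do.call(rbind, lapply(seq_along(vois), function(i) {
    data.frame(voi = i, center_x = vois[[i]]$center[1],
               center_y = vois[[i]]$center[2], center_z = vois[[i]]$center[3],
               pred_voxels = sum(preds[[i]]$data))
  }))
  list(mask = mask, coarse_mask = cmask, vois = vois, manifest = manifest)
}

#' Evaluate a cohort of predictions
#'
#' Per-case dice, Hausdorff distance (mm) and volumetric similarity, plus
#' mean and sd per metric. Cases with an undefined Hausdorff distance (an
#' empty mask on either side) are counted and excluded from the HD mean. A
#' ground-truth 26-component counts as detected when any predicted voxel
#' overlaps it.
#'
#' @param preds,gts Equal-length lists of geometry-matched `binary_mask`
#'   objects.
#' @return A list with `per_case` (data frame), `summary` (mean, sd, n per
#'   metric), `hd_undefined` (count), and `detection` (matched / total
#'   component tally).
#' @export
evaluate_cohort <- function(preds, gts) {
  if (length(preds) != length(gts) || length(preds) == 0L) {
    stop("preds and gts must be nonempty lists of equal length",
         call. = FALSE)
  }
  rows <- lapply(seq_along(preds), function(i) {
    sc <- seg_scores(gts[[i]], preds[[i]])
    data.frame(case = i, dsc = sc$dsc, hd_mm = sc$hd_mm, vs = sc$vs)
  })
  per_case <- do.call(rbind, rows)
  hd_ok <- !is.na(per_case$hd_mm)
  summary <- data.frame(
    metric = c("dsc", "hd_mm", "vs"),
    mean = c(mean(per_case$dsc),
             if (any(hd_ok)) mean(per_case$hd_mm[hd_ok]) else NA_real_,
             mean(per_case$vs)),
    sd = c(stats::sd(per_case$dsc),
           if (sum(hd_ok) > 1) stats::sd(per_case$hd_mm[hd_ok]) else NA_real_,
           stats::sd(per_case$vs)),
    n = c(nrow(per_case), sum(hd_ok), nrow(per_case)))
  matched <- 0L
  total <- 0L
  for (i in seq_along(gts)) {
    comps <- label_components(gts[[i]])
    total <- total + comps$n
    for (k in seq_len(comps$n)) {
      if (sum(preds[[i]]$data[comps$labels == k]) > 0) matched <- matched + 1L
    }
  }
  list(per_case = per_case, summary = summary,
       hd_undefined = sum(!hd_ok),
       detection = list(matched = matched, total = total))
}

#' Beta-sweep ablation of the weighted dice loss
#'
#' Trains the fine network once per exponent and scores the validation split
#' within each VOI crop, emitting one row per beta value.
#'
#' @param cohort Output of [prepare_fine_cohort()].
#' @param plan A fine-stage [train_plan()] (the same seed/split per beta).
#' @param betas Exponents to sweep.
#' @param channels 1 or 2 input channels.
#' @param cfg Optional [dunet_config()].
#' @return Data frame with one row per beta: mean dice, HD (mm) and
#'   volumetric similarity over the validation cases.
#' @export
ablate_beta <- function(cohort, plan = train_plan("fine"),
                        betas = seq(0.1, 1, by = 0.1), channels = 2L,
                        cfg = NULL) {
  rows <- lapply(betas, function(b) {
    fit <- train_fine(cohort, plan, loss_config(beta = b),
                      channels = channels, cfg = cfg)
    preds <- list()
    gts <- list()
    for (i in fit$val_idx) {
      prob <- net_forward(fit$net, fine_case_input(cohort[[i]], channels))
      sp <- cohort[[i]]$spacing
      preds <- c(preds, list(binary_mask(prob_foreground_mask(prob), sp)))
      gts <- c(gts, list(binary_mask(cohort[[i]]$y, sp)))
    }
    ev <- evaluate_cohort(preds, gts)
    data.frame(beta = b,
               dsc = ev$summary$mean[ev$summary$metric == "dsc"],
               hd_mm = ev$summary$mean[ev$summary$metric == "hd_mm"],
               vs = ev$summary$mean[ev$summary$metric == "vs"])
  })
  do.call(rbind, rows)
}
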