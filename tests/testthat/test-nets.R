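tiny_dunet_cfg <- function(in_channels = 2L) {
  dunet_config(in_channels = in_channels, base_filters = 2L, depth = 3L,
               dropout_p = 0.3, se_reduction = 2L,
               deep_supervision_levels = 1L)
}

test_that("fine network keeps spatial shape and normalizes per-voxel probabilities", {
  set.seed(101)
  for (ch in c(2L, 1L)) {
    net <- build_dunet(tiny_dunet_cfg(ch))
    x <- array(rnorm(8^3 * ch), c(8, 8, 8, ch))
    p <- net_forward(net, x)
    expect_equal(dim(p), c(8, 8, 8, 2))
    expect_lt(max(abs(apply(p, 1:3, sum) - 1)), 1e-5)
    expect_true(all(p >= 0 & p <= 1))
  }
  net <- build_dunet(tiny_dunet_cfg())
  expect_error(net_forward(net, array(0, c(6, 6, 6, 2))), "divisible")
  expect_error(net_forward(net, array(0, c(8, 8, 8, 1))), "input")
})

test_that("coarse network honours its shape contract at several sides", {
  set.seed(102)
  net <- build_coarse_cnn(coarse_config(base_filters = 2L))
  for (s in c(8L, 16L)) {
    p <- net_forward(net, array(rnorm(s^3), c(s, s, s, 1)))
    expect_equal(dim(p), c(s, s, s, 2))
    expect_lt(max(abs(apply(p, 1:3, sum) - 1)), 1e-5)
  }
  # parameter budget: within 10x of the fine desk preset
  fine_desk <- build_dunet(dunet_config(base_filters = 4L))
  coarse_default <- build_coarse_cnn(coarse_config())
  expect_lte(net_num_params(coarse_default), 10 * net_num_params(fine_desk))
})

test_that("parameter count is a pure function of the config; eval passes are deterministic", {
  set.seed(1); n1 <- net_num_params(build_dunet(tiny_dunet_cfg()))
  set.seed(999); n2 <- net_num_params(build_dunet(tiny_dunet_cfg()))
  expect_identical(n1, n2)
  set.seed(5)
  net <- build_dunet(tiny_dunet_cfg())
  x <- array(rnorm(8^3 * 2), c(8, 8, 8, 2))
  expect_identical(net_forward(net, x), net_forward(net, x))
})

test_that("end-to-end analytic gradients match finite differences", {
  set.seed(42)
  net <- build_dunet(dunet_config(in_channels = 2L, base_filters = 2L,
                                  depth = 3L, dropout_p = 0,
                                  se_reduction = 2L,
                                  deep_supervision_levels = 1L))
  x <- array(rnorm(8^3 * 2), c(8, 8, 8, 2))
  g <- array(0L, c(8, 8, 8)); g[3:5, 3:5, 3:5] <- 1L
  cfg <- loss_config(beta = 0.5, detach_weight = FALSE)
  loss_of <- function(n) {
    cascseg:::weighted_dice_loss_grad(net_forward(n, x)[, , , 2], g, cfg)$loss
  }
  fw <- cascseg:::net_forward_tape(net, x)
  lg <- cascseg:::weighted_dice_loss_grad(fw$prob$value[, , , 2], g, cfg)
  seedg <- array(0, dim(fw$prob$value)); seedg[, , , 2] <- lg$grad
  cascseg:::tape_backward(fw$tape, fw$prob, seedg)
  grads <- cascseg:::collect_grads(fw)
  set.seed(9)
  for (nm in c("in.w", "ctx2.conv1.w", "down2.w", "up1.w", "seg1.w",
               "se_enc.fc1.W", "ctx1.conv1.gamma")) {
    i <- sample(length(net$params[[nm]]), 1)
    eps <- 1e-5
    n1 <- net; n1$params[[nm]][i] <- n1$params[[nm]][i] + eps
    n2 <- net; n2$params[[nm]][i] <- n2$params[[nm]][i] - eps
    num <- (loss_of(n1) - loss_of(n2)) / (2 * eps)
    expect_lt(abs(num - grads[[nm]][i]) / max(abs(num), 1e-10), 1e-5)
  }
})

test_that("checkpoints round-trip weights and write a config sidecar", {
  set.seed(7)
  net <- build_coarse_cnn(coarse_config(base_filters = 2L))
  f <- file.path(tempdir(), "coarse_ckpt.rds")
  save_checkpoint(net, f)
  expect_true(file.exists(paste0(f, ".json")))
  net2 <- load_checkpoint(f)
  expect_identical(net2$params, net$params)
  x <- array(rnorm(8^3), c(8, 8, 8, 1))
  expect_identical(net_forward(net, x), net_forward(net2, x))
  expect_error(load_checkpoint(file.path(tempdir(), "missing.rds")),
               "not found")
})
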