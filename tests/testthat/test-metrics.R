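test_that("soft dice matches direct arithmetic incl. smoothing limits", {
  g <- array(0L, c(4, 4, 4))
  g[1:2, 1, 1] <- 1L
  p <- array(0, c(4, 4, 4))
  p[1:2, 1, 1] <- 0.5
  # 2 gt voxels, prob 0.5 exactly there: (2*(1 + S/2)) / (3 + S), S = 1e-4
  expect_equal(soft_dice(p, g, 1e-4), (2 * 1 + 1e-4) / (3 + 1e-4),
               tolerance = 1e-12)
  expect_gte(soft_dice(array(as.numeric(g), dim(g)), g, 1e-4), 1 - 1e-4)
  expect_equal(soft_dice(array(0, c(3, 3, 3)), array(0L, c(3, 3, 3))), 1)
  expect_error(soft_dice(array(0, c(2, 2, 2)), g), "mismatch")
})

test_that("weighted dice loss reduces to -soft_dice at beta 0 and vanishes at perfect overlap", {
  set.seed(21)
  for (i in 1:5) {
    g <- random_mask(c(6, 6, 6), 0.2)
    p <- array(runif(216), c(6, 6, 6))
    expect_lt(abs(weighted_dice_loss(p, g, loss_config(beta = 0)) +
                    soft_dice(p, g)), 1e-12)
  }
  g <- random_mask(c(6, 6, 6), 0.3)
  perfect <- weighted_dice_loss(array(as.numeric(g), dim(g)), g,
                                loss_config(beta = 0.1))
  expect_lt(abs(perfect), 10 * 1e-4)
  expect_error(loss_config(beta = 1.2), "0, 1")
})

test_that("the (1-d)^beta weight strictly up-weights worse overlaps", {
  d <- seq(0, 1, by = 0.01)
  for (beta in seq(0.1, 1, by = 0.1)) {
    w <- (1 - d)^beta
    expect_true(all(diff(w) < 0))
  }
  # composed value: D = 0.5, beta = 0.5 -> -0.5 * sqrt(0.5)
  expect_equal(-(1 - 0.5)^0.5 * 0.5, -0.35355, tolerance = 1e-4)
  g <- array(c(1L, 1L, 0L, 0L), c(4, 1, 1))
  p <- array(c(0.5, 0.5, 0.5, 0.5), c(4, 1, 1))  # soft dice ~ 0.5 up to S terms
  expect_equal(weighted_dice_loss(p, g, loss_config(beta = 0.5)),
               -0.35355, tolerance = 1e-3)
})

test_that("loss gradients agree with finite differences in both weight modes", {
  set.seed(31)
  g <- random_mask(c(5, 5, 5), 0.2)
  p <- array(runif(125, 0.05, 0.95), c(5, 5, 5))
  for (detach in c(TRUE, FALSE)) {
    cfg <- loss_config(beta = 0.4, detach_weight = detach)
    lg <- cascseg:::weighted_dice_loss_grad(p, g, cfg)
    for (i in sample(125, 4)) {
      eps <- 1e-6
      p1 <- p; p1[i] <- p[i] + eps
      p2 <- p; p2[i] <- p[i] - eps
      if (detach) {
        # detached weight: only the D factor varies
        d1 <- soft_dice(p1, g); d2 <- soft_dice(p2, g)
        w <- (1 - soft_dice(p, g))^cfg$beta
        num <- -w * (d1 - d2) / (2 * eps)
      } else {
        num <- (cascseg:::weighted_dice_loss_grad(p1, g, cfg)$loss -
                  cascseg:::weighted_dice_loss_grad(p2, g, cfg)$loss) / (2 * eps)
      }
      expect_lt(abs(num - lg$grad[i]) / max(abs(num), 1e-8), 1e-5)
    }
  }
})

test_that("binary dice and volumetric similarity match counting oracles", {
  g <- array(0L, c(4, 4, 4)); g[1:4, 1, 1] <- 1L
  p <- array(0L, c(4, 4, 4)); p[3:4, 1:2, 1] <- 1L  # |P|=4, overlap 2
  expect_equal(dice_coefficient(g, p), 0.5)
  expect_equal(volumetric_similarity(g, p), 1)
  p2 <- array(0L, c(4, 4, 4)); p2[1:2, 1, 1] <- 1L
  expect_equal(volumetric_similarity(g, p2), 1 - 2 / 6)
  expect_equal(dice_coefficient(g, g), 1)
  disj <- array(0L, c(4, 4, 4)); disj[1, 4, 4] <- 1L
  expect_equal(dice_coefficient(g, disj), 0)
  expect_equal(dice_coefficient(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2))), 1)
  expect_equal(volumetric_similarity(g, array(0L, c(4, 4, 4))), 0)
})

test_that("hausdorff distance is exact, symmetric and spacing-aware", {
  m1 <- array(0L, c(8, 8, 8)); m1[2, 2, 2] <- 1L
  m2 <- array(0L, c(8, 8, 8)); m2[5, 2, 2] <- 1L
  expect_equal(hausdorff_mm(binary_mask(m1), binary_mask(m2)), 3)
  half <- binary_mask(m1, spacing = c(0.5, 0.5, 0.5))
  half2 <- binary_mask(m2, spacing = c(0.5, 0.5, 0.5))
  expect_equal(hausdorff_mm(half, half2), 1.5)
  expect_equal(hausdorff_mm(binary_mask(m1), binary_mask(m1)), 0)
  expect_true(is.na(hausdorff_mm(binary_mask(m1),
                                 binary_mask(array(0L, c(8, 8, 8))))))
  set.seed(41)
  for (i in 1:20) {
    a <- random_mask(c(9, 7, 8), 0.08)
    b <- random_mask(c(9, 7, 8), 0.08)
    if (sum(a) == 0 || sum(b) == 0) next
    sp <- c(0.5, 0.7, 1.1)
    got <- hausdorff_mm(binary_mask(a, spacing = sp), binary_mask(b, spacing = sp))
    expect_lt(abs(got - oracle_hausdorff(a, b, sp)), 1e-9)
    expect_equal(got, hausdorff_mm(binary_mask(b, spacing = sp),
                                   binary_mask(a, spacing = sp)))
  }
})
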