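test_that("zscore standardizes to zero mean / unit sd and is idempotent", {
  a <- array(rep(c(0, 2), each = 32), c(4, 4, 4))
  z <- zscore(volume_image(a))
  expect_equal(sort(unique(as.vector(z$data))), c(-1, 1))
  set.seed(4)
  v <- volume_image(array(rnorm(16^3, 50, 7), c(16, 16, 16)))
  z1 <- zscore(v)
  expect_lt(abs(mean(z1$data)), 1e-6)
  expect_lt(abs(sqrt(mean(z1$data^2)) - 1), 1e-6)
  z2 <- zscore(z1)
  expect_lt(max(abs(z2$data - z1$data)), 1e-6)
  expect_error(zscore(volume_image(array(3, c(4, 4, 4)))), "constant")
})

test_that("sobel_contour matches the brute-force 3x3x3 convolution oracle", {
  set.seed(7)
  for (i in 1:3) {
    a <- array(rnorm(16^3), c(16, 16, 16))
    got <- sobel_contour(volume_image(a))$data
    expect_lt(max(abs(got - oracle_sobel(a))), 1e-6)
  }
})

test_that("sobel_contour is zero on uniform input and localizes cube surfaces", {
  expect_equal(max(sobel_contour(volume_image(array(5, c(8, 8, 8))))$data), 0)
  a <- array(0, c(32, 32, 32))
  a[12:21, 12:21, 12:21] <- 1
  ct <- sobel_contour(volume_image(a))$data
  strong <- which(ct > 0.5, arr.ind = TRUE)
  on_surface <- apply(strong, 1, function(p) {
    inside_expanded <- all(p >= 11) && all(p <= 22)
    outside_shrunk <- any(p <= 12) || any(p >= 21)
    inside_expanded && outside_shrunk
  })
  expect_true(all(on_surface))
})

test_that("sobel response to a linear ramp is constant in the interior", {
  a <- array(rep(seq_len(20), times = 20 * 20), c(20, 20, 20))
  ct <- sobel_contour(volume_image(a))$data
  interior <- ct[3:18, 3:18, 3:18]
  expect_lt(diff(range(interior)), 1e-12)
})

test_that("adaptive label dilation follows the size-adaptive ball rule", {
  lab <- array(0L, c(12, 12, 12))
  lab[6, 6, 6] <- 1L
  out <- adaptive_dilate_label(binary_mask(lab, spacing = c(0.5, 0.5, 0.5)))
  expect_identical(out$data, oracle_dilate(lab, 1L))

  # two components: the larger one must grow by a larger radius
  lab2 <- array(0L, c(40, 40, 16))
  lab2[6, 6, 8] <- 1L                       # single voxel, r = 1
  lab2[20:29, 20:29, 4:13] <- 1L            # 10-voxel cube, d_eq ~ 6.2 mm
  m2 <- binary_mask(lab2, spacing = c(0.5, 0.5, 0.5))
  out2 <- adaptive_dilate_label(m2)
  expect_true(all(out2$data >= lab2))
  big <- array(0L, dim(lab2)); big[20:29, 20:29, 4:13] <- 1L
  small <- array(0L, dim(lab2)); small[6, 6, 8] <- 1L
  d_eq_big <- 2 * (3 * sum(big) * 0.125 / (4 * pi))^(1 / 3)
  r_big <- max(1L, as.integer(floor(0.25 * d_eq_big / 0.5 + 0.5)))
  expect_gt(r_big, 1L)
  expected <- pmax(oracle_dilate(small, 1L), oracle_dilate(big, r_big))
  expect_identical(out2$data, array(as.integer(expected), dim(lab2)))
  expect_error(adaptive_dilate_label(
    binary_mask(array(0L, c(8, 8, 8)))), "empty")
})

test_that("histogram equalization preserves range and monotone order", {
  set.seed(11)
  v <- volume_image(array(rgamma(16^3, 2, 1), c(16, 16, 16)))
  h <- hist_equalize(v)
  expect_equal(range(h$data), range(v$data))
  o <- order(as.vector(v$data))
  expect_true(all(diff(as.vector(h$data)[o]) >= -1e-12))
})

test_that("eightfold augmentation has exact cardinality and transform contracts", {
  set.seed(2)
  bundles <- replicate(3, tiny_bundle(), simplify = FALSE)
  aug <- augment_eightfold(bundles)
  expect_length(aug, 24L)

  # z-flip is an involution and preserves label foreground counts
  n <- length(bundles)
  for (i in seq_len(n)) {
    flip <- aug[[n + i]]
    expect_identical(
      cascseg:::flip3(flip$vessel$data, 3L), bundles[[i]]$vessel$data)
    expect_equal(sum(flip$label$data), sum(bundles[[i]]$label$data))
  }
  # Gaussian-filtered copies keep their source labels voxel-identical
  for (i in seq_len(2 * n)) {
    expect_identical(aug[[2 * n + i]]$label$data, aug[[i]]$label$data)
  }
  # derived contours are recomputed from the transformed vessel volume
  g1 <- aug[[2 * n + 1]]
  expect_identical(g1$contour$data, sobel_contour(g1$vessel)$data)
  expect_error(augment_eightfold(list()), "empty")
})
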