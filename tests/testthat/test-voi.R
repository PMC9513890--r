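test_that("label centroids average foreground indices with half-up rounding", {
  m <- array(0L, c(20, 20, 20))
  m[10, 12, 14] <- 1L
  expect_equal(label_centroid(binary_mask(m)), c(10L, 12L, 14L))
  m2 <- array(0L, c(20, 20, 20))
  m2[c(1, 3), 1, 1] <- 1L
  expect_equal(label_centroid(binary_mask(m2)), c(2L, 1L, 1L))
  expect_error(label_centroid(binary_mask(array(0L, c(4, 4, 4)))), "empty")
})

test_that("crop_cube yields exact cubes with correct bounds and zero padding", {
  set.seed(3)
  a <- array(rnorm(128^3 / 64), c(64, 64, 32))  # asymmetric host volume
  big <- volume_image(array(rnorm(128^3), c(128, 128, 128)))
  cr <- crop_cube(big, c(65, 65, 65), 64L)
  expect_equal(dim(cr$data), c(64, 64, 64))
  expect_equal(cr$box$lo, c(33L, 33L, 33L))
  expect_equal(cr$box$hi, c(96L, 96L, 96L))
  expect_equal(cr$box$pad_before, c(0L, 0L, 0L))
  expect_identical(cr$data, big$data[33:96, 33:96, 33:96])

  corner <- crop_cube(big, c(1, 1, 1), 64L)
  expect_equal(corner$box$pad_before, c(32L, 32L, 32L))
  expect_true(all(corner$data[1:32, , ] == 0))
  expect_true(all(corner$data[, 1:32, ] == 0))
  expect_true(all(corner$data[, , 1:32] == 0))

  single <- crop_cube(big, c(5, 6, 7), 1L)
  expect_equal(as.vector(single$data), big$data[5, 6, 7])
  expect_error(crop_cube(big, c(0, 5, 5), 8L), "outside")
})

test_that("voi_box invariants hold for random centres incl. border clipping", {
  set.seed(8)
  shape <- c(50L, 40L, 60L)
  for (i in 1:50) {
    ctr <- sapply(shape, function(n) sample.int(n, 1))
    bx <- voi_box(ctr, 16L, shape)
    expect_equal((bx$hi - bx$lo + 1L) + bx$pad_before + bx$pad_after,
                 rep(16L, 3))
    expect_true(all(bx$lo >= 1L) && all(bx$hi <= shape))
  }
})

test_that("paste_back inverts crop_cube on the box interior and ORs overlaps", {
  set.seed(5)
  lab <- array(as.integer(runif(24^3) < 0.05), c(24, 24, 24))
  m <- binary_mask(lab)
  cr <- crop_cube(m, c(12, 12, 12), 16L)
  back <- paste_back(list(cr), c(24, 24, 24))
  expect_identical(back$data[cr$box$lo[1]:cr$box$hi[1],
                             cr$box$lo[2]:cr$box$hi[2],
                             cr$box$lo[3]:cr$box$hi[3]],
                   lab[cr$box$lo[1]:cr$box$hi[1],
                       cr$box$lo[2]:cr$box$hi[2],
                       cr$box$lo[3]:cr$box$hi[3]])
  outside <- back$data
  outside[cr$box$lo[1]:cr$box$hi[1], cr$box$lo[2]:cr$box$hi[2],
          cr$box$lo[3]:cr$box$hi[3]] <- 0L
  expect_equal(sum(outside), 0)

  # overlapping boxes: 1 wins over 0
  b1 <- voi_box(c(8, 8, 8), 8L, c(24, 24, 24))
  b2 <- voi_box(c(10, 8, 8), 8L, c(24, 24, 24))
  ones <- array(1L, c(8, 8, 8))
  zeros <- array(0L, c(8, 8, 8))
  both <- paste_back(list(list(data = ones, box = b1),
                          list(data = zeros, box = b2)), c(24, 24, 24))
  expect_equal(both$data[8, 8, 8], 1L)

  empty <- paste_back(list(), c(10, 10, 10))
  expect_equal(sum(empty$data), 0)
})

test_that("propose_vois makes one box per component and merges near-duplicates", {
  m <- array(0L, c(160, 40, 40))
  m[20:22, 20:22, 20:22] <- 1L
  m[120:122, 20:22, 20:22] <- 1L
  two <- propose_vois(binary_mask(m), side = 64L)
  expect_length(two, 2L)

  close_m <- array(0L, c(64, 64, 64))
  close_m[20, 20, 20] <- 1L
  close_m[30, 20, 20] <- 1L   # centroids 10 apart < 64/2 -> merged
  one <- propose_vois(binary_mask(close_m), side = 64L)
  expect_length(one, 1L)
  expect_equal(one[[1]]$center, c(25L, 20L, 20L))

  expect_length(propose_vois(binary_mask(array(0L, c(40, 40, 40))), 64L), 0L)

  # never more boxes than coarse components
  set.seed(10)
  rnd <- binary_mask(random_mask(c(30, 30, 30), 0.02))
  expect_lte(length(propose_vois(rnd, 16L)), label_components(rnd)$n)
})
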