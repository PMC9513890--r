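test_that("phantom generation is deterministic in the seed and distinct across seeds", {
  sp <- desk_spec32(seed = 5L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$bundle$vessel$data, b$bundle$vessel$data)
  expect_identical(a$bundle$label$data, b$bundle$label$data)
  c3 <- generate_phantom(desk_spec32(seed = 6L))
  expect_false(identical(a$bundle$vessel$data, c3$bundle$vessel$data))
})

test_that("labels are bright-foreground subsets with one 26-component per aneurysm", {
  for (seed in c(2L, 3L, 4L)) {
    ph <- generate_phantom(phantom_spec(seed = seed))
    expect_true(all(ph$bundle$label$data <= ph$foreground$data))
    expect_equal(label_components(ph$bundle$label)$n, 1L)
  }
  ph2 <- generate_phantom(phantom_spec(
    n_aneurysms = 2L,
    aneurysm_diameter_mm = list(fixed = 5), seed = 8L))
  expect_equal(label_components(ph2$bundle$label)$n, 2L)
  expect_equal(length(ph2$aneurysm_records), 2L)
})

test_that("a fixed-diameter bulge voxelizes near its requested size", {
  sp <- phantom_spec(n_aneurysms = 1L,
                     aneurysm_diameter_mm = list(fixed = 6), seed = 3L)
  ph <- generate_phantom(sp)
  V <- sum(ph$bundle$label$data) * prod(sp$spacing)
  d_eq <- 2 * (3 * V / (4 * pi))^(1 / 3)
  expect_lt(abs(d_eq - 6) / 6, 0.15)
})

test_that("an aneurysm-free spec yields an all-zero label", {
  ph <- generate_phantom(phantom_spec(n_aneurysms = 0L, seed = 2L))
  expect_equal(sum(ph$bundle$label$data), 0)
})

test_that("diameter sampling recovers the configured truncated-lognormal mean", {
  set.seed(123)
  d <- sample_aneurysm_diameters(200, list(mean = 5.468, sd = 3.283,
                                           trunc = c(2, 20)))
  expect_true(all(d >= 2 & d <= 20))
  expect_gt(mean(d), 4.7)
  expect_lt(mean(d), 6.1)
  expect_equal(sample_aneurysm_diameters(3, list(fixed = 4.2)),
               rep(4.2, 3))
})

test_that("cohorts are reproducible, pairwise distinct, and validated", {
  co <- generate_cohort(5, desk_spec32(), seed = 9L)
  expect_length(co, 5L)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_false(identical(co[[i]]$bundle$vessel$data,
                           co[[j]]$bundle$vessel$data))
  }
  co2 <- generate_cohort(5, desk_spec32(), seed = 9L)
  expect_identical(co[[3]]$bundle$vessel$data, co2[[3]]$bundle$vessel$data)
  expect_error(generate_cohort(0, desk_spec32()), ">= 1")
})

test_that("spec validation rejects volumes too small for a meaningful crop", {
  expect_error(phantom_spec(shape = c(16, 64, 64)), "32")
})
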