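test_that("stepwise decay halves the rate on schedule", {
  every <- ceiling(30 / 3)
  expect_equal(step_decay_lr(1, 1e-3, 0.5, every), 1e-3)
  expect_equal(step_decay_lr(every, 1e-3, 0.5, every), 1e-3)
  expect_equal(step_decay_lr(every + 1, 1e-3, 0.5, every), 0.5e-3)
  expect_equal(step_decay_lr(2 * every + 1, 1e-3, 0.5, every), 0.25e-3)
})

test_that("plateau scheduler halves after exactly the patience window", {
  sch <- plateau_scheduler(5e-4, patience = 10L, factor = 0.5)
  expect_equal(sch$observe(1.0), 5e-4)      # first value becomes best
  for (i in 1:9) expect_equal(sch$observe(1.0), 5e-4)
  expect_equal(sch$observe(1.0), 2.5e-4)    # 10th frozen epoch triggers
  # an improvement resets the wait counter
  sch2 <- plateau_scheduler(1e-3, patience = 3L)
  sch2$observe(1.0)
  sch2$observe(1.0); sch2$observe(1.0)
  expect_equal(sch2$observe(0.5), 1e-3)     # improved just in time
  sch2$observe(0.5); sch2$observe(0.5)
  expect_equal(sch2$observe(0.5), 0.5e-3)   # then 3 frozen epochs
})

test_that("early stopping fires after exactly the no-improvement patience", {
  st <- early_stopping(patience = 50L)
  expect_false(st$observe(1.0))
  for (i in 1:49) expect_false(st$observe(1.0))
  expect_true(st$observe(1.0))
  st2 <- early_stopping(patience = 2L)
  st2$observe(3); st2$observe(2.9)          # improving
  expect_false(st2$observe(2.95))
  expect_true(st2$observe(2.95))
})

test_that("both optimizers descend a simple quadratic", {
  par <- list(w = c(5, -3))
  gr <- function(p) list(w = 2 * p$w)
  f <- function(p) sum(p$w^2)
  for (opt in list(optimizer_rmsprop(lr = 0.1), optimizer_adam(lr = 0.1))) {
    p <- par
    for (i in 1:200) p <- opt$step(p, gr(p))
    expect_lt(f(p), 1e-2)
  }
})
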