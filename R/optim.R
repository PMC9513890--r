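# Optimizers and learning-rate schedules for the two training stages.
# Optimizers operate on named lists of parameter arrays and keep their moment
# estimates in a closure; the learning rate can be changed between steps.

#' RMSProp optimizer
#'
#' Root-mean-square propagation with optional L1/L2 penalty gradients
#' (`l1 * sign(w) + l2 * w` added to each gradient), as used for the coarse
#' stage.
#'
#' @param lr Initial learning rate.
#' @param rho Decay of the squared-gradient average.
#' @param eps Numerical stabilizer.
#' @param l1,l2 Penalty coefficients.
#' @return An optimizer object with `$step(params, grads)`, `$set_lr(lr)`,
#'   `$get_lr()`.
#' @export
optimizer_rmsprop <- function(lr = 1e-3, rho = 0.9, eps = 1e-8,
                              l1 = 0, l2 = 0) {
  state <- new.env(parent = emptyenv())
  state$v <- NULL
  state$lr <- lr
  list(
    step = function(params, grads) {
      if (is.null(state$v)) {
        state$v <- lapply(params, function(p) { p[] <- 0; p })
      }
      for (nm in names(params)) {
        g <- grads[[nm]] + l1 * sign(params[[nm]]) + l2 * params[[nm]]
        state$v[[nm]] <- rho * state$v[[nm]] + (1 - rho) * g^2
        params[[nm]] <- params[[nm]] -
          state$lr * g / (sqrt(state$v[[nm]]) + eps)
      }
      params
    },
    set_lr = function(lr) state$lr <- lr,
    get_lr = function() state$lr
  )
}

#' Adam optimizer
#'
#' Used for the fine stage.
#'
#' @param lr Initial learning rate.
#' @param beta1,beta2 Moment decays.
#' @param eps Numerical stabilizer.
#' @return An optimizer object with `$step(params, grads)`, `$set_lr(lr)`,
#'   `$get_lr()`.
#' @export
optimizer_adam <- function(lr = 5e-4, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  state <- new.env(parent = emptyenv())
  state$m <- NULL
  state$v <- NULL
  state$t <- 0L
  state$lr <- lr
  list(
    step = function(params, grads) {
      if (is.null(state$m)) {
        zeros <- lapply(params, function(p) { p[] <- 0; p })
        state$m <- zeros
        state$v <- zeros
      }
      state$t <- state$t + 1L
      bc1 <- 1 - beta1^state$t
      bc2 <- 1 - beta2^state$t
      for (nm in names(params)) {
        g <- grads[[nm]]
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
        params[[nm]] <- params[[nm]] - state$lr *
          (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
      }
      params
    },
    set_lr = function(lr) state$lr <- lr,
    get_lr = function() state$lr
  )
}

#' Stepwise learning-rate decay
#'
#' Learning rate for a given epoch under a schedule that multiplies the rate
#' by `factor` every `every` epochs (the coarse stage's gradually dropping
#' rate).
#'
#' @param epoch Epoch number (1-based).
#' @param lr0 Initial learning rate.
#' @param factor Multiplicative drop.
#' @param every Epochs between drops.
#' @return The learning rate for `epoch`.
#' @export
step_decay_lr <- function(epoch, lr0, factor = 0.5, every = 1L) {
  stopifnot(epoch >= 1, every >= 1)
  lr0 * factor^((epoch - 1) %/% every)
}

#' Plateau learning-rate scheduler
#'
#' Halves (by default) the learning rate whenever the validation loss has not
#' improved for `patience` consecutive observations, matching the fine
#' stage's schedule: the rate decreases to 1/2 of its last value if the
#' validation loss does not improve within 10 iterations.
#'
#' @param lr0 Initial learning rate.
#' @param patience Observations without improvement before a drop.
#' @param factor Multiplicative drop.
#' @return A scheduler with `$observe(val_loss)` returning the learning rate
#'   to use next, and `$get_lr()`.
#' @export
plateau_scheduler <- function(lr0, patience = 10L, factor = 0.5) {
  stopifnot(lr0 > 0, patience >= 1L, factor > 0)
  st <- new.env(parent = emptyenv())
  st$lr <- lr0
  st$best <- Inf
  st$wait <- 0L
  list(
    observe = function(val_loss) {
      if (val_loss < st$best) {
        st$best <- val_loss
        st$wait <- 0L
      } else {
        st$wait <- st$wait + 1L
        if (st$wait >= patience) {
          st$lr <- st$lr * factor
          st$wait <- 0L
        }
      }
      st$lr
    },
    get_lr = function() st$lr
  )
}

#' Early-stopping monitor
#'
#' Signals a stop after `patience` consecutive observations without
#' improvement of the validation loss (fine stage: training stops after 50
#' epochs without improvement).
#'
#' @param patience Observations without improvement before stopping.
#' @return A monitor with `$observe(val_loss)` returning `TRUE` when training
#'   should stop, and `$best()` returning the best loss seen.
#' @export
early_stopping <- function(patience = 50L) {
  stopifnot(patience >= 1L)
  st <- new.env(parent = emptyenv())
  st$best <- Inf
  st$wait <- 0L
  list(
    observe = function(val_loss) {
      if (val_loss < st$best) {
        st$best <- val_loss
        st$wait <- 0L
        FALSE
      } else {
        st$wait <- st$wait + 1L
        st$wait >= patience
      }
    },
    best = function() st$best
  )
}
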