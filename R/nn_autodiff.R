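# Reverse-mode autodiff tape for the 3D network engine.
#
# Feature maps are dense 4D arrays (X, Y, Z, C). Each op appends a node to
# the tape recording its value and a closure that routes the incoming
# gradient to its parents; backward() replays the tape in reverse creation
# order (creation order is a topological order of the DAG). Convolutions run
# through the compiled im2col/GEMM kernels; everything else is vectorized R.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tape_node <- function(tp, value, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backfn <- backfn
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[tp$n]] <- nd
  nd
}

tape_leaf <- function(tp, value) tape_node(tp, value)

accum_grad <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Seed `out` with `seed_grad` and propagate to all leaves.
tape_backward <- function(tp, out, seed_grad) {
  out$grad <- seed_grad
  for (i in seq.int(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

op_conv3d <- function(tp, x, w, b, stride = 1L) {
  k <- dim(w$value)[1]
  val <- cpp_conv3d_forward(x$value, dim(x$value), w$value, b$value,
                            k, as.integer(stride))
  tape_node(tp, val, function(g) {
    res <- cpp_conv3d_backward(x$value, dim(x$value), w$value, g,
                               k, as.integer(stride))
    accum_grad(x, res$dx)
    accum_grad(w, res$dw)
    accum_grad(b, res$db)
  })
}

op_lrelu <- function(tp, x, alpha = 0.01) {
  neg <- x$value < 0
  v <- x$value
  v[neg] <- alpha * v[neg]
  tape_node(tp, v, function(g) {
    g[neg] <- alpha * g[neg]
    accum_grad(x, g)
  })
}

op_add <- function(tp, a, b) {
  tape_node(tp, a$value + b$value, function(g) {
    accum_grad(a, g)
    accum_grad(b, g)
  })
}

op_concat_channels <- function(tp, a, b) {
  da <- dim(a$value)
  db <- dim(b$value)
  stopifnot(all(da[1:3] == db[1:3]))
  val <- array(c(a$value, b$value), c(da[1:3], da[4] + db[4]))
  tape_node(tp, val, function(g) {
    accum_grad(a, array(g[, , , seq_len(da[4]), drop = FALSE], da))
    accum_grad(b, array(g[, , , da[4] + seq_len(db[4]), drop = FALSE], db))
  })
}

op_upsample2 <- function(tp, x) {
  d <- dim(x$value)
  ix <- rep(seq_len(d[1]), each = 2L)
  iy <- rep(seq_len(d[2]), each = 2L)
  iz <- rep(seq_len(d[3]), each = 2L)
  val <- x$value[ix, iy, iz, , drop = FALSE]
  tape_node(tp, val, function(g) {
    g7 <- array(g, c(2L, d[1], 2L, d[2], 2L, d[3], d[4]))
    acc <- array(0, d)
    for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
      acc <- acc + array(g7[a, , b, , cc, , ], d)
    }
    accum_grad(x, acc)
  })
}

op_dropout <- function(tp, x, p, training) {
  if (!training || p <= 0) return(x)
  keep <- (stats::runif(length(x$value)) >= p) / (1 - p)
  tape_node(tp, x$value * keep, function(g) accum_grad(x, g * keep))
}

op_instnorm <- function(tp, x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  V <- prod(d[1:3])
  C <- d[4]
  Xm <- matrix(x$value, V, C)
  mu <- colMeans(Xm)
  xc <- sweep(Xm, 2, mu)
  inv <- 1 / sqrt(colMeans(xc^2) + eps)
  xhat <- sweep(xc, 2, inv, "*")
  Y <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
  tape_node(tp, array(Y, d), function(g) {
    Gm <- matrix(g, V, C)
    accum_grad(beta, colSums(Gm))
    accum_grad(gamma, colSums(Gm * xhat))
    dxh <- sweep(Gm, 2, gamma$value, "*")
    m1 <- colMeans(dxh)
    m2 <- colMeans(dxh * xhat)
    dX <- sweep(dxh - matrix(m1, V, C, byrow = TRUE) -
                  xhat * matrix(m2, V, C, byrow = TRUE), 2, inv, "*")
    accum_grad(x, array(dX, d))
  })
}

# Global average pool over spatial dims -> per-channel vector.
op_gap <- function(tp, x) {
  d <- dim(x$value)
  V <- prod(d[1:3])
  val <- colMeans(matrix(x$value, V, d[4]))
  tape_node(tp, val, function(g) {
    accum_grad(x, array(rep(g / V, each = V), d))
  })
}

op_dense <- function(tp, v, W, b) {
  val <- drop(v$value %*% W$value) + b$value
  tape_node(tp, val, function(g) {
    accum_grad(v, drop(W$value %*% g))
    accum_grad(W, outer(v$value, g))
    accum_grad(b, g)
  })
}

op_sigmoid <- function(tp, x) {
  s <- 1 / (1 + exp(-x$value))
  tape_node(tp, s, function(g) accum_grad(x, g * s * (1 - s)))
}

# Multiply each channel of x by scalar s[c] (the SE excitation).
op_scale_channels <- function(tp, x, s) {
  d <- dim(x$value)
  V <- prod(d[1:3])
  sx <- array(rep(s$value, each = V), d)
  tape_node(tp, x$value * sx, function(g) {
    accum_grad(x, g * sx)
    accum_grad(s, colSums(matrix(g * x$value, V, d[4])))
  })
}

op_softmax_channels <- function(tp, x) {
  d <- dim(x$value)
  V <- prod(d[1:3])
  C <- d[4]
  Zm <- matrix(x$value, V, C)
  Zm <- Zm - do.call(pmax, lapply(seq_len(C), function(j) Zm[, j]))
  E <- exp(Zm)
  Pm <- E / rowSums(E)
  tape_node(tp, array(Pm, d), function(g) {
    Gm <- matrix(g, V, C)
    s <- rowSums(Pm * Gm)
    accum_grad(x, array(Pm * (Gm - s), d))
  })
}
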