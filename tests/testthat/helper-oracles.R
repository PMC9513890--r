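# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (triple loops, all-pairs scans) so they cannot share a
# defect with the vectorized/compiled implementation paths they check.

# Full 3x3x3 correlation with edge-replicate borders:
# out(i) = sum_k K[k] * a(clamp(i + k - 2)).
brute_conv333 <- function(a, K) {
  d <- dim(a)
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- 0
    for (kx in 1:3) for (ky in 1:3) for (kz in 1:3) {
      ix <- min(max(x + kx - 2L, 1L), d[1])
      iy <- min(max(y + ky - 2L, 1L), d[2])
      iz <- min(max(z + kz - 2L, 1L), d[3])
      acc <- acc + K[kx, ky, kz] * a[ix, iy, iz]
    }
    out[x, y, z] <- acc
  }
  out
}

# Sobel gradient-magnitude oracle from outer-product kernels.
oracle_sobel <- function(a) {
  d <- c(-1, 0, 1); s <- c(1, 2, 1)
  Kx <- outer(outer(d, s), s); dim(Kx) <- c(3, 3, 3)
  Ky <- outer(outer(s, d), s); dim(Ky) <- c(3, 3, 3)
  Kz <- outer(outer(s, s), d); dim(Kz) <- c(3, 3, 3)
  mag <- sqrt(brute_conv333(a, Kx)^2 + brute_conv333(a, Ky)^2 +
                brute_conv333(a, Kz)^2)
  m <- max(mag)
  if (m > 0) mag / m else mag
}

# Euclidean-ball dilation oracle: voxel-by-voxel neighbourhood scan.
oracle_dilate <- function(arr, r) {
  d <- dim(arr)
  out <- arr
  idx <- which(arr != 0, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      if (dx^2 + dy^2 + dz^2 > r^2) next
      q <- p + c(dx, dy, dz)
      if (all(q >= 1) && all(q <= d)) out[q[1], q[2], q[3]] <- 1L
    }
  }
  out
}

# All-pairs symmetric Hausdorff oracle in mm.
oracle_hausdorff <- function(g, p, spacing) {
  A <- which(g != 0, arr.ind = TRUE)
  B <- which(p != 0, arr.ind = TRUE)
  A <- sweep(A, 2, spacing, "*")
  B <- sweep(B, 2, spacing, "*")
  d2 <- function(P, Q) {
    outer(rowSums(P^2), rep(1, nrow(Q))) +
      outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * P %*% t(Q)
  }
  D <- pmax(d2(A, B), 0)
  max(sqrt(max(apply(D, 1, min))), sqrt(max(apply(D, 2, min))))
}

random_mask <- function(shape, p = 0.1) {
  array(as.integer(stats::runif(prod(shape)) < p), shape)
}

# A small synthetic bundle (random vessel texture + a 2-voxel label) for
# augmentation and plumbing tests where phantom realism is irrelevant.
tiny_bundle <- function(side = 12L, spacing = c(0.5, 0.5, 0.5)) {
  v <- volume_image(array(stats::rnorm(side^3, 100, 20), rep(side, 3L)),
                    spacing = spacing)
  lab <- array(0L, rep(side, 3L))
  lab[side %/% 2 + 0:1, side %/% 2, side %/% 2] <- 1L
  volume_bundle(v, sobel_contour(v), binary_mask(lab, spacing = spacing))
}

# Desk-scale phantom spec for 32^3 tests: diameters restricted to what
# physically fits a 15.5 mm field of view.
desk_spec32 <- function(seed = 1L, n_aneurysms = 1L) {
  phantom_spec(shape = c(32L, 32L, 32L), n_vessels = 2L,
               n_aneurysms = n_aneurysms,
               aneurysm_diameter_mm = list(mean = 5.468, sd = 3.283,
                                           trunc = c(2, 7)),
               seed = seed)
}
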