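# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the DFT is a direct triple sum, connected
# components come from an explicit BFS flood fill, and the Laplacian is a
# literal second-difference stencil loop.

rand_vol <- function(shape, seed = 1, nonneg = TRUE) {
  withr::with_seed(seed, {
    x <- array(rnorm(prod(shape)), shape)
    if (nonneg) x <- abs(x)
    volume(x)
  })
}

# Direct triple-sum DFT; per output coefficient the full sum over all input
# voxels is evaluated from per-axis twiddle vectors.
dft3_direct <- function(x, inverse = FALSE) {
  dm <- dim(x)
  s <- if (inverse) 1 else -1
  W <- lapply(dm, function(n)
    exp(s * 2i * pi * outer(0:(n - 1), 0:(n - 1)) / n))
  out <- array(0 + 0i, dm)
  for (k1 in 0:(dm[1] - 1)) for (k2 in 0:(dm[2] - 1)) for (k3 in 0:(dm[3] - 1)) {
    phase <- outer(outer(W[[1]][k1 + 1, ], W[[2]][k2 + 1, ]), W[[3]][k3 + 1, ])
    out[k1 + 1, k2 + 1, k3 + 1] <- sum(x * phase)
  }
  if (inverse) out / prod(dm) else out
}

# Re-centre a 0-based-frequency DFT so frequency 0 sits at 0-based index
# floor(N/2), by explicit index arithmetic.
center_spectrum_direct <- function(S) {
  dm <- dim(S)
  out <- array(0 + 0i, dm)
  for (m1 in 0:(dm[1] - 1)) for (m2 in 0:(dm[2] - 1)) for (m3 in 0:(dm[3] - 1)) {
    k <- c((m1 - dm[1] %/% 2) %% dm[1],
           (m2 - dm[2] %/% 2) %% dm[2],
           (m3 - dm[3] %/% 2) %% dm[3])
    out[m1 + 1, m2 + 1, m3 + 1] <- S[k[1] + 1, k[2] + 1, k[3] + 1]
  }
  out
}

# 0/1 mask of the centered band of width w along one axis, built by the
# documented index rule only.
band_mask_direct <- function(shape, axis, w) {
  M <- array(0, shape)
  n <- shape[axis]
  start0 <- n %/% 2 - w %/% 2
  sel0 <- start0:(start0 + w - 1)
  for (i1 in 0:(shape[1] - 1)) for (i2 in 0:(shape[2] - 1)) for (i3 in 0:(shape[3] - 1)) {
    idx <- c(i1, i2, i3)
    if (idx[axis] %in% sel0) M[i1 + 1, i2 + 1, i3 + 1] <- 1
  }
  M
}

# BFS flood fill under 26-connectivity; labels ordered by first foreground
# voxel in column-major scan order.
flood_fill_26 <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs == 0) != 3, , drop = FALSE]
  for (lin in which(mask)) {
    if (lab[lin] != 0L) next
    nxt <- nxt + 1L
    queue <- lin
    lab[lin] <- nxt
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      ci <- arrayInd(cur, dm)
      for (r in seq_len(nrow(offs))) {
        nb <- ci + offs[r, ]
        if (any(nb < 1) || any(nb > dm)) next
        nlin <- nb[1] + (nb[2] - 1) * dm[1] + (nb[3] - 1) * dm[1] * dm[2]
        if (mask[nlin] && lab[nlin] == 0L) {
          lab[nlin] <- nxt
          queue <- c(queue, nlin)
        }
      }
    }
  }
  lab
}

# Literal 6-neighbour second-difference stencil with edge replication.
laplacian_direct <- function(v) {
  dm <- dim(v)
  out <- array(0, dm)
  cl <- function(i, n) min(max(i, 1L), n)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    out[i, j, k] <-
      v[cl(i - 1L, dm[1]), j, k] + v[cl(i + 1L, dm[1]), j, k] +
      v[i, cl(j - 1L, dm[2]), k] + v[i, cl(j + 1L, dm[2]), k] +
      v[i, j, cl(k - 1L, dm[3])] + v[i, j, cl(k + 1L, dm[3])] - 6 * v[i, j, k]
  }
  out
}

rmse_to <- function(vol, truth) sqrt(mean((vol$data - truth$data)^2))

# Hand-built fixture: constant lesion and NAWM intensities plus a two-point
# noise region whose sample sd is exactly 10, giving closed-form metrics.
closed_form_fixture <- function() {
  v <- array(0, c(6, 6, 6))
  lesion <- nawm <- noise <- array(FALSE, c(6, 6, 6))
  lesion[1:2, 1:2, 1] <- TRUE
  nawm[4:5, 4:5, 1] <- TRUE
  noise[1:2, 1, 6] <- TRUE
  v[lesion] <- 100
  v[nawm] <- 80
  v[noise] <- 100 + c(-1, 1) * 10 / sqrt(2)  # sample sd exactly 10
  list(v = v, lesion = lesion, nawm = nawm, noise = noise)
}

geom_cor <- function() acquisition_geometry(1.7, 5, slice_axis = 2)
geom_ax <- function() acquisition_geometry(1.7, 5, slice_axis = 3)
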