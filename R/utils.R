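# Internal helpers shared across modules. All arrays are plain 3D R arrays;
# axis indices are 1-based throughout the package.

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_3d <- function(data, what = "volume data") {
  if (!(is.array(data) && length(dim(data)) == 3L))
    stopf("%s must be a 3D array, got %s", what,
          paste(class(data), collapse = "/"))
  if (any(dim(data) < 2L))
    stopf("%s must have length >= 2 along every axis (got %s)",
          what, paste(dim(data), collapse = "x"))
  invisible(data)
}

# Extract the data array from a fousr_volume or pass a bare array through.
as_vol_array <- function(x, what = "volume") {
  if (inherits(x, "fousr_volume")) return(x$data)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stopf("%s must be a fousr_volume or a 3D array", what)
}

# Coerce a mask argument (fousr_volume, numeric or logical array) to logical.
as_mask <- function(x, what = "mask") {
  m <- as_vol_array(x, what)
  if (is.logical(m)) return(m)
  vals <- unique(as.vector(m))
  if (!all(vals %in% c(0, 1)))
    stopf("%s must be binary (0/1 or logical); found other values", what)
  array(m != 0, dim(m))
}

# Shift an array by integer offset d (length 3), filling vacated voxels.
shift_fill <- function(a, d, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (abs(d[ax]) >= dm[ax]) return(out)
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(dm[ax] - d[ax])
      dst[[ax]] <- src[[ax]] + d[ax]
    } else {
      dst[[ax]] <- seq_len(dm[ax] + d[ax])
      src[[ax]] <- dst[[ax]] - d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Shift with edge replication (clamped indices) -- used by the Laplacian.
shift_clamp <- function(a, d) {
  dm <- dim(a)
  idx <- lapply(1:3, function(ax) pmin(pmax(seq_len(dm[ax]) - d[ax], 1L), dm[ax]))
  a[idx[[1]], idx[[2]], idx[[3]]]
}

# All 26 unit offsets of the 3x3x3 neighbourhood (excluding the centre).
offsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(g == 0) != 3L, , drop = FALSE]
}

# Run code under a fixed RNG seed without disturbing the caller's stream;
# seed = NULL leaves the current stream untouched.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}
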