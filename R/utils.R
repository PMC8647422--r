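# Internal numerical helpers shared across modules.

# Normalize a vector to unit length; error on (near-)zero input.
.unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n < 1e-12)
    stop("cannot normalize a zero-length vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Trilinear interpolation of a 3-D array at continuous 0-based voxel
# coordinates (N x 3 matrix). Returns NA outside the grid hull.
.trilinear <- function(vol, ijk) {
  d <- dim(vol)
  ok <- ijk[, 1L] >= 0 & ijk[, 1L] <= d[1L] - 1 &
        ijk[, 2L] >= 0 & ijk[, 2L] <= d[2L] - 1 &
        ijk[, 3L] >= 0 & ijk[, 3L] <= d[3L] - 1
  out <- rep(NA_real_, nrow(ijk))
  if (!any(ok)) return(out)
  p <- ijk[ok, , drop = FALSE]
  i0 <- floor(p)
  f <- p - i0
  # clamp upper corner so exact-boundary points stay in range
  i1 <- sweep(i0 + 1, 2L, d - 1, pmin)
  lin <- function(ix, iy, iz) vol[1L + ix + d[1L] * (iy + d[2L] * iz)]
  fx <- f[, 1L]; fy <- f[, 2L]; fz <- f[, 3L]
  c000 <- lin(i0[, 1L], i0[, 2L], i0[, 3L]); c100 <- lin(i1[, 1L], i0[, 2L], i0[, 3L])
  c010 <- lin(i0[, 1L], i1[, 2L], i0[, 3L]); c110 <- lin(i1[, 1L], i1[, 2L], i0[, 3L])
  c001 <- lin(i0[, 1L], i0[, 2L], i1[, 3L]); c101 <- lin(i1[, 1L], i0[, 2L], i1[, 3L])
  c011 <- lin(i0[, 1L], i1[, 2L], i1[, 3L]); c111 <- lin(i1[, 1L], i1[, 2L], i1[, 3L])
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

# Connected-component labelling of a logical 2-D or 3-D array with full
# (8- or 26-) connectivity. Returns an integer array of labels (0 =
# background). BFS flood fill; intended for sparse foreground masks.
.labelComponents <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  stopifnot(nd %in% c(2L, 3L))
  offs <- as.matrix(do.call(expand.grid, rep(list(-1L:1L), nd)))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  lab <- array(0L, d)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  nextLab <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    nextLab <- nextLab + 1L
    lab[seed] <- nextLab
    frontier <- seed
    while (length(frontier) > 0L) {
      co <- arrayInd(frontier, d)
      nb <- matrix(0L, nrow(co) * nrow(offs), nd)
      for (k in seq_len(nd))
        nb[, k] <- rep(co[, k], each = nrow(offs)) + rep(offs[, k], nrow(co))
      keep <- rep(TRUE, nrow(nb))
      for (k in seq_len(nd))
        keep <- keep & nb[, k] >= 1L & nb[, k] <= d[k]
      nb <- nb[keep, , drop = FALSE]
      if (nrow(nb) == 0L) break
      idx <- nb[, 1L]
      mult <- 1L
      for (k in 2L:nd) {
        mult <- mult * d[k - 1L]
        idx <- idx + (nb[, k] - 1L) * mult
      }
      idx <- unique(idx[mask[idx] & lab[idx] == 0L])
      lab[idx] <- nextLab
      frontier <- idx
    }
  }
  lab
}

# Dilate a logical 2-D mask by one pixel (8-neighbourhood), npass times.
.dilate2D <- function(mask, npass = 1L) {
  if (npass <= 0L) return(mask)
  d <- dim(mask)
  for (p in seq_len(npass)) {
    padded <- matrix(FALSE, d[1L] + 2L, d[2L] + 2L)
    padded[2:(d[1L] + 1L), 2:(d[2L] + 1L)] <- mask
    acc <- matrix(FALSE, d[1L], d[2L])
    for (di in -1:1) for (dj in -1:1)
      acc <- acc | padded[(2:(d[1L] + 1L)) + di, (2:(d[2L] + 1L)) + dj]
    mask <- acc
  }
  mask
}

# Row-wise median of a 6-column matrix via a fixed compare-exchange
# network (vectorized; avoids apply() on large voxel sets).
.rowMedian6 <- function(m) {
  a <- m[, 1L]; b <- m[, 2L]; c <- m[, 3L]
  d <- m[, 4L]; e <- m[, 5L]; f <- m[, 6L]
  sw <- function(x, y) list(pmin(x, y), pmax(x, y))
  s <- sw(a, b); a <- s[[1L]]; b <- s[[2L]]
  s <- sw(c, d); c <- s[[1L]]; d <- s[[2L]]
  s <- sw(e, f); e <- s[[1L]]; f <- s[[2L]]
  s <- sw(a, c); a <- s[[1L]]; c <- s[[2L]]
  s <- sw(b, d); b <- s[[1L]]; d <- s[[2L]]
  s <- sw(c, e); c <- s[[1L]]; e <- s[[2L]]
  s <- sw(d, f); d <- s[[1L]]; f <- s[[2L]]
  s <- sw(b, c); b <- s[[1L]]; c <- s[[2L]]
  s <- sw(d, e); d <- s[[1L]]; e <- s[[2L]]
  s <- sw(c, d); c <- s[[1L]]; d <- s[[2L]]
  (c + d) / 2
}

# Trapezoidal integral of y(x); x in ms, y in mL/s -> result in mL when
# divided by 1000 (done by the caller when appropriate).
.trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
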