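# Small 3D array primitives shared across modules: axis shifts, cube
# dilation, separable Gaussian smoothing, 26-connected components, and
# neighbor enumeration. Written here because no installed package offers
# 3D morphology/labeling on plain arrays.

# Shift a 3D array by `by` voxels along `axis`, filling vacated slabs.
.shiftArray <- function(a, axis, by, fill = 0) {
  if (by == 0) return(a)
  d <- dim(a)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  if (axis == 1) out[dst, , ] <- a[src, , ]
  else if (axis == 2) out[, dst, ] <- a[, src, ]
  else out[, , dst] <- a[, , src]
  out
}

# Binary dilation with a (2r+1)^3 cube structuring element (26-connectivity
# at r = 1), via separable per-axis running OR.
.dilateCube <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- mask
  for (axis in 1:3) {
    acc <- out
    for (s in seq_len(r)) {
      acc <- acc | .shiftArray(out, axis, s, FALSE) |
             .shiftArray(out, axis, -s, FALSE)
    }
    out <- acc
  }
  out
}

# Separable Gaussian smoothing with per-axis sigma in voxels; edges use
# replicate padding (kernel renormalized implicitly by clamped indexing).
.gaussSmooth <- function(a, sigma_vox) {
  d <- dim(a)
  out <- a
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r):r / s)^2)
    k <- k / sum(k)
    n <- d[axis]
    acc <- array(0, d)
    for (t in (-r):r) {
      idx <- pmin(pmax(seq_len(n) + t, 1L), n)  # replicate padding
      w <- k[t + r + 1]
      if (axis == 1) acc <- acc + w * a[idx, , , drop = FALSE]
      else if (axis == 2) acc <- acc + w * a[, idx, , drop = FALSE]
      else acc <- acc + w * a[, , idx, drop = FALSE]
    }
    a <- acc
  }
  a
}

.NEIGHBOR_OFFSETS_26 <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
.NEIGHBOR_OFFSETS_26 <- .NEIGHBOR_OFFSETS_26[
  rowSums(abs(.NEIGHBOR_OFFSETS_26)) > 0, , drop = FALSE]

# 26-neighbors of a set of linear indices; returns unique in-bounds linear
# indices (may include members of the input set).
.neighbors26 <- function(lin, dims) {
  ijk <- arrayInd(lin, dims)
  n <- nrow(ijk)
  off <- .NEIGHBOR_OFFSETS_26
  i <- rep(ijk[, 1], times = nrow(off)) + rep(off[, 1], each = n)
  j <- rep(ijk[, 2], times = nrow(off)) + rep(off[, 2], each = n)
  k <- rep(ijk[, 3], times = nrow(off)) + rep(off[, 3], each = n)
  ok <- i >= 1 & i <= dims[1] & j >= 1 & j <= dims[2] & k >= 1 & k <= dims[3]
  unique((k[ok] - 1L) * (dims[1] * dims[2]) + (j[ok] - 1L) * dims[1] + i[ok])
}

# 26-connected components of a logical array. Returns a list of integer
# vectors of linear indices, ordered by their smallest linear index.
.connectedComponents26 <- function(mask) {
  dims <- dim(mask)
  todo <- which(mask)
  if (!length(todo)) return(list())
  visited <- array(FALSE, dims)
  comps <- list()
  for (seed in todo) {
    if (visited[seed]) next
    visited[seed] <- TRUE
    comp <- seed
    frontier <- seed
    while (length(frontier)) {
      nb <- .neighbors26(frontier, dims)
      nb <- nb[mask[nb] & !visited[nb]]
      if (!length(nb)) break
      visited[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Exact 1D squared distance transform (lower envelope of parabolas,
# Felzenszwalb & Huttenlocher) at physical spacing s. f holds per-site
# costs (0 at sources, BIG elsewhere).
.dt1d <- function(f, s) {
  n <- length(f)
  if (n == 1L) return(f)
  x <- (seq_len(n) - 1) * s
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      p <- v[k]
      sx <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
      if (sx <= z[k] && k > 1L) { k <- k - 1L } else {
        if (sx <= z[k]) { v[k] <- q; z[k + 1L] <- Inf } else {
          k <- k + 1L; v[k] <- q; z[k] <- sx; z[k + 1L] <- Inf
        }
        break
      }
    }
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    p <- v[k]
    d[q] <- (x[q] - x[p])^2 + f[p]
  }
  d
}

# Exact squared Euclidean distance transform (mm^2) to the TRUE voxels of a
# 3D logical array, with per-axis spacing; separable, exact, O(N) per axis.
.edtSquared <- function(src, spacing) {
  BIG <- 1e20
  d <- dim(src)
  f <- array(ifelse(src, 0, BIG), d)
  for (axis in 1:3) {
    if (d[axis] == 1L) next
    s <- spacing[axis]
    if (axis == 1) {
      for (j in seq_len(d[2])) for (k in seq_len(d[3]))
        f[, j, k] <- .dt1d(f[, j, k], s)
    } else if (axis == 2) {
      for (i in seq_len(d[1])) for (k in seq_len(d[3]))
        f[i, , k] <- .dt1d(f[i, , k], s)
    } else {
      for (i in seq_len(d[1])) for (j in seq_len(d[2]))
        f[i, j, ] <- .dt1d(f[i, j, ], s)
    }
  }
  f
}

# Exact min Euclidean distance (mm) from each query point to a point set,
# chunked; uses BLAS for the cross terms and max.col for the row minima.
.minDistToSet <- function(query, set, chunk = 4000L) {
  nq <- nrow(query)
  out <- numeric(nq)
  s2 <- rowSums(set^2)
  for (start in seq(1L, nq, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nq)
    Q <- query[idx, , drop = FALSE]
    D2 <- matrix(rowSums(Q^2), length(idx), nrow(set)) +
          matrix(s2, length(idx), nrow(set), byrow = TRUE) -
          2 * tcrossprod(Q, set)
    jmin <- max.col(-D2, ties.method = "first")
    out[idx] <- sqrt(pmax(0, D2[cbind(seq_along(idx), jmin)]))
  }
  out
}

# Deterministic seed derivation: keeps derived seeds in 32-bit range.
.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}
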