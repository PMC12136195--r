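# Shared fixtures: everything is generated in code at load time. The
# half-resolution (0.4 mm) phantom keeps unit tests fast; acceptance tests
# build the full-resolution phantom themselves.

.fixtures <- new.env()

# Half-resolution male phantom with the default bladder hotspot.
smallSpec <- function(seed = 5L, sex = "male", ...) {
  phantomSpec(sex = sex, seed = seed, spacing = 0.4, ...)
}

smallAnatomy <- function() {
  if (is.null(.fixtures$an)) .fixtures$an <- buildAnatomy(smallSpec())
  .fixtures$an
}

smallSession <- function(day = 18L, seed = 5L, sex = "male") {
  key <- sprintf("ses_%d_%d_%s", day, seed, sex)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generateSession(smallSpec(seed, sex), day,
                                        smallAnatomy())
  .fixtures[[key]]
}

# Zero-excretion, zero-lesion variants share the same anatomy grid.
cleanBladder <- function() c(x = 0, y = 4.6, z = 3.4, peak = 0, decay = 1.5)

# Paint a voxelized solid cylinder (for axis-recovery tests independent of
# the phantom generator): direction u, length L mm, radius r mm, on an
# isotropic grid with identity-orientation affine.
paintCylinder <- function(u, L = 12, r = 1.2, spacing = 0.4, pad = 3) {
  u <- u / sqrt(sum(u^2))
  half <- L / 2 + r + pad
  n <- ceiling(2 * half / spacing)
  ax <- spacing * (seq_len(n) - (n + 1) / 2)
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  t <- X * u[1] + Y * u[2] + Z * u[3]
  rad2 <- X^2 + Y^2 + Z^2 - t^2
  mask <- abs(t) <= L / 2 & rad2 <= r^2
  A <- diag(4)
  A[1:3, 1:3] <- diag(spacing, 3, 3)
  A[1:3, 4] <- ax[1]
  list(mask = mask, transform = A)
}

# Welch two-sample t-test from the textbook formulas (independent oracle).
welchOracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Quantile by explicit sort-and-linear-interpolation of order statistics.
quantileOracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
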