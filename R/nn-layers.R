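# Minimal 2D conv-net layer kit: im2col convolutions, max-pooling, nearest
# upsampling, activations, softmax cross-entropy and soft-Dice losses, and
# Adam. Forward functions return caches; backward functions consume them.
# Feature maps are [H, W, C] arrays; weights are [kh, kw, Cin, Cout].
# Everything is plain R so gradients can be verified numerically.

.im2col3 <- function(xp, H, W, C) {
  # xp is zero-padded [H+2, W+2, C]; columns ordered (offset-major, then
  # channel), offsets scanned oy = 1..3 outer, ox = 1..3 inner.
  M <- matrix(0, H * W, 9L * C)
  o <- 0L
  for (oy in 0:2) for (ox in 0:2) {
    o <- o + 1L
    blk <- xp[oy + seq_len(H), ox + seq_len(W), , drop = FALSE]
    M[, (o - 1L) * C + seq_len(C)] <- blk
    # note: dim(blk) = c(H, W, C); matrix fill is column-major = (H*W) x C
  }
  M
}

.wmat3 <- function(W) {
  C <- dim(W)[3]; F <- dim(W)[4]
  M <- matrix(0, 9L * C, F)
  o <- 0L
  for (oy in 1:3) for (ox in 1:3) {
    o <- o + 1L
    M[(o - 1L) * C + seq_len(C), ] <- matrix(W[oy, ox, , ], C, F)
  }
  M
}

nnConv3Forward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]
  F <- dim(W)[4]
  xp <- array(0, c(H + 2L, Wd + 2L, C))
  xp[1L + seq_len(H), 1L + seq_len(Wd), ] <- x
  M <- .im2col3(xp, H, Wd, C)
  out <- M %*% .wmat3(W) + matrix(b, H * Wd, F, byrow = TRUE)
  list(out = array(out, c(H, Wd, F)), cache = list(M = M, W = W, dims = d))
}

nnConv3Backward <- function(dout, cache) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]; C <- d[3]
  W <- cache$W; F <- dim(W)[4]
  dOutMat <- matrix(dout, H * Wd, F)
  dWmat <- crossprod(cache$M, dOutMat)
  dW <- array(0, dim(W))
  o <- 0L
  for (oy in 1:3) for (ox in 1:3) {
    o <- o + 1L
    dW[oy, ox, , ] <- dWmat[(o - 1L) * C + seq_len(C), ]
  }
  db <- colSums(dOutMat)
  dM <- dOutMat %*% t(.wmat3(W))
  dxp <- array(0, c(H + 2L, Wd + 2L, C))
  o <- 0L
  for (oy in 0:2) for (ox in 0:2) {
    o <- o + 1L
    dxp[oy + seq_len(H), ox + seq_len(Wd), ] <-
      dxp[oy + seq_len(H), ox + seq_len(Wd), , drop = FALSE] +
      array(dM[, (o - 1L) * C + seq_len(C)], c(H, Wd, C))
  }
  list(dx = dxp[1L + seq_len(H), 1L + seq_len(Wd), , drop = FALSE],
       dW = dW, db = db)
}

nnConv1Forward <- function(x, W, b) {
  d <- dim(x)
  X <- matrix(x, d[1] * d[2], d[3])
  out <- X %*% W + matrix(b, d[1] * d[2], ncol(W), byrow = TRUE)
  list(out = array(out, c(d[1], d[2], ncol(W))),
       cache = list(X = X, W = W, dims = d))
}

nnConv1Backward <- function(dout, cache) {
  d <- cache$dims
  dOutMat <- matrix(dout, d[1] * d[2], ncol(cache$W))
  list(dx = array(dOutMat %*% t(cache$W), d),
       dW = crossprod(cache$X, dOutMat), db = colSums(dOutMat))
}

nnReluForward <- function(x) list(out = pmax(x, 0), cache = x > 0)
nnReluBackward <- function(dout, cache) dout * cache

nnSigmoid <- function(x) 1 / (1 + exp(-x))

nnPool2Forward <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[1], 2L); ie <- io + 1L
  jo <- seq(1L, d[2], 2L); je <- jo + 1L
  a <- x[io, jo, , drop = FALSE]; b <- x[ie, jo, , drop = FALSE]
  cc <- x[io, je, , drop = FALSE]; dd <- x[ie, je, , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  # deterministic tie priority: a over b over c over d
  sel <- array(1L, dim(m))
  sel[a < m & b == m] <- 2L
  sel[a < m & b < m & cc == m] <- 3L
  sel[a < m & b < m & cc < m] <- 4L
  list(out = m, cache = list(sel = sel, dims = d))
}

nnPool2Backward <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  io <- seq(1L, d[1], 2L); ie <- io + 1L
  jo <- seq(1L, d[2], 2L); je <- jo + 1L
  sel <- cache$sel
  g <- function(which) dout * (sel == which)
  dx[io, jo, ] <- g(1L); dx[ie, jo, ] <- dx[ie, jo, , drop = FALSE] + g(2L)
  dx[io, je, ] <- dx[io, je, , drop = FALSE] + g(3L)
  dx[ie, je, ] <- dx[ie, je, , drop = FALSE] + g(4L)
  dx
}

nnUp2Forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

nnUp2Backward <- function(dout) {
  d <- dim(dout)
  io <- seq(1L, d[1], 2L); ie <- io + 1L
  jo <- seq(1L, d[2], 2L); je <- jo + 1L
  dout[io, jo, , drop = FALSE] + dout[ie, jo, , drop = FALSE] +
    dout[io, je, , drop = FALSE] + dout[ie, je, , drop = FALSE]
}

# Softmax over the channel dimension of [H, W, K] logits.
nnSoftmax <- function(logits) {
  d <- dim(logits)
  m <- logits[, , 1, drop = FALSE]
  for (k in seq_len(d[3])[-1]) m <- pmax(m, logits[, , k, drop = FALSE])
  e <- exp(logits - array(m, d))
  s <- array(0, c(d[1], d[2], 1))
  for (k in seq_len(d[3])) s <- s + e[, , k, drop = FALSE]
  e / array(s, d)
}

# Combined loss on one slice: softmax cross-entropy and/or soft Dice over
# the K classes. labels are 0-based class indices [H, W].
# Returns loss value and the gradient w.r.t. the logits.
nnSegLoss <- function(logits, labels, loss = c("sum", "cross_entropy", "dice"),
                      eps = 1) {
  loss <- match.arg(loss)
  d <- dim(logits); K <- d[3]; npix <- d[1] * d[2]
  p <- nnSoftmax(logits)
  onehot <- array(0, d)
  for (k in seq_len(K)) onehot[, , k] <- labels == (k - 1L)
  val <- 0
  g <- array(0, d)  # dL/dp
  if (loss %in% c("sum", "cross_entropy")) {
    pt <- pmax(apply(p * onehot, c(1, 2), sum), 1e-12)
    val <- val - mean(log(pt))
    # CE gradient goes directly to logits: (p - y)/n
  }
  if (loss %in% c("sum", "dice")) {
    for (k in seq_len(K)) {
      pc <- p[, , k]; yc <- onehot[, , k]
      inter <- sum(pc * yc); S <- sum(pc) + sum(yc)
      val <- val + (1 - (2 * inter + eps) / (S + eps)) / K
      g[, , k] <- g[, , k] -
        (2 * yc * (S + eps) - (2 * inter + eps)) / (K * (S + eps)^2)
    }
  }
  # chain dL/dp through softmax: dlogit = p * (g - sum_k g_k p_k)
  dl <- array(0, d)
  if (loss %in% c("sum", "dice")) {
    gp <- array(0, c(d[1], d[2], 1))
    for (k in seq_len(K)) gp <- gp + g[, , k, drop = FALSE] * p[, , k, drop = FALSE]
    dl <- p * (g - array(gp, d))
  }
  if (loss %in% c("sum", "cross_entropy"))
    dl <- dl + (p - onehot) / npix
  list(loss = val, dlogits = dl)
}

# Adam step over a flat list of parameter arrays.
nnAdamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

nnAdamInit <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
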