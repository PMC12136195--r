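# Slice-wise multi-label bone segmentation.
#
# A compact attention U-Net operates on 2D sagittal CT slices: an
# encoder-decoder with skip connections, each skip passing through a
# learnable attention gate driven by the coarser decoder feature, and a
# fixed sinusoidal positional encoding of the slice index concatenated to
# the final decoder feature map before one extra convolution that maps to
# the 6 class scores. Sagittal slices of a mouse carry no visual cue to
# tell the left from the right femur - two mirrored slices can be pixel
# identical - and the positional encoding is what disambiguates them.
# Slice predictions are stacked back into a 3D label map and evaluated
# with Dice / mIoU / recall / precision per ROI.

#' Segmentation model configuration
#'
#' @param n_levels encoder depth including the bottleneck (default 4).
#' @param base_channels feature channels at the first level (default 16);
#'   doubled per level.
#' @param n_classes number of output classes; fixed at 6 (background + 5
#'   ROIs).
#' @param pe_dim positional-encoding length (even, default 32).
#' @param pe_max_len index range the encoding is scaled to (default 256).
#' @param use_pe concatenate the positional encoding (TRUE) or an
#'   equal-sized zero block (FALSE; same parameter count, for ablation).
#' @param loss "sum" (cross-entropy + soft Dice, default), "cross_entropy"
#'   or "dice".
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param seed integer seed fixing initialization and data order.
#' @return Named list of configuration values.
#' @export
segConfig <- function(n_levels = 4L, base_channels = 16L, n_classes = 6L,
                      pe_dim = 32L, pe_max_len = 256L, use_pe = TRUE,
                      loss = c("sum", "cross_entropy", "dice"),
                      lr = 3e-3, epochs = 30L, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(n_classes == 6L, pe_dim %% 2L == 0L, n_levels >= 2L)
  list(n_levels = as.integer(n_levels),
       base_channels = as.integer(base_channels), n_classes = 6L,
       pe_dim = as.integer(pe_dim), pe_max_len = as.integer(pe_max_len),
       use_pe = isTRUE(use_pe), loss = loss, lr = lr,
       epochs = as.integer(epochs), seed = as.integer(seed))
}

#' Sinusoidal positional encoding of a slice index
#'
#' PE[2i+1] = sin(p / 10000^(2i/d)), PE[2i+2] = cos(p / 10000^(2i/d)) for
#' i = 0..d/2-1, with p the slice index. Deterministic and training-free;
#' index 0 encodes to (0, 1, 0, 1, ...).
#'
#' @param slice_index 0-based slice index, 0 <= index < max_len.
#' @param pe_dim encoding length (even).
#' @param max_len exclusive upper bound on the index.
#' @return Numeric vector of length \code{pe_dim}, components in [-1, 1].
#' @export
positionalEncoding <- function(slice_index, pe_dim, max_len = 256L) {
  if (pe_dim %% 2L != 0L) stop("pe_dim must be even")
  if (slice_index < 0 || slice_index >= max_len)
    stop("slice_index out of range [0, max_len)")
  i <- seq_len(pe_dim %/% 2L) - 1L
  freq <- 1 / 10000^(2 * i / pe_dim)
  pe <- numeric(pe_dim)
  pe[2 * i + 1] <- sin(slice_index * freq)
  pe[2 * i + 2] <- cos(slice_index * freq)
  pe
}

# Map a 1-based slice position among n slices onto the encoding index range.
.slicePosition <- function(i, n, max_len) {
  if (n <= 1L) return(0L)
  as.integer(round((i - 1) / (n - 1) * (max_len - 1)))
}

#' SegModel: a slice-wise segmentation network
#'
#' @slot params named list of weight arrays.
#' @slot config list from [segConfig()].
#' @export
setClass("SegModel", representation(params = "list", config = "list"))

setMethod("show", "SegModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf(
    "SegModel: attention U-Net, %d level(s), base %d channels, %s, %d parameters\n",
    object@config$n_levels, object@config$base_channels,
    if (object@config$use_pe) sprintf("PE dim %d", object@config$pe_dim)
    else "no positional encoding", np))
})

# He-uniform initialization for a conv weight [kh, kw, Cin, Cout].
.heInit <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  lim <- sqrt(6 / fan_in)
  array(stats::runif(kh * kw * cin * cout, -lim, lim), c(kh, kw, cin, cout))
}

#' Build a segmentation model
#'
#' Constructs the attention U-Net weights from a seeded initialization.
#' The resulting model maps a (2D CT slice, slice index) pair to per-pixel
#' class scores over the 6 labels; the output spatial shape equals the
#' input's, which must be divisible by 2^(n_levels - 1) along both axes.
#'
#' @param config list from [segConfig()].
#' @return A \linkS4class{SegModel}.
#' @export
segBuildModel <- function(config = segConfig()) {
  set.seed(config$seed)
  L <- config$n_levels; b <- config$base_channels
  ch <- b * 2^(seq_len(L) - 1L)
  params <- list()
  for (l in seq_len(L)) {
    cin <- if (l == 1L) 1L else ch[l - 1L]
    params[[paste0("enc", l, "_W")]] <- .heInit(3, 3, cin, ch[l])
    params[[paste0("enc", l, "_b")]] <- numeric(ch[l])
  }
  for (l in seq_len(L - 1L)) {
    ci <- max(ch[l] %/% 2L, 1L)
    params[[paste0("att", l, "_Wg")]] <- .heInit(1, 1, ch[l + 1L], ci)[1, 1, , ]
    params[[paste0("att", l, "_Wx")]] <- .heInit(1, 1, ch[l], ci)[1, 1, , ]
    params[[paste0("att", l, "_bq")]] <- numeric(ci)
    params[[paste0("att", l, "_psi")]] <- matrix(.heInit(1, 1, ci, 1)[1, 1, , ], ci, 1)
    params[[paste0("att", l, "_bp")]] <- 0
    params[[paste0("dec", l, "_W")]] <- .heInit(3, 3, ch[l + 1L] + ch[l], ch[l])
    params[[paste0("dec", l, "_b")]] <- numeric(ch[l])
  }
  params[["head_W"]] <- matrix(
    .heInit(1, 1, ch[1] + config$pe_dim, config$n_classes)[1, 1, , ],
    ch[1] + config$pe_dim, config$n_classes)
  params[["head_b"]] <- numeric(config$n_classes)
  # keep 2D weights as matrices even when ci == 1
  for (l in seq_len(L - 1L)) {
    ci <- max(ch[l] %/% 2L, 1L)
    params[[paste0("att", l, "_Wg")]] <- matrix(params[[paste0("att", l, "_Wg")]], ch[l + 1L], ci)
    params[[paste0("att", l, "_Wx")]] <- matrix(params[[paste0("att", l, "_Wx")]], ch[l], ci)
  }
  new("SegModel", params = params, config = config)
}

# Forward pass; returns logits and (optionally) all caches for backprop.
.segForward <- function(params, config, x, slice_index, want_cache = FALSE) {
  L <- config$n_levels
  d <- dim(x)
  if (any(d %% 2^(L - 1L) != 0))
    stop("input spatial size must be divisible by ", 2^(L - 1L))
  h <- array(x, c(d[1], d[2], 1L))
  cache <- list()
  enc <- vector("list", L)
  for (l in seq_len(L)) {
    cv <- nnConv3Forward(h, params[[paste0("enc", l, "_W")]],
                         params[[paste0("enc", l, "_b")]])
    rl <- nnReluForward(cv$out)
    enc[[l]] <- rl$out
    if (want_cache) cache[[paste0("enc", l)]] <- list(cv = cv$cache, rl = rl$cache)
    if (l < L) {
      pl <- nnPool2Forward(rl$out)
      h <- pl$out
      if (want_cache) cache[[paste0("pool", l)]] <- pl$cache
    }
  }
  feat <- enc[[L]]
  for (l in rev(seq_len(L - 1L))) {
    up <- nnUp2Forward(feat)
    xskip <- enc[[l]]
    du <- dim(up)
    # attention gate: q = relu(Wg g + Wx x), alpha = sigmoid(psi q)
    G <- matrix(up, du[1] * du[2], du[3]) %*% params[[paste0("att", l, "_Wg")]]
    X <- matrix(xskip, du[1] * du[2], dim(xskip)[3]) %*% params[[paste0("att", l, "_Wx")]]
    Q <- G + X + matrix(params[[paste0("att", l, "_bq")]], nrow(G), ncol(G),
                        byrow = TRUE)
    Qr <- pmax(Q, 0)
    A <- nnSigmoid(Qr %*% params[[paste0("att", l, "_psi")]] +
                   params[[paste0("att", l, "_bp")]])
    alpha <- array(A, c(du[1], du[2], 1L))
    xa <- xskip * array(alpha, dim(xskip))
    cat_in <- array(c(up, xa), c(du[1], du[2], du[3] + dim(xskip)[3]))
    cv <- nnConv3Forward(cat_in, params[[paste0("dec", l, "_W")]],
                         params[[paste0("dec", l, "_b")]])
    rl <- nnReluForward(cv$out)
    feat <- rl$out
    if (want_cache)
      cache[[paste0("dec", l)]] <- list(
        up = up, xskip = xskip, Q = Q, Qr_mask = Q > 0, A = A,
        alpha = alpha, cv = cv$cache, rl = rl$cache, du = du)
  }
  df <- dim(feat)
  pe <- if (config$use_pe)
    positionalEncoding(slice_index, config$pe_dim, config$pe_max_len)
  else numeric(config$pe_dim)
  peMap <- array(rep(pe, each = df[1] * df[2]),
                 c(df[1], df[2], config$pe_dim))
  head_in <- array(c(feat, peMap), c(df[1], df[2], df[3] + config$pe_dim))
  hd <- nnConv1Forward(head_in, params$head_W, params$head_b)
  if (want_cache) {
    cache$head <- hd$cache
    cache$feat_channels <- df[3]
    cache$enc_top <- enc
  }
  list(logits = hd$out, cache = if (want_cache) cache else NULL)
}

# Backward pass; returns gradient list matching params.
.segBackward <- function(params, config, cache, dlogits) {
  L <- config$n_levels
  grads <- list()
  hb <- nnConv1Backward(dlogits, cache$head)
  grads$head_W <- hb$dW; grads$head_b <- hb$db
  fc <- cache$feat_channels
  dfeat <- hb$dx[, , seq_len(fc), drop = FALSE]  # PE block has no params
  denc <- vector("list", L)  # gradient flowing into each encoder output
  for (l in seq_len(L - 1L)) denc[[l]] <- NULL
  for (l in seq_len(L - 1L)) {
    cc <- cache[[paste0("dec", l)]]
    drl <- nnReluBackward(dfeat, cc$rl)
    cb <- nnConv3Backward(drl, cc$cv)
    grads[[paste0("dec", l, "_W")]] <- cb$dW
    grads[[paste0("dec", l, "_b")]] <- cb$db
    du <- cc$du
    nup <- du[3]; nsk <- dim(cc$xskip)[3]
    dup <- cb$dx[, , seq_len(nup), drop = FALSE]
    dxa <- cb$dx[, , nup + seq_len(nsk), drop = FALSE]
    # xa = xskip * alpha
    dskip_direct <- dxa * array(cc$alpha, dim(cc$xskip))
    dalpha <- rowSums(matrix(dxa * cc$xskip, du[1] * du[2], nsk))
    dA <- matrix(dalpha, du[1] * du[2], 1) * cc$A * (1 - cc$A)
    Qr <- pmax(cc$Q, 0)
    grads[[paste0("att", l, "_psi")]] <- crossprod(Qr, dA)
    grads[[paste0("att", l, "_bp")]] <- sum(dA)
    dQr <- dA %*% t(params[[paste0("att", l, "_psi")]])
    dQ <- dQr * cc$Qr_mask
    grads[[paste0("att", l, "_bq")]] <- colSums(dQ)
    G_in <- matrix(cc$up, du[1] * du[2], du[3])
    X_in <- matrix(cc$xskip, du[1] * du[2], nsk)
    grads[[paste0("att", l, "_Wg")]] <- crossprod(G_in, dQ)
    grads[[paste0("att", l, "_Wx")]] <- crossprod(X_in, dQ)
    dup_att <- array(dQ %*% t(params[[paste0("att", l, "_Wg")]]), dim(cc$up))
    dskip_att <- array(dQ %*% t(params[[paste0("att", l, "_Wx")]]),
                       dim(cc$xskip))
    dup_total <- dup + dup_att
    denc[[l]] <- dskip_direct + dskip_att
    # route up-path gradient down to the coarser feature
    dfeat <- nnUp2Backward(dup_total)
  }
  # dfeat now targets the bottleneck encoder output
  dcur <- dfeat
  for (l in rev(seq_len(L))) {
    if (l < L) {
      dpool <- nnPool2Backward(dcur, cache[[paste0("pool", l)]])
      dcur <- dpool + denc[[l]]
    }
    ec <- cache[[paste0("enc", l)]]
    drl <- nnReluBackward(dcur, ec$rl)
    cb <- nnConv3Backward(drl, ec$cv)
    grads[[paste0("enc", l, "_W")]] <- cb$dW
    grads[[paste0("enc", l, "_b")]] <- cb$db
    dcur <- cb$dx
  }
  grads
}

#' Per-pixel class scores for one slice
#'
#' @param model a \linkS4class{SegModel}.
#' @param slice 2D numeric matrix (normalized CT intensities).
#' @param slice_index 0-based encoding index of the slice.
#' @return [H, W, 6] array of class scores (logits).
#' @export
segPredictSlice <- function(model, slice, slice_index) {
  .segForward(model@params, model@config, slice, slice_index)$logits
}

#' Train a segmentation model
#'
#' Optimizes the configured loss with Adam over the slice dataset; the seed
#' fixes initialization and the per-epoch sample order, so identical calls
#' produce bitwise-identical loss traces.
#'
#' @param model a \linkS4class{SegModel} from [segBuildModel()].
#' @param dataset list of samples, each a list with elements \code{slice}
#'   (2D matrix), \code{index} (0-based encoding index) and \code{label}
#'   (2D integer matrix with values 0..5).
#' @param epochs,lr optional overrides of the model's config.
#' @return list(model = trained \linkS4class{SegModel}, loss_trace =
#'   per-epoch mean loss).
#' @export
segTrain <- function(model, dataset, epochs = NULL, lr = NULL) {
  if (!length(dataset)) stop("empty dataset")
  for (s in dataset) {
    if (any(!(s$label %in% 0:5))) stop("label values outside {0..5}")
  }
  config <- model@config
  epochs <- epochs %||% config$epochs
  lr <- lr %||% config$lr
  params <- model@params
  st <- nnAdamInit(params)
  set.seed(.deriveSeed(config$seed, 17L))
  trace <- numeric(epochs)
  n <- length(dataset)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (ii in ord) {
      smp <- dataset[[ii]]
      fw <- .segForward(params, config, smp$slice, smp$index,
                        want_cache = TRUE)
      ls <- nnSegLoss(fw$logits, smp$label, config$loss)
      tot <- tot + ls$loss
      grads <- .segBackward(params, config, fw$cache, ls$dlogits)
      upd <- nnAdamStep(params, grads, st, lr)
      params <- upd$params; st <- upd$state
    }
    trace[ep] <- tot / n
  }
  list(model = new("SegModel", params = params, config = config),
       loss_trace = trace)
}

# Normalize HU into [0, 1] for the network input.
.normalizeHU <- function(hu) pmin(pmax((hu + 1000) / 2200, 0), 1)

# Identify which index axis runs along the world left-right (x) direction.
.sagittalAxis <- function(transform) {
  A <- transform[1:3, 1:3]
  xshare <- abs(A[1, ]) / sqrt(colSums(A^2))
  ord <- order(xshare, decreasing = TRUE)
  if (xshare[ord[1]] < 1.05 * xshare[ord[2]] + 1e-9)
    stop("cannot resolve the sagittal axis from the transform; ",
         "pass `axis` explicitly")
  ord[1]
}

#' Build a training dataset from a session
#'
#' Extracts sagittal CT slices and matching label slices, normalized and
#' cropped/padded so both spatial dims are divisible by the model's
#' downsampling factor.
#'
#' @param ct HU \linkS4class{ImageVolume}.
#' @param labels \linkS4class{LabelMap} on the same grid.
#' @param config list from [segConfig()].
#' @param axis sagittal index axis; default resolved from the transform.
#' @param slices which slice positions to include (default all).
#' @return list of samples suitable for [segTrain()].
#' @export
segSliceDataset <- function(ct, labels, config = segConfig(), axis = NULL,
                            slices = NULL) {
  if (!identical(dim(ct@data), dim(labels@data))) stop("grid mismatch")
  axis <- axis %||% .sagittalAxis(ct@transform)
  n <- dim(ct@data)[axis]
  slices <- slices %||% seq_len(n)
  fac <- 2^(config$n_levels - 1L)
  lapply(slices, function(i) {
    sl <- .extractSlice(ct@data, axis, i)
    lb <- .extractSlice(labels@data, axis, i)
    sl <- .padToMultiple(sl, fac, -1000)
    lb <- .padToMultiple(lb, fac, 0L)
    list(slice = .normalizeHU(sl), label = lb,
         index = .slicePosition(i, n, config$pe_max_len))
  })
}

.extractSlice <- function(arr, axis, i) {
  if (axis == 1) arr[i, , ] else if (axis == 2) arr[, i, ] else arr[, , i]
}

.padToMultiple <- function(m, fac, fill) {
  d <- dim(m)
  nd <- ceiling(d / fac) * fac
  if (all(nd == d)) return(m)
  out <- matrix(fill, nd[1], nd[2])
  out[seq_len(d[1]), seq_len(d[2])] <- m
  out
}

#' Predict a 3D label map slice-by-slice
#'
#' Runs the model over every sagittal slice of the CT, takes the per-pixel
#' argmax, and stacks the predictions into a \linkS4class{LabelMap} on the
#' CT grid.
#'
#' @param model a trained \linkS4class{SegModel}.
#' @param ct HU \linkS4class{ImageVolume}.
#' @param axis sagittal index axis; default resolved from the transform.
#' @return A \linkS4class{LabelMap}.
#' @export
segPredictVolume <- function(model, ct, axis = NULL) {
  axis <- axis %||% .sagittalAxis(ct@transform)
  d <- dim(ct@data)
  n <- d[axis]
  fac <- 2^(model@config$n_levels - 1L)
  out <- array(0L, d)
  for (i in seq_len(n)) {
    sl <- .padToMultiple(.extractSlice(ct@data, axis, i), fac, -1000)
    logits <- segPredictSlice(model, .normalizeHU(sl),
                              .slicePosition(i, n, model@config$pe_max_len))
    dl <- dim(logits)
    pred <- matrix(max.col(matrix(logits, dl[1] * dl[2], dl[3]),
                           ties.method = "first") - 1L, dl[1], dl[2])
    sd2 <- dim(.extractSlice(ct@data, axis, i))
    pred <- pred[seq_len(sd2[1]), seq_len(sd2[2])]
    if (axis == 1) out[i, , ] <- pred
    else if (axis == 2) out[, i, ] <- pred
    else out[, , i] <- pred
  }
  LabelMap(out, transform = ct@transform)
}

#' Evaluate predicted versus reference label maps
#'
#' Per label and for the pooled spine+sacrum and ppj+sacrum rows:
#' Dice = 2|A∩B| / (|A| + |B|), IoU = |A∩B| / |A∪B|,
#' recall = |A∩B| / |B|, precision = |A∩B| / |A|, computed on the 3D binary
#' sets A (prediction) and B (truth). Labels absent from both maps are
#' reported as NA (undefined), not 0 or 1.
#'
#' @param pred predicted \linkS4class{LabelMap}.
#' @param truth reference \linkS4class{LabelMap} on the same grid.
#' @return data.frame with columns region, dice, miou, recall, precision,
#'   n_pred, n_truth.
#' @export
evaluateMasks <- function(pred, truth) {
  if (!identical(dim(pred@data), dim(truth@data)))
    stop("grid mismatch between pred and truth")
  lab <- roiLabels()
  sets <- c(as.list(names(lab)[-1]),
            list(c("spine", "sacrum"), c("ppj", "sacrum")))
  names(sets) <- c(names(lab)[-1], "spine_sacrum", "ppj_sacrum")
  rows <- lapply(names(sets), function(nm) {
    ids <- lab[sets[[nm]]]
    A <- pred@data %in% ids
    B <- truth@data %in% ids
    na <- sum(A); nb <- sum(B)
    if (na == 0L && nb == 0L)
      return(data.frame(region = nm, dice = NA_real_, miou = NA_real_,
                        recall = NA_real_, precision = NA_real_,
                        n_pred = 0L, n_truth = 0L))
    inter <- sum(A & B)
    data.frame(region = nm, dice = 2 * inter / (na + nb),
               miou = inter / (na + nb - inter),
               recall = if (nb > 0) inter / nb else NA_real_,
               precision = if (na > 0) inter / na else NA_real_,
               n_pred = na, n_truth = nb)
  })
  do.call(rbind, rows)
}
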