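# Positional encoding, network contracts, gradients, training, evaluation.

test_that("positional encoding follows the sinusoidal definition", {
  pe0 <- positionalEncoding(0, 8)
  expect_equal(pe0, rep(c(0, 1), 4))
  # bounded for all indices, and matches the explicit formula
  for (p in c(1, 7, 63, 255)) {
    pe <- positionalEncoding(p, 32)
    expect_true(all(pe >= -1 & pe <= 1))
    i <- 0:15
    expect_equal(pe[2 * i + 1], sin(p / 10000^(2 * i / 32)), tolerance = 1e-12)
    expect_equal(pe[2 * i + 2], cos(p / 10000^(2 * i / 32)), tolerance = 1e-12)
  }
  # pairwise distinct over 0..63
  E <- sapply(0:63, positionalEncoding, pe_dim = 32)
  expect_equal(nrow(unique(t(E))), 64L)
  expect_error(positionalEncoding(0, 7), "even")
  expect_error(positionalEncoding(300, 8, 256), "range")
})

test_that("model output shape, determinism and PE sensitivity", {
  cfg <- segConfig(n_levels = 2, base_channels = 4, pe_dim = 8,
                   pe_max_len = 32, seed = 5)
  mod <- segBuildModel(cfg)
  set.seed(6)
  x <- matrix(runif(16 * 12), 16, 12)
  out <- segPredictSlice(mod, x, 3L)
  expect_equal(dim(out), c(16, 12, 6))
  expect_identical(out, segPredictSlice(mod, x, 3L))
  # identical content at two indices scores differently once the head
  # weights touching the encoding are nonzero (they are, at init)
  out2 <- segPredictSlice(mod, x, 17L)
  expect_gt(max(abs(out - out2)), 0)
  # without the encoding the index has no effect
  modN <- segBuildModel(segConfig(n_levels = 2, base_channels = 4,
                                  pe_dim = 8, pe_max_len = 32, seed = 5,
                                  use_pe = FALSE))
  expect_identical(segPredictSlice(modN, x, 3L), segPredictSlice(modN, x, 17L))
  expect_error(segPredictSlice(mod, matrix(0, 15, 12), 0L), "divisible")
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- segConfig(n_levels = 2, base_channels = 2, pe_dim = 4,
                   pe_max_len = 16, seed = 3)
  mod <- segBuildModel(cfg)
  set.seed(9)
  x <- matrix(runif(8 * 8), 8, 8)
  y <- matrix(sample(0:5, 64, TRUE), 8, 8)
  for (lossname in c("cross_entropy", "dice", "sum")) {
    fw <- skelquant:::.segForward(mod@params, cfg, x, 3L, want_cache = TRUE)
    ls <- skelquant:::nnSegLoss(fw$logits, y, lossname)
    gr <- skelquant:::.segBackward(mod@params, cfg, fw$cache, ls$dlogits)
    lossAt <- function(params) {
      f <- skelquant:::.segForward(params, cfg, x, 3L)
      skelquant:::nnSegLoss(f$logits, y, lossname)$loss
    }
    eps <- 1e-6
    set.seed(31)
    for (nm in names(mod@params)) {
      p <- mod@params[[nm]]
      pick <- if (length(p) > 4) sample.int(length(p), 4) else seq_along(p)
      for (i in pick) {
        pp <- mod@params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- mod@params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
        expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training reduces the loss and is seed-deterministic", {
  set.seed(50)
  mk <- function() {
    sl <- matrix(runif(16 * 16), 16, 16)
    lb <- matrix(0L, 16, 16)
    lb[sl > 0.6] <- 1L
    list(slice = sl, index = sample(0:15, 1), label = lb)
  }
  ds <- replicate(6, mk(), simplify = FALSE)
  cfg <- segConfig(n_levels = 2, base_channels = 4, pe_dim = 8,
                   pe_max_len = 16, lr = 5e-3, seed = 4)
  tr1 <- segTrain(segBuildModel(cfg), ds, epochs = 8)
  expect_lt(tail(tr1$loss_trace, 1), tr1$loss_trace[1])
  tr2 <- segTrain(segBuildModel(cfg), ds, epochs = 8)
  expect_identical(tr1$loss_trace, tr2$loss_trace)
  expect_error(segTrain(segBuildModel(cfg), list()), "empty")
  bad <- ds
  bad[[1]]$label[1, 1] <- 9L
  expect_error(segTrain(segBuildModel(cfg), bad), "0..5")
})

test_that("a saturated model reproduces a blocky phantom's label map", {
  # five visually distinct structures on 16 sagittal slices
  d <- c(16, 32, 32)
  ct <- array(-1000, d)
  lab <- array(0L, d)
  put <- function(lb, ys, zs, hu) {
    lab[, ys, zs] <<- lb
    ct[, ys, zs] <<- hu
  }
  ct[, 3:30, 3:30] <- 40  # body
  put(1L, 5:12, 5:12, 1200)
  put(2L, 20:28, 5:12, 900)
  put(3L, 20:28, 16:23, 650)
  put(4L, 5:12, 16:28, 1100)
  put(5L, 14:18, 25:30, 500)
  ctv <- ImageVolume(ct, spacing = c(0.4, 0.4, 0.4), modality = "HU")
  lmv <- LabelMap(lab, spacing = c(0.4, 0.4, 0.4))
  cfg <- segConfig(n_levels = 2, base_channels = 8, pe_dim = 8,
                   pe_max_len = 32, lr = 8e-3, seed = 2)
  ds <- segSliceDataset(ctv, lmv, cfg)
  tr <- segTrain(segBuildModel(cfg), ds, epochs = 60)
  pred <- segPredictVolume(tr$model, ctv)
  ev <- evaluateMasks(pred, lmv)
  per_roi <- ev[ev$region %in% c("spine", "femur_r", "femur_l", "ppj",
                                 "sacrum"), ]
  expect_true(all(per_roi$dice >= 0.95))
})

test_that("an all-air volume maps to background with a background-biased model", {
  d <- c(8, 16, 16)
  air <- ImageVolume(array(-1000, d), spacing = c(0.4, 0.4, 0.4),
                     modality = "HU")
  lab <- LabelMap(array(0L, d), spacing = c(0.4, 0.4, 0.4))
  cfg <- segConfig(n_levels = 2, base_channels = 2, pe_dim = 4,
                   pe_max_len = 16, lr = 1e-2, seed = 8)
  tr <- segTrain(segBuildModel(cfg), segSliceDataset(air, lab, cfg),
                 epochs = 25)
  pred <- segPredictVolume(tr$model, air)
  expect_true(all(imgData(pred) == 0L))
  expect_equal(dim(imgData(pred)), d)
})

test_that("evaluation identities: Dice, mIoU, recall, precision", {
  d <- c(6, 6, 6)
  set.seed(51)
  t1 <- LabelMap(array(sample(0:5, prod(d), TRUE), d))
  ev <- evaluateMasks(t1, t1)
  expect_true(all(ev$dice == 1 & ev$miou == 1 & ev$recall == 1 &
                  ev$precision == 1))
  # disjoint non-empty sets -> all zero
  a <- array(0L, d); a[1:3, , ] <- 2L
  b <- array(0L, d); b[4:6, , ] <- 2L
  ev2 <- evaluateMasks(LabelMap(a), LabelMap(b))
  r <- ev2[ev2$region == "femur_r", ]
  expect_equal(unname(unlist(r[c("dice", "miou", "recall", "precision")])),
               c(0, 0, 0, 0))
  # |A|=|B|=8, |A∩B|=4
  a <- array(0L, d); a[1:8] <- 4L
  b <- array(0L, d); b[5:12] <- 4L
  ev3 <- evaluateMasks(LabelMap(a), LabelMap(b))
  r3 <- ev3[ev3$region == "ppj", ]
  expect_equal(r3$dice, 0.5)
  expect_equal(r3$miou, 1 / 3)
  expect_equal(r3$recall, 0.5)
  expect_equal(r3$precision, 0.5)
  # labels absent from both maps are undefined, not 0 or 1
  expect_true(is.na(ev3$dice[ev3$region == "spine"]))
  expect_true(is.na(ev3$dice[ev3$region == "sacrum"]))
})

test_that("Dice equals 2 IoU / (1 + IoU) on random mask pairs", {
  set.seed(52)
  d <- c(8, 8, 8)
  for (i in 1:100) {
    a <- array(sample(0:5, prod(d), TRUE), d)
    b <- array(sample(0:5, prod(d), TRUE), d)
    ev <- evaluateMasks(LabelMap(a), LabelMap(b))
    ok <- !is.na(ev$dice)
    expect_equal(ev$dice[ok], 2 * ev$miou[ok] / (1 + ev$miou[ok]),
                 tolerance = 1e-12)
  }
})

test_that("evaluation is invariant under simultaneous voxel permutation", {
  set.seed(53)
  d <- c(6, 6, 6)
  a <- array(sample(0:5, prod(d), TRUE), d)
  b <- array(sample(0:5, prod(d), TRUE), d)
  perm <- sample(prod(d))
  ev1 <- evaluateMasks(LabelMap(a), LabelMap(b))
  ev2 <- evaluateMasks(LabelMap(array(a[perm], d)),
                       LabelMap(array(b[perm], d)))
  expect_equal(ev1, ev2)
})
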