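# The ROI classifier: conv(f1, k x k) -> BN -> ReLU -> maxpool 2x2 ->
# conv(f2) -> BN -> ReLU -> maxpool -> dropout -> flatten ->
# dense1 -> BN -> ReLU -> dense2 -> BN -> ReLU -> dropout ->
# dense3 -> ReLU -> dense4(2) -> softmax.
# Trained with Adam on categorical cross-entropy. Batches are 4-d arrays
# (h, w, channels, n); dense activations are n x units matrices.

.heInit <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)

.bnEps <- 1e-5
.bnMomentum <- 0.9

# batch norm over a 2-d (samples x units) matrix
.bn2Forward <- function(x, g, b, rm, rv, train) {
  if (train) {
    mu <- colMeans(x)
    va <- colMeans(sweep(x, 2, mu)^2)
  } else {
    mu <- rm; va <- rv
  }
  xh <- sweep(sweep(x, 2, mu), 2, sqrt(va + .bnEps), "/")
  y <- sweep(sweep(xh, 2, g, "*"), 2, b, "+")
  list(y = y, xh = xh, mu = mu, va = va)
}

.bn2Backward <- function(dy, xh, va, g) {
  M <- nrow(dy)
  dg <- colSums(dy * xh)
  db <- colSums(dy)
  dxh <- sweep(dy, 2, g, "*")
  s1 <- colSums(dxh)
  s2 <- colSums(dxh * xh)
  dx <- sweep(M * dxh - matrix(s1, M, length(s1), byrow = TRUE) -
                xh * matrix(s2, M, length(s2), byrow = TRUE),
              2, M * sqrt(va + .bnEps), "/")
  list(dx = dx, dg = dg, db = db)
}

# channel-wise batch norm over a 4-d (h, w, c, n) array
.bn4ToMat <- function(x) {
  d <- dim(x)
  list(mat = matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3]), d = d)
}

.bn4FromMat <- function(mat, d) {
  aperm(array(mat, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
}

.bn4Forward <- function(x, g, b, rm, rv, train) {
  m <- .bn4ToMat(x)
  f <- .bn2Forward(m$mat, g, b, rm, rv, train)
  list(y = .bn4FromMat(f$y, m$d), xh = f$xh, mu = f$mu, va = f$va, d = m$d)
}

.bn4Backward <- function(dy, cacheBn, g) {
  m <- .bn4ToMat(dy)
  bk <- .bn2Backward(m$mat, cacheBn$xh, cacheBn$va, g)
  list(dx = .bn4FromMat(bk$dx, cacheBn$d), dg = bk$dg, db = bk$db)
}

.denseForward <- function(x, W, b) sweep(x %*% W, 2, b, "+")

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Build an untrained ROI classifier
#'
#' Allocates and initializes (He-normal, seeded) the weights of the network
#' described by a \code{\link{ClassifierConfig-class}}. Two builds with the
#' same configuration and seed produce identical initial predictions.
#'
#' @param config a \code{\link{ClassifierConfig-class}}.
#' @param seed integer initialization seed.
#' @return an object of class \code{roiClassifier}.
#' @export
buildClassifier <- function(config = ClassifierConfig(), seed = 1L) {
  validObject(config)
  k <- config@convKernel
  C <- config@channels
  f <- config@convFilters
  h <- config@inputSize[1]; w <- config@inputSize[2]
  oh1 <- h - k + 1; ow1 <- w - k + 1
  ph1 <- oh1 %/% 2; pw1 <- ow1 %/% 2
  oh2 <- ph1 - k + 1; ow2 <- pw1 - k + 1
  ph2 <- oh2 %/% 2; pw2 <- ow2 %/% 2
  if (ph2 < 1 || pw2 < 1) stop("inputSize too small for two conv/pool stages")
  flat <- ph2 * pw2 * f[2]
  du <- config@denseUnits
  if (length(du) != 4) stop("the dense head uses exactly four layers")
  params <- withLocalSeed(seed, {
    p <- list(conv1W = .heInit(k * k * C, f[1]), conv1b = rep(0, f[1]),
              bn1g = rep(1, f[1]), bn1b = rep(0, f[1]),
              conv2W = .heInit(k * k * f[1], f[2]), conv2b = rep(0, f[2]),
              bn2g = rep(1, f[2]), bn2b = rep(0, f[2]))
    dims <- c(flat, du)
    for (i in seq_along(du)) {
      p[[paste0("dense", i, "W")]] <- .heInit(dims[i], dims[i + 1])
      p[[paste0("dense", i, "b")]] <- rep(0, dims[i + 1])
    }
    p$bnd1g <- rep(1, du[1]); p$bnd1b <- rep(0, du[1])
    p$bnd2g <- rep(1, du[2]); p$bnd2b <- rep(0, du[2])
    p
  })
  running <- list(bn1m = rep(0, f[1]), bn1v = rep(1, f[1]),
                  bn2m = rep(0, f[2]), bn2v = rep(1, f[2]),
                  bnd1m = rep(0, du[1]), bnd1v = rep(1, du[1]),
                  bnd2m = rep(0, du[2]), bnd2v = rep(1, du[2]))
  structure(list(config = config, params = params, running = running,
                 initSeed = as.integer(seed)),
            class = "roiClassifier")
}

# forward pass; train = TRUE keeps caches, applies dropout (consumes RNG) and
# returns batch statistics for the running-average update
.nnForward <- function(model, x, train = FALSE) {
  p <- model$params; r <- model$running; cfg <- model$config
  cache <- list(x = x)
  z1 <- .cpp_conv_forward(x, p$conv1W, p$conv1b)
  bn1 <- .bn4Forward(z1, p$bn1g, p$bn1b, r$bn1m, r$bn1v, train)
  a1 <- pmax(bn1$y, 0)
  pl1 <- .cpp_maxpool_forward(a1)
  z2 <- .cpp_conv_forward(pl1$y, p$conv2W, p$conv2b)
  bn2 <- .bn4Forward(z2, p$bn2g, p$bn2b, r$bn2m, r$bn2v, train)
  a2 <- pmax(bn2$y, 0)
  pl2 <- .cpp_maxpool_forward(a2)
  hout <- pl2$y
  maskC <- NULL
  if (train && cfg@convDropout > 0) {
    keep <- 1 - cfg@convDropout
    maskC <- array((runif(length(hout)) < keep) / keep, dim = dim(hout))
    hout <- hout * maskC
  }
  N <- dim(x)[4]
  X0 <- t(matrix(hout, ncol = N))
  zd1 <- .denseForward(X0, p$dense1W, p$dense1b)
  bnd1 <- .bn2Forward(zd1, p$bnd1g, p$bnd1b, r$bnd1m, r$bnd1v, train)
  ad1 <- pmax(bnd1$y, 0)
  zd2 <- .denseForward(ad1, p$dense2W, p$dense2b)
  bnd2 <- .bn2Forward(zd2, p$bnd2g, p$bnd2b, r$bnd2m, r$bnd2v, train)
  ad2 <- pmax(bnd2$y, 0)
  maskD <- NULL
  if (train && cfg@denseDropout > 0) {
    keep <- 1 - cfg@denseDropout
    maskD <- matrix((runif(length(ad2)) < keep) / keep, nrow(ad2))
    ad2 <- ad2 * maskD
  }
  zd3 <- .denseForward(ad2, p$dense3W, p$dense3b)
  ad3 <- pmax(zd3, 0)
  zd4 <- .denseForward(ad3, p$dense4W, p$dense4b)
  probs <- .softmax(zd4)
  if (!train) return(list(probs = probs))
  list(probs = probs,
       cache = list(x = x, z1 = z1, bn1 = bn1, a1 = a1, pl1 = pl1, z2 = z2,
                    bn2 = bn2, a2 = a2, pl2 = pl2, maskC = maskC, X0 = X0,
                    zd1 = zd1, bnd1 = bnd1, ad1 = ad1, zd2 = zd2, bnd2 = bnd2,
                    ad2 = ad2, maskD = maskD, zd3 = zd3, ad3 = ad3))
}

.nnBackward <- function(model, fw, Y) {
  p <- model$params
  cc <- fw$cache
  N <- nrow(Y)
  g <- list()
  dz4 <- (fw$probs - Y) / N
  g$dense4W <- t(cc$ad3) %*% dz4
  g$dense4b <- colSums(dz4)
  dad3 <- dz4 %*% t(p$dense4W)
  dzd3 <- dad3 * (cc$zd3 > 0)
  g$dense3W <- t(cc$ad2) %*% dzd3
  g$dense3b <- colSums(dzd3)
  dad2 <- dzd3 %*% t(p$dense3W)
  if (!is.null(cc$maskD)) dad2 <- dad2 * cc$maskD
  dbnd2y <- dad2 * (cc$bnd2$y > 0)
  bk2 <- .bn2Backward(dbnd2y, cc$bnd2$xh, cc$bnd2$va, p$bnd2g)
  g$bnd2g <- bk2$dg; g$bnd2b <- bk2$db
  dzd2 <- bk2$dx
  g$dense2W <- t(cc$ad1) %*% dzd2
  g$dense2b <- colSums(dzd2)
  dad1 <- dzd2 %*% t(p$dense2W)
  dbnd1y <- dad1 * (cc$bnd1$y > 0)
  bk1 <- .bn2Backward(dbnd1y, cc$bnd1$xh, cc$bnd1$va, p$bnd1g)
  g$bnd1g <- bk1$dg; g$bnd1b <- bk1$db
  dzd1 <- bk1$dx
  g$dense1W <- t(cc$X0) %*% dzd1
  g$dense1b <- colSums(dzd1)
  dX0 <- dzd1 %*% t(p$dense1W)
  dh <- array(t(dX0), dim = dim(cc$pl2$y))
  if (!is.null(cc$maskC)) dh <- dh * cc$maskC
  da2 <- .cpp_maxpool_backward(cc$pl2$idx, dh, dim(cc$a2))
  dbn2y <- da2 * (cc$bn2$y > 0)
  bkc2 <- .bn4Backward(dbn2y, cc$bn2, p$bn2g)
  g$bn2g <- bkc2$dg; g$bn2b <- bkc2$db
  cb2 <- .cpp_conv_backward(cc$pl1$y, p$conv2W, bkc2$dx)
  g$conv2W <- cb2$dW; g$conv2b <- cb2$db
  da1 <- .cpp_maxpool_backward(cc$pl1$idx, cb2$dx, dim(cc$a1))
  dbn1y <- da1 * (cc$bn1$y > 0)
  bkc1 <- .bn4Backward(dbn1y, cc$bn1, p$bn1g)
  g$bn1g <- bkc1$dg; g$bn1b <- bkc1$db
  cb1 <- .cpp_conv_backward(cc$x, p$conv1W, bkc1$dx)
  g$conv1W <- cb1$dW; g$conv1b <- cb1$db
  g
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.updateRunning <- function(running, fwCache) {
  mo <- .bnMomentum
  upd <- function(old, new) mo * old + (1 - mo) * new
  running$bn1m <- upd(running$bn1m, fwCache$bn1$mu)
  running$bn1v <- upd(running$bn1v, fwCache$bn1$va)
  running$bn2m <- upd(running$bn2m, fwCache$bn2$mu)
  running$bn2v <- upd(running$bn2v, fwCache$bn2$va)
  running$bnd1m <- upd(running$bnd1m, fwCache$bnd1$mu)
  running$bnd1v <- upd(running$bnd1v, fwCache$bnd1$va)
  running$bnd2m <- upd(running$bnd2m, fwCache$bnd2$mu)
  running$bnd2v <- upd(running$bnd2v, fwCache$bnd2$va)
  running
}

# stack a list of images into the (h, w, c, n) batch the model expects
.prepareBatch <- function(config, images) {
  h <- config@inputSize[1]; w <- config@inputSize[2]; C <- config@channels
  n <- length(images)
  x <- array(0, dim = c(h, w, C, n))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (length(dim(img)) == 2) {
      rs <- resizeImage(img, h, w) / 255
      for (k in seq_len(C)) x[, , k, i] <- rs
    } else {
      rs <- resizeImage(img, h, w) / 255
      if (C == 1) x[, , 1, i] <- 0.299 * rs[, , 1] + 0.587 * rs[, , 2] + 0.114 * rs[, , 3]
      else for (k in seq_len(C)) x[, , k, i] <- rs[, , min(k, dim(rs)[3])]
    }
  }
  x
}

#' Predict ROI probabilities
#'
#' @param model a \code{roiClassifier}.
#' @param images list of images (matrices or RGB arrays, 0-255), or a single
#'   image, or a prepared (h, w, c, n) batch in [0, 1].
#' @return n x 2 matrix of softmax probabilities, columns
#'   \code{c("Non-ROI", "ROI")}.
#' @export
predictClassifier <- function(model, images) {
  stopifnot(inherits(model, "roiClassifier"))
  x <- if (is.array(images) && length(dim(images)) == 4) images
    else .prepareBatch(model$config, if (is.list(images)) images else list(images))
  out <- .nnForward(model, x, train = FALSE)$probs
  colnames(out) <- c("Non-ROI", "ROI")
  out
}

#' Train the ROI classifier
#'
#' Shuffles the data once (seeded), holds out \code{1 - trainFraction} as the
#' validation split, and optimizes categorical cross-entropy with Adam for
#' the configured number of epochs; training batches are optionally augmented
#' with random horizontal flips (ROI-ness is flip-invariant). Per-epoch
#' training and validation accuracy are recorded.
#'
#' @param model a \code{roiClassifier} from \code{\link{buildClassifier}}.
#' @param dataset list with \code{images} (list of images) and \code{labels}
#'   (integer 0 = Non-ROI / 1 = ROI), as from \code{\link{makeTrainingSet}}.
#' @param trainConfig a \code{\link{TrainConfig-class}}.
#' @return list with \code{model} (trained) and \code{history} (data.frame
#'   with epoch, trainLoss, trainAccuracy, valAccuracy).
#' @export
trainClassifier <- function(model, dataset, trainConfig = TrainConfig()) {
  stopifnot(inherits(model, "roiClassifier"))
  validObject(trainConfig)
  labels <- as.integer(dataset$labels)
  if (length(unique(labels)) < 2)
    stop("training data must contain both classes (Non-ROI and ROI)")
  if (length(dataset$images) != length(labels))
    stop("images and labels differ in length")
  x <- .prepareBatch(model$config, dataset$images)
  n <- length(labels)
  Y <- cbind(labels == 0L, labels == 1L) * 1  # one-hot, column order (Non-ROI, ROI)

  withLocalSeed(trainConfig@seed, {
    perm <- sample.int(n)
    nTrain <- max(1L, min(n - 1L, floor(trainConfig@trainFraction * n)))
    trIdx <- perm[seq_len(nTrain)]
    vaIdx <- perm[(nTrain + 1L):n]
    xva <- x[, , , vaIdx, drop = FALSE]
    yva <- labels[vaIdx]
    state <- .adamInit(model$params)
    hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                       trainAccuracy = numeric(0), valAccuracy = numeric(0))
    w <- dim(x)[2]
    for (ep in seq_len(trainConfig@epochs)) {
      epIdx <- trIdx[sample.int(nTrain)]
      batches <- split(epIdx, ceiling(seq_along(epIdx) / trainConfig@batchSize))
      losses <- accs <- numeric(0)
      for (b in batches) {
        xb <- x[, , , b, drop = FALSE]
        if (trainConfig@augmentFlip) {
          flip <- runif(length(b)) < 0.5
          if (any(flip)) xb[, , , flip] <- xb[, w:1, , flip, drop = FALSE]
        }
        yb <- Y[b, , drop = FALSE]
        fw <- .nnForward(model, xb, train = TRUE)
        eps <- 1e-12
        losses <- c(losses, -mean(log(rowSums(fw$probs * yb) + eps)))
        accs <- c(accs, mean((fw$probs[, 2] >= 0.5) == (yb[, 2] == 1)))
        grads <- .nnBackward(model, fw, yb)
        st <- .adamStep(model$params, grads, state, trainConfig@learningRate)
        model$params <- st$params
        state <- st$state
        model$running <- .updateRunning(model$running, fw$cache)
      }
      pv <- .nnForward(model, xva, train = FALSE)$probs
      valAcc <- mean((pv[, 2] >= 0.5) == (yva == 1L))
      hist <- rbind(hist, data.frame(epoch = ep, trainLoss = mean(losses),
                                     trainAccuracy = mean(accs),
                                     valAccuracy = valAcc))
    }
    list(model = model, history = hist)
  })
}

#' Save / load a trained classifier
#'
#' The weights go to \code{path} in R's native serialization format; a JSON
#' sidecar \code{<path>.json} records the architecture (and, if supplied, the
#' training protocol) so a saved model is self-describing.
#'
#' @param model a \code{roiClassifier}.
#' @param path destination file (conventionally \code{.rds}).
#' @param trainConfig optional \code{\link{TrainConfig-class}} recorded in the
#'   sidecar.
#' @return \code{path}, invisibly.
#' @export
saveClassifier <- function(model, path, trainConfig = NULL) {
  stopifnot(inherits(model, "roiClassifier"))
  cfg <- model$config
  saveRDS(list(params = model$params, running = model$running,
               initSeed = model$initSeed,
               config = list(inputSize = cfg@inputSize, channels = cfg@channels,
                             convFilters = cfg@convFilters,
                             convKernel = cfg@convKernel,
                             convDropout = cfg@convDropout,
                             denseUnits = cfg@denseUnits,
                             denseDropout = cfg@denseDropout)),
          path)
  side <- list(classifier_config = list(
    input_size = cfg@inputSize, channels = cfg@channels,
    conv_filters = cfg@convFilters, conv_kernel = cfg@convKernel,
    conv_dropout = cfg@convDropout, dense_units = cfg@denseUnits,
    dense_dropout = cfg@denseDropout))
  if (!is.null(trainConfig))
    side$train_config <- list(epochs = trainConfig@epochs,
                              batch_size = trainConfig@batchSize,
                              train_fraction = trainConfig@trainFraction,
                              augment_flip = trainConfig@augmentFlip,
                              learning_rate = trainConfig@learningRate,
                              seed = trainConfig@seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  x <- readRDS(path)
  cfg <- do.call(ClassifierConfig, x$config)
  structure(list(config = cfg, params = x$params, running = x$running,
                 initSeed = x$initSeed),
            class = "roiClassifier")
}

#' @export
print.roiClassifier <- function(x, ...) {
  cfg <- x$config
  nPar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(paste0("roiClassifier: input %dx%dx%d, conv %s (k=%d), ",
                     "dense %s, %s parameters\n"),
              cfg@inputSize[1], cfg@inputSize[2], cfg@channels,
              paste(cfg@convFilters, collapse = "-"), cfg@convKernel,
              paste(cfg@denseUnits, collapse = "-"),
              format(nPar, big.mark = ",")))
  invisible(x)
}
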