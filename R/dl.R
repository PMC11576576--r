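# U-Net image-to-image regression from a two-channel VMI pair to an SPR map,
# trained with L1 / MSE / perceptual composite losses via Adam, plus the
# repeated-training variability protocol.

#' Training configuration for the U-Net SPR regressor
#'
#' The optimizer settings mirror the study protocol (Adam, learning rate
#' 1e-4, beta1 = 0.5, beta2 = 0.9, batch size 2, channel multipliers
#' (1,1,2,2,2,2,2), lambda1 = lambda2 = 1, 80/20 splits). Desk-scale
#' defaults use 64x64 inputs, 12 base features, the L1 loss and a modest
#' epoch count; the full-scale protocol (256x256, 64 features, 350 epochs,
#' perceptual+L1 loss, 15 repeats) is reached by overriding those fields.
#'
#' @param learningRate Adam learning rate
#' @param adamBeta1,adamBeta2 Adam moment decay rates
#' @param batchSize minibatch size
#' @param epochs training epochs
#' @param baseFeatures channel width at the first resolution
#' @param channelMultipliers per-level width multipliers
#' @param inputSize image side length (must be divisible by
#'   2^(levels - 1))
#' @param loss "L1", "MSE", "VGG16" or "VGG16_L1"
#' @param lambda1,lambda2 perceptual and L1 weights of the composite loss
#' @param splitRatio train fraction of each 80/20 split
#' @param seed seed controlling initialization, splits and shuffling
#' @param nRepeats repeats for [repeatTraining()]
#' @param lrSchedule "constant" or "cosine" (per-epoch cosine decay to 0;
#'   useful for short desk-scale runs where the L1 gradient's constant
#'   magnitude otherwise leaves an oscillation floor)
#' @return a [TrainConfig]
#' @export
trainConfig <- function(learningRate = 1e-4, adamBeta1 = 0.5,
                        adamBeta2 = 0.9, batchSize = 2L, epochs = 50L,
                        baseFeatures = 12L,
                        channelMultipliers = c(1L, 1L, 2L, 2L, 2L, 2L, 2L),
                        inputSize = 64L, loss = "L1", lambda1 = 1,
                        lambda2 = 1, splitRatio = 0.8, seed = 1L,
                        nRepeats = 15L, lrSchedule = "constant") {
  stopifnot(lrSchedule %in% c("constant", "cosine"))
  new("TrainConfig", learningRate = learningRate, adamBeta1 = adamBeta1,
      adamBeta2 = adamBeta2, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), baseFeatures = as.integer(baseFeatures),
      channelMultipliers = as.integer(channelMultipliers),
      inputSize = as.integer(inputSize), loss = loss, lambda1 = lambda1,
      lambda2 = lambda2, splitRatio = splitRatio, seed = as.integer(seed),
      nRepeats = as.integer(nRepeats), lrSchedule = lrSchedule)
}

# He-style initialization for one conv weight matrix
.heInit <- function(fanIn, nOut) {
  matrix(rnorm(fanIn * nOut, sd = sqrt(2 / fanIn)), fanIn, nOut)
}

#' Build an (untrained) U-Net model
#'
#' Encoder-decoder with skip connections, one residual block per resolution,
#' channel widths `baseFeatures * channelMultipliers`, average-pool
#' downsampling and nearest-neighbor upsampling; no time embeddings and no
#' FIR filtering. Two input channels (low/high-energy VMI), one output
#' channel (SPR). Initialization is deterministic given `config@seed`.
#'
#' @param config a [TrainConfig]
#' @return a [TrainedModel] with freshly initialized parameters
#' @export
buildModel <- function(config = trainConfig()) {
  validObject(config)
  ch <- config@baseFeatures * config@channelMultipliers
  L <- length(ch)
  params <- withSeed(config@seed, {
    p <- list()
    p$in_w <- .heInit(9 * 2, ch[1]); p$in_b <- numeric(ch[1])
    addRes <- function(p, prefix, cin, cout) {
      p[[paste0(prefix, "_w1")]] <- .heInit(9 * cin, cout)
      p[[paste0(prefix, "_b1")]] <- numeric(cout)
      # last conv of the residual branch starts at zero so every block is
      # an identity map at initialization (keeps deep stacks well-scaled)
      p[[paste0(prefix, "_w2")]] <- matrix(0, 9 * cout, cout)
      p[[paste0(prefix, "_b2")]] <- numeric(cout)
      if (cin != cout) {
        p[[paste0(prefix, "_ws")]] <- .heInit(cin, cout)
        p[[paste0(prefix, "_bs")]] <- numeric(cout)
      }
      p
    }
    for (i in seq_len(L))
      p <- addRes(p, paste0("enc", i), if (i == 1) ch[1] else ch[i - 1], ch[i])
    p <- addRes(p, "mid", ch[L], ch[L])
    for (i in seq_len(L)) {
      hch <- if (i == L) ch[L] else ch[i + 1]
      p <- addRes(p, paste0("dec", i), hch + ch[i], ch[i])
    }
    p$out_w <- matrix(0, 9 * ch[1], 1); p$out_b <- numeric(1)
    p
  })
  new("TrainedModel", params = params, config = config,
      arch = list(channels = ch, levels = L),
      normalization = list(xScale = 1000),
      log = data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric()))
}

# forward pass; x is H x W x 2 (normalized). Returns prediction and caches.
.unetF <- function(params, x, arch) {
  L <- arch$levels
  cin <- .conv3F(x, params$in_w, params$in_b)
  h <- cin$y
  encs <- vector("list", L); pools <- vector("list", L - 1)
  skips <- vector("list", L)
  for (i in seq_len(L)) {
    encs[[i]] <- .resF(h, params, paste0("enc", i))
    skips[[i]] <- encs[[i]]$y
    h <- encs[[i]]$y
    if (i < L) {
      pools[[i]] <- .poolF(h)
      h <- pools[[i]]$y
    }
  }
  mid <- .resF(h, params, "mid")
  h <- mid$y
  decs <- vector("list", L); cats <- vector("list", L); ups <- vector("list", L)
  for (i in rev(seq_len(L))) {
    cats[[i]] <- .concatF(h, skips[[i]])
    decs[[i]] <- .resF(cats[[i]]$y, params, paste0("dec", i))
    h <- decs[[i]]$y
    if (i > 1) {
      ups[[i]] <- .upF(h)
      h <- ups[[i]]$y
    }
  }
  out <- .conv3F(h, params$out_w, params$out_b)
  list(y = out$y[, , 1], cache = list(cin = cin, encs = encs, pools = pools,
                                      mid = mid, cats = cats, decs = decs,
                                      ups = ups, out = out, L = L))
}

# backward pass; dy is H x W gradient at the output
.unetB <- function(params, cache, dy, arch) {
  L <- cache$L
  grads <- lapply(params, function(p) p * 0)
  dout <- array(dy, c(dim(dy), 1))
  g <- .conv3B(dout, cache$out, params$out_w)
  grads$out_w <- grads$out_w + g$dW; grads$out_b <- grads$out_b + g$db
  dh <- g$dx
  dskips <- vector("list", L)
  for (i in seq_len(L)) {
    if (i > 1) dh <- .upB(dh, cache$ups[[i]])
    rb <- .resB(dh, cache$decs[[i]], params, paste0("dec", i), grads)
    grads <- rb$grads
    cb <- .concatB(rb$dx, cache$cats[[i]])
    dh <- cb$da
    dskips[[i]] <- cb$db
  }
  rb <- .resB(dh, cache$mid, params, "mid", grads)
  grads <- rb$grads
  dh <- rb$dx
  for (i in rev(seq_len(L))) {
    if (i < L) dh <- .poolB(dh, cache$pools[[i]])
    dh <- dh + dskips[[i]]
    rb <- .resB(dh, cache$encs[[i]], params, paste0("enc", i), grads)
    grads <- rb$grads
    dh <- rb$dx
  }
  g <- .conv3B(dh, cache$cin, params$in_w)
  grads$in_w <- grads$in_w + g$dW; grads$in_b <- grads$in_b + g$db
  grads
}

#' Composite training loss (perceptual + pixel terms)
#'
#' loss = lambda1 * MSE(F(pred), F(truth)) + lambda2 * L1(pred, truth),
#' where F is a perceptual feature extractor; "L1" and "MSE" select the pure
#' pixel losses, and "VGG16" the pure perceptual term. With lambda1 = 0 the
#' composite reduces bit-for-bit to L1 (and with lambda2 = 0 to the
#' perceptual term). No pretrained feature extractor ships with the package;
#' perceptual variants require `featureExtractor`, a function taking the
#' 3-channel replicated, rescaled image and returning
#' `list(features, backward)` with `backward(dFeatures)` mapping a feature
#' gradient back to the image.
#'
#' @param pred,truth SPR maps (matrices or [SPRMap])
#' @param config a [TrainConfig] (loss variant and lambda weights)
#' @param featureExtractor optional perceptual feature extractor
#' @param withGrad also return the gradient with respect to `pred`
#' @return scalar loss, or list(loss, grad) when `withGrad = TRUE`
#' @export
compositeLoss <- function(pred, truth, config = trainConfig(),
                          featureExtractor = NULL, withGrad = FALSE) {
  p <- if (is(pred, "SPRMap")) pred@values else pred
  t <- if (is(truth, "SPRMap")) truth@values else truth
  if (!all(dim(p) == dim(t))) stop("pred and truth must have equal shapes")
  n <- length(p)
  d <- p - t
  lam1 <- switch(config@loss, MSE = 0, L1 = 0, VGG16 = config@lambda1,
                 VGG16_L1 = config@lambda1)
  lam2 <- switch(config@loss, MSE = 0, L1 = 1, VGG16 = 0,
                 VGG16_L1 = config@lambda2)
  useMSE <- config@loss == "MSE"
  loss <- 0; grad <- matrix(0, nrow(p), ncol(p))
  if (useMSE) {
    loss <- mean(d^2)
    grad <- 2 * d / n
  }
  if (lam2 != 0) {
    loss <- loss + lam2 * mean(abs(d))
    grad <- grad + lam2 * sign(d) / n
  }
  if (lam1 != 0) {
    if (is.null(featureExtractor))
      stop("perceptual loss requested but no feature extractor is ",
           "available: no pretrained VGG16 weights ship with this package. ",
           "Use loss = 'L1' or 'MSE', or supply `featureExtractor`.")
    fp <- featureExtractor(.toPerceptualInput(p))
    ft <- featureExtractor(.toPerceptualInput(t))
    df <- fp$features - ft$features
    loss <- loss + lam1 * mean(df^2)
    if (withGrad) {
      gimg <- fp$backward(2 * df / length(df))
      # undo replication/rescaling: sum channel gradients, scale back
      grad <- grad + lam1 * .fromPerceptualGrad(gimg, p)
    }
  }
  if (withGrad) list(loss = loss, grad = grad) else loss
}

# replicate a single-channel map to 3 channels and rescale roughly to the
# statistics expected by ImageNet-pretrained extractors
.perceptualMean <- c(0.485, 0.456, 0.406)
.perceptualSd <- c(0.229, 0.224, 0.225)

.toPerceptualInput <- function(x) {
  x01 <- pmin(pmax(x / 2, 0), 1)   # SPR maps live roughly in [0, 2]
  arr <- array(0, c(dim(x), 3))
  for (c in 1:3) arr[, , c] <- (x01 - .perceptualMean[c]) / .perceptualSd[c]
  arr
}

.fromPerceptualGrad <- function(gimg, x) {
  g <- 0
  for (c in 1:3) g <- g + gimg[, , c] / .perceptualSd[c]
  g <- g / 2
  g[x / 2 < 0 | x / 2 > 1] <- 0
  g
}

# seeded 80/20 split (indices)
.splitIndices <- function(n, ratio, seed) {
  withSeed(seed, {
    idx <- sample.int(n)
    nTrain <- round(ratio * n)
    list(train = sort(idx[seq_len(nTrain)]), held = sort(idx[-seq_len(nTrain)]))
  })
}

# normalize one example to network input (H x W x 2)
.exampleInput <- function(ex, xScale) {
  x <- array(0, c(dim(ex$x1), 2))
  x[, , 1] <- ex$x1 / xScale
  x[, , 2] <- ex$x2 / xScale
  x
}

#' Train the U-Net on (VMI pair, SPR map) examples
#'
#' The dataset is split 80/20 into train/test and the train part again 80/20
#' into train/val by seeded shuffles; the model is optimized with Adam on
#' minibatches of the composite loss. Deterministic given the config seed
#' (single-threaded execution).
#'
#' @param examples list of examples, each a list with `x1`, `x2` (HU
#'   matrices of the low/high-energy VMIs) and `y` (SPR matrix)
#' @param config a [TrainConfig]
#' @param featureExtractor optional perceptual feature extractor (see
#'   [compositeLoss()])
#' @param verbose print per-epoch losses
#' @return a [TrainedModel]; the split indices are stored in `arch$splits`
#' @export
trainModel <- function(examples, config = trainConfig(),
                       featureExtractor = NULL, verbose = FALSE) {
  nEx <- length(examples)
  if (nEx < 2) stop("need at least 2 examples")
  sp1 <- .splitIndices(nEx, config@splitRatio, config@seed)
  sp2 <- .splitIndices(length(sp1$train), config@splitRatio, config@seed + 1L)
  trainIdx <- sp1$train[sp2$train]
  valIdx <- sp1$train[sp2$held]
  testIdx <- sp1$held
  if (!length(trainIdx)) stop("empty training split")

  model <- buildModel(config)
  xs <- config@inputSize
  for (i in seq_len(nEx)) {
    d <- dim(examples[[i]]$x1)
    if (!all(d == xs))
      stop("example ", i, " is ", d[1], "x", d[2], " but inputSize is ", xs)
  }
  params <- model@params
  mAd <- lapply(params, function(p) p * 0)
  vAd <- lapply(params, function(p) p * 0)
  b1 <- config@adamBeta1; b2 <- config@adamBeta2
  lr <- config@learningRate; epsA <- 1e-8
  step <- 0L
  xScale <- model@normalization$xScale
  logDf <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())

  evalLoss <- function(idx) {
    if (!length(idx)) return(NA_real_)
    mean(vapply(idx, function(i) {
      fw <- .unetF(params, .exampleInput(examples[[i]], xScale), model@arch)
      compositeLoss(fw$y, examples[[i]]$y, config, featureExtractor)
    }, numeric(1)))
  }

  for (epoch in seq_len(config@epochs)) {
    lrE <- if (config@lrSchedule == "cosine")
      lr * 0.5 * (1 + cos(pi * (epoch - 1) / config@epochs)) else lr
    ord <- withSeed(config@seed + 1000L + epoch,
                    trainIdx[sample.int(length(trainIdx))])
    batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
    epLoss <- 0
    for (bt in batches) {
      grads <- NULL
      btLoss <- 0
      for (i in bt) {
        fw <- .unetF(params, .exampleInput(examples[[i]], xScale), model@arch)
        lg <- compositeLoss(fw$y, examples[[i]]$y, config, featureExtractor,
                            withGrad = TRUE)
        btLoss <- btLoss + lg$loss
        g <- .unetB(params, fw$cache, lg$grad, model@arch)
        grads <- if (is.null(grads)) g
                 else mapply(function(a, b) a + b, grads, g, SIMPLIFY = FALSE)
      }
      nb <- length(bt)
      epLoss <- epLoss + btLoss
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (k in names(params)) {
        gk <- grads[[k]] / nb
        mAd[[k]] <- b1 * mAd[[k]] + (1 - b1) * gk
        vAd[[k]] <- b2 * vAd[[k]] + (1 - b2) * gk^2
        params[[k]] <- params[[k]] -
          lrE * corr * mAd[[k]] / (sqrt(vAd[[k]]) + epsA)
      }
    }
    trLoss <- epLoss / length(ord)
    vlLoss <- evalLoss(valIdx)
    logDf <- rbind(logDf, data.frame(epoch = epoch, train_loss = trLoss,
                                     val_loss = vlLoss))
    if (verbose)
      message(sprintf("epoch %d: train %.5f val %.5f", epoch, trLoss, vlLoss))
  }
  model@params <- params
  model@log <- logDf
  model@arch$splits <- list(train = trainIdx, val = valIdx, test = testIdx)
  model
}

#' Predict an SPR map from a VMI pair
#'
#' @param model a [TrainedModel]
#' @param x1,x2 HU matrices of the low/high-energy VMIs
#' @return an [SPRMap] with provenance "predicted_dl"
#' @export
predictSPR <- function(model, x1, x2) {
  if (!all(dim(x1) == dim(x2))) stop("VMI pair must share dimensions")
  fw <- .unetF(model@params,
               .exampleInput(list(x1 = x1, x2 = x2),
                             model@normalization$xScale), model@arch)
  if (any(!is.finite(fw$y))) stop("non-finite prediction")
  new("SPRMap", values = fw$y, provenance = "predicted_dl")
}

#' Repeated-training variability protocol
#'
#' Trains `n` models on identical data with differing per-repeat seeds
#' (initialization and shuffling vary) and summarizes a per-ROI evaluation
#' across repeats as mean and sample standard deviation.
#'
#' @param examples training examples (see [trainModel()])
#' @param config a [TrainConfig]; repeat r uses seed `seeds[r]`
#' @param n number of repeats (>= 2)
#' @param evaluate function(model) returning a named numeric vector of
#'   per-ROI scores (e.g. RMSE percentages); may also be used with a stub
#' @param seeds per-repeat seeds (default: consecutive from the config seed)
#' @param ... passed to [trainModel()]
#' @return list with `models`, `scores` (repeats x ROIs matrix) and
#'   `summary` (data.frame of mean and SD per ROI)
#' @export
repeatTraining <- function(examples, config, n = config@nRepeats, evaluate,
                           seeds = config@seed + seq_len(n) - 1L, ...) {
  if (n < 2) stop("need at least 2 repeats")
  models <- vector("list", n)
  scores <- NULL
  for (r in seq_len(n)) {
    cfg <- config
    cfg@seed <- as.integer(seeds[r])
    models[[r]] <- trainModel(examples, cfg, ...)
    s <- evaluate(models[[r]])
    scores <- rbind(scores, s)
  }
  rownames(scores) <- paste0("repeat", seq_len(n))
  summary <- data.frame(roi = colnames(scores),
                        mean = colMeans(scores),
                        sd = apply(scores, 2, sd))
  rownames(summary) <- NULL
  list(models = models, scores = scores, summary = summary)
}
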