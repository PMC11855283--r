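#' Configuration of the binding-score network
#'
#' The published architecture fixes the input (41x41x41x22 grids), four
#' residual stages of dilated bottleneck blocks ending at 2048 trunk
#' channels, a 1x1x1 compression to 256 channels (batch-normalised, ReLU), a
#' self-attention transformer block over the spatial tokens, global average
#' pooling, dropout 0.1 and a sigmoid head. Per-stage block counts, strides,
#' dilation rates and head count are not published; the defaults here are a
#' canonical 3D ResNet-50-style reconstruction (stages of 3/4/6/3
#' bottlenecks, dilation growing in the deeper stages, 8 attention heads),
#' every piece overridable.
#'
#' @param inChannels input feature channels (22).
#' @param gridSize voxels per axis of the input grid (odd; 41).
#' @param stemChannels,stemKernel,stemStride,stemPool initial convolution
#'   spec; the default 7x7x7/stride-2 conv plus 3x3x3/stride-2 max-pool.
#' @param blocks bottleneck blocks per residual stage.
#' @param stageChannels output width of each stage (trunk ends at 2048).
#' @param stageMid bottleneck inner widths.
#' @param stageStride,stageDilation per-stage stride and dilation.
#' @param compressTo channel width after the 1x1x1 compression layer (256).
#' @param heads attention heads in the transformer block.
#' @param mlpMult transformer feed-forward expansion factor.
#' @param dropout dropout rate before the fully connected head (0.1).
#' @return a validated \code{ModelConfig} list.
#' @export
modelConfig <- function(inChannels = 22, gridSize = 41,
                        stemChannels = 64, stemKernel = 7, stemStride = 2,
                        stemPool = TRUE,
                        blocks = c(3, 4, 6, 3),
                        stageChannels = c(256, 512, 1024, 2048),
                        stageMid = c(64, 128, 256, 512),
                        stageStride = c(1, 2, 2, 2),
                        stageDilation = c(1, 1, 2, 4),
                        compressTo = 256, heads = 8, mlpMult = 4,
                        dropout = 0.1) {
  ns <- length(blocks)
  if (!(length(stageChannels) == ns && length(stageMid) == ns &&
        length(stageStride) == ns && length(stageDilation) == ns))
    stop("per-stage vectors must all have length ", ns)
  if (gridSize %% 2 != 1) stop("gridSize must be odd")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (compressTo %% heads != 0)
    stop("compressTo must be divisible by the head count")
  cfg <- list(inChannels = inChannels, gridSize = gridSize,
              stemChannels = stemChannels, stemKernel = stemKernel,
              stemStride = stemStride, stemPool = stemPool, blocks = blocks,
              stageChannels = stageChannels, stageMid = stageMid,
              stageStride = stageStride, stageDilation = stageDilation,
              compressFrom = stageChannels[ns], compressTo = compressTo,
              heads = heads, mlpMult = mlpMult, dropout = dropout)
  class(cfg) <- "ModelConfig"
  cfg
}

#' @describeIn modelConfig a width-reduced configuration (trunk ending at 64
#'   channels, compression to 16, 9-voxel grids) sized so training runs on a
#'   single CPU; first-class, not a test shim.
#' @export
reducedModelConfig <- function(gridSize = 9, inChannels = 22) {
  modelConfig(inChannels = inChannels, gridSize = gridSize,
              stemChannels = 16, stemKernel = 3, stemStride = 1,
              stemPool = FALSE, blocks = 1, stageChannels = 64,
              stageMid = 16, stageStride = 2, stageDilation = 1,
              compressTo = 16, heads = 2, mlpMult = 2, dropout = 0.1)
}

#' Training configuration
#'
#' Binary cross-entropy with Adam; the learning rate starts at 1e-4 and is
#' divided by 5 every 5 epochs (\code{lr(e) = initialLr / 5^floor(e/5)},
#' epochs 0-based); batch size 64.
#'
#' @param epochs training epochs.
#' @param initialLr initial learning rate (default 1e-4).
#' @param batchSize minibatch size (default 64).
#' @param valFraction fraction of the dataset held out for validation.
#' @param patience early-stopping patience in epochs (default Inf: off).
#' @param seed RNG seed governing shuffling, dropout and initialisation.
#' @return a \code{TrainConfig} list.
#' @export
trainConfig <- function(epochs = 10, initialLr = 1e-4, batchSize = 64,
                        valFraction = 0.2, patience = Inf, seed = 1) {
  if (initialLr <= 0) stop("initialLr must be positive")
  cfg <- list(epochs = epochs, initialLr = initialLr, batchSize = batchSize,
              valFraction = valFraction, patience = patience, seed = seed)
  class(cfg) <- "TrainConfig"
  cfg
}

#' Learning-rate schedule
#'
#' @param epoch 0-based epoch index (vectorised).
#' @param initialLr starting learning rate.
#' @return \code{initialLr / 5^floor(epoch / 5)}.
#' @export
lrSchedule <- function(epoch, initialLr = 1e-4) initialLr / 5^floor(epoch / 5)

#' Build the binding-score model
#'
#' Assembles stem, residual stages, compression, transformer block, pooling
#' and sigmoid head from a [modelConfig()]. The callable contract: a batch of
#' (gridSize^3 x inChannels) grids maps to scores in [0, 1]; the activation
#' right after the compression layer has exactly \code{compressTo} channels.
#'
#' @param cfg a \code{ModelConfig}.
#' @param seed RNG seed for weight initialisation.
#' @return a \code{BindingModel} list (layers + config).
#' @export
buildModel <- function(cfg = modelConfig(), seed = 1) {
  if (!inherits(cfg, "ModelConfig")) stop("cfg must come from modelConfig()")
  outDim <- function(inD, K, s, p, d) (inD + 2 * p - d * (K - 1) - 1) %/% s + 1
  withSeed(seed, {
    layers <- list()
    sdim <- cfg$gridSize
    pad <- (cfg$stemKernel - 1) %/% 2
    layers$stem <- layerConv(cfg$stemKernel, cfg$inChannels, cfg$stemChannels,
                             stride = cfg$stemStride, pad = pad)
    sdim <- outDim(sdim, cfg$stemKernel, cfg$stemStride, pad, 1)
    layers$stemBN <- layerBN(cfg$stemChannels)
    layers$stemReLU <- layerReLU()
    if (cfg$stemPool) {
      layers$stemPool <- layerMaxPool(3, 2, 1)
      sdim <- outDim(sdim, 3, 2, 1, 1)
    }
    Cprev <- cfg$stemChannels
    for (si in seq_along(cfg$blocks)) {
      for (bi in seq_len(cfg$blocks[si])) {
        st <- if (bi == 1) cfg$stageStride[si] else 1
        dl <- cfg$stageDilation[si]
        nm <- sprintf("stage%d_block%d", si, bi)
        layers[[nm]] <- layerBottleneck(Cprev, cfg$stageMid[si],
                                        cfg$stageChannels[si],
                                        stride = st, dilation = dl)
        if (bi == 1) sdim <- outDim(sdim, 3, st, dl, dl)
        Cprev <- cfg$stageChannels[si]
      }
    }
    layers$compress <- layerConv(1, Cprev, cfg$compressTo)
    layers$compressBN <- layerBN(cfg$compressTo)
    layers$compressReLU <- layerReLU()
    layers$transformer <- layerTransformer(sdim^3, cfg$compressTo, cfg$heads,
                                           cfg$mlpMult)
    layers$gap <- layerGAP()
    layers$dropout <- layerDropout(cfg$dropout)
    layers$fc <- layerFC(cfg$compressTo, 1)
    model <- list(layers = layers, cfg = cfg, tokenDim = sdim, seed = seed)
    class(model) <- "BindingModel"
    model
  })
}

#' @export
print.BindingModel <- function(x, ...) {
  np <- sum(unlist(rapply(x$layers, function(p) length(p), how = "unlist",
                          classes = c("numeric", "matrix", "array"))))
  cat(sprintf(paste0("BindingModel: %d-voxel grids x %d channels -> trunk %d",
                     " -> compress %d -> %d tokens -> sigmoid head\n"),
              x$cfg$gridSize, x$cfg$inChannels, x$cfg$compressFrom,
              x$cfg$compressTo, x$tokenDim^3))
  cat(sprintf("  ~%.2fM parameters, %d attention heads, dropout %.2f\n",
              np / 1e6, x$cfg$heads, x$cfg$dropout))
  invisible(x)
}

# Forward through the whole model. probes: named activations captured on the
# way ("compression" = post-compression ReLU). Returns logits.
modelForward <- function(model, x, training = FALSE, keepCache = FALSE,
                         probe = NULL) {
  layers <- model$layers
  caches <- if (keepCache) vector("list", length(layers)) else NULL
  probes <- list()
  h <- x
  for (i in seq_along(layers)) {
    r <- nnForward(layers[[i]], h, training = training)
    h <- r$out
    if (keepCache) caches[[i]] <- r$cache
    if (training) layers[[i]] <- r$layer
    nm <- names(model$layers)[i]
    if (!is.null(probe) && nm == "compressReLU" && "compression" %in% probe)
      probes$compression <- h
  }
  model$layers <- layers
  list(z = as.vector(h), model = model, caches = caches, probes = probes)
}

modelBackward <- function(model, caches, gz) {
  layers <- model$layers
  n <- length(layers)
  grads <- vector("list", n)
  names(grads) <- names(layers)
  g <- matrix(gz, ncol = 1)
  for (i in rev(seq_len(n))) {
    b <- nnBackward(layers[[i]], caches[[i]], g)
    g <- b$gin
    grads[i] <- list(if (!is.null(b$gpar)) list(gpar = b$gpar)
                     else if (!is.null(b$gsub)) list(gsub = b$gsub))
  }
  grads
}

#' Score feature grids
#'
#' Runs the model in evaluation mode (batch-norm running statistics, no
#' dropout). Batched evaluation agrees with one-by-one evaluation to 1e-6.
#'
#' @param model a \code{BindingModel}.
#' @param grids a [FeatureGridSet-class] or a (D,H,W,C,N) array.
#' @param batchSize evaluation batch size.
#' @return numeric vector of scores in [0, 1], one per grid, in input order.
#' @export
predictScores <- function(model, grids, batchSize = 32) {
  x <- if (methods::is(grids, "FeatureGridSet")) grids@grids else grids
  d <- dim(x)
  if (length(d) == 4) { dim(x) <- c(d, 1); d <- dim(x) }
  if (d[4] != model$cfg$inChannels)
    stop("channel mismatch: model expects ", model$cfg$inChannels,
         " channels, grids have ", d[4])
  if (d[1] != model$cfg$gridSize)
    stop("grid size mismatch: model expects ", model$cfg$gridSize,
         " voxels per axis, grids have ", d[1])
  n <- d[5]
  out <- numeric(n)
  for (s in seq(1, n, by = batchSize)) {
    e <- min(n, s + batchSize - 1)
    xb <- x[, , , , s:e, drop = FALSE]
    out[s:e] <- plogis(modelForward(model, xb)$z)
  }
  out
}

#' Probe the post-compression activation
#'
#' Runs one forward pass and returns the captured activation immediately
#' after the compression layer's ReLU; its 4th dimension is the compressed
#' channel width (256 for the full-size model).
#'
#' @param model a \code{BindingModel}.
#' @param x a (D,H,W,C,N) input array.
#' @return the activation array (Do,Ho,Wo,compressTo,N).
#' @export
probeCompression <- function(model, x) {
  modelForward(model, x, probe = "compression")$probes$compression
}

# ---- Adam ---------------------------------------------------------------

adamInit <- function(layers) {
  lapply(layers, function(l) {
    st <- list()
    if (!is.null(l$par)) st$par <- lapply(l$par, function(p)
      list(m = p * 0, v = p * 0))
    if (!is.null(l$sub)) st$sub <- adamInit(l$sub)
    st
  })
}

adamStep <- function(layers, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (!is.null(g$gpar)) {
      for (nm in names(g$gpar)) {
        st <- state[[i]]$par[[nm]]
        st$m <- beta1 * st$m + (1 - beta1) * g$gpar[[nm]]
        st$v <- beta2 * st$v + (1 - beta2) * g$gpar[[nm]]^2
        mh <- st$m / (1 - beta1^t)
        vh <- st$v / (1 - beta2^t)
        layers[[i]]$par[[nm]] <- layers[[i]]$par[[nm]] - lr * mh / (sqrt(vh) + eps)
        state[[i]]$par[[nm]] <- st
      }
    }
    if (!is.null(g$gsub)) {
      sub <- layers[[i]]$sub
      subGrads <- lapply(g$gsub, function(gg) list(gpar = gg))
      # align by name: gsub entries are named by sub-layer
      subGrads <- stats::setNames(subGrads, names(g$gsub))
      ordered <- lapply(names(sub), function(nm) subGrads[[nm]])
      r <- adamStep(sub, ordered, state[[i]]$sub, lr, t, beta1, beta2, eps)
      layers[[i]]$sub <- r$layers
      state[[i]]$sub <- r$state
    }
  }
  list(layers = layers, state = state)
}

bceFromLogits <- function(z, y) {
  sp <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  mean(sp - y * z)
}

#' Train the binding-score model
#'
#' Binary cross-entropy on the logits with Adam; learning rate follows
#' [lrSchedule()]. A validation split is held out, per-epoch training and
#' validation loss plus learning rate are recorded, and the weights from the
#' best validation epoch are restored into the returned model
#' (checkpointing). Deterministic given \code{cfg$seed}.
#'
#' @param model a \code{BindingModel} from [buildModel()].
#' @param grids a [FeatureGridSet-class] with both classes present.
#' @param cfg a \code{TrainConfig}.
#' @param manifestPath optional path: per-epoch loss/lr log written as
#'   tab-separated text.
#' @return list with elements \code{model} (best-validation weights) and
#'   \code{history} (data.frame epoch/lr/loss/valLoss).
#' @export
trainModel <- function(model, grids, cfg = trainConfig(), manifestPath = NULL) {
  if (!methods::is(grids, "FeatureGridSet")) stop("grids must be a FeatureGridSet")
  y <- grids@labels
  if (length(unique(y)) < 2)
    stop("training set contains a single class; binary cross-entropy is degenerate")
  x <- grids@grids
  n <- length(y)
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        loss = numeric(0), valLoss = numeric(0))
  withSeed(cfg$seed, {
    idx <- sample(n)
    nval <- max(1L, floor(cfg$valFraction * n))
    val <- idx[seq_len(nval)]
    tr <- idx[-seq_len(nval)]
    if (length(unique(y[tr])) < 2)
      stop("training split contains a single class")
    state <- adamInit(model$layers)
    t <- 0
    best <- list(loss = Inf, layers = model$layers)
    bad <- 0
    for (e in seq_len(cfg$epochs) - 1L) {
      lr <- lrSchedule(e, cfg$initialLr)
      ord <- sample(tr)
      epochLoss <- 0
      nb <- 0
      for (s in seq(1, length(ord), by = cfg$batchSize)) {
        bidx <- ord[s:min(length(ord), s + cfg$batchSize - 1)]
        xb <- x[, , , , bidx, drop = FALSE]
        yb <- y[bidx]
        fw <- modelForward(model, xb, training = TRUE, keepCache = TRUE)
        model <- fw$model
        z <- fw$z
        loss <- bceFromLogits(z, yb)
        gz <- (plogis(z) - yb) / length(yb)
        grads <- modelBackward(model, fw$caches, gz)
        t <- t + 1
        r <- adamStep(model$layers, grads, state, lr, t)
        model$layers <- r$layers
        state <- r$state
        epochLoss <- epochLoss + loss
        nb <- nb + 1
      }
      vz <- numeric(0)
      for (s in seq(1, length(val), by = cfg$batchSize)) {
        vidx <- val[s:min(length(val), s + cfg$batchSize - 1)]
        vz <- c(vz, modelForward(model, x[, , , , vidx, drop = FALSE])$z)
      }
      valLoss <- bceFromLogits(vz, y[val])
      history[nrow(history) + 1, ] <- list(e, lr, epochLoss / nb, valLoss)
      if (valLoss < best$loss) {
        best <- list(loss = valLoss, layers = model$layers)
        bad <- 0
      } else bad <- bad + 1
      if (bad > cfg$patience) break
    }
    model$layers <- best$layers
  })
  if (!is.null(manifestPath))
    utils::write.table(history, manifestPath, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  list(model = model, history = history)
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the weights, the full model and training configuration
#' and the initialisation seed, so a run can be reproduced exactly.
#'
#' @param model a \code{BindingModel}.
#' @param path checkpoint file path (RDS).
#' @param trainCfg optional \code{TrainConfig} stored alongside.
#' @return \code{saveCheckpoint}: the path, invisibly; \code{loadCheckpoint}:
#'   the \code{BindingModel} (with \code{trainConfig} attribute when stored).
#' @export
saveCheckpoint <- function(model, path, trainCfg = NULL) {
  saveRDS(list(model = model, trainCfg = trainCfg), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  m <- ck$model
  attr(m, "trainConfig") <- ck$trainCfg
  m
}
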