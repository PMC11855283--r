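# Layer primitives for the binding-score network: explicit forward/backward
# pairs (no autograd available in this stack). Activations are 5-D arrays
# (D, H, W, C, N) between convolutional layers and N x C matrices after
# global pooling. nnForward() returns list(out, cache, layer) -- the layer
# comes back because batch-norm running statistics update during training;
# nnBackward() returns list(gin, gpar) with gpar mirroring layer$par.

layerConv <- function(K, Cin, Cout, stride = 1, pad = 0, dilation = 1) {
  w <- array(stats::rnorm(K^3 * Cin * Cout, sd = sqrt(2 / (K^3 * Cin))),
             dim = c(K, K, K, Cin, Cout))
  list(type = "conv", par = list(w = w, b = numeric(Cout)),
       stride = stride, pad = pad, dilation = dilation)
}

layerBN <- function(C, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", par = list(gamma = rep(1, C), beta = numeric(C)),
       rm = numeric(C), rv = rep(1, C), momentum = momentum, eps = eps)
}

layerReLU <- function() list(type = "relu", par = NULL)
layerMaxPool <- function(K = 3, stride = 2, pad = 1)
  list(type = "maxpool", par = NULL, K = K, stride = stride, pad = pad)
layerGAP <- function() list(type = "gap", par = NULL)
layerDropout <- function(rate) list(type = "dropout", par = NULL, rate = rate)

layerFC <- function(Cin, Cout = 1) {
  list(type = "fc",
       par = list(w = matrix(stats::rnorm(Cin * Cout, sd = 1 / sqrt(Cin)), Cin, Cout),
                  b = numeric(Cout)))
}

layerBottleneck <- function(Cin, Cmid, Cout, stride = 1, dilation = 1) {
  sub <- list(
    conv1 = layerConv(1, Cin, Cmid),
    bn1 = layerBN(Cmid),
    conv2 = layerConv(3, Cmid, Cmid, stride = stride, pad = dilation,
                      dilation = dilation),
    bn2 = layerBN(Cmid),
    conv3 = layerConv(1, Cmid, Cout),
    bn3 = layerBN(Cout)
  )
  if (Cin != Cout || stride != 1) {
    sub$convP <- layerConv(1, Cin, Cout, stride = stride)
    sub$bnP <- layerBN(Cout)
  }
  list(type = "bottleneck", par = NULL, sub = sub)
}

layerTransformer <- function(Tlen, C, heads, mlpMult = 4) {
  if (C %% heads != 0) stop("channels must be divisible by head count")
  Hd <- C * mlpMult
  lin <- function(a, b, sd) matrix(stats::rnorm(a * b, sd = sd), a, b)
  list(type = "transformer", heads = heads, Tlen = Tlen, C = C,
       par = list(
         pos = matrix(stats::rnorm(Tlen * C, sd = 0.02), Tlen, C),
         Wq = lin(C, C, 1 / sqrt(C)), bq = numeric(C),
         Wk = lin(C, C, 1 / sqrt(C)), bk = numeric(C),
         Wv = lin(C, C, 1 / sqrt(C)), bv = numeric(C),
         Wo = lin(C, C, 1 / sqrt(C)), bo = numeric(C),
         ln1g = rep(1, C), ln1b = numeric(C),
         ln2g = rep(1, C), ln2b = numeric(C),
         W1 = lin(C, Hd, sqrt(2 / C)), b1 = numeric(Hd),
         W2 = lin(Hd, C, sqrt(2 / Hd)), b2 = numeric(C)
       ))
}

# ---- batch norm over (spatial x batch) per channel ---------------------

bnStats <- function(x3, S, N) {
  cs <- colSums(x3, dims = 1)            # C x N sums over spatial
  mu <- rowSums(cs) / (S * N)
  cs2 <- colSums(x3^2, dims = 1)
  v <- rowSums(cs2) / (S * N) - mu^2
  list(mu = mu, v = pmax(v, 0))
}

nnForward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      out <- conv3d_fw_cpp(x, dim(x), layer$par$w, dim(layer$par$w),
                           layer$par$b, layer$stride, layer$pad, layer$dilation)
      list(out = out, cache = list(x = x), layer = layer)
    },
    bn = {
      d <- dim(x)
      S <- prod(d[1:3]); C <- d[4]; N <- d[5]
      x3 <- x; dim(x3) <- c(S, C, N)
      if (training) {
        st <- bnStats(x3, S, N)
        layer$rm <- (1 - layer$momentum) * layer$rm + layer$momentum * st$mu
        layer$rv <- (1 - layer$momentum) * layer$rv + layer$momentum * st$v
        mu <- st$mu; v <- st$v
      } else {
        mu <- layer$rm; v <- layer$rv
      }
      sd <- sqrt(v + layer$eps)
      xhat <- (x3 - rep(mu, each = S)) / rep(sd, each = S)
      out <- xhat * rep(layer$par$gamma, each = S) + rep(layer$par$beta, each = S)
      dim(out) <- d
      list(out = out,
           cache = if (training) list(xhat = xhat, sd = sd, d = d) else NULL,
           layer = layer)
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask), layer = layer)
    },
    maxpool = {
      r <- maxpool3d_fw_cpp(x, dim(x), layer$K, layer$stride, layer$pad)
      list(out = r$out, cache = list(idx = r$idx, xd = dim(x), od = dim(r$out)),
           layer = layer)
    },
    bottleneck = forwardBottleneck(layer, x, training),
    transformer = forwardTransformer(layer, x, training),
    gap = {
      d <- dim(x)
      S <- prod(d[1:3])
      x3 <- x; dim(x3) <- c(S, d[4], d[5])
      out <- t(colSums(x3, dims = 1)) / S      # N x C
      list(out = out, cache = list(d = d), layer = layer)
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- (stats::runif(length(x)) >= layer$rate) / (1 - layer$rate)
        dim(mask) <- dim(x)
        list(out = x * mask, cache = list(mask = mask), layer = layer)
      } else list(out = x, cache = list(mask = NULL), layer = layer)
    },
    fc = {
      z <- sweep(x %*% layer$par$w, 2, layer$par$b, "+")
      list(out = z, cache = list(x = x), layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

nnBackward <- function(layer, cache, g) {
  switch(layer$type,
    conv = {
      r <- conv3d_bw_cpp(cache$x, dim(cache$x), layer$par$w, dim(layer$par$w),
                         g, layer$stride, layer$pad, layer$dilation)
      list(gin = r$gx, gpar = list(w = r$gw, b = r$gb))
    },
    bn = {
      d <- cache$d
      S <- prod(d[1:3]); C <- d[4]; N <- d[5]
      g3 <- g; dim(g3) <- c(S, C, N)
      gxhat <- g3 * rep(layer$par$gamma, each = S)
      m <- S * N
      sum1 <- rowSums(colSums(gxhat, dims = 1))              # per channel
      sum2 <- rowSums(colSums(gxhat * cache$xhat, dims = 1))
      gx <- (gxhat - rep(sum1 / m, each = S) -
               cache$xhat * rep(sum2 / m, each = S)) / rep(cache$sd, each = S)
      dim(gx) <- d
      list(gin = gx,
           gpar = list(gamma = rowSums(colSums(g3 * cache$xhat, dims = 1)),
                       beta = rowSums(colSums(g3, dims = 1))))
    },
    relu = list(gin = g * cache$mask, gpar = NULL),
    maxpool = list(gin = maxpool3d_bw_cpp(cache$idx, g, cache$xd, cache$od),
                   gpar = NULL),
    bottleneck = backwardBottleneck(layer, cache, g),
    transformer = backwardTransformer(layer, cache, g),
    gap = {
      d <- cache$d
      S <- prod(d[1:3])
      gx <- array(rep(as.vector(t(g)) / S, each = S), dim = c(S, d[4], d[5]))
      dim(gx) <- d
      list(gin = gx, gpar = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(gin = g, gpar = NULL)
      else list(gin = g * cache$mask, gpar = NULL)
    },
    fc = list(gin = g %*% t(layer$par$w),
              gpar = list(w = t(cache$x) %*% g, b = colSums(g))),
    stop("unknown layer type")
  )
}

forwardBottleneck <- function(layer, x, training) {
  s <- layer$sub
  caches <- list()
  f1 <- nnForward(s$conv1, x, training); caches$conv1 <- f1$cache; s$conv1 <- f1$layer
  f2 <- nnForward(s$bn1, f1$out, training); caches$bn1 <- f2$cache; s$bn1 <- f2$layer
  m1 <- f2$out > 0
  f3 <- nnForward(s$conv2, f2$out * m1, training); caches$conv2 <- f3$cache; s$conv2 <- f3$layer
  f4 <- nnForward(s$bn2, f3$out, training); caches$bn2 <- f4$cache; s$bn2 <- f4$layer
  m2 <- f4$out > 0
  f5 <- nnForward(s$conv3, f4$out * m2, training); caches$conv3 <- f5$cache; s$conv3 <- f5$layer
  f6 <- nnForward(s$bn3, f5$out, training); caches$bn3 <- f6$cache; s$bn3 <- f6$layer
  if (!is.null(s$convP)) {
    p1 <- nnForward(s$convP, x, training); caches$convP <- p1$cache; s$convP <- p1$layer
    p2 <- nnForward(s$bnP, p1$out, training); caches$bnP <- p2$cache; s$bnP <- p2$layer
    skip <- p2$out
  } else skip <- x
  total <- f6$out + skip
  m3 <- total > 0
  layer$sub <- s
  list(out = total * m3,
       cache = if (training) c(caches, list(m1 = m1, m2 = m2, m3 = m3)) else NULL,
       layer = layer)
}

backwardBottleneck <- function(layer, cache, g) {
  s <- layer$sub
  gsum <- g * cache$m3
  gpar <- list()
  b6 <- nnBackward(s$bn3, cache$bn3, gsum); gpar$bn3 <- b6$gpar
  b5 <- nnBackward(s$conv3, cache$conv3, b6$gin); gpar$conv3 <- b5$gpar
  gr2 <- b5$gin * cache$m2
  b4 <- nnBackward(s$bn2, cache$bn2, gr2); gpar$bn2 <- b4$gpar
  b3 <- nnBackward(s$conv2, cache$conv2, b4$gin); gpar$conv2 <- b3$gpar
  gr1 <- b3$gin * cache$m1
  b2 <- nnBackward(s$bn1, cache$bn1, gr1); gpar$bn1 <- b2$gpar
  b1 <- nnBackward(s$conv1, cache$conv1, b2$gin); gpar$conv1 <- b1$gpar
  gx <- b1$gin
  if (!is.null(s$convP)) {
    p2 <- nnBackward(s$bnP, cache$bnP, gsum); gpar$bnP <- p2$gpar
    p1 <- nnBackward(s$convP, cache$convP, p2$gin); gpar$convP <- p1$gpar
    gx <- gx + p1$gin
  } else gx <- gx + gsum
  list(gin = gx, gpar = NULL, gsub = gpar)
}

layerNormFw <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd
  list(out = sweep(xhat, 2, gamma, "*") + matrix(beta, nrow(X), length(beta), byrow = TRUE),
       xhat = xhat, sd = sd)
}

layerNormBw <- function(g, cache, gamma) {
  gxhat <- sweep(g, 2, gamma, "*")
  m1 <- rowMeans(gxhat)
  m2 <- rowMeans(gxhat * cache$xhat)
  gx <- (gxhat - m1 - cache$xhat * m2) / cache$sd
  list(gx = gx, ggamma = colSums(g * cache$xhat), gbeta = colSums(g))
}

forwardTransformer <- function(layer, x, training) {
  p <- layer$par
  d <- dim(x)
  Tl <- prod(d[1:3]); C <- d[4]; N <- d[5]
  if (Tl != layer$Tlen) stop("token count mismatch: model built for ",
                             layer$Tlen, " tokens, got ", Tl)
  heads <- layer$heads
  dh <- C / heads
  out <- x
  caches <- if (training) vector("list", N) else NULL
  for (n in seq_len(N)) {
    X <- matrix(x[, , , , n], Tl, C)
    X0 <- X + p$pos
    ln1 <- layerNormFw(X0, p$ln1g, p$ln1b)
    A <- ln1$out
    Q <- sweep(A %*% p$Wq, 2, p$bq, "+")
    K <- sweep(A %*% p$Wk, 2, p$bk, "+")
    V <- sweep(A %*% p$Wv, 2, p$bv, "+")
    O <- matrix(0, Tl, C)
    Plist <- if (training) vector("list", heads) else NULL
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
      S <- S - apply(S, 1, max)
      P <- exp(S)
      P <- P / rowSums(P)
      O[, cols] <- P %*% V[, cols, drop = FALSE]
      if (training) Plist[[h]] <- P
    }
    Attn <- sweep(O %*% p$Wo, 2, p$bo, "+")
    X1 <- X0 + Attn
    ln2 <- layerNormFw(X1, p$ln2g, p$ln2b)
    B <- ln2$out
    pre <- sweep(B %*% p$W1, 2, p$b1, "+")
    Mh <- pre * (pre > 0)
    M <- sweep(Mh %*% p$W2, 2, p$b2, "+")
    X2 <- X1 + M
    out[, , , , n] <- array(X2, dim = d[1:4])
    if (training)
      caches[[n]] <- list(ln1 = ln1, ln2 = ln2, A = A, Q = Q, K = K, V = V,
                          O = O, P = Plist, B = B, preMask = pre > 0, Mh = Mh)
  }
  list(out = out, cache = if (training) list(samples = caches, d = d) else NULL,
       layer = layer)
}

backwardTransformer <- function(layer, cache, g) {
  p <- layer$par
  d <- cache$d
  Tl <- prod(d[1:3]); C <- d[4]; N <- d[5]
  heads <- layer$heads
  dh <- C / heads
  gp <- lapply(seq_along(p), function(i) {
    z <- p[[i]]
    if (is.matrix(z)) matrix(0, nrow(z), ncol(z)) else numeric(length(z))
  })
  names(gp) <- names(p)
  gx <- g
  for (n in seq_len(N)) {
    cs <- cache$samples[[n]]
    g2 <- matrix(g[, , , , n], Tl, C)
    # MLP branch
    gM <- g2
    gMh <- (gM %*% t(p$W2)) * cs$preMask
    gp$W2 <- gp$W2 + t(cs$Mh) %*% gM
    gp$b2 <- gp$b2 + colSums(gM)
    gB <- gMh %*% t(p$W1)
    gp$W1 <- gp$W1 + t(cs$B) %*% gMh
    gp$b1 <- gp$b1 + colSums(gMh)
    l2 <- layerNormBw(gB, cs$ln2, p$ln2g)
    gp$ln2g <- gp$ln2g + l2$ggamma
    gp$ln2b <- gp$ln2b + l2$gbeta
    gX1 <- g2 + l2$gx
    # attention branch
    gAttn <- gX1
    gO <- gAttn %*% t(p$Wo)
    gp$Wo <- gp$Wo + t(cs$O) %*% gAttn
    gp$bo <- gp$bo + colSums(gAttn)
    gQ <- matrix(0, Tl, C); gK <- matrix(0, Tl, C); gV <- matrix(0, Tl, C)
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      P <- cs$P[[h]]
      gOh <- gO[, cols, drop = FALSE]
      gP <- tcrossprod(gOh, cs$V[, cols, drop = FALSE])
      gV[, cols] <- crossprod(P, gOh)
      gS <- P * (gP - rowSums(gP * P))
      gQ[, cols] <- gS %*% cs$K[, cols, drop = FALSE] / sqrt(dh)
      gK[, cols] <- crossprod(gS, cs$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    gA <- gQ %*% t(p$Wq) + gK %*% t(p$Wk) + gV %*% t(p$Wv)
    gp$Wq <- gp$Wq + t(cs$A) %*% gQ; gp$bq <- gp$bq + colSums(gQ)
    gp$Wk <- gp$Wk + t(cs$A) %*% gK; gp$bk <- gp$bk + colSums(gK)
    gp$Wv <- gp$Wv + t(cs$A) %*% gV; gp$bv <- gp$bv + colSums(gV)
    l1 <- layerNormBw(gA, cs$ln1, p$ln1g)
    gp$ln1g <- gp$ln1g + l1$ggamma
    gp$ln1b <- gp$ln1b + l1$gbeta
    gX0 <- gX1 + l1$gx
    gp$pos <- gp$pos + gX0
    gx[, , , , n] <- array(gX0, dim = d[1:4])
  }
  list(gin = gx, gpar = gp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
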