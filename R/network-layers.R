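#' @include AllClasses.R utils.R
NULL

# ---------------------------------------------------------------------------
# Low-level layers for the windowed inverse network.
#
# Activation layout convention: a temporal feature map with n instances
# (instance = one sensor of one example), T time points and C channels is a
# (n*T) x C matrix whose row r = i + (t-1)*n holds instance i at time t.
# With instances ordered example-fastest (i = b + (s-1)*B) the initial map is
# simply matrix(as.vector(windows), ncol = 1), and the temporal collapse to
# T = 1 leaves a (B*S) x C matrix that reshapes to the flattened B x (S*C)
# input of the fully-connected block without any permutation.
# ---------------------------------------------------------------------------

.convRowSel <- function(n, Tout, j) {
  # rows of the input map feeding kernel tap j for every output time
  rep.int((seq_len(Tout) + j - 2L) * n, rep.int(n, Tout)) + seq_len(n)
}

.im2col <- function(A, n, Tin, k) {
  Tout <- Tin - k + 1L
  cin <- ncol(A)
  out <- matrix(0, n * Tout, k * cin)
  for (j in seq_len(k))
    out[, (j - 1L) * cin + seq_len(cin)] <- A[.convRowSel(n, Tout, j), , drop = FALSE]
  out
}

.convForward <- function(A, layer, n, Tin) {
  Xc <- .im2col(A, n, Tin, layer$k)
  Y <- sweep(Xc %*% layer$W, 2, layer$b, "+")
  list(Y = Y, Xc = Xc, Tout = Tin - layer$k + 1L)
}

.convBackward <- function(dY, cache, layer, n, Tin) {
  dW <- crossprod(cache$Xc, dY)
  db <- colSums(dY)
  dXc <- tcrossprod(dY, layer$W)
  cin <- nrow(layer$W) %/% layer$k
  dA <- matrix(0, n * Tin, cin)
  for (j in seq_len(layer$k)) {
    sel <- .convRowSel(n, cache$Tout, j)
    dA[sel, ] <- dA[sel, , drop = FALSE] +
      dXc[, (j - 1L) * cin + seq_len(cin), drop = FALSE]
  }
  list(dA = dA, dW = dW, db = db)
}

.bnForward <- function(X, bn, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu, "-")
    v <- colMeans(xc^2)
    invstd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, invstd, "*")
    bn$runMean <- (1 - momentum) * bn$runMean + momentum * mu
    bn$runVar <- (1 - momentum) * bn$runVar + momentum * v
    list(Y = sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+"),
         xhat = xhat, invstd = invstd, bn = bn)
  } else {
    invstd <- 1 / sqrt(bn$runVar + eps)
    xhat <- sweep(sweep(X, 2, bn$runMean, "-"), 2, invstd, "*")
    list(Y = sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+"),
         xhat = xhat, invstd = invstd, bn = bn)
  }
}

.bnBackward <- function(dY, cache, bn) {
  m <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, bn$gamma, "*")
  t1 <- sweep(dxhat, 2, colSums(dxhat) / m, "-")
  t2 <- sweep(cache$xhat, 2, colSums(dxhat * cache$xhat) / m, "*")
  dX <- sweep(t1 - t2, 2, cache$invstd, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

.reluForward <- function(X) {
  mask <- X > 0
  list(Y = X * mask, mask = mask)
}

.fcForward <- function(X, layer) sweep(X %*% layer$W, 2, layer$b, "+")

.fcBackward <- function(dY, X, layer) {
  list(dX = tcrossprod(dY, layer$W), dW = crossprod(X, dY), db = colSums(dY))
}

# He-normal initialization of all parameters; deterministic given the RNG
.initParams <- function(config) {
  nconv <- length(config@convKernels)
  conv <- vector("list", nconv)
  cin <- 1L
  for (l in seq_len(nconv)) {
    k <- config@convKernels[l]; cout <- config@convFeatures[l]
    conv[[l]] <- list(
      W = matrix(stats::rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))),
                 k * cin, cout),
      b = numeric(cout), k = k)
    cin <- cout
  }
  bn <- vector("list", max(nconv - 1L, 0L))
  for (l in seq_along(bn)) {
    c <- config@convFeatures[l]
    bn[[l]] <- list(gamma = rep(1, c), beta = numeric(c),
                    runMean = numeric(c), runVar = rep(1, c))
  }
  fcIn <- config@nSensors * config@convFeatures[nconv]
  widths <- c(fcIn, rep(config@fcWidth, config@fcLayers), config@nSources)
  fc <- vector("list", length(widths) - 1L)
  for (l in seq_along(fc)) {
    fc[[l]] <- list(
      W = matrix(stats::rnorm(widths[l] * widths[l + 1L],
                              sd = sqrt(2 / widths[l])),
                 widths[l], widths[l + 1L]),
      b = numeric(widths[l + 1L]))
  }
  list(conv = conv, bn = bn, fc = fc)
}

# full forward pass; X is the B x S x W window array (or one S x W matrix)
.netForward <- function(params, config, X, train = FALSE) {
  if (length(dim(X)) == 2L) X <- array(X, c(1L, dim(X)))
  B <- dim(X)[1]
  n <- B * config@nSensors
  A <- matrix(as.vector(X), ncol = 1L)  # (n*W) x 1, example-fastest rows
  Tcur <- config@W
  nconv <- length(params$conv)
  cache <- list(conv = vector("list", nconv), bn = vector("list", nconv),
                relu = vector("list", nconv), fc = list(), B = B, n = n)
  for (l in seq_len(nconv)) {
    cv <- .convForward(A, params$conv[[l]], n, Tcur)
    cache$conv[[l]] <- list(Xc = cv$Xc, Tin = Tcur, Tout = cv$Tout)
    A <- cv$Y
    Tcur <- cv$Tout
    if (l < nconv) {
      bnf <- .bnForward(A, params$bn[[l]], train)
      cache$bn[[l]] <- bnf
      if (train) params$bn[[l]] <- bnf$bn  # running stats updated
      A <- bnf$Y
    }
    rl <- .reluForward(A)
    cache$relu[[l]] <- rl$mask
    A <- rl$Y
  }
  # temporal extent is now 1: A is (B*S) x C_last == flattened B x (S*C_last)
  F <- A
  dim(F) <- c(B, config@nSensors * config@convFeatures[nconv])
  cache$fcIn <- list()
  nf <- length(params$fc)
  for (l in seq_len(nf)) {
    cache$fcIn[[l]] <- F
    F <- .fcForward(F, params$fc[[l]])
    if (l < nf) {
      rl <- .reluForward(F)
      cache$fc[[l]] <- rl$mask
      F <- rl$Y
    }
  }
  list(pred = F, cache = cache, params = params)
}

# backward pass from dPred; returns gradients in the params structure
.netBackward <- function(params, config, dPred, cache) {
  grads <- list(conv = vector("list", length(params$conv)),
                bn = vector("list", length(params$bn)),
                fc = vector("list", length(params$fc)))
  G <- dPred
  nf <- length(params$fc)
  for (l in rev(seq_len(nf))) {
    if (l < nf) G <- G * cache$fc[[l]]
    bk <- .fcBackward(G, cache$fcIn[[l]], params$fc[[l]])
    grads$fc[[l]] <- list(W = bk$dW, b = bk$db)
    G <- bk$dX
  }
  nconv <- length(params$conv)
  dim(G) <- c(cache$n, config@convFeatures[nconv])
  for (l in rev(seq_len(nconv))) {
    G <- G * cache$relu[[l]]
    if (l < nconv) {
      bb <- .bnBackward(G, cache$bn[[l]], params$bn[[l]])
      grads$bn[[l]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
      G <- bb$dX
    }
    cb <- .convBackward(G, cache$conv[[l]], params$conv[[l]],
                        cache$n, cache$conv[[l]]$Tin)
    grads$conv[[l]] <- list(W = cb$dW, b = cb$db)
    G <- cb$dA
  }
  grads
}

# Adam state mirrors the trainable leaves of params
.adamInit <- function(params) {
  st <- list(t = 0)
  st$conv <- lapply(params$conv, function(l) list(W = l$W * 0, b = l$b * 0))
  st$bn <- lapply(params$bn, function(l) list(gamma = l$gamma * 0, beta = l$beta * 0))
  st$fc <- lapply(params$fc, function(l) list(W = l$W * 0, b = l$b * 0))
  list(m = st, v = st)
}

.adamStep <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$m$t <- state$m$t + 1
  t <- state$m$t
  corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (l in seq_along(params$conv)) for (f in c("W", "b")) {
    u <- upd(params$conv[[l]][[f]], grads$conv[[l]][[f]],
             state$m$conv[[l]][[f]], state$v$conv[[l]][[f]])
    params$conv[[l]][[f]] <- u$p
    state$m$conv[[l]][[f]] <- u$m; state$v$conv[[l]][[f]] <- u$v
  }
  for (l in seq_along(params$bn)) for (f in c("gamma", "beta")) {
    u <- upd(params$bn[[l]][[f]], grads$bn[[l]][[f]],
             state$m$bn[[l]][[f]], state$v$bn[[l]][[f]])
    params$bn[[l]][[f]] <- u$p
    state$m$bn[[l]][[f]] <- u$m; state$v$bn[[l]][[f]] <- u$v
  }
  for (l in seq_along(params$fc)) for (f in c("W", "b")) {
    u <- upd(params$fc[[l]][[f]], grads$fc[[l]][[f]],
             state$m$fc[[l]][[f]], state$v$fc[[l]][[f]])
    params$fc[[l]][[f]] <- u$p
    state$m$fc[[l]][[f]] <- u$m; state$v$fc[[l]][[f]] <- u$v
  }
  list(params = params, state = state)
}
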