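# Minimal neural-network engine: dense and 1-D convolutional layers with
# explicit backpropagation, adaptive average pooling, L2 row normalization
# and an AdamW optimizer. Parameters are nested lists with numeric arrays at
# the leaves; gradients mirror the structure. Everything is vectorised
# base-R matrix algebra; all internal.

## ---- parameter trees ----------------------------------------------------

nn_leaves <- function(x) {
  if (is.list(x)) unlist(lapply(x, nn_leaves), recursive = FALSE) else list(x)
}

nn_set_leaves <- function(x, leaves, counter = new.env()) {
  if (is.null(counter$i)) counter$i <- 0L
  if (is.list(x)) {
    for (k in seq_along(x)) x[[k]] <- nn_set_leaves(x[[k]], leaves, counter)
    x
  } else {
    counter$i <- counter$i + 1L
    leaves[[counter$i]]
  }
}

nn_zeros_like <- function(x) {
  if (is.list(x)) lapply(x, nn_zeros_like) else array(0, dim = dim(x) %||% length(x))
}

# elementwise a + b over two identically shaped trees
nn_add <- function(a, b) {
  if (is.list(a)) mapply(nn_add, a, b, SIMPLIFY = FALSE) else a + b
}

## ---- AdamW --------------------------------------------------------------

nn_adamw_init <- function(params) {
  list(m = nn_zeros_like(params), v = nn_zeros_like(params), t = 0L)
}

# Decoupled weight decay (AdamW): p <- p - lr * (mhat/(sqrt(vhat)+eps) + wd*p)
nn_adamw_step <- function(params, grads, state, lr, beta1 = 0.9,
                          beta2 = 0.999, eps = 1e-8, weightDecay = 0) {
  state$t <- state$t + 1L
  pl <- nn_leaves(params); gl <- nn_leaves(grads)
  ml <- nn_leaves(state$m); vl <- nn_leaves(state$v)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (i in seq_along(pl)) {
    ml[[i]] <- beta1 * ml[[i]] + (1 - beta1) * gl[[i]]
    vl[[i]] <- beta2 * vl[[i]] + (1 - beta2) * gl[[i]]^2
    step <- (ml[[i]] / c1) / (sqrt(vl[[i]] / c2) + eps) + weightDecay * pl[[i]]
    pl[[i]] <- pl[[i]] - lr * step
  }
  list(params = nn_set_leaves(params, pl),
       state = list(m = nn_set_leaves(state$m, ml),
                    v = nn_set_leaves(state$v, vl), t = state$t))
}

## ---- dense / MLP --------------------------------------------------------

nn_dense_init <- function(nin, nout, zero = FALSE) {
  W <- if (zero) matrix(0, nin, nout) else {
    matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  }
  list(W = W, b = matrix(0, 1, nout))
}

# dims: c(in, h1, ..., out); ReLU between layers, last layer linear.
nn_mlp_init <- function(dims, zeroLast = FALSE) {
  k <- length(dims) - 1L
  lapply(seq_len(k), function(l) {
    nn_dense_init(dims[l], dims[l + 1L], zero = zeroLast && l == k)
  })
}

nn_mlp_fwd <- function(X, layers) {
  k <- length(layers)
  inputs <- vector("list", k)
  masks <- vector("list", k)
  H <- X
  for (l in seq_len(k)) {
    inputs[[l]] <- H
    S <- H %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(H), ncol(layers[[l]]$b), byrow = TRUE)
    if (l < k) {
      masks[[l]] <- S > 0
      H <- S * masks[[l]]
    } else {
      H <- S
    }
  }
  list(out = H, inputs = inputs, masks = masks)
}

nn_mlp_bwd <- function(dY, layers, cache) {
  k <- length(layers)
  grads <- vector("list", k)
  dS <- dY
  for (l in rev(seq_len(k))) {
    X <- cache$inputs[[l]]
    grads[[l]] <- list(W = crossprod(X, dS), b = matrix(colSums(dS), 1))
    dX <- dS %*% t(layers[[l]]$W)
    if (l > 1L) dS <- dX * cache$masks[[l - 1L]]
  }
  list(dX = dX, grads = grads)
}

## ---- L2 row normalization ----------------------------------------------

nn_l2norm_fwd <- function(H) {
  nr <- sqrt(rowSums(H^2) + 1e-12)
  list(out = H / nr, norms = nr)
}

nn_l2norm_bwd <- function(dZ, Z, norms) {
  (dZ - Z * rowSums(dZ * Z)) / norms
}

## ---- 1-D convolution (kernel 3, stride 1, same padding) -----------------

nn_conv_init <- function(cin, cout, k = 3L) {
  list(W = array(rnorm(cout * cin * k, sd = sqrt(2 / (cin * k))),
                 dim = c(cout, cin, k)),
       b = numeric(cout))
}

# Convolution is evaluated as one BLAS matrix product over an im2col
# expansion: B is (n*p) x (cin*k) with one column per (channel, offset)
# pair, and the kernel is reshaped to (cin*k) x cout.

nn_conv_fwd <- function(A, layer) {
  n <- dim(A)[1]; p <- dim(A)[3]
  cout <- dim(layer$W)[1]; cin <- dim(layer$W)[2]; k <- dim(layer$W)[3]
  B <- matrix(0, n * p, cin * k)
  for (ci in seq_len(cin)) {
    M <- matrix(0, n, p + 2L)
    M[, 2:(p + 1L)] <- matrix(A[, ci, ], n, p)
    for (kk in seq_len(k)) {
      B[, (ci - 1L) * k + kk] <- M[, kk:(kk + p - 1L)]
    }
  }
  Wmat <- matrix(aperm(layer$W, c(3, 2, 1)), cin * k, cout)
  O <- B %*% Wmat
  for (co in seq_len(cout)) O[, co] <- O[, co] + layer$b[co]
  out <- aperm(array(O, dim = c(n, p, cout)), c(1, 3, 2))
  list(out = out, B = B)
}

nn_conv_bwd <- function(dOut, layer, B) {
  n <- dim(dOut)[1]; p <- dim(dOut)[3]
  cout <- dim(layer$W)[1]; cin <- dim(layer$W)[2]; k <- dim(layer$W)[3]
  D <- matrix(aperm(dOut, c(1, 3, 2)), n * p, cout)
  G <- crossprod(B, D)                                   # (cin*k) x cout
  dW <- aperm(array(G, dim = c(k, cin, cout)), c(3, 2, 1))
  db <- colSums(D)
  dB <- tcrossprod(D, matrix(aperm(layer$W, c(3, 2, 1)), cin * k, cout))
  dA <- array(0, dim = c(n, cin, p))
  for (ci in seq_len(cin)) {
    M <- matrix(0, n, p + 2L)
    for (kk in seq_len(k)) {
      M[, kk:(kk + p - 1L)] <- M[, kk:(kk + p - 1L)] +
        matrix(dB[, (ci - 1L) * k + kk], n, p)
    }
    dA[, ci, ] <- M[, 2:(p + 1L)]
  }
  list(dA = dA, grads = list(W = dW, b = db))
}

## ---- batch normalization (per channel over batch x position) ------------

nn_bn_init <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels))
}

# A: n x C x p. In training mode statistics are computed from the batch
# (and returned for later calibration); in eval mode `stats` supplies the
# frozen channel means/vars.
nn_bn_fwd <- function(A, bn, stats = NULL) {
  n <- dim(A)[1]; cc <- dim(A)[2]; p <- dim(A)[3]
  out <- array(0, dim = dim(A))
  xhat <- array(0, dim = dim(A))
  mu <- numeric(cc); v <- numeric(cc)
  for (ci in seq_len(cc)) {
    M <- matrix(A[, ci, ], n, p)
    if (is.null(stats)) {
      mu[ci] <- mean(M)
      v[ci] <- mean((M - mu[ci])^2)
    } else {
      mu[ci] <- stats$mean[ci]
      v[ci] <- stats$var[ci]
    }
    xh <- (M - mu[ci]) / sqrt(v[ci] + 1e-5)
    xhat[, ci, ] <- xh
    out[, ci, ] <- bn$gamma[ci] * xh + bn$beta[ci]
  }
  list(out = out, xhat = xhat, var = v,
       stats = list(mean = mu, var = v), training = is.null(stats))
}

nn_bn_bwd <- function(dOut, bn, cache) {
  n <- dim(dOut)[1]; cc <- dim(dOut)[2]; p <- dim(dOut)[3]
  m <- n * p
  dA <- array(0, dim = dim(dOut))
  dgamma <- numeric(cc); dbeta <- numeric(cc)
  for (ci in seq_len(cc)) {
    dY <- matrix(dOut[, ci, ], n, p)
    xh <- matrix(cache$xhat[, ci, ], n, p)
    dgamma[ci] <- sum(dY * xh)
    dbeta[ci] <- sum(dY)
    istd <- 1 / sqrt(cache$var[ci] + 1e-5)
    if (cache$training) {
      dA[, ci, ] <- (bn$gamma[ci] * istd / m) *
        (m * dY - sum(dY) - xh * sum(dY * xh))
    } else {
      dA[, ci, ] <- bn$gamma[ci] * istd * dY
    }
  }
  list(dA = dA, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- adaptive average pooling -------------------------------------------

pool_bins <- function(p, L) {
  lapply(seq_len(L), function(i) {
    (floor((i - 1) * p / L) + 1L):ceiling(i * p / L)
  })
}

nn_pool_fwd <- function(A, L) {
  n <- dim(A)[1]; cc <- dim(A)[2]; p <- dim(A)[3]
  bins <- pool_bins(p, L)
  out <- array(0, dim = c(n, cc, L))
  for (ci in seq_len(cc)) {
    M <- matrix(A[, ci, ], n, p)
    for (i in seq_len(L)) {
      out[, ci, i] <- rowMeans(M[, bins[[i]], drop = FALSE])
    }
  }
  list(out = out, bins = bins, p = p)
}

nn_pool_bwd <- function(dOut, cache) {
  n <- dim(dOut)[1]; cc <- dim(dOut)[2]; L <- dim(dOut)[3]
  dA <- array(0, dim = c(n, cc, cache$p))
  for (ci in seq_len(cc)) {
    for (i in seq_len(L)) {
      b <- cache$bins[[i]]
      dA[, ci, b] <- dA[, ci, b] + matrix(dOut[, ci, i], n, length(b)) / length(b)
    }
  }
  dA
}

## ---- residual block: relu(bn2(conv2(relu(bn1(conv1(x))))) + x) -----------

nn_resblock_init <- function(channels) {
  list(c1 = nn_conv_init(channels, channels), b1 = nn_bn_init(channels),
       c2 = nn_conv_init(channels, channels), b2 = nn_bn_init(channels))
}

nn_resblock_fwd <- function(A, blk, stats = NULL) {
  f1 <- nn_conv_fwd(A, blk$c1)
  n1 <- nn_bn_fwd(f1$out, blk$b1, stats$b1)
  m1 <- n1$out > 0
  h1 <- n1$out * m1
  f2 <- nn_conv_fwd(h1, blk$c2)
  n2 <- nn_bn_fwd(f2$out, blk$b2, stats$b2)
  s <- n2$out + A
  m2 <- s > 0
  list(out = s * m2,
       stats = list(b1 = n1$stats, b2 = n2$stats),
       cache = list(f1 = f1, n1 = n1, m1 = m1, f2 = f2, n2 = n2, m2 = m2))
}

nn_resblock_bwd <- function(dOut, blk, cache) {
  dS <- dOut * cache$m2
  bn2 <- nn_bn_bwd(dS, blk$b2, cache$n2)
  b2 <- nn_conv_bwd(bn2$dA, blk$c2, cache$f2$B)
  dH1 <- b2$dA * cache$m1
  bn1 <- nn_bn_bwd(dH1, blk$b1, cache$n1)
  b1 <- nn_conv_bwd(bn1$dA, blk$c1, cache$f1$B)
  list(dA = b1$dA + dS,
       grads = list(c1 = b1$grads, b1 = bn1$grads,
                    c2 = b2$grads, b2 = bn2$grads))
}
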