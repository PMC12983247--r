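# The dual-branch MeNet architecture. The fixed-effect branch (VE) is a
# one-dimensional residual convolutional network over the marker sequence:
# conv (kernel 3, stride 1, same padding) -> two residual blocks ->
# adaptive average pooling -> fully connected layers -> embedding. The
# random-effect branch is the RepGeno encoder. Branch embeddings interact
# through cross-information feature fusion,
#   zhat_m = z_m + F_m([z_1; ...; z_k; z_RepGeno]),
# where each correction network F_m is a three-layer bottleneck MLP, and the
# corrected embeddings are concatenated into a three-layer prediction head.

#' MeNetModel: trained dual-branch genomic prediction model
#'
#' Produced by [trainMeNet()]; apply with `predict(model, genotypes)`,
#' inspect branch contributions with [attributeContributions()].
#'
#' @slot repgeno the frozen [RepGenoEncoder-class] (random-effect branch).
#' @slot params list with elements `ve` (per-segment VE branch parameters),
#'   `fusion` (per-branch correction networks) and `head`.
#' @slot config architecture configuration, including the marker segments
#'   and the fused-embedding index sets for each branch.
#' @slot history per-epoch training log (train MAE, validation R2, lr).
#' @slot meta trait standardisation, seeds, transfer provenance.
#' @include repgeno.R
#' @exportClass MeNetModel
setClass("MeNetModel", representation(
  repgeno = "RepGenoEncoder", params = "list", config = "list",
  history = "data.frame", meta = "list"
))

setMethod("show", "MeNetModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "MeNetModel: %d markers in %d segment(s); VE %d channel(s), embed %d\n",
    cfg$nMarkers, length(cfg$segments), cfg$veChannels, cfg$embedDim))
  if (nrow(object@history)) {
    best <- which.max(object@history$valR2)
    cat(sprintf("best checkpoint: epoch %d, validation R2 %.3f\n",
                object@history$epoch[best], object@history$valR2[best]))
  }
  if (!is.null(object@meta$transfer)) {
    cat("fine-tuned by transfer learning (F_VE + head only)\n")
  }
  invisible(NULL)
})

#' Partition markers into VE segments
#'
#' With `p <= threshold` markers, a single segment is used. Above the
#' threshold, markers are split by chromosome (one VE instance each); any
#' chromosome still exceeding the threshold is cut into consecutive
#' fixed-size windows. Segments are disjoint and cover all markers.
#'
#' @param genotypes a [GenotypeData].
#' @param threshold maximum markers per VE instance (default 100000).
#' @return named list of integer marker-index vectors.
#' @export
chromosomePartition <- function(genotypes, threshold = 100000L) {
  stopifnot(is(genotypes, "GenotypeData"), threshold >= 1)
  info <- markerInfo(genotypes)
  p <- nrow(info)
  if (p <= threshold) return(list(seg1 = seq_len(p)))
  segs <- list()
  for (chr in unique(info$chrom)) {
    idx <- which(info$chrom == chr)
    if (length(idx) <= threshold) {
      segs[[chr]] <- idx
    } else {
      nw <- ceiling(length(idx) / threshold)
      for (w in seq_len(nw)) {
        lo <- (w - 1L) * threshold + 1L
        segs[[paste0(chr, "_w", w)]] <- idx[lo:min(w * threshold, length(idx))]
      }
    }
  }
  segs
}

# ---- VE branch -----------------------------------------------------------

#' Initialise one VE branch
#'
#' @param veChannels convolution channels (published search grid \{1, 2, 4, 8, 16, 64\};
#'   desk-scale default 4).
#' @param embedDim embedding dimension.
#' @param poolLen adaptive-average-pooling output length.
#' @param hidden width of the hidden fully connected layer.
#' @param normalize L2-normalize the embedding rows (default `TRUE`), so the
#'   VE embedding enters fusion on the same unit scale as the normalized
#'   RepGeno embedding.
#' @param seed integer seed.
#' @return parameter list for [veForward()].
#' @export
initVEBranch <- function(veChannels = 4L, embedDim = 64L, poolLen = 8L,
                         hidden = 32L, normalize = TRUE, seed = NULL) {
  with_seed(seed, {
    structure(
      list(conv0 = nn_conv_init(1L, veChannels),
           bn0 = nn_bn_init(veChannels),
           rb1 = nn_resblock_init(veChannels),
           rb2 = nn_resblock_init(veChannels),
           fc = nn_mlp_init(c(veChannels * poolLen, hidden, embedDim))),
      cfg = list(channels = veChannels, poolLen = poolLen,
                 embedDim = embedDim, normalize = normalize)
    )
  })
}

# Forward through one VE branch. `stats` carries frozen batch-norm channel
# statistics (eval mode); NULL computes them from the batch (training mode)
# and reports the observed values in the cache for calibration.
ve_fwd <- function(X, ve, stats = NULL) {
  cfg <- attr(ve, "cfg")
  n <- nrow(X); p <- ncol(X)
  L <- cfg$poolLen
  if (p < L) {
    warnf("segment of %d markers narrower than pooling length %d; zero-padding",
          p, L)
    X <- cbind(X, matrix(0, n, L - p)); p <- L
  }
  A0 <- array(0, dim = c(n, 1L, p)); A0[, 1L, ] <- X
  f0 <- nn_conv_fwd(A0, ve$conv0)
  n0 <- nn_bn_fwd(f0$out, ve$bn0, stats$bn0)
  m0 <- n0$out > 0
  r1 <- nn_resblock_fwd(n0$out * m0, ve$rb1, stats$rb1)
  r2 <- nn_resblock_fwd(r1$out, ve$rb2, stats$rb2)
  pl <- nn_pool_fwd(r2$out, L)
  flat <- matrix(pl$out, n, cfg$channels * L)
  fc <- nn_mlp_fwd(flat, ve$fc)
  cache <- list(f0 = f0, n0 = n0, m0 = m0, r1 = r1, r2 = r2, pl = pl,
                fc = fc)
  obs <- list(bn0 = n0$stats, rb1 = r1$stats, rb2 = r2$stats)
  if (isTRUE(cfg$normalize)) {
    nz <- nn_l2norm_fwd(fc$out)
    cache$nz <- nz
    list(out = nz$out, cache = cache, stats = obs)
  } else {
    list(out = fc$out, cache = cache, stats = obs)
  }
}

ve_bwd <- function(dZ, ve, cache) {
  cfg <- attr(ve, "cfg")
  n <- nrow(dZ)
  if (isTRUE(cfg$normalize)) {
    dZ <- nn_l2norm_bwd(dZ, cache$nz$out, cache$nz$norms)
  }
  bfc <- nn_mlp_bwd(dZ, ve$fc, cache$fc)
  dPool <- array(bfc$dX, dim = c(n, cfg$channels, cfg$poolLen))
  dR2 <- nn_pool_bwd(dPool, cache$pl)
  b2 <- nn_resblock_bwd(dR2, ve$rb2, cache$r2$cache)
  b1 <- nn_resblock_bwd(b2$dA, ve$rb1, cache$r1$cache)
  dC0 <- b1$dA * cache$m0
  bn0 <- nn_bn_bwd(dC0, ve$bn0, cache$n0)
  b0 <- nn_conv_bwd(bn0$dA, ve$conv0, cache$f0$B)
  list(grads = list(conv0 = b0$grads, bn0 = bn0$grads, rb1 = b1$grads,
                    rb2 = b2$grads, fc = bfc$grads))
}

#' Forward pass of the VE branch
#'
#' Maps a samples-x-markers code matrix to per-sample embeddings. Output
#' dimension is `embedDim` regardless of the marker count (adaptive
#' pooling); a segment narrower than the pooling length is zero-padded with
#' a warning.
#'
#' @param X samples-x-markers matrix (or [GenotypeData]).
#' @param ve parameters from [initVEBranch()].
#' @param stats frozen batch-normalization channel statistics (as stored in
#'   a trained model's `meta$veStats`); `NULL` uses the batch's own.
#' @return n x embedDim embedding matrix.
#' @export
veForward <- function(X, ve, stats = NULL) {
  if (is(X, "GenotypeData")) X <- genoMatrix(X)
  ve_fwd(as.matrix(X), ve, stats)$out
}

# ---- fusion --------------------------------------------------------------

#' Initialise a correction network
#'
#' Three fully connected layers with a bottleneck
#' (`inDim -> max(4, embedDim/2) -> max(4, embedDim/2) -> embedDim`). The
#' output layer is zero-initialised, so the fusion starts at the residual
#' identity `zhat = z`.
#'
#' @param inDim input width (total fused embedding width).
#' @param embedDim output (branch embedding) width.
#' @param seed integer seed.
#' @return MLP parameter list.
#' @export
initCorrectionNet <- function(inDim, embedDim, seed = NULL) {
  b <- max(4L, as.integer(embedDim / 2))
  with_seed(seed, nn_mlp_init(c(inDim, b, b, embedDim), zeroLast = TRUE))
}

fusion_fwd <- function(zs, fusion) {
  zAll <- do.call(cbind, zs)
  caches <- list(); hats <- list()
  for (m in names(zs)) {
    f <- nn_mlp_fwd(zAll, fusion[[m]])
    hats[[m]] <- zs[[m]] + f$out
    caches[[m]] <- f
  }
  list(hats = hats, zAll = zAll, caches = caches)
}

fusion_bwd <- function(dHats, zs, fusion, fw) {
  dims <- vapply(zs, ncol, 1L)
  ends <- cumsum(dims); starts <- ends - dims + 1L
  dZAll <- matrix(0, nrow(fw$zAll), ncol(fw$zAll))
  grads <- list()
  for (m in names(zs)) {
    b <- nn_mlp_bwd(dHats[[m]], fusion[[m]], fw$caches[[m]])
    grads[[m]] <- b$grads
    dZAll <- dZAll + b$dX
  }
  dZs <- list()
  for (i in seq_along(zs)) {
    m <- names(zs)[i]
    dZs[[m]] <- dHats[[m]] + dZAll[, starts[i]:ends[i], drop = FALSE]
  }
  list(dZs = dZs, grads = grads)
}

#' Cross-information feature fusion of two branch embeddings
#'
#' Applies the residual corrections
#' `zhatVE = zVE + F_VE([zVE; zRepGeno])` and
#' `zhatRepGeno = zRepGeno + F_RepGeno([zVE; zRepGeno])`.
#'
#' @param zVE,zRepGeno n x d embedding matrices (equal width).
#' @param fVE,fRepGeno correction networks from [initCorrectionNet()].
#' @return `list(zVEhat, zRepGenohat)`, shapes preserved.
#' @export
crossFusion <- function(zVE, zRepGeno, fVE, fRepGeno) {
  if (ncol(zVE) != ncol(zRepGeno) || nrow(zVE) != nrow(zRepGeno)) {
    stopf("zVE and zRepGeno must have identical dimensions")
  }
  fw <- fusion_fwd(list(ve = zVE, repgeno = zRepGeno),
                   list(ve = fVE, repgeno = fRepGeno))
  list(zVEhat = fw$hats$ve, zRepGenohat = fw$hats$repgeno)
}

#' Prediction head
#'
#' Three fully connected layers mapping the concatenated corrected
#' embeddings to one scalar per sample.
#'
#' @param Z n x d matrix of concatenated corrected embeddings.
#' @param head MLP parameters (`nn` layout, e.g. from [trainMeNet()] models
#'   via `model@params$head`).
#' @return numeric vector of length n.
#' @export
predictHead <- function(Z, head) {
  as.vector(nn_mlp_fwd(as.matrix(Z), head)$out)
}

# ---- full model ----------------------------------------------------------

init_menet_params <- function(segments, veChannels, embedDim, poolLen,
                              veHidden, headHidden, seed) {
  k <- length(segments)
  fusedDim <- (k + 1L) * embedDim
  with_seed(seed, {
    ve <- lapply(seq_len(k), function(i) {
      initVEBranch(veChannels, embedDim, poolLen, veHidden)
    })
    names(ve) <- names(segments)
    fusion <- lapply(seq_len(k + 1L), function(i) {
      initCorrectionNet(fusedDim, embedDim)
    })
    names(fusion) <- c(names(segments), "repgeno")
    head <- nn_mlp_init(c(fusedDim, headHidden, 1L))
    list(ve = ve, fusion = fusion, head = head)
  })
}

# forward through VE segments + fusion + head; zRG precomputed n x E.
# veStats: per-segment frozen batch-norm statistics (NULL = training mode).
menet_fwd <- function(params, cfg, X, zRG, veStats = NULL) {
  zs <- list()
  veCaches <- list()
  for (m in names(cfg$segments)) {
    f <- ve_fwd(X[, cfg$segments[[m]], drop = FALSE], params$ve[[m]],
                veStats[[m]])
    zs[[m]] <- f$out
    veCaches[[m]] <- f$cache
  }
  zs$repgeno <- zRG
  fw <- fusion_fwd(zs, params$fusion)
  Zcat <- do.call(cbind, fw$hats)
  hd <- nn_mlp_fwd(Zcat, params$head)
  list(yhat = as.vector(hd$out), zs = zs, fw = fw, hd = hd,
       veCaches = veCaches, Zcat = Zcat)
}

# Frozen batch-norm statistics for every VE segment, from one training-mode
# pass over the (training) samples with the final parameters.
calibrate_ve_stats <- function(params, cfg, X) {
  out <- list()
  for (m in names(cfg$segments)) {
    out[[m]] <- ve_fwd(X[, cfg$segments[[m]], drop = FALSE],
                       params$ve[[m]])$stats
  }
  out
}

# backward from dY (n x 1, d loss / d standardized prediction)
menet_bwd <- function(dY, params, cfg, cache, encoderGrad = FALSE) {
  bh <- nn_mlp_bwd(dY, params$head, cache$hd)
  dims <- vapply(cache$zs, ncol, 1L)
  ends <- cumsum(dims); starts <- ends - dims + 1L
  dHats <- list()
  for (i in seq_along(cache$zs)) {
    m <- names(cache$zs)[i]
    dHats[[m]] <- bh$dX[, starts[i]:ends[i], drop = FALSE]
  }
  bf <- fusion_bwd(dHats, cache$zs, params$fusion, cache$fw)
  veGrads <- list()
  for (m in names(cfg$segments)) {
    veGrads[[m]] <- ve_bwd(bf$dZs[[m]], params$ve[[m]],
                           cache$veCaches[[m]])$grads
  }
  out <- list(grads = list(ve = veGrads, fusion = bf$grads, head = bh$grads))
  if (encoderGrad) out$dZRG <- bf$dZs$repgeno
  out
}

#' Fused embedding of samples under a trained model
#'
#' Concatenates the (pre-correction) branch embeddings
#' `[z_VE(seg 1); ...; z_VE(seg k); z_RepGeno]` — the representation over
#' which integrated-gradients attributions are computed. Branch membership
#' is tracked by named index sets in the `"index"` attribute, never by
#' position.
#'
#' @param model a [MeNetModel-class].
#' @param genotypes [GenotypeData] or code matrix.
#' @return n x ((k+1) * embedDim) matrix with attribute `index`
#'   (`list(ve =, repgeno =)`).
#' @export
fusedEmbedding <- function(model, genotypes) {
  stopifnot(is(model, "MeNetModel"))
  X <- if (is(genotypes, "GenotypeData")) genoMatrix(genotypes) else
    as.matrix(genotypes)
  zRG <- encodeSamples(model@repgeno, X)
  zs <- list()
  for (m in names(model@config$segments)) {
    zs[[m]] <- ve_fwd(X[, model@config$segments[[m]], drop = FALSE],
                      model@params$ve[[m]],
                      model@meta$veStats[[m]])$out
  }
  zs$repgeno <- zRG
  Z <- do.call(cbind, zs)
  attr(Z, "index") <- model@config$fusedIndex
  Z
}

# Scalar prediction (trait units) and gradient as a function of the fused
# embedding; the differentiable F used by integrated gradients.
fused_predict_grad <- function(model, Z) {
  fused_pg(model@params, model@config, model@meta, Z)
}

#' Predict trait values with a trained MeNet model
#'
#' @param object a [MeNetModel-class].
#' @param genotypes [GenotypeData] or samples-x-markers code matrix.
#' @param ... unused.
#' @return numeric vector of predictions in trait units.
#' @export
setMethod("predict", "MeNetModel", function(object, genotypes, ...) {
  X <- if (is(genotypes, "GenotypeData")) genoMatrix(genotypes) else
    as.matrix(genotypes)
  zRG <- encodeSamples(object@repgeno, X)
  fw <- menet_fwd(object@params, object@config, X, zRG,
                  object@meta$veStats)
  stats::setNames(fw$yhat * object@meta$yScale + object@meta$yCenter,
                  rownames(X))
})
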