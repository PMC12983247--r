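# Integrated-gradients attribution over the fused embedding, and the
# branch-contribution scores: IG_i(z) = (z_i - z'_i) * integral over alpha of
# dF/dz_i along the straight path from the zero baseline z' to z, then
# S_branch = sum over the branch's dimensions of the mean absolute
# attribution across samples, normalised to contribution weights.

#' Integrated gradients along a straight path from a baseline
#'
#' Approximates `IG_i(z) = (z_i - z'_i) * integral_0^1 dF/dz_i(z' + a(z-z'))
#' da`. For piecewise-linear networks (ReLU activations) the path gradient
#' is piecewise constant in `a`, so a fixed-grid rule converges only at
#' rate O(1/steps); the default integrator therefore evaluates the gradient
#' on a grid of `steps` intervals and adaptively bisects any interval whose
#' endpoint gradients differ, localising the gradient jumps until each
#' sub-interval is constant (or `maxDepth` is reached). With
#' `refine = FALSE` the plain midpoint Riemann rule on `steps` points is
#' used instead. For a linear F either rule is exact for any number of
#' steps; the completeness identity `sum_i IG_i ~= F(z) - F(z')` is the
#' practical accuracy check.
#'
#' @param f function mapping an n x d matrix to n scalar outputs.
#' @param z input vector (length d) or n x d matrix.
#' @param baseline baseline z' (default zero vector).
#' @param steps number of base path intervals (default 256).
#' @param grad optional function returning the n x d gradient of `f`;
#'   central finite differences are used when absent.
#' @param refine adaptively bisect intervals containing gradient jumps
#'   (default `TRUE`).
#' @param maxDepth maximum bisection depth per interval.
#' @return attribution vector/matrix shaped like `z`.
#' @examples
#' f <- function(Z) Z %*% c(2, -1)
#' integratedGradients(f, c(3, 5), steps = 4)   # exactly w_i * z_i
#' @export
integratedGradients <- function(f, z, baseline = NULL, steps = 256L,
                                grad = NULL, refine = TRUE,
                                maxDepth = 10L) {
  stopifnot(steps >= 1L)
  vec <- is.null(dim(z))
  Z <- if (vec) matrix(z, nrow = 1L) else as.matrix(z)
  B <- if (is.null(baseline)) matrix(0, nrow(Z), ncol(Z)) else {
    if (is.null(dim(baseline))) {
      matrix(baseline, nrow(Z), ncol(Z), byrow = TRUE)
    } else as.matrix(baseline)
  }
  if (is.null(grad)) grad <- function(M) num_grad(f, M)
  gradAt <- function(idx, alpha) {
    # gradient rows for samples `idx` at per-row path positions `alpha`
    G <- grad(B[idx, , drop = FALSE] +
                alpha * (Z[idx, , drop = FALSE] - B[idx, , drop = FALSE]))
    if (!all(is.finite(G))) stopf("non-finite gradient on the IG path")
    G
  }
  n <- nrow(Z); d <- ncol(Z)
  acc <- matrix(0, n, d)
  if (!refine) {
    for (t in seq_len(steps)) {
      acc <- acc + gradAt(seq_len(n), (t - 0.5) / steps)
    }
    ig <- (Z - B) * acc / steps
    return(if (vec) as.vector(ig) else ig)
  }
  # endpoint grid: one gradient call per grid point, batched over samples
  alphas <- seq(0, 1, length.out = steps + 1L)
  Gk <- lapply(alphas, function(a) gradAt(seq_len(n), a))
  # settle constant intervals with their (exact) plateau value; queue the rest
  qs <- integer(0); qa <- numeric(0); qb <- numeric(0)
  qga <- list(); qgb <- list()
  h <- 1 / steps
  for (k in seq_len(steps)) {
    same <- rowSums(abs(Gk[[k]] - Gk[[k + 1L]])) < 1e-12
    if (any(same)) {
      acc[same, ] <- acc[same, , drop = FALSE] +
        Gk[[k]][same, , drop = FALSE] * h
    }
    for (j in which(!same)) {
      qs <- c(qs, j); qa <- c(qa, alphas[k]); qb <- c(qb, alphas[k + 1L])
      qga[[length(qs)]] <- Gk[[k]][j, ]
      qgb[[length(qs)]] <- Gk[[k + 1L]][j, ]
    }
  }
  depth <- 0L
  while (length(qs)) {
    mid <- (qa + qb) / 2
    Gm <- gradAt(qs, mid)
    ns <- integer(0); na <- numeric(0); nb <- numeric(0)
    nga <- list(); ngb <- list()
    for (r in seq_along(qs)) {
      j <- qs[r]; gm <- Gm[r, ]
      len <- qb[r] - qa[r]
      # Simpson is exact when the gradient is linear on the interval (and
      # for plateaus); only a jump inside keeps the midpoint away from the
      # endpoint average, so bisect exactly there
      dis <- sum(abs(gm - (qga[[r]] + qgb[[r]]) / 2)) * len
      if (dis < 1e-8 * (1 + sum(abs(gm))) || depth >= maxDepth) {
        acc[j, ] <- acc[j, ] + (qga[[r]] + 4 * gm + qgb[[r]]) / 6 * len
      } else {
        halves <- list(list(a = qa[r], b = mid[r], ga = qga[[r]], gb = gm),
                       list(a = mid[r], b = qb[r], ga = gm, gb = qgb[[r]]))
        for (hv in halves) {
          if (sum(abs(hv$ga - hv$gb)) < 1e-12) {
            acc[j, ] <- acc[j, ] + hv$ga * (hv$b - hv$a)
          } else {
            ns <- c(ns, j); na <- c(na, hv$a); nb <- c(nb, hv$b)
            nga[[length(ns)]] <- hv$ga; ngb[[length(ns)]] <- hv$gb
          }
        }
      }
    }
    qs <- ns; qa <- na; qb <- nb; qga <- nga; qgb <- ngb
    depth <- depth + 1L
  }
  ig <- (Z - B) * acc
  if (vec) as.vector(ig) else ig
}

# central finite-difference gradient, row-wise
num_grad <- function(f, M) {
  G <- matrix(0, nrow(M), ncol(M))
  for (j in seq_len(ncol(M))) {
    h <- 1e-5 * pmax(1, abs(M[, j]))
    Mp <- M; Mp[, j] <- M[, j] + h
    Mm <- M; Mm[, j] <- M[, j] - h
    G[, j] <- (f(Mp) - f(Mm)) / (2 * h)
  }
  G
}

#' Branch contribution scores from attribution vectors
#'
#' `S_branch = sum_{i in branch} mean_j |a_{j,i}|` over N samples, and the
#' normalised weights `w = S / (S_VE + S_RepGeno)`. Branch membership is
#' given by explicit index sets.
#'
#' @param attributions N x d attribution matrix (rows = samples).
#' @param veIndex,repgenoIndex disjoint column index sets of the two
#'   branches.
#' @return `list(S_VE, S_RepGeno, w_VE, w_RepGeno, nSamples)`; weights are
#'   `NA` (with a warning) when the total attribution is zero.
#' @export
moduleContributions <- function(attributions, veIndex, repgenoIndex) {
  A <- as.matrix(attributions)
  if (length(intersect(veIndex, repgenoIndex))) {
    stopf("branch index sets overlap")
  }
  mabs <- colMeans(abs(A))
  sVE <- sum(mabs[veIndex]); sRG <- sum(mabs[repgenoIndex])
  tot <- sVE + sRG
  if (tot > 0) {
    w <- c(sVE, sRG) / tot
  } else {
    warnf("zero total attribution; contribution weights undefined")
    w <- c(NA_real_, NA_real_)
  }
  list(S_VE = sVE, S_RepGeno = sRG, w_VE = w[1], w_RepGeno = w[2],
       nSamples = nrow(A))
}

#' Attribute a trained model's prediction to its two branches
#'
#' Computes integrated gradients of the prediction (fusion + head, in trait
#' units) with respect to the fused embedding `[z_VE; z_RepGeno]`, using the
#' zero baseline, then aggregates per-branch contribution scores with
#' [moduleContributions()].
#'
#' @param model a [MeNetModel-class].
#' @param genotypes samples to attribute ([GenotypeData] or code matrix).
#' @param steps IG path points (default 256).
#' @return `list(attributions, S_VE, S_RepGeno, w_VE, w_RepGeno, nSamples,
#'   steps, index)` — an attribution report.
#' @export
attributeContributions <- function(model, genotypes, steps = 256L) {
  stopifnot(is(model, "MeNetModel"))
  Z <- fusedEmbedding(model, genotypes)
  idx <- attr(Z, "index")
  A <- ig_fused(model@params, model@config, model@meta, Z, steps)
  mc <- moduleContributions(A, idx$ve, idx$repgeno)
  c(list(attributions = A), mc, list(steps = steps, index = idx))
}

# IG of the fusion+head map over fused embeddings, zero baseline, adaptive
# kink-refined quadrature; internal (shared by attributeContributions).
ig_fused <- function(params, cfg, meta, Z, steps) {
  integratedGradients(function(M) fused_pg(params, cfg, meta, M)$value,
                      Z, steps = steps,
                      grad = function(M) fused_pg(params, cfg, meta, M)$grad)
}

# prediction value (trait units) + gradient wrt the fused embedding
fused_pg <- function(params, cfg, meta, Z) {
  dims <- rep(cfg$embedDim, length(cfg$segments) + 1L)
  nm <- c(names(cfg$segments), "repgeno")
  ends <- cumsum(dims); starts <- ends - dims + 1L
  zs <- list()
  for (i in seq_along(nm)) zs[[nm[i]]] <- Z[, starts[i]:ends[i], drop = FALSE]
  fw <- fusion_fwd(zs, params$fusion)
  hd <- nn_mlp_fwd(do.call(cbind, fw$hats), params$head)
  dY <- matrix(meta$yScale, nrow(Z), 1L)
  bh <- nn_mlp_bwd(dY, params$head, hd)
  dHats <- list()
  for (i in seq_along(nm)) {
    dHats[[nm[i]]] <- bh$dX[, starts[i]:ends[i], drop = FALSE]
  }
  bf <- fusion_bwd(dHats, zs, params$fusion, fw)
  list(value = as.vector(hd$out) * meta$yScale + meta$yCenter,
       grad = do.call(cbind, bf$dZs))
}
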