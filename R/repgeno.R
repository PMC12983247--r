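# RepGeno: phenotype-aware genetic-relatedness embeddings learned with
# trait-aware triplet contrastive learning. The encoder maps a genotype
# vector to a unit-norm embedding; distances between embeddings (scaled to
# [0, 1]) act as a trait-specific alternative to a kinship matrix.

#' RepGenoEncoder: trained genotype-to-embedding encoder
#'
#' A fully connected encoder (markers -> hidden layers -> embedding) with a
#' final L2 normalization, trained with the trait-aware triplet loss. Use
#' [encodeSamples()] to embed genotypes and [relatednessMatrix()] for the
#' scaled pairwise distances; [trainRepGeno()] is the constructor.
#'
#' @slot params list of dense-layer parameter matrices.
#' @slot config list: `embedDim`, `hidden`, `margin`, `epsilon`, training
#'   settings, the trait standardisation used for phenotype deltas.
#' @slot history data.frame with per-epoch mean triplet loss.
#' @slot seed integer seed the training run used.
#' @exportClass RepGenoEncoder
setClass("RepGenoEncoder", representation(
  params = "list", config = "list", history = "data.frame", seed = "integer"
))

setMethod("show", "RepGenoEncoder", function(object) {
  cfg <- object@config
  cat(sprintf("RepGenoEncoder: %d markers -> %s -> %d dims (unit norm)\n",
              cfg$nMarkers, paste(cfg$hidden, collapse = "/"), cfg$embedDim))
  cat(sprintf("margin %.2f, epsilon %.2f, %d epochs, final loss %.4f\n",
              cfg$margin, cfg$epsilon, nrow(object@history),
              utils::tail(object@history$loss, 1)))
  invisible(NULL)
})

#' Trait-aware triplet loss
#'
#' `L = log(1 + exp(d_pos - d_neg + m))` with adaptive margin
#' `m = deltaNeg - deltaPos + epsilon * margin`, where `d_pos`/`d_neg` are
#' Euclidean distances between the normalized embeddings of the
#' anchor-positive and anchor-negative pairs and `deltaPos`/`deltaNeg` the
#' absolute phenotypic differences of those pairs. The softplus form is
#' numerically stable for large arguments. Vectorised over triplets.
#'
#' @param dPos,dNeg non-negative embedding distances.
#' @param deltaPos,deltaNeg non-negative phenotype differences.
#' @param epsilon margin scale (default 1).
#' @param margin base margin (default 0.3).
#' @return loss value(s), strictly positive.
#' @examples
#' tripletLoss(0.5, 0.5, 0.1, 0.1, epsilon = 0, margin = 0.3) # log(2)
#' @export
tripletLoss <- function(dPos, dNeg, deltaPos, deltaNeg,
                        epsilon = 1, margin = 0.3) {
  m <- deltaNeg - deltaPos + epsilon * margin
  softplus(dPos - dNeg + m)
}

#' Sample one triplet per anchor
#'
#' With population labels: the positive is drawn from the anchor's
#' population, the negative from a different one. Without labels (or when
#' only one population is present, with a warning), two distinct candidates
#' are drawn per anchor and the one with the smaller absolute phenotype
#' difference serves as positive. Every sample is an anchor exactly once.
#'
#' @param pheno numeric phenotype vector (one trait, one environment).
#' @param labels population labels or `NULL`.
#' @param seed integer seed.
#' @return `data.frame(anchor, positive, negative, deltaPos, deltaNeg)` of
#'   row indices into `pheno`.
#' @export
sampleTriplets <- function(pheno, labels = NULL, seed = NULL) {
  n <- length(pheno)
  if (n < 3L) stopf("triplet sampling needs at least 3 samples")
  if (!is.null(labels) && length(unique(labels)) < 2L) {
    warnf("single population: falling back to label-free triplet sampling")
    labels <- NULL
  }
  with_seed(seed, {
    anchor <- seq_len(n)
    pos <- integer(n); neg <- integer(n)
    if (!is.null(labels)) {
      for (i in anchor) {
        same <- which(labels == labels[i]); same <- same[same != i]
        diff <- which(labels != labels[i])
        if (length(same) == 0L) {
          # singleton family: label-free pair for this anchor
          cand <- sample(setdiff(anchor, i), 2L)
          ord <- order(abs(pheno[cand] - pheno[i]))
          pos[i] <- cand[ord[1]]; neg[i] <- cand[ord[2]]
        } else {
          pos[i] <- if (length(same) == 1L) same else sample(same, 1L)
          neg[i] <- if (length(diff) == 1L) diff else sample(diff, 1L)
        }
      }
    } else {
      for (i in anchor) {
        cand <- setdiff(anchor, i)
        cand <- if (length(cand) == 2L) sample(cand) else sample(cand, 2L)
        ord <- order(abs(pheno[cand] - pheno[i]))
        pos[i] <- cand[ord[1]]; neg[i] <- cand[ord[2]]
      }
    }
    data.frame(
      anchor = anchor, positive = pos, negative = neg,
      deltaPos = unname(abs(pheno[anchor] - pheno[pos])),
      deltaNeg = unname(abs(pheno[anchor] - pheno[neg]))
    )
  })
}

#' Train the RepGeno encoder with trait-aware triplet contrastive learning
#'
#' Stage-1 training of the random-effect branch. Phenotypes are z-scored
#' (on the supplied samples) before computing the triplet deltas so the
#' adaptive margin is scale-free. One triplet per anchor is resampled every
#' epoch; minibatch AdamW minimises the mean [tripletLoss()].
#'
#' @param genotypes signed-coding [GenotypeData] (QC'd).
#' @param pheno numeric phenotype vector aligned with the samples (see
#'   [phenoVector()]).
#' @param labels population labels or `NULL`.
#' @param embedDim embedding dimension (desk-scale default 64).
#' @param hidden integer vector of hidden-layer widths.
#' @param margin,epsilon margin parameters of the loss.
#' @param batchSize,epochs,lr,weightDecay AdamW training settings.
#' @param seed integer seed (deterministic training for a fixed seed).
#' @return A [RepGenoEncoder-class] object.
#' @export
trainRepGeno <- function(genotypes, pheno, labels = NULL, embedDim = 64L,
                         hidden = 128L, margin = 0.3, epsilon = 1,
                         batchSize = 128L, epochs = 30L, lr = 1e-3,
                         weightDecay = 1e-4, seed = 1L) {
  stopifnot(is(genotypes, "GenotypeData"))
  X <- genoMatrix(genotypes)
  stopifnot(length(pheno) == nrow(X))
  ctr <- mean(pheno); scl <- sd(pheno); if (scl == 0) scl <- 1
  ph <- (pheno - ctr) / scl
  p <- ncol(X)
  with_seed(derive_seed(seed, "init"), {
    params <- nn_mlp_init(c(p, hidden, embedDim))
  })
  state <- nn_adamw_init(params)
  hist <- data.frame(epoch = integer(0), loss = numeric(0))
  for (ep in seq_len(epochs)) {
    tri <- sampleTriplets(ph, labels,
                          seed = derive_seed(seed, "triplets") + ep)
    ord <- with_seed(derive_seed(seed, "batch") + ep,
                     sample(nrow(tri)))
    tri <- tri[ord, ]
    nb <- ceiling(nrow(tri) / batchSize)
    epLoss <- 0
    for (b in seq_len(nb)) {
      rows <- tri[((b - 1L) * batchSize + 1L):min(b * batchSize, nrow(tri)), ]
      res <- triplet_batch_grad(params, X, rows, epsilon, margin)
      if (!is.finite(res$loss)) {
        stopf("non-finite triplet loss at epoch %d batch %d", ep, b)
      }
      epLoss <- epLoss + res$loss * nrow(rows)
      upd <- nn_adamw_step(params, res$grads, state, lr,
                           weightDecay = weightDecay)
      params <- upd$params; state <- upd$state
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = epLoss / nrow(tri)))
  }
  new("RepGenoEncoder", params = params,
      config = list(nMarkers = p, embedDim = embedDim, hidden = hidden,
                    margin = margin, epsilon = epsilon, lr = lr,
                    weightDecay = weightDecay, batchSize = batchSize,
                    phenoCenter = ctr, phenoScale = scl),
      history = hist, seed = as.integer(seed))
}

# Mean loss and parameter gradients for one triplet minibatch.
triplet_batch_grad <- function(params, X, rows, epsilon, margin) {
  B <- nrow(rows)
  enc <- function(idx) {
    f <- nn_mlp_fwd(X[idx, , drop = FALSE], params)
    nz <- nn_l2norm_fwd(f$out)
    list(f = f, z = nz$out, norms = nz$norms)
  }
  ea <- enc(rows$anchor); ep <- enc(rows$positive); en <- enc(rows$negative)
  dpv <- ea$z - ep$z; dnv <- ea$z - en$z
  dPos <- sqrt(rowSums(dpv^2) + 1e-12)
  dNeg <- sqrt(rowSums(dnv^2) + 1e-12)
  arg <- dPos - dNeg + (rows$deltaNeg - rows$deltaPos + epsilon * margin)
  loss <- mean(softplus(arg))
  g <- stats::plogis(arg) / B            # dL/darg per triplet
  dZa <- (g / dPos) * dpv - (g / dNeg) * dnv
  dZp <- -(g / dPos) * dpv
  dZn <- (g / dNeg) * dnv
  back <- function(e, dZ) {
    dH <- nn_l2norm_bwd(dZ, e$z, e$norms)
    nn_mlp_bwd(dH, params, e$f)$grads
  }
  grads <- nn_add(nn_add(back(ea, dZa), back(ep, dZp)), back(en, dZn))
  list(loss = loss, grads = grads)
}

#' Embed genotypes with a trained RepGeno encoder
#'
#' @param encoder a [RepGenoEncoder-class].
#' @param genotypes a [GenotypeData] or a samples-x-markers code matrix with
#'   the marker set the encoder was trained on.
#' @return n x embedDim matrix; every row has unit Euclidean norm.
#' @export
encodeSamples <- function(encoder, genotypes) {
  stopifnot(is(encoder, "RepGenoEncoder"))
  X <- if (is(genotypes, "GenotypeData")) genoMatrix(genotypes) else
    as.matrix(genotypes)
  if (ncol(X) != encoder@config$nMarkers) {
    stopf("encoder expects %d markers, got %d",
          encoder@config$nMarkers, ncol(X))
  }
  Z <- nn_l2norm_fwd(nn_mlp_fwd(X, encoder@params)$out)$out
  rownames(Z) <- rownames(X)
  Z
}

#' Scaled pairwise relatedness from unit-norm embeddings
#'
#' Entry (a, b) is `||e_a - e_b|| / 2` — Euclidean distance divided by its
#' analytic maximum for unit vectors — so the matrix is symmetric with zero
#' diagonal and entries in \[0, 1\]. `scaling = "minmax"` instead rescales
#' the observed distances to span \[0, 1\].
#'
#' @param embeddings n x d matrix of unit-norm embeddings (or a
#'   [RepGenoEncoder-class] plus `genotypes` to embed first).
#' @param genotypes optional genotypes when `embeddings` is an encoder.
#' @param scaling `"analytic"` (divide by 2) or `"minmax"`.
#' @return n x n relatedness-distance matrix.
#' @export
relatednessMatrix <- function(embeddings, genotypes = NULL,
                              scaling = c("analytic", "minmax")) {
  scaling <- match.arg(scaling)
  if (is(embeddings, "RepGenoEncoder")) {
    embeddings <- encodeSamples(embeddings, genotypes)
  }
  nr <- sqrt(rowSums(embeddings^2))
  if (any(abs(nr - 1) > 1e-6)) stopf("embeddings must have unit row norms")
  D <- as.matrix(stats::dist(embeddings))
  if (scaling == "analytic") {
    D <- D / 2
  } else if (max(D) > 0) {
    D <- (D - min(D)) / (max(D) - min(D))
  }
  diag(D) <- 0
  D
}
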