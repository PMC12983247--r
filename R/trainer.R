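# Data splitting, stage-2 MeNet training (the RepGeno encoder is stage 1,
# see trainRepGeno), cross-environment transfer learning, and grid search.
# Training minimises mean absolute error with AdamW in minibatches of 128;
# the learning rate is reduced by a factor when the validation R2 plateaus
# and the checkpoint with the best validation R2 is returned.

#' Split samples into train / validation / test sets
#'
#' Supported ratio presets follow common genomic-prediction designs
#' (6:2:2, 3:2:5, 0.5:0.5:9) but any positive ratio triple works. Sizes are
#' assigned by largest remainder, so `n = 100` under 6:2:2 gives exactly
#' 60/20/20. Stratified mode bins the phenotype into quantile bins and
#' splits each bin proportionally, so all three sets show the same
#' phenotype distribution.
#'
#' @param n number of samples (or a vector whose length is used).
#' @param pheno phenotype vector (required when `stratify = TRUE`).
#' @param ratios positive ratio triple (train, validation, test).
#' @param stratify preserve phenotype-quantile proportions across sets.
#' @param bins number of quantile bins for stratification.
#' @param seed integer seed.
#' @return `list(train, val, test)` of disjoint, exhaustive index vectors.
#' @export
makeSplits <- function(n, pheno = NULL, ratios = c(6, 2, 2),
                       stratify = FALSE, bins = 4L, seed = NULL) {
  if (length(n) > 1L) n <- length(n)
  n <- as.integer(n)
  if (length(ratios) != 3L || any(ratios <= 0)) {
    stopf("ratios must be 3 positive numbers")
  }
  if (stratify) {
    if (is.null(pheno)) stopf("stratified splits need phenotypes")
    if (n < 10L) stopf("stratified splits need n >= 10")
    stopifnot(length(pheno) == n)
  }
  alloc <- function(m) {
    tgt <- ratios / sum(ratios) * m
    base <- floor(tgt)
    rem <- m - sum(base)
    if (rem > 0) {
      extra <- order(tgt - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    base
  }
  with_seed(seed, {
    groups <- if (stratify) {
      br <- unique(quantile(pheno, probs = seq(0, 1, length.out = bins + 1L)))
      split(seq_len(n), cut(pheno, br, include.lowest = TRUE))
    } else {
      list(seq_len(n))
    }
    out <- list(train = integer(0), val = integer(0), test = integer(0))
    for (g in groups) {
      if (!length(g)) next
      g <- if (length(g) == 1L) g else sample(g)
      k <- alloc(length(g))
      out$train <- c(out$train, g[seq_len(k[1])])
      out$val <- c(out$val, g[seq_len(k[2]) + k[1]])
      if (k[3] > 0) out$test <- c(out$test, g[seq_len(k[3]) + k[1] + k[2]])
    }
    lapply(out, function(i) unname(sort(i)))
  })
}

# squared-Pearson R2 used for checkpoint selection (same default as
# computeMetrics); 0 when either vector is constant.
val_r2 <- function(y, yhat) {
  if (sd(y) == 0 || sd(yhat) == 0) return(0)
  cor(y, yhat)^2
}

# Optimizer over selected top-level parameter paths only; frozen subtrees
# are never touched (no weight decay drift).
opt_init <- function(params, paths) {
  lapply(paths, function(pt) nn_adamw_init(params[[pt]]))
}

opt_step <- function(params, grads, states, paths, lr, weightDecay) {
  for (i in seq_along(paths)) {
    pt <- paths[[i]]
    upd <- nn_adamw_step(params[[pt]], grads[[pt]], states[[i]], lr,
                         weightDecay = weightDecay)
    params[[pt]] <- upd$params
    states[[i]] <- upd$state
  }
  list(params = params, states = states)
}

# Shared minibatch training loop for trainMeNet / transferFinetune.
# veStats = NULL: VE batch norm runs on batch statistics and the frozen
# statistics are calibrated from the training set at the end (stage 2);
# non-NULL: the VE trunk is frozen and evaluated under the given statistics
# throughout (transfer fine-tuning).
menet_fit <- function(params, cfg, X, y, zRG, splits, paths,
                      batchSize, epochs, lr, weightDecay,
                      plateauPatience, plateauFactor, minLr, stopPatience,
                      seed, veStats = NULL) {
  yc <- mean(y[splits$train]); ys <- sd(y[splits$train]); if (ys == 0) ys <- 1
  yst <- (y - yc) / ys
  states <- opt_init(params, paths)
  best <- list(r2 = -Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), trainMAE = numeric(0),
                     valR2 = numeric(0), lr = numeric(0))
  sinceImprove <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, "batch") + ep, sample(splits$train))
    nb <- ceiling(length(ord) / batchSize)
    epErr <- 0
    diverged <- FALSE
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * batchSize + 1L):min(b * batchSize, length(ord))]
      fw <- menet_fwd(params, cfg, X[idx, , drop = FALSE],
                      zRG[idx, , drop = FALSE], veStats)
      resid <- fw$yhat - yst[idx]
      batchLoss <- mean(abs(resid))
      if (!is.finite(batchLoss)) {
        warnf("non-finite loss at epoch %d; reverting to last checkpoint", ep)
        diverged <- TRUE
        break
      }
      epErr <- epErr + batchLoss * length(idx)
      dY <- matrix(sign(resid) / length(idx), ncol = 1L)
      bw <- menet_bwd(dY, params, cfg, fw)
      st <- opt_step(params, bw$grads, states, paths, lr, weightDecay)
      params <- st$params; states <- st$states
    }
    if (diverged) break
    vfw <- menet_fwd(params, cfg, X[splits$val, , drop = FALSE],
                     zRG[splits$val, , drop = FALSE], veStats)
    r2 <- val_r2(yst[splits$val], vfw$yhat)
    hist <- rbind(hist, data.frame(
      epoch = ep, trainMAE = epErr / length(ord) * ys, valR2 = r2, lr = lr))
    if (r2 > best$r2) {
      best <- list(r2 = r2, params = params, epoch = ep)
      sinceImprove <- 0L
    } else {
      sinceImprove <- sinceImprove + 1L
      if (sinceImprove %% plateauPatience == 0L) {
        lr <- max(minLr, lr * plateauFactor)
      }
      if (sinceImprove >= stopPatience) break
    }
  }
  if (is.null(veStats)) {
    veStats <- calibrate_ve_stats(best$params, cfg,
                                  X[splits$train, , drop = FALSE])
  }
  list(params = best$params, history = hist, bestEpoch = best$epoch,
       yCenter = yc, yScale = ys, veStats = veStats)
}

#' Train MeNet (stage 2) on top of a trained RepGeno encoder
#'
#' Trains the VE branch(es), the cross-information fusion networks and the
#' prediction head with AdamW on the mean-absolute-error objective; the
#' RepGeno encoder stays frozen (its embeddings are precomputed once). The
#' checkpoint maximising validation R2 is returned. Deterministic for a
#' fixed seed.
#'
#' @param genotypes QC'd signed-coding [GenotypeData].
#' @param pheno numeric phenotype vector aligned to the samples.
#' @param encoder a trained [RepGenoEncoder-class] (stage 1); its embedding
#'   dimension is shared by the VE branch.
#' @param splits `list(train, val, test)` from [makeSplits()]; default is a
#'   stratified 6:2:2 split.
#' @param veChannels,poolLen,veHidden,headHidden VE / head architecture
#'   (published search grid \{1, 2, 4, 8, 16, 64\}; desk-scale default 4).
#' @param windowThreshold marker count above which [chromosomePartition()]
#'   splits the genome across VE instances (default 100000).
#' @param batchSize,epochs,lr,weightDecay AdamW settings (batch default 128).
#' @param plateauPatience,plateauFactor,minLr validation-plateau learning
#'   rate schedule; `stopPatience` epochs without improvement stop training.
#' @param seed integer seed.
#' @return A [MeNetModel-class]; `model@history` logs per-epoch train MAE
#'   (trait units), validation R2 and learning rate, `model@meta$splits`
#'   records the split.
#' @export
trainMeNet <- function(genotypes, pheno, encoder, splits = NULL,
                       veChannels = 4L, poolLen = 8L, veHidden = 32L,
                       headHidden = c(64L, 32L), windowThreshold = 100000L,
                       batchSize = 128L, epochs = 60L, lr = 1e-3,
                       weightDecay = 1e-4, plateauPatience = 10L,
                       plateauFactor = 0.5, minLr = 1e-6,
                       stopPatience = 30L, seed = 1L) {
  stopifnot(is(genotypes, "GenotypeData"), is(encoder, "RepGenoEncoder"))
  X <- genoMatrix(genotypes)
  stopifnot(length(pheno) == nrow(X))
  embedDim <- encoder@config$embedDim
  if (is.null(splits)) {
    splits <- makeSplits(nrow(X), pheno, c(6, 2, 2), stratify = TRUE,
                         seed = derive_seed(seed, "splits"))
  }
  segments <- chromosomePartition(genotypes, windowThreshold)
  params <- init_menet_params(segments, veChannels, embedDim, poolLen,
                              veHidden, headHidden,
                              seed = derive_seed(seed, "init"))
  k <- length(segments)
  cfg <- list(segments = segments, veChannels = veChannels,
              embedDim = embedDim, poolLen = poolLen,
              headHidden = headHidden, nMarkers = ncol(X),
              markerIds = markerInfo(genotypes)$id,
              fusedIndex = list(
                ve = seq_len(k * embedDim),
                repgeno = k * embedDim + seq_len(embedDim)))
  zRG <- encodeSamples(encoder, X)
  fit <- menet_fit(params, cfg, X, pheno, zRG, splits,
                   paths = list("ve", "fusion", "head"),
                   batchSize, epochs, lr, weightDecay,
                   plateauPatience, plateauFactor, minLr, stopPatience, seed)
  new("MeNetModel", repgeno = encoder, params = fit$params, config = cfg,
      history = fit$history,
      meta = list(yCenter = fit$yCenter, yScale = fit$yScale,
                  bestEpoch = fit$bestEpoch, splits = splits,
                  veStats = fit$veStats, seed = as.integer(seed)))
}

#' Cross-environment transfer learning
#'
#' Fine-tunes a source-environment model on a small fraction of target
#' samples, split half into training and half into validation (default 10%
#' of samples as 5% / 5%); the remainder is the test set. Exactly the
#' VE-side correction network(s) F_VE and the three-layer prediction head
#' are trainable; the RepGeno encoder, the VE trunk(s) and F_RepGeno are
#' frozen and bit-identical before and after.
#'
#' @param model source-trained [MeNetModel-class].
#' @param genotypes target [GenotypeData] with the source marker set.
#' @param pheno target-environment phenotype vector.
#' @param fraction total fraction of target samples used (train + val).
#' @param splits optional `list(train, val, test)` overriding `fraction`.
#' @param batchSize,epochs,lr,weightDecay,plateauPatience,plateauFactor,minLr,stopPatience
#'   fine-tuning settings.
#' @param seed integer seed.
#' @return A fine-tuned [MeNetModel-class]; `model@meta$splits` holds the
#'   target split and `model@meta$transfer` the provenance.
#' @export
transferFinetune <- function(model, genotypes, pheno, fraction = 0.10,
                             splits = NULL, batchSize = 128L, epochs = 40L,
                             lr = 1e-3, weightDecay = 1e-4,
                             plateauPatience = 10L, plateauFactor = 0.5,
                             minLr = 1e-6, stopPatience = 30L, seed = 1L) {
  stopifnot(is(model, "MeNetModel"))
  X <- if (is(genotypes, "GenotypeData")) genoMatrix(genotypes) else
    as.matrix(genotypes)
  if (ncol(X) != model@config$nMarkers) {
    stopf("target marker set (%d) does not match the source model (%d)",
          ncol(X), model@config$nMarkers)
  }
  if (is(genotypes, "GenotypeData") &&
      !identical(markerInfo(genotypes)$id, model@config$markerIds)) {
    stopf("target marker identifiers do not match the source model")
  }
  stopifnot(length(pheno) == nrow(X))
  if (is.null(splits)) {
    half <- fraction / 2
    splits <- makeSplits(nrow(X), pheno,
                         c(half, half, 1 - fraction), stratify = TRUE,
                         seed = derive_seed(seed, "transfer"))
  }
  cfg <- model@config
  paths <- c(lapply(names(cfg$segments), function(m) c("fusion", m)),
             list("head"))
  zRG <- encodeSamples(model@repgeno, X)
  fit <- menet_fit(model@params, cfg, X, pheno, zRG, splits, paths,
                   batchSize, epochs, lr, weightDecay,
                   plateauPatience, plateauFactor, minLr, stopPatience, seed,
                   veStats = model@meta$veStats)
  new("MeNetModel", repgeno = model@repgeno, params = fit$params,
      config = cfg, history = fit$history,
      meta = list(yCenter = fit$yCenter, yScale = fit$yScale,
                  bestEpoch = fit$bestEpoch, splits = splits,
                  veStats = fit$veStats, seed = as.integer(seed),
                  transfer = list(trainable = c("F_VE", "head"),
                                  fraction = fraction)))
}

#' Grid search over architecture hyperparameters
#'
#' Evaluates every grid point with the same fixed seed(s) and returns the
#' configuration maximising validation R2 plus the full results table. The
#' default grids follow the published search spaces (margin
#' \{0.1, ..., 0.5\}, channels \{1, 2, 4, 8, 16, 64\}, embedding dimension
#' \{512, 1024, 4096, 8192\}); pass smaller grids for desk-scale work.
#'
#' @param genotypes,pheno,labels training data.
#' @param grids named list with numeric vectors `margin`, `veChannels`,
#'   `embedDim`.
#' @param splits optional split; default stratified 6:2:2.
#' @param repgenoEpochs,menetEpochs training lengths per grid point.
#' @param seed integer seed (shared across grid points).
#' @param ... further arguments to [trainMeNet()].
#' @return `list(best = <config row>, results = data.frame, model = best
#'   MeNetModel)`.
#' @export
gridSearch <- function(genotypes, pheno, labels = NULL,
                       grids = list(margin = seq(0.1, 0.5, 0.1),
                                    veChannels = c(1L, 2L, 4L, 8L, 16L, 64L),
                                    embedDim = c(512L, 1024L, 4096L, 8192L)),
                       splits = NULL, repgenoEpochs = 20L, menetEpochs = 30L,
                       seed = 1L, ...) {
  if (!length(grids) || any(!lengths(grids))) stopf("empty grid")
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  if (is.null(splits)) {
    splits <- makeSplits(ncol(genotypes), pheno, c(6, 2, 2), stratify = TRUE,
                         seed = derive_seed(seed, "splits"))
  }
  results <- combos
  results$valR2 <- NA_real_
  bestModel <- NULL; bestR2 <- -Inf
  for (r in seq_len(nrow(combos))) {
    enc <- trainRepGeno(genotypes, pheno, labels,
                        embedDim = combos$embedDim[r],
                        margin = combos$margin[r],
                        epochs = repgenoEpochs, seed = seed)
    mod <- trainMeNet(genotypes, pheno, enc, splits = splits,
                      veChannels = combos$veChannels[r],
                      epochs = menetEpochs, seed = seed, ...)
    results$valR2[r] <- max(mod@history$valR2)
    if (results$valR2[r] > bestR2) {
      bestR2 <- results$valR2[r]; bestModel <- mod
    }
  }
  list(best = results[which.max(results$valR2), , drop = FALSE],
       results = results, model = bestModel)
}
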