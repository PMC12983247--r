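test_that("VE output dimension is independent of marker count", {
  ve <- initVEBranch(veChannels = 2L, embedDim = 6L, poolLen = 4L,
                     hidden = 5L, seed = 1)
  X1 <- matrix(sample(c(-1, 0, 1), 10 * 50, TRUE), 10, 50)
  X2 <- matrix(sample(c(-1, 0, 1), 10 * 150, TRUE), 10, 150)
  expect_equal(dim(veForward(X1, ve)), c(10L, 6L))
  expect_equal(dim(veForward(X2, ve)), c(10L, 6L))
})

test_that("VE acts per sample and is deterministic", {
  ve <- initVEBranch(2L, 6L, 4L, 5L, seed = 2)
  set.seed(3)
  X <- matrix(sample(c(-1, 0, 1), 8 * 30, TRUE), 8, 30)
  Z <- veForward(X, ve)
  expect_identical(Z, veForward(X, ve))           # repeated pass identical
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  expect_equal(veForward(X[perm, ], ve), Z[perm, ])  # row permutation
})

test_that("a too-narrow segment is zero-padded with a warning", {
  ve <- initVEBranch(2L, 6L, poolLen = 8L, hidden = 5L, seed = 4)
  X <- matrix(sample(c(-1, 0, 1), 5 * 3, TRUE), 5, 3)
  expect_warning(Z <- veForward(X, ve), "zero-padding")
  expect_equal(dim(Z), c(5L, 6L))
})

test_that("VE backward gradients match finite differences", {
  # continuous inputs and non-zero biases keep pre-activations off the
  # ReLU kinks where one-sided derivatives differ
  set.seed(5)
  X <- matrix(rnorm(6 * 20), 6, 20)
  ve <- initVEBranch(2L, 4L, 4L, 5L, seed = 6)
  ve$conv0$b <- rnorm(2, sd = 0.1)
  for (rb in c("rb1", "rb2")) for (cv in c("c1", "c2")) {
    ve[[rb]][[cv]]$b <- rnorm(2, sd = 0.1)
  }
  lossfn <- function(v) sum(menet:::ve_fwd(X, v)$out^2) / 2
  f <- menet:::ve_fwd(X, ve)
  g <- menet:::ve_bwd(f$out, ve, f$cache)$grads
  leaves <- menet:::nn_leaves(ve)
  gl <- menet:::nn_leaves(g)
  h <- 1e-6
  for (li in seq_along(leaves)) {
    for (ii in seq_len(min(3, length(leaves[[li]])))) {
      lp <- leaves; lp[[li]][ii] <- lp[[li]][ii] + h
      lm <- leaves; lm[[li]][ii] <- lm[[li]][ii] - h
      num <- (lossfn(menet:::nn_set_leaves(ve, lp)) -
                lossfn(menet:::nn_set_leaves(ve, lm))) / (2 * h)
      expect_equal(gl[[li]][ii], num, tolerance = 1e-4)
    }
  }
})

test_that("zero-initialised correction networks give the residual identity", {
  E <- 6L
  fVE <- initCorrectionNet(2L * E, E, seed = 7)     # last layer zero by design
  fRG <- initCorrectionNet(2L * E, E, seed = 8)
  set.seed(9)
  zVE <- matrix(rnorm(5 * E), 5, E)
  zRG <- matrix(rnorm(5 * E), 5, E)
  out <- crossFusion(zVE, zRG, fVE, fRG)
  expect_identical(out$zVEhat, zVE)
  expect_identical(out$zRepGenohat, zRG)
})

test_that("purely linear correction networks match hand matrix algebra", {
  E <- 3L
  mk_linear <- function(seed) {
    set.seed(seed)
    # ReLU identity trick: layer 1 splits into [relu(z), relu(-z)] (all
    # non-negative, so the middle ReLU is a no-op on layer 2's identity),
    # and layer 3 recombines with [W; -W], making the net exactly linear
    W <- matrix(rnorm(2 * E * E), 2 * E, E)
    l1 <- list(W = cbind(diag(2 * E), -diag(2 * E)), b = matrix(0, 1, 4 * E))
    l2 <- list(W = diag(4 * E), b = matrix(0, 1, 4 * E))
    l3 <- list(W = rbind(W, -W), b = matrix(0, 1, E))
    list(layers = list(l1, l2, l3), W = W)
  }
  fVE <- mk_linear(10); fRG <- mk_linear(11)
  set.seed(12)
  zVE <- matrix(rnorm(4 * E), 4, E)
  zRG <- matrix(rnorm(4 * E), 4, E)
  out <- crossFusion(zVE, zRG, fVE$layers, fRG$layers)
  zAll <- cbind(zVE, zRG)
  # hand algebra oracle: the net reduces to F(z) = z W
  expect_equal(out$zVEhat, zVE + zAll %*% fVE$W, tolerance = 1e-10)
  expect_equal(out$zRepGenohat, zRG + zAll %*% fRG$W, tolerance = 1e-10)
  # shape contract
  expect_equal(dim(out$zVEhat), dim(zVE))
  expect_error(crossFusion(zVE, zRG[, 1:2], fVE$layers, fRG$layers),
               "identical dimensions")
})

test_that("prediction head maps batches to one scalar per sample", {
  head <- menet:::nn_mlp_init(c(6, 4, 3, 1))
  set.seed(13)
  Z <- matrix(rnorm(7 * 6), 7, 6)
  out <- predictHead(Z, head)
  expect_length(out, 7L)
  expect_identical(out, predictHead(Z, head))
  # zeroed weights with bias b -> constant prediction b
  zeroHead <- menet:::nn_mlp_init(c(6, 4, 3, 1), zeroLast = TRUE)
  zeroHead[[3]]$b[] <- 2.5
  expect_equal(predictHead(Z, zeroHead), rep(2.5, 7))
})

test_that("chromosome partitioning follows the threshold rules", {
  sim <- simulateGenotypes(nSamples = 10, nMarkers = 60, nChromosomes = 3,
                           seed = 14)
  g <- sim$genotypes
  # p below threshold: single segment
  expect_equal(chromosomePartition(g, threshold = 100L),
               list(seg1 = 1:60))
  # p above threshold: one segment per chromosome, disjoint and exhaustive
  segs <- chromosomePartition(g, threshold = 30L)
  expect_equal(length(segs), 3L)
  expect_equal(unname(sort(unlist(segs))), 1:60)
  expect_equal(sum(duplicated(unlist(segs))), 0L)
  # a chromosome larger than the threshold splits into windows
  segs2 <- chromosomePartition(g, threshold = 15L)
  expect_gte(length(segs2), 4L)
  expect_equal(unname(sort(unlist(segs2))), 1:60)
})

test_that("end-to-end forward pass is deterministic and supports ablation", {
  m <- small_model()
  pp <- small_panel()
  X <- genoMatrix(pp$geno)[1:10, ]
  p1 <- predict(m, X)
  p2 <- predict(m, X)
  expect_identical(p1, p2)
  # RepGeno branch ablated: zero embedding still yields a working regressor
  zRG0 <- matrix(0, 10, m@config$embedDim)
  fw <- menet:::menet_fwd(m@params, m@config, X, zRG0)
  expect_length(fw$yhat, 10L)
  expect_true(all(is.finite(fw$yhat)))
  # VE branch ablated: zero VE embedding, true RepGeno embedding
  zRG <- encodeSamples(m@repgeno, X)
  zs <- list(seg1 = matrix(0, 10, m@config$embedDim), repgeno = zRG)
  fwFusion <- menet:::fusion_fwd(zs, m@params$fusion)
  yhat <- predictHead(do.call(cbind, fwFusion$hats), m@params$head)
  expect_true(all(is.finite(yhat)))
})

test_that("partitioned and single-segment models agree in output dimensionality", {
  pp <- small_panel()
  enc <- trainRepGeno(pp$geno, pp$y, pp$labels, embedDim = 8L, hidden = 16L,
                      epochs = 2L, seed = 31)
  m1 <- trainMeNet(pp$geno, pp$y, enc, veChannels = 2L, poolLen = 4L,
                   veHidden = 8L, headHidden = c(8L, 4L), epochs = 2L,
                   batchSize = 32L, windowThreshold = 100000L, seed = 32)
  m2 <- trainMeNet(pp$geno, pp$y, enc, veChannels = 2L, poolLen = 4L,
                   veHidden = 8L, headHidden = c(8L, 4L), epochs = 2L,
                   batchSize = 32L, windowThreshold = 20L, seed = 32)
  expect_gt(length(m2@config$segments), 1L)
  X <- genoMatrix(pp$geno)[1:5, ]
  expect_length(predict(m1, X), 5L)
  expect_length(predict(m2, X), 5L)
})
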