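test_that("splits are disjoint, exhaustive and match the preset ratios", {
  sp <- makeSplits(100, ratios = c(6, 2, 2), seed = 1)
  expect_equal(lengths(sp), c(train = 60L, val = 20L, test = 20L))
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:100)
  sp2 <- makeSplits(100, ratios = c(3, 2, 5), seed = 2)
  expect_equal(lengths(sp2), c(train = 30L, val = 20L, test = 50L))
  sp3 <- makeSplits(100, ratios = c(0.5, 0.5, 9), seed = 3)
  expect_equal(lengths(sp3), c(train = 5L, val = 5L, test = 90L))
  # odd n still partitions exactly
  sp4 <- makeSplits(97, ratios = c(6, 2, 2), seed = 4)
  expect_equal(unname(sort(unlist(sp4))), 1:97)
  expect_error(makeSplits(50, ratios = c(1, 2)), "3 positive")
})

test_that("stratified splits preserve phenotype-bin proportions", {
  set.seed(5)
  y <- rnorm(400)
  sp <- makeSplits(400, y, c(6, 2, 2), stratify = TRUE, bins = 4, seed = 6)
  br <- quantile(y, seq(0, 1, 0.25))
  bins <- cut(y, br, include.lowest = TRUE)
  for (set in sp) {
    prop <- table(bins[set]) / length(set)
    expect_true(all(abs(prop - 0.25) <= 0.05))
  }
  expect_error(makeSplits(5, rnorm(5), stratify = TRUE), "n >= 10")
})

test_that("reported training loss is the mean absolute error on the batch", {
  pp <- small_panel()
  enc <- trainRepGeno(pp$geno, pp$y, pp$labels, embedDim = 8L, hidden = 16L,
                      epochs = 2L, seed = 41)
  # lr = 0 and no decay: parameters never move, so the single full-batch
  # epoch's logged MAE must equal mean |y - yhat| of the returned model
  sp <- makeSplits(length(pp$y), pp$y, c(6, 2, 2), seed = 42)
  m <- trainMeNet(pp$geno, pp$y, enc, splits = sp, veChannels = 2L,
                  poolLen = 4L, veHidden = 8L, headHidden = c(8L, 4L),
                  epochs = 1L, batchSize = 1000L, lr = 0, weightDecay = 0,
                  seed = 43)
  pr <- predict(m, genoMatrix(pp$geno)[sp$train, ])
  expect_equal(m@history$trainMAE[1], mean(abs(pp$y[sp$train] - pr)),
               tolerance = 1e-6)
})

test_that("checkpoint selection and schedule follow validation R2", {
  pp <- small_panel()
  enc <- trainRepGeno(pp$geno, pp$y, pp$labels, embedDim = 8L, hidden = 16L,
                      epochs = 2L, seed = 51)
  m <- trainMeNet(pp$geno, pp$y, enc, veChannels = 2L, poolLen = 4L,
                  veHidden = 8L, headHidden = c(8L, 4L), epochs = 8L,
                  batchSize = 32L, plateauPatience = 2L, seed = 52)
  h <- m@history
  expect_equal(m@meta$bestEpoch, h$epoch[which.max(h$valR2)])
  expect_true(all(diff(h$lr) <= 0))  # lr never increases
  # training progress: best checkpoint beats the untrained model on train MAE
  expect_lt(min(h$trainMAE), h$trainMAE[1] * 1.05)
})

test_that("training is deterministic given the seed", {
  pp <- small_panel()
  enc <- trainRepGeno(pp$geno, pp$y, pp$labels, embedDim = 8L, hidden = 16L,
                      epochs = 2L, seed = 61)
  m1 <- trainMeNet(pp$geno, pp$y, enc, veChannels = 2L, poolLen = 4L,
                   veHidden = 8L, headHidden = c(8L, 4L), epochs = 3L,
                   batchSize = 32L, seed = 62)
  m2 <- trainMeNet(pp$geno, pp$y, enc, veChannels = 2L, poolLen = 4L,
                   veHidden = 8L, headHidden = c(8L, 4L), epochs = 3L,
                   batchSize = 32L, seed = 62)
  expect_identical(m1@history, m2@history)
  expect_identical(m1@params, m2@params)
})

test_that("transfer learning freezes everything except F_VE and the head", {
  pp <- small_panel()
  m <- small_model()
  set.seed(71)
  yTarget <- pp$y + rnorm(length(pp$y), sd = 0.5)
  ft <- transferFinetune(m, pp$geno, yTarget, fraction = 0.2,
                         epochs = 3L, batchSize = 16L, seed = 72)
  # frozen tensors bit-identical pre/post
  expect_identical(ft@params$ve, m@params$ve)
  expect_identical(ft@params$fusion$repgeno, m@params$fusion$repgeno)
  expect_identical(ft@repgeno@params, m@repgeno@params)
  # trainable set = {F_VE, head}: both must have moved
  expect_false(identical(ft@params$fusion$seg1, m@params$fusion$seg1))
  expect_false(identical(ft@params$head, m@params$head))
  expect_equal(ft@meta$transfer$trainable, c("F_VE", "head"))
  # 10% default split halves into train and validation
  sp <- transferFinetune(m, pp$geno, yTarget, fraction = 0.2, epochs = 1L,
                         seed = 73)@meta$splits
  expect_equal(length(sp$train), length(sp$val))
  # per-quantile-bin rounding can shift the total by at most one per bin
  expect_lt(abs(length(sp$train) + length(sp$val) - 0.2 * length(pp$y)), 4)
})

test_that("transfer rejects a mismatched marker set", {
  pp <- small_panel()
  m <- small_model()
  expect_error(transferFinetune(m, pp$geno[1:10, ], pp$y, seed = 1),
               "marker set")
})

test_that("grid search evaluates every point and returns the argmax", {
  pp <- small_panel()
  gs <- gridSearch(pp$geno, pp$y, pp$labels,
                   grids = list(margin = c(0.1, 0.3), veChannels = c(1L, 2L),
                                embedDim = 8L),
                   repgenoEpochs = 2L, menetEpochs = 2L, seed = 81,
                   poolLen = 4L, veHidden = 8L, headHidden = c(8L, 4L),
                   batchSize = 32L)
  expect_equal(nrow(gs$results), 4L)
  expect_false(anyNA(gs$results$valR2))
  expect_equal(gs$best$valR2, max(gs$results$valR2))
  expect_s4_class(gs$model, "MeNetModel")
  expect_error(gridSearch(pp$geno, pp$y, grids = list(margin = numeric(0))),
               "empty grid")
})
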