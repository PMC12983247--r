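test_that("genotype simulation is seed-deterministic with valid codes", {
  a <- simulateGenotypes(nSamples = 30, nMarkers = 25, nPopulations = 3,
                         seed = 5)
  b <- simulateGenotypes(nSamples = 30, nMarkers = 25, nPopulations = 3,
                         seed = 5)
  expect_identical(genoMatrix(a$genotypes), genoMatrix(b$genotypes))
  expect_identical(a$labels, b$labels)
  expect_true(all(genoMatrix(a$genotypes) %in% c(-1, 0, 1)))
  expect_equal(length(unique(a$labels)), 3L)
  expect_equal(length(a$labels), 30L)
})

test_that("empirical MAF matches the base MAF in a large panmictic panel", {
  sim <- simulateGenotypes(nSamples = 5000, nMarkers = 40, nPopulations = 1,
                           divergence = 0, baseMaf = 0.5, mutationRate = 1,
                           seed = 9)
  pAlt <- (colMeans(genoMatrix(sim$genotypes)) + 1) / 2
  # binomial sampling check: 3-standard-error band around 0.5
  se <- sqrt(0.5 * 0.5 / 5000)
  expect_gte(mean(abs(pAlt - 0.5) < 3 * se), 0.95)
  expect_lt(abs(mean(pAlt) - 0.5), 3 * se / sqrt(40) * 2)
})

test_that("markers within an LD block are correlated, across blocks are not", {
  sim <- simulateGenotypes(nSamples = 2000, nMarkers = 40, nPopulations = 1,
                           divergence = 0, ldBlockSize = 10,
                           mutationRate = 0.1, seed = 21)
  X <- genoMatrix(sim$genotypes)
  r2 <- suppressWarnings(cor(X))^2
  r2[is.na(r2)] <- 0
  blk <- ceiling(seq_len(40) / 10)
  same <- outer(blk, blk, "==") & upper.tri(r2)
  diffb <- outer(blk, blk, "!=") & upper.tri(r2)
  expect_gt(mean(r2[same]), 5 * mean(r2[diffb]))
  expect_lt(mean(r2[diffb]), 0.02)
  # mutationRate 1 destroys the block structure
  iid <- simulateGenotypes(nSamples = 2000, nMarkers = 40, nPopulations = 1,
                           divergence = 0, ldBlockSize = 10,
                           mutationRate = 1, seed = 22)
  r2i <- cor(genoMatrix(iid$genotypes))^2
  expect_lt(mean(r2i[upper.tri(r2i)]), 0.005)
})

test_that("noiseless additive trait equals an elementwise dot-product oracle", {
  codes <- matrix(c(1, -1, 0, 1,
                    -1, 1, 1, 0,
                    0, 0, -1, 1,
                    1, 1, 1, -1,
                    -1, -1, 0, 0), 5, 4, byrow = TRUE)
  mk <- data.frame(id = paste0("m", 1:4), chrom = "1",
                   pos = c(1L, 2L, 3L, 4L) * 100L, ref = "A", alt = "T")
  g <- GenotypeData(codes, mk, samples = paste0("S", 1:5))
  beta <- c(0.5, -1, 2, 0.25)
  arch <- traitArchitecture(intercept = 3,
                            additive = additiveEffects(1:4, beta),
                            targetH2 = 1, seed = 1)
  ph <- simulateTrait(g, NULL, arch)
  oracle <- 3 + as.vector(codes %*% beta)  # independent brute-force product
  expect_equal(ph$value, oracle)
})

test_that("epistatic terms enter as coded products; theta = 0 is a no-op", {
  sim <- simulateGenotypes(nSamples = 40, nMarkers = 10, seed = 3)
  base <- traitArchitecture(additive = additiveEffects(1:2, c(1, -1)),
                            targetH2 = 1, seed = 2)
  withEp0 <- traitArchitecture(additive = additiveEffects(1:2, c(1, -1)),
                               epistasis = data.frame(i = 3, j = 7, theta = 0),
                               targetH2 = 1, seed = 2)
  y0 <- simulateTrait(sim$genotypes, NULL, base)$value
  y1 <- simulateTrait(sim$genotypes, NULL, withEp0)$value
  expect_identical(y0, y1)
  withEp <- traitArchitecture(
    epistasis = data.frame(i = 3, j = 7, theta = 2), targetH2 = 1, seed = 2)
  X <- genoMatrix(sim$genotypes)
  expect_equal(simulateTrait(sim$genotypes, NULL, withEp)$value,
               unname(2 * X[, 3] * X[, 7]))
})

test_that("realized heritability is calibrated to the target", {
  sim <- simulateGenotypes(nSamples = 5000, nMarkers = 50, nPopulations = 2,
                           seed = 31)
  set.seed(32)
  arch <- traitArchitecture(
    additive = additiveEffects(1:20, rnorm(20)),
    epistasis = data.frame(i = 1:5, j = 11:15, theta = rnorm(5)),
    targetH2 = 0.5, seed = 33)
  noiseless <- traitArchitecture(
    additive = arch$additive, epistasis = arch$epistasis,
    targetH2 = 1, seed = 33)
  y <- simulateTrait(sim$genotypes, sim$labels, arch)$value
  gpart <- simulateTrait(sim$genotypes, sim$labels, noiseless)$value
  h2 <- var(gpart) / var(y)
  expect_gt(h2, 0.45); expect_lt(h2, 0.55)
})

test_that("family random effect is constant within and varies across families", {
  sim <- simulateGenotypes(nSamples = 60, nMarkers = 10, nPopulations = 3,
                           seed = 8)
  arch <- traitArchitecture(polygenicVar = 4, targetH2 = 1, seed = 9)
  y <- simulateTrait(sim$genotypes, sim$labels, arch)$value
  for (lab in unique(sim$labels)) {
    expect_equal(sd(y[sim$labels == lab]), 0)
  }
  expect_gt(sd(tapply(y, sim$labels, mean)), 0)
})

test_that("identical environment profiles give perfectly correlated noiseless values", {
  sim <- simulateGenotypes(nSamples = 50, nMarkers = 20, seed = 12)
  arch <- traitArchitecture(
    additive = additiveEffects(1:5, c(1, 2, -1, 0.5, -2)), targetH2 = 1,
    envProfiles = list(list(name = "E1", scale = 1, noiseVar = NULL),
                       list(name = "E2", scale = 1, noiseVar = NULL)),
    seed = 13)
  ph <- simulateTrait(sim$genotypes, NULL, arch)
  y1 <- ph$value[ph$environment == "E1"]
  y2 <- ph$value[ph$environment == "E2"]
  expect_equal(cor(y1, y2), 1)
})

test_that("correlated environment profiles hit the target genetic correlation", {
  sim <- simulateGenotypes(nSamples = 3000, nMarkers = 200, nPopulations = 1,
                           divergence = 0, mutationRate = 1, seed = 14)
  set.seed(15)
  arch <- traitArchitecture(
    additive = additiveEffects(1:200, rnorm(200)), targetH2 = 1,
    envProfiles = correlatedEnvProfiles(200, 0.7, seed = 16), seed = 17)
  ph <- simulateTrait(sim$genotypes, NULL, arch)
  y1 <- ph$value[ph$environment == "E1"]
  y2 <- ph$value[ph$environment == "E2"]
  expect_gt(cor(y1, y2), 0.55)
  expect_lt(cor(y1, y2), 0.85)
})

test_that("out-of-range effect indices are rejected", {
  sim <- simulateGenotypes(nSamples = 10, nMarkers = 5, seed = 2)
  arch <- traitArchitecture(additive = additiveEffects(9, 1), targetH2 = 1)
  expect_error(simulateTrait(sim$genotypes, NULL, arch), "out of range")
  arch2 <- traitArchitecture(
    epistasis = data.frame(i = 2, j = 9, theta = 1), targetH2 = 1)
  expect_error(simulateTrait(sim$genotypes, NULL, arch2), "out of range")
  expect_error(traitArchitecture(
    epistasis = data.frame(i = 2, j = 2, theta = 1)), "i != j")
})
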