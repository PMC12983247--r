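test_that("VCF reading matches an independent hand parse", {
  fx <- write_tiny_vcf()
  g <- readGenotypes(fx$path, format = "vcf")
  expect_s4_class(g, "GenotypeData")
  expect_identical(genoCoding(g), "dosage")
  expect_equal(genoMatrix(g), fx$truth)
  info <- markerInfo(g)
  expect_equal(info$id, c("v1", "v2", "v3"))
  expect_equal(info$pos, c(100L, 200L, 150L))
  expect_equal(info$chrom, c("chr1", "chr1", "chr2"))
})

test_that("empty and malformed VCF inputs error", {
  empty <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"),
             empty)
  expect_error(readGenotypes(empty, format = "vcf"), "no records")
  expect_error(readGenotypes(tempfile(), format = "vcf"), "not found")
})

test_that("multiallelic and non-SNP records are skipped with a warning", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\tv1\tA\tT,G\t.\tPASS\t.\tGT\t0/0\t1/2",
    "chr1\t200\tv2\tAT\tA\t.\tPASS\t.\tGT\t0/0\t1/1",
    "chr1\t300\tv3\tA\tC\t.\tPASS\t.\tGT\t0/1\t1/1"
  ), path)
  expect_warning(g <- readGenotypes(path, format = "vcf"),
                 "multiallelic or non-SNP")
  expect_equal(markerInfo(g)$id, "v3")
})

test_that("non-diploid calls are an error", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\tv1\tA\tT\t.\tPASS\t.\tGT\t0/1/1"
  ), path)
  expect_error(readGenotypes(path, format = "vcf"), "non-diploid")
})

test_that("encoding maps calls per the signed convention and is idempotent", {
  fx <- write_tiny_vcf()
  g <- encodeGenotypes(readGenotypes(fx$path, format = "vcf"))
  expect_identical(genoCoding(g), "signed")
  X <- genoMatrix(g)
  # 0/0 -> -1, 1/1 -> 1, 0/1 -> 0, ./. -> 0
  expect_equal(unname(X["S1", ]), c(-1, 0, 1))
  expect_equal(unname(X["S2", ]), c(1, 0, 0))
  expect_false(anyNA(X))
  expect_true(all(X %in% c(-1, 0, 1)))
  expect_equal(genoMatrix(encodeGenotypes(g)), X)  # idempotent
})

test_that("matrix dialect round-trips through write and read", {
  pp <- small_panel()
  path <- tempfile(fileext = ".tsv")
  writeGenotypes(pp$geno, path)
  g2 <- readGenotypes(path, format = "matrix")
  expect_equal(genoMatrix(g2), genoMatrix(pp$geno))
  expect_equal(markerInfo(g2), markerInfo(pp$geno))
})

test_that("MAF filter removes rare markers at the 0.01 threshold", {
  # 200 samples (400 alleles); one homozygous-minor sample in marker 1
  # gives minor-allele count 2 -> MAF 0.005 < 0.01
  n <- 200
  codes <- cbind(c(rep(1, 199), -1),
                 rep(c(1, -1), 100),
                 c(rep(1, 196), rep(-1, 4)))
  mk <- data.frame(id = paste0("m", 1:3), chrom = "1",
                   pos = c(100L, 5000L, 9000L), ref = "A", alt = "T")
  g <- GenotypeData(codes, mk, samples = paste0("S", 1:n))
  q <- applyQC(g, mafMin = 0.01, ldR2Max = 1)
  expect_equal(markerInfo(q)$id, c("m2", "m3"))
})

test_that("LD pruning keeps the earlier of a perfectly correlated pair", {
  col <- rep(c(1, -1), 50)
  codes <- cbind(col, col, rep(c(1, 1, -1, -1), 25))
  mk <- data.frame(id = c("a", "b", "c"), chrom = "1",
                   pos = c(100L, 600L, 800L), ref = "A", alt = "T")
  g <- GenotypeData(codes, mk, samples = paste0("S", 1:100))
  q <- applyQC(g, mafMin = 0, ldWindowBp = 2000, ldStepBp = 1000,
               ldR2Max = 0.5)
  expect_true("a" %in% markerInfo(q)$id)   # earlier kept
  expect_false("b" %in% markerInfo(q)$id)  # r2 = 1 with a -> dropped
  expect_true("c" %in% markerInfo(q)$id)   # uncorrelated with a
})

test_that("identical columns on different chromosomes are both retained", {
  col <- rep(c(1, -1), 50)
  codes <- cbind(col, col)
  mk <- data.frame(id = c("a", "b"), chrom = c("1", "2"),
                   pos = c(100L, 100L), ref = "A", alt = "T")
  g <- GenotypeData(codes, mk, samples = paste0("S", 1:100))
  q <- applyQC(g, mafMin = 0, ldR2Max = 0.2)
  expect_equal(nrow(markerInfo(q)), 2L)
})

test_that("QC post-conditions hold exhaustively on a toy panel", {
  sim <- simulateGenotypes(nSamples = 120, nMarkers = 50, nPopulations = 2,
                           ldBlockSize = 5, seed = 77)
  q <- applyQC(sim$genotypes, mafMin = 0.05, ldWindowBp = 2000,
               ldStepBp = 1000, ldR2Max = 0.6)
  X <- genoMatrix(q); info <- markerInfo(q)
  expect_true(all(info$id %in% markerInfo(sim$genotypes)$id))  # subset
  maf <- pmin((colMeans(X) + 1) / 2, 1 - (colMeans(X) + 1) / 2)
  expect_true(all(maf >= 0.05))
  # no surviving within-window pair above the r2 ceiling
  for (chr in unique(info$chrom)) {
    idx <- which(info$chrom == chr)
    for (a in idx) for (b in idx) {
      if (b > a && abs(info$pos[b] - info$pos[a]) < 2000) {
        r2 <- suppressWarnings(cor(X[, a], X[, b])^2)
        if (!is.na(r2)) expect_lte(r2, 0.6 + 1e-12)
      }
    }
  }
})

test_that("pruning is invariant to sample order", {
  sim <- simulateGenotypes(nSamples = 80, nMarkers = 40, nPopulations = 2,
                           ldBlockSize = 5, seed = 55)
  g <- sim$genotypes
  set.seed(9)
  perm <- sample(ncol(g))
  g2 <- g[, perm]
  q1 <- applyQC(g, mafMin = 0.02, ldR2Max = 0.5)
  q2 <- applyQC(g2, mafMin = 0.02, ldR2Max = 0.5)
  expect_equal(markerInfo(q1)$id, markerInfo(q2)$id)
})

test_that("all-markers-removed QC warns and returns an empty panel", {
  codes <- cbind(c(rep(1, 16), rep(-1, 4)), c(rep(-1, 16), rep(1, 4)))
  mk <- data.frame(id = c("a", "b"), chrom = "1", pos = c(100L, 200L),
                   ref = "A", alt = "T")
  g <- GenotypeData(codes, mk, samples = paste0("S", 1:20))
  expect_warning(q <- applyQC(g, mafMin = 0.5), "all markers removed")
  expect_equal(nrow(q), 0L)
})
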