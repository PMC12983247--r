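# Shared fixtures, built in code at test time.

# Tiny VCF written to a temp file; returns the path and the hand-parsed
# dosage matrix (2 samples x 3 biallelic sites).
write_tiny_vcf <- function(dir = tempdir()) {
  path <- file.path(dir, "tiny.vcf")
  lines <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\tv1\tA\tT\t.\tPASS\t.\tGT\t0/0\t1/1",
    "chr1\t200\tv2\tG\tC\t.\tPASS\t.\tGT\t0/1\t./.",
    "chr2\t150\tv3\tT\tA\t.\tPASS\t.\tGT\t1|1\t0|1"
  )
  writeLines(lines, path)
  # independent hand parse: dosage = count of alt alleles, NA if missing
  truth <- matrix(c(0, 2, 1, NA, 2, 1), nrow = 2,
                  dimnames = list(c("S1", "S2"), c("v1", "v2", "v3")))
  list(path = path, truth = truth)
}

# Small labelled panel with a population-correlated additive trait; cached
# across tests within a run.
.panel_cache <- new.env()
small_panel <- function() {
  if (is.null(.panel_cache$p)) {
    sim <- simulateGenotypes(nSamples = 90, nMarkers = 60, nPopulations = 3,
                             divergence = 0.25, ldBlockSize = 6, seed = 401)
    arch <- traitArchitecture(
      additive = additiveEffects(c(5, 20, 41), c(1.2, -1, 0.8)),
      polygenicVar = 0.5, targetH2 = 0.8, seed = 402)
    pheno <- simulateTrait(sim$genotypes, sim$labels, arch)
    .panel_cache$p <- list(
      geno = sim$genotypes, labels = sim$labels, pheno = pheno,
      y = phenoVector(pheno, sim$genotypes))
  }
  .panel_cache$p
}

# A quickly trained small MeNet model (shared by model/interpret tests).
small_model <- function() {
  if (is.null(.panel_cache$m)) {
    pp <- small_panel()
    enc <- trainRepGeno(pp$geno, pp$y, pp$labels, embedDim = 8L,
                        hidden = 16L, epochs = 4L, seed = 403)
    .panel_cache$m <- trainMeNet(pp$geno, pp$y, enc, veChannels = 2L,
                                 poolLen = 4L, veHidden = 8L,
                                 headHidden = c(8L, 4L), epochs = 4L,
                                 batchSize = 32L, seed = 404)
  }
  .panel_cache$m
}
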