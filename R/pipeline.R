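# Pipeline orchestration: named stages wired through a run directory, driven
# by a YAML config. Each stage reads its inputs from (and writes its outputs
# to) the run directory, so stages can be run singly or as a chain; the
# resolved config and seed are snapshotted for reproducibility. Everything
# is deterministic given the seed. The thin command-line wrapper lives at
# inst/scripts/menet.R.

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic panel + trait), `preprocess` (encode + QC),
#' `train-repgeno` (stage-1 encoder), `train` (stage-2 MeNet), `transfer`
#' (fine-tune onto a second environment), `attribute` (integrated-gradients
#' branch contributions) and `evaluate` (test metrics for MeNet and the
#' ridge baseline). See `system.file("extdata", "demo-config.yaml",
#' package = "menet")` for the config schema.
#'
#' @param stage stage name.
#' @param config config list (or path to a YAML file).
#' @param outDir run directory (created if needed).
#' @param seed integer seed; expanded deterministically per component and
#'   recorded in the run directory.
#' @return invisibly, a list of artifact paths written by the stage.
#' @export
runStage <- function(stage, config, outDir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("simulate", "preprocess", "train-repgeno", "train", "transfer",
             "attribute", "evaluate")
  if (!stage %in% known) {
    stopf("unknown stage '%s' (expected one of: %s)", stage,
          paste(known, collapse = ", "))
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  writeLines(as.character(seed), file.path(outDir, "seed.txt"))
  fn <- switch(stage,
    "simulate" = stage_simulate, "preprocess" = stage_preprocess,
    "train-repgeno" = stage_repgeno, "train" = stage_train,
    "transfer" = stage_transfer, "attribute" = stage_attribute,
    "evaluate" = stage_evaluate)
  invisible(fn(config, outDir, as.integer(seed)))
}

#' Run a chain of pipeline stages
#'
#' @param config config list or YAML path; its `stages` entry (default: the
#'   full simulate-to-evaluate chain) names the stages to run in order.
#' @param outDir run directory.
#' @param seed integer seed governing every stage.
#' @return invisibly, named list of per-stage artifact paths.
#' @export
runPipeline <- function(config, outDir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("simulate", "preprocess", "train-repgeno",
                                 "train", "attribute", "evaluate")
  out <- lapply(stages, function(s) runStage(s, config, outDir, seed))
  names(out) <- stages
  invisible(out)
}

pipe_path <- function(outDir, name) file.path(outDir, name)

read_pheno_table <- function(outDir) {
  read.table(pipe_path(outDir, "phenotypes.tsv"), header = TRUE, sep = "\t",
             stringsAsFactors = FALSE)
}

stage_simulate <- function(config, outDir, seed) {
  sc <- config$simulate %||% list()
  sim <- simulateGenotypes(
    nSamples = sc$nSamples %||% 300L, nMarkers = sc$nMarkers %||% 200L,
    nPopulations = sc$nPopulations %||% 3L,
    divergence = sc$divergence %||% 0.15,
    ldBlockSize = sc$ldBlockSize %||% 10L, baseMaf = sc$baseMaf %||% 0.3,
    mutationRate = sc$mutationRate %||% 0.1,
    nChromosomes = sc$nChromosomes %||% 5L,
    seed = derive_seed(seed, "simulate"))
  tc <- sc$trait %||% list()
  p <- ncol(genoMatrix(sim$genotypes))
  arch <- with_seed(derive_seed(seed, "trait"), {
    nAdd <- tc$nAdditive %||% 5L
    idx <- sample(p, nAdd)
    ep <- NULL
    nEp <- tc$nEpistatic %||% 0L
    if (nEp > 0) {
      i <- sample(p - 1L, nEp)
      ep <- data.frame(i = i, j = i + 1L,
                       theta = rnorm(nEp, sd = tc$thetaSd %||% 1))
    }
    traitArchitecture(
      intercept = tc$intercept %||% 0,
      additive = additiveEffects(idx, rnorm(nAdd, sd = tc$betaSd %||% 1)),
      epistasis = ep, polygenicVar = tc$polygenicVar %||% 0,
      targetH2 = tc$targetH2 %||% 0.7,
      envProfiles = if (!is.null(tc$envCorrelation)) {
        correlatedEnvProfiles(p, tc$envCorrelation,
                              seed = derive_seed(seed, "trait") + 1L)
      } else {
        list(list(name = "E1", scale = 1, noiseVar = NULL))
      },
      seed = derive_seed(seed, "trait") + 2L)
  })
  pheno <- simulateTrait(sim$genotypes, sim$labels, arch)
  writeGenotypes(sim$genotypes, pipe_path(outDir, "genotypes.tsv"))
  write.table(pheno, pipe_path(outDir, "phenotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(genotypes = pipe_path(outDir, "genotypes.tsv"),
                 phenotypes = pipe_path(outDir, "phenotypes.tsv")))
}

stage_preprocess <- function(config, outDir, seed) {
  qc <- config$preprocess %||% list()
  g <- readGenotypes(pipe_path(outDir, "genotypes.tsv"), format = "matrix")
  g <- encodeGenotypes(g)
  g <- applyQC(g, mafMin = qc$mafMin %||% 0.01,
               ldWindowBp = qc$ldWindowBp %||% 2000L,
               ldStepBp = qc$ldStepBp %||% 1000L,
               ldR2Max = qc$ldR2Max %||% 0.95)
  writeGenotypes(g, pipe_path(outDir, "genotypes_qc.tsv"))
  invisible(list(genotypes_qc = pipe_path(outDir, "genotypes_qc.tsv")))
}

load_qc <- function(outDir) {
  readGenotypes(pipe_path(outDir, "genotypes_qc.tsv"), format = "matrix")
}

stage_repgeno <- function(config, outDir, seed) {
  rc <- config$repgeno %||% list()
  g <- load_qc(outDir)
  pheno <- read_pheno_table(outDir)
  y <- phenoVector(pheno, g, environment = config$environment %||% NULL)
  labels <- pheno$population[match(colnames(g), pheno$sample)]
  if (all(is.na(labels))) labels <- NULL
  enc <- trainRepGeno(g, y, labels,
                      embedDim = rc$embedDim %||% 16L,
                      hidden = rc$hidden %||% 32L,
                      margin = rc$margin %||% 0.3,
                      epsilon = rc$epsilon %||% 1,
                      batchSize = rc$batchSize %||% 128L,
                      epochs = rc$epochs %||% 10L, lr = rc$lr %||% 1e-3,
                      seed = derive_seed(seed, "repgeno"))
  saveRDS(enc, pipe_path(outDir, "repgeno.rds"))
  write.table(enc@history, pipe_path(outDir, "repgeno_history.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  D <- relatednessMatrix(enc, g)
  writeRelatedness(D, pipe_path(outDir, "relatedness.tsv"))
  invisible(list(encoder = pipe_path(outDir, "repgeno.rds"),
                 relatedness = pipe_path(outDir, "relatedness.tsv")))
}

stage_train <- function(config, outDir, seed) {
  tc <- config$train %||% list()
  g <- load_qc(outDir)
  pheno <- read_pheno_table(outDir)
  y <- phenoVector(pheno, g, environment = config$environment %||% NULL)
  enc <- readRDS(pipe_path(outDir, "repgeno.rds"))
  model <- trainMeNet(g, y, enc,
                      veChannels = tc$veChannels %||% 2L,
                      poolLen = tc$poolLen %||% 8L,
                      headHidden = tc$headHidden %||% c(32L, 16L),
                      batchSize = tc$batchSize %||% 128L,
                      epochs = tc$epochs %||% 15L, lr = tc$lr %||% 1e-3,
                      seed = derive_seed(seed, "menet"))
  saveRDS(model, pipe_path(outDir, "menet.rds"))
  write.table(model@history, pipe_path(outDir, "train_history.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(model = pipe_path(outDir, "menet.rds"),
                 history = pipe_path(outDir, "train_history.tsv")))
}

stage_transfer <- function(config, outDir, seed) {
  tc <- config$transfer %||% list()
  g <- load_qc(outDir)
  pheno <- read_pheno_table(outDir)
  env <- tc$environment %||% utils::tail(unique(pheno$environment), 1)
  y <- phenoVector(pheno, g, environment = env)
  model <- readRDS(pipe_path(outDir, "menet.rds"))
  ft <- transferFinetune(model, g, y, fraction = tc$fraction %||% 0.10,
                         epochs = tc$epochs %||% 20L,
                         seed = derive_seed(seed, "transfer"))
  saveRDS(ft, pipe_path(outDir, "menet_transfer.rds"))
  write.table(ft@history, pipe_path(outDir, "transfer_history.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(model = pipe_path(outDir, "menet_transfer.rds")))
}

stage_attribute <- function(config, outDir, seed) {
  ac <- config$attribute %||% list()
  g <- load_qc(outDir)
  model <- readRDS(pipe_path(outDir, "menet.rds"))
  idx <- model@meta$splits$val
  rep <- attributeContributions(model, genoMatrix(g)[idx, , drop = FALSE],
                                steps = ac$steps %||% 64L)
  tab <- data.frame(S_VE = rep$S_VE, S_RepGeno = rep$S_RepGeno,
                    w_VE = rep$w_VE, w_RepGeno = rep$w_RepGeno,
                    nSamples = rep$nSamples, steps = rep$steps)
  write.table(tab, pipe_path(outDir, "attribution.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(attribution = pipe_path(outDir, "attribution.tsv")))
}

stage_evaluate <- function(config, outDir, seed) {
  g <- load_qc(outDir)
  pheno <- read_pheno_table(outDir)
  env <- config$environment %||% pheno$environment[1]
  y <- phenoVector(pheno, g, environment = env)
  model <- readRDS(pipe_path(outDir, "menet.rds"))
  sp <- model@meta$splits
  X <- genoMatrix(g)
  preds <- list(
    MeNet = predict(model, X[sp$test, , drop = FALSE]),
    ridge = ridgeBaseline(X[sp$train, , drop = FALSE], y[sp$train],
                          X[sp$test, , drop = FALSE])
  )
  rows <- lapply(names(preds), function(m) {
    met <- computeMetrics(y[sp$test], as.vector(preds[[m]]))
    data.frame(model = m, environment = env, split = "test",
               metric = names(met), value = as.numeric(met[1, ]))
  })
  tab <- do.call(rbind, rows)
  write.table(tab, pipe_path(outDir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(metrics = pipe_path(outDir, "metrics.tsv")))
}

#' Write a relatedness matrix as a square tab-separated file
#'
#' Kinship-matrix convention: sample IDs as both header and first column.
#'
#' @param D square relatedness matrix with sample IDs as dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRelatedness <- function(D, path) {
  ids <- rownames(D) %||% paste0("S", seq_len(nrow(D)))
  tab <- data.frame(sample = ids, D, check.names = FALSE)
  colnames(tab) <- c("sample", ids)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
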