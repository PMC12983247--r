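# Synthetic populations and quantitative traits.
#
# The simulator emulates the statistical structure multi-family breeding
# panels (RIL / MAGIC style) present to a genomic-prediction model:
# several inbred families with diverged allele frequencies, LD blocks,
# a handful of large-effect loci or a polygenic background, pairwise
# epistasis, a family-level random effect, and environment-specific
# effect scaling plus noise. Traits follow the nonlinear mixed model
#   y = b0 + sum_i b_i X_i + sum_(i,j) theta_ij X_i X_j + Z gamma + eps.

#' Simulate a multi-family inbred genotype panel
#'
#' Samples are fully inbred (codes in \{1, -1\}; no heterozygotes), split
#' evenly into `nPopulations` families. Each family has its own allele
#' frequencies (the base frequency perturbed by `divergence`). Within each
#' LD block of `ldBlockSize` consecutive markers, every family carries
#' `nFounders` founder haplotypes (2 by default, biparental-RIL style); a
#' sample draws one founder per block and copies it with per-marker
#' mutation probability `mutationRate`. The shared founder makes markers
#' within a block correlated, while independent founder draws across blocks
#' keep blocks independent; `mutationRate = 1` gives markers drawn
#' independently (no LD). Markers are laid out on `nChromosomes`
#' chromosomes at `spacingBp` intervals.
#'
#' @param nSamples,nMarkers panel dimensions.
#' @param nPopulations number of families (labels `P1`, `P2`, ...).
#' @param divergence SD of the per-family allele-frequency perturbation
#'   (0 = panmictic).
#' @param ldBlockSize markers per LD block (default: 10, capped at
#'   `nMarkers`).
#' @param baseMaf base minor allele frequency in (0, 0.5].
#' @param mutationRate probability a marker deviates from the block founder.
#' @param nFounders founder haplotypes per family and block.
#' @param nChromosomes,spacingBp marker layout.
#' @param seed integer seed; same seed gives a bit-identical panel.
#' @return `list(genotypes = GenotypeData (signed), labels = character)`.
#' @examples
#' sim <- simulateGenotypes(nSamples = 20, nMarkers = 50, nPopulations = 2,
#'                          seed = 7)
#' table(sim$labels)
#' @export
simulateGenotypes <- function(nSamples, nMarkers, nPopulations = 3L,
                              divergence = 0.15, ldBlockSize = NULL,
                              baseMaf = 0.3, mutationRate = 0.1,
                              nFounders = 2L, nChromosomes = 5L,
                              spacingBp = 500L, seed = NULL) {
  if (is.null(ldBlockSize)) ldBlockSize <- min(10L, nMarkers)
  stopifnot(nSamples >= 1, nMarkers >= 1, nPopulations >= 1,
            nPopulations <= nSamples, ldBlockSize >= 1,
            ldBlockSize <= nMarkers, baseMaf > 0, baseMaf <= 0.5,
            divergence >= 0, nFounders >= 1)
  with_seed(seed, {
    labels <- paste0("P", rep_len(seq_len(nPopulations), nSamples))
    labels <- labels[order(rep_len(seq_len(nPopulations), nSamples))]
    # base alt-allele frequency per marker, then family-specific deviation
    qBase <- runif(nMarkers, baseMaf, 1 - baseMaf)
    blocks <- split(seq_len(nMarkers),
                    ceiling(seq_len(nMarkers) / ldBlockSize))
    X <- matrix(0, nSamples, nMarkers)
    for (k in seq_len(nPopulations)) {
      members <- which(labels == paste0("P", k))
      qPop <- pmin(0.95, pmax(0.05, qBase + rnorm(nMarkers, 0, divergence)))
      for (b in blocks) {
        founders <- matrix(rbinom(nFounders * length(b), 1L,
                                  rep(qPop[b], each = nFounders)),
                           nFounders, length(b))
        pick <- sample.int(nFounders, length(members), replace = TRUE)
        for (si in seq_along(members)) {
          hap <- founders[pick[si], ]
          mut <- runif(length(b)) < mutationRate
          hap[mut] <- rbinom(sum(mut), 1L, qPop[b][mut])
          X[members[si], b] <- 2 * hap - 1
        }
      }
    }
    perChr <- ceiling(nMarkers / nChromosomes)
    chrom <- paste0("chr", ceiling(seq_len(nMarkers) / perChr))
    posInChr <- stats::ave(seq_len(nMarkers), chrom, FUN = seq_along)
    markers <- data.frame(
      id = sprintf("m%05d", seq_len(nMarkers)),
      chrom = chrom,
      pos = posInChr * spacingBp,
      ref = "A", alt = "T", stringsAsFactors = FALSE
    )
    rownames(X) <- sprintf("S%05d", seq_len(nSamples))
    gd <- GenotypeData(X, markers, coding = "signed")
    list(genotypes = gd, labels = labels)
  })
}

#' Describe a trait architecture
#'
#' Bundles the terms of the nonlinear mixed model: intercept `b0`, additive
#' effects `b_i`, epistatic pair effects `theta_ij` over a pair set C, a
#' family-level random effect Z gamma, the target heritability and the
#' environment profiles.
#'
#' @param intercept scalar `b0`.
#' @param additive named or indexed numeric vector of additive effects; names
#'   or an `idx` attribute give marker column indices, otherwise effects are
#'   matched to the first `length(additive)` markers. Use
#'   `additiveEffects(idx, beta)` for explicit placement.
#' @param epistasis `data.frame(i, j, theta)` of interacting marker-index
#'   pairs and their effects (i != j).
#' @param polygenicVar variance of the family-level random effect Z gamma
#'   (0 disables it).
#' @param targetH2 target broad-sense heritability in \[0, 1\]; per
#'   environment, noise variance is calibrated from the realised genetic
#'   variance so that Var(genetic) / Var(y) is `targetH2` (ignored for
#'   environments that specify `noiseVar` directly).
#' @param envProfiles list of environment profiles, each
#'   `list(name =, scale =, noiseVar = NULL)`; `scale` is a scalar or
#'   per-marker vector multiplying additive effects (epistatic effects are
#'   scaled by the mean of the two marker scalings).
#' @param seed integer seed for effect/noise draws in [simulateTrait()].
#' @return A validated `TraitArchitecture` list.
#' @export
traitArchitecture <- function(intercept = 0,
                              additive = numeric(0),
                              epistasis = NULL,
                              polygenicVar = 0,
                              targetH2 = NA_real_,
                              envProfiles = list(list(name = "E1", scale = 1,
                                                      noiseVar = NULL)),
                              seed = NULL) {
  if (!is.null(epistasis)) {
    stopifnot(all(c("i", "j", "theta") %in% names(epistasis)))
    if (any(epistasis$i == epistasis$j)) {
      stopf("epistatic pairs must have i != j")
    }
  }
  if (!is.na(targetH2) && (targetH2 < 0 || targetH2 > 1)) {
    stopf("targetH2 must lie in [0, 1]")
  }
  stopifnot(polygenicVar >= 0)
  structure(
    list(intercept = intercept, additive = additive, epistasis = epistasis,
         polygenicVar = polygenicVar, targetH2 = targetH2,
         envProfiles = envProfiles, seed = seed),
    class = "TraitArchitecture"
  )
}

#' @rdname traitArchitecture
#' @param idx integer marker indices.
#' @param beta numeric effects, same length as `idx`.
#' @export
additiveEffects <- function(idx, beta) {
  stopifnot(length(idx) == length(beta))
  structure(as.numeric(beta), idx = as.integer(idx))
}

#' Environment profiles with a chosen genetic correlation
#'
#' Builds two environment profiles whose per-marker effect scalings give the
#' (expected) genetic correlation `rho` between the environments' genetic
#' values: the first environment uses unit scaling and the second scales each
#' marker effect by `rho + sqrt(1 - rho^2) * z_i`, `z_i ~ N(0, 1)`.
#'
#' @param nMarkers number of markers.
#' @param rho target genetic correlation in \[-1, 1\].
#' @param names environment names.
#' @param seed integer seed.
#' @return list of two environment profiles for [traitArchitecture()].
#' @export
correlatedEnvProfiles <- function(nMarkers, rho, names = c("E1", "E2"),
                                  seed = NULL) {
  stopifnot(abs(rho) <= 1)
  with_seed(seed, {
    s2 <- rho + sqrt(1 - rho^2) * rnorm(nMarkers)
    list(list(name = names[1], scale = 1, noiseVar = NULL),
         list(name = names[2], scale = s2, noiseVar = NULL))
  })
}

#' Simulate phenotypes from a trait architecture
#'
#' Per environment e with per-marker scaling s_e:
#' `y = b0 + sum_i s_e[i] b_i X_i + sum_(i,j) mean(s_e[i], s_e[j]) theta_ij
#' X_i X_j + Z gamma + eps_e`, with `eps_e ~ N(0, sigma2_e)`. When the
#' architecture requests a target heritability, `sigma2_e` is solved from
#' the realised variance of the genetic component (including Z gamma) so
#' that the realised heritability matches; `targetH2 = 1` forces zero noise.
#'
#' @param genotypes a signed-coding [GenotypeData].
#' @param labels family labels (required when `polygenicVar > 0`).
#' @param arch a [traitArchitecture()].
#' @return `data.frame(sample, environment, value, population)` — one row per
#'   (sample, environment).
#' @export
simulateTrait <- function(genotypes, labels = NULL, arch) {
  stopifnot(is(genotypes, "GenotypeData"), inherits(arch, "TraitArchitecture"))
  X <- genoMatrix(genotypes)
  n <- nrow(X); p <- ncol(X)
  beta <- as.numeric(arch$additive)
  bIdx <- attr(arch$additive, "idx") %||% seq_along(beta)
  if (length(bIdx) && max(bIdx) > p) stopf("additive index out of range")
  ep <- arch$epistasis
  if (!is.null(ep) && nrow(ep) && max(c(ep$i, ep$j)) > p) {
    stopf("epistatic index out of range")
  }
  if (arch$polygenicVar > 0 && is.null(labels)) {
    stopf("polygenicVar > 0 requires family labels")
  }
  with_seed(arch$seed, {
    fam <- 0
    if (arch$polygenicVar > 0) {
      u <- rnorm(length(unique(labels)), 0, sqrt(arch$polygenicVar))
      names(u) <- unique(labels)
      fam <- u[labels]
    }
    out <- lapply(arch$envProfiles, function(prof) {
      s <- prof$scale
      if (length(s) == 1L) s <- rep(s, p)
      if (length(s) != p) stopf("environment scale length != marker count")
      g <- rep(arch$intercept, n)
      if (length(beta)) {
        g <- g + as.vector(X[, bIdx, drop = FALSE] %*% (s[bIdx] * beta))
      }
      if (!is.null(ep) && nrow(ep)) {
        th <- ep$theta * (s[ep$i] + s[ep$j]) / 2
        g <- g + as.vector((X[, ep$i, drop = FALSE] *
                              X[, ep$j, drop = FALSE]) %*% th)
      }
      g <- g + fam
      vG <- var(g)
      sigma2 <- prof$noiseVar
      if (is.null(sigma2)) {
        h2 <- arch$targetH2
        if (is.na(h2)) {
          sigma2 <- 0
        } else if (h2 == 1) {
          sigma2 <- 0
        } else {
          if (vG == 0 && h2 > 0) stopf("zero genetic variance with targetH2 > 0")
          sigma2 <- vG * (1 - h2) / h2
        }
      }
      eps <- if (sigma2 > 0) rnorm(n, 0, sqrt(sigma2)) else numeric(n)
      data.frame(
        sample = rownames(X), environment = prof$name %||% "E1",
        value = g + eps,
        population = if (is.null(labels)) NA_character_ else labels,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}

#' Extract one environment's phenotype vector aligned to a genotype panel
#'
#' @param pheno a phenotype table from [simulateTrait()] (or the same layout).
#' @param genotypes the [GenotypeData] whose sample order to follow.
#' @param environment environment name; default = first in the table.
#' @return named numeric vector, one value per sample.
#' @export
phenoVector <- function(pheno, genotypes, environment = NULL) {
  env <- environment %||% pheno$environment[1]
  sub <- pheno[pheno$environment == env, ]
  ids <- colnames(genotypes)
  m <- match(ids, sub$sample)
  if (anyNA(m)) stopf("phenotypes missing for %d sample(s)", sum(is.na(m)))
  stats::setNames(sub$value[m], ids)
}
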