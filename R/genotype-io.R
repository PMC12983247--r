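# Genotype input, encoding and quality control.
#
# Preprocessing follows the standard genomic-prediction pipeline: biallelic
# SNPs only; markers with minor allele frequency < 0.01 excluded; sliding
# window LD pruning (2000 bp window, 1000 bp step by default); genotypes
# coded 1 / -1 for the homozygotes, 0 for heterozygotes, missing imputed
# to 0.

#' Read genotypes from VCF or the plain-matrix dialect
#'
#' For `format = "vcf"` (VCF 4.x, uncompressed or gzipped), biallelic SNP
#' records are read into alt-allele dosages (0/1/2, `NA` when missing);
#' multiallelic or non-SNP records are skipped with a warning. Non-diploid
#' genotype calls are an error. For `format = "matrix"`, the file is
#' tab-separated with a `sample` column followed by one column per marker
#' holding signed codes in \{1, 0, -1\} (empty/NA = missing), and marker
#' metadata (columns id, chrom, pos, ref, alt) is read from `markerFile`
#' (default `<path>.markers`).
#'
#' @param path input file.
#' @param format `"vcf"` or `"matrix"`.
#' @param markerFile marker-metadata file for the matrix dialect.
#' @return A [GenotypeData] — `"dosage"` coding for VCF input, `"signed"`
#'   for matrix input. Pass through [encodeGenotypes()] before modelling.
#' @seealso [encodeGenotypes()], [applyQC()], [writeGenotypes()]
#' @export
readGenotypes <- function(path, format = c("vcf", "matrix"),
                          markerFile = paste0(path, ".markers")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "vcf") read_vcf_genotypes(path) else {
    read_matrix_genotypes(path, markerFile)
  }
}

read_vcf_genotypes <- function(path) {
  vcf <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) NULL
  )
  if (is.null(vcf) || nrow(vcf@fix) == 0L) stopf("no records in %s", path)
  fix <- vcf@fix
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L
  if (!all(snp)) {
    warnf("skipping %d multiallelic or non-SNP record(s)", sum(!snp))
  }
  if (!any(snp)) stopf("no biallelic SNP records in %s", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  if (is.null(colnames(gt)) || ncol(gt) == 0L) stopf("zero samples in %s", path)
  dos <- apply(gt, c(1, 2), gt_to_dosage)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  markers <- data.frame(
    id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], stringsAsFactors = FALSE
  )
  GenotypeData(t(dos), markers, samples = colnames(gt), coding = "dosage")
}

# One diploid GT string -> alt dosage (NA for missing); errors on ploidy != 2.
gt_to_dosage <- function(g) {
  if (is.na(g) || g == "." || g == "./." || g == ".|.") return(NA_real_)
  alleles <- strsplit(g, "[/|]")[[1]]
  if (length(alleles) != 2L) {
    stopf("non-diploid genotype call '%s'", g)
  }
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles == "1")
}

read_matrix_genotypes <- function(path, markerFile) {
  if (!file.exists(markerFile)) {
    stopf("marker metadata file not found: %s", markerFile)
  }
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stopf("no records in %s", path)
  if (names(tab)[1] != "sample") {
    stopf("matrix dialect requires first column 'sample'")
  }
  codes <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(codes) <- "double"
  rownames(codes) <- tab$sample
  markers <- read.table(markerFile, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE,
                        colClasses = c(id = "character", chrom = "character",
                                       pos = "integer", ref = "character",
                                       alt = "character"))
  mm <- match(colnames(codes), markers$id)
  if (anyNA(mm)) stopf("marker metadata missing for: %s",
                       paste(head(colnames(codes)[is.na(mm)], 3),
                             collapse = ", "))
  GenotypeData(codes, markers[mm, , drop = FALSE],
               samples = tab$sample, coding = "signed")
}

#' Write genotypes in the plain-matrix dialect
#'
#' Writes the tab-separated sample-x-marker code matrix to `path` and the
#' marker metadata to `paste0(path, ".markers")`, the format read back by
#' [readGenotypes()] with `format = "matrix"`.
#'
#' @param x a [GenotypeData] in signed coding.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(x, path) {
  stopifnot(is(x, "GenotypeData"))
  X <- genoMatrix(x)
  tab <- data.frame(sample = rownames(X), X, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(markerInfo(x), paste0(path, ".markers"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Encode genotypes to the signed coding and impute missing calls
#'
#' Maps homozygous alt to 1, homozygous ref to -1, heterozygous to 0 and
#' missing to 0. Heterozygous and (imputed) missing calls are therefore
#' indistinguishable downstream — a property of the coding itself, not a
#' defect. Idempotent: signed input is returned with any remaining `NA`
#' zero-filled.
#'
#' @param x a [GenotypeData] in dosage or signed coding.
#' @return A [GenotypeData] in signed coding with no missing entries.
#' @export
encodeGenotypes <- function(x) {
  stopifnot(is(x, "GenotypeData"))
  a <- assay(x, "codes")
  if (identical(genoCoding(x), "dosage")) {
    a <- a - 1
  }
  a[is.na(a)] <- 0
  out <- x
  SummarizedExperiment::assay(out, "codes") <- a
  metadata(out)$coding <- "signed"
  validObject(out)
  out
}

#' Quality control: MAF filter then sliding-window LD pruning
#'
#' Markers with minor allele frequency below `mafMin` are removed first.
#' Within each chromosome a sliding window (`ldWindowBp` wide, advanced by
#' `ldStepBp`) is then scanned and, for every pair of retained markers in a
#' window with squared Pearson correlation r2 above `ldR2Max`, the
#' later-position marker is dropped (greedy, earlier marker kept).
#' Chromosomes are pruned independently. Allele frequency is computed from
#' the signed codes as (mean(code) + 1) / 2.
#'
#' @param x a [GenotypeData] in signed coding with no missing entries.
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @param ldWindowBp window size (default 2000; base pairs, or marker count
#'   when `windowType = "count"`).
#' @param ldStepBp step size (default 1000; same units as `ldWindowBp`).
#' @param ldR2Max maximum tolerated r2 within a window (default 0.5).
#' @param windowType `"bp"` windows over positions (default) or `"count"`
#'   windows over marker indices (PLINK `--indep-pairwise` style).
#' @return The filtered [GenotypeData] (possibly with zero markers, with a
#'   warning).
#' @export
applyQC <- function(x, mafMin = 0.01, ldWindowBp = 2000L, ldStepBp = 1000L,
                    ldR2Max = 0.5, windowType = c("bp", "count")) {
  windowType <- match.arg(windowType)
  stopifnot(is(x, "GenotypeData"))
  if (!identical(genoCoding(x), "signed")) {
    stopf("applyQC requires signed coding; run encodeGenotypes() first")
  }
  if (anyNA(assay(x, "codes"))) {
    stopf("missing entries present; run encodeGenotypes() first")
  }
  if (mafMin < 0 || mafMin > 0.5) stopf("mafMin must lie in [0, 0.5]")
  if (ldStepBp > ldWindowBp) stopf("ldStepBp must not exceed ldWindowBp")
  X <- genoMatrix(x)
  pAlt <- (colMeans(X) + 1) / 2
  maf <- pmin(pAlt, 1 - pAlt)
  keep <- maf >= mafMin
  info <- markerInfo(x)
  keep <- ld_prune(X, info, keep, ldWindowBp, ldStepBp, ldR2Max, windowType)
  if (!any(keep)) {
    warnf("all markers removed by QC")
  }
  x[which(keep), ]
}

# Greedy within-window pruning; returns updated logical keep vector.
ld_prune <- function(X, info, keep, windowBp, stepBp, r2max, windowType) {
  for (chr in unique(info$chrom)) {
    on_chr <- which(info$chrom == chr)
    if (windowType == "bp") {
      pos <- info$pos[on_chr]
      starts <- seq(min(pos), max(pos), by = stepBp)
      windows <- lapply(starts, function(s) {
        on_chr[pos >= s & pos < s + windowBp]
      })
    } else {
      n <- length(on_chr)
      starts <- seq(1L, n, by = stepBp)
      windows <- lapply(starts, function(s) {
        on_chr[s:min(n, s + windowBp - 1L)]
      })
    }
    for (w in windows) {
      w <- w[keep[w]]
      if (length(w) < 2L) next
      r <- suppressWarnings(cor(X[, w, drop = FALSE]))
      r[is.na(r)] <- 0
      r2 <- r * r
      for (i in seq_along(w)) {
        if (!keep[w[i]]) next
        for (j in seq_along(w)) {
          if (j > i && keep[w[j]] && r2[i, j] > r2max) keep[w[j]] <- FALSE
        }
      }
    }
  }
  keep
}
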