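#' GenotypeData: sample-by-marker genotype codes with marker metadata
#'
#' `GenotypeData` extends [SummarizedExperiment::RangedSummarizedExperiment]:
#' markers are rows (with a `GRanges` carrying chromosome, position, ref and
#' alt alleles) and samples are columns. The single assay `"codes"` holds
#' numeric genotype codes. Two codings are used, recorded in
#' `metadata(x)$coding`:
#'
#' * `"dosage"` — raw alt-allele dosage in \{0, 1, 2\} with `NA` for missing
#'   calls, as produced by [readGenotypes()] from a VCF;
#' * `"signed"` — the model-ready coding \{1, 0, -1\} (homozygous alt = 1,
#'   homozygous ref = -1, heterozygous = 0, missing imputed to 0), as
#'   produced by [encodeGenotypes()].
#'
#' @slot .. inherited from `RangedSummarizedExperiment`.
#'
#' @param codes numeric matrix, samples x markers (transposed internally to
#'   the markers-x-samples assay convention).
#' @param markers `data.frame` with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`, one row per marker, in the column order of `codes`.
#' @param samples character vector of sample identifiers; defaults to the
#'   row names of `codes`.
#' @param coding `"signed"` or `"dosage"`.
#'
#' @return A `GenotypeData` object with markers sorted by (chromosome,
#'   position).
#'
#' @examples
#' codes <- rbind(s1 = c(1, -1, 0), s2 = c(0, 1, -1))
#' mk <- data.frame(id = paste0("m", 1:3), chrom = "1",
#'                  pos = c(100L, 300L, 900L), ref = "A", alt = "T")
#' gd <- GenotypeData(codes, mk)
#' genoMatrix(gd)
#'
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors metadata metadata<-
#' @export GenotypeData
#' @exportClass GenotypeData
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

GenotypeData <- function(codes, markers, samples = rownames(codes),
                         coding = c("signed", "dosage")) {
  coding <- match.arg(coding)
  codes <- as.matrix(codes)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(codes)))
  required <- c("id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols)) {
    stopf("marker metadata lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(markers) != ncol(codes)) {
    stopf("marker metadata has %d rows but codes has %d columns",
          nrow(markers), ncol(codes))
  }
  ord <- order(as.character(markers$chrom), markers$pos)
  markers <- markers[ord, , drop = FALSE]
  codes <- codes[, ord, drop = FALSE]
  dup <- duplicated(paste(markers$chrom, markers$pos))
  if (any(dup)) {
    stopf("duplicated (chromosome, position): %s",
          paste(head(markers$id[dup], 3), collapse = ", "))
  }
  gr <- GRanges(
    seqnames = as.character(markers$chrom),
    ranges = IRanges(start = as.integer(markers$pos), width = 1L),
    id = as.character(markers$id),
    ref = as.character(markers$ref),
    alt = as.character(markers$alt)
  )
  names(gr) <- as.character(markers$id)
  a <- t(codes)
  dimnames(a) <- NULL
  se <- SummarizedExperiment(
    assays = list(codes = a),
    rowRanges = gr,
    metadata = list(coding = coding)
  )
  colnames(se) <- as.character(samples)
  obj <- new("GenotypeData", se)
  validObject(obj)
  obj
}

setValidity("GenotypeData", function(object) {
  if (!"codes" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'codes' is required")
  }
  a <- assay(object, "codes")
  if (!is.numeric(a)) return("codes must be numeric")
  coding <- metadata(object)$coding %||% "signed"
  vals <- a[!is.na(a)]
  if (identical(coding, "signed")) {
    if (length(vals) && !all(vals %in% c(-1, 0, 1))) {
      return("signed codes must lie in {1, 0, -1}")
    }
  } else if (identical(coding, "dosage")) {
    if (length(vals) && !all(vals %in% c(0, 1, 2))) {
      return("dosage codes must lie in {0, 1, 2} or NA")
    }
  } else {
    return(sprintf("unknown coding '%s'", coding))
  }
  pos <- GenomicRanges::start(rowRanges(object))
  chr <- as.character(GenomicRanges::seqnames(rowRanges(object)))
  for (c1 in unique(chr)) {
    p <- pos[chr == c1]
    if (is.unsorted(p, strictly = TRUE)) {
      return(sprintf("positions not strictly increasing on chromosome %s", c1))
    }
  }
  TRUE
})

#' Accessors for GenotypeData
#'
#' `genoMatrix()` returns the samples-x-markers numeric code matrix (the
#' orientation all model code consumes); `markerInfo()` returns the marker
#' metadata as a `data.frame` (id, chrom, pos, ref, alt); `genoCoding()`
#' returns `"signed"` or `"dosage"`.
#'
#' @param x a `GenotypeData`.
#' @return see description.
#' @examples
#' gd <- simulateGenotypes(nSamples = 4, nMarkers = 6, seed = 1)$genotypes
#' dim(genoMatrix(gd))
#' head(markerInfo(gd))
#' @export
genoMatrix <- function(x) {
  stopifnot(is(x, "GenotypeData"))
  t(assay(x, "codes"))
}

#' @rdname genoMatrix
#' @export
markerInfo <- function(x) {
  stopifnot(is(x, "GenotypeData"))
  gr <- rowRanges(x)
  data.frame(
    id = gr$id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    ref = gr$ref,
    alt = gr$alt,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' @rdname genoMatrix
#' @export
genoCoding <- function(x) {
  stopifnot(is(x, "GenotypeData"))
  metadata(x)$coding %||% "signed"
}

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d samples x %d markers (%s coding)\n",
              ncol(object), nrow(object), genoCoding(object)))
  chr <- as.character(GenomicRanges::seqnames(rowRanges(object)))
  cat(sprintf("chromosomes: %s\n", paste(unique(chr), collapse = ", ")))
  if (anyNA(assay(object, "codes"))) {
    cat(sprintf("missing calls: %d\n", sum(is.na(assay(object, "codes")))))
  }
  invisible(NULL)
})
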