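#' @import S4Vectors
#' @import GenomicRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
#' @importFrom IRanges IRanges IntegerList
NULL

#' GenotypeMatrix: allele counts with per-variant metadata
#'
#' Thin extension of [SummarizedExperiment::RangedSummarizedExperiment-class]
#' holding one assay `"counts"` (variants in rows, individuals in columns,
#' values 0/1/2 copies of the alternate allele, `NA` for missing calls) and a
#' variant-level `GRanges` with `ref`, `alt`, `maf` and `monomorphic` columns.
#' The minor allele frequency is always the in-sample frequency
#' `min(f, 1 - f)` computed over non-missing calls.
#'
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  cnt <- SummarizedExperiment::assay(object, "counts")
  ok <- cnt[!is.na(cnt)]
  if (length(ok) && !all(ok %in% c(0, 1, 2)))
    return("genotype counts must be 0, 1, 2 or NA")
  rr <- SummarizedExperiment::rowRanges(object)
  need <- c("ref", "alt", "maf")
  if (!all(need %in% names(S4Vectors::mcols(rr))))
    return("variant metadata must contain ref, alt and maf")
  maf <- S4Vectors::mcols(rr)$maf
  if (nrow(cnt)) {
    rec <- .computeMAF(cnt)
    if (max(abs(rec - maf), na.rm = TRUE) > 1e-12)
      return("stored maf does not match allele counts")
    pos <- GenomicRanges::start(rr)
    for (ch in unique(as.character(GenomicRanges::seqnames(rr)))) {
      p <- pos[as.character(GenomicRanges::seqnames(rr)) == ch]
      if (is.unsorted(p)) return("variant positions must be non-decreasing per chromosome")
    }
  }
  TRUE
})

# MAF per variant row from a variants x samples count matrix
.computeMAF <- function(cnt) {
  f <- unname(rowMeans(cnt, na.rm = TRUE)) / 2
  f[is.nan(f)] <- 0
  pmin(f, 1 - f)
}

#' Construct a GenotypeMatrix
#'
#' @param counts integer matrix of alternate-allele counts, individuals in
#'   rows and variants in columns (the natural orientation for association
#'   work); transposed internally to the assay convention.
#' @param variants `GRanges` with one range per variant (1-based positions)
#'   and optional `ref`/`alt` metadata columns.
#' @param samples character vector of individual ids; defaults to the row
#'   names of `counts`.
#' @return A [GenotypeMatrix-class] object. Variants are sorted by
#'   chromosome and position.
#' @export
GenotypeMatrix <- function(counts, variants, samples = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(counts)))
  stopifnot2(length(variants) == ncol(counts),
             "one GRanges entry per variant column required")
  mc <- S4Vectors::mcols(variants)
  if (is.null(mc$ref)) mc$ref <- rep("A", length(variants))
  if (is.null(mc$alt)) mc$alt <- rep("T", length(variants))
  S4Vectors::mcols(variants) <- mc
  if (is.null(names(variants)))
    names(variants) <- paste0("var", seq_along(variants))
  cnt <- t(counts)
  rownames(cnt) <- names(variants)
  colnames(cnt) <- samples
  o <- order(as.character(GenomicRanges::seqnames(variants)),
             GenomicRanges::start(variants))
  variants <- variants[o]
  cnt <- cnt[o, , drop = FALSE]
  maf <- .computeMAF(cnt)
  S4Vectors::mcols(variants)$maf <- maf
  S4Vectors::mcols(variants)$monomorphic <- maf == 0
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt), rowRanges = variants)
  methods::new("GenotypeMatrix", se)
}

#' @describeIn GenotypeMatrix-class individual ids (assay columns)
#' @param x a GenotypeMatrix
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) colnames(x))

#' Allele-count matrix in individuals x variants orientation
#'
#' @param x a [GenotypeMatrix-class]
#' @param impute replace missing calls by the variant mean count `2 * maf`
#'   (preserves the allele frequency); the default keeps `NA`s.
#' @return numeric matrix, individuals in rows.
#' @export
setGeneric("genotypes", function(x, impute = FALSE) standardGeneric("genotypes"))

#' @export
setMethod("genotypes", "GenotypeMatrix", function(x, impute = FALSE) {
  cnt <- SummarizedExperiment::assay(x, "counts")
  if (impute && anyNA(cnt)) {
    fill <- rowMeans(cnt, na.rm = TRUE) # 2 * alt frequency per variant
    idx <- which(is.na(cnt), arr.ind = TRUE)
    cnt[idx] <- fill[idx[, 1]]
  }
  t(cnt)
})

#' Variant-level ranges and metadata
#' @param x a GenotypeMatrix
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))

#' @export
setMethod("variantRanges", "GenotypeMatrix", function(x)
  SummarizedExperiment::rowRanges(x))

#' In-sample minor allele frequencies
#' @param x a GenotypeMatrix
#' @export
setGeneric("variantMAF", function(x) standardGeneric("variantMAF"))

#' @export
setMethod("variantMAF", "GenotypeMatrix", function(x)
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$maf)

#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", ncol(object), "individuals x", nrow(object),
      "variants\n")
  maf <- variantMAF(object)
  if (length(maf))
    cat("  MAF range:", format(min(maf), digits = 3), "-",
        format(max(maf), digits = 3), "|", sum(maf == 0), "monomorphic\n")
})

#' GeneTable: gene intervals joined to variant columns
#'
#' Wraps a named `GRanges` of gene intervals whose `variantIndices` metadata
#' column (an `IntegerList`) records, for each gene, the column indices of its
#' member variants in a companion [GenotypeMatrix-class].
#'
#' @export
setClass("GeneTable", representation(genes = "GRanges"))

setValidity("GeneTable", function(object) {
  gr <- object@genes
  if (length(gr)) {
    if (is.null(names(gr)) || anyDuplicated(names(gr)))
      return("genes must have unique names")
    vi <- S4Vectors::mcols(gr)$variantIndices
    if (is.null(vi)) return("variantIndices metadata column required")
    for (v in as.list(vi)) {
      if (length(v) > 1 && any(diff(v) <= 0))
        return("variantIndices must be strictly increasing")
      if (length(v) && any(v < 1)) return("variant indices must be positive")
    }
  }
  TRUE
})

#' @param genes named `GRanges` with an `IntegerList` column `variantIndices`
#' @rdname GeneTable-class
#' @export
GeneTable <- function(genes) methods::new("GeneTable", genes = genes)

#' @export
setMethod("length", "GeneTable", function(x) length(x@genes))

#' Gene identifiers
#' @param x a GeneTable
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setMethod("geneIds", "GeneTable", function(x) names(x@genes))

#' Per-gene variant column indices
#' @param x a GeneTable
#' @export
setGeneric("variantIndices", function(x) standardGeneric("variantIndices"))

#' @export
setMethod("variantIndices", "GeneTable", function(x)
  S4Vectors::mcols(x@genes)$variantIndices)

#' Gene interval ranges
#' @param x a GeneTable
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @export
setMethod("geneRanges", "GeneTable", function(x) x@genes)

#' @export
setMethod("[", "GeneTable", function(x, i, j, ..., drop = TRUE)
  GeneTable(x@genes[i]))

#' @export
setMethod("show", "GeneTable", function(object) {
  k <- lengths(variantIndices(object))
  cat("GeneTable:", length(object), "genes")
  if (length(object))
    cat("; variants per gene", min(k), "-", max(k))
  cat("\n")
})

#' KinshipMatrix: SNP-estimated genetic relationship matrix
#'
#' Symmetric relatedness matrix over individuals on the genetic-relationship
#' scale (self-relatedness near 1, full sibs near 0.5), with the eigenvalue
#' floor used when forming its inverse square root.
#'
#' @export
setClass("KinshipMatrix",
         representation(sigma = "matrix", eigenFloor = "numeric"))

setValidity("KinshipMatrix", function(object) {
  s <- object@sigma
  if (nrow(s) != ncol(s)) return("sigma must be square")
  if (nrow(s) && max(abs(s - t(s))) > 1e-10) return("sigma must be symmetric")
  if (nrow(s) && any(diag(s) <= 0)) return("diagonal entries must be positive")
  if (object@eigenFloor <= 0) return("eigenFloor must be > 0")
  TRUE
})

#' @param sigma symmetric relatedness matrix with sample-id dimnames
#' @param eigenFloor smallest eigenvalue retained during inversion
#' @rdname KinshipMatrix-class
#' @export
KinshipMatrix <- function(sigma, eigenFloor = 1e-6) {
  sigma <- (sigma + t(sigma)) / 2
  methods::new("KinshipMatrix", sigma = sigma, eigenFloor = eigenFloor)
}

#' Relatedness matrix of a KinshipMatrix
#' @param x a KinshipMatrix
#' @export
setGeneric("kinship", function(x) standardGeneric("kinship"))

#' @export
setMethod("kinship", "KinshipMatrix", function(x) x@sigma)

#' @export
setMethod("sampleIds", "KinshipMatrix", function(x) rownames(x@sigma))

#' @export
setMethod("show", "KinshipMatrix", function(object) {
  n <- nrow(object@sigma)
  cat("KinshipMatrix:", n, "individuals; mean diagonal",
      format(mean(diag(object@sigma)), digits = 3), "\n")
})

#' ExpressionMatrix: probe-level expression over individuals
#'
#' @export
setClass("ExpressionMatrix", representation(values = "matrix"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values needs sample row names and probe column names")
  if (ncol(v) && any(colSums(!is.na(v)) == 0))
    return("all-missing probe columns are not allowed")
  TRUE
})

#' @param values numeric matrix, individuals in rows, probes in columns
#' @rdname ExpressionMatrix-class
#' @export
ExpressionMatrix <- function(values) {
  methods::new("ExpressionMatrix", values = as.matrix(values))
}

#' Expression values (individuals x probes)
#' @param x an ExpressionMatrix
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' Probe identifiers
#' @param x an ExpressionMatrix
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @export
setMethod("probeIds", "ExpressionMatrix", function(x) colnames(x@values))

#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) rownames(x@values))

#' @export
setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix:", nrow(object@values), "individuals x",
      ncol(object@values), "probes\n")
})

#' TransformedPhenotype: decorrelated (and optionally residualized) trait
#'
#' Holds the phenotype after pre-multiplication by the inverse square root of
#' the kinship matrix, under which individuals are exchangeable.
#'
#' @export
setClass("TransformedPhenotype",
         representation(values = "numeric", residualized = "logical",
                        measurement = "character", h2 = "numeric"),
         prototype(h2 = NA_real_))

setValidity("TransformedPhenotype", function(object) {
  if (any(!is.finite(object@values))) return("values must be finite")
  if (is.null(names(object@values))) return("values must carry sample ids")
  TRUE
})

#' @param values named numeric vector of transformed phenotype values
#' @param residualized whether stratification axes have been regressed out
#' @param measurement source measurement name
#' @rdname TransformedPhenotype-class
#' @export
TransformedPhenotype <- function(values, residualized = FALSE,
                                 measurement = "trait") {
  methods::new("TransformedPhenotype", values = values,
               residualized = residualized, measurement = measurement)
}

#' Numeric values of a TransformedPhenotype
#' @param x a TransformedPhenotype
#' @export
setGeneric("phenoValues", function(x) standardGeneric("phenoValues"))

#' @export
setMethod("phenoValues", "TransformedPhenotype", function(x) x@values)

#' @export
setMethod("sampleIds", "TransformedPhenotype", function(x) names(x@values))

#' @export
setMethod("show", "TransformedPhenotype", function(object) {
  cat("TransformedPhenotype (", object@measurement, "): ",
      length(object@values), " individuals; residualized: ",
      object@residualized, "\n", sep = "")
})

#' GeneTestResult: outcome of the sequential sum test for one gene
#'
#' @export
setClass("GeneTestResult",
         representation(gene = "character", k = "integer",
                        statistic = "numeric", pValue = "numeric",
                        signs = "numeric", vWeights = "numeric",
                        B = "integer", seed = "integer"))

setValidity("GeneTestResult", function(object) {
  if (object@pValue <= 0 || object@pValue > 1) return("pValue must lie in (0, 1]")
  b <- object@pValue * (object@B + 1) - 1
  if (abs(b - round(b)) > 1e-9 || round(b) < 0 || round(b) > object@B)
    return("pValue must equal (b + 1) / (B + 1) for an exceedance count b")
  if (!all(object@signs %in% c(-1, 0, 1)))
    return("signs must be -1, 0 or +1")
  if (length(object@signs) != object@k) return("signs must have length k")
  TRUE
})

#' @export
setMethod("show", "GeneTestResult", function(object) {
  cat("GeneTestResult ", object@gene, ": k = ", object@k,
      ", statistic = ", format(object@statistic, digits = 4),
      ", p = ", format(object@pValue, digits = 4),
      " (B = ", object@B, ")\n", sep = "")
  cat("  signs:", paste(sprintf("%+d", as.integer(object@signs)),
                        collapse = " "), "\n")
})

#' p-value of a GeneTestResult
#' @param x a GeneTestResult
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @export
setMethod("pValue", "GeneTestResult", function(x) x@pValue)

#' Test statistic of a GeneTestResult
#' @param x a GeneTestResult
#' @export
setGeneric("testStatistic", function(x) standardGeneric("testStatistic"))

#' @export
setMethod("testStatistic", "GeneTestResult", function(x) x@statistic)

#' Selected variant signs of a GeneTestResult
#' @param x a GeneTestResult
#' @export
setGeneric("variantSigns", function(x) standardGeneric("variantSigns"))

#' @export
setMethod("variantSigns", "GeneTestResult", function(x) x@signs)
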