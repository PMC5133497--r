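#' Read genotypes from a VCF file
#'
#' Parses GT fields of a VCF 4.x file into a [GenotypeMatrix-class] of
#' alternate-allele counts. Sites with more than one ALT allele are rejected
#' unless `splitMultiallelic = TRUE`, in which case each ALT allele becomes
#' its own biallelic pseudo-variant whose count is the number of copies of
#' that allele. MAF is computed in the analyzed sample set from non-missing
#' calls as `min(f, 1 - f)`.
#'
#' @param path VCF file (plain or bgzipped)
#' @param samples optional character vector restricting (and ordering) the
#'   individuals; an error lists any requested id absent from the file
#' @param splitMultiallelic split multi-ALT records instead of rejecting them
#' @return a [GenotypeMatrix-class]
#' @export
readVCFGenotypes <- function(path, samples = NULL, splitMultiallelic = FALSE) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) stop("VCF contains no variant records")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt))
    if (length(missing))
      stop("samples absent from VCF: ", paste(missing, collapse = ", "),
           call. = FALSE)
    gt <- gt[, samples, drop = FALSE]
  }
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi) && !splitMultiallelic)
    stop(sum(multi), " multiallelic record(s) found (first at ",
         fix[which(multi)[1], "CHROM"], ":", fix[which(multi)[1], "POS"],
         "); rerun with splitMultiallelic = TRUE or normalize upstream",
         call. = FALSE)

  # allele-count lookup computed once per distinct GT string
  norm <- gsub("|", "/", gt, fixed = TRUE)
  u <- unique(as.vector(norm))
  countIn <- function(allele) {
    val <- vapply(strsplit(u, "/", fixed = TRUE), function(p) {
      if (!length(p) || anyNA(p) || any(p == ".")) return(NA_real_)
      sum(p == allele)
    }, numeric(1))
    matrix(val[match(norm, u)], nrow = nrow(norm))
  }

  altList <- strsplit(alt, ",", fixed = TRUE)
  nAlt <- lengths(altList)
  rowIdx <- rep(seq_along(nAlt), nAlt)          # expanded record index
  alleleIdx <- unlist(lapply(nAlt, seq_len))
  countsByAllele <- lapply(seq_len(max(nAlt)), function(a)
    countIn(as.character(a)))
  counts <- matrix(NA_real_, length(rowIdx), ncol(gt))
  for (a in seq_len(max(nAlt))) {
    sel <- alleleIdx == a
    counts[sel, ] <- countsByAllele[[a]][rowIdx[sel], , drop = FALSE]
  }

  altVec <- unlist(altList)
  ids <- fix[rowIdx, "ID"]
  auto <- is.na(ids) | ids == "."
  ids[auto] <- paste0(fix[rowIdx, "CHROM"], ":", fix[rowIdx, "POS"],
                      "_", altVec)[auto]
  ids[!auto & nAlt[rowIdx] > 1] <-
    paste0(ids, "_", altVec)[!auto & nAlt[rowIdx] > 1]
  variants <- GenomicRanges::GRanges(
    fix[rowIdx, "CHROM"],
    IRanges::IRanges(as.integer(fix[rowIdx, "POS"]), width = 1),
    ref = fix[rowIdx, "REF"], alt = altVec)
  names(variants) <- ids
  GenotypeMatrix(t(counts), variants, samples = colnames(gt))
}

#' Read gene intervals from a BED file
#'
#' BED coordinates are 0-based half-open; the returned `GRanges` follows the
#' 1-based closed convention of `rtracklayer::import`. When a
#' [GenotypeMatrix-class] is supplied the genes are joined to its variants and
#' a [GeneTable-class] is returned.
#'
#' @param path BED file with at least 4 columns (chrom, start, end, name)
#' @param geno optional [GenotypeMatrix-class] to join against
#' @return `GRanges` of genes, or a [GeneTable-class] when `geno` is given
#' @export
readGeneAnnotation <- function(path, geno = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || anyNA(nm))
    stop("BED file must carry gene names in column 4", call. = FALSE)
  if (anyDuplicated(nm)) {
    dup <- unique(nm[duplicated(nm)])
    stop("duplicate gene names in BED: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  names(gr) <- nm
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (is.null(geno)) gr else assignVariantsToGenes(gr, geno)
}

#' Join gene intervals to the variants of a GenotypeMatrix
#'
#' A variant at 1-based position `pos` belongs to a gene whose BED interval
#' is `[start, end)` (0-based half-open) when `start <= pos - 1 < end`, i.e.
#' when the positions overlap in the 1-based closed system used here.
#'
#' @param genes named `GRanges` of gene intervals (1-based closed)
#' @param geno a [GenotypeMatrix-class]
#' @return a [GeneTable-class]; genes without member variants keep an empty
#'   index vector
#' @export
assignVariantsToGenes <- function(genes, geno) {
  stopifnot2(!is.null(names(genes)), "genes must be named")
  hits <- GenomicRanges::findOverlaps(variantRanges(geno), genes,
                                      ignore.strand = TRUE)
  idx <- split(S4Vectors::queryHits(hits),
               factor(S4Vectors::subjectHits(hits), seq_along(genes)))
  idx <- lapply(idx, function(v) sort(unique(v)))
  S4Vectors::mcols(genes)$variantIndices <- IRanges::IntegerList(idx)
  GeneTable(genes)
}

#' Read a long-format phenotype table
#'
#' Expected columns: `individual`, `visit`, `measurement`, `value`.
#'
#' @param path TSV file
#' @return data.frame
#' @export
readPhenotypeTable <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "visit", "measurement", "value")
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  key <- paste(ph$individual, ph$visit, ph$measurement)
  if (anyDuplicated(key))
    stop("duplicate (individual, visit, measurement) records in ", path)
  ph
}

#' Average a measurement over visits
#'
#' The per-individual summary phenotype is the arithmetic mean of the
#' measurement over all visits with a non-missing value. Individuals with no
#' usable value are dropped with a warning.
#'
#' @param pheno long-format phenotype data.frame
#'   (individual/visit/measurement/value)
#' @param measurement measurement name to summarize
#' @return named numeric vector over individuals
#' @export
averageVisits <- function(pheno, measurement) {
  if (!nrow(pheno)) stop("empty phenotype table", call. = FALSE)
  sub <- pheno[pheno$measurement == measurement, , drop = FALSE]
  if (!nrow(sub)) stop("no records for measurement '", measurement, "'",
                       call. = FALSE)
  means <- tapply(sub$value, sub$individual,
                  function(v) mean(v, na.rm = TRUE))
  means <- means[unique(sub$individual)]    # keep first-appearance order
  bad <- !is.finite(means)
  if (any(bad)) {
    warning(sum(bad), " individual(s) dropped: no non-missing '",
            measurement, "' value", call. = FALSE)
    means <- means[!bad]
  }
  out <- as.numeric(means)
  names(out) <- names(means)
  out
}

#' Read an expression matrix from TSV
#'
#' First column holds sample ids, remaining columns one probe each. Missing
#' values are kept by default (each weight regression then uses the samples
#' observed for its probe) or imputed to the probe mean.
#'
#' @param path TSV file
#' @param missing `"keep"` or `"probeMean"`
#' @return an [ExpressionMatrix-class]
#' @export
readExpressionMatrix <- function(path, missing = c("keep", "probeMean")) {
  missing <- match.arg(missing)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) stop("expression TSV needs sample-id + >=1 probe column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  if (missing == "probeMean" && anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2]]
  }
  ExpressionMatrix(m)
}

#' Write per-gene results to TSV
#'
#' Columns: `gene`, `chrom`, `n_rare_variants`, then for each phenotype
#' `<ph>_raw_p`, `<ph>_weight`, `<ph>_adjusted_p` (plus any flag columns
#' present). Numbers print with 6 significant digits, or fixed 3 decimals in
#' display mode.
#'
#' @param results data.frame of per-gene results
#' @param path output file
#' @param display3 round numeric columns to 3 decimals for display
#' @return `path`, invisibly
#' @export
writeResults <- function(results, path, display3 = FALSE) {
  out <- results
  num <- vapply(out, is.numeric, logical(1)) &
    !names(out) %in% c("n_rare_variants", "chrom")
  for (j in which(num)) {
    out[[j]] <- if (display3) sprintf("%.3f", out[[j]])
                else formatC(out[[j]], digits = 6, format = "g")
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write results to '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read back a results TSV written by [writeResults()]
#' @param path TSV file
#' @return data.frame with numeric columns restored
#' @export
readResults <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
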