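#' Filter genes to the analyzable rare-variant set
#'
#' Restricts every gene to its rare variants — polymorphic in the analyzed
#' sample with `0 < MAF < mafThreshold` — and keeps the genes whose rare
#' count lies within `[minVariants, maxVariants]` (default 2-49, i.e. more
#' than 1 and fewer than 50).
#'
#' @param genes a [GeneTable-class] joined to `geno`
#' @param geno the companion [GenotypeMatrix-class]
#' @param mafThreshold rare-variant MAF bound (default 0.01)
#' @param minVariants minimum rare variants per gene (default 2)
#' @param maxVariants maximum rare variants per gene (default 49)
#' @param verbose log kept/dropped counts
#' @return filtered [GeneTable-class] whose `variantIndices` contain only
#'   rare variants
#' @export
filterGenes <- function(genes, geno, mafThreshold = 0.01, minVariants = 2,
                        maxVariants = 49, verbose = TRUE) {
  stopifnot2(mafThreshold > 0 && mafThreshold <= 0.5,
             "mafThreshold must lie in (0, 0.5]")
  stopifnot2(minVariants >= 2 && maxVariants <= 49,
             "variant-count bounds must lie within [2, 49]")
  maf <- variantMAF(geno)
  rare <- which(maf > 0 & maf < mafThreshold)
  gr <- geneRanges(genes)
  idx <- lapply(as.list(variantIndices(genes)), intersect, rare)
  keep <- lengths(idx) >= minVariants & lengths(idx) <= maxVariants
  S4Vectors::mcols(gr)$variantIndices <- IRanges::IntegerList(idx)
  if (verbose)
    message(sum(keep), " of ", length(genes), " genes kept (",
            length(rare), " rare variants at MAF < ", mafThreshold, ")")
  GeneTable(gr[keep])
}

# align genotype, expression and phenotype vectors on shared sample ids
.alignSamples <- function(geno, expr, phenos) {
  sets <- c(list(genotypes = sampleIds(geno),
                 expression = sampleIds(expr)),
            lapply(phenos, names))
  ids <- Reduce(intersect, sets)
  if (!length(ids)) {
    ex <- vapply(sets, function(s) paste(utils::head(s, 2), collapse = ","),
                 character(1))
    stop("no individuals shared across inputs; leading ids per input: ",
         paste(names(sets), ex, sep = "=", collapse = "; "), call. = FALSE)
  }
  dropped <- sum(lengths(sets) - length(ids))
  if (dropped)
    message("complete-case alignment: ", length(ids),
            " individuals analyzed")
  ids
}

#' Run the full weighted rare-variant analysis on in-memory objects
#'
#' The end-to-end procedure: complete-case sample alignment, kinship
#' estimation from common markers, phenotype decorrelation
#' (`Y* = Sigma^{-1/2} Y`), residualization on the leading stratification
#' axes, gene filtering, the sequential sum test with permutation p-values
#' per gene and phenotype, expression-informed weights normalized to mean 1
#' within each phenotype's tested gene set, and weight-adjusted p-values
#' with dual significance flags.
#'
#' @param geno a [GenotypeMatrix-class] (rare variants and common markers)
#' @param genes gene intervals: a named `GRanges` or a [GeneTable-class]
#' @param expr an [ExpressionMatrix-class]
#' @param phenos named list of per-individual summary phenotype vectors
#'   (named by individual id), one entry per measurement
#' @param mafThreshold,minVariants,maxVariants gene filter, see
#'   [filterGenes()]
#' @param B permutations per gene (default 500)
#' @param K stratification axes (default 3)
#' @param alpha significance level (default 0.05)
#' @param seed root RNG seed; per-gene streams are derived from it
#' @param kinshipMafMin MAF bound for the kinship marker set (default 0.05)
#' @param verbose log progress
#' @return list with `results` (per-gene data.frame, sorted by best adjusted
#'   p), `weights` (per-phenotype weight decompositions), `kin`, `axes` and
#'   `genes` (the filtered [GeneTable-class])
#' @export
analyzeDataset <- function(geno, genes, expr, phenos,
                           mafThreshold = 0.01, minVariants = 2,
                           maxVariants = 49, B = 500, K = 3, alpha = 0.05,
                           seed = 1, kinshipMafMin = 0.05, verbose = TRUE) {
  stopifnot2(length(phenos) >= 1, "at least one phenotype required")
  stopifnot2(!is.null(names(phenos)), "phenos must be a named list")
  ids <- .alignSamples(geno, expr, phenos)
  # rebuild so per-variant MAF reflects the analyzed sample set
  sub <- geno[, ids]
  geno <- GenotypeMatrix(genotypes(sub), variantRanges(sub), samples = ids)
  E <- exprValues(expr)[ids, , drop = FALSE]

  # relatedness and stratification both come from the common-marker panel
  commonGm <- geno[variantMAF(geno) > kinshipMafMin, ]
  if (!nrow(commonGm))
    stop("no common markers (MAF > ", kinshipMafMin,
         ") available for kinship estimation")
  kin <- estimateKinship(commonGm, mafMin = kinshipMafMin)
  axes <- stratificationAxes(commonGm, K = K)
  resid <- lapply(names(phenos), function(ph) {
    y <- phenos[[ph]][ids]
    yt <- transformPhenotype(y, kin, measurement = ph)
    residualize(yt, axes)
  })
  names(resid) <- names(phenos)

  if (!methods::is(genes, "GeneTable"))
    genes <- assignVariantsToGenes(genes, geno)
  genes <- filterGenes(genes, geno, mafThreshold, minVariants, maxVariants,
                       verbose = verbose)
  if (!length(genes)) stop("no genes pass the rare-variant filter")

  Gall <- genotypes(geno, impute = TRUE)
  idx <- as.list(variantIndices(genes))
  gids <- geneIds(genes)
  chrom <- as.character(GenomicRanges::seqnames(geneRanges(genes)))

  out <- data.frame(gene = gids, chrom = chrom,
                    n_rare_variants = lengths(idx))
  decomps <- list()
  for (ph in names(phenos)) {
    y <- resid[[ph]]
    rawP <- numeric(length(gids))
    crude <- numeric(length(gids))
    dlist <- vector("list", length(gids))
    for (i in seq_along(gids)) {
      Gg <- Gall[, idx[[i]], drop = FALSE]
      rawP[i] <- pValue(seqASumVS(Gg, y, B = B, seed = seed,
                                  geneId = gids[i]))
      cw <- suppressWarnings(crudeWeight(collapseGeneBurden(Gg), E, y))
      crude[i] <- cw$crude
      dlist[[i]] <- cbind(gene = gids[i], cw$decomposition)
      if (verbose && i %% 50 == 0)
        message(ph, ": ", i, "/", length(gids), " genes tested")
    }
    w <- normalizeWeights(crude)
    adj <- ifelse(w > 0, pmin(1, rawP / w), 1)
    out[[paste0(ph, "_raw_p")]] <- rawP
    out[[paste0(ph, "_weight")]] <- w
    out[[paste0(ph, "_adjusted_p")]] <- adj
    out[[paste0(ph, "_sig_raw")]] <- rawP <= alpha
    out[[paste0(ph, "_sig_adjusted")]] <- adj <= alpha
    decomps[[ph]] <- do.call(rbind, dlist)
  }
  adjCols <- paste0(names(phenos), "_adjusted_p")
  best <- do.call(pmin, out[adjCols])
  out <- out[order(best, out$gene), ]
  rownames(out) <- NULL
  list(results = out, weights = decomps, kin = kin, axes = axes,
       genes = genes)
}

#' Run the pipeline from files on disk
#'
#' Thin file-based front end over [analyzeDataset()]: reads the VCF, BED,
#' expression and phenotype tables, averages each measurement over visits,
#' runs the analysis, and (optionally) writes `results.tsv`,
#' `results_display.tsv` (3-decimal display) and per-phenotype
#' `weights_<ph>.tsv` audit files.
#'
#' @param vcf,bed,expr,pheno input file paths (see the I/O readers)
#' @param phenoNames measurements to analyze (e.g. `c("SBP", "DBP")`)
#' @param outDir optional output directory
#' @param splitMultiallelic passed to [readVCFGenotypes()]
#' @param ... further arguments to [analyzeDataset()]
#' @return the [analyzeDataset()] result list, invisibly when writing
#' @export
runPipeline <- function(vcf, bed, expr, pheno, phenoNames = "SBP",
                        outDir = NULL, splitMultiallelic = FALSE, ...) {
  geno <- readVCFGenotypes(vcf, splitMultiallelic = splitMultiallelic)
  genes <- readGeneAnnotation(bed)
  ex <- readExpressionMatrix(expr)
  ph <- readPhenotypeTable(pheno)
  phenos <- lapply(phenoNames, function(m) averageVisits(ph, m))
  names(phenos) <- phenoNames
  res <- analyzeDataset(geno, genes, ex, phenos, ...)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeResults(res$results, file.path(outDir, "results.tsv"))
    writeResults(res$results, file.path(outDir, "results_display.tsv"),
                 display3 = TRUE)
    for (phn in names(res$weights))
      utils::write.table(res$weights[[phn]],
                         file.path(outDir, paste0("weights_", phn, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(res))
  }
  res
}
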