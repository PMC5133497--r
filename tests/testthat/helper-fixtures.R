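# In-code fixtures shared across the suite; everything is generated, nothing
# is stored on disk.

# small GenotypeMatrix from an explicit counts matrix (individuals x variants)
toyGenotypes <- function(counts, pos = NULL, chrom = "1") {
  m <- ncol(counts)
  pos <- pos %||% seq(100, by = 100, length.out = m)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
  names(gr) <- paste0("v", seq_len(m))
  GenotypeMatrix(counts, gr, samples = rownames(counts) %||%
                   paste0("S", seq_len(nrow(counts))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a VCF text fixture; gt is a variants x samples matrix of GT strings
writeTestVCF <- function(chrom, pos, ref, alt, gt, samples,
                         path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i)
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  path
}

randomSPD <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + diag(n) * 0.5
}

# independent OLS oracle: coefficients and standard errors from the normal
# equations, solved explicitly
olsOracle <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - ncol(X))
  se <- sqrt(diag(solve(XtX)) * s2)
  list(beta = drop(beta), se = se)
}
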