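#' Estimate the genetic relationship matrix from SNP genotypes
#'
#' Standard allele-frequency-standardized GRM:
#' `Sigma_kl = (1/M) * sum_m (g_km - 2 p_m)(g_lm - 2 p_m) / (2 p_m (1 - p_m))`
#' over the `M` variants passing the MAF filter, with `p_m` the in-sample ALT
#' frequency. Missing calls are mean-imputed (`2 p_m`), which contributes zero
#' to the centered cross-products. On this scale self-relatedness is near 1
#' and full sibs near 0.5.
#'
#' @param geno a [GenotypeMatrix-class]
#' @param mafMin keep variants with MAF strictly above this bound (default
#'   0.05: common markers carry the relatedness signal)
#' @param eigenFloor eigenvalue floor recorded for later inversion
#' @return a [KinshipMatrix-class]
#' @export
estimateKinship <- function(geno, mafMin = 0.05, eigenFloor = 1e-6) {
  G <- genotypes(geno, impute = TRUE)
  if (nrow(G) < 2) stop("kinship estimation needs >= 2 individuals")
  p <- colMeans(G) / 2
  keep <- variantMAF(geno) > mafMin & p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic variants pass the MAF filter")
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(G, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = nrow(G))
  sigma <- tcrossprod(Z) / ncol(Z)
  dimnames(sigma) <- list(rownames(G), rownames(G))
  KinshipMatrix(sigma, eigenFloor = eigenFloor)
}

#' Symmetric inverse square root of a kinship matrix
#'
#' Eigendecomposes `Sigma = Q L Q'`, floors the eigenvalues at the matrix's
#' `eigenFloor` (empirical GRMs are near-singular) and returns
#' `Q L^{-1/2} Q'`.
#'
#' @param kin a [KinshipMatrix-class]
#' @return symmetric numeric matrix
#' @export
inverseSqrt <- function(kin) {
  s <- kinship(kin)
  if (max(abs(s - t(s))) > 1e-8) stop("kinship matrix is not symmetric")
  e <- eigen(s, symmetric = TRUE)
  lam <- pmax(e$values, kin@eigenFloor)
  m <- e$vectors %*% (t(e$vectors) / sqrt(lam))
  m <- (m + t(m)) / 2
  dimnames(m) <- dimnames(s)
  m
}

#' Heritability estimate by Haseman-Elston moment regression
#'
#' Regresses the off-diagonal phenotypic cross-products on the corresponding
#' relatedness entries: under a polygenic model
#' `E[(y_i - mu)(y_j - mu)] = sigma_A^2 * Sigma_ij`, so the slope over the
#' phenotypic variance estimates the narrow-sense heritability. Clipped to
#' `[0, 1]`.
#'
#' @param y numeric phenotype vector
#' @param kin a [KinshipMatrix-class]
#' @return heritability estimate in `[0, 1]`
#' @export
estimateHeritability <- function(y, kin) {
  s <- kinship(kin)
  if (length(y) != nrow(s)) stop("phenotype and kinship sizes differ")
  yc <- y - mean(y)
  off <- s
  diag(off) <- 0
  num <- drop(crossprod(yc, off %*% yc)) / 2
  den <- sum(off^2) / 2
  if (den <= 0) return(0)
  sigmaA2 <- num / den
  min(max(sigmaA2 / mean(yc^2), 0), 1)
}

#' Decorrelate a phenotype through the kinship matrix
#'
#' Whitens the phenotype by the inverse square root of its polygenic
#' covariance `h2 * Sigma + (1 - h2) * I`, so that individuals from the
#' same family become exchangeable — the property the permutation test
#' relies on. With `h2 = 1` this is the raw transform
#' `Y* = Sigma^{-1/2} Y`, exact when the phenotypic covariance is
#' proportional to `Sigma` (fully heritable trait); for partially heritable
#' traits that raw transform over-corrects, inducing negative within-family
#' correlation, so by default `h2` is estimated from the data
#' ([estimateHeritability()]). The overall variance scale cancels in
#' permutation inference.
#'
#' @param y named numeric phenotype vector (no missing values; drop and
#'   realign upstream)
#' @param kin a [KinshipMatrix-class] whose sample order matches `y`
#' @param h2 heritability used in the covariance model: `"auto"` (default)
#'   or a fixed value in `[0, 1]` (`1` = raw inverse-root-kinship transform)
#' @param measurement label stored on the result
#' @return a [TransformedPhenotype-class]
#' @export
transformPhenotype <- function(y, kin, h2 = "auto", measurement = "trait") {
  s <- kinship(kin)
  if (length(y) != nrow(s))
    stop("phenotype length ", length(y), " does not match kinship dimension ",
         nrow(s))
  if (anyNA(y)) stop("phenotype contains missing values")
  if (!is.null(names(y)) && !is.null(rownames(s)) &&
      !identical(names(y), rownames(s)))
    stop("sample order of phenotype and kinship matrix differ")
  if (identical(h2, "auto")) h2 <- estimateHeritability(y, kin)
  stopifnot2(is.numeric(h2) && h2 >= 0 && h2 <= 1,
             "h2 must be 'auto' or a number in [0, 1]")
  sy <- h2 * s + diag(1 - h2, nrow(s))
  dimnames(sy) <- dimnames(s)
  ystar <- drop(inverseSqrt(KinshipMatrix(sy, eigenFloor = kin@eigenFloor))
                %*% y)
  names(ystar) <- names(y) %||% rownames(s) %||% paste0("S", seq_along(y))
  out <- TransformedPhenotype(ystar, residualized = FALSE,
                              measurement = measurement)
  out@h2 <- h2
  out
}

#' Leading stratification axes from genome-wide genotypes
#'
#' Classical (Torgerson) multidimensional scaling of Euclidean distances
#' between column-standardized genotype vectors, which equals the top-K
#' principal-component scores. The sign of each axis is fixed by making its
#' largest-magnitude coordinate positive, so results are deterministic.
#'
#' @param geno a [GenotypeMatrix-class]
#' @param K number of axes (default 3)
#' @return numeric matrix, individuals x K, columns mutually orthogonal
#' @export
stratificationAxes <- function(geno, K = 3) {
  G <- genotypes(geno, impute = TRUE)
  n <- nrow(G)
  if (K >= n) stop("K must be smaller than the number of individuals")
  mu <- colMeans(G)
  sds <- sqrt(pmax(colMeans(G^2) - mu^2, 0) * n / (n - 1))
  keep <- sds > 0
  Z <- (G[, keep, drop = FALSE] - rep(mu[keep], each = n)) /
    rep(sds[keep], each = n)
  if (!ncol(Z)) stop("no variants with nonzero variance")
  if (K >= ncol(Z)) stop("K must be smaller than the number of usable variants")
  ax <- stats::cmdscale(stats::dist(Z), k = K)
  for (j in seq_len(ncol(ax))) {
    i <- which.max(abs(ax[, j]))
    if (ax[i, j] < 0) ax[, j] <- -ax[, j]
  }
  rownames(ax) <- rownames(G)
  colnames(ax) <- paste0("axis", seq_len(K))
  ax
}

#' Residualize a transformed phenotype on stratification axes
#'
#' Ordinary least-squares residuals of the decorrelated phenotype on an
#' intercept plus the K axes; the returned vector is orthogonal to every
#' axis. This residual is the quantity all downstream association tests and
#' weight regressions use.
#'
#' @param yt a [TransformedPhenotype-class]
#' @param axes matrix of stratification axes, individuals x K
#' @return named numeric residual vector
#' @export
residualize <- function(yt, axes) {
  y <- phenoValues(yt)
  axes <- as.matrix(axes)
  if (nrow(axes) != length(y)) stop("axes and phenotype sizes differ")
  zero <- apply(axes, 2, function(v) all(v == 0))
  if (any(zero))
    stop("all-zero axis column(s): ",
         paste(colnames(axes)[zero] %||% which(zero), collapse = ", "))
  X <- cbind(`(Intercept)` = 1, axes)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop <- setdiff(colnames(X), colnames(X)[q$pivot[seq_len(q$rank)]])
    stop("collinear axis column(s): ", paste(drop, collapse = ", "))
  }
  r <- stats::lm.fit(X, y)$residuals
  names(r) <- names(y)
  r
}
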