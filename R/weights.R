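#' Collapse a gene's rare variants into a per-individual burden
#'
#' The gene burden `g` is the total rare-allele count across the gene's
#' variant columns (row sums), the single regressor used in both weight
#' regressions.
#'
#' @param G allele-count matrix for one gene, individuals x variants
#' @return named numeric burden vector
#' @export
collapseGeneBurden <- function(G) {
  G <- as.matrix(G)
  if (ncol(G) < 1) stop("gene has no variants")
  rowSums(G)
}

#' Squared Wald statistic
#'
#' `(beta / se)^2`; defined as 0 when the coefficient is inestimable
#' (`se = 0` or a degenerate regression).
#'
#' @param beta coefficient estimate
#' @param se its standard error (>= 0)
#' @return nonnegative scalar
#' @export
waldSquared <- function(beta, se) {
  if (is.na(se) || se < 0) stop("standard error must be nonnegative")
  if (se == 0 || is.na(beta)) return(0)
  (beta / se)^2
}

# OLS of y on cbind(1, x1, x2); squared Wald statistic of the x1 coefficient.
# Complete cases only; degenerate fits yield 0 with a warning.
.pairWald <- function(y, x1, x2, label) {
  ok <- stats::complete.cases(y, x1, x2)
  y <- y[ok]; x1 <- x1[ok]; x2 <- x2[ok]
  if (length(y) < 4) {
    warning("too few complete observations for ", label, "; weight set to 0",
            call. = FALSE)
    return(0)
  }
  fit <- stats::lm(y ~ x1 + x2)
  co <- summary(fit)$coefficients
  if (!"x1" %in% rownames(co)) {
    warning(label, " coefficient inestimable (collinear or constant); ",
            "weight set to 0", call. = FALSE)
    return(0)
  }
  waldSquared(co["x1", "Estimate"], co["x1", "Std. Error"])
}

#' Burden-to-expression weight for one probe
#'
#' Fits `E_j ~ intercept + g + P` by ordinary least squares and returns the
#' squared Wald statistic of the burden coefficient: evidence that the
#' gene's rare-allele load shifts this expression probe, adjusting for the
#' phenotype.
#'
#' @param g gene burden vector ([collapseGeneBurden()])
#' @param Ej expression values for one probe
#' @param P phenotype vector (the decorrelated residual used throughout)
#' @return nonnegative scalar weight component
#' @export
weightGeneExpression <- function(g, Ej, P) {
  stopifnot2(length(g) == length(Ej) && length(g) == length(P),
             "g, Ej and P must be aligned")
  .pairWald(Ej, g, P, "burden-expression")
}

#' Expression-to-phenotype weight for one probe
#'
#' Fits `P ~ intercept + E_j + g` and returns the squared Wald statistic of
#' the expression coefficient: evidence the probe tracks the phenotype,
#' adjusting for the gene burden.
#'
#' @inheritParams weightGeneExpression
#' @return nonnegative scalar weight component
#' @export
weightExpressionPhenotype <- function(Ej, P, g) {
  stopifnot2(length(g) == length(Ej) && length(g) == length(P),
             "g, Ej and P must be aligned")
  .pairWald(P, Ej, g, "expression-phenotype")
}

#' Crude expression-informed weight for one gene
#'
#' For every probe j the two Wald components are multiplied,
#' `w_gE(j) * w_EP(j)`; the crude gene weight is the maximum product over
#' all probes. A probe supports the gene only if the burden moves its
#' expression *and* its expression tracks the phenotype — if either
#' component is zero the product is zero.
#'
#' @param g gene burden vector
#' @param expr an [ExpressionMatrix-class] or numeric matrix
#'   (individuals x probes)
#' @param P phenotype vector
#' @return list with `crude` (the max product), `probe` (argmax probe id)
#'   and `decomposition` (data.frame probe/wGE/wEP/product)
#' @export
crudeWeight <- function(g, expr, P) {
  E <- if (methods::is(expr, "ExpressionMatrix")) exprValues(expr) else
    as.matrix(expr)
  if (ncol(E) < 1) stop("expression matrix has no probes")
  stopifnot2(nrow(E) == length(g) && length(g) == length(P),
             "g, expression and P must be aligned")
  J <- ncol(E)
  probes <- colnames(E) %||% paste0("probe", seq_len(J))

  if (anyNA(E) || anyNA(g) || anyNA(P)) {
    wGE <- vapply(seq_len(J), function(j)
      suppressWarnings(weightGeneExpression(g, E[, j], P)), numeric(1))
    wEP <- vapply(seq_len(J), function(j)
      suppressWarnings(weightExpressionPhenotype(E[, j], P, g)), numeric(1))
  } else {
    n <- length(g)
    X <- cbind(1, g, P)
    qx <- qr(X)
    if (qx$rank < 3) {
      warning("burden and phenotype are degenerate (constant or collinear); ",
              "all probe weights are 0", call. = FALSE)
      wGE <- wEP <- rep(0, J)
    } else {
      # Eq. "E_j ~ 1 + g + P": one shared design, all probes in one solve
      XtXinv <- solve(crossprod(X))
      Bhat <- XtXinv %*% crossprod(X, E)            # 3 x J
      res <- E - X %*% Bhat
      s2 <- colSums(res^2) / (n - 3)
      seG <- sqrt(s2 * XtXinv[2, 2])
      wGE <- ifelse(seG > 0, (Bhat[2, ] / seG)^2, 0)

      # Eq. "P ~ 1 + E_j + g" via Frisch-Waugh: partial out (1, g)
      Z <- cbind(1, g)
      Pz <- stats::lm.fit(Z, P)$residuals
      Ez <- E - Z %*% qr.coef(qr(Z), E)
      ee <- colSums(Ez^2)
      ep <- drop(crossprod(Ez, Pz))
      beta <- ifelse(ee > 1e-12 * n, ep / ee, NA_real_)
      rss <- sum(Pz^2) - ifelse(is.na(beta), 0, beta^2 * ee)
      seE <- sqrt((rss / (n - 3)) / ee)
      wEP <- ifelse(is.na(beta) | seE <= 0, 0, (beta / seE)^2)
    }
  }
  prod <- unname(wGE * wEP)
  best <- which.max(prod)
  list(crude = prod[best], probe = probes[best],
       decomposition = data.frame(probe = probes, wGE = wGE, wEP = wEP,
                                  product = prod))
}

#' Normalize crude weights to mean one
#'
#' Weighted-Bonferroni FWER control requires positive weights averaging one
#' over the tested gene family; crude weights are divided by their mean.
#'
#' @param crude nonnegative crude weights over the analyzed gene set
#' @return weights with mean exactly 1
#' @export
normalizeWeights <- function(crude) {
  if (!length(crude)) stop("no genes to normalize over")
  if (any(crude < 0)) stop("crude weights must be nonnegative")
  m <- mean(crude)
  if (m <= 0) stop("all crude weights are zero; normalization undefined")
  crude / m
}

#' Weight-adjusted p-values
#'
#' `min(1, p / w*)` per gene: genes whose normalized weight exceeds 1 gain
#' smaller adjusted p-values, others are penalized; values exceeding 1 after
#' division are set to 1.
#'
#' @param rawP raw permutation p-values in (0, 1]
#' @param wStar normalized weights (positive, mean 1)
#' @return adjusted p-values in (0, 1]
#' @export
adjustPvalues <- function(rawP, wStar) {
  stopifnot2(length(rawP) == length(wStar), "rawP and wStar lengths differ")
  if (any(rawP <= 0 | rawP > 1)) stop("raw p-values must lie in (0, 1]")
  if (any(wStar <= 0)) stop("weights must be positive")
  pmin(1, rawP / wStar)
}

#' Weighted-Bonferroni rejections
#'
#' Rejects gene i when `p_i / w_i <= alpha`; with all weights equal to 1
#' this is plain thresholding at `alpha`.
#'
#' @param rawP raw p-values
#' @param wStar positive weights with mean 1
#' @param alpha significance level in (0, 1)
#' @return logical rejection vector
#' @export
weightedRejections <- function(rawP, wStar, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (any(wStar <= 0)) stop("weights must be positive")
  rawP / wStar <= alpha
}

#' Bonferroni threshold
#'
#' @param alpha family-wise error level
#' @param m number of tested genes
#' @return per-gene threshold `alpha / m`
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}
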