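test_that("GRM entries follow the standardized cross-product formula", {
  # identical genotype rows: their 2x2 block has all entries equal
  counts <- rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 1, 0, 0))
  gm <- toyGenotypes(counts)
  s <- kinship(estimateKinship(gm, mafMin = 0.01))
  expect_equal(s[1, 1], s[1, 2])
  expect_equal(s[1, 2], s[2, 2])
  # single variant, p = 0.5, genotypes (0, 2): off-diagonal -2
  gm2 <- toyGenotypes(cbind(c(0, 2)))
  s2 <- kinship(estimateKinship(gm2, mafMin = 0.01))
  expect_equal(s2[1, 2], -2)
  expect_equal(s2[1, 1], 2)
})

test_that("kinship estimation errors on degenerate input", {
  expect_error(estimateKinship(toyGenotypes(cbind(c(0, 0), c(2, 2)))),
               "polymorphic")
  expect_error(estimateKinship(toyGenotypes(rbind(c(0, 1)))), ">= 2")
})

test_that("GRM recovers sib relatedness from gene-dropped genotypes", {
  set.seed(5)
  pedinfo <- simulatePedigrees(40, nChildren = 2)  # sib pairs + parents
  cfg <- simConfig(nFamilies = 40, nGenes = 2, nCommon = 5000)
  sim <- simulateGenotypes(pedinfo, cfg, seed = 5)
  s <- kinship(estimateKinship(sim$common, mafMin = 0.05))
  ped <- pedinfo$ped
  sibs <- which(pedinfo$expected == 0.5 & upper.tri(pedinfo$expected) &
                  outer(ped$founder, ped$founder, function(a, b) !a & !b),
                arr.ind = TRUE)
  expect_gt(nrow(sibs), 30)
  expect_lt(abs(mean(s[sibs]) - 0.5), 0.05)
  unrel <- which(pedinfo$expected == 0 & upper.tri(pedinfo$expected),
                 arr.ind = TRUE)
  expect_lt(abs(mean(s[unrel])), 0.05)
})

test_that("inverse square root satisfies its algebraic identity", {
  expect_equal(inverseSqrt(KinshipMatrix(diag(3))), diag(3))
  expect_equal(inverseSqrt(KinshipMatrix(diag(c(4, 1)))), diag(c(0.5, 1)))
  set.seed(7)
  for (rep in 1:5) {
    sig <- randomSPD(6)
    m <- inverseSqrt(KinshipMatrix(sig))
    expect_equal(m %*% m %*% sig, diag(6), tolerance = 1e-8)
    expect_equal(m, t(m), tolerance = 1e-10)
  }
})

test_that("non-symmetric input to inverseSqrt is rejected", {
  bad <- matrix(c(1, 0.5, 0.1, 1), 2)
  expect_error(KinshipMatrix(bad) -> k, NA) # constructor symmetrizes
  skew <- methods::new("KinshipMatrix", sigma = diag(2), eigenFloor = 1e-6)
  skew@sigma[1, 2] <- 1e-4
  expect_error(inverseSqrt(skew), "symmetric")
})

test_that("decorrelation turns family covariance into near-identity", {
  set.seed(13)
  pedinfo <- simulatePedigrees(2, nChildren = 2)   # 8 individuals
  sig <- pedinfo$expected + diag(1e-6, 8)
  kin <- KinshipMatrix(sig)
  # identity kinship leaves the phenotype untouched
  y0 <- stats::setNames(rnorm(8), rownames(sig))
  expect_equal(phenoValues(transformPhenotype(y0, KinshipMatrix(diag(8)))),
               stats::setNames(unname(y0), paste0("S", 1:8)),
               ignore_attr = TRUE)
  # Monte-Carlo: empirical covariance of Y* over draws from MVN(0, Sigma)
  L <- chol(sig)
  Z <- matrix(rnorm(8 * 2000), 8)
  Y <- t(L) %*% Z
  M <- inverseSqrt(kin)
  Ystar <- M %*% Y
  emp <- tcrossprod(Ystar) / ncol(Ystar)
  expect_lt(max(abs(emp - diag(8))), 4 / sqrt(2000) + 0.05)
  offd <- emp[upper.tri(emp)]
  expect_lt(max(abs(offd)), 4 / sqrt(2000))
})

test_that("transform rejects misaligned or missing phenotypes", {
  kin <- KinshipMatrix(diag(3))
  expect_error(transformPhenotype(c(1, 2), kin), "match")
  expect_error(transformPhenotype(c(1, NA, 3), kin), "missing")
})

test_that("stratification axes equal PCA scores and separate populations", {
  set.seed(31)
  # two allele-frequency-differentiated subpopulations
  n1 <- 30; n2 <- 30; m <- 400
  p1 <- runif(m, 0.1, 0.9)
  shift <- sample(c(-0.25, 0.25), m, replace = TRUE)
  p2 <- pmin(pmax(p1 + shift, 0.05), 0.95)
  G <- rbind(
    matrix(rbinom(n1 * m, 2, rep(p1, each = n1)), n1),
    matrix(rbinom(n2 * m, 2, rep(p2, each = n2)), n2))
  gm <- toyGenotypes(G, pos = seq_len(m) * 10)
  ax <- stratificationAxes(gm, K = 3)
  grp <- rep(c(1, 2), c(n1, n2))
  expect_true(max(ax[grp == 1, 1]) < min(ax[grp == 2, 1]) ||
                min(ax[grp == 1, 1]) > max(ax[grp == 2, 1]))
  # classical MDS axes match PCA scores up to the fixed sign
  sds <- apply(G, 2, sd)
  Z <- scale(G[, sds > 0])
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)$x[, 1:3]
  for (j in 1:3) {
    d <- min(max(abs(ax[, j] - pc[, j])), max(abs(ax[, j] + pc[, j])))
    expect_lt(d, 1e-8)
  }
  # orthogonality
  cp <- crossprod(ax)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
})

test_that("a rank-1 genotype pattern yields a proportional single axis", {
  pattern <- c(0, 0, 1, 1, 2, 2)
  G <- cbind(pattern, pattern, pattern, 2 - pattern)
  gm <- toyGenotypes(G, pos = 1:4 * 10)
  ax <- stratificationAxes(gm, K = 1)
  cc <- cor(ax[, 1], pattern)
  expect_equal(abs(cc), 1, tolerance = 1e-10)
})

test_that("K bounds for stratification axes are enforced", {
  gm <- toyGenotypes(matrix(rbinom(40, 2, 0.4), 4, 10), pos = 1:10 * 5)
  expect_error(stratificationAxes(gm, K = 4), "smaller")
})

test_that("residualization matches the normal-equations oracle", {
  set.seed(41)
  n <- 50
  axes <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("axis", 1:3)))
  y <- stats::setNames(rnorm(n), paste0("S", 1:n))
  yt <- TransformedPhenotype(y, measurement = "SBP")
  r <- residualize(yt, axes)
  X <- cbind(1, axes)
  oracle <- y - X %*% solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(r), drop(oracle), tolerance = 1e-10)
  # exact orthogonality to every axis
  expect_lt(max(abs(crossprod(axes, r))), 1e-8)
  expect_lt(abs(sum(r)), 1e-8)
})

test_that("degenerate axes are rejected with the offending column named", {
  y <- stats::setNames(rnorm(10), paste0("S", 1:10))
  yt <- TransformedPhenotype(y)
  zeroAx <- cbind(axis1 = rnorm(10), axis2 = rep(0, 10))
  expect_error(residualize(yt, zeroAx), "axis2")
  a <- rnorm(10)
  collin <- cbind(axis1 = a, axis2 = 2 * a)
  expect_error(residualize(yt, collin), "collinear")
})

test_that("phenotype orthogonal to axes residualizes to centered values", {
  set.seed(43)
  n <- 24
  axes <- qr.Q(qr(matrix(rnorm(n * 2), n)))
  axes <- sweep(axes, 2, colMeans(axes))   # centered, so intercept-safe
  colnames(axes) <- c("axis1", "axis2")
  base <- rnorm(n)
  y <- drop(base - axes %*% solve(crossprod(axes), crossprod(axes, base)))
  names(y) <- paste0("S", 1:n)
  r <- residualize(TransformedPhenotype(y), axes)
  expect_equal(unname(r), unname(y - mean(y)), tolerance = 1e-10)
})
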