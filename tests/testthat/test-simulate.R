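test_that("pedigree expected relatedness has the textbook structure", {
  tri <- simulatePedigrees(1, nChildren = 1)
  e <- tri$expected
  expect_equal(dim(e), c(3, 3))
  expect_equal(unname(diag(e)), rep(1, 3))
  expect_equal(e["F001_P1", "F001_P2"], 0)       # spouses unrelated
  expect_equal(e["F001_P1", "F001_C1"], 0.5)     # parent-child
  # many sib-quad families: block-diagonal expected matrix
  quads <- simulatePedigrees(50, nChildren = 2)
  e2 <- quads$expected
  fid <- quads$ped$fid
  expect_true(all(e2[outer(fid, fid, `!=`)] == 0))
  expect_equal(e2["F002_C1", "F002_C2"], 0.5)    # full sibs
  expect_error(simulatePedigrees(0), ">= 1")
})

test_that("gene-dropped genotypes are Mendelian-consistent", {
  cfg <- simConfig(nFamilies = 30, nChildren = 3, nGenes = 10,
                   variantsPerGene = c(2, 10), nCommon = 300)
  pedinfo <- simulatePedigrees(30, nChildren = 3)
  sim <- simulateGenotypes(pedinfo, cfg, seed = 99)
  ped <- pedinfo$ped
  for (panel in list(sim$rare, sim$common)) {
    cnt <- genotypes(panel)
    kids <- which(!ped$founder)
    fa <- cnt[match(ped$father[kids], ped$iid), , drop = FALSE]
    mo <- cnt[match(ped$mother[kids], ped$iid), , drop = FALSE]
    ch <- cnt[kids, , drop = FALSE]
    # a child inherits one allele per parent: bounds are exact
    expect_true(all(ch >= (fa == 2) + (mo == 2)))
    expect_true(all(ch <= (fa >= 1) + (mo >= 1)))
  }
})

test_that("founder allele frequencies match the target MAF", {
  cfg <- simConfig(nFamilies = 2000, nChildren = 1, nGenes = 5,
                   variantsPerGene = c(5, 10), mafRange = c(0.004, 0.006),
                   nCommon = 10)
  pedinfo <- simulatePedigrees(2000, nChildren = 1)
  sim <- simulateGenotypes(pedinfo, cfg, seed = 17)
  cnt <- genotypes(sim$rare)[pedinfo$ped$founder, , drop = FALSE]
  est <- mean(colMeans(cnt) / 2)                  # pooled founder frequency
  # pooled across >= 25 variants x 8,000 founder haplotypes: binomial band
  expect_lt(abs(est - 0.005), 3 * sqrt(0.005 * 0.995 / (8000 * ncol(cnt))))
})

test_that("SNP-estimated kinship recovers the pedigree expectation", {
  cfg <- simConfig(nFamilies = 30, nChildren = 2, nGenes = 2,
                   nCommon = 5000)
  pedinfo <- simulatePedigrees(30, nChildren = 2)
  sim <- simulateGenotypes(pedinfo, cfg, seed = 3)
  s <- kinship(estimateKinship(sim$common, mafMin = 0.05))
  off <- upper.tri(s)
  expect_lt(mean(abs(s[off] - pedinfo$expected[off])), 0.05)
})

test_that("null effects leave phenotype independent of genotype", {
  cfg <- simConfig(nFamilies = 40, nGenes = 12, variantsPerGene = c(2, 15),
                   nCommon = 50, causalFraction = 0, sdPolygenic = 0)
  pedinfo <- simulatePedigrees(40, 2)
  sim <- simulateGenotypes(pedinfo, cfg, seed = 21)
  ep <- simulateExpressionPhenotype(sim, pedinfo, cfg, seed = 22)
  expect_true(all(ep$truth$label == "null"))
  g <- collapseGeneBurden(genotypes(sim$rare))
  expect_lt(abs(cor(g, ep$latent)), 0.2)
})

test_that("causal-chain genes earn larger crude weights than null genes", {
  cfg <- simConfig(nFamilies = 65, nGenes = 24, variantsPerGene = c(5, 20),
                   nProbes = 24, nCommon = 50, causalFraction = 0.25)
  pedinfo <- simulatePedigrees(cfg$nFamilies, cfg$nChildren)
  sim <- simulateGenotypes(pedinfo, cfg, seed = 31)
  ep <- simulateExpressionPhenotype(sim, pedinfo, cfg, seed = 32)
  G <- genotypes(sim$rare)
  gt <- assignVariantsToGenes(sim$genes, sim$rare)
  E <- exprValues(ep$expr)
  crude <- vapply(seq_len(length(gt)), function(i) {
    g <- collapseGeneBurden(G[, variantIndices(gt)[[i]], drop = FALSE])
    suppressWarnings(crudeWeight(g, E, ep$latent)$crude)
  }, numeric(1))
  causal <- ep$truth$label == "causal_chain"
  wt <- wilcox.test(crude[causal], crude[!causal], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("polygenic effects induce sib phenotype correlation", {
  cfg <- simConfig(nFamilies = 200, nGenes = 2, variantsPerGene = c(2, 3),
                   nCommon = 10, causalFraction = 0, sdPolygenic = 2,
                   sdPheno = 0.5)
  pedinfo <- simulatePedigrees(200, 2)
  sim <- simulateGenotypes(pedinfo, cfg, seed = 41)
  ep <- simulateExpressionPhenotype(sim, pedinfo, cfg, seed = 42)
  ped <- pedinfo$ped
  sib1 <- ep$latent[match(sprintf("F%03d_C1", 1:200), ped$iid)]
  sib2 <- ep$latent[match(sprintf("F%03d_C2", 1:200), ped$iid)]
  unrelated <- ep$latent[match(sprintf("F%03d_P1", 1:200), ped$iid)]
  shuffled <- unrelated[c(101:200, 1:100)]
  expect_gt(cor(sib1, sib2), cor(unrelated, shuffled) + 0.2)
})

test_that("dataset bundles are deterministic and round-trip exactly", {
  cfg <- simConfig(nFamilies = 12, nGenes = 8, variantsPerGene = c(2, 8),
                   nProbes = 6, nCommon = 60)
  d1 <- generateDataset(cfg, file.path(tempdir(), "bundleA"), seed = 5)
  d2 <- generateDataset(cfg, file.path(tempdir(), "bundleB"), seed = 5)
  for (f in names(d1$paths))
    expect_identical(readLines(d1$paths[[f]]), readLines(d2$paths[[f]]),
                     label = f)
  # read-back equals the in-memory objects
  gm <- readVCFGenotypes(d1$paths$vcf)
  inMem <- cbind(genotypes(d1$sim$rare), genotypes(d1$sim$common))
  expect_equal(unname(genotypes(gm)), unname(inMem))
  em <- readExpressionMatrix(d1$paths$expr)
  expect_equal(exprValues(em), exprValues(d1$data$expr), tolerance = 1e-12)
  ph <- readPhenotypeTable(d1$paths$pheno)
  expect_equal(averageVisits(ph, cfg$phenoName),
               tapply(d1$data$pheno$value, d1$data$pheno$individual, mean)[
                 unique(d1$data$pheno$individual)],
               tolerance = 1e-9, ignore_attr = TRUE)
  gt <- readGeneAnnotation(d1$paths$bed, gm)
  expect_equal(sort(geneIds(gt)), sort(names(d1$sim$genes)))
})

test_that("simulation configuration is validated", {
  expect_error(simConfig(mafRange = c(0.001, 0.05)), "MAF")
  expect_error(simConfig(variantsPerGene = c(1, 10)), "variantsPerGene")
  expect_error(simConfig(causalFraction = 1.3), "causalFraction")
  expect_error(simConfig(sdExpr = -1), "SDs")
})
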