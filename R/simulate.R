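#' Simulation configuration
#'
#' Collects the parameters of the family-data generator. Defaults emulate
#' the cohort the method targets: about 260 related individuals (nuclear
#' families of two founders and two children), genes carrying 2-49 rare
#' variants with in-population MAF below 0.01, a genome-wide common-marker
#' panel for kinship estimation, and expression probes partly driven by gene
#' burden.
#'
#' @param nFamilies number of nuclear families (default 65 -> 260 people)
#' @param nChildren children per family (default 2)
#' @param nGenes number of genes (default 50)
#' @param variantsPerGene inclusive range of rare variants per gene, within
#'   `[2, 49]`
#' @param mafRange population MAF range for rare variants, within (0, 0.01)
#' @param nProbes expression probes (default 20)
#' @param nCommon common markers for kinship (default 2000)
#' @param commonMafRange MAF range of the common panel
#' @param bGE burden -> expression effect per rare allele (causative chain)
#' @param bEP expression -> phenotype effect (causative chain; also the
#'   phenotype -> expression feedback in the reactive model)
#' @param bGP direct burden -> phenotype effect (direct and reactive models)
#' @param sdExpr expression noise SD
#' @param sdPheno phenotype environmental noise SD
#' @param sdPolygenic SD of the polygenic family effect
#'   (`MVN(0, sd^2 * Sigma_expected)`)
#' @param sdVisit visit-level measurement noise SD
#' @param nVisits phenotype visits per individual (default 3)
#' @param causalFraction fraction of genes that are causal (default 0.1)
#' @param causalModel `"causal_chain"` (SNP -> E -> P), `"reactive"`
#'   (SNP -> P -> E) or `"direct"` (SNP -> P, expression independent)
#' @param phenoName measurement name written to the phenotype table
#' @param seed default RNG seed carried by the configuration
#' @return validated configuration list
#' @export
simConfig <- function(nFamilies = 65, nChildren = 2, nGenes = 50,
                      variantsPerGene = c(2, 49), mafRange = c(0.001, 0.01),
                      nProbes = 20, nCommon = 2000,
                      commonMafRange = c(0.05, 0.5),
                      bGE = 1.0, bEP = 0.5, bGP = 0.5,
                      sdExpr = 1, sdPheno = 1, sdPolygenic = 0.5,
                      sdVisit = 1, nVisits = 3,
                      causalFraction = 0.1, causalModel = "causal_chain",
                      phenoName = "SBP", seed = 1) {
  cfg <- as.list(environment())
  stopifnot2(nFamilies >= 1 && nChildren >= 1, "family sizes must be >= 1")
  stopifnot2(variantsPerGene[1] >= 2 && variantsPerGene[2] <= 49 &&
               variantsPerGene[1] <= variantsPerGene[2],
             "variantsPerGene must lie within [2, 49]")
  stopifnot2(mafRange[1] > 0 && mafRange[2] < 0.01 + 1e-12,
             "rare-variant MAF range must lie within (0, 0.01)")
  stopifnot2(all(c(sdExpr, sdPheno, sdPolygenic, sdVisit) >= 0),
             "noise SDs must be nonnegative")
  stopifnot2(causalFraction >= 0 && causalFraction <= 1,
             "causalFraction must lie in [0, 1]")
  stopifnot2(causalModel %in% c("causal_chain", "reactive", "direct"),
             "unknown causal model")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig:", x$nFamilies, "families x",
      2 + x$nChildren, "members;", x$nGenes, "genes;",
      x$nProbes, "probes; model", x$causalModel,
      sprintf("(%.0f%% causal)\n", 100 * x$causalFraction))
  invisible(x)
}

#' Simulate nuclear-family pedigrees and their expected relatedness
#'
#' Families of two unrelated founders and `nChildren` offspring. The
#' expected relatedness matrix is on the genetic-relationship scale
#' (diagonal 1): parent-child and full-sib entries 0.5, spouses and
#' between-family entries 0.
#'
#' @param nFamilies number of families
#' @param nChildren children per family
#' @return list with `ped` (data.frame fid/iid/father/mother/founder) and
#'   `expected` (relatedness matrix with individual-id dimnames)
#' @export
simulatePedigrees <- function(nFamilies, nChildren = 2) {
  if (nFamilies < 1 || nChildren < 1) stop("family sizes must be >= 1")
  rows <- list()
  for (f in seq_len(nFamilies)) {
    fa <- sprintf("F%03d_P1", f); mo <- sprintf("F%03d_P2", f)
    rows[[length(rows) + 1L]] <- data.frame(
      fid = f, iid = c(fa, mo), father = "0", mother = "0", founder = TRUE)
    kid <- sprintf("F%03d_C%d", f, seq_len(nChildren))
    rows[[length(rows) + 1L]] <- data.frame(
      fid = f, iid = kid, father = fa, mother = mo, founder = FALSE)
  }
  ped <- do.call(rbind, rows)
  n <- nrow(ped)
  expected <- matrix(0, n, n, dimnames = list(ped$iid, ped$iid))
  diag(expected) <- 1
  for (f in seq_len(nFamilies)) {
    idx <- which(ped$fid == f)
    kids <- idx[!ped$founder[idx]]
    pars <- idx[ped$founder[idx]]
    for (k in kids) expected[k, pars] <- expected[pars, k] <- 0.5
    if (length(kids) > 1)
      for (a in kids) for (b in kids)
        if (a != b) expected[a, b] <- 0.5
  }
  list(ped = ped, expected = expected)
}

# Gene-drop one marker set through the pedigree: founder haplotypes are
# Bernoulli(maf) draws, children inherit one random haplotype per parent per
# variant (no linkage between variants).
.geneDrop <- function(ped, maf) {
  n <- nrow(ped); M <- length(maf)
  H1 <- matrix(0L, n, M); H2 <- matrix(0L, n, M)
  fIdx <- which(ped$founder)
  H1[fIdx, ] <- stats::rbinom(length(fIdx) * M, 1, rep(maf, each = length(fIdx)))
  H2[fIdx, ] <- stats::rbinom(length(fIdx) * M, 1, rep(maf, each = length(fIdx)))
  kids <- which(!ped$founder)
  if (length(kids)) {
    # all offspring are children of founders, so one vectorized draw works
    fa <- match(ped$father[kids], ped$iid)
    mo <- match(ped$mother[kids], ped$iid)
    pickF <- matrix(stats::runif(length(kids) * M) < 0.5, length(kids))
    pickM <- matrix(stats::runif(length(kids) * M) < 0.5, length(kids))
    H1[kids, ] <- ifelse(pickF, H1[fa, , drop = FALSE],
                         H2[fa, , drop = FALSE])
    H2[kids, ] <- ifelse(pickM, H1[mo, , drop = FALSE],
                         H2[mo, , drop = FALSE])
  }
  cnt <- H1 + H2
  rownames(cnt) <- ped$iid
  cnt
}

#' Simulate family genotypes by Mendelian gene-dropping
#'
#' Produces a rare-variant [GenotypeMatrix-class] whose variants are grouped
#' into genes, and a separate common-marker panel for kinship estimation.
#' Rare variants sit on chromosome 1 inside disjoint gene intervals; common
#' markers on chromosome 2.
#'
#' @param pedinfo result of [simulatePedigrees()]
#' @param config a [simConfig()] configuration
#' @param seed RNG seed (defaults to the configuration's)
#' @return list with `rare` and `common` ([GenotypeMatrix-class]), `genes`
#'   (named `GRanges` of gene intervals) and `geneSizes`
#' @export
simulateGenotypes <- function(pedinfo, config, seed = config$seed) {
  set.seed(seed)
  ped <- pedinfo$ped
  sizes <- sample(seq(config$variantsPerGene[1], config$variantsPerGene[2]),
                  config$nGenes, replace = TRUE)
  M <- sum(sizes)
  mafR <- stats::runif(M, config$mafRange[1], config$mafRange[2])
  cntR <- .geneDrop(ped, mafR)

  geneStart <- cumsum(c(0, utils::head(sizes, -1))) * 1000 + # 1-based gene origins
    (seq_along(sizes) - 1) * 5000 + 1
  pos <- unlist(lapply(seq_along(sizes), function(g)
    geneStart[g] + seq_len(sizes[g]) * 10))
  variants <- GenomicRanges::GRanges("1", IRanges::IRanges(pos, width = 1),
                                     ref = "A", alt = "T")
  names(variants) <- sprintf("rv%05d", seq_len(M))
  rare <- GenotypeMatrix(cntR, variants, samples = ped$iid)

  genes <- GenomicRanges::GRanges(
    "1", IRanges::IRanges(geneStart,
                          geneStart + sizes * 10 + 5))
  names(genes) <- sprintf("GENE%03d", seq_along(sizes))

  mafC <- stats::runif(config$nCommon, config$commonMafRange[1],
                       config$commonMafRange[2])
  cntC <- .geneDrop(ped, mafC)
  variantsC <- GenomicRanges::GRanges(
    "2", IRanges::IRanges(seq_len(config$nCommon) * 100, width = 1),
    ref = "A", alt = "T")
  names(variantsC) <- sprintf("cm%05d", seq_len(config$nCommon))
  common <- GenotypeMatrix(cntC, variantsC, samples = ped$iid)

  list(rare = rare, common = common, genes = genes, geneSizes = sizes)
}

#' Simulate expression and phenotype with known truth
#'
#' Linear-Gaussian structural equations on top of the simulated genotypes.
#' For each causal gene with burden `g` and its causal probe `E`:
#' causative chain `E = bGE g + e1`, `P += bEP E`; reactive
#' `P += bGP g`, then `E = bEP P + e1`; direct `P += bGP g` with all probes
#' independent of `g`. The phenotype always receives a polygenic family
#' effect `MVN(0, sdPolygenic^2 * Sigma_expected)` plus environmental noise,
#' and each visit adds independent measurement noise around the latent `P`.
#'
#' @param sim result of [simulateGenotypes()]
#' @param pedinfo result of [simulatePedigrees()]
#' @param config a [simConfig()] configuration
#' @param seed RNG seed (defaults to the configuration's, offset)
#' @return list with `expr` ([ExpressionMatrix-class]), `pheno` (long-format
#'   visit table), `truth` (per-gene labels, probes, effects) and `latent`
#'   (the latent per-individual phenotype)
#' @export
simulateExpressionPhenotype <- function(sim, pedinfo, config,
                                        seed = config$seed + 1) {
  set.seed(seed)
  ped <- pedinfo$ped
  n <- nrow(ped)
  G <- genotypes(sim$rare)
  gt <- assignVariantsToGenes(sim$genes, sim$rare)
  J <- config$nProbes
  probes <- sprintf("probe%03d", seq_len(J))

  burdens <- vapply(as.list(variantIndices(gt)), function(ix)
    rowSums(G[, ix, drop = FALSE]), numeric(n))
  colnames(burdens) <- geneIds(gt)

  nCausal <- round(config$causalFraction * config$nGenes)
  if (nCausal > min(config$nGenes, J))
    stop("more causal genes than genes or probes available")
  labels <- rep("null", config$nGenes)
  causalIdx <- if (nCausal) sample(config$nGenes, nCausal) else integer(0)
  labels[causalIdx] <- config$causalModel
  causalProbe <- rep(NA_character_, config$nGenes)
  if (nCausal) causalProbe[causalIdx] <- probes[sample(J, nCausal)]

  E <- matrix(stats::rnorm(n * J, sd = config$sdExpr), n, J,
              dimnames = list(ped$iid, probes))
  polygenic <- if (config$sdPolygenic > 0) {
    L <- chol(pedinfo$expected + diag(1e-8, n))
    drop(config$sdPolygenic * (t(L) %*% stats::rnorm(n)))
  } else rep(0, n)
  P <- polygenic + stats::rnorm(n, sd = config$sdPheno)

  if (config$causalModel == "causal_chain") {
    for (i in causalIdx) {
      j <- causalProbe[i]
      E[, j] <- config$bGE * burdens[, i] +
        stats::rnorm(n, sd = config$sdExpr)
      P <- P + config$bEP * E[, j]
    }
  } else if (config$causalModel %in% c("reactive", "direct")) {
    for (i in causalIdx) P <- P + config$bGP * burdens[, i]
    if (config$causalModel == "reactive")
      for (i in causalIdx)
        E[, causalProbe[i]] <- config$bEP * P +
          stats::rnorm(n, sd = config$sdExpr)
  }

  visits <- expand.grid(individual = ped$iid, visit = seq_len(config$nVisits),
                        stringsAsFactors = FALSE)
  visits <- visits[order(match(visits$individual, ped$iid), visits$visit), ]
  visits$measurement <- config$phenoName
  visits$value <- P[match(visits$individual, ped$iid)] +
    stats::rnorm(nrow(visits), sd = config$sdVisit)
  rownames(visits) <- NULL

  truth <- data.frame(gene = geneIds(gt), label = labels,
                      probe = causalProbe,
                      bGE = ifelse(labels == "causal_chain", config$bGE, 0),
                      bEP = ifelse(labels %in% c("causal_chain", "reactive"),
                                   config$bEP, 0),
                      bGP = ifelse(labels %in% c("reactive", "direct"),
                                   config$bGP, 0))
  list(expr = ExpressionMatrix(E), pheno = visits, truth = truth, latent = P)
}

# write a minimal VCF 4.2 with GT-only genotype columns
.writeVCF <- function(geno, path) {
  cnt <- t(genotypes(geno))                     # variants x samples
  rr <- variantRanges(geno)
  gtStr <- matrix(c("0/0", "0/1", "1/1")[cnt + 1], nrow = nrow(cnt))
  gtStr[is.na(cnt)] <- "./."
  body <- paste(as.character(GenomicRanges::seqnames(rr)),
                GenomicRanges::start(rr), names(rr),
                S4Vectors::mcols(rr)$ref, S4Vectors::mcols(rr)$alt,
                ".", "PASS", ".", "GT",
                apply(gtStr, 1, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sampleIds(geno)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate a complete on-disk dataset bundle
#'
#' Simulates pedigrees, genotypes, expression and phenotype under one
#' configuration and writes every file the analysis pipeline reads:
#' `genotypes.vcf` (rare + common markers), `genes.bed`, `expression.tsv`,
#' `phenotype.tsv`, plus `truth.tsv` and `pedigree.tsv` for validation.
#' Deterministic: the same configuration and seed reproduce the bundle
#' byte for byte.
#'
#' @param config a [simConfig()] configuration
#' @param dir output directory (created if needed)
#' @param seed RNG seed (defaults to the configuration's)
#' @return invisibly, a list of the written paths and the in-memory objects
#' @export
generateDataset <- function(config, dir, seed = config$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pedinfo <- simulatePedigrees(config$nFamilies, config$nChildren)
  sim <- simulateGenotypes(pedinfo, config, seed = seed)
  ep <- simulateExpressionPhenotype(sim, pedinfo, config, seed = seed + 1)

  # one VCF holding rare (chr 1) and common (chr 2) markers
  merged <- GenotypeMatrix(
    cbind(genotypes(sim$rare), genotypes(sim$common)),
    suppressWarnings(c(variantRanges(sim$rare), variantRanges(sim$common))),
    samples = sampleIds(sim$rare))
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    bed = file.path(dir, "genes.bed"),
    expr = file.path(dir, "expression.tsv"),
    pheno = file.path(dir, "phenotype.tsv"),
    truth = file.path(dir, "truth.tsv"),
    ped = file.path(dir, "pedigree.tsv"))
  .writeVCF(merged, paths$vcf)

  bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(sim$genes)),
                    start = GenomicRanges::start(sim$genes) - 1L,
                    end = GenomicRanges::end(sim$genes),
                    name = names(sim$genes))
  utils::write.table(bed, paths$bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  ex <- data.frame(sample = rownames(exprValues(ep$expr)),
                   exprValues(ep$expr), check.names = FALSE)
  utils::write.table(ex, paths$expr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ep$pheno, paths$pheno, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ep$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pedinfo$ped, paths$ped, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = paths, pedinfo = pedinfo, sim = sim, data = ep))
}
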