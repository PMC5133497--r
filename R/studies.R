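#' Type-I error study of the gene-level test on null family data
#'
#' Simulates one family cohort with no genetic effects, runs the full
#' decorrelation + residualization preprocessing, applies the sequential sum
#' test to every eligible gene and reports the rejection rate at `alpha`.
#' With a calibrated test the rate stays inside the binomial band around
#' `alpha`.
#'
#' @param nGenes simulated null genes (default 500)
#' @param nFamilies nuclear families of four (default 75, i.e. 300
#'   individuals)
#' @param B permutations per gene (default 200)
#' @param alpha nominal level (default 0.05)
#' @param seed RNG seed
#' @return list with `rate`, `nTested`, `pValues` and the binomial 95%
#'   interval around `alpha`
#' @export
typeIErrorStudy <- function(nGenes = 500, nFamilies = 75, B = 200,
                            alpha = 0.05, seed = 1) {
  cfg <- simConfig(nFamilies = nFamilies, causalFraction = 0,
                   nCommon = 2000, seed = seed)
  pedinfo <- simulatePedigrees(cfg$nFamilies, cfg$nChildren)
  sim <- simulateGenotypes(pedinfo, cfg, seed = seed)
  kin <- estimateKinship(sim$common, mafMin = 0.05)
  axes <- stratificationAxes(sim$common, K = 3)
  ped <- pedinfo$ped
  n <- nrow(ped)
  L <- chol(pedinfo$expected + diag(1e-8, n))

  # each null gene is an independent draw of (genotypes, phenotype), so the
  # rejection count is genuinely binomial across genes
  ps <- numeric(nGenes)
  g <- 0L; tries <- 0L
  while (g < nGenes) {
    tries <- tries + 1L
    set.seed(deriveSeed(seed, paste0("null", tries)))
    k <- sample(seq(cfg$variantsPerGene[1], cfg$variantsPerGene[2]), 1)
    maf <- stats::runif(k, cfg$mafRange[1], cfg$mafRange[2])
    G <- .geneDrop(ped, maf)
    poly <- apply(G, 2, function(col) {
      f <- mean(col) / 2
      f > 0 && min(f, 1 - f) < 0.01
    })
    if (sum(poly) < 2) next               # fails the rare-variant filter
    G <- G[, poly, drop = FALSE]
    y <- cfg$sdPolygenic * drop(t(L) %*% stats::rnorm(n)) +
      stats::rnorm(n, sd = cfg$sdPheno)
    names(y) <- ped$iid
    r <- residualize(transformPhenotype(y, kin), axes)
    g <- g + 1L
    ps[g] <- pValue(seqASumVS(G, r, B = B,
                              seed = deriveSeed(seed, paste0("perm", tries))))
  }
  ci <- stats::qbinom(c(0.025, 0.975), nGenes, alpha) / nGenes
  list(rate = mean(ps <= alpha), nTested = nGenes, pValues = ps,
       interval = ci)
}

# one global-null or causal-chain replicate: returns the per-gene raw p and
# normalized weight of the analyzed genes plus their truth labels
.studyReplicate <- function(cfg, B, seed) {
  pedinfo <- simulatePedigrees(cfg$nFamilies, cfg$nChildren)
  sim <- simulateGenotypes(pedinfo, cfg, seed = seed)
  ep <- simulateExpressionPhenotype(sim, pedinfo, cfg, seed = seed + 1)
  merged <- GenotypeMatrix(
    cbind(genotypes(sim$rare), genotypes(sim$common)),
    suppressWarnings(c(variantRanges(sim$rare), variantRanges(sim$common))),
    samples = sampleIds(sim$rare))
  y <- ep$latent
  names(y) <- pedinfo$ped$iid
  res <- analyzeDataset(merged, sim$genes, ep$expr,
                        stats::setNames(list(y), cfg$phenoName),
                        B = B, seed = seed, verbose = FALSE)
  tab <- res$results
  tab$label <- ep$truth$label[match(tab$gene, ep$truth$gene)]
  tab
}

#' Family-wise error rate study of the weighted-Bonferroni pipeline
#'
#' Runs the complete pipeline (kinship, decorrelation, gene tests,
#' expression weights, weighted-Bonferroni decision at `alpha / m`) on
#' independent global-null replicates and reports how often at least one
#' gene is falsely rejected — the family-wise error, which the mean-one
#' weighting must keep at or below `alpha`.
#'
#' @param nReplicates number of simulated cohorts (default 200)
#' @param nGenes genes per cohort (default 200)
#' @param nFamilies families of four per cohort (default 50)
#' @param B permutations per gene (default 200)
#' @param alpha FWER target (default 0.05)
#' @param seed RNG seed
#' @return list with `fwer` (weighted), `fwerUnweighted`, per-replicate
#'   logical vectors, and the one-sided binomial 95% upper bound around
#'   `alpha`
#' @export
fwerStudy <- function(nReplicates = 200, nGenes = 200, nFamilies = 50,
                      B = 200, alpha = 0.05, seed = 1) {
  cfg <- simConfig(nFamilies = nFamilies, nGenes = nGenes,
                   causalFraction = 0, nProbes = 10, nCommon = 500,
                   seed = seed)
  anyRej <- logical(nReplicates); anyRejUnw <- logical(nReplicates)
  for (r in seq_len(nReplicates)) {
    repSeed <- deriveSeed(seed, paste0("fwer", r))
    tab <- .studyReplicate(cfg, B, repSeed)
    thr <- bonferroniThreshold(alpha, nrow(tab))
    ph <- cfg$phenoName
    anyRej[r] <- any(tab[[paste0(ph, "_raw_p")]] /
                       tab[[paste0(ph, "_weight")]] <= thr)
    anyRejUnw[r] <- any(tab[[paste0(ph, "_raw_p")]] <= thr)
  }
  list(fwer = mean(anyRej), fwerUnweighted = mean(anyRejUnw),
       anyRejection = anyRej,
       upperBound = stats::qbinom(0.975, nReplicates, alpha) / nReplicates)
}

#' Power comparison: weighted versus unweighted Bonferroni decisions
#'
#' Simulates causal-chain cohorts (rare alleles shift an expression probe,
#' the probe shifts the phenotype) and contrasts the power to reject causal
#' genes under the weighted rule `p_i / w_i <= alpha / m` against the plain
#' Bonferroni rule `p_i <= alpha / m`. Informative expression weights
#' concentrate the error budget on genes with an expression chain, so the
#' weighted rule should recover at least as many causal genes.
#'
#' @param nReplicates number of simulated cohorts (default 200)
#' @param nGenes genes per cohort (default 20; keeps the Bonferroni
#'   threshold above the permutation floor at `B = 500`)
#' @param nFamilies families of four per cohort (default 65, about the
#'   cohort size the method targets)
#' @param B permutations per gene (default 500)
#' @param alpha FWER target (default 0.05)
#' @param seed RNG seed
#' @return list with `powerWeighted`, `powerUnweighted`, per-gene decision
#'   counts and the discordant-pair breakdown
#' @export
powerStudy <- function(nReplicates = 200, nGenes = 20, nFamilies = 65,
                       B = 500, alpha = 0.05, seed = 1) {
  cfg <- simConfig(nFamilies = nFamilies, nGenes = nGenes,
                   causalFraction = 0.1, causalModel = "causal_chain",
                   nProbes = 10, nCommon = 500, seed = seed)
  win <- 0L; lose <- 0L; nCausal <- 0L
  rejW <- 0L; rejU <- 0L
  for (r in seq_len(nReplicates)) {
    repSeed <- deriveSeed(seed, paste0("power", r))
    tab <- .studyReplicate(cfg, B, repSeed)
    thr <- bonferroniThreshold(alpha, nrow(tab))
    ph <- cfg$phenoName
    causal <- tab$label == "causal_chain"
    w <- tab[[paste0(ph, "_raw_p")]][causal] /
      tab[[paste0(ph, "_weight")]][causal] <= thr
    u <- tab[[paste0(ph, "_raw_p")]][causal] <= thr
    nCausal <- nCausal + sum(causal)
    rejW <- rejW + sum(w); rejU <- rejU + sum(u)
    win <- win + sum(w & !u); lose <- lose + sum(!w & u)
  }
  list(powerWeighted = rejW / nCausal, powerUnweighted = rejU / nCausal,
       nCausal = nCausal, discordantWeightedOnly = win,
       discordantUnweightedOnly = lose)
}
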