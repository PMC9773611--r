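#' Configuration for the synthetic tumor/normal single-cell cohort
#'
#' Builds and validates the parameter set of the synthetic cohort generator.
#' The generator emulates a multi-patient gastric tumor/normal droplet
#' single-cell cohort at desk scale: negative-binomial (Gamma-Poisson) counts
#' with cluster-specific marker shifts, a sample-specific dissociation-stress
#' (heat-shock-like) gene program, planted ligand-receptor communication axes
#' radiating from one hub cluster, tumor-enriched/depleted cell types sampled
#' through a Dirichlet-multinomial composition model, and per-cluster "program"
#' gene blocks that back the synthetic bulk DEG lists.
#'
#' Every cell type is a "minor" cluster \code{M<i>.<j>} nested in a "major"
#' type \code{M<i>}; minors share their major's marker block and add their own.
#'
#' @param nPatients patients; each contributes one tumor and one normal sample.
#' @param cellsPerSample cells drawn per sample.
#' @param nGenes total genes.
#' @param nMajorTypes,nMinorPerMajor major cell types and minors per major.
#' @param markerGenesPerCluster marker genes for every major and every minor.
#' @param markerLog2Effect log2 mean shift of marker genes in their cluster.
#' @param baselineMean mean of the per-gene lognormal negative-binomial means.
#' @param nbDispersion shared NB dispersion (variance = mu + dispersion*mu^2).
#' @param mitoGeneFraction fraction of genes flagged mitochondrial; their means
#'   are scaled so the expected per-cell mitochondrial fraction is ~5%.
#' @param artifactGeneCount genes in the dissociation-artifact program.
#' @param artifactSamples sample ids carrying the artifact (default: both
#'   samples of patient 1).
#' @param artifactEffect log2 mean shift of artifact genes in those samples.
#' @param lrPairs data.frame(ligand, receptor, sender, receiver, effect) of
#'   planted communication axes, or \code{NULL} for the default five axes from
#'   \code{hubCluster} to five other minors at log2 effect 3. Gene names may be
#'   \code{NA}; dedicated ligand/receptor genes are then assigned.
#' @param nDecoyPairs non-planted ligand-receptor pairs (background genes)
#'   added to the shipped pair database.
#' @param hubCluster planted sender hub (default first minor, "M1.1").
#' @param tumorEnriched named numeric: minor cluster -> fold change of its
#'   expected per-sample percentage in tumor vs normal. Fold changes are
#'   planted exactly; unmapped clusters absorb the renormalization.
#' @param degsPerModule dedicated program genes per minor cluster, used by
#'   \code{\link{generateBulkDEGs}}.
#' @param dirichletConcentration concentration of the per-sample Dirichlet
#'   composition prior (higher = less compositional variability).
#' @param junkCellsPerSample low-quality cells per sample (marker-free,
#'   restricted to a background-gene subset, doubled mitochondrial load);
#'   labeled cluster "junk" in the ground truth. Default 0.
#' @param seed master seed; child seeds for gene setup / composition / counts
#'   are derived by fixed offsets (see vignette).
#' @return a validated \code{SyntheticConfig} (list).
#' @export
syntheticConfig <- function(nPatients = 6, cellsPerSample = 120, nGenes = 600,
                            nMajorTypes = 4, nMinorPerMajor = 2,
                            markerGenesPerCluster = 10, markerLog2Effect = 2,
                            baselineMean = 1.5, nbDispersion = 0.5,
                            mitoGeneFraction = 0.03,
                            artifactGeneCount = 50, artifactSamples = NULL,
                            artifactEffect = 2,
                            lrPairs = NULL, nDecoyPairs = 20,
                            hubCluster = NULL, tumorEnriched = NULL,
                            degsPerModule = 20,
                            dirichletConcentration = 60,
                            junkCellsPerSample = 0, seed = 1L) {
  minors <- paste0(rep(paste0("M", seq_len(nMajorTypes)), each = nMinorPerMajor),
                   ".", rep(seq_len(nMinorPerMajor), nMajorTypes))
  if (is.null(hubCluster)) hubCluster <- minors[1]
  if (!hubCluster %in% minors) stop("hubCluster is not a minor cluster id")
  if (is.null(lrPairs)) {
    receivers <- setdiff(minors, hubCluster)
    receivers <- receivers[seq_len(min(5L, length(receivers)))]
    lrPairs <- data.frame(ligand = NA_character_, receptor = NA_character_,
                          sender = hubCluster, receiver = receivers,
                          effect = 3, stringsAsFactors = FALSE)
  }
  if (!all(c(lrPairs$sender, lrPairs$receiver) %in% minors))
    stop("every planted axis must reference existing minor clusters")
  if (is.null(tumorEnriched)) {
    tumorEnriched <- c(5, 0.2)
    names(tumorEnriched) <- minors[c(min(4, length(minors)),
                                     min(5, length(minors)))]
  }
  if (any(tumorEnriched <= 0)) stop("tumorEnriched fold changes must be > 0")
  if (!all(names(tumorEnriched) %in% minors))
    stop("tumorEnriched names must be minor cluster ids")
  pNormal <- rep(1 / length(minors), length(minors))
  if (sum(pNormal[match(names(tumorEnriched), minors)] * tumorEnriched) >= 1)
    stop("tumorEnriched fold changes leave no mass for unmapped clusters")
  if (is.null(artifactSamples)) artifactSamples <- c("P1T", "P1N")
  nMito <- round(mitoGeneFraction * nGenes)
  demand <- nMito + markerGenesPerCluster * (nMajorTypes + length(minors)) +
    degsPerModule * length(minors) + 2L * nrow(lrPairs) + artifactGeneCount
  if (demand > nGenes)
    stop("gene demand (", demand, ") exceeds nGenes (", nGenes, ")")
  if (seed < 0 || seed >= 2^30) stop("seed must lie in [0, 2^30)")
  cfg <- list(nPatients = nPatients, cellsPerSample = cellsPerSample,
              nGenes = nGenes, nMajorTypes = nMajorTypes,
              nMinorPerMajor = nMinorPerMajor,
              markerGenesPerCluster = markerGenesPerCluster,
              markerLog2Effect = markerLog2Effect,
              baselineMean = baselineMean, nbDispersion = nbDispersion,
              mitoGeneFraction = mitoGeneFraction,
              artifactGeneCount = artifactGeneCount,
              artifactSamples = artifactSamples,
              artifactEffect = artifactEffect,
              lrPairs = lrPairs, nDecoyPairs = nDecoyPairs,
              hubCluster = hubCluster, tumorEnriched = tumorEnriched,
              degsPerModule = degsPerModule,
              dirichletConcentration = dirichletConcentration,
              junkCellsPerSample = junkCellsPerSample,
              seed = as.integer(seed), minors = minors)
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Generate a synthetic tumor/normal single-cell cohort
#'
#' Draws a gene x cell count matrix from the generative model described in
#' \code{\link{syntheticConfig}} together with full ground truth. Counts are
#' negative-binomial with per-gene lognormal means; marker, program, ligand,
#' receptor and artifact genes receive multiplicative log2 mean shifts in
#' their cluster (or sample) of action. Per-sample cell-type composition is
#' Dirichlet-multinomial with planted tumor fold changes on the expected
#' percentage scale. Deterministic for a fixed \code{config$seed}
#' (Mersenne-Twister; child seeds by fixed offsets).
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return a \code{SingleCellExperiment} with assay \code{counts}
#'   (sparse), per-cell \code{colData} (patient, sample, tissue, batch,
#'   true_minor, true_major) and ground truth in
#'   \code{S4Vectors::metadata(sce)$truth}: gene modules, marker/program sets,
#'   planted axes, the shipped LR database (planted + decoys), artifact genes
#'   and samples, planted abundance fold changes, expected compositions.
#' @export
generateCohort <- function(config) {
  if (!inherits(config, "SyntheticConfig"))
    stop("config must be created by syntheticConfig()")
  cfg <- config
  minors <- cfg$minors
  majors <- paste0("M", seq_len(cfg$nMajorTypes))
  K <- length(minors)
  rng <- RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  on.exit(do.call(RNGkind, as.list(rng)), add = TRUE)

  ## ---- gene universe (child seed offset 1) ----
  set.seed(.childSeed(cfg$seed, 1))
  nMito <- round(cfg$mitoGeneFraction * cfg$nGenes)
  genes <- sprintf("g%04d", seq_len(cfg$nGenes))
  module <- rep("noise", cfg$nGenes)
  cursor <- 0L
  take <- function(n) {
    idx <- cursor + seq_len(n); cursor <<- cursor + n; idx
  }
  mitoIdx <- take(nMito); module[mitoIdx] <- "mito"
  markerSets <- list()
  for (mj in majors) {
    idx <- take(cfg$markerGenesPerCluster)
    module[idx] <- paste0("marker:", mj); markerSets[[mj]] <- genes[idx]
  }
  for (mn in minors) {
    idx <- take(cfg$markerGenesPerCluster)
    module[idx] <- paste0("marker:", mn); markerSets[[mn]] <- genes[idx]
  }
  programGenes <- list()
  for (mn in minors) {
    idx <- take(cfg$degsPerModule)
    module[idx] <- paste0("program:", mn); programGenes[[mn]] <- genes[idx]
  }
  lr <- cfg$lrPairs
  for (i in seq_len(nrow(lr))) {
    if (is.na(lr$ligand[i])) {
      idx <- take(1L); module[idx] <- paste0("ligand:", i)
      lr$ligand[i] <- genes[idx]
    }
    if (is.na(lr$receptor[i])) {
      idx <- take(1L); module[idx] <- paste0("receptor:", i)
      lr$receptor[i] <- genes[idx]
    }
  }
  if (any(c(lr$ligand, lr$receptor) %in% genes[mitoIdx]))
    stop("ligand/receptor genes must lie outside the mitochondrial set")
  artifactIdx <- take(cfg$artifactGeneCount); module[artifactIdx] <- "artifact"
  noiseIdx <- which(module == "noise")

  mu <- stats::rlnorm(cfg$nGenes, meanlog = log(cfg$baselineMean) - 0.32,
                      sdlog = 0.8)
  # canonical markers and signalling genes are detectable by construction:
  # floor their baseline means at the cohort's mean scale
  floorIdx <- c(match(unlist(markerSets), genes),
                match(c(lr$ligand, lr$receptor), genes))
  mu[floorIdx] <- pmax(mu[floorIdx], cfg$baselineMean)
  # scale mitochondrial means to an expected ~5% mitochondrial fraction
  m0 <- 0.05
  f <- m0 / (1 - m0) * sum(mu[-mitoIdx]) / sum(mu[mitoIdx])
  mu[mitoIdx] <- mu[mitoIdx] * f

  # per-minor multiplicative factors
  fac <- matrix(1, cfg$nGenes, K, dimnames = list(genes, minors))
  eff <- 2^cfg$markerLog2Effect
  for (mn in minors) {
    mj <- sub("\\..*$", "", mn)
    fac[markerSets[[mj]], mn] <- eff
    fac[markerSets[[mn]], mn] <- eff
    fac[programGenes[[mn]], mn] <- eff
  }
  for (i in seq_len(nrow(lr))) {
    fac[lr$ligand[i], lr$sender[i]] <- fac[lr$ligand[i], lr$sender[i]] *
      2^lr$effect[i]
    fac[lr$receptor[i], lr$receiver[i]] <- fac[lr$receptor[i], lr$receiver[i]] *
      2^lr$effect[i]
  }

  # decoy LR pairs over background genes (database bookkeeping only)
  decoy <- NULL
  if (cfg$nDecoyPairs > 0) {
    pool <- sample(genes[noiseIdx])
    nd <- min(cfg$nDecoyPairs, floor(length(pool) / 2))
    decoy <- data.frame(ligand = pool[seq_len(nd)],
                        receptor = pool[nd + seq_len(nd)],
                        stringsAsFactors = FALSE)
  }
  lrDatabase <- rbind(
    data.frame(ligand = lr$ligand, receptor = lr$receptor, planted = TRUE,
               stringsAsFactors = FALSE),
    if (!is.null(decoy)) cbind(decoy, planted = FALSE))

  # junk-cell support: background genes only, scaled to preserve depth
  junkSupport <- genes[noiseIdx]
  junkMu <- rep(0, cfg$nGenes)
  junkMu[noiseIdx] <- mu[noiseIdx] * sum(mu[-mitoIdx]) / sum(mu[noiseIdx])
  junkMu[mitoIdx] <- mu[mitoIdx] * 2

  ## ---- composition (child seed offset 2) ----
  set.seed(.childSeed(cfg$seed, 2))
  pNormal <- stats::setNames(rep(1 / K, K), minors)
  pTumor <- pNormal
  fcIdx <- match(names(cfg$tumorEnriched), minors)
  pTumor[fcIdx] <- pNormal[fcIdx] * cfg$tumorEnriched
  rest <- setdiff(seq_len(K), fcIdx)
  pTumor[rest] <- pNormal[rest] * (1 - sum(pTumor[fcIdx])) / sum(pNormal[rest])

  samples <- data.frame(
    sample = paste0("P", rep(seq_len(cfg$nPatients), each = 2),
                    rep(c("T", "N"), cfg$nPatients)),
    patient = paste0("P", rep(seq_len(cfg$nPatients), each = 2)),
    tissue = rep(c("tumor", "normal"), cfg$nPatients),
    stringsAsFactors = FALSE)
  samples$batch <- ifelse(as.integer(sub("P", "", samples$patient)) %% 2 == 1,
                          "3prime", "5prime")

  cellSample <- character(0); cellCluster <- character(0)
  for (s in seq_len(nrow(samples))) {
    p <- if (samples$tissue[s] == "tumor") pTumor else pNormal
    alpha <- cfg$dirichletConcentration * p
    g <- stats::rgamma(K, shape = alpha, rate = 1)
    pi_s <- g / sum(g)
    cl <- sample(minors, cfg$cellsPerSample, replace = TRUE, prob = pi_s)
    if (cfg$junkCellsPerSample > 0)
      cl <- c(cl, rep("junk", cfg$junkCellsPerSample))
    cellSample <- c(cellSample, rep(samples$sample[s], length(cl)))
    cellCluster <- c(cellCluster, cl)
  }
  nCells <- length(cellCluster)
  cellIds <- sprintf("c%05d", seq_len(nCells))

  ## ---- counts (child seed offset 3) ----
  set.seed(.childSeed(cfg$seed, 3))
  size <- 1 / cfg$nbDispersion
  counts <- matrix(0L, cfg$nGenes, nCells, dimnames = list(genes, cellIds))
  artMul <- rep(1, cfg$nGenes); artMul[artifactIdx] <- 2^cfg$artifactEffect
  isArt <- cellSample %in% cfg$artifactSamples
  groups <- split(seq_len(nCells),
                  paste(cellCluster, ifelse(isArt, "A", "-"), sep = "|"))
  for (gn in sort(names(groups))) {
    idx <- groups[[gn]]
    parts <- strsplit(gn, "|", fixed = TRUE)[[1]]
    base <- if (parts[1] == "junk") junkMu else mu * fac[, parts[1]]
    if (parts[2] == "A") base <- base * artMul
    counts[, idx] <- matrix(
      stats::rnbinom(cfg$nGenes * length(idx), size = size, mu = base),
      nrow = cfg$nGenes)
  }

  cd <- S4Vectors::DataFrame(
    sample = cellSample,
    patient = samples$patient[match(cellSample, samples$sample)],
    tissue = samples$tissue[match(cellSample, samples$sample)],
    batch = samples$batch[match(cellSample, samples$sample)],
    true_minor = cellCluster,
    true_major = ifelse(cellCluster == "junk", "junk",
                        sub("\\..*$", "", cellCluster)),
    row.names = cellIds)
  rd <- S4Vectors::DataFrame(mito = seq_len(cfg$nGenes) %in% mitoIdx,
                             module = module, row.names = genes)
  truth <- list(
    cellClusters = stats::setNames(cellCluster, cellIds),
    cellMajor = stats::setNames(as.character(cd$true_major), cellIds),
    geneModules = stats::setNames(module, genes),
    markerSets = markerSets,
    programGenes = programGenes,
    lrAxes = lr,
    lrDatabase = lrDatabase,
    artifactGenes = genes[artifactIdx],
    artifactSamples = cfg$artifactSamples,
    abundanceFC = cfg$tumorEnriched,
    hubCluster = cfg$hubCluster,
    expectedProportions = list(normal = pNormal, tumor = pTumor),
    generativeMeans = list(baseline = stats::setNames(mu, genes),
                           clusterFactors = fac))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = cd, rowData = rd)
  S4Vectors::metadata(sce)$truth <- truth
  S4Vectors::metadata(sce)$config <- cfg
  sce
}

#' Ground truth of a synthetic cohort
#' @param sce a \code{SingleCellExperiment} from \code{\link{generateCohort}}.
#' @return the ground-truth list stored at generation time.
#' @export
groundTruth <- function(sce) {
  tr <- S4Vectors::metadata(sce)$truth
  if (is.null(tr)) stop("no ground truth: not a generated cohort")
  tr
}

#' Generate synthetic bulk DEG lists mapping to planted cell-type programs
#'
#' Emulates the bulk RNA-seq differential-expression lists consumed by the
#' bi-clustering integration: for each requested cell-type program it emits
#' that cluster's dedicated program genes with synthetic positive log2 fold
#' changes and small adjusted p-values, plus a stated fraction of decoy
#' (background) genes.
#'
#' @param truth ground truth from \code{\link{groundTruth}}.
#' @param modules minor cluster ids to draw programs from (default: all).
#' @param degsPerModule genes per program (default: all available program
#'   genes per module).
#' @param decoyFraction decoys as a fraction of the planted gene total.
#' @param seed RNG seed for fold changes / p-values / decoy choice.
#' @return data.frame(gene, log2fc, padj, module); \code{module} is generator
#'   bookkeeping ("decoy" for decoys), not part of the DEG-list contract.
#' @export
generateBulkDEGs <- function(truth, modules = NULL, degsPerModule = NULL,
                             decoyFraction = 0, seed = 1L) {
  if (length(truth$programGenes) < 1) stop("truth contains no planted programs")
  if (is.null(modules)) modules <- names(truth$programGenes)
  if (!all(modules %in% names(truth$programGenes)))
    stop("unknown program module requested")
  set.seed(.childSeed(seed, 7))
  rows <- list()
  for (mn in modules) {
    gs <- truth$programGenes[[mn]]
    k <- if (is.null(degsPerModule)) length(gs) else min(degsPerModule,
                                                         length(gs))
    if (k == 0) next
    rows[[mn]] <- data.frame(gene = gs[seq_len(k)],
                             log2fc = stats::runif(k, 0.5, 3),
                             padj = 10^-stats::runif(k, 6, 20),
                             module = mn, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene = character(), log2fc = numeric(),
                                      padj = numeric(), module = character())
  nDecoy <- round(decoyFraction * nrow(out))
  if (nDecoy > 0) {
    pool <- names(truth$geneModules)[truth$geneModules == "noise"]
    dg <- sample(pool, min(nDecoy, length(pool)))
    out <- rbind(out, data.frame(gene = dg,
                                 log2fc = stats::runif(length(dg), 0.5, 3),
                                 padj = 10^-stats::runif(length(dg), 6, 20),
                                 module = "decoy", stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
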