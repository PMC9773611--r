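# Shared synthetic cohorts, generated once per test run.

suppressPackageStartupMessages({
  library(SingleCellExperiment)
})

# Default desk-scale cohort (6 patients x tumor/normal x 120 cells).
defaultCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sce <- generateCohort(syntheticConfig())
      cache <<- normalizeCounts(sce)
    }
    cache
  }
})

cohortTruth <- function(sce = defaultCohort()) groundTruth(sce)

majorMarkerSets <- function(tr, nMajor = 4)
  tr$markerSets[paste0("M", seq_len(nMajor))]

minorMarkerSets <- function(tr, nMajor = 4)
  tr$markerSets[setdiff(names(tr$markerSets), paste0("M", seq_len(nMajor)))]

# Cohort whose only planted variable structure is the marker blocks
# (no artifact, no program genes, null LR effects).
plainMarkerConfig <- function(seed = 13)
  syntheticConfig(nPatients = 3, cellsPerSample = 120, degsPerModule = 0,
                  artifactEffect = 0, markerLog2Effect = 2.5,
                  lrPairs = data.frame(ligand = NA_character_,
                                       receptor = NA_character_,
                                       sender = "M1.1", receiver = "M2.1",
                                       effect = 0),
                  seed = seed)

# Small two-cluster cohort for effect-size checks.
twoClusterConfig <- function(seed = 1, ...)
  syntheticConfig(nPatients = 2, cellsPerSample = 50, nGenes = 500,
                  nMajorTypes = 2, nMinorPerMajor = 1,
                  markerGenesPerCluster = 10,
                  lrPairs = data.frame(ligand = NA_character_,
                                       receptor = NA_character_,
                                       sender = "M1.1", receiver = "M2.1",
                                       effect = 3),
                  tumorEnriched = c(M2.1 = 1.5), degsPerModule = 5,
                  seed = seed, ...)
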