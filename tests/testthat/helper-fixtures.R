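# Shared fixtures, memoized so expensive simulations/discoveries run once
# per test session.

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# Small study for unit tests: 3 cohorts x 25 samples, 600 genes,
# 80 matrisome genes, 20 + 20 planted signature genes.
smallConfig <- function(seed = 11, effect = 1.0, ...) {
  simulationConfig(nGenes = 600L, nMatrisome = 80L,
                   nSignaturePerSubtype = 20L,
                   nSamplesPerCohort = c(25L, 25L, 25L),
                   effectLog2fc = effect, seed = seed, ...)
}

# Normalize + batch-correct + center a simulated study; returns the pieces
# downstream stages need.
preparedStudy <- function(study, doTMM = TRUE) {
  f <- if (doTMM) tmmFactors(study$counts) else NULL
  lc <- logCPM(study$counts, f)
  bc <- removeBatch(lc)
  gm <- rowMeans(exprValues(bc))
  cen <- centerGenes(bc)
  sub <- subsetExpression(cen, genes = setGenes(study$matrisome))
  list(study = study, logcpm = bc, geneMeans = gm, centered = cen,
       matrisome = sub)
}

smallPrepared <- function() memo("smallPrepared", {
  preparedStudy(simulateBulk(smallConfig()))
})

# One full small-scale discovery (consensus rank 2, core samples, DE,
# signatures), shared by signature/pipeline tests.
smallDiscovery <- function() memo("smallDiscovery", {
  prep <- smallPrepared()
  res <- consensusNMF(prep$matrisome, ranks = 2, nRuns = 15, seed = 5)[[1]]
  core <- coreSamples(res)
  labs <- clusterLabels(res)
  classLab <- setNames(ifelse(labs[core] == 1L, "A", "B"), core)
  coreX <- subsetExpression(prep$logcpm, samples = core)
  de <- wilcoxonDE(coreX, classLab)
  sigs <- deriveSignatures(de)
  c(prep, list(consensus = res, core = core, labels = labs,
               classLab = classLab, de = de, signatures = sigs))
})

# Map consensus cluster ids to truth labels by majority overlap; returns
# the truth label ("hi"/"lo") corresponding to cluster 1.
clusterOneTruth <- function(labels, truth) {
  tab <- table(truth[names(labels)], labels)
  rownames(tab)[which.max(tab[, "1"])]
}

# Acceptance-scale study: the discovery conditions (3 cohorts x 50, 2000
# genes, 200 matrisome, 40+40 planted signature genes at 1.0 log2FC).
acceptancePrepared <- function() memo("acceptancePrepared", {
  preparedStudy(simulateBulk(simulationConfig(seed = 101L)))
})

# Write the small study to disk once; pipeline runs read these files.
studyFiles <- function() memo("studyFiles", {
  d <- file.path(tempdir(), "ecmstates-study")
  dir.create(d, showWarnings = FALSE)
  st <- smallPrepared()$study
  writeExpression(st$counts, file.path(d, "counts.tsv"))
  writeClinical(st$clinical, file.path(d, "clinical.tsv"))
  writeGMT(st$matrisome, file.path(d, "matrisome.gmt"))
  list(dir = d, counts = file.path(d, "counts.tsv"),
       clinical = file.path(d, "clinical.tsv"),
       geneset = file.path(d, "matrisome.gmt"), study = st)
})

acceptanceConsensus <- function() memo("acceptanceConsensus", {
  consensusNMF(acceptancePrepared()$matrisome, ranks = 2:4, nRuns = 30,
               seed = 7L)
})
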