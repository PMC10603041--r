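test_that("adjusted Rand index matches hand values and symmetries", {
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # all-singletons vs one block: no agreement beyond chance
  expect_equal(adjustedRandIndex(c("a", "b"), c("x", "x")), 0)
  # index 1, expected 1, max 2.5 -> ARI 0
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0)
  set.seed(1)
  a <- sample(1:3, 12, replace = TRUE)
  b <- sample(1:4, 12, replace = TRUE)
  expect_equal(adjustedRandIndex(a, b), adjustedRandIndex(b, a))
  expect_equal(adjustedRandIndex(a, b),
               adjustedRandIndex(c("x", "y", "z")[a], b))
  expect_error(adjustedRandIndex(1:3, 1:4), "equal length")
})

test_that("ARI agrees with a pair-counting oracle and mclust", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b), oracleARI(a, b), tolerance = 1e-12)
  }
  skip_if_not_installed("mclust")
  set.seed(3)
  a <- sample(1:4, 40, replace = TRUE)
  b <- sample(1:3, 40, replace = TRUE)
  expect_equal(adjustedRandIndex(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
})

test_that("silhouette widths match a brute-force implementation", {
  set.seed(4)
  for (i in 1:5) {
    n <- sample(10:30, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    d <- as.matrix(dist(x))
    got <- ecmstates:::silhouetteWidthsFromDist(labels, d)
    expect_equal(unname(got), oracleSilhouette(labels, d), tolerance = 1e-9)
  }
})

test_that("consensus NMF recovers planted subtypes and ranks them by cophenetic", {
  prep <- smallPrepared()
  res <- consensusNMF(prep$matrisome, ranks = 2:3, nRuns = 12, seed = 3)
  r2 <- res[["rank2"]]
  core <- coreSamples(r2)
  truth <- prep$study$truthLabels[core]
  expect_gte(adjustedRandIndex(clusterLabels(r2)[core], truth), 0.9)
  expect_gt(copheneticCoef(r2), copheneticCoef(res[["rank3"]]))
  # consensus entries are valid co-clustering frequencies
  C <- consensusMatrix(r2)
  expect_true(all(C >= 0 & C <= 1))
  expect_equal(unname(diag(C)), rep(1, ncol(C)))
})

test_that("a perfectly separated dataset gives cophenetic 1 and silhouettes 1", {
  set.seed(8)
  v <- cbind(matrix(rnorm(40 * 8, mean = 5), 40, 8),
             matrix(rnorm(40 * 8, mean = -5), 40, 8))
  dimnames(v) <- list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:16))
  v <- v - rowMeans(v)
  res <- consensusNMF(v, ranks = 2, nRuns = 10, seed = 2)[[1]]
  expect_true(all(consensusMatrix(res) %in% c(0, 1)))
  expect_equal(copheneticCoef(res), 1)
  expect_equal(unname(silhouetteWidths(res)), rep(1, 16))
  expect_true(all(res@coreMask))
})

test_that("consensus matrices are equivariant under sample reordering", {
  prep <- smallPrepared()
  v <- exprValues(prep$matrisome)[, 1:30]
  res <- consensusNMF(v, ranks = 2, nRuns = 5, seed = 9)[[1]]
  set.seed(1)
  perm <- sample(30)
  resP <- consensusNMF(v[, perm], ranks = 2, nRuns = 5, seed = 9)[[1]]
  back <- consensusMatrix(resP)[order(perm), order(perm)]
  expect_lt(max(abs(back - consensusMatrix(res))), 1e-12)
})

test_that("hierarchical consensus agrees with NMF consensus on planted data", {
  prep <- smallPrepared()
  hres <- consensusHclust(prep$matrisome, rank = 2, nResamples = 100,
                          subsampleFrac = 0.8, seed = 4)
  nres <- consensusNMF(prep$matrisome, ranks = 2, nRuns = 12, seed = 3)[[1]]
  expect_gte(adjustedRandIndex(clusterLabels(hres), clusterLabels(nres)), 0.8)
  C <- consensusMatrix(hres)
  expect_true(all(C >= 0 & C <= 1))
})

test_that("degenerate hierarchical consensus reduces to plain hclust", {
  prep <- smallPrepared()
  v <- exprValues(prep$matrisome)[, 1:20]
  res <- consensusHclust(v, rank = 2, nResamples = 1, subsampleFrac = 1,
                         seed = 1)
  plain <- cutree(hclust(dist(t(v)), method = "average"), k = 2)
  expect_equal(adjustedRandIndex(clusterLabels(res), plain), 1)
})

test_that("bin-matched controls come from the source gene's bin", {
  set.seed(5)
  means <- setNames(sort(rnorm(300, 6, 2)), sprintf("g%03d", 1:300))
  src <- sample(names(means), 40)
  ctrl <- binMatchedControls(src, means, nBins = 30, seed = 2)
  bins <- ecmstates:::expressionBins(means, 30)
  expect_equal(unname(bins[ctrl]), unname(bins[src]))  # per-gene invariant
  expect_length(ctrl, 40)
  expect_false(any(ctrl == src))  # source gene excluded

  # nBins = 1: controls are a uniform draw from all analyzed genes
  c1 <- binMatchedControls(src, means, nBins = 1, seed = 3)
  expect_true(all(c1 %in% names(means)))

  # quantile-bin geometry: |mean difference| <= bin width for >= 95% of pairs
  binWidth <- diff(range(means)) / 30 * 3  # generous: equal-frequency bins
  expect_gte(mean(abs(means[ctrl] - means[src]) <= binWidth), 0.95)

  # empty bin after exclusion: every gene alone in its bin
  two <- setNames(c(1, 10), c("a", "b"))
  expect_error(binMatchedControls("a", two, nBins = 2), "empty bin")
})

test_that("bootstrap stability separates planted signal from the null", {
  # the analysis set must be a small fraction of the genome, otherwise
  # bin-matched controls are contaminated with planted signature genes
  cfg <- simulationConfig(nGenes = 1200L, nMatrisome = 60L,
                          nSignaturePerSubtype = 15L,
                          nSamplesPerCohort = c(20L, 20L, 20L), seed = 23)
  prep <- preparedStudy(simulateBulk(cfg))
  res <- consensusNMF(prep$matrisome, ranks = 2, nRuns = 10, seed = 3)[[1]]
  sr <- bootstrapStability(prep$centered, prep$study$matrisome,
                           prep$geneMeans, referenceLabels = clusterLabels(res),
                           B = 20, seed = 6)
  expect_gt(median(sr@observedARI), quantile(sr@nullARI, 0.95))
  expect_true(all(abs(c(sr@observedARI, sr@nullARI)) <= 1))

  one <- bootstrapStability(prep$centered, prep$study$matrisome,
                            prep$geneMeans, referenceLabels = clusterLabels(res),
                            B = 1, seed = 7)
  expect_length(one@observedARI, 1)
  expect_length(one@nullARI, 1)
  expect_error(bootstrapStability(prep$centered, prep$study$matrisome,
                                  prep$geneMeans,
                                  referenceLabels = clusterLabels(res),
                                  B = 0), "B must be")
})

test_that("consensus clustering rejects invalid ranks and tiny inputs", {
  v <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:12)))
  expect_error(consensusNMF(v[, 1:8], ranks = 2), ">= 10 samples")
  expect_error(consensusNMF(v, ranks = 12), "smaller than the number")
})
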