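mkLog <- function(v, batch = rep("c1", ncol(v))) {
  if (is.null(dimnames(v)))
    dimnames(v) <- list(sprintf("g%04d", seq_len(nrow(v))),
                        sprintf("s%02d", seq_len(ncol(v))))
  ExpressionMatrix(v, batch = batch, scale = "logcpm")
}

test_that("Wilcoxon DE reproduces the exact small-sample p-value", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1)
  x <- mkLog(v)
  labels <- setNames(c("A", "A", "A", "B", "B", "B"), sampleIds(x))
  de <- wilcoxonDE(x, labels)
  expect_equal(de$p, 0.1, tolerance = 1e-12)       # most extreme of 20 splits
  expect_equal(de$log2fc, -3)                      # mean(A) - mean(B)
  expect_equal(de$p, oracleWilcoxP(v[1:3], v[4:6]), tolerance = 1e-12)

  ident <- mkLog(matrix(c(1, 2, 3, 1, 2, 3), nrow = 1))
  de0 <- wilcoxonDE(ident, labels)
  expect_equal(de0$p, 1)
  expect_equal(de0$log2fc, 0)
})

test_that("exact Wilcoxon p agrees with enumeration for group sizes <= (5,5)", {
  set.seed(12)
  for (i in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- rnorm(na); b <- rnorm(nb)
    v <- matrix(c(a, b), nrow = 1,
                dimnames = list("g1", sprintf("s%02d", seq_len(na + nb))))
    x <- ExpressionMatrix(v, scale = "logcpm")
    labels <- setNames(rep(c("A", "B"), c(na, nb)), colnames(v))
    de <- wilcoxonDE(x, labels)
    expect_equal(de$p, oracleWilcoxP(a, b), tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(oracleBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  prep <- smallDiscovery()
  de <- prep$de
  for (coh in unique(de$cohort)) {
    d <- de[de$cohort == coh, ]
    expect_equal(d$padj, oracleBH(d$p), tolerance = 1e-12)
  }
})

test_that("Wilcoxon DE requires both classes in every cohort", {
  v <- matrix(rnorm(8), 2, 4,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  x <- ExpressionMatrix(v, batch = c("c1", "c1", "c2", "c2"),
                        scale = "logcpm")
  labels <- setNames(c("A", "B", "A", "A"), paste0("s", 1:4))
  expect_error(wilcoxonDE(x, labels), "cohort 'c1'")
})

test_that("signature derivation is a strict cross-cohort intersection", {
  de <- expand.grid(gene_id = c("g1", "g2", "g3"),
                    cohort = c("c1", "c2", "c3"), stringsAsFactors = FALSE)
  de$log2fc <- 2
  de$p <- 0.001
  de$padj <- 0.01
  # g2 not significant in cohort 3 (2/3 rule); g3 downregulated there
  de$padj[de$gene_id == "g2" & de$cohort == "c3"] <- 0.2
  de$log2fc[de$gene_id == "g3" & de$cohort == "c3"] <- -2
  sigs <- suppressWarnings(deriveSignatures(de))
  expect_equal(setGenes(signatureA(sigs)), "g1")
  # reversing cohort order changes nothing
  sigs2 <- suppressWarnings(deriveSignatures(de[order(de$cohort,
                                                      decreasing = TRUE), ]))
  expect_equal(setGenes(signatureA(sigs2)), setGenes(signatureA(sigs)))
})

test_that("planted signatures are recovered with no false positives", {
  d <- smallDiscovery()
  hiOfOne <- clusterOneTruth(d$labels[d$core], d$study$truthLabels)
  sigHi <- if (hiOfOne == "hi") signatureA(d$signatures) else signatureB(d$signatures)
  sigLo <- if (hiOfOne == "hi") signatureB(d$signatures) else signatureA(d$signatures)
  plantedHi <- setGenes(d$study$truthSignatureHi)
  plantedLo <- setGenes(d$study$truthSignatureLo)
  expect_gte(length(intersect(setGenes(sigHi), plantedHi)) / length(plantedHi),
             0.8)
  expect_length(setdiff(setGenes(sigHi), plantedHi), 0)
  expect_length(setdiff(setGenes(sigLo), plantedLo), 0)
})

test_that("signature scores match a hand-computed toy example", {
  v <- cbind(s1 = c(1, 2, 3, 10, 11, 12), s2 = c(3, 2, 1, 12, 11, 10))
  rownames(v) <- paste0("g", 1:6)
  x <- ExpressionMatrix(v, batch = c("b", "b"), scale = "logcpm")
  # two equal-frequency bins: {g1,g2,g3} and {g4,g5,g6}; whole-pool controls
  sc <- signatureScore(x, c("g2", "g4"), nBins = 2, nControlsPerGene = 100,
                       excludeSource = FALSE)
  expect_equal(unname(sc["s1"]), mean(c(2 - 2, 10 - 11)), tolerance = 1e-12)
  expect_equal(unname(sc["s2"]), mean(c(2 - 2, 12 - 11)), tolerance = 1e-12)
})

test_that("scoring identities: self-control zero, translation, delta shift", {
  set.seed(30)
  v <- matrix(rnorm(10 * 8, 5), 10, 8,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  x <- ExpressionMatrix(v, scale = "logcpm")
  # control pool == signature set itself -> exact zero
  sc <- signatureScore(x, rownames(v), nBins = 1, excludeSource = FALSE)
  expect_lt(max(abs(sc)), 1e-9)

  # translation: add c to every gene of one sample, bins held fixed
  set.seed(31)
  big <- matrix(rnorm(300 * 6, 6, 2), 300, 6,
                dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:6)))
  xb <- ExpressionMatrix(big, scale = "logcpm")
  gm <- rowMeans(big)
  sig <- rownames(big)[order(gm)][seq(15, 285, by = 30)]  # one per bin
  s0 <- signatureScore(xb, sig, seed = 5, geneMeans = gm)
  shifted <- big; shifted[, "s3"] <- shifted[, "s3"] + 2.5
  s1 <- signatureScore(ExpressionMatrix(shifted, scale = "logcpm"), sig,
                       seed = 5, geneMeans = gm)
  expect_lt(abs(s1["s3"] - s0["s3"]), 1e-12)

  # delta shift of the signature genes of one sample moves its score by delta
  shifted2 <- big; shifted2[sig, "s2"] <- shifted2[sig, "s2"] + 0.7
  s2 <- signatureScore(ExpressionMatrix(shifted2, scale = "logcpm"), sig,
                       seed = 5, geneMeans = gm)
  expect_lt(abs((s2["s2"] - s0["s2"]) - 0.7), 1e-9)
  expect_lt(max(abs(s2[-2] - s0[-2])), 1e-12)
})

test_that("signature scoring validates gene presence", {
  v <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  x <- ExpressionMatrix(v, scale = "logcpm")
  expect_error(signatureScore(x, c("nope1", "nope2")), "no signature gene")
  expect_warning(sc <- signatureScore(x, c("g1", "nope"), nBins = 1),
                 "dropping 1")
  expect_length(sc, 4)
})

test_that("sign-based classification follows the strict-inequality rule", {
  expect_equal(unname(classifyBySign(0.5, -0.2)), "A")
  expect_equal(unname(classifyBySign(-0.4, 0.3)), "B")
  expect_equal(unname(classifyBySign(0.3, 0.4)), "intermediate")
  expect_equal(unname(classifyBySign(-0.3, -0.4)), "intermediate")
  expect_equal(unname(classifyBySign(0.0, -0.1)), "intermediate")
  expect_equal(unname(classifyBySign(c(1, -1), c(-1, 1))), c("A", "B"))
})

test_that("marker selection applies detection, fold-change and top-N rules", {
  nT <- 20; nO <- 20
  genes <- c("m90", "low40", sprintf("p%02d", 1:60), sprintf("bg%02d", 1:38))
  counts <- matrix(0L, nT + nO, length(genes),
                   dimnames = list(sprintf("c%02d", 1:(nT + nO)), genes))
  counts[1:18, "m90"] <- 400L                # 90% detection in target
  counts[1:8, "low40"] <- 500L               # 40% detection, huge FC
  for (j in 1:60) counts[1:nT, sprintf("p%02d", j)] <- 201L - j
  counts[, sprintf("bg%02d", 1:38)] <- 5L    # uniform background
  labels <- setNames(rep(c("T", "O"), c(nT, nO)), rownames(counts))
  markers <- selectMarkers(counts, labels, "T")
  got <- setGenes(markers)
  expect_length(got, 50)                      # 62 pass, top 50 kept
  expect_true("m90" %in% got)
  expect_false("low40" %in% got)              # detection < 50% removed
  expect_true(all(sprintf("p%02d", 1:49) %in% got))
  expect_false(any(sprintf("bg%02d", 1:38) %in% got))

  expect_error(selectMarkers(counts, labels, "missing"), "not present")
  # identical expression in both types: nothing passes the FC filter
  flat <- matrix(5L, 10, 4, dimnames = list(sprintf("c%02d", 1:10),
                                            sprintf("g%02d", 1:4)))
  flatLab <- setNames(rep(c("T", "O"), each = 5), rownames(flat))
  expect_warning(none <- selectMarkers(flat, flatLab, "O"), "no marker")
  expect_length(setGenes(none), 0)
})

test_that("markers planted by the single-cell generator are selected", {
  plan <- list(A = list(genes = c("scg00010", "scg00011"), exprProb = 0.9,
                        foldChange = 4))
  sc <- simulateSingleCell(c(A = 300L, B = 300L), nGenes = 200L,
                           markerPlan = plan, seed = 13)
  markers <- selectMarkers(sc$counts, sc$cellLabels, "A")
  expect_true(all(c("scg00010", "scg00011") %in% setGenes(markers)))
})

test_that("stratification honours the type-7 quartile convention", {
  s <- setNames(as.numeric(1:8), paste0("s", 1:8))
  out <- stratifyScores(s, "quartile")
  expect_equal(sum(out == "high"), 2)   # scores above Q3 = 6.25
  expect_equal(sum(out == "low"), 2)    # scores below Q1 = 2.75
  expect_equal(sum(out == "unassigned"), 4)

  expect_equal(unname(stratifyScores(c(0.5, 1.5), "cutoff", cutoff = 1)),
               c("low", "high"))
  allEq <- stratifyScores(rep(2, 6), "quartile")
  expect_true(all(allEq == "unassigned"))
  expect_error(stratifyScores(1:3, "quartile"), ">= 4")
})

test_that("pseudobulk sums cell counts and conserves totals", {
  counts <- rbind(c1 = c(1, 2), c2 = c(3, 4), c3 = c(10, 0))
  colnames(counts) <- c("gA", "gB")
  map <- c(c1 = "s1", c2 = "s1", c3 = "s2")
  pb <- pseudobulk(counts, map)
  expect_equal(unname(exprValues(pb)[, "s1"]), c(4, 6))
  expect_equal(sum(exprValues(pb)), sum(counts))
  expect_equal(exprScale(pb), "counts")
  expect_error(pseudobulk(counts, map[1:2]), "unmapped")
})

test_that("pseudobulk profiles from planted-subtype cells classify correctly", {
  d <- smallDiscovery()
  bulk <- exprValues(d$study$counts)
  samples <- colnames(bulk)[c(1:6, 70:75)]   # mix of hi and lo samples
  # split each bulk sample into 15 cells (multinomial over genes)
  set.seed(17)
  cellCounts <- NULL; cellNames <- character(0); map <- character(0)
  for (s in samples) {
    cells <- t(rmultinom(15, size = sum(bulk[, s]) %/% 15, prob = bulk[, s]))
    colnames(cells) <- rownames(bulk)
    rn <- paste0(s, "_cell", 1:15)
    cellCounts <- rbind(cellCounts, cells)
    cellNames <- c(cellNames, rn)
    map <- c(map, setNames(rep(s, 15), rn))
  }
  rownames(cellCounts) <- cellNames
  pb <- pseudobulk(cellCounts, map)
  lc <- logCPM(pb, tmmFactors(pb))
  sA <- signatureScore(lc, signatureA(d$signatures), seed = 1)
  sB <- signatureScore(lc, signatureB(d$signatures), seed = 2)
  called <- classifyBySign(sA, sB)
  truth <- d$study$truthLabels[names(called)]
  hiOfOne <- clusterOneTruth(d$labels[d$core], d$study$truthLabels)
  expected <- ifelse(truth == hiOfOne, "A", "B")
  expect_gte(mean(called == expected), 0.9)
})
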