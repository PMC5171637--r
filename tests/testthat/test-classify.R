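nullRse <- function(nFeat = 12, nPer = 10, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(nFeat * 2 * nPer), nrow = nFeat,
                 dimnames = list(sprintf("f%02d", seq_len(nFeat)),
                                 sprintf("s%02d", seq_len(2 * nPer))))
  riskExpressionSet(vals, biotype = rep("lncRNA", nFeat),
                    sampleType = rep(c("tumor", "normal"), each = nPer))
}

test_that("rank-based AUC equals the Mann-Whitney U statistic", {
  set.seed(2)
  for (i in 1:10) {
    pos <- rnorm(7, 1)
    neg <- rnorm(9)
    scores <- c(pos, neg)
    labels <- rep(c(TRUE, FALSE), c(7, 9))
    U <- unname(stats::wilcox.test(pos, neg, exact = FALSE)$statistic)
    expect_equal(aucFromScores(scores, labels), U / (7 * 9))
  }
  # fixed score set with ties
  expect_equal(aucFromScores(c(3, 2, 2, 1), c(TRUE, TRUE, FALSE, FALSE)),
               (1 + 0.5 + 1 + 1) / 4)
})

test_that("ROC points run monotonically from (0,0) to (1,1)", {
  set.seed(3)
  roc <- rocPoints(rnorm(30), rep(c(TRUE, FALSE), 15))
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  if (requireNamespace("pROC", quietly = TRUE)) {
    sc <- rnorm(40); lb <- rep(c(1, 0), 20)
    ref <- as.numeric(suppressMessages(pROC::auc(lb, sc,
                                                 direction = "<")))
    expect_equal(aucFromScores(sc, lb == 1), ref)
  }
})

test_that("signal-to-noise follows its closed form and antisymmetry", {
  x <- rbind(f1 = c(2, 2, 0, 0), f2 = c(1, 3, 1, 3))
  lb <- c("tumor", "tumor", "normal", "normal")
  expect_warning(s2n <- signalToNoise(x, lb), "zero combined SD")
  expect_equal(unname(s2n["f1"]), 0)   # sd1 + sd2 = 0 -> 0 with warning
  expect_equal(unname(s2n["f2"]), 0)   # equal class means
  set.seed(4)
  y <- matrix(rnorm(40), 4, 10)
  lb2 <- rep(c("tumor", "normal"), 5)
  expect_equal(signalToNoise(y, lb2), -signalToNoise(y, lb2 == "normal"))
  # mu1 = 2, sd1 = 1, mu2 = 0, sd2 = 1 -> 1 (exact moments)
  z <- rbind(f = c(1, 3, -1, 1))
  expect_equal(unname(signalToNoise(z, c("tumor", "tumor", "normal",
                                         "normal"))), 2 / (sqrt(2) * 2))
})

test_that("a perfectly separating feature yields AUC 1 for both classifiers", {
  rse <- nullRse(seed = 8)
  v <- SummarizedExperiment::assay(rse, "exprs")
  v["f01", ] <- rep(c(5, -5), each = 10) + rnorm(20, sd = 0.1)
  rse2 <- riskExpressionSet(v, rep("lncRNA", nrow(v)),
                            rep(c("tumor", "normal"), each = 10))
  for (clf in c("svm", "naive_bayes")) {
    res <- cvClassify(rse2, "f01", classifier = clf, repeats = 3,
                      seed = 5L)
    expect_equal(res$aucPerRepeat, rep(1, 3))
  }
})

test_that("shuffled labels give chance-level AUC and seeds reproduce runs", {
  rse <- nullRse(nFeat = 6, nPer = 12, seed = 9)
  res <- cvClassify(rse, rownames(rse)[1:4], repeats = 30, seed = 17L,
                    nullLabels = TRUE)
  expect_lt(abs(res$meanAuc - 0.5), 0.1)
  res2 <- cvClassify(rse, rownames(rse)[1:4], repeats = 30, seed = 17L,
                     nullLabels = TRUE)
  expect_identical(res$aucPerRepeat, res2$aucPerRepeat)
  # loocv is deterministic: collapses to a single evaluation
  lo <- cvClassify(rse, rownames(rse)[1:4], scheme = "loocv",
                   repeats = 100, seed = 1L)
  expect_equal(lo$repeats, 1L)
})

test_that("implanted risk lncRNAs separate tumor from normal strongly", {
  sim <- cachedSim()
  st <- cohortStages(sim, "C3", B = 50L)
  res <- cvClassify(st$rse, sim$truth$riskLncrnas, repeats = 5,
                    seed = 19L)
  expect_gte(res$meanAuc, 0.8)
})

test_that("weighted voting is exact on a tiny hand-simulated dataset", {
  # 3 features x 12 samples; oracle below replays the algorithm with
  # explicit per-sample loops
  set.seed(77)
  vals <- matrix(rnorm(36), nrow = 3,
                 dimnames = list(c("a", "b", "c"), sprintf("s%02d", 1:12)))
  vals[1, 1:6] <- vals[1, 1:6] + 2.5
  rse <- riskExpressionSet(vals, rep("lncRNA", 3),
                           rep(c("tumor", "normal"), each = 6))
  got <- weightedVotingCurve(rse, c("a", "b", "c"), k = 3, repeats = 2,
                             seed = 23L)
  oracle <- local({
    y <- rep(c("tumor", "normal"), each = 6)
    seeds <- lncRiskPath:::childSeeds(23L, 2)
    total <- matrix(0, 2, 3)
    for (rp in 1:2) {
      total[rp, ] <- lncRiskPath:::withSeed(seeds[rp], {
        fold <- splitTrainValidate(colnames(vals), y, k = 3,
                                   seed = sample.int(2^30, 1))
        cnt <- c(0, 0, 0)
        for (f in 1:3) {
          tr <- fold != f
          s2n <- sapply(rownames(vals), function(g) {
            a <- vals[g, tr & y == "tumor"]; b <- vals[g, tr & y == "normal"]
            (mean(a) - mean(b)) / (sd(a) + sd(b))
          })
          ord <- order(abs(s2n), decreasing = TRUE)
          mid <- sapply(rownames(vals), function(g)
            (mean(vals[g, tr & y == "tumor"]) +
             mean(vals[g, tr & y == "normal"])) / 2)
          for (s in which(!tr)) {
            votes <- s2n * (vals[, s] - mid)
            for (g in 1:3) {
              pred <- sum(votes[ord[1:g]]) > 0
              if (pred != (y[s] == "tumor")) cnt[g] <- cnt[g] + 1
            }
          }
        }
        cnt
      })
    }
    colMeans(total)
  })
  expect_equal(got$curve$meanMisclassified, oracle)
})

test_that("duplicated features vote proportionally: identical curve values", {
  set.seed(88)
  vals <- matrix(rnorm(24), nrow = 1,
                 dimnames = list("a", sprintf("s%02d", 1:24)))
  vals["a", 1:12] <- vals["a", 1:12] + 2
  vals <- rbind(vals, b = vals["a", ])
  rse <- riskExpressionSet(vals, rep("lncRNA", 2),
                           rep(c("tumor", "normal"), each = 12))
  vc <- weightedVotingCurve(rse, c("a", "b"), k = 4, repeats = 5,
                            seed = 3L)
  expect_equal(vc$curve$meanMisclassified[1],
               vc$curve$meanMisclassified[2])
})

test_that("leaky feature ranking never looks worse than the honest one on null data", {
  rse <- nullRse(nFeat = 40, nPer = 10, seed = 55)
  feats <- rownames(rse)
  honest <- weightedVotingCurve(rse, feats, k = 5, repeats = 40,
                                seed = 91L)
  leaky <- weightedVotingCurve(rse, feats, k = 5, repeats = 40,
                               seed = 91L, rankOn = "all")
  # compare the best-prefix apparent error: selection on all samples leaks
  # the test labels and can only help apparent performance
  expect_lte(min(leaky$curve$meanMisclassified),
             min(honest$curve$meanMisclassified) + 0.5)
})
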