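test_that("delta-e subtracts the matched-normal mean on the log2 scale", {
  m <- rbind(f1 = c(5, 2, 1, 2, 3), f2 = c(4, 4, 4, 4, 4))
  colnames(m) <- c("t1", "t2", "n1", "n2", "n3")
  rse <- riskExpressionSet(m, biotype = c("lncRNA", "mRNA"),
                           sampleType = c("tumor", "tumor", "normal",
                                          "normal", "normal"))
  d <- computeDeltaE(rse, features = c("f1", "f2"))
  expect_equal(d["f1", "t1"], 5 - mean(c(1, 2, 3)))
  expect_equal(d["f1", "t1"], 3)
  expect_equal(d["f2", "t2"], 0)  # tumor equals the normal mean
  # translation invariance: shifting one feature everywhere changes nothing
  m2 <- m; m2["f1", ] <- m2["f1", ] + 11
  rse2 <- riskExpressionSet(m2, biotype = c("lncRNA", "mRNA"),
                            sampleType = c("tumor", "tumor", "normal",
                                           "normal", "normal"))
  expect_equal(computeDeltaE(rse2, features = "f1")["f1", ],
               d["f1", ])
  # median matching is available
  dm <- computeDeltaE(rse, features = "f1", center = "median")
  expect_equal(dm["f1", "t1"], 5 - 2)
})

test_that("pathway scoring pools member delta-e values set-wise", {
  delta <- matrix(c(1, 2, 3, 4, 5, -1, -2, -3, -4, -5), nrow = 2,
                  byrow = TRUE,
                  dimnames = list(c("up", "down"), paste0("t", 1:5)))
  # single member, five tumors, all positive: the n = 5 exact case
  s <- pathwayScore(delta, "up", minMembers = 1L)
  expect_equal(s$p.value, 0.0625)
  # order of members must not matter
  s1 <- pathwayScore(delta, c("up", "down"), minMembers = 1L)
  s2 <- pathwayScore(delta, c("down", "up"), minMembers = 1L)
  expect_equal(s1, s2)
  # all-zero member values give p = 1
  dz <- matrix(0, 1, 4, dimnames = list("z", paste0("t", 1:4)))
  expect_equal(pathwayScore(dz, "z", minMembers = 1L)$p.value, 1)
  # under min_members the pathway is untestable, not significant
  expect_false(pathwayScore(delta, "up")$testable)
})

test_that("permutation p matches exhaustive subset enumeration on a tiny universe", {
  set.seed(21)
  delta <- matrix(rnorm(6 * 4, mean = c(2, 2, 2, 0, 0, 0)), nrow = 6,
                  dimnames = list(paste0("f", 1:6), paste0("t", 1:4)))
  pc <- PathwayCollection(list(pw = c("f1", "f2", "f3")))
  res <- permutationCalibrate(delta, pc, B = 1L, seed = 1L,
                              exhaustive = TRUE)
  # oracle: enumerate all C(6,3) = 20 subsets with an independent test
  obs <- stats::wilcox.test(as.vector(delta[1:3, ]), exact = FALSE,
                            correct = TRUE)$p.value
  subsets <- utils::combn(rownames(delta), 3, simplify = FALSE)
  pb <- vapply(subsets, function(s)
    wilcoxonSignedRank(as.vector(delta[s, ]))$p.value, numeric(1))
  pObs <- wilcoxonSignedRank(as.vector(delta[1:3, ]))$p.value
  expect_equal(res$permP[1], (sum(pb <= pObs) + 1) / (length(pb) + 1))
})

test_that("strongest observed statistic reaches the +1-corrected floor", {
  set.seed(4)
  # one coherent pathway in an otherwise symmetric universe
  delta <- rbind(matrix(3 + rnorm(5 * 8, sd = 0.2), nrow = 5),
                 matrix(rnorm(45 * 8), nrow = 45))
  rownames(delta) <- paste0("f", 1:50)
  colnames(delta) <- paste0("t", 1:8)
  pc <- PathwayCollection(list(coherent = paste0("f", 1:5)))
  res <- permutationCalibrate(delta, pc, B = 200L, seed = 2L)
  expect_equal(res$permP[1], 1 / 201)
})

test_that("insignificance-share reading is available and bounded", {
  set.seed(12)
  delta <- matrix(rnorm(40 * 6), nrow = 40,
                  dimnames = list(paste0("f", 1:40), paste0("t", 1:6)))
  pc <- PathwayCollection(list(a = paste0("f", 1:4),
                               b = paste0("f", 30:36)))
  res <- permutationCalibrate(delta, pc, B = 60L, seed = 3L,
                              mode = "insignificance")
  expect_true(all(res$permP >= 0 & res$permP <= 1))
})

test_that("stratified folds partition samples and are seed-stable", {
  ids <- sprintf("s%02d", 1:20)
  labels <- rep(c("tumor", "normal"), each = 10)
  f1 <- splitTrainValidate(ids, labels, k = 5, seed = 6L)
  f2 <- splitTrainValidate(ids, labels, k = 5, seed = 6L)
  expect_identical(f1, f2)
  expect_setequal(names(f1), ids)
  # each fold holds 2 tumors + 2 normals
  for (k in 1:5) {
    expect_equal(sum(f1 == k & labels == "tumor"), 2)
    expect_equal(sum(f1 == k & labels == "normal"), 2)
  }
  expect_error(splitTrainValidate(ids[1:6], labels[c(1:3, 11:13)], k = 5),
               "at least k")
})

test_that("cross-cohort intersection recovers exactly the implanted pathways", {
  sim <- cachedSim()
  stages <- lapply(names(sim$counts), function(co)
    cohortStages(sim, co, B = 200L, seed = 40L + match(co,
                                                       names(sim$counts))))
  names(stages) <- names(sim$counts)
  rs <- intersectCandidates(lapply(stages, `[[`, "pathways"))
  expect_setequal(rs$riskPathways, sim$truth$riskPathways)
  # the decoys are candidates somewhere but never survive the intersection
  allCand <- unique(unlist(rs$candidates))
  expect_true(any(sim$truth$decoyPathways %in% allCand))
  expect_length(intersect(rs$riskPathways, sim$truth$decoyPathways), 0L)
})

test_that("a cohort with no candidates empties the intersection", {
  a <- data.frame(pathway = c("p1", "p2"), fdr = c(0.01, 0.2),
                  cohort = "A")
  b <- data.frame(pathway = c("p1", "p2"), fdr = c(0.9, 0.9),
                  cohort = "B")
  expect_warning(rs <- intersectCandidates(list(a, b)), "no pathway")
  expect_length(rs$riskPathways, 0L)
  expect_error(intersectCandidates(list(a)), "at least 2 cohorts")
})
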