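test_that("risk grouping splits at the median score deterministically", {
  vals <- rbind(l1 = c(1, 2, 3, 4, 0, 0), l2 = c(1, 2, 3, 4, 0, 0))
  colnames(vals) <- c(paste0("t", 1:4), "n1", "n2")
  rse <- riskExpressionSet(vals, biotype = c("lncRNA", "lncRNA"),
                           sampleType = c(rep("tumor", 4),
                                          rep("normal", 2)))
  g <- assignRiskGroups(rse, c("l1", "l2"))
  expect_setequal(g$sample[g$riskGroup == "high"], c("t3", "t4"))
  expect_setequal(g$sample[g$riskGroup == "low"], c("t1", "t2"))
  # two samples with distinct scores: one per group
  g2 <- assignRiskGroups(rse[, c("t1", "t2")], c("l1", "l2"))
  expect_setequal(g2$riskGroup, c("high", "low"))
  # identical scores cannot be split
  same <- rse
  SummarizedExperiment::assay(same, "exprs")[, 1:4] <- 1
  expect_error(assignRiskGroups(same, c("l1", "l2")), "identical")
})

test_that("z-scoring makes the grouping invariant to affine rescaling", {
  set.seed(10)
  vals <- matrix(rnorm(5 * 12), nrow = 5,
                 dimnames = list(paste0("l", 1:5), paste0("t", 1:12)))
  rse <- riskExpressionSet(vals, rep("lncRNA", 5), rep("tumor", 12))
  g1 <- assignRiskGroups(rse, paste0("l", 1:5))
  vals2 <- vals * c(3, 0.5, 10, 2, 7) + c(-4, 2, 100, 0, 1)
  rse2 <- riskExpressionSet(vals2, rep("lncRNA", 5), rep("tumor", 12))
  g2 <- assignRiskGroups(rse2, paste0("l", 1:5))
  expect_identical(g1$riskGroup, g2$riskGroup)
})

test_that("product-limit estimates match hand-computed tables", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: survival stays at 1
  km2 <- kmEstimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  # censoring after the last event leaves event-time estimates unchanged
  km3 <- kmEstimate(c(1, 2, 3, 10), c(1, 1, 1, 0))
  expect_equal(km3$surv[km3$time %in% c(1, 2, 3)], c(3 / 4, 2 / 4, 1 / 4))
  expect_error(kmEstimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank equals the hand risk-table tally and is label-symmetric", {
  times <- c(1, 2, 3, 4)
  events <- c(1, 1, 1, 1)
  groups <- c("A", "A", "B", "B")
  lr <- logrankTest(times, events, groups)
  expect_equal(lr$chisq, handLogrank(times, events, groups),
               tolerance = 1e-10)
  lrSwap <- logrankTest(times, events, c("B", "B", "A", "A"))
  expect_equal(lr$p, lrSwap$p)
  # identical groups: no separation
  lr0 <- logrankTest(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # a larger random table against the independent tally
  set.seed(14)
  t2 <- round(rexp(40, 0.01), 1)
  e2 <- rbinom(40, 1, 0.8)
  g2 <- rep(c("A", "B"), 20)
  expect_equal(logrankTest(t2, e2, g2)$chisq, handLogrank(t2, e2, g2),
               tolerance = 1e-8)
})

test_that("Cox sign equivariance and degenerate inputs", {
  set.seed(15)
  times <- rexp(60, 0.01)
  events <- rbinom(60, 1, 0.8)
  x <- rnorm(60)
  fit <- coxUnivariate(times, events, x)
  fitNeg <- coxUnivariate(times, events, -x)
  expect_equal(fit$beta, -fitNeg$beta, tolerance = 1e-8)
  expect_equal(fit$p, fitNeg$p, tolerance = 1e-8)
  expect_gt(fit$hr, 0)
  expect_error(coxUnivariate(times, events, rep(1, 60)), "constant")
})

test_that("log-rank chi-square approximates the Cox score geometry", {
  # two-group comparison: log-rank and Cox agree asymptotically
  set.seed(16)
  n <- 120
  grp <- rep(0:1, each = n / 2)
  times <- rexp(n, 0.01 * ifelse(grp == 1, 2, 1))
  events <- rep(1L, n)
  lr <- logrankTest(times, events, grp)
  cx <- coxUnivariate(times, events, grp)
  z2 <- (cx$beta / cx$se)^2
  expect_equal(lr$chisq, z2, tolerance = 0.15)
})

test_that("true hazard ratios are recovered from simulated clinical tables", {
  # generator check: Cox on the latent high-risk group, true HR = 2
  hrs <- vapply(1:6, function(sd) {
    cfg <- simulationConfig(nCohorts = 1L, tumorsPerCohort = 500L,
                            normalsPerCohort = 5L, nMrna = 30L,
                            nLncrna = 10L, exonsPerFeature = 1L,
                            nPathways = 4L, pathwaySizeRange = c(8L, 10L),
                            nRiskPathways = 1L, nRiskLncrnas = 4L,
                            nDecoyPathways = 0L, nHallmarks = 0L,
                            hazardRatioHighRisk = 2,
                            censoringRate = 0.1, seed = 400L + sd)
    sim <- simulateCohorts(cfg)
    cl <- sim$clinical[sim$clinical$sampleType == "tumor", ]
    hi <- cl$sample %in% sim$truth$highriskSamples$C1
    coxUnivariate(cl$osDays, cl$event, as.integer(hi))$hr
  }, numeric(1))
  expect_true(median(hrs) > 1.7 && median(hrs) < 2.35)
  expect_gte(mean(hrs > 1.7 & hrs < 2.35), 0.5)
})

test_that("survivalAnalysis stratifies implanted cohorts significantly", {
  sim <- cachedSim()
  st <- cohortStages(sim, "C1", B = 50L)
  sv <- survivalAnalysis(st$rse, sim$clinical[sim$clinical$cohort == "C1", ],
                         sim$truth$riskLncrnas)
  expect_s3_class(sv, "SurvivalResult")
  # KM curves start at or below 1 and never increase within a group
  for (g in unique(sv$km$group)) {
    s <- sv$km$surv[sv$km$group == g]
    expect_true(all(diff(s) <= 1e-12))
  }
  expect_true(sv$coxGroup$hr > 0)
  # the expression-derived split tracks the latent high-risk truth
  agree <- mean((sv$groups$sample %in% sim$truth$highriskSamples$C1) ==
                  (sv$groups$riskGroup == "high"))
  expect_gte(max(agree, 1 - agree), 0.8)
})
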