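test_that("identical config and seed reproduce the simulation exactly", {
  cfg <- simulationConfig(nMrna = 120L, nLncrna = 40L, nPathways = 12L,
                          nDecoyPathways = 2L, seed = 5L)
  a <- simulateCohorts(cfg)
  b <- simulateCohorts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  # and the generator does not disturb the caller's RNG
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulateCohorts(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("pathway sizes respect the configured interval", {
  cfg <- simulationConfig(nPathways = 50L, pathwaySizeRange = c(10L, 40L),
                          nMrna = 400L, nLncrna = 100L, seed = 9L)
  sim <- simulateCohorts(cfg)
  sz <- pathwaySizes(sim$pathways)
  expect_length(sz, 50L)
  expect_true(all(sz >= 10 & sz <= 40))
})

test_that("ground truth is internally consistent across cohorts", {
  sim <- cachedSim()
  tr <- sim$truth
  riskMembers <- unlist(lapply(tr$riskPathways,
                               function(p) sim$pathways[[p]]))
  expect_true(all(tr$riskLncrnas %in% riskMembers))
  # risk pathway ids and member sets are cohort-independent by construction
  expect_length(tr$riskPathways, sim$config@nRiskPathways)
  # risk members (incl. the risk lncRNAs) are DE in every cohort
  for (co in names(tr$deFeatures))
    expect_true(all(riskMembers %in% tr$deFeatures[[co]]))
  # risk lncRNAs appear in no non-risk pathway
  other <- setdiff(names(sim$pathways), tr$riskPathways)
  otherMembers <- unique(unlist(lapply(other,
                                       function(p) sim$pathways[[p]])))
  expect_length(intersect(tr$riskLncrnas, otherMembers), 0L)
})

test_that("implanted fold changes show up in the marginal count means", {
  # many exons so the tumor/normal mean ratio concentrates: 2500 features
  # x 2 exons = 5000 exons
  cfg <- simulationConfig(nCohorts = 1L, nMrna = 2200L, nLncrna = 300L,
                          exonsPerFeature = 2L, nPathways = 40L,
                          missingRate = 0, deLog2fc = 1.5, seed = 33L)
  sim <- simulateCohorts(cfg)
  cnt <- sim$counts$C1
  tum <- grepl("_T", colnames(cnt))
  shifts <- sim$truth$shifts$C1
  ann <- sim$annotation
  for (sgn in c(1, -1)) {
    feats <- names(shifts)[shifts == sgn * 1.5]
    exons <- ann$exonId[ann$featureId %in% feats]
    ratio <- mean(cnt[exons, tum]) / mean(cnt[exons, !tum])
    expect_equal(ratio, 2^(sgn * 1.5), tolerance = 0.05)
  }
})

test_that("inconsistent risk sizes are rejected at construction", {
  expect_error(simulationConfig(nRiskLncrnas = 11L,
                                pathwaySizeRange = c(10L, 40L)),
               "smallest allowed pathway size")
  expect_error(simulationConfig(nRiskPathways = 80L,
                                nDecoyPathways = 30L, nPathways = 100L),
               "exceed nPathways")
  expect_error(simulationConfig(missingRate = 1.2), "missingRate")
})

test_that("null configuration still records truth but implants nothing", {
  cfg <- simulationConfig(deLog2fc = 0, hazardRatioHighRisk = 1,
                          nMrna = 300L, nLncrna = 100L, nPathways = 20L,
                          seed = 77L)
  sim <- simulateCohorts(cfg)
  expect_length(sim$truth$riskPathways, 3L)
  expect_true(all(unlist(sim$truth$shifts) == 0))
})

test_that("written fixtures round-trip and have stable checksums", {
  cfg <- simulationConfig(nCohorts = 2L, nMrna = 60L, nLncrna = 20L,
                          nPathways = 8L, nDecoyPathways = 2L,
                          exonsPerFeature = 2L, missingRate = 0,
                          seed = 3L)
  sim <- simulateCohorts(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- writeFixture(d1, sim)
  m2 <- writeFixture(d2, simulateCohorts(cfg))
  expect_identical(m1$md5, m2$md5)
  back <- readCounts(file.path(d1, "counts_C1.tsv"))
  expect_equal(back, sim$counts$C1)
  pc <- readGMT(file.path(d1, "pathways.gmt"))
  expect_identical(names(pc), names(sim$pathways))
  expect_identical(pc@sets, sim$pathways@sets)
  cl <- readClinical(file.path(d1, "clinical.tsv"))
  expect_equal(nrow(cl), nrow(sim$clinical))
})

test_that("an empty cohort list still writes annotation and pathway files", {
  cfg <- simulationConfig(nCohorts = 0L, nMrna = 40L, nLncrna = 10L,
                          nPathways = 5L, nDecoyPathways = 0L,
                          nRiskPathways = 0L, nRiskLncrnas = 0L,
                          nHallmarks = 0L, seed = 2L)
  sim <- simulateCohorts(cfg)
  d <- withr::local_tempdir()
  manifest <- writeFixture(d, sim)
  expect_true(all(c("annotation.tsv", "pathways.gmt") %in% manifest$file))
  expect_false(any(grepl("^counts_", manifest$file)))
})
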