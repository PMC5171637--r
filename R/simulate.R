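#' Simulation settings for multi-cohort tumor/normal RNA-seq
#'
#' Holds all knobs of the synthetic-cohort generator.  Defaults describe the
#' package's reference fixture: three cohorts of 20 tumors + 20 normals,
#' 2000 features (1600 mRNAs, 400 lncRNAs, 3 exons each), 100 pathways of
#' 10--40 members among which 3 "risk" pathways carry a coordinated
#' 1.5-log2 repression in every cohort and share 8 risk lncRNAs, plus 3
#' decoy pathways shifted in exactly one cohort each.  Tumor survival is
#' exponential with a 3-fold hazard for a latent high-risk half of tumors
#' whose risk-lncRNA repression is partially relieved.
#'
#' @slot nCohorts,tumorsPerCohort,normalsPerCohort cohort layout.
#' @slot nMrna,nLncrna,exonsPerFeature feature layout.
#' @slot nPathways,pathwaySizeRange number of pathway sets and the
#'   inclusive member-count interval.
#' @slot nRiskPathways,nRiskLncrnas pathways implanted with a coordinated
#'   shift in all cohorts, and the lncRNAs shared by all risk pathways.
#' @slot nDecoyPathways pathways shifted in exactly one cohort (round robin).
#' @slot deFraction fraction of remaining features made DE per cohort with a
#'   random sign, so the DE universe mixes directions as real tumors do.
#' @slot deLog2fc implanted log2 fold change.
#' @slot nbDispersion negative-binomial dispersion (var = mu + disp*mu^2).
#' @slot baselineMeanLog mean of log exon baseline counts (lognormal).
#' @slot missingRate probability a feature is unquantified (NA) in a sample.
#' @slot hazardRatioHighRisk,censoringRate survival generator settings.
#' @slot nHallmarks,hallmarkSizeRange hallmark term layout.
#' @slot seed master seed; all cohort streams derive from it.
#' @seealso [simulationConfig()], [simulateCohorts()]
#' @export
setClass("SimulationConfig", representation(
  nCohorts = "integer", tumorsPerCohort = "integer",
  normalsPerCohort = "integer", nMrna = "integer", nLncrna = "integer",
  exonsPerFeature = "integer", nPathways = "integer",
  pathwaySizeRange = "integer", nRiskPathways = "integer",
  nRiskLncrnas = "integer", nDecoyPathways = "integer",
  deFraction = "numeric", deLog2fc = "numeric", nbDispersion = "numeric",
  baselineMeanLog = "numeric", missingRate = "numeric",
  hazardRatioHighRisk = "numeric", censoringRate = "numeric",
  nHallmarks = "integer", hallmarkSizeRange = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  for (sl in c("nCohorts", "tumorsPerCohort", "normalsPerCohort", "nMrna",
               "nLncrna", "nPathways", "nRiskPathways", "nRiskLncrnas",
               "nDecoyPathways", "nHallmarks"))
    if (!isCount(slot(object, sl)))
      msg <- c(msg, paste(sl, "must be a nonnegative integer"))
  if (!isCount(object@exonsPerFeature, min = 1L))
    msg <- c(msg, "exonsPerFeature must be >= 1")
  if (length(object@pathwaySizeRange) != 2L ||
      object@pathwaySizeRange[1] < 2L ||
      object@pathwaySizeRange[2] < object@pathwaySizeRange[1])
    msg <- c(msg, "pathwaySizeRange must be an increasing interval with min >= 2")
  if (object@nRiskLncrnas > object@pathwaySizeRange[1])
    msg <- c(msg, "nRiskLncrnas exceeds the smallest allowed pathway size")
  if (object@nRiskPathways + object@nDecoyPathways > object@nPathways)
    msg <- c(msg, "risk + decoy pathways exceed nPathways")
  if (object@nRiskLncrnas > object@nLncrna)
    msg <- c(msg, "nRiskLncrnas exceeds nLncrna")
  if (!isFraction(object@deFraction)) msg <- c(msg, "deFraction not in [0,1]")
  if (!isFraction(object@missingRate)) msg <- c(msg, "missingRate not in [0,1]")
  if (!isFraction(object@censoringRate) || object@censoringRate >= 1)
    msg <- c(msg, "censoringRate not in [0,1)")
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
  if (object@hazardRatioHighRisk <= 0)
    msg <- c(msg, "hazardRatioHighRisk must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param nCohorts,tumorsPerCohort,normalsPerCohort cohort layout.
#' @param nMrna,nLncrna,exonsPerFeature feature layout.
#' @param nPathways,pathwaySizeRange pathway layout (size interval, min >= 2).
#' @param nRiskPathways,nRiskLncrnas implanted common risk structure.
#' @param nDecoyPathways cohort-specific implanted pathways.
#' @param deFraction extra per-cohort DE features (random sign), as a
#'   fraction of all features.
#' @param deLog2fc implanted log2 fold change (0 gives a global null).
#' @param nbDispersion negative-binomial dispersion.
#' @param baselineMeanLog lognormal mean of exon baseline counts.
#' @param missingRate per feature-sample probability of missing (NA) counts.
#' @param hazardRatioHighRisk hazard multiplier of latent high-risk tumors
#'   (1 gives a survival null).
#' @param censoringRate expected fraction of censored tumors.
#' @param nHallmarks,hallmarkSizeRange hallmark gene-set layout.
#' @param seed master seed.
#' @return A validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(nCohorts = 2, seed = 7)
#' @export
simulationConfig <- function(nCohorts = 3L, tumorsPerCohort = 20L,
    normalsPerCohort = 20L, nMrna = 1600L, nLncrna = 400L,
    exonsPerFeature = 3L, nPathways = 100L, pathwaySizeRange = c(10L, 40L),
    nRiskPathways = 3L, nRiskLncrnas = 8L, nDecoyPathways = 3L,
    deFraction = 0.05, deLog2fc = 1.5, nbDispersion = 0.2,
    baselineMeanLog = 4, missingRate = 0.02, hazardRatioHighRisk = 3,
    censoringRate = 0.3, nHallmarks = 10L, hallmarkSizeRange = c(20L, 50L),
    seed = 1L) {
  new("SimulationConfig",
      nCohorts = as.integer(nCohorts),
      tumorsPerCohort = as.integer(tumorsPerCohort),
      normalsPerCohort = as.integer(normalsPerCohort),
      nMrna = as.integer(nMrna), nLncrna = as.integer(nLncrna),
      exonsPerFeature = as.integer(exonsPerFeature),
      nPathways = as.integer(nPathways),
      pathwaySizeRange = as.integer(pathwaySizeRange),
      nRiskPathways = as.integer(nRiskPathways),
      nRiskLncrnas = as.integer(nRiskLncrnas),
      nDecoyPathways = as.integer(nDecoyPathways),
      deFraction = deFraction, deLog2fc = deLog2fc,
      nbDispersion = nbDispersion, baselineMeanLog = baselineMeanLog,
      missingRate = missingRate,
      hazardRatioHighRisk = hazardRatioHighRisk,
      censoringRate = censoringRate, nHallmarks = as.integer(nHallmarks),
      hallmarkSizeRange = as.integer(hallmarkSizeRange),
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nCohorts, "cohorts,",
      object@tumorsPerCohort, "T +", object@normalsPerCohort, "N each;",
      object@nMrna + object@nLncrna, "features;",
      object@nPathways, "pathways (", object@nRiskPathways, "risk,",
      object@nDecoyPathways, "decoy ); log2FC =", object@deLog2fc,
      "; seed =", object@seed, "\n")
})

#' Simulate paired tumor/normal cohorts with known ground truth
#'
#' Draws exon-level negative-binomial counts around feature-specific
#' lognormal baselines for each cohort, implants a coordinated
#' \code{deLog2fc} repression in the members of the shared risk pathways
#' (all cohorts), a coordinated activation of one decoy pathway per cohort,
#' and a random-sign shift in an extra DE set per cohort; injects missing
#' (NA) quantifications; and generates exponential overall-survival times
#' for tumors with hazard multiplied by \code{hazardRatioHighRisk} for a
#' latent high-risk half whose risk-lncRNA repression is partially relieved
#' (by \code{deLog2fc/2}), so expression stratifies survival.  Fully deterministic given
#' \code{config@seed}; each cohort uses its own derived RNG stream.
#'
#' @param config a [SimulationConfig-class].
#' @return A list of class \code{"CohortSimulation"} with elements
#'   \code{counts} (named list of exon x sample integer matrices),
#'   \code{annotation} (data.frame: exonId, featureId, biotype, exonLength),
#'   \code{pathways}, \code{hallmarks} ([PathwayCollection-class]),
#'   \code{clinical} (data.frame: sample, cohort, sampleType, osDays, event),
#'   \code{truth} (deFeatures/highriskSamples/shifts per cohort,
#'   riskPathways, riskLncrnas, decoyPathways) and \code{config}.
#' @examples
#' sim <- simulateCohorts(simulationConfig(nCohorts = 2, nMrna = 100,
#'   nLncrna = 30, nPathways = 10, seed = 3))
#' names(sim$counts)
#' @export
simulateCohorts <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  cfg <- config
  seeds <- childSeeds(cfg@seed, 3L + cfg@nCohorts)

  nFeat <- cfg@nMrna + cfg@nLncrna
  featureId <- c(sprintf("MRNA%05d", seq_len(cfg@nMrna)),
                 sprintf("LNC%05d", seq_len(cfg@nLncrna)))
  biotype <- rep(c("mRNA", "lncRNA"), c(cfg@nMrna, cfg@nLncrna))
  mrnaIds <- featureId[biotype == "mRNA"]
  lncIds <- featureId[biotype == "lncRNA"]

  # -- annotation + baselines (shared across cohorts) --
  ann <- withSeed(seeds[1], {
    exonLength <- sample(100:2000, nFeat * cfg@exonsPerFeature,
                         replace = TRUE)
    data.frame(
      exonId = paste0(rep(featureId, each = cfg@exonsPerFeature), ":",
                      seq_len(cfg@exonsPerFeature)),
      featureId = rep(featureId, each = cfg@exonsPerFeature),
      biotype = rep(biotype, each = cfg@exonsPerFeature),
      exonLength = exonLength, stringsAsFactors = FALSE)
  })
  # lognormal baselines; sdlog 0.5 keeps any single feature from dominating
  # library composition, so RPKM stays comparable across sample groups
  baseline <- withSeed(seeds[2],
    exp(stats::rnorm(nrow(ann), mean = cfg@baselineMeanLog, sd = 0.5)))

  # -- pathways, hallmarks, implanted structure --
  pw <- withSeed(seeds[3], {
    sizes <- sample(seq(cfg@pathwaySizeRange[1], cfg@pathwaySizeRange[2]),
                    cfg@nPathways, replace = TRUE)
    riskLnc <- sort(sample(lncIds, cfg@nRiskLncrnas))
    sets <- vector("list", cfg@nPathways)
    names(sets) <- sprintf("PW%04d", seq_len(cfg@nPathways))
    riskIdx <- seq_len(cfg@nRiskPathways)
    decoyIdx <- seq_len(cfg@nDecoyPathways) + cfg@nRiskPathways
    for (i in seq_len(cfg@nPathways)) {
      if (i %in% riskIdx) {
        # risk pathways: the shared risk lncRNAs plus mRNA fill, so the set
        # of lncRNAs common to all cohorts inside them is exactly riskLnc
        fill <- sample(mrnaIds, sizes[i] - cfg@nRiskLncrnas)
        sets[[i]] <- c(riskLnc, fill)
      } else {
        # risk lncRNAs stay exclusive to risk pathways so the ground-truth
        # common-lncRNA set is unambiguous
        sets[[i]] <- sample(setdiff(featureId, riskLnc), sizes[i])
      }
    }
    hmSizes <- sample(seq(cfg@hallmarkSizeRange[1], cfg@hallmarkSizeRange[2]),
                      cfg@nHallmarks, replace = TRUE)
    hm <- lapply(hmSizes, function(s) sample(mrnaIds, s))
    names(hm) <- sprintf("HALLMARK%02d", seq_len(cfg@nHallmarks))
    # seed one hallmark with risk-pathway mRNAs so enrichment has signal
    if (cfg@nHallmarks > 0L && cfg@nRiskPathways > 0L) {
      riskM <- unique(unlist(sets[riskIdx]))
      riskM <- riskM[riskM %in% mrnaIds]
      take <- utils::head(riskM, min(length(riskM), hmSizes[1] %/% 2))
      hm[[1]] <- unique(c(take, hm[[1]]))[seq_len(max(hmSizes[1],
                                                      length(take)))]
    }
    list(sets = sets, hallmarks = hm, riskLnc = riskLnc,
         riskIdx = riskIdx, decoyIdx = decoyIdx)
  })
  pathways <- PathwayCollection(pw$sets)
  hallmarks <- PathwayCollection(pw$hallmarks)
  riskPathwayIds <- names(pathways)[pw$riskIdx]
  decoyPathwayIds <- names(pathways)[pw$decoyIdx]
  riskMembers <- unique(unlist(pw$sets[pw$riskIdx], use.names = FALSE))

  cohorts <- sprintf("C%d", seq_len(cfg@nCohorts))
  shifts <- list()
  counts <- vector("list", cfg@nCohorts)
  names(counts) <- cohorts
  clinical <- list()
  deFeatures <- list()
  highrisk <- list()
  size <- 1 / cfg@nbDispersion

  for (ci in seq_along(cohorts)) {
    co <- cohorts[ci]
    res <- withSeed(seeds[3L + ci], {
      tumors <- sprintf("%s_T%03d", co, seq_len(cfg@tumorsPerCohort))
      normals <- sprintf("%s_N%03d", co, seq_len(cfg@normalsPerCohort))
      samples <- c(tumors, normals)

      # per-cohort DE composition
      decoyMembers <- if (cfg@nDecoyPathways > 0L)
        pw$sets[[pw$decoyIdx[(ci - 1L) %% cfg@nDecoyPathways + 1L]]]
      else character()
      # extra DE features live outside the pathway annotation, as most of
      # the DE transcriptome does in real cohorts: they mix directions into
      # the DE universe used by the size-preserving permutations without
      # manufacturing pathway-level signal
      annotated <- unique(unlist(pw$sets, use.names = FALSE))
      pool <- setdiff(featureId, c(annotated, riskMembers, decoyMembers))
      nExtra <- round(cfg@deFraction * nFeat)
      extra <- if (nExtra > 0L) sample(pool, min(nExtra, length(pool)))
               else character()
      de <- unique(c(riskMembers, decoyMembers, extra))
      # implanted log2 shift per DE feature, coordinated per pathway with
      # sign chosen to keep the net shifted read mass small: RPKM measures
      # relative abundance, so a large one-sided mass change would
      # re-express itself as an artificial global shift of every
      # unperturbed feature.  Risk pathways are implanted as coordinated
      # repression, the cohort's decoy pathway as coordinated activation,
      # and the extra DE set with random signs so the DE universe mixes
      # directions the way real tumors do.
      shift <- stats::setNames(rep(0, nFeat), featureId)
      shift[decoyMembers] <- cfg@deLog2fc
      shift[riskMembers] <- -cfg@deLog2fc
      shift[extra] <- cfg@deLog2fc * sample(c(-1, 1), length(extra),
                                            replace = TRUE)

      # latent high-risk tumors: partial relief (fc/2) of the risk-lncRNA
      # repression plus the hazard multiplier, so expression stratifies
      # survival
      hr <- sort(sample(tumors, floor(length(tumors) / 2)))
      exShift <- shift[ann$featureId]  # per exon
      mu <- matrix(baseline, nrow = nrow(ann), ncol = length(samples),
                   dimnames = list(ann$exonId, samples))
      mu[, tumors] <- mu[, tumors] * 2^exShift
      riskLncExon <- ann$featureId %in% pw$riskLnc
      if (length(hr) > 0 && any(riskLncExon))
        mu[riskLncExon, hr] <- mu[riskLncExon, hr] * 2^(cfg@deLog2fc / 2)
      cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                   size = size),
                    nrow = nrow(mu), dimnames = dimnames(mu))
      # missing quantifications: whole feature-sample cells go NA
      if (cfg@missingRate > 0) {
        miss <- matrix(stats::runif(nFeat * length(samples)) <
                         cfg@missingRate, nFeat, length(samples))
        if (any(miss)) {
          missExon <- miss[match(ann$featureId, featureId), , drop = FALSE]
          cnt[missExon] <- NA_integer_
        }
      }

      # survival for tumor samples (exponential, censoring-matched rate)
      rate0 <- 1 / 1000
      rate <- ifelse(tumors %in% hr, rate0 * cfg@hazardRatioHighRisk, rate0)
      evt <- stats::rexp(length(tumors), rate)
      osDays <- evt
      event <- rep(1L, length(tumors))
      if (cfg@censoringRate > 0) {
        cRate <- rate * cfg@censoringRate / (1 - cfg@censoringRate)
        cens <- stats::rexp(length(tumors), cRate)
        event <- as.integer(evt <= cens)
        osDays <- pmin(evt, cens)
      }
      clin <- rbind(
        data.frame(sample = tumors, cohort = co, sampleType = "tumor",
                   osDays = round(osDays, 2), event = event,
                   stringsAsFactors = FALSE),
        data.frame(sample = normals, cohort = co, sampleType = "normal",
                   osDays = NA_real_, event = NA_integer_,
                   stringsAsFactors = FALSE))
      list(counts = cnt, clinical = clin, de = sort(de), highrisk = hr,
           shifts = shift[sort(de)])
    })
    counts[[co]] <- res$counts
    clinical[[co]] <- res$clinical
    deFeatures[[co]] <- res$de
    highrisk[[co]] <- res$highrisk
    shifts[[co]] <- res$shifts
  }

  out <- list(counts = counts, annotation = ann, pathways = pathways,
              hallmarks = hallmarks,
              clinical = if (length(clinical))
                do.call(rbind, c(clinical, make.row.names = FALSE))
              else data.frame(sample = character(), cohort = character(),
                              sampleType = character(), osDays = numeric(),
                              event = integer()),
              truth = list(deFeatures = deFeatures,
                           riskPathways = riskPathwayIds,
                           riskLncrnas = pw$riskLnc,
                           decoyPathways = decoyPathwayIds,
                           highriskSamples = highrisk,
                           shifts = shifts),
              config = cfg)
  class(out) <- "CohortSimulation"
  out
}

#' @export
print.CohortSimulation <- function(x, ...) {
  cat("CohortSimulation:", length(x$counts), "cohorts,",
      nrow(x$annotation), "exons,", length(x$pathways), "pathways\n")
  cat("  risk pathways:", paste(x$truth$riskPathways, collapse = ", "), "\n")
  cat("  risk lncRNAs:", length(x$truth$riskLncrnas), "\n")
  invisible(x)
}

#' Write a simulated fixture to disk
#'
#' Serializes a [simulateCohorts()] result as plain-text files: per-cohort
#' counts TSV, annotation TSV, pathway/hallmark GMT, clinical TSV and
#' ground-truth TSVs, plus a manifest with md5 checksums.
#'
#' @param dir output directory (created if needed).
#' @param sim a \code{CohortSimulation}.
#' @return Invisibly, a data.frame manifest (file, md5); also written as
#'   \code{manifest.tsv}.
#' @export
writeFixture <- function(dir, sim) {
  stopifnot(inherits(sim, "CohortSimulation"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  files <- character()
  wf <- function(name) { files <<- c(files, name); file.path(dir, name) }

  for (co in names(sim$counts))
    writeMatrixTSV(sim$counts[[co]], wf(paste0("counts_", co, ".tsv")),
                   idColumn = "exonId")
  utils::write.table(sim$annotation, wf("annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeGMT(sim$pathways, wf("pathways.gmt"))
  writeGMT(sim$hallmarks, wf("hallmarks.gmt"))
  if (nrow(sim$clinical) > 0)
    utils::write.table(sim$clinical, wf("clinical.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  truthSets <- data.frame(
    set = c(rep("riskPathway", length(tr$riskPathways)),
            rep("riskLncrna", length(tr$riskLncrnas)),
            rep("decoyPathway", length(tr$decoyPathways))),
    id = c(tr$riskPathways, tr$riskLncrnas, tr$decoyPathways),
    stringsAsFactors = FALSE)
  utils::write.table(truthSets, wf("truth_sets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(tr$deFeatures) > 0) {
    deTab <- do.call(rbind, lapply(names(tr$deFeatures), function(co)
      data.frame(cohort = co, featureId = tr$deFeatures[[co]],
                 stringsAsFactors = FALSE)))
    utils::write.table(deTab, wf("truth_de.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    hrTab <- do.call(rbind, lapply(names(tr$highriskSamples), function(co)
      data.frame(cohort = co, sample = tr$highriskSamples[[co]],
                 stringsAsFactors = FALSE)))
    utils::write.table(hrTab, wf("truth_highrisk.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
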