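#' Assemble a pipeline configuration
#'
#' Either a simulation block (a [SimulationConfig-class] or a list of
#' [simulationConfig()] arguments) or file inputs (per-cohort counts TSVs
#' plus shared annotation/GMT/clinical files) drive the run.
#'
#' @param simulation [SimulationConfig-class] or argument list, or NULL.
#' @param inputs list with \code{counts} (named character vector of paths,
#'   one per cohort), \code{annotation}, \code{pathways}, \code{hallmarks},
#'   \code{clinical} paths; or NULL.
#' @param fdrDe,fdrPathway,fdrEnrich FDR thresholds (defaults 0.05).
#' @param missingThreshold,zeroFill expression-filter settings.
#' @param B permutations for pathway/lncRNA calibration (default 1000).
#' @param cvK,cvRepeats classifier cross-validation settings.
#' @param k train/validation folds for the pathway stage (default 5).
#' @param seed master seed for the whole run.
#' @return validated config list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(simulation = NULL, inputs = NULL, fdrDe = 0.05,
                           fdrPathway = 0.05, fdrEnrich = 0.05,
                           missingThreshold = 0.30, zeroFill = 0.05,
                           B = 1000L, cvK = 5L, cvRepeats = 10L, k = 5L,
                           seed = 1L) {
  if (is.null(simulation) && is.null(inputs))
    stop("provide a simulation block or file inputs")
  for (th in c(fdrDe, fdrPathway, fdrEnrich))
    if (!isFraction(th) || th <= 0 || th >= 1)
      stop("FDR thresholds must lie in (0, 1)")
  if (B < 1L) stop("B must be >= 1")
  if (cvK < 2L || k < 2L) stop("fold counts must be >= 2")
  if (!is.null(simulation) && !is(simulation, "SimulationConfig"))
    simulation <- do.call(simulationConfig, simulation)
  structure(list(simulation = simulation, inputs = inputs, fdrDe = fdrDe,
                 fdrPathway = fdrPathway, fdrEnrich = fdrEnrich,
                 missingThreshold = missingThreshold, zeroFill = zeroFill,
                 B = as.integer(B), cvK = as.integer(cvK),
                 cvRepeats = as.integer(cvRepeats), k = as.integer(k),
                 seed = as.integer(seed)), class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipelineConfig()] arguments; a
#' \code{simulation:} mapping is passed to [simulationConfig()].
#'
#' @param path YAML file.
#' @return a \code{PipelineConfig}.
#' @export
loadPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipelineConfig, cfg)
}

#' Run the full discovery workflow
#'
#' Executes the end-to-end pipeline on simulated or file-based cohorts:
#' expression screening (RPKM, filters, log2), per-cohort DE (t-test + BH),
#' a fixed stratified train/validation split, delta-e on the training
#' samples, pathway scoring with size-preserving permutation calibration,
#' cross-cohort intersection into risk pathways, risk-lncRNA extraction
#' and subset evaluation, hallmark hypergeometric enrichment, SVM
#' classification of tumor vs normal on the risk lncRNAs, and survival
#' stratification.  All stage outputs are written as plain TSV under
#' \code{outDir} together with a machine-readable \code{summary.json}.
#' Given a fixed \code{config$seed} the run is byte-identical.
#'
#' @param config a \code{PipelineConfig} (or list accepted by
#'   [pipelineConfig()]).
#' @param outDir output directory, created if needed.
#' @param verbose print per-stage progress.
#' @return invisibly, the summary list (also serialized as JSON).
#' @export
runPipeline <- function(config, outDir, verbose = TRUE) {
  if (!inherits(config, "PipelineConfig"))
    config <- do.call(pipelineConfig, config)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  say <- function(...) if (verbose) message("[lncRiskPath] ", ...)
  seeds <- childSeeds(config$seed, 6L)

  # ---- stage 0: inputs ----
  if (!is.null(config$simulation)) {
    say("simulating cohorts (seed ", config$simulation@seed, ")")
    sim <- simulateCohorts(config$simulation)
    counts <- sim$counts
    annotation <- sim$annotation
    pathways <- sim$pathways
    hallmarks <- sim$hallmarks
    clinical <- sim$clinical
    truth <- sim$truth
  } else {
    inp <- config$inputs
    say("loading inputs for ", length(inp$counts), " cohorts")
    counts <- lapply(inp$counts, readCounts)
    if (is.null(names(counts)))
      names(counts) <- paste0("C", seq_along(counts))
    annotation <- readAnnotation(inp$annotation)
    pathways <- readGMT(inp$pathways)
    hallmarks <- readGMT(inp$hallmarks)
    clinical <- readClinical(inp$clinical)
    truth <- NULL
  }
  cohorts <- names(counts)

  # ---- stage 1: expression screening ----
  rses <- list()
  for (co in cohorts) {
    say("quantifying ", co)
    rses[[co]] <- quantifyCohort(counts[[co]], annotation,
                                 clinical[clinical$cohort == co, ],
                                 cohort = co,
                                 missingThreshold = config$missingThreshold,
                                 zeroFill = config$zeroFill)
    writeExpressionTSV(exprsValues(rses[[co]]),
                       file.path(outDir, paste0("expression_", co, ".tsv")))
  }

  # ---- stage 2: train/validation split, DE, delta-e, pathways ----
  splitSeeds <- childSeeds(seeds[1], length(cohorts))
  permSeeds <- childSeeds(seeds[2], length(cohorts))
  deTabs <- list()
  pathRes <- list()
  deltas <- list()
  trainSets <- list()
  for (ci in seq_along(cohorts)) {
    co <- cohorts[ci]
    rse <- rses[[co]]
    fold <- splitTrainValidate(colnames(rse),
                               SummarizedExperiment::colData(rse)$sampleType,
                               k = config$k, seed = splitSeeds[ci])
    train <- names(fold)[fold != 1L]  # fold 1 held out for validation
    trainSets[[co]] <- train
    rseTr <- methods::as(rse[, train], "RiskExpressionSet")
    S4Vectors::metadata(rseTr)$cohort <- co
    say("DE testing ", co, " on ", length(train), " training samples")
    deTabs[[co]] <- tTestDE(rseTr, alphaFdr = config$fdrDe)
    utils::write.table(deTabs[[co]],
                       file.path(outDir, paste0("de_", co, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    nDe <- sum(deTabs[[co]]$isDE)
    say(co, ": ", nDe, " DE features")
    if (nDe == 0L) stop("no DE features in cohort ", co,
                        "; pathway stage cannot run")
    deltas[[co]] <- computeDeltaE(rseTr, deTabs[[co]])
    say("pathway testing ", co, " (B = ", config$B, ")")
    pathRes[[co]] <- testPathways(deltas[[co]], pathways, B = config$B,
                                  seed = permSeeds[ci],
                                  alphaFdr = config$fdrPathway)
    utils::write.table(pathRes[[co]],
                       file.path(outDir, paste0("pathways_", co, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # ---- stage 3: intersection + risk lncRNAs ----
  riskSet <- intersectCandidates(pathRes, alphaFdr = config$fdrPathway)
  say(length(riskSet$riskPathways), " common risk pathways")
  riskLnc <- extractCommonLncrnas(riskSet, deTabs, pathways)
  say(length(riskLnc), " risk lncRNAs")
  lncReport <- NULL
  if (length(riskSet$riskPathways) > 0L && length(riskLnc) > 0L) {
    lncUniverse <- unique(unlist(lapply(names(pathways),
                                        function(nm) pathways[[nm]])))
    deltaLnc <- lapply(cohorts, function(co) {
      rseTr <- methods::as(rses[[co]][, trainSets[[co]]],
                           "RiskExpressionSet")
      S4Vectors::metadata(rseTr)$cohort <- co
      feats <- intersect(lncUniverse, rownames(rseTr))
      feats <- feats[featureBiotype(rseTr)[feats] == "lncRNA"]
      computeDeltaE(rseTr, features = feats)
    })
    names(deltaLnc) <- cohorts
    lncReport <- evaluateCommonSubset(deltaLnc, riskSet, pathways,
                                      riskLnc, B = config$B,
                                      seed = seeds[3])
    utils::write.table(lncReport$comparison,
                       file.path(outDir, "risk_lncrna_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(riskLnc, file.path(outDir, "risk_lncrnas.txt"))
  writeLines(riskSet$riskPathways, file.path(outDir, "risk_pathways.txt"))

  # ---- stage 4: hallmark enrichment ----
  enrich <- NULL
  if (length(riskSet$riskPathways) > 0L && length(hallmarks) > 0L) {
    say("hallmark enrichment of ", length(riskSet$riskPathways),
        " risk pathways")
    enrich <- enrichAll(pathways[riskSet$riskPathways], hallmarks,
                        alphaFdr = config$fdrEnrich,
                        universe = pathwayUniverse(pathways, hallmarks))
    utils::write.table(enrich, file.path(outDir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # ---- stage 5: classification + survival ----
  classSeeds <- childSeeds(seeds[4], length(cohorts))
  aucs <- stats::setNames(rep(NA_real_, length(cohorts)), cohorts)
  survP <- stats::setNames(rep(NA_real_, length(cohorts)), cohorts)
  survHr <- stats::setNames(rep(NA_real_, length(cohorts)), cohorts)
  features <- intersect(riskLnc,
                        Reduce(intersect, lapply(rses, rownames)))
  for (ci in seq_along(cohorts)) {
    co <- cohorts[ci]
    if (length(features) == 0L) break
    say("classification + survival ", co)
    cls <- cvClassify(rses[[co]], features, classifier = "svm",
                      scheme = "5fold", repeats = config$cvRepeats,
                      k = config$cvK, seed = classSeeds[ci])
    aucs[co] <- cls$meanAuc
    cl <- clinical[clinical$cohort == co, ]
    sv <- tryCatch(survivalAnalysis(rses[[co]], cl, features),
                   error = function(e) NULL)
    if (!is.null(sv)) {
      survP[co] <- sv$logrank$p
      survHr[co] <- sv$coxGroup$hr
      utils::write.table(sv$km,
                         file.path(outDir, paste0("km_", co, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  summary <- list(
    seed = config$seed,
    cohorts = cohorts,
    nCandidatesPerCohort = vapply(riskSet$candidates, length, integer(1)),
    riskPathways = riskSet$riskPathways,
    riskLncrnas = riskLnc,
    subsetBeatsFullFraction = if (!is.null(lncReport) &&
                                  nrow(lncReport$comparison))
      mean(lncReport$comparison$subsetLeqFull) else NA,
    nEnrichedPairs = if (!is.null(enrich)) sum(enrich$significant) else 0L,
    meanAucPerCohort = as.list(round(aucs, 6)),
    logrankPPerCohort = as.list(signif(survP, 6)),
    coxHrPerCohort = as.list(signif(survHr, 6)))
  if (!is.null(truth))
    summary$truth <- list(riskPathways = truth$riskPathways,
                          riskLncrnas = truth$riskLncrnas)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done; summary at ", file.path(outDir, "summary.json"))
  invisible(summary)
}
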