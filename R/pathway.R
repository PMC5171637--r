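#' Per-tumor expression change (delta-e) for DE features
#'
#' For every selected feature \eqn{m} and tumor sample \eqn{n}, the
#' expression change is
#' \eqn{\Delta e_m^n = x_m^n - \bar y_m}, the tumor's log2 RPKM minus the
#' mean (or median) log2 RPKM of the cohort's matched normal samples.  By
#' default every tumor is matched against all normals of its cohort.
#'
#' @param rse a [RiskExpressionSet-class].
#' @param de DE table from [tTestDE()]; rows with \code{isDE} define the
#'   feature set.  Alternatively supply \code{features} directly.
#' @param features optional explicit feature ids (overrides \code{de}).
#' @param center \code{"mean"} (default) or \code{"median"} summary of the
#'   matched normals.
#' @return numeric matrix, features x tumor samples, with attributes
#'   \code{cohort} and \code{normals} (the matched normal ids).
#' @examples
#' m <- rbind(f1 = c(5, 5, 1, 2, 3))
#' colnames(m) <- c("t1", "t2", "n1", "n2", "n3")
#' rse <- riskExpressionSet(m, "lncRNA",
#'   c("tumor", "tumor", "normal", "normal", "normal"))
#' computeDeltaE(rse, features = "f1")  # 5 - mean(1,2,3) = 3
#' @export
computeDeltaE <- function(rse, de = NULL, features = NULL,
                          center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(is(rse, "RiskExpressionSet"))
  if (is.null(features)) {
    if (is.null(de)) stop("supply either a DE table or explicit features")
    features <- de$feature[de$isDE]
  }
  if (length(features) == 0L) stop("empty feature set for delta-e")
  missing <- setdiff(features, rownames(rse))
  if (length(missing))
    stop("feature(s) absent from the expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  nor <- normalSamples(rse)
  tum <- tumorSamples(rse)
  if (length(nor) == 0L) stop("cohort has no normal samples")
  if (length(tum) == 0L) stop("cohort has no tumor samples")
  x <- exprsValues(rse)[features, , drop = FALSE]
  yc <- if (center == "mean") rowMeans(x[, nor, drop = FALSE], na.rm = TRUE)
        else apply(x[, nor, drop = FALSE], 1, stats::median, na.rm = TRUE)
  delta <- x[, tum, drop = FALSE] - yc
  attr(delta, "cohort") <- cohortName(rse)
  attr(delta, "normals") <- nor
  delta
}

#' Score one pathway on pooled delta-e values
#'
#' Pools the delta-e values of the pathway members present in \code{delta}
#' across all tumor samples into a single vector and applies
#' [wilcoxonSignedRank()].  Pathways with fewer than \code{minMembers}
#' members in the matrix are untestable.
#'
#' @param delta delta-e matrix from [computeDeltaE()].
#' @param members character vector of member feature ids.
#' @param minMembers minimum members with delta-e rows (default 3).
#' @return list with \code{statistic}, \code{p.value}, \code{nMembers},
#'   \code{testable}.  Untestable pathways return NA statistic/p.
#' @export
pathwayScore <- function(delta, members, minMembers = 3L) {
  present <- intersect(members, rownames(delta))
  if (length(present) < minMembers)
    return(list(statistic = NA_real_, p.value = NA_real_,
                nMembers = length(present), testable = FALSE))
  v <- as.vector(delta[present, , drop = FALSE])
  v <- v[is.finite(v)]
  if (length(v) == 0L || all(v == 0))
    return(list(statistic = 0, p.value = 1,
                nMembers = length(present), testable = TRUE))
  w <- wilcoxonSignedRank(v)
  list(statistic = w$statistic, p.value = w$p.value,
       nMembers = length(present), testable = TRUE)
}

#' Size-preserving permutation calibration of pathway scores
#'
#' For each pathway, draws \code{B} random feature sets of the same size as
#' the pathway's tested membership from the universe of features carrying
#' delta-e values, re-scores each, and reports the permutation p-value.
#' Default is the (+1)-corrected exceedance
#' \eqn{(\#\{p_b \le p_{obs}\} + 1) / (B + 1)}; the literal
#' "share of insignificant permutations" reading
#' (\eqn{\#\{p_b \ge 0.05\} / B}) is available as
#' \code{mode = "insignificance"}.  With \code{exhaustive = TRUE} and a
#' small universe, all same-size subsets are enumerated instead of sampled.
#'
#' @param delta delta-e matrix.
#' @param pathways a [PathwayCollection-class].
#' @param B number of permutations (default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param universe feature universe to draw from (default: rownames of
#'   \code{delta}).
#' @param minMembers minimum tested members per pathway.
#' @param mode \code{"exceedance"} (default) or \code{"insignificance"}.
#' @param exhaustive enumerate all subsets when feasible.
#' @param alphaInsig significance cut used by the insignificance reading.
#' @return data.frame: \code{pathway}, \code{nMembersTested},
#'   \code{statistic}, \code{p} (observed Wilcoxon), \code{permP},
#'   \code{testable}.
#' @export
permutationCalibrate <- function(delta, pathways, B = 1000L, seed = NULL,
                                 universe = NULL, minMembers = 3L,
                                 mode = c("exceedance", "insignificance"),
                                 exhaustive = FALSE, alphaInsig = 0.05) {
  mode <- match.arg(mode)
  stopifnot(is(pathways, "PathwayCollection"))
  if (B < 1L) stop("B must be >= 1")
  if (is.null(universe)) universe <- rownames(delta)
  universe <- intersect(universe, rownames(delta))
  obs <- lapply(names(pathways), function(nm)
    pathwayScore(delta, pathways[[nm]], minMembers = minMembers))
  sizes <- vapply(obs, `[[`, integer(1), "nMembers")
  withSeed(seed, {
    permP <- rep(NA_real_, length(pathways))
    for (i in seq_along(pathways)) {
      if (!obs[[i]]$testable) next
      s <- sizes[i]
      if (s > length(universe))
        stop("universe smaller than pathway size for ", names(pathways)[i])
      if (exhaustive && choose(length(universe), s) <= 5000) {
        sets <- utils::combn(universe, s, simplify = FALSE)
      } else {
        sets <- replicate(B, sample(universe, s), simplify = FALSE)
      }
      pb <- vapply(sets, function(st)
        pathwayScore(delta, st, minMembers = 1L)$p.value, numeric(1))
      permP[i] <- if (mode == "exceedance")
        (sum(pb <= obs[[i]]$p.value) + 1) / (length(pb) + 1)
      else sum(pb >= alphaInsig) / length(pb)
    }
    data.frame(pathway = names(pathways),
               nMembersTested = sizes,
               statistic = vapply(obs, `[[`, numeric(1), "statistic"),
               p = vapply(obs, `[[`, numeric(1), "p.value"),
               permP = permP,
               testable = vapply(obs, `[[`, logical(1), "testable"),
               stringsAsFactors = FALSE)
  })
}

#' Full pathway test for one cohort
#'
#' [permutationCalibrate()] plus BH adjustment of the permutation p-values
#' across testable pathways and the candidate flag at \code{fdr < alphaFdr}.
#'
#' @inheritParams permutationCalibrate
#' @param alphaFdr FDR threshold for candidacy (default 0.05).
#' @param ... passed to [permutationCalibrate()].
#' @return the [permutationCalibrate()] data.frame with added \code{fdr},
#'   \code{isCandidate} and \code{cohort} columns.
#' @export
testPathways <- function(delta, pathways, B = 1000L, seed = NULL,
                         alphaFdr = 0.05, minMembers = 3L, ...) {
  res <- permutationCalibrate(delta, pathways, B = B, seed = seed,
                              minMembers = minMembers, ...)
  res$fdr <- NA_real_
  ok <- res$testable & !is.na(res$permP)
  if (any(ok)) res$fdr[ok] <- bhAdjust(res$permP[ok])
  res$isCandidate <- !is.na(res$fdr) & res$fdr < alphaFdr
  res$cohort <- attr(delta, "cohort") %||% NA_character_
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified train/validation fold assignment
#'
#' Splits samples into \code{k} non-overlapping folds, stratified by
#' tumor/normal label, for the train-then-validate protocol (pathway
#' identification on the k-1 training folds, classifier evaluation on the
#' held-out fold).
#'
#' @param sampleIds character vector of sample ids.
#' @param labels tumor/normal label per sample.
#' @param k number of folds (default 5); every class must have >= k samples.
#' @param seed RNG seed.
#' @return named integer vector of fold numbers (1..k) per sample.
#' @export
splitTrainValidate <- function(sampleIds, labels, k = 5L, seed = NULL) {
  stopifnot(length(sampleIds) == length(labels))
  tab <- table(labels)
  if (any(tab < k))
    stop("every class needs at least k samples (k = ", k, ")")
  withSeed(seed, {
    fold <- integer(length(sampleIds))
    for (lb in names(tab)) {
      idx <- which(labels == lb)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    stats::setNames(fold, sampleIds)
  })
}

#' Intersect candidate pathways across cohorts
#'
#' Risk pathways are the pathways that are significant candidates
#' (permutation FDR < \code{alphaFdr}) in every cohort.
#'
#' @param perCohort list of [testPathways()] data.frames (>= 2 cohorts).
#' @param alphaFdr FDR threshold (default 0.05; candidacy is recomputed
#'   from the stored \code{fdr} column).
#' @return list of class \code{"RiskSet"}: \code{riskPathways} (character),
#'   \code{candidates} (named list per cohort), \code{alphaFdr}.
#'   An empty intersection is valid and warned about.
#' @export
intersectCandidates <- function(perCohort, alphaFdr = 0.05) {
  if (length(perCohort) < 2L) stop("need results from at least 2 cohorts")
  cand <- lapply(perCohort, function(df)
    df$pathway[!is.na(df$fdr) & df$fdr < alphaFdr])
  if (is.null(names(cand)) || any(!nzchar(names(cand))))
    names(cand) <- vapply(seq_along(perCohort), function(i) {
      co <- unique(perCohort[[i]]$cohort)
      if (length(co) == 1 && !is.na(co)) co else paste0("cohort", i)
    }, character(1))
  risk <- sort(Reduce(intersect, cand))
  if (length(risk) == 0L)
    warning("no pathway is a candidate in every cohort")
  structure(list(riskPathways = risk, candidates = cand,
                 alphaFdr = alphaFdr), class = "RiskSet")
}

#' @export
print.RiskSet <- function(x, ...) {
  cat("RiskSet:", length(x$riskPathways), "common risk pathways across",
      length(x$candidates), "cohorts\n")
  if (length(x$riskPathways))
    cat(" ", paste(x$riskPathways, collapse = ", "), "\n")
  cat("  per-cohort candidates:",
      paste(vapply(x$candidates, length, integer(1)), collapse = ", "), "\n")
  invisible(x)
}
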