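#' Area under the ROC curve from decision scores
#'
#' Rank-based (Mann-Whitney) AUC: ties in the scores contribute 1/2.
#' Equals \eqn{U / (n_1 n_0)} for the Mann-Whitney U of the positive-class
#' scores.
#'
#' @param scores numeric decision scores, larger = more tumor-like.
#' @param labels logical or factor; TRUE / "tumor" marks the positive class.
#' @return AUC in [0, 1].
#' @export
aucFromScores <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "tumor"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("need both classes to compute AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points from decision scores
#'
#' @inheritParams aucFromScores
#' @return data.frame \code{fpr}, \code{tpr}, monotone from (0,0) to (1,1).
#' @export
rocPoints <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "tumor"
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  keep <- c(diff(scores[ord]) != 0, TRUE)  # one point per threshold
  data.frame(fpr = c(0, fp[keep] / sum(!pos)),
             tpr = c(0, tp[keep] / sum(pos)))
}

#' Signal-to-noise feature ranking statistic
#'
#' Per feature, \eqn{(\mu_1 - \mu_2) / (\sigma_1 + \sigma_2)} between the
#' two sample classes (class 1 = tumor).  A zero combined SD yields 0 with
#' a warning.
#'
#' @param x features x samples matrix.
#' @param labels tumor/normal (or logical) per sample.
#' @return named numeric vector per feature.
#' @export
signalToNoise <- function(x, labels) {
  pos <- if (is.logical(labels)) labels else labels == "tumor"
  if (sum(pos) < 2L || sum(!pos) < 2L)
    stop("both classes need at least 2 samples")
  x1 <- x[, pos, drop = FALSE]
  x2 <- x[, !pos, drop = FALSE]
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  s1 <- apply(x1, 1, stats::sd, na.rm = TRUE)
  s2 <- apply(x2, 1, stats::sd, na.rm = TRUE)
  den <- s1 + s2
  out <- (m1 - m2) / den
  if (any(den == 0)) {
    warning("zero combined SD; signal-to-noise set to 0")
    out[den == 0] <- 0
  }
  out
}

# z-score columns of train/test by train statistics (zero SDs -> 1)
scaleByTrain <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(test, 2, mu), 2, sd, "/"))
}

# decision scores oriented so that larger = tumor
classifierScores <- function(classifier, trainX, trainY, testX) {
  trainY <- factor(trainY, levels = c("normal", "tumor"))
  if (classifier == "svm") {
    fit <- e1071::svm(trainX, trainY, kernel = "linear", cost = 1,
                      scale = FALSE)
    dv <- attr(stats::predict(fit, testX, decision.values = TRUE),
               "decision.values")
    sgn <- if (grepl("^tumor", colnames(dv)[1])) 1 else -1
    sgn * dv[, 1]
  } else {
    fit <- e1071::naiveBayes(trainX, trainY)
    stats::predict(fit, testX, type = "raw")[, "tumor"]
  }
}

#' Cross-validated classification with risk-lncRNA features
#'
#' Evaluates a feature set as tumor-vs-normal classification features.
#' For each repeat, samples are split into stratified folds (or
#' leave-one-out), features are z-scored with training-fold statistics, a
#' linear SVM (cost 1) or Gaussian naive Bayes is trained, and held-out
#' decision scores are pooled over folds into one AUC per repeat.
#' Leave-one-out is deterministic, so it is computed once regardless of
#' \code{repeats}.  \code{nullLabels = TRUE} shuffles the class labels
#' independently per repeat (permutation null).
#'
#' @param rse a [RiskExpressionSet-class].
#' @param features feature ids used as classifier inputs.
#' @param classifier \code{"svm"} (default) or \code{"naive_bayes"}.
#' @param scheme \code{"5fold"} (stratified k-fold) or \code{"loocv"}.
#' @param repeats randomized split repeats (default 10).
#' @param k folds for the k-fold scheme (default 5).
#' @param seed RNG seed.
#' @param nullLabels shuffle labels before classification.
#' @return list of class \code{"ClassificationResult"}: \code{classifier},
#'   \code{scheme}, \code{aucPerRepeat}, \code{meanAuc}, \code{roc}
#'   (pooled scores of the first repeat).
#' @export
cvClassify <- function(rse, features,
                       classifier = c("svm", "naive_bayes"),
                       scheme = c("5fold", "loocv"), repeats = 10L,
                       k = 5L, seed = NULL, nullLabels = FALSE) {
  classifier <- match.arg(classifier)
  scheme <- match.arg(scheme)
  stopifnot(is(rse, "RiskExpressionSet"))
  missing <- setdiff(features, rownames(rse))
  if (length(missing))
    stop("feature(s) absent from expression: ",
         paste(utils::head(missing, 5), collapse = ", "))
  x <- t(exprsValues(rse)[features, , drop = FALSE])
  x[is.na(x)] <- 0  # z-scored later; missing cells carry no signal
  y <- SummarizedExperiment::colData(rse)$sampleType
  if (min(table(y)) < 2L) stop("need >= 2 samples per class")
  nrep <- if (scheme == "loocv") 1L else as.integer(repeats)
  seeds <- childSeeds(seed, nrep)
  auc <- numeric(nrep)
  roc <- NULL
  for (rp in seq_len(nrep)) {
    resRp <- withSeed(seeds[rp], {
      yr <- if (nullLabels) sample(y) else y
      fold <- if (scheme == "loocv") seq_along(yr)
              else splitTrainValidate(rownames(x), yr, k = k,
                                      seed = sample.int(2^30, 1))
      scores <- numeric(nrow(x))
      for (f in unique(fold)) {
        te <- fold == f
        sc <- scaleByTrain(x[!te, , drop = FALSE], x[te, , drop = FALSE])
        scores[te] <- classifierScores(classifier, sc$train, yr[!te],
                                       sc$test)
      }
      list(auc = aucFromScores(scores, yr == "tumor"),
           scores = scores, labels = yr)
    })
    auc[rp] <- resRp$auc
    if (rp == 1L)
      roc <- rocPoints(resRp$scores, resRp$labels == "tumor")
  }
  structure(list(classifier = classifier, scheme = scheme,
                 repeats = nrep, aucPerRepeat = auc, meanAuc = mean(auc),
                 roc = roc, cohort = cohortName(rse)),
            class = "ClassificationResult")
}

#' @export
print.ClassificationResult <- function(x, ...) {
  cat("ClassificationResult [", x$classifier, ",", x$scheme, "] cohort",
      x$cohort, ": mean AUC =", round(x$meanAuc, 4), "over", x$repeats,
      "repeat(s)\n")
  invisible(x)
}

#' Golub-style weighted-voting misclassification curve
#'
#' Ranks features by absolute signal-to-noise computed on the training
#' folds, then for each prefix size \eqn{g} of the ranking classifies
#' held-out samples by the sign of the summed votes
#' \eqn{v_f = S2N_f (x_f - (\mu_1 + \mu_2)/2)} (positive = tumor) and
#' counts misclassifications.  The curve is the mean misclassified count
#' per \eqn{g} over repeated randomized k-fold splits.  \code{rankOn =
#' "all"} is an intentionally leaky variant (ranking uses all samples)
#' kept for leakage diagnostics.
#'
#' @inheritParams cvClassify
#' @param rankOn \code{"train"} (honest, default) or \code{"all"} (leaky).
#' @return list of class \code{"VotingCurve"}: \code{ranking} (features
#'   ranked by |S2N| on the full data, for reporting), \code{curve}
#'   (data.frame \code{g}, \code{meanMisclassified}).
#' @export
weightedVotingCurve <- function(rse, features, k = 5L, repeats = 100L,
                                seed = NULL, rankOn = c("train", "all")) {
  rankOn <- match.arg(rankOn)
  stopifnot(is(rse, "RiskExpressionSet"))
  x <- exprsValues(rse)[features, , drop = FALSE]
  x[is.na(x)] <- 0
  y <- SummarizedExperiment::colData(rse)$sampleType
  G <- length(features)
  seeds <- childSeeds(seed, repeats)
  mis <- matrix(0, nrow = repeats, ncol = G)
  s2nAll <- signalToNoise(x, y)
  for (rp in seq_len(repeats)) {
    mis[rp, ] <- withSeed(seeds[rp], {
      fold <- splitTrainValidate(colnames(x), y, k = k,
                                 seed = sample.int(2^30, 1))
      cnt <- numeric(G)
      for (f in seq_len(k)) {
        te <- fold == f
        xtr <- x[, !te, drop = FALSE]
        ytr <- y[!te]
        s2n <- if (rankOn == "train") signalToNoise(xtr, ytr) else s2nAll
        ord <- order(abs(s2n), decreasing = TRUE)
        mu1 <- rowMeans(xtr[, ytr == "tumor", drop = FALSE])
        mu2 <- rowMeans(xtr[, ytr == "normal", drop = FALSE])
        mid <- (mu1 + mu2) / 2
        votes <- s2n * (x[, te, drop = FALSE] - mid)  # features x test
        vc <- apply(votes[ord, , drop = FALSE], 2, cumsum)
        if (G == 1L) vc <- matrix(vc, nrow = 1L)
        predTumor <- vc > 0
        isTumor <- matrix(rep(y[te] == "tumor", each = G), nrow = G)
        cnt <- cnt + rowSums(predTumor != isTumor)
      }
      cnt
    })
  }
  structure(list(
    ranking = features[order(abs(s2nAll), decreasing = TRUE)],
    curve = data.frame(g = seq_len(G), meanMisclassified = colMeans(mis)),
    rankOn = rankOn, repeats = repeats), class = "VotingCurve")
}

#' @export
print.VotingCurve <- function(x, ...) {
  best <- x$curve$g[which.min(x$curve$meanMisclassified)]
  cat("VotingCurve over", nrow(x$curve), "feature prefix sizes (",
      x$repeats, "repeats ); best g =", best, "with",
      round(min(x$curve$meanMisclassified), 2), "mean misclassified\n")
  invisible(x)
}
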