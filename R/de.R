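#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate
#' (delegates to \code{stats::p.adjust}), with strict input validation.
#'
#' @param p numeric vector of p-values in [0, 1]; NA/NaN are rejected.
#' @return adjusted p-values, same order as input.
#' @examples
#' bhAdjust(c(0.005, 0.04, 0.5))  # 0.015 0.060 0.500
#' @export
bhAdjust <- function(p) {
  if (anyNA(p)) stop("NA/NaN p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression by two-tailed t-test
#'
#' Tests every feature of a cohort for a tumor-vs-normal mean difference in
#' log2 RPKM with a two-sample t-test (Welch by default), then adjusts with
#' Benjamini-Hochberg.  Adjustment families are, by default, separate for
#' lncRNAs and mRNAs within the cohort.  NA cells (missing quantifications)
#' are dropped per feature; features left with fewer than 2 finite values
#' per group get NA statistics and are never flagged DE.
#'
#' @param rse a [RiskExpressionSet-class] with >= 2 tumor and >= 2 normal
#'   samples.
#' @param alphaFdr FDR threshold for the DE flag (default 0.05).
#' @param varEqual use the pooled-variance t-test instead of Welch.
#' @param separateFamilies adjust lncRNAs and mRNAs as separate BH families
#'   (default TRUE); FALSE pools all features.
#' @return data.frame with columns \code{feature}, \code{biotype},
#'   \code{statistic}, \code{p}, \code{fdr}, \code{isDE}.
#' @export
tTestDE <- function(rse, alphaFdr = 0.05, varEqual = FALSE,
                    separateFamilies = TRUE) {
  stopifnot(is(rse, "RiskExpressionSet"))
  x <- exprsValues(rse)
  tum <- tumorSamples(rse)
  nor <- normalSamples(rse)
  if (length(tum) < 2L || length(nor) < 2L)
    stop("need at least 2 tumor and 2 normal samples")
  res <- rowTTest(x[, tum, drop = FALSE], x[, nor, drop = FALSE],
                  varEqual = varEqual)
  bt <- featureBiotype(rse)
  out <- data.frame(feature = rownames(x), biotype = unname(bt[rownames(x)]),
                    statistic = res$t, p = res$p, fdr = NA_real_,
                    isDE = FALSE, stringsAsFactors = FALSE)
  ok <- !is.na(out$p)
  if (separateFamilies) {
    for (b in unique(out$biotype)) {
      sel <- ok & out$biotype == b
      if (any(sel)) out$fdr[sel] <- bhAdjust(out$p[sel])
    }
  } else if (any(ok)) {
    out$fdr[ok] <- bhAdjust(out$p[ok])
  }
  out$isDE <- !is.na(out$fdr) & out$fdr < alphaFdr
  rownames(out) <- NULL
  out
}

# vectorized two-sample t over matrix rows, NA-tolerant
rowTTest <- function(x1, x2, varEqual = FALSE) {
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((x2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  tt <- p <- rep(NA_real_, nrow(x1))
  ok <- n1 >= 2 & n2 >= 2
  if (varEqual) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  }
  diffm <- m1 - m2
  zeroSE <- ok & se == 0
  # degenerate rows: no variance in either group
  tt[zeroSE & diffm == 0] <- 0
  p[zeroSE & diffm == 0] <- 1
  tt[zeroSE & diffm != 0] <- sign(diffm[zeroSE & diffm != 0]) * Inf
  p[zeroSE & diffm != 0] <- 0
  use <- ok & se > 0
  tt[use] <- diffm[use] / se[use]
  p[use] <- 2 * stats::pt(-abs(tt[use]), df[use])
  list(t = tt, p = p, df = df, n1 = n1, n2 = n2)
}
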