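#' Feature-level RPKM from exon-level counts
#'
#' Aggregates raw exon read counts to features and normalizes to reads per
#' kilobase of exonic length per million mapped reads:
#' \deqn{RPKM_{f,s} = 10^9 \cdot rr_{f,s} / (tr_s \cdot L_f)}
#' where \eqn{rr_{f,s}} is the summed count over all exons of feature
#' \eqn{f} in sample \eqn{s}, \eqn{tr_s} the total exon count of sample
#' \eqn{s}, and \eqn{L_f} the summed exonic length (bp).  Annotated exons of
#' a feature are assumed non-overlapping, so the summed length equals the
#' union length.  A feature-sample cell with any missing exon count
#' propagates to an NA RPKM (missing quantification, distinct from zero).
#'
#' @param counts integer matrix, exons x samples, rownames = exon ids.
#' @param annotation data.frame with \code{exonId}, \code{featureId},
#'   \code{biotype}, \code{exonLength}.
#' @return numeric matrix, features x samples, with attributes
#'   \code{biotype} and \code{exonicLength} (named by feature).
#' @examples
#' cnt <- matrix(c(60, 40), 2, 1, dimnames = list(c("f1:1", "f1:2"), "s1"))
#' ann <- data.frame(exonId = c("f1:1", "f1:2"), featureId = "f1",
#'   biotype = "mRNA", exonLength = c(400, 600))
#' computeRPKM(cnt, ann)  # 1e9 * 100 / (100 * 1000) = 1e6
#' @export
computeRPKM <- function(counts, annotation) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  idx <- match(rownames(counts), annotation$exonId)
  orphan <- rownames(counts)[is.na(idx)]
  if (length(orphan))
    stop("exon(s) with no feature mapping: ",
         paste(utils::head(orphan, 5), collapse = ", "),
         if (length(orphan) > 5) " ..." else "")
  feat <- annotation$featureId[idx]
  len <- annotation$exonLength[idx]
  if (any(len <= 0)) stop("exon lengths must be positive")
  tr <- colSums(counts, na.rm = TRUE)
  if (any(tr <= 0))
    stop("sample(s) with zero total reads cannot be normalized: ",
         paste(colnames(counts)[tr <= 0], collapse = ", "))
  rr <- rowsum(counts, group = feat, reorder = TRUE)  # NA propagates
  L <- rowsum(len, group = feat, reorder = TRUE)[, 1]
  rpkm <- 1e9 * sweep(sweep(rr, 2, tr, "/"), 1, L, "/")
  bt <- annotation$biotype[idx][match(rownames(rpkm), feat)]
  attr(rpkm, "biotype") <- stats::setNames(bt, rownames(rpkm))
  attr(rpkm, "exonicLength") <- L
  rpkm
}

#' Filter and log-transform an RPKM matrix
#'
#' Applies the expression-screening rules: features whose RPKM is zero in
#' every (quantified) sample are discarded; features missing (NA) in
#' strictly more than \code{missingThreshold} of samples are discarded;
#' remaining zeros are replaced by \code{zeroFill} and all values log2
#' transformed.  With \code{missingAs = "zero"}, zeros are counted as
#' missing instead of NAs (alternative reading of platform "missing
#' values").
#'
#' @param rpkm nonnegative feature x sample matrix (NAs = missing).
#' @param missingThreshold removal threshold on the missing fraction
#'   (strictly greater; default 0.30).
#' @param zeroFill replacement for zero RPKM before log2 (default 0.05).
#' @param missingAs what counts as a missing value: \code{"na"} (default)
#'   or \code{"zero"}.
#' @return log2-transformed filtered matrix; attributes \code{biotype}/
#'   \code{exonicLength} are subset along.  Zero surviving rows triggers a
#'   warning and attribute \code{empty = TRUE}.
#' @examples
#' m <- matrix(c(0, 0, 2, 4), 2, 2,
#'   dimnames = list(c("dead", "ok"), c("s1", "s2")))
#' filterAndLog(m)  # "dead" removed; log2 of (2, 4) kept
#' @export
filterAndLog <- function(rpkm, missingThreshold = 0.30, zeroFill = 0.05,
                         missingAs = c("na", "zero")) {
  missingAs <- match.arg(missingAs)
  stopifnot(is.matrix(rpkm))
  if (any(rpkm < 0, na.rm = TRUE)) stop("RPKM values must be nonnegative")
  miss <- if (missingAs == "na") is.na(rpkm) else (is.na(rpkm) | rpkm == 0)
  allZero <- apply(rpkm, 1, function(x) all(x[!is.na(x)] == 0) ||
                     all(is.na(x)))
  missFrac <- rowMeans(miss)
  keep <- !allZero & missFrac <= missingThreshold
  out <- rpkm[keep, , drop = FALSE]
  out[!is.na(out) & out == 0] <- zeroFill
  out <- log2(out)
  for (a in c("biotype", "exonicLength")) {
    at <- attr(rpkm, a)
    if (!is.null(at)) attr(out, a) <- at[rownames(out)]
  }
  if (nrow(out) == 0L) {
    warning("no features survive expression filtering")
    attr(out, "empty") <- TRUE
  }
  out
}

#' Quantify one cohort into a RiskExpressionSet
#'
#' Convenience wrapper: [computeRPKM()] then [filterAndLog()] then
#' [riskExpressionSet()], attaching tumor/normal labels.
#'
#' @param counts exon x sample count matrix.
#' @param annotation exon annotation data.frame (see [computeRPKM()]).
#' @param sampleType character vector (\code{"tumor"}/\code{"normal"}) per
#'   column of \code{counts}, or a clinical data.frame with \code{sample}
#'   and \code{sampleType} columns.
#' @param cohort cohort id.
#' @param ... passed to [filterAndLog()].
#' @return A [RiskExpressionSet-class] of log2 RPKM values.
#' @export
quantifyCohort <- function(counts, annotation, sampleType,
                           cohort = "cohort", ...) {
  if (is.data.frame(sampleType)) {
    idx <- match(colnames(counts), sampleType$sample)
    if (anyNA(idx)) stop("samples missing from clinical table")
    sampleType <- sampleType$sampleType[idx]
  }
  stopifnot(length(sampleType) == ncol(counts))
  rpkm <- computeRPKM(counts, annotation)
  expr <- filterAndLog(rpkm, ...)
  if (isTRUE(attr(expr, "empty")))
    stop("expression matrix is empty after filtering; refusing to continue")
  riskExpressionSet(expr,
                    biotype = attr(expr, "biotype"),
                    sampleType = sampleType, cohort = cohort,
                    exonicLength = attr(expr, "exonicLength"))
}
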