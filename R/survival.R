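#' Assign high/low risk groups by risk-lncRNA expression
#'
#' Per tumor sample, the risk score is the mean of the z-scored (across
#' tumors) log2 RPKM of the risk lncRNAs.  Samples at or above the median
#' score form the high group, the rest the low group; ties at the median
#' are broken deterministically by sample id so the split is always
#' reproducible.  Z-scoring makes the grouping invariant to per-feature
#' affine rescaling of expression.
#'
#' @param rse a [RiskExpressionSet-class] with >= 2 tumor samples.
#' @param features risk lncRNA ids present in \code{rse}.
#' @return data.frame: \code{sample}, \code{score}, \code{riskGroup}
#'   (\code{"high"}/\code{"low"}).
#' @export
assignRiskGroups <- function(rse, features) {
  stopifnot(is(rse, "RiskExpressionSet"))
  tum <- tumorSamples(rse)
  if (length(tum) < 2L) stop("need >= 2 tumor samples")
  missing <- setdiff(features, rownames(rse))
  if (length(missing))
    stop("feature(s) absent from expression: ",
         paste(utils::head(missing, 5), collapse = ", "))
  x <- exprsValues(rse)[features, tum, drop = FALSE]
  mu <- rowMeans(x, na.rm = TRUE)
  sd <- apply(x, 1, stats::sd, na.rm = TRUE)
  sd[sd == 0 | is.na(sd)] <- 1
  z <- (x - mu) / sd
  score <- colMeans(z, na.rm = TRUE)
  if (length(unique(score)) == 1L)
    stop("all risk scores identical; no median split possible")
  ord <- order(-score, tum)  # ties at the median broken by sample id
  nHigh <- ceiling(length(tum) / 2)
  group <- rep("low", length(tum))
  group[ord[seq_len(nHigh)]] <- "high"
  data.frame(sample = tum, score = unname(score), riskGroup = group,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimator with right censoring (via
#' \code{survival::survfit}), tidied into one data.frame.
#'
#' @param times nonnegative survival times.
#' @param events event indicator (1 = death, 0 = censored).
#' @param groups group label per sample (single group allowed).
#' @return data.frame: \code{group}, \code{time}, \code{surv},
#'   \code{nRisk}, \code{nEvent}.
#' @export
kmEstimate <- function(times, events, groups = NULL) {
  if (any(times < 0)) stop("negative survival times")
  if (is.null(groups)) groups <- rep("all", length(times))
  df <- data.frame(times = times, events = events,
                   groups = as.factor(groups))
  fit <- survival::survfit(survival::Surv(times, events) ~ groups,
                           data = df)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(df$groups)[1],
                                     length(sm$time))
         else sub("^groups=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, surv = sm$surv,
             nRisk = sm$n.risk, nEvent = sm$n.event,
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square (via \code{survival::survdiff}).
#'
#' @inheritParams kmEstimate
#' @param groups two-level group label per sample.
#' @return list: \code{chisq}, \code{p}.
#' @export
logrankTest <- function(times, events, groups) {
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) != 2L) stop("need exactly 2 nonempty groups")
  if (sum(events) < 1) stop("need at least one event")
  df <- data.frame(times = times, events = events, g = g)
  sd <- survival::survdiff(survival::Surv(times, events) ~ g, data = df)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' Single-covariate partial-likelihood fit with Efron tie handling (via
#' \code{survival::coxph}); used once per lncRNA (continuous expression)
#' and once for the binary risk group.
#'
#' @inheritParams kmEstimate
#' @param covariate numeric (or 2-level factor) covariate per sample.
#' @return list: \code{beta}, \code{hr}, \code{se}, \code{p} (Wald),
#'   \code{converged}.
#' @export
coxUnivariate <- function(times, events, covariate) {
  if (is.factor(covariate) || is.character(covariate))
    covariate <- as.numeric(as.factor(covariate)) - 1
  if (length(unique(covariate)) < 2L) stop("constant covariate")
  if (sum(events) < 1) stop("need at least one event")
  df <- data.frame(times = times, events = events, covariate = covariate)
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, events) ~ covariate, data = df,
                    ties = "efron"),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(times, events) ~ covariate,
                        data = df, ties = "efron"))
      attr(f, "flagged") <- TRUE
      f
    })
  s <- summary(fit)
  list(beta = unname(stats::coef(fit)[1]),
       hr = unname(exp(stats::coef(fit)[1])),
       se = unname(s$coefficients[1, "se(coef)"]),
       p = unname(s$coefficients[1, "Pr(>|z|)"]),
       converged = is.null(attr(fit, "flagged")))
}

#' Survival analysis of a cohort's risk lncRNAs
#'
#' Runs the full survival stage for one cohort: risk-group assignment by
#' [assignRiskGroups()], Kaplan-Meier curves, the two-group log-rank test,
#' Cox on the binary risk group, and per-lncRNA Cox on continuous
#' expression.
#'
#' @param rse a [RiskExpressionSet-class].
#' @param clinical clinical data.frame (\code{sample}, \code{osDays},
#'   \code{event}); only tumor samples with nonmissing survival are used.
#' @param features risk lncRNA ids.
#' @return list of class \code{"SurvivalResult"}: \code{groups},
#'   \code{km}, \code{logrank}, \code{coxGroup}, \code{coxPerFeature}.
#' @export
survivalAnalysis <- function(rse, clinical, features) {
  grp <- assignRiskGroups(rse, features)
  idx <- match(grp$sample, clinical$sample)
  if (anyNA(idx)) stop("tumor sample(s) missing from clinical table")
  os <- clinical$osDays[idx]
  ev <- clinical$event[idx]
  keep <- !is.na(os) & !is.na(ev)
  grp <- grp[keep, ]
  os <- os[keep]
  ev <- ev[keep]
  km <- kmEstimate(os, ev, grp$riskGroup)
  lr <- logrankTest(os, ev, grp$riskGroup)
  cg <- coxUnivariate(os, ev, as.integer(grp$riskGroup == "high"))
  x <- exprsValues(rse)[features, grp$sample, drop = FALSE]
  perFeat <- do.call(rbind, lapply(features, function(f) {
    cov <- x[f, ]
    if (length(unique(cov[!is.na(cov)])) < 2L)
      return(data.frame(feature = f, beta = NA, hr = NA, p = NA))
    cf <- coxUnivariate(os[!is.na(cov)], ev[!is.na(cov)],
                        cov[!is.na(cov)])
    data.frame(feature = f, beta = cf$beta, hr = cf$hr, p = cf$p)
  }))
  rownames(perFeat) <- NULL
  structure(list(groups = grp, km = km, logrank = lr, coxGroup = cg,
                 coxPerFeature = perFeat, cohort = cohortName(rse)),
            class = "SurvivalResult")
}

#' @export
print.SurvivalResult <- function(x, ...) {
  cat("SurvivalResult cohort", x$cohort, ": log-rank chisq =",
      round(x$logrank$chisq, 3), ", p =", signif(x$logrank$p, 3),
      "; risk-group HR =", round(x$coxGroup$hr, 3), "\n")
  invisible(x)
}
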