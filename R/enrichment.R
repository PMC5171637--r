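#' Upper-tail hypergeometric enrichment of one pathway in one term
#'
#' With a universe of \eqn{N} genes, a pathway of \eqn{K} genes, a term of
#' \eqn{n} genes and \eqn{k} genes in common, the enrichment p-value is the
#' upper hypergeometric tail
#' \deqn{p = \sum_{j=k}^{\min(n,K)} \binom{K}{j}\binom{N-K}{n-j} /
#'   \binom{N}{n},}
#' evaluated in log space (log-binomials and log-sum-exp) for numerical
#' stability.  \eqn{k = 0} gives p = 1 exactly.
#'
#' @param pathwayGenes,termGenes character vectors, subsets of
#'   \code{universe}.
#' @param universe character vector of all genes under consideration.
#' @return one-row data.frame: \code{N}, \code{n}, \code{K}, \code{k},
#'   \code{p}.
#' @examples
#' hypergeomEnrich(paste0("g", 1:5), paste0("g", 2:5),
#'   paste0("g", 1:10))$p  # C(5,4)*C(5,0)/C(10,4) = 5/210
#' @export
hypergeomEnrich <- function(pathwayGenes, termGenes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  K <- length(intersect(pathwayGenes, universe))
  n <- length(intersect(termGenes, universe))
  k <- length(intersect(intersect(pathwayGenes, termGenes), universe))
  data.frame(N = length(universe), n = n, K = K, k = k,
             p = hypergeomTailP(length(universe), K, n, k))
}

# log-space upper tail P(X >= k), X ~ Hypergeometric(N, K, n)
hypergeomTailP <- function(N, K, n, k) {
  if (k <= 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  j <- k:hi
  logTerms <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  mx <- max(logTerms)
  p <- exp(mx + log(sum(exp(logTerms - mx))))
  min(1, max(p, 0))
}

#' Hallmark enrichment of a pathway collection
#'
#' Tests every pathway x hallmark-term pair with [hypergeomEnrich()] and
#' adjusts jointly with Benjamini-Hochberg across all pairs.  The default
#' universe is the union of genes appearing in any pathway or any hallmark
#' set (a fixed annotation universe); \code{universe = "pairwise"} uses the
#' literal per-pair union of the two sets instead.
#'
#' @param pathways,hallmarks [PathwayCollection-class] objects.
#' @param alphaFdr significance threshold on the FDR (default 0.05).
#' @param universe \code{"union"} (default), \code{"pairwise"}, or an
#'   explicit character vector of gene ids.
#' @return data.frame with one row per pair: \code{pathway}, \code{term},
#'   \code{N}, \code{n}, \code{K}, \code{k}, \code{p}, \code{fdr},
#'   \code{significant}.
#' @export
enrichAll <- function(pathways, hallmarks, alphaFdr = 0.05,
                      universe = "union") {
  stopifnot(is(pathways, "PathwayCollection"),
            is(hallmarks, "PathwayCollection"))
  if (length(pathways) == 0L || length(hallmarks) == 0L)
    stop("need at least one pathway and one hallmark term")
  fixedUni <- NULL
  if (is.character(universe) && length(universe) == 1L &&
      universe %in% c("union", "pairwise")) {
    if (universe == "union")
      fixedUni <- pathwayUniverse(pathways, hallmarks)
  } else {
    fixedUni <- unique(as.character(universe))
  }
  rows <- list()
  for (pid in names(pathways)) {
    pg <- pathways[[pid]]
    for (tid in names(hallmarks)) {
      tg <- hallmarks[[tid]]
      uni <- if (is.null(fixedUni)) union(pg, tg) else fixedUni
      r <- hypergeomEnrich(pg, tg, uni)
      r$pathway <- pid
      r$term <- tid
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("pathway", "term", "N", "n", "K", "k", "p")]
  out$fdr <- bhAdjust(out$p)
  out$significant <- out$fdr < alphaFdr
  rownames(out) <- NULL
  out
}
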