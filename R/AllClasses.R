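#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Collection of named feature sets
#'
#' A \code{PathwayCollection} holds named gene/feature sets (pathways or
#' hallmark terms) as character vectors, the in-memory counterpart of a GMT
#' file.  Set sizes are preserved by all permutation machinery in the
#' package, which is what the size-preserving null construction relies on.
#'
#' @slot sets named \code{list} of character vectors, one per set; names are
#'   unique, every set has at least one member.
#' @slot description character vector of per-set descriptions (GMT column 2).
#'
#' @seealso [readGMT()], [writeGMT()], [pathwaySizes()]
#' @export
setClass("PathwayCollection",
  representation(sets = "list", description = "character"))

setValidity("PathwayCollection", function(object) {
  s <- object@sets
  if (length(s) == 0L)
    return(TRUE)
  nm <- names(s)
  if (is.null(nm) || any(!nzchar(nm)))
    return("all sets must be named")
  if (anyDuplicated(nm))
    return("duplicate set names")
  if (!all(vapply(s, is.character, logical(1))))
    return("sets must be character vectors")
  if (any(vapply(s, length, integer(1)) < 1L))
    return("every set needs at least one member")
  if (length(object@description) != length(s))
    return("description length must match number of sets")
  TRUE
})

#' Construct a PathwayCollection
#'
#' @param sets named list of character vectors.
#' @param description optional character vector of descriptions, recycled
#'   from \code{""} when missing.
#' @return A [PathwayCollection-class] object.
#' @examples
#' pc <- PathwayCollection(list(p1 = c("g1", "g2"), p2 = c("g2", "g3")))
#' pathwaySizes(pc)
#' @export
PathwayCollection <- function(sets, description = NULL) {
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (is.null(description))
    description <- rep("", length(sets))
  new("PathwayCollection", sets = sets,
      description = as.character(description))
}

#' @describeIn PathwayCollection-class number of sets
#' @param x a \code{PathwayCollection}
#' @export
setMethod("length", "PathwayCollection", function(x) length(x@sets))

#' @describeIn PathwayCollection-class set names
#' @export
setMethod("names", "PathwayCollection", function(x) names(x@sets))

#' @describeIn PathwayCollection-class extract one set's members
#' @param i index or name
#' @export
setMethod("[[", "PathwayCollection", function(x, i) x@sets[[i]])

#' @describeIn PathwayCollection-class subset to several sets
#' @param j,drop,... ignored
#' @export
setMethod("[", "PathwayCollection", function(x, i, j, ..., drop = FALSE) {
  new("PathwayCollection", sets = x@sets[i],
      description = x@description[if (is.character(i))
        match(i, names(x@sets)) else i])
})

setMethod("show", "PathwayCollection", function(object) {
  cat("PathwayCollection with", length(object), "sets\n")
  if (length(object) > 0) {
    sz <- pathwaySizes(object)
    cat("  sizes:", min(sz), "-", max(sz),
        "(median", stats::median(sz), ")\n")
    cat("  names:", paste(utils::head(names(object), 4), collapse = ", "),
        if (length(object) > 4) "..." else "", "\n")
  }
})

#' Set sizes of a PathwayCollection
#' @param pc a [PathwayCollection-class]
#' @return named integer vector of member counts.
#' @export
pathwaySizes <- function(pc) {
  stopifnot(is(pc, "PathwayCollection"))
  vapply(pc@sets, length, integer(1))
}

#' Union of all members across a collection
#' @param ... one or more [PathwayCollection-class] objects
#' @return character vector of all feature ids seen in any set.
#' @export
pathwayUniverse <- function(...) {
  pcs <- list(...)
  unique(unlist(lapply(pcs, function(pc) unlist(pc@sets, use.names = FALSE)),
                use.names = FALSE))
}

#' Expression container for a tumor/normal cohort
#'
#' Thin extension of \code{SummarizedExperiment} carrying a single
#' \code{"exprs"} assay of log2 RPKM values with the row/column annotation
#' the pipeline needs: \code{rowData()$biotype} (\code{"lncRNA"} or
#' \code{"mRNA"}) and \code{colData()$sampleType} (\code{"tumor"} or
#' \code{"normal"}).  Validity enforces those columns so downstream stages
#' can rely on them.
#'
#' @seealso [riskExpressionSet()], [filterAndLog()], [tTestDE()]
#' @export
setClass("RiskExpressionSet", contains = "SummarizedExperiment")

setValidity("RiskExpressionSet", function(object) {
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    return("assay 'exprs' is required")
  rd <- rowData(object)
  if (!"biotype" %in% colnames(rd))
    return("rowData column 'biotype' is required")
  if (!all(rd$biotype %in% c("lncRNA", "mRNA")))
    return("biotype must be 'lncRNA' or 'mRNA'")
  cd <- colData(object)
  if (!"sampleType" %in% colnames(cd))
    return("colData column 'sampleType' is required")
  if (!all(cd$sampleType %in% c("tumor", "normal")))
    return("sampleType must be 'tumor' or 'normal'")
  TRUE
})

#' Construct a RiskExpressionSet
#'
#' @param exprs numeric matrix of log2 RPKM values, features x samples, with
#'   row and column names.
#' @param biotype character vector per feature, \code{"lncRNA"}/\code{"mRNA"}.
#' @param sampleType character vector per sample, \code{"tumor"}/\code{"normal"}.
#' @param cohort single cohort id (stored in \code{metadata()}).
#' @param exonicLength optional numeric vector of summed exonic length (bp).
#' @return A [RiskExpressionSet-class].
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' rse <- riskExpressionSet(m, biotype = c("lncRNA", "mRNA", "mRNA"),
#'   sampleType = c("tumor", "tumor", "normal", "normal"), cohort = "C1")
#' tumorSamples(rse)
#' @export
riskExpressionSet <- function(exprs, biotype, sampleType, cohort = "cohort",
                              exonicLength = NULL) {
  stopifnot(is.matrix(exprs), !is.null(rownames(exprs)),
            !is.null(colnames(exprs)),
            length(biotype) == nrow(exprs),
            length(sampleType) == ncol(exprs))
  rd <- DataFrame(biotype = as.character(biotype),
                  row.names = rownames(exprs))
  if (!is.null(exonicLength))
    rd$exonicLength <- exonicLength
  cd <- DataFrame(sampleType = as.character(sampleType),
                  cohort = cohort, row.names = colnames(exprs))
  se <- SummarizedExperiment(assays = list(exprs = exprs),
                             rowData = rd, colData = cd)
  obj <- new("RiskExpressionSet", se)
  S4Vectors::metadata(obj)$cohort <- cohort
  obj
}

setMethod("show", "RiskExpressionSet", function(object) {
  cat("RiskExpressionSet:", nrow(object), "features x", ncol(object),
      "samples (cohort", cohortName(object), ")\n")
  cat("  tumors:", length(tumorSamples(object)),
      " normals:", length(normalSamples(object)),
      " lncRNAs:", sum(rowData(object)$biotype == "lncRNA"), "\n")
})

#' @rdname riskExpressionSet
#' @param rse a [RiskExpressionSet-class]
#' @return \code{exprsValues}: the log2 RPKM matrix.
#' @export
exprsValues <- function(rse) assay(rse, "exprs")

#' @rdname riskExpressionSet
#' @return \code{tumorSamples}/\code{normalSamples}: sample id vectors.
#' @export
tumorSamples <- function(rse) colnames(rse)[colData(rse)$sampleType == "tumor"]

#' @rdname riskExpressionSet
#' @export
normalSamples <- function(rse) colnames(rse)[colData(rse)$sampleType == "normal"]

#' @rdname riskExpressionSet
#' @return \code{featureBiotype}: named biotype vector.
#' @export
featureBiotype <- function(rse) {
  stats::setNames(rowData(rse)$biotype, rownames(rse))
}

#' @rdname riskExpressionSet
#' @return \code{cohortName}: the cohort id.
#' @export
cohortName <- function(rse) {
  md <- S4Vectors::metadata(rse)$cohort
  if (is.null(md)) unique(colData(rse)$cohort)[1] else md
}
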