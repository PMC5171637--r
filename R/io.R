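#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated \code{name}, \code{description},
#' then members.  Lines with no member and duplicate set names are rejected
#' with the offending line number.
#'
#' @param path file path.
#' @return A [PathwayCollection-class].  An empty file yields an empty
#'   collection with a warning.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(PathwayCollection(list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad))
    stop("GMT line(s) with fewer than one member: line ",
         paste(bad, collapse = ", "))
  nm <- vapply(parts, `[[`, character(1), 1L)
  dup <- which(duplicated(nm))
  if (length(dup))
    stop("duplicate pathway name at line ", paste(dup, collapse = ", "),
         ": ", paste(unique(nm[dup]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  PathwayCollection(sets, vapply(parts, `[[`, character(1), 2L))
}

#' Write a PathwayCollection as GMT
#' @param pc a [PathwayCollection-class].
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeGMT <- function(pc, path) {
  stopifnot(is(pc, "PathwayCollection"))
  desc <- pc@description
  if (length(desc) == 0L) desc <- character(0)
  lines <- vapply(seq_len(length(pc)), function(i)
    paste(c(names(pc)[i],
            if (nzchar(desc[i])) desc[i] else "na",
            pc@sets[[i]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

# matrix -> TSV with an explicit id column (round-trips through readMatrixTSV)
writeMatrixTSV <- function(m, path, idColumn = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read/write interchange tables
#'
#' \code{readCounts} reads an exon x sample count TSV (first column exon id),
#' \code{readAnnotation} the exon annotation table (columns \code{exonId},
#' \code{featureId}, \code{biotype}, \code{exonLength}),
#' \code{readClinical} a clinical table (columns \code{sample},
#' \code{cohort}, \code{sampleType}, \code{osDays}, \code{event}) and
#' \code{readExpressionTSV}/\code{writeExpressionTSV} a feature x sample
#' expression matrix.
#'
#' @param path file path.
#' @return \code{readCounts}/\code{readExpressionTSV}: numeric matrix;
#'   \code{readAnnotation}/\code{readClinical}: data.frame.
#' @name interchange
#' @export
readCounts <- function(path) readMatrixTSV(path)

#' @rdname interchange
#' @export
readAnnotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("exonId", "featureId", "biotype", "exonLength")
  miss <- setdiff(need, colnames(ann))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  ann
}

#' @rdname interchange
#' @export
readClinical <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "cohort", "sampleType", "osDays", "event")
  miss <- setdiff(need, colnames(cl))
  if (length(miss))
    stop("clinical table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(cl$sampleType %in% c("tumor", "normal")))
    stop("sampleType must be 'tumor' or 'normal'")
  ev <- cl$event[!is.na(cl$event)]
  if (!all(ev %in% c(0L, 1L))) stop("event must be 0/1")
  os <- cl$osDays[!is.na(cl$osDays)]
  if (any(os < 0)) stop("negative osDays")
  cl
}

#' @rdname interchange
#' @export
readExpressionTSV <- function(path) readMatrixTSV(path)

#' @rdname interchange
#' @param m feature x sample matrix with dimnames.
#' @export
writeExpressionTSV <- function(m, path) {
  writeMatrixTSV(m, path, idColumn = "featureId")
}
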