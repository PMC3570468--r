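#' Read a square relational matrix from TSV/CSV
#'
#' Reads a similarity or distance matrix.  The field separator is taken
#' from the file extension (comma for \code{.csv}, tab otherwise).  A
#' header row and a first column of node labels are auto-detected: if the
#' first field of the first line is non-numeric the file is assumed to
#' carry labels.
#'
#' @param path file path.
#' @param type \code{"similarity"} (entries in \[0, 1\], used as-is) or
#'   \code{"distance"} (passed through \code{\link{asSimilarity}}).
#' @param scale distance-to-similarity scale, see \code{\link{asSimilarity}}.
#' @return A \linkS4class{SimilarityMatrix}.
#' @export
readSimilarity <- function(path, type = c("similarity", "distance"),
                           scale = "auto") {
  type <- match.arg(type)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  labelled <- is.na(suppressWarnings(as.numeric(first[1])))
  df <- utils::read.table(path, sep = sep, header = labelled,
                          row.names = if (labelled) 1 else NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df)
  if (!is.numeric(M))
    stop("non-numeric entries in ", path, " (first bad column: ",
         colnames(df)[which(!vapply(df, is.numeric, logical(1)))[1]], ")")
  if (nrow(M) != ncol(M))
    stop("matrix in ", path, " is not square: ", nrow(M), " x ", ncol(M))
  labels <- if (labelled) rownames(M) else NULL
  if (type == "distance") asSimilarity(M, scale = scale, labels = labels)
  else SimilarityMatrix(M, labels = labels)
}

#' Write a labelled square matrix as TSV
#'
#' @param M numeric matrix; dimnames, if present, become the header row and
#'   label column.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeMatrixTSV <- function(M, path) {
  utils::write.table(M, path, sep = "\t", quote = FALSE,
                     row.names = !is.null(rownames(M)),
                     col.names = if (!is.null(colnames(M))) NA else FALSE)
  invisible(path)
}

#' Write a point cloud as TSV
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param path output file for the coordinates (one point per row).
#' @param labelsPath optional output file for the planted labels.
#' @return Invisibly, \code{path}.
#' @export
writePointCloud <- function(cloud, path, labelsPath = NULL) {
  stopifnot(is(cloud, "PointCloud"))
  co <- cloud@coordinates
  colnames(co) <- paste0("x", seq_len(ncol(co)))
  utils::write.table(co, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!is.null(labelsPath))
    utils::write.table(
      data.frame(point = seq_len(nrow(co)), label = cloud@trueLabels),
      labelsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
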