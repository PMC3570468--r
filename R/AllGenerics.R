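#' Accessors
#'
#' Small accessor generics for the package classes.
#'
#' @param x an object of one of the package classes.
#' @return The underlying matrix, labels or parameter the accessor names.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("similarity", function(x) standardGeneric("similarity"))
#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))
#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname accessors
#' @export
setGeneric("removalOrder", function(x) standardGeneric("removalOrder"))
#' @rdname accessors
#' @export
setGeneric("recurrenceTimes", function(x) standardGeneric("recurrenceTimes"))
#' @rdname accessors
#' @export
setGeneric("sharingProb", function(x) standardGeneric("sharingProb"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname accessors
#' @export
setGeneric("criticalTemps", function(x) standardGeneric("criticalTemps"))
#' @rdname accessors
#' @export
setGeneric("levelTemps", function(x) standardGeneric("levelTemps"))
#' @rdname accessors
#' @export
setGeneric("levelPartitions", function(x) standardGeneric("levelPartitions"))
#' @rdname accessors
#' @export
setGeneric("ultrametric", function(x) standardGeneric("ultrametric"))
#' @rdname accessors
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))
#' @rdname accessors
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))

#' @rdname accessors
setMethod("similarity", "SimilarityMatrix", function(x) {
  S <- x@S
  dimnames(S) <- list(x@labels, x@labels)
  S
})
#' @rdname accessors
setMethod("nodeLabels", "SimilarityMatrix", function(x) x@labels)
#' @rdname accessors
setMethod("nNodes", "SimilarityMatrix", function(x) nrow(x@S))
#' @rdname accessors
setMethod("removalOrder", "WalkRecord", function(x) x@removalOrder)
#' @rdname accessors
setMethod("recurrenceTimes", "WalkRecord", function(x) x@recurrenceTimes)
#' @rdname accessors
setMethod("sharingProb", "SharingMatrix", function(x) x@Phat)
#' @rdname accessors
setMethod("clusterLabels", "ClusterConfiguration", function(x) x@labels)
#' @rdname accessors
setMethod("nClusters", "ClusterConfiguration", function(x) x@K)
#' @rdname accessors
setMethod("criticalTemps", "LevelScan", function(x) x@criticalTemps)
#' @rdname accessors
setMethod("levelTemps", "DCGTree", function(x) x@levelTemps)
#' @rdname accessors
setMethod("levelPartitions", "DCGTree", function(x) x@partitions)
#' @rdname accessors
setMethod("nodeLabels", "DCGTree", function(x) x@labels)
#' @rdname accessors
setMethod("ultrametric", "DCGTree", function(x) {
  U <- x@U
  dimnames(U) <- list(x@labels, x@labels)
  U
})
#' @rdname accessors
setMethod("coordinates", "PointCloud", function(x) x@coordinates)
#' @rdname accessors
setMethod("trueLabels", "PointCloud", function(x) x@trueLabels)

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix with", nrow(object@S), "nodes\n")
  off <- object@S[row(object@S) != col(object@S)]
  cat("  off-diagonal range:", format(range(off), digits = 4), "\n")
})

setMethod("show", "WalkRecord", function(object) {
  cat("WalkRecord:", length(object@removalOrder), "removals, visit cap",
      object@visitCap, "\n")
  cat("  total steps:", sum(object@recurrenceTimes),
      " restarts:", object@restarts,
      " isolated nodes:", length(object@isolated), "\n")
})

setMethod("show", "SharingMatrix", function(object) {
  cat("SharingMatrix at T =", format(object@temperature, digits = 4),
      "from", object@nWalks, "walks;", nrow(object@Phat), "nodes\n")
})

setMethod("show", "ClusterConfiguration", function(object) {
  cat("ClusterConfiguration: K =", object@K, "at T =",
      format(object@temperature, digits = 4), "\n")
})

setMethod("show", "LevelScan", function(object) {
  cat("LevelScan over", length(object@temperatures), "temperatures, K from",
      max(object@KofT), "to", min(object@KofT), "\n")
  if (length(object@criticalTemps)) {
    Ks <- vapply(object@criticalConfigs, function(cc) cc@K, integer(1))
    cat("  critical levels (T : K): ",
        paste(sprintf("%.4g : %d", object@criticalTemps, Ks),
              collapse = ", "), "\n", sep = "")
  } else cat("  critical levels not yet selected\n")
})

setMethod("show", "DCGTree", function(object) {
  Ks <- vapply(object@partitions, function(p) length(unique(p)), integer(1))
  cat("DCGTree on", length(object@labels), "leaves with",
      length(object@levelTemps), "levels\n")
  cat("  K per level:", paste(Ks, collapse = " > "), "\n")
  cat("  merge heights:",
      paste(format(object@levelTemps, digits = 4), collapse = " < "), "\n")
})

setMethod("show", "ParisiMatrix", function(object) {
  cat("ParisiMatrix:", nrow(object@M), "x", nrow(object@M),
      "block-constant ultrametric\n")
})

setMethod("show", "PointCloud", function(object) {
  cat("PointCloud:", nrow(object@coordinates), "points in",
      ncol(object@coordinates), "dimension(s),",
      length(unique(object@trueLabels)), "planted groups\n")
})
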