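#' @import methods
NULL

.is_symmetric <- function(M, tol = 1e-9) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol
}

#' Normalized similarity matrix over a data cloud
#'
#' Container for an N x N symmetric matrix of normalized similarity weights
#' in \[0, 1\] together with node labels.  The diagonal is ignored by every
#' consumer (no self-loops); it is stored as 0.
#'
#' @slot S numeric matrix of pairwise similarities.
#' @slot labels character vector of node identifiers.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(S = "matrix", labels = "character"),
  validity = function(object) {
    S <- object@S
    if (!is.numeric(S) || !is.matrix(S)) return("S must be a numeric matrix")
    if (nrow(S) < 2) return("need at least 2 nodes")
    if (nrow(S) != ncol(S)) return("S must be square")
    if (!.is_symmetric(S)) return("S must be symmetric")
    off <- S[row(S) != col(S)]
    if (any(!is.finite(off))) return("similarities must be finite")
    if (any(off < 0) || any(off > 1))
      return("off-diagonal similarities must lie in [0, 1]")
    if (length(object@labels) != nrow(S))
      return("labels length must equal matrix dimension")
    TRUE
  }
)

#' One regulated random walk
#'
#' The removal order and recurrence-time profile of a single visit-capped,
#' node-removing random walk.  \code{recurrenceTimes[i]} is the number of
#' arrivals between the (i-1)-th and i-th node removals.
#'
#' @slot removalOrder integer node indices in order of removal.
#' @slot recurrenceTimes integer arrivals between consecutive removals.
#' @slot visitCap integer visit cap m.
#' @slot seed integer RNG seed of this walk.
#' @slot nNodes integer total node count (including isolated nodes).
#' @slot isolated integer indices of zero-weight nodes excluded from the walk.
#' @slot restarts integer number of uniform restarts (stranded chain).
#' @exportClass WalkRecord
setClass("WalkRecord",
  representation(removalOrder = "integer", recurrenceTimes = "integer",
                 visitCap = "integer", seed = "integer", nNodes = "integer",
                 isolated = "integer", restarts = "integer"),
  validity = function(object) {
    if (length(object@removalOrder) != length(object@recurrenceTimes))
      return("removalOrder and recurrenceTimes must have equal length")
    if (any(object@recurrenceTimes < 1))
      return("recurrence times must be >= 1")
    act <- sort(c(object@removalOrder, object@isolated))
    if (!identical(act, seq_len(object@nNodes)))
      return("removalOrder plus isolated must be a permutation of the nodes")
    TRUE
  }
)

#' Binary co-well indicator matrix
#'
#' Symmetric 0/1 matrix from one walk: entry (i, j) is 1 iff nodes i and j
#' were removed within the same inter-spike segment (and so very likely
#' share the base of one potential well).
#'
#' @slot B binary matrix.
#' @slot segmentIds integer segment index per node.
#' @exportClass CoWellMatrix
setClass("CoWellMatrix",
  representation(B = "matrix", segmentIds = "integer"),
  validity = function(object) {
    B <- object@B
    if (!.is_symmetric(B, tol = 0)) return("B must be symmetric")
    if (!all(B %in% c(0, 1))) return("B must be binary")
    if (any(diag(B) != 1)) return("diagonal of B must be 1")
    if (length(object@segmentIds) != nrow(B))
      return("segmentIds length must equal matrix dimension")
    TRUE
  }
)

#' Cluster-sharing probability matrix at one temperature
#'
#' Ensemble mean of co-well indicator matrices over E regulated walks on the
#' same temperature-regulated landscape.
#'
#' @slot Phat numeric matrix of sharing probabilities in \[0, 1\], unit diagonal.
#' @slot temperature numeric temperature T at which the ensemble was run.
#' @slot nWalks integer ensemble size E.
#' @exportClass SharingMatrix
setClass("SharingMatrix",
  representation(Phat = "matrix", temperature = "numeric", nWalks = "integer"),
  validity = function(object) {
    P <- object@Phat
    if (!.is_symmetric(P)) return("Phat must be symmetric")
    if (any(P < -1e-12) || any(P > 1 + 1e-12))
      return("Phat entries must lie in [0, 1]")
    if (max(abs(diag(P) - 1)) > 1e-12) return("Phat diagonal must be 1")
    if (length(object@temperature) != 1 || object@temperature <= 0)
      return("temperature must be a positive scalar")
    if (object@nWalks < 1) return("nWalks must be >= 1")
    TRUE
  }
)

#' Cluster configuration at one temperature
#'
#' @slot temperature numeric temperature.
#' @slot K integer number of clusters.
#' @slot labels integer cluster label per node, in 1..K, every class non-empty.
#' @exportClass ClusterConfiguration
setClass("ClusterConfiguration",
  representation(temperature = "numeric", K = "integer", labels = "integer"),
  validity = function(object) {
    if (object@K < 1) return("K must be >= 1")
    if (object@K > length(object@labels)) return("K cannot exceed N")
    u <- sort(unique(object@labels))
    if (!identical(u, seq_len(object@K)))
      return("labels must use every value in 1..K")
    TRUE
  }
)

#' Temperature scan of the cluster count
#'
#' Per-temperature cluster counts and memberships over an increasing grid,
#' plus (after level selection) the critical-temperature sequence that
#' defines the tree levels.
#'
#' @slot temperatures increasing numeric grid.
#' @slot KofT integer cluster count per grid point.
#' @slot configs list of \linkS4class{ClusterConfiguration}, one per grid point.
#' @slot criticalTemps increasing numeric critical temperatures (may be empty
#'   before \code{criticalTemperatures()} is applied).
#' @slot criticalConfigs list of configurations at the critical temperatures.
#' @slot params list of scan parameters (E, m, spike factor, eigen floor, seed).
#' @exportClass LevelScan
setClass("LevelScan",
  representation(temperatures = "numeric", KofT = "integer", configs = "list",
                 criticalTemps = "numeric", criticalConfigs = "list",
                 params = "list"),
  validity = function(object) {
    if (is.unsorted(object@temperatures, strictly = TRUE))
      return("temperatures must be strictly increasing")
    if (length(object@KofT) != length(object@temperatures))
      return("KofT length must match the grid")
    if (length(object@configs) != length(object@temperatures))
      return("configs length must match the grid")
    k <- length(object@criticalTemps)
    if (length(object@criticalConfigs) != k)
      return("criticalConfigs must match criticalTemps")
    if (k > 0) {
      if (is.unsorted(object@criticalTemps, strictly = TRUE))
        return("critical temperatures must be strictly increasing")
      Ks <- vapply(object@criticalConfigs, function(cc) cc@K, integer(1))
      if (any(diff(Ks) >= 0))
        return("K must strictly decrease along critical levels")
      if (Ks[k] != 1) return("top critical configuration must have K = 1")
    }
    TRUE
  }
)

#' Multi-level ultrametric clustering tree
#'
#' Nested partitions of the nodes, one per critical temperature; the level-l
#' partition refines the level-(l+1) partition, and the top level is a single
#' cluster.  The cophenetic distance of the tree equals the stored
#' ultrametric matrix exactly.
#'
#' @slot labels character node labels (tree leaves).
#' @slot levelTemps increasing numeric merge heights T_1 < ... < T_k.
#' @slot partitions list of integer label vectors, one per level.
#' @slot U the N x N ultrametric matrix the tree represents.
#' @exportClass DCGTree
setClass("DCGTree",
  representation(labels = "character", levelTemps = "numeric",
                 partitions = "list", U = "matrix"),
  validity = function(object) {
    k <- length(object@levelTemps)
    if (k < 1) return("need at least one level")
    if (is.unsorted(object@levelTemps, strictly = TRUE))
      return("level temperatures must be strictly increasing")
    if (length(object@partitions) != k)
      return("one partition per level required")
    n <- length(object@labels)
    for (p in object@partitions)
      if (length(p) != n) return("partition length must equal leaf count")
    if (length(unique(object@partitions[[k]])) != 1)
      return("top level must be a single cluster")
    # refinement bottom-up: same label at level l implies same at level l+1
    if (k > 1) for (l in seq_len(k - 1)) {
      lo <- object@partitions[[l]]; hi <- object@partitions[[l + 1]]
      if (anyDuplicated(unique(cbind(lo, hi))[, 1L]))
        return("partitions must be nested (each level refines the next)")
    }
    TRUE
  }
)

#' Parisi matrix: the ultrametric re-indexed to reveal its blocks
#'
#' Rows and columns of the ultrametric are permuted along a depth-first
#' traversal of the tree so every cluster at every level occupies a
#' contiguous index range, rendering the matrix block-constant.
#'
#' @slot order integer permutation of node indices.
#' @slot M re-indexed ultrametric matrix, with the permuted labels on dimnames.
#' @exportClass ParisiMatrix
setClass("ParisiMatrix",
  representation(order = "integer", M = "matrix"),
  validity = function(object) {
    n <- nrow(object@M)
    if (!identical(sort(object@order), seq_len(n)))
      return("order must be a permutation of 1..N")
    if (!.is_symmetric(object@M)) return("M must be symmetric")
    if (any(diag(object@M) != 0)) return("M diagonal must be 0")
    TRUE
  }
)

#' Synthetic point cloud with planted group labels
#'
#' @slot coordinates numeric matrix, one row per point (1 or 2 columns).
#' @slot trueLabels integer planted group per point.
#' @slot params list of generator settings including the seed.
#' @exportClass PointCloud
setClass("PointCloud",
  representation(coordinates = "matrix", trueLabels = "integer",
                 params = "list"),
  validity = function(object) {
    if (nrow(object@coordinates) != length(object@trueLabels))
      return("one label per point required")
    if (!ncol(object@coordinates) %in% c(1L, 2L))
      return("coordinates must be 1- or 2-dimensional")
    TRUE
  }
)
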