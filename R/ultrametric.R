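#' Cluster-sharing status sequences across the critical levels
#'
#' For every node pair (i, j) and level l = 1..k, the binary indicator that
#' i and j are co-clustered in the configuration at critical temperature
#' T_l.  The top configuration must be a single cluster, so every pair ends
#' in 1.  A pair may switch between 0 and 1 more than once when the level
#' configurations are not nested; the ultrametric construction resolves
#' this.
#'
#' @param configs list of \linkS4class{ClusterConfiguration} at increasing
#'   critical temperatures, or a \linkS4class{LevelScan} with critical
#'   levels selected.
#' @return Integer array of dimension N x N x k of 0/1 indicators.
#' @export
statusSequences <- function(configs) {
  if (is(configs, "LevelScan")) configs <- configs@criticalConfigs
  if (!length(configs)) stop("need at least one configuration")
  if (!all(vapply(configs, is, logical(1), "ClusterConfiguration")))
    stop("configs must be ClusterConfiguration objects")
  k <- length(configs)
  if (configs[[k]]@K != 1)
    stop("top configuration must have K = 1 (a single all-node cluster)")
  n <- length(configs[[1]]@labels)
  delta <- array(0L, dim = c(n, n, k))
  for (l in seq_len(k)) {
    lab <- configs[[l]]@labels
    if (length(lab) != n) stop("configurations disagree on node count")
    delta[, , l] <- 1L * outer(lab, lab, "==")
  }
  delta
}

#' Self-correcting ultrametric from status sequences
#'
#' The raw barrier height of a pair is the critical temperature at which the
#' last 0-to-1 switch of its status sequence occurs; pairs co-clustered at
#' every level (no switch) take the bottom temperature T_1.  A sequence with
#' several switches means earlier co-cluster assignments are revised — the
#' built-in self-correction.  When the level configurations are not nested
#' the raw heights can violate the strong triangle inequality, so the
#' subdominant ultrametric closure (minimax path value, computed via
#' single-linkage cophenetic heights) is applied; it is the minimal
#' ultrametric dominated by the raw heights and leaves them unchanged
#' whenever the configurations are nested.
#'
#' @param delta N x N x k status array from \code{\link{statusSequences}}.
#' @param temps increasing critical temperatures T_1 < ... < T_k.
#' @return Symmetric N x N ultrametric matrix with zero diagonal and
#'   off-diagonal entries drawn from \{T_1, ..., T_k\}.
#' @export
ultrametricFromStatus <- function(delta, temps) {
  stopifnot(is.array(delta), length(dim(delta)) == 3)
  k <- dim(delta)[3]
  n <- dim(delta)[1]
  if (length(temps) != k) stop("temps must have one value per level")
  if (k > 1 && is.unsorted(temps, strictly = TRUE))
    stop("temps must be strictly increasing")
  if (any(delta[, , k] != 1))
    stop("top level must co-cluster every pair")
  # level of the last 0 -> 1 switch, vectorized across pairs
  lastSwitch <- matrix(0L, n, n)
  if (k > 1) for (l in 2:k) {
    sw <- delta[, , l] == 1L & delta[, , l - 1] == 0L
    lastSwitch[sw] <- l
  }
  R <- matrix(temps[pmax(lastSwitch, 1L)], n, n)
  R[lastSwitch == 0L] <- temps[1]  # never separated: bottom temperature
  diag(R) <- 0
  .subdominantUltrametric(R)
}

# Minimax-path (subdominant ultrametric) closure via single-linkage
# cophenetic heights: the largest ultrametric dominated by R.
.subdominantUltrametric <- function(R) {
  n <- nrow(R)
  h <- stats::hclust(stats::as.dist(R), method = "single")
  U <- as.matrix(stats::cophenetic(h))
  dimnames(U) <- NULL
  diag(U) <- 0
  U
}

# Strong triangle inequality check; exhaustive for n <= nExhaustive,
# sampled triples above that.
.checkUltrametric <- function(U, tol = 1e-9, nExhaustive = 200,
                              nSample = 1e5) {
  n <- nrow(U)
  if (n <= 2) return(TRUE)
  if (n <= nExhaustive) {
    for (j in seq_len(n)) {
      # U_ik <= max(U_ij, U_jk) for all i, k given j, as a matrix test
      m <- pmax(matrix(U[, j], n, n), matrix(U[j, ], n, n, byrow = TRUE))
      if (max(U - m) > tol) return(FALSE)
    }
    TRUE
  } else {
    idx <- matrix(sample.int(n, 3 * nSample, replace = TRUE), ncol = 3)
    all(U[idx[, c(1, 3)]] <=
          pmax(U[idx[, c(1, 2)]], U[idx[, c(2, 3)]]) + tol)
  }
}

#' Build the multi-level clustering tree from an ultrametric
#'
#' The level-l partition is the set of equivalence classes of the relation
#' U_ij <= T_l (transitive because U is ultrametric); merges between
#' consecutive levels give the tree, whose root sits at the top critical
#' temperature.  The cophenetic distance of the resulting tree reproduces U
#' exactly.
#'
#' @param U symmetric ultrametric matrix (validated on entry).
#' @param temps increasing level temperatures; off-diagonal entries of U
#'   must be drawn from them.
#' @param labels optional leaf labels.
#' @return A \linkS4class{DCGTree}.
#' @export
buildTree <- function(U, temps, labels = NULL) {
  if (!is.matrix(U) || nrow(U) != ncol(U)) stop("U must be square")
  if (max(abs(U - t(U))) > 1e-9) stop("U must be symmetric")
  if (!.checkUltrametric(U))
    stop("U violates the strong triangle inequality")
  n <- nrow(U)
  if (is.null(labels)) {
    labels <- rownames(U)
    if (is.null(labels)) labels <- paste0("n", seq_len(n))
  }
  temps <- sort(unique(temps))
  off <- U[row(U) != col(U)]
  if (length(off) && max(off) > max(temps) + 1e-9)
    stop("U contains heights above the top level temperature")
  partitions <- vector("list", length(temps))
  for (l in seq_along(temps)) {
    partitions[[l]] <- .componentsBelow(U, temps[l])
  }
  new("DCGTree", labels = as.character(labels), levelTemps = temps,
      partitions = partitions, U = unname(U))
}

# Equivalence classes of U_ij <= h as integer labels 1..K (first-appearance
# order).  Transitive closure is a connected-components pass; for an
# ultrametric the relation is already transitive.
.componentsBelow <- function(U, h, tol = 1e-9) {
  n <- nrow(U)
  adj <- U <= h + tol
  lab <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (lab[i] == 0L) {
      nxt <- nxt + 1L
      # breadth-first sweep
      frontier <- i
      lab[i] <- nxt
      while (length(frontier)) {
        reach <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & lab == 0L)
        lab[reach] <- nxt
        frontier <- reach
      }
    }
  }
  lab
}

#' Merge table of a DCG tree
#'
#' One row per parent-child link between consecutive levels (level 0 being
#' the leaves): the cluster id of the child at its level, the parent cluster
#' id, and the merge height (the parent's level temperature).
#'
#' @param tree a \linkS4class{DCGTree}.
#' @return A data.frame with columns \code{level}, \code{parent},
#'   \code{childLevel}, \code{child}, \code{height}.
#' @export
mergeTable <- function(tree) {
  stopifnot(is(tree, "DCGTree"))
  k <- length(tree@levelTemps)
  n <- length(tree@labels)
  rows <- list()
  prev <- seq_len(n)           # level-0 "partition": every leaf its own class
  for (l in seq_len(k)) {
    cur <- tree@partitions[[l]]
    map <- unique(cbind(child = prev, parent = cur))
    rows[[l]] <- data.frame(level = l, parent = map[, "parent"],
                            childLevel = l - 1L, child = map[, "child"],
                            height = tree@levelTemps[l])
    prev <- cur
  }
  do.call(rbind, rows)
}

# Recursive tree walk shared by toNewick and parisiOrder.
# For a member set whose lowest containing level is l, the children are the
# classes of the partition one level down (leaves when l == 1), ordered by
# size descending then smallest member index.
.childrenOf <- function(tree, members, level) {
  if (level == 1) {
    kids <- as.list(members)
  } else {
    sub <- tree@partitions[[level - 1]][members]
    kids <- split(members, factor(sub, levels = unique(sub)))
  }
  sizes <- lengths(kids)
  mins <- vapply(kids, min, numeric(1))
  kids[order(-sizes, mins)]
}

# Lowest level at which `members` forms a single cluster, descending from
# `level`; returns the level and the node height T at it.
.lowestLevel <- function(tree, members, level) {
  while (level > 1 &&
         length(unique(tree@partitions[[level - 1]][members])) == 1)
    level <- level - 1
  level
}

#' Newick export of a DCG tree
#'
#' Branch lengths are parent height minus child height, leaves sit at height
#' 0 and internal nodes at their level temperature, so the cophenetic
#' distances of the exported tree equal the ultrametric matrix.  Internal
#' nodes are labelled \code{L<level>}.
#'
#' @param tree a \linkS4class{DCGTree}.
#' @return A single Newick string terminated by ";".
#' @examples
#' U <- matrix(c(0, 2, 2, 0), 2)
#' toNewick(buildTree(U, 2, labels = c("a", "b")))
#' @export
toNewick <- function(tree) {
  stopifnot(is(tree, "DCGTree"))
  k <- length(tree@levelTemps)
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.9f", x))
  rec <- function(members, level) {
    if (length(members) == 1)
      return(list(str = tree@labels[members], height = 0))
    lvl <- .lowestLevel(tree, members, level)
    h <- tree@levelTemps[lvl]
    kids <- .childrenOf(tree, members, lvl)
    parts <- vapply(kids, function(mem) {
      ch <- rec(mem, if (lvl > 1) lvl - 1 else 1)
      paste0(ch$str, ":", fmt(h - ch$height))
    }, character(1))
    list(str = paste0("(", paste(parts, collapse = ","), ")L", lvl),
         height = h)
  }
  root <- rec(seq_along(tree@labels), k)
  paste0(root$str, ";")
}

#' Parisi matrix of a DCG tree
#'
#' Orders the leaves by a depth-first traversal (children by size descending,
#' ties by smallest member index) so that the members of every ultrametric
#' ball occupy an undivided index range, and re-indexes the ultrametric by
#' that order.  Each entry then records the highest energy barrier (critical
#' temperature) separating its row and column nodes, and the matrix is
#' block-constant by construction.
#'
#' @param tree a \linkS4class{DCGTree}.
#' @return A \linkS4class{ParisiMatrix}.
#' @export
parisiMatrix <- function(tree) {
  stopifnot(is(tree, "DCGTree"))
  k <- length(tree@levelTemps)
  rec <- function(members, level) {
    if (length(members) == 1) return(members)
    lvl <- .lowestLevel(tree, members, level)
    kids <- .childrenOf(tree, members, lvl)
    unlist(lapply(kids, rec, level = if (lvl > 1) lvl - 1 else 1),
           use.names = FALSE)
  }
  ord <- rec(seq_along(tree@labels), k)
  M <- tree@U[ord, ord]
  dimnames(M) <- list(tree@labels[ord], tree@labels[ord])
  new("ParisiMatrix", order = as.integer(ord), M = M)
}

#' Plot a Parisi matrix as a block heatmap
#'
#' Minimal \code{graphics::image} rendering of the re-indexed ultrametric;
#' darker cells are lower barriers (tighter clusters).
#'
#' @param x a \linkS4class{ParisiMatrix}.
#' @param ... passed to \code{graphics::image}.
#' @return Invisibly, \code{x}.
#' @export
plotParisi <- function(x, ...) {
  stopifnot(is(x, "ParisiMatrix"))
  n <- nrow(x@M)
  graphics::image(seq_len(n), seq_len(n), t(x@M[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  xlab = "", ylab = "", axes = FALSE, ...)
  invisible(x)
}
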