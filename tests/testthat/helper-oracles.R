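# Independent brute-force oracles used across the test files.

# Row-normalization by explicit loops (oracle for transitionMatrix).
oracle_transition <- function(W) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) if (j != i) s <- s + W[i, j]
    if (s > 0) for (j in seq_len(n)) if (j != i) P[i, j] <- W[i, j] / s
  }
  P
}

# Minimax path value (subdominant ultrametric) by exhaustive enumeration of
# all simple paths; tractable for tiny n.
oracle_minimax <- function(R) {
  n <- nrow(R)
  U <- matrix(Inf, n, n)
  diag(U) <- 0
  nodes <- seq_len(n)
  for (i in nodes) for (j in nodes) {
    if (i >= j) next
    others <- setdiff(nodes, c(i, j))
    best <- R[i, j]
    for (k in 0:length(others)) {
      if (k == 0) next
      combos <- utils::combn(others, k, simplify = FALSE)
      for (mid in combos) {
        perms <- all_perms(mid)
        for (p in perms) {
          path <- c(i, p, j)
          w <- max(R[cbind(path[-length(path)], path[-1])])
          if (w < best) best <- w
        }
      }
    }
    U[i, j] <- U[j, i] <- best
  }
  U
}

all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in all_perms(x[-i])) out <- c(out, list(c(x[i], p)))
  out
}

# Rand index by explicit pair enumeration (oracle for randIndex).
oracle_rand <- function(a, b) {
  n <- length(a)
  agree <- 0; total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1
  }
  agree / total
}

# Strong triangle inequality over every triple, by loops.
oracle_ultrametric_ok <- function(U, tol = 1e-9) {
  n <- nrow(U)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    if (U[i, k] > max(U[i, j], U[j, k]) + tol) return(FALSE)
  TRUE
}

# Cophenetic matrix of a DCGTree recomputed from its level partitions: the
# smallest level temperature at which a pair is co-clustered.
oracle_cophenetic <- function(tree) {
  n <- length(nodeLabels(tree))
  temps <- levelTemps(tree)
  U <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    for (l in seq_along(temps)) {
      if (levelPartitions(tree)[[l]][i] == levelPartitions(tree)[[l]][j]) {
        U[i, j] <- U[j, i] <- temps[l]
        break
      }
    }
  }
  U
}

# Every cluster of every level occupies a contiguous range of the Parisi
# ordering.
parisi_contiguous <- function(tree, pm) {
  ord <- pm@order
  for (p in levelPartitions(tree)) {
    po <- p[ord]
    for (cl in unique(po)) {
      idx <- which(po == cl)
      if (any(diff(idx) != 1)) return(FALSE)
    }
  }
  TRUE
}

# Deterministic planted two-block fixture shared by walk/sharing tests.
two_block_fixture <- function(sizes = c(10, 10), sIn = 0.9, sOut = 1e-6) {
  blockSimilarity(sizes, sIn, sOut, jitter = 0, seed = 1)
}
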