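#' Cluster-sharing probability matrix from an ensemble of walks
#'
#' Element-wise mean of the binary co-well matrices of E independent
#' regulated walks on the same landscape: entry (i, j) estimates the
#' probability that i and j share a potential well at temperature T.
#'
#' @param cowells list of \linkS4class{CoWellMatrix} over identical node sets.
#' @param temperature the temperature the walks were run at.
#' @return A \linkS4class{SharingMatrix}.
#' @export
sharingMatrix <- function(cowells, temperature) {
  if (!length(cowells)) stop("need at least one co-well matrix")
  if (!all(vapply(cowells, is, logical(1), "CoWellMatrix")))
    stop("cowells must be a list of CoWellMatrix objects")
  n <- nrow(cowells[[1]]@B)
  if (!all(vapply(cowells, function(x) nrow(x@B), integer(1)) == n))
    stop("co-well matrices have inconsistent dimensions")
  P <- Reduce(`+`, lapply(cowells, function(x) x@B)) / length(cowells)
  P <- (P + t(P)) / 2
  diag(P) <- 1
  new("SharingMatrix", Phat = P, temperature = temperature,
      nWalks = length(cowells))
}

# Run E regulated walks at one temperature and aggregate them.
# Per-walk seeds are derived deterministically from `seed`.
.sharingAtTemperature <- function(S, temperature, nWalks = 50, m = 5,
                                  spikeFactor = 5, seed = 1) {
  W <- temperatureWeights(S, temperature)
  n <- nrow(W)
  cw <- vector("list", nWalks)
  for (e in seq_len(nWalks)) {
    ws <- .deriveSeed(seed, e)
    res <- .regulated_walk_cpp(W, as.integer(m), ws)
    rec <- new("WalkRecord",
               removalOrder = as.integer(res$removal_order),
               recurrenceTimes = as.integer(res$recurrence_times),
               visitCap = as.integer(m), seed = ws,
               nNodes = n, isolated = as.integer(res$isolated),
               restarts = as.integer(res$restarts))
    sp <- if (length(rec@recurrenceTimes))
      detectSpikes(rec@recurrenceTimes, c = spikeFactor) else integer(0)
    cw[[e]] <- cowellMatrix(rec, sp)
  }
  sharingMatrix(cw, temperature)
}

# Deterministic 31-bit seed stream: master seed mixed with an index.
.deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 69621 + 11) %%
               2147483647)
}

#' Count clusters from the eigen-spectrum of the sharing matrix
#'
#' The number of potential wells equals the number of significantly
#' non-zero eigenvalues of the sharing matrix: K is the count of
#' eigenvalues at or above \code{floor} times the leading eigenvalue.  A
#' well of s nodes sharing with probability p contributes an eigenvalue of
#' roughly s * p, while the unit diagonal alone contributes a noise floor
#' near 1, so the relative floor separates well modes from noise modes.  On
#' an exact block-constant matrix with B blocks this returns exactly B, and
#' on the identity (no sharing at all) it returns N.
#'
#' @param Phat a \linkS4class{SharingMatrix} or a symmetric numeric matrix.
#' @param floor relative eigenvalue floor (default 0.05) below which
#'   eigenvalues are not counted as significant.
#' @return Integer cluster count K >= 1.
#' @examples
#' countClusters(matrix(1, 4, 4))           # 1
#' countClusters(diag(4))                   # 4
#' @export
countClusters <- function(Phat, floor = 0.05) {
  P <- if (is(Phat, "SharingMatrix")) Phat@Phat else Phat
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop("Phat must be square")
  lam <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  max(1L, sum(lam >= floor * lam[1]))
}

#' Extract cluster memberships from the sharing matrix
#'
#' Clusters the nodes into K groups using 1 - Phat as a distance.  The
#' default \code{"consensus"} method cuts an average-linkage agglomerative
#' tree of that distance at K groups — the standard way to read a consensus
#' (co-clustering probability) matrix, and markedly more robust to single
#' bridge nodes than a centroid method.  \code{"spectral"} embeds the nodes
#' into the top-K eigenvectors of Phat (rows L2-normalized) and runs
#' K-means with \code{nstart = 10} under a fixed seed, retrying with a
#' derived sub-seed if a class comes back empty (up to 5 attempts) and
#' finally splitting the largest class at its farthest pair.  \code{"raw"}
#' runs K-means directly on the rows of 1 - Phat, the literal "sharing
#' probability as a distance" reading.
#'
#' @param Phat a \linkS4class{SharingMatrix} or symmetric numeric matrix.
#' @param K number of clusters, 1 <= K <= N.
#' @param seed RNG seed (used by the K-means based methods).
#' @param method \code{"consensus"} (default), \code{"spectral"} or
#'   \code{"raw"}.
#' @return A \linkS4class{ClusterConfiguration}.
#' @export
extractMembership <- function(Phat, K, seed = 1,
                              method = c("consensus", "spectral", "raw")) {
  method <- match.arg(method)
  temperature <- if (is(Phat, "SharingMatrix")) Phat@temperature else 1
  P <- if (is(Phat, "SharingMatrix")) Phat@Phat else Phat
  n <- nrow(P)
  K <- as.integer(K)
  if (K < 1 || K > n) stop("K must be between 1 and N")
  if (K == 1)
    return(new("ClusterConfiguration", temperature = temperature,
               K = 1L, labels = rep(1L, n)))
  if (K == n)
    return(new("ClusterConfiguration", temperature = temperature,
               K = K, labels = seq_len(n)))
  if (method == "consensus") {
    hc <- stats::hclust(stats::as.dist(1 - (P + t(P)) / 2),
                        method = "average")
    labels <- stats::cutree(hc, k = K)
    labels <- as.integer(factor(labels, levels = unique(labels)))
    return(new("ClusterConfiguration", temperature = temperature,
               K = K, labels = labels))
  }
  if (method == "raw") {
    emb <- 1 - P
  } else {
    ev <- eigen((P + t(P)) / 2, symmetric = TRUE)
    emb <- ev$vectors[, seq_len(K), drop = FALSE]
    nrm <- sqrt(rowSums(emb^2))
    nrm[nrm == 0] <- 1
    emb <- emb / nrm
  }
  labels <- NULL
  for (attempt in 0:5) {
    km <- .withSeed(.deriveSeed(seed, attempt), function()
      tryCatch(stats::kmeans(emb, centers = K, nstart = 10, iter.max = 50),
               error = function(e) NULL))
    if (!is.null(km) && length(unique(km$cluster)) == K) {
      labels <- km$cluster
      break
    }
  }
  if (is.null(labels)) {
    # degenerate embedding (duplicated rows): fall back to splitting the
    # largest class at its farthest pair until K classes exist
    labels <- rep(1L, n)
    d2 <- as.matrix(stats::dist(emb))
    while (length(unique(labels)) < K) {
      big <- as.integer(names(which.max(table(labels))))
      idx <- which(labels == big)
      sub <- d2[idx, idx, drop = FALSE]
      far <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      a <- idx[far[1]]; b <- idx[far[2]]
      newlab <- max(labels) + 1L
      labels[idx[d2[idx, b] < d2[idx, a]]] <- newlab
      labels[b] <- newlab
      if (!any(labels == big)) labels[a] <- big  # keep the old class alive
    }
  }
  labels <- as.integer(factor(labels, levels = unique(labels)))
  new("ClusterConfiguration", temperature = temperature,
      K = as.integer(length(unique(labels))), labels = labels)
}

# Evaluate fn() under a temporary R RNG seed, restoring the caller's state.
.withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}
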