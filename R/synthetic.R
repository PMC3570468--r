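#' Five collinear Gaussian dots
#'
#' Five node-centers A..E on a line with successive gaps 1, 1, 1.99 and 2.01
#' (positions 0, 1, 2, 3.99, 6.00), each emitting \code{nPerCenter}
#' independent Gaussian points.  The configuration plants a structural triad
#' \{A, B, C\} that a faithful multi-scale tree should carry as one single
#' branch, with D and E separate.
#'
#' @param sd Gaussian standard deviation around each center (default 0.15,
#'   small relative to the unit gap).
#' @param nPerCenter points per center (default 20, so N = 100).
#' @param seed RNG seed.
#' @return A \linkS4class{PointCloud} with 1-D coordinates and planted
#'   labels 1..5 (A..E).
#' @examples
#' fiveDots(seed = 1)
#' @export
fiveDots <- function(sd = 0.15, nPerCenter = 20, seed = 1) {
  stopifnot(sd > 0, nPerCenter >= 1)
  centers <- cumsum(c(0, 1, 1, 1.99, 2.01))
  x <- .withSeed(seed, function()
    rep(centers, each = nPerCenter) +
      stats::rnorm(5 * nPerCenter, 0, sd))
  new("PointCloud", coordinates = matrix(x, ncol = 1),
      trueLabels = rep(seq_len(5), each = as.integer(nPerCenter)),
      params = list(sd = sd, nPerCenter = nPerCenter, seed = seed,
                    centers = centers))
}

#' Two interlocking moons
#'
#' A data cloud of two moon conformations: a gibbous moon (upper arc
#' sweeping 200 degrees on the unit circle) and a crescent (lower arc
#' sweeping 140 degrees, offset center), interlocking so that neither is
#' linearly separable from the other, plus isotropic Gaussian noise.
#'
#' @param nPerMoon points per moon (default 1000, N = 2000).
#' @param noise Gaussian noise standard deviation (default 0.05).
#' @param seed RNG seed.
#' @return A \linkS4class{PointCloud} with 2-D coordinates and planted
#'   labels 1 (gibbous) and 2 (crescent).
#' @examples
#' twoMoons(nPerMoon = 50, seed = 1)
#' @export
twoMoons <- function(nPerMoon = 1000, noise = 0.05, seed = 1) {
  stopifnot(nPerMoon >= 10, noise >= 0)
  deg <- pi / 180
  co <- .withSeed(seed, function() {
    a1 <- stats::runif(nPerMoon, -10 * deg, 190 * deg)
    a2 <- stats::runif(nPerMoon, 200 * deg, 340 * deg)
    xy <- rbind(cbind(cos(a1), sin(a1)),
                cbind(1 + cos(a2), 0.5 + sin(a2)))
    xy + matrix(stats::rnorm(4 * nPerMoon, 0, noise), ncol = 2)
  })
  new("PointCloud", coordinates = co,
      trueLabels = rep(1:2, each = as.integer(nPerMoon)),
      params = list(nPerMoon = nPerMoon, noise = noise, seed = seed))
}

#' Planted-block similarity matrix
#'
#' Similarity \code{sIn} within planted blocks and \code{sOut} across, with
#' optional uniform jitter, symmetrized and clipped to \[1e-12, 1\] so no
#' node is ever fully disconnected.
#'
#' @param sizes integer block sizes.
#' @param sIn within-block similarity (> \code{sOut}).
#' @param sOut cross-block similarity (>= 0).
#' @param jitter half-width of uniform noise (requires
#'   \code{sIn + jitter <= 1}).
#' @param seed RNG seed.
#' @return A list with \code{S} (a \linkS4class{SimilarityMatrix}) and
#'   \code{trueLabels} (integer block ids).
#' @examples
#' blockSimilarity(c(5, 5), 0.9, 0.01, seed = 1)
#' @export
blockSimilarity <- function(sizes, sIn = 0.9, sOut = 0.01, jitter = 0,
                            seed = 1) {
  stopifnot(all(sizes >= 1), sIn > sOut, sOut >= 0, jitter >= 0,
            sIn + jitter <= 1)
  lab <- rep(seq_along(sizes), times = sizes)
  n <- length(lab)
  S <- matrix(sOut, n, n)
  S[outer(lab, lab, "==")] <- sIn
  if (jitter > 0) {
    J <- .withSeed(seed, function()
      matrix(stats::runif(n * n, -jitter, jitter), n, n))
    J[lower.tri(J)] <- t(J)[lower.tri(J)]
    S <- S + J
  }
  S <- pmin(pmax(S, 1e-12), 1)
  S <- (S + t(S)) / 2
  diag(S) <- 0
  list(S = SimilarityMatrix(S), trueLabels = lab)
}

#' Similarity matrix of a point cloud
#'
#' Euclidean distances of the cloud passed through
#' \code{\link{asSimilarity}}.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param scale passed to \code{\link{asSimilarity}} (default "auto").
#' @return A \linkS4class{SimilarityMatrix}.
#' @export
cloudSimilarity <- function(cloud, scale = "auto") {
  stopifnot(is(cloud, "PointCloud"))
  D <- as.matrix(stats::dist(cloud@coordinates))
  asSimilarity(D, scale = scale)
}

#' Rand index and adjusted Rand index
#'
#' The Rand index is the fraction of node pairs on which two partitions
#' agree (both co-clustered or both separated); the adjusted variant
#' corrects for chance agreement.
#'
#' @param a,b equal-length label vectors.
#' @return A score: Rand in \[0, 1\]; adjusted Rand <= 1 with 0 expected
#'   under random labellings.
#' @examples
#' randIndex(c(1, 1, 2), c(1, 1, 2))      # 1
#' adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' @export
randIndex <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least two items")
  tab <- table(a, b)
  sumnij <- sum(choose(tab, 2))
  sumai <- sum(choose(rowSums(tab), 2))
  sumbj <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sumnij - sumai - sumbj) / total
}

#' @rdname randIndex
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least two items")
  tab <- table(a, b)
  sumnij <- sum(choose(tab, 2))
  sumai <- sum(choose(rowSums(tab), 2))
  sumbj <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- sumai * sumbj / total
  maxidx <- (sumai + sumbj) / 2
  if (maxidx == expected) return(1)
  (sumnij - expected) / (maxidx - expected)
}
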