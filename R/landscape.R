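#' Construct a SimilarityMatrix
#'
#' Wraps a symmetric matrix of normalized similarities in \[0, 1\] as a
#' \linkS4class{SimilarityMatrix}.  The diagonal is forced to 0: the walks
#' take no self-transitions, so self-similarity carries no information.
#'
#' @param S square symmetric numeric matrix with off-diagonal entries in
#'   \[0, 1\].
#' @param labels optional character node labels; defaults to the dimnames of
#'   \code{S} or \code{"n1" ... "nN"}.
#' @return A \linkS4class{SimilarityMatrix}.
#' @examples
#' S <- matrix(0.5, 3, 3); diag(S) <- 0
#' SimilarityMatrix(S)
#' @export
SimilarityMatrix <- function(S, labels = NULL) {
  if (!is.matrix(S) || !is.numeric(S))
    stop("S must be a numeric matrix")
  if (is.null(labels)) {
    labels <- rownames(S)
    if (is.null(labels)) labels <- paste0("n", seq_len(nrow(S)))
  }
  diag(S) <- 0
  dimnames(S) <- NULL
  new("SimilarityMatrix", S = S, labels = as.character(labels))
}

#' Transform a distance matrix into a similarity matrix
#'
#' Applies the bounded monotone transform S_ij = exp(-D_ij / scale).  With
#' \code{scale = "auto"} the scale is the median off-diagonal distance, which
#' makes the link energies -log(S) dimensionless with median 1.
#'
#' @param D square symmetric non-negative distance matrix with zero diagonal.
#' @param scale positive scalar, or \code{"auto"} (median off-diagonal
#'   distance).
#' @param labels optional node labels, as in \code{\link{SimilarityMatrix}}.
#' @return A \linkS4class{SimilarityMatrix} with entries in (0, 1\].
#' @examples
#' D <- as.matrix(dist(c(0, 1, 3)))
#' asSimilarity(D, scale = 1)
#' @export
asSimilarity <- function(D, scale = "auto", labels = NULL) {
  if (!is.matrix(D) || !is.numeric(D)) stop("D must be a numeric matrix")
  if (nrow(D) != ncol(D)) stop("D must be square")
  if (max(abs(D - t(D))) > 1e-9) stop("D must be symmetric")
  if (any(D < 0)) stop("D must be non-negative")
  off <- D[row(D) != col(D)]
  if (identical(scale, "auto")) {
    scale <- stats::median(off)
    if (!is.finite(scale) || scale <= 0)
      stop("cannot auto-scale: all off-diagonal distances are zero")
  }
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    stop("scale must be a positive scalar or \"auto\"")
  S <- exp(-D / scale)
  if (is.null(labels)) labels <- rownames(D)
  SimilarityMatrix(S, labels = labels)
}

#' Temperature-regulated link weights
#'
#' Turns similarities into Boltzmann weights W_ij(T) = S_ij^(1/T) =
#' exp(-E_ij / T) with link energy E_ij = -log(S_ij).  Large T flattens the
#' potential landscape (all positive weights approach 1); small T deepens the
#' wells by amplifying the contrast between strong and weak links.  The
#' ordering of the entries of S is preserved at every temperature.
#'
#' @param S a \linkS4class{SimilarityMatrix}.
#' @param temperature positive scalar temperature.
#' @return Numeric matrix W(T) with zero diagonal.
#' @examples
#' S <- SimilarityMatrix(matrix(c(0, .25, .25, 0), 2))
#' temperatureWeights(S, 2)   # off-diagonal 0.5
#' @export
temperatureWeights <- function(S, temperature) {
  stopifnot(is(S, "SimilarityMatrix"))
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a positive scalar")
  W <- S@S^(1 / temperature)
  diag(W) <- 0
  W
}

#' Row-normalize a weight matrix into a Markov transition matrix
#'
#' P = Delta^-1 W where Delta is the diagonal matrix of row-sums (the degree
#' matrix).  Nodes with zero row-sum are isolated: they take no transitions,
#' are excluded from the walk, and end up as singleton clusters; their rows
#' are returned as all zero.
#'
#' @param W non-negative symmetric matrix with zero diagonal.
#' @return A list with elements \code{P} (row-stochastic over active rows)
#'   and \code{active} (logical vector, FALSE for isolated nodes).
#' @examples
#' transitionMatrix(matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3))$P
#' @export
transitionMatrix <- function(W) {
  if (!is.matrix(W) || !is.numeric(W)) stop("W must be a numeric matrix")
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (any(W < 0)) stop("W must be non-negative")
  if (max(abs(W - t(W))) > 1e-9) stop("W must be symmetric")
  diag(W) <- 0
  deg <- rowSums(W)
  active <- deg > 0
  P <- W
  P[active, ] <- W[active, , drop = FALSE] / deg[active]
  P[!active, ] <- 0
  list(P = P, active = active)
}

# Link energies -log S over informative off-diagonal pairs (0 < S < 1).
# Used to anchor the default temperature grid.
.medianLinkEnergy <- function(S) {
  stopifnot(is(S, "SimilarityMatrix"))
  s <- S@S[row(S@S) != col(S@S)]
  s <- s[s > 0 & s < 1]
  if (!length(s)) return(1)
  e <- stats::median(-log(s))
  if (!is.finite(e) || e <= 0) 1 else e
}
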