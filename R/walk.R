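#' Run one regulated random walk
#'
#' Simulates the re-engineered MCMC on the temperature-regulated landscape
#' W(T): from a uniformly random start, the chain steps according to the
#' row-normalized weights; every arrival increments the current node's visit
#' count; when a count reaches the visit cap m, the node is removed (its
#' removal and the number of arrivals since the previous removal are
#' recorded), the transition matrix is renormalized over the remaining
#' nodes, and the chain continues with one Markov step from the removed
#' node's row.  A chain stranded with no positive-weight neighbor restarts
#' uniformly among the remaining nodes.  The walk terminates when a single
#' node remains; that node closes the record with the arrivals since the
#' prior removal (minimum 1).
#'
#' Low temperatures can drive cross-well weights below double precision;
#' the resulting disconnections are handled by the restart rule, so the walk
#' always terminates (total arrivals are bounded by N * m).
#'
#' @param S a \linkS4class{SimilarityMatrix}.
#' @param temperature positive temperature regulating the landscape.
#' @param m visit cap (default 5): larger m explores each well more
#'   thoroughly at higher total cost.
#' @param seed integer seed; walks are bit-reproducible given
#'   (S, temperature, m, seed).
#' @return A \linkS4class{WalkRecord}.
#' @examples
#' S <- blockSimilarity(c(5, 5), 0.9, 0.01, seed = 1)$S
#' runRegulatedWalk(S, temperature = 0.5, m = 3, seed = 7)
#' @export
runRegulatedWalk <- function(S, temperature, m = 5, seed = 1) {
  stopifnot(is(S, "SimilarityMatrix"))
  W <- temperatureWeights(S, temperature)
  res <- .regulated_walk_cpp(W, as.integer(m), as.integer(seed))
  new("WalkRecord",
      removalOrder = as.integer(res$removal_order),
      recurrenceTimes = as.integer(res$recurrence_times),
      visitCap = as.integer(m), seed = as.integer(seed),
      nNodes = nrow(W), isolated = as.integer(res$isolated),
      restarts = as.integer(res$restarts))
}

#' Detect recurrence-time spikes
#'
#' A spike marks the walk's entry into a fresh potential well: the removal
#' cadence there is slow because visit counts start from zero.  Position t
#' (1-based) is a spike iff recurrence_times\[t\] exceeds \code{c} times the
#' running baseline, the median of all earlier recurrence times.  The first
#' position is never a spike (no baseline exists yet).
#'
#' @param recurrenceTimes positive integer vector, or a
#'   \linkS4class{WalkRecord}.
#' @param c spike factor (> 1, default 5); the running-median baseline makes
#'   the rule robust to the heavy-tailed intra-well recurrence distribution.
#' @return Strictly increasing integer positions (possibly empty).
#' @examples
#' detectSpikes(c(2, 2, 2, 40, 2, 2), c = 5)  # 4
#' @export
detectSpikes <- function(recurrenceTimes, c = 5) {
  if (is(recurrenceTimes, "WalkRecord"))
    recurrenceTimes <- recurrenceTimes@recurrenceTimes
  if (!length(recurrenceTimes) || any(recurrenceTimes < 1))
    stop("recurrenceTimes must be a non-empty positive sequence")
  if (!is.numeric(c) || c <= 1) stop("spike factor c must be > 1")
  n <- length(recurrenceTimes)
  if (n == 1) return(integer(0))
  spikes <- logical(n)
  for (t in 2:n) {
    baseline <- stats::median(recurrenceTimes[seq_len(t - 1)])
    spikes[t] <- recurrenceTimes[t] > c * baseline
  }
  which(spikes)
}

#' Co-well indicator matrix from one walk
#'
#' Cuts the removal order at each spike (the spike node starts a new
#' segment, having been reached after the long excursion) and marks node
#' pairs that fall in the same inter-spike segment as sharing a potential
#' well.  Isolated nodes excluded from the walk each form their own
#' segment.
#'
#' @param record a \linkS4class{WalkRecord}.
#' @param spikes strictly increasing spike positions within the removal
#'   order, as returned by \code{\link{detectSpikes}}.
#' @return A \linkS4class{CoWellMatrix} over all N nodes.
#' @examples
#' rec <- new("WalkRecord", removalOrder = 1:4,
#'            recurrenceTimes = c(5L, 1L, 30L, 1L), visitCap = 1L,
#'            seed = 1L, nNodes = 4L, isolated = integer(0), restarts = 0L)
#' cowellMatrix(rec, detectSpikes(rec))
#' @export
cowellMatrix <- function(record, spikes = integer(0)) {
  stopifnot(is(record, "WalkRecord"))
  ord <- record@removalOrder
  nOrd <- length(ord)
  spikes <- as.integer(spikes)
  if (length(spikes)) {
    if (is.unsorted(spikes, strictly = TRUE) ||
        any(spikes < 1) || any(spikes > nOrd))
      stop("spikes must be strictly increasing positions in the removal order")
  }
  seg <- cumsum(seq_len(nOrd) %in% spikes) + 1L
  segIds <- integer(record@nNodes)
  segIds[ord] <- seg
  nseg <- if (nOrd) max(seg) else 0L
  if (length(record@isolated))
    segIds[record@isolated] <- nseg + seq_along(record@isolated)
  B <- 1 * outer(segIds, segIds, "==")
  new("CoWellMatrix", B = B, segmentIds = segIds)
}
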