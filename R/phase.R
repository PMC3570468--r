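#' Default temperature grid for the phase scan
#'
#' A geometric grid of \code{n} points spanning \[0.05, 5\] times the median
#' link energy of the similarity matrix (the median of -log S over
#' informative pairs).  With the auto-scaled distance transform the median
#' link energy is 1, so the grid spans \[0.05, 5\] directly.
#'
#' @param S a \linkS4class{SimilarityMatrix}.
#' @param n number of grid points (default 24).
#' @param lo,hi grid range as multiples of the median link energy.
#' @return Strictly increasing numeric vector of temperatures.
#' @export
defaultTemperatureGrid <- function(S, n = 24, lo = 0.05, hi = 5) {
  e <- .medianLinkEnergy(S)
  exp(seq(log(lo * e), log(hi * e), length.out = n))
}

#' Scan the temperature axis for phase transitions of the cluster count
#'
#' For each grid temperature T: build the regulated landscape W(T), run an
#' ensemble of E regulated walks, aggregate the cluster-sharing probability
#' matrix, count clusters via the eigenvalue floor, and extract
#' memberships.  Two automatic grid adjustments follow the base scan:
#' \itemize{
#'   \item if the cluster count at the top of the grid exceeds the number
#'     attainable by merging (1, plus any isolated nodes), the grid is
#'     extended geometrically (factor 2, at most \code{maxExtend} times);
#'   \item plateaus of the cluster-count curve shorter than
#'     \code{plateauMin} grid points are refined: midpoint temperatures are
#'     inserted at their boundaries (up to \code{refineRounds} rounds), so
#'     a genuine phase crossed between two coarse grid points gains support
#'     while a one-point fluctuation stays short and is later discarded.  A
#'     geometric grid of g points over a temperature range of ratio R
#'     resolves only phases spanning a factor R^((plateauMin)/(g-1)); the
#'     refinement removes that resolution floor where it matters.
#' }
#'
#' Per-evaluation seeds are derived deterministically from the master seed
#' in evaluation order, so the scan is reproducible end to end.
#'
#' @param S a \linkS4class{SimilarityMatrix}.
#' @param grid strictly increasing positive temperatures; default
#'   \code{defaultTemperatureGrid(S)}.
#' @param nWalks ensemble size E per temperature (default 50).
#' @param m visit cap per walk (default 5).
#' @param spikeFactor recurrence-time spike factor (default 5).
#' @param eigenFloor relative eigenvalue floor for cluster counting.
#' @param seed master seed.
#' @param maxExtend maximum number of geometric grid extensions (default 10).
#' @param plateauMin minimum plateau length (in grid points) a level must
#'   reach; shorter plateaus trigger refinement here and are dropped by
#'   \code{\link{criticalTemperatures}}.
#' @param refineRounds rounds of plateau-boundary refinement (default 3; 0
#'   disables refinement).
#' @return A \linkS4class{LevelScan} (critical levels not yet selected; see
#'   \code{\link{criticalTemperatures}}).
#' @export
scanTemperatures <- function(S, grid = NULL, nWalks = 50, m = 5,
                             spikeFactor = 5, eigenFloor = 0.05, seed = 1,
                             maxExtend = 10, plateauMin = 2,
                             refineRounds = 3) {
  stopifnot(is(S, "SimilarityMatrix"))
  if (is.null(grid)) grid <- defaultTemperatureGrid(S)
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing and positive")
  # isolated nodes can never merge with the rest; the reachable floor for K
  nIso <- sum(rowSums(S@S) - diag(S@S) == 0)
  kFloor <- 1L + nIso

  evalCount <- 0L
  evalT <- function(temperature) {
    evalCount <<- evalCount + 1L
    ts <- .deriveSeed(seed, evalCount * 1009L)
    Phat <- .sharingAtTemperature(S, temperature, nWalks = nWalks, m = m,
                                  spikeFactor = spikeFactor, seed = ts)
    K <- countClusters(Phat, floor = eigenFloor)
    cfg <- extractMembership(Phat, K, seed = .deriveSeed(ts, 999L))
    cfg@temperature <- temperature
    list(config = cfg, Phat = Phat@Phat)
  }

  evals <- lapply(grid, evalT)
  getK <- function(ev) vapply(ev, function(x) x$config@K, integer(1))

  # upward extension until the cluster count can merge no further
  ext <- 0
  while (evals[[length(evals)]]$config@K > kFloor && ext < maxExtend) {
    ext <- ext + 1
    grid <- c(grid, grid[length(grid)] * 2)
    evals[[length(grid)]] <- evalT(grid[length(grid)])
  }
  if (evals[[length(evals)]]$config@K > kFloor)
    stop("cluster count never reached ", kFloor,
         " even after extending the grid to T = ", max(grid),
         "; the graph may be disconnected beyond its isolated nodes")

  # refinement of sub-minimum plateaus at their boundaries
  for (round in seq_len(refineRounds)) {
    K <- getK(evals)
    runs <- rle(K)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    short <- which(runs$lengths < plateauMin)
    short <- short[short < length(runs$lengths)]  # final (top) run is kept
    if (!length(short)) break
    newT <- numeric(0)
    for (j in short) {
      s <- starts[j]; e <- ends[j]
      if (s > 1 && grid[s] / grid[s - 1] > 1.02)
        newT <- c(newT, sqrt(grid[s - 1] * grid[s]))
      if (e < length(grid) && grid[e + 1] / grid[e] > 1.02)
        newT <- c(newT, sqrt(grid[e] * grid[e + 1]))
    }
    newT <- setdiff(sort(unique(newT)), grid)
    if (!length(newT)) break
    newEvals <- lapply(newT, evalT)
    grid <- c(grid, newT)
    ord <- order(grid)
    grid <- grid[ord]
    evals <- c(evals, newEvals)[ord]
  }

  new("LevelScan",
      temperatures = grid,
      KofT = getK(evals),
      configs = lapply(evals, `[[`, "config"),
      criticalTemps = numeric(0), criticalConfigs = list(),
      params = list(nWalks = nWalks, m = m, spikeFactor = spikeFactor,
                    eigenFloor = eigenFloor, seed = seed,
                    plateauMin = plateauMin,
                    sharing = lapply(evals, `[[`, "Phat")))
}

#' Select critical temperatures from a scan
#'
#' Partitions the temperature grid into maximal runs of constant cluster
#' count (plateaus).  Plateaus of length >= \code{plateauMin} are kept as
#' major levels, plus the K = 1 plateau regardless of length.  The
#' representative temperature of a plateau is its largest grid point — the
#' barrier top just before the next merge, the natural energy-barrier
#' height for the ultrametric.  The representative configuration is
#' extracted from the plateau-pooled sharing matrix (the element-wise mean
#' over the plateau's grid points), which uses the walk ensembles of the
#' whole phase rather than a single — possibly transitional — temperature.
#' Working down from the top, levels are de-duplicated so K strictly
#' decreases as T increases.
#'
#' @param scan a \linkS4class{LevelScan} from \code{\link{scanTemperatures}}.
#' @param plateauMin minimum plateau length in grid points (default, the
#'   value used by the scan), suppressing single-point fluctuations of the
#'   cluster count.
#' @return The scan with \code{criticalTemps} and \code{criticalConfigs}
#'   filled in.
#' @export
criticalTemperatures <- function(scan, plateauMin = NULL) {
  stopifnot(is(scan, "LevelScan"))
  if (is.null(plateauMin))
    plateauMin <- if (!is.null(scan@params$plateauMin))
      scan@params$plateauMin else 2
  K <- scan@KofT
  nG <- length(K)
  if (K[nG] != min(K))
    stop("scan must reach its minimum cluster count at the top temperature")
  runs <- rle(K)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$lengths >= plateauMin | runs$values == K[nG]
  repEnd <- ends[keep]
  repStart <- starts[keep]
  repK <- runs$values[keep]
  # top-down de-duplication: enforce strictly decreasing K with increasing T
  sel <- integer(0)
  lastK <- 0L
  for (j in rev(seq_along(repEnd))) {
    if (repK[j] > lastK) {
      sel <- c(j, sel)
      lastK <- repK[j]
    }
  }
  sharing <- scan@params$sharing
  seed <- if (!is.null(scan@params$seed)) scan@params$seed else 1
  cfgs <- vector("list", length(sel))
  for (i in seq_along(sel)) {
    j <- sel[i]
    idx <- repStart[j]:repEnd[j]
    temperature <- scan@temperatures[repEnd[j]]
    if (!is.null(sharing)) {
      pooled <- Reduce(`+`, sharing[idx]) / length(idx)
      cfg <- extractMembership(pooled, repK[j],
                               seed = .deriveSeed(seed, 7919L + j))
      cfg@temperature <- temperature
    } else {
      cfg <- scan@configs[[repStart[j]]]
      cfg@temperature <- temperature
    }
    cfgs[[i]] <- cfg
  }
  scan@criticalTemps <- scan@temperatures[repEnd[sel]]
  scan@criticalConfigs <- cfgs
  scan
}

#' Number of major levels of a completed scan
#'
#' Convenience count of the selected critical levels below the final
#' single-cluster merge.
#'
#' @param scan a \linkS4class{LevelScan} with critical levels selected.
#' @return Integer count of levels with K > 1.
#' @export
nMajorLevels <- function(scan) {
  stopifnot(is(scan, "LevelScan"), length(scan@criticalTemps) > 0)
  sum(vapply(scan@criticalConfigs, function(cc) cc@K, integer(1)) > 1L)
}
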