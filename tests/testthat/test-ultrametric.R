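cfg <- function(labels, temperature = 1) {
  labels <- as.integer(labels)
  new("ClusterConfiguration", temperature = temperature,
      K = length(unique(labels)), labels = labels)
}

test_that("status sequences indicate co-clustering per level", {
  configs <- list(cfg(c(1, 1, 2, 3)), cfg(c(1, 1, 1, 2)), cfg(c(1, 1, 1, 1)))
  delta <- statusSequences(configs)
  expect_equal(dim(delta), c(4, 4, 3))
  expect_equal(delta[1, 2, ], c(1, 1, 1))   # together everywhere
  expect_equal(delta[3, 4, ], c(0, 0, 1))   # only at the top
  expect_equal(delta[1, 3, ], c(0, 1, 1))
  expect_true(all(delta[, , 3] == 1))
  expect_error(statusSequences(list(cfg(c(1, 2)))), "K = 1")
})

test_that("last 0-to-1 switch sets the barrier height, with closure", {
  temps <- c(1, 2, 3)
  # a 3-level, 3-node system exercising the plain cases
  configs <- list(cfg(c(1, 1, 2)), cfg(c(1, 2, 2)), cfg(c(1, 1, 1)))
  delta <- statusSequences(configs)
  U <- ultrametricFromStatus(delta, temps)
  # pair (1,2): delta (1,0,1) -> last switch at level 3
  expect_equal(U[1, 2], 3)
  # pair (2,3): delta (0,1,1) -> switch at level 2, but the closure may
  # shorten nothing here
  expect_equal(U[2, 3], 2)
  expect_true(oracle_ultrametric_ok(U))

  # never-separated pairs sit at the bottom temperature
  configs2 <- list(cfg(c(1, 1)), cfg(c(1, 1)))
  U2 <- ultrametricFromStatus(statusSequences(configs2), c(0.5, 2))
  expect_equal(U2[1, 2], 0.5)
})

test_that("non-nested levels still yield a true ultrametric", {
  temps <- c(1, 2, 3, 4)
  # 4 nodes with deliberately non-nested intermediate configurations;
  # the multiple-switch pairs are revised to the last 0-to-1 switch
  configs <- list(cfg(c(1, 1, 2, 2)), cfg(c(1, 2, 2, 1)),
                  cfg(c(1, 1, 2, 2)), cfg(c(1, 1, 1, 1)))
  delta <- statusSequences(configs)
  k <- length(temps)
  # raw last-switch heights, computed independently pair by pair
  raw <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    d <- delta[i, j, ]
    sw <- which(d[-1] == 1 & d[-k] == 0) + 1
    raw[i, j] <- raw[j, i] <- if (length(sw)) temps[max(sw)] else temps[1]
  }
  expect_equal(raw[1, 2], 3)   # delta (1,0,1,1): revised upward to level 3
  expect_equal(raw[1, 4], 4)   # delta (0,1,0,1): revised to the top
  U <- ultrametricFromStatus(delta, temps)
  expect_true(oracle_ultrametric_ok(U))
  expect_equal(U, oracle_minimax(raw))      # exhaustive path enumeration
  # level partitions are transitive within each level, which makes the raw
  # last-switch heights already ultrametric; the closure changes nothing
  expect_equal(U, raw)

  # an arbitrary (non-partition) status array CAN violate the strong
  # triangle inequality; the minimax closure repairs exactly that
  d2 <- array(1L, dim = c(3, 3, 2))
  d2[1, 3, 1] <- d2[3, 1, 1] <- 0L   # co-sharing 1~2, 2~3 but not 1~3
  U2 <- ultrametricFromStatus(d2, c(1, 5))
  raw2 <- matrix(c(0, 1, 5, 1, 0, 1, 5, 1, 0), 3)
  expect_false(oracle_ultrametric_ok(raw2))
  expect_equal(U2, oracle_minimax(raw2))
  expect_equal(U2[1, 3], 1)          # repaired through the 1-2-3 path
  expect_true(oracle_ultrametric_ok(U2))

  # nested configurations pass through the closure unchanged
  nested <- list(cfg(c(1, 2, 3, 4)), cfg(c(1, 1, 2, 2)), cfg(c(1, 1, 1, 1)))
  dn <- statusSequences(nested)
  raw_n <- matrix(3, 4, 4)
  raw_n[1, 2] <- raw_n[2, 1] <- 2
  raw_n[3, 4] <- raw_n[4, 3] <- 2
  diag(raw_n) <- 0
  expect_equal(ultrametricFromStatus(dn, 1:3), raw_n)
})

test_that("trees reproduce the ultrametric exactly", {
  U2 <- matrix(c(0, 2, 2, 0), 2)
  tr <- buildTree(U2, 2, labels = c("a", "b"))
  expect_equal(length(levelTemps(tr)), 1)
  expect_equal(ultrametric(tr)["a", "b"], 2)

  # 2 + 2 block pattern with two heights
  U <- matrix(2, 4, 4)
  U[1, 2] <- U[2, 1] <- U[3, 4] <- U[4, 3] <- 1
  diag(U) <- 0
  tr <- buildTree(U, c(1, 2))
  expect_equal(levelPartitions(tr)[[1]], c(1L, 1L, 2L, 2L))
  expect_equal(length(unique(levelPartitions(tr)[[2]])), 1)
  expect_equal(oracle_cophenetic(tr), unname(ultrametric(tr)))

  # a non-ultrametric matrix is rejected
  bad <- matrix(c(0, 1, 5, 1, 0, 1, 5, 1, 0), 3)
  expect_error(buildTree(bad, c(1, 5)), "triangle")
})

test_that("newick export round-trips through ape with exact cophenetics", {
  skip_if_not_installed("ape")
  U <- matrix(2, 4, 4)
  U[1, 2] <- U[2, 1] <- U[3, 4] <- U[4, 3] <- 1
  diag(U) <- 0
  tr <- buildTree(U, c(1, 2), labels = letters[1:4])
  nwk <- toNewick(tr)
  expect_match(nwk, ";$")
  ph <- ape::read.tree(text = nwk)
  co <- ape::cophenetic.phylo(ph)[letters[1:4], letters[1:4]]
  expect_equal(unname(co), 2 * unname(ultrametric(tr)), tolerance = 1e-9)

  # two leaves at height 2: both branches have length 2
  tr2 <- buildTree(matrix(c(0, 2, 2, 0), 2), 2, labels = c("a", "b"))
  ph2 <- ape::read.tree(text = toNewick(tr2))
  expect_equal(sort(ph2$tip.label), c("a", "b"))
  expect_equal(unname(ph2$edge.length), c(2, 2))

  # root height equals the top level temperature on a planted instance
  bl <- blockSimilarity(c(6, 5, 4), 0.9, 0.05, jitter = 0.02, seed = 3)
  fit <- dcgTree(bl$S, nWalks = 20, seed = 2)
  ph3 <- ape::read.tree(text = toNewick(fit$tree))
  co3 <- ape::cophenetic.phylo(ph3)
  labs <- nodeLabels(fit$tree)
  expect_equal(unname(co3[labs, labs]), 2 * fit$tree@U, tolerance = 1e-9)
})

test_that("the Parisi ordering renders every ball contiguous", {
  # deterministic 2+2 example
  U <- matrix(2, 4, 4)
  U[1, 2] <- U[2, 1] <- U[3, 4] <- U[4, 3] <- 1
  diag(U) <- 0
  tr <- buildTree(U, c(1, 2))
  pm <- parisiMatrix(tr)
  expect_true(parisi_contiguous(tr, pm))
  expect_identical(unname(pm@M), U[pm@order, pm@order])
  expect_true(all(diag(pm@M) == 0))

  # single cluster at every level: constant off-diagonal
  U1 <- matrix(1, 3, 3); diag(U1) <- 0
  pm1 <- parisiMatrix(buildTree(U1, 1))
  expect_true(all(pm1@M[row(pm1@M) != col(pm1@M)] == 1))

  # random planted instances
  for (s in 1:20) {
    set.seed(s)
    sizes <- sample(2:5, sample(2:4, 1), replace = TRUE)
    bl <- blockSimilarity(sizes, 0.9, 0.02, jitter = 0.05, seed = s)
    # build nested partitions directly from the planted labels plus a
    # random coarsening, then check contiguity of the resulting tree
    lab <- bl$trueLabels
    coarse <- sample(1:2, length(unique(lab)), replace = TRUE)[lab]
    configs <- list(cfg(lab), cfg(as.integer(factor(coarse))),
                    cfg(rep(1, length(lab))))
    if (configs[[2]]@K == 1) configs <- configs[-2]
    temps <- seq_along(configs)
    U <- ultrametricFromStatus(statusSequences(configs), temps)
    tr <- buildTree(U, temps)
    expect_true(parisi_contiguous(tr, parisiMatrix(tr)))
  }
})
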