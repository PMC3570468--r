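fake_config <- function(K, n = 6, temperature = 1) {
  labels <- rep_len(seq_len(K), n)
  new("ClusterConfiguration", temperature = temperature, K = as.integer(K),
      labels = sort(labels))
}

test_that("plateau selection follows the constant-run rule", {
  temps <- 1:7
  K <- c(5L, 5L, 3L, 3L, 3L, 1L, 1L)
  scan <- new("LevelScan", temperatures = as.numeric(temps), KofT = K,
              configs = lapply(K, fake_config),
              criticalTemps = numeric(0), criticalConfigs = list(),
              params = list())
  out <- criticalTemperatures(scan, plateauMin = 2)
  expect_equal(criticalTemps(out), c(2, 5, 7))
  expect_equal(vapply(out@criticalConfigs, nClusters, integer(1)),
               c(5L, 3L, 1L))

  # all-ones cluster count collapses to a single level
  scan1 <- new("LevelScan", temperatures = c(1, 2, 3),
               KofT = rep(1L, 3), configs = lapply(c(1, 1, 1), fake_config),
               criticalTemps = numeric(0), criticalConfigs = list(),
               params = list())
  out1 <- criticalTemperatures(scan1)
  expect_equal(criticalTemps(out1), 3)
  expect_equal(nMajorLevels(out1), 0)

  # single-point plateaus between kept levels are dropped, and duplicated K
  # values keep only the hottest occurrence
  K2 <- c(6L, 6L, 4L, 3L, 3L, 3L, 1L)
  scan2 <- new("LevelScan", temperatures = as.numeric(1:7), KofT = K2,
               configs = lapply(K2, fake_config),
               criticalTemps = numeric(0), criticalConfigs = list(),
               params = list())
  out2 <- criticalTemperatures(scan2, plateauMin = 2)
  expect_equal(vapply(out2@criticalConfigs, nClusters, integer(1)),
               c(6L, 3L, 1L))
})

test_that("two near-isolated cliques merge only at high temperature", {
  bl <- blockSimilarity(c(6, 6), 0.9, 1e-12, seed = 2)
  scan <- scanTemperatures(bl$S, nWalks = 25, seed = 3)
  expect_identical(scan@KofT[1], 2L)
  expect_identical(scan@KofT[length(scan@KofT)], 1L)
  out <- criticalTemperatures(scan)
  Ks <- vapply(out@criticalConfigs, nClusters, integer(1))
  expect_true(all(diff(Ks) < 0))
  expect_true(all(diff(criticalTemps(out)) > 0))
  expect_identical(Ks[length(Ks)], 1L)
  # bottom level recovers the planted blocks exactly
  expect_equal(adjustedRandIndex(clusterLabels(out@criticalConfigs[[1]]),
                                 bl$trueLabels), 1)
})

test_that("a connected pair always reaches one cluster at the grid top", {
  S <- SimilarityMatrix(matrix(c(0, 0.6, 0.6, 0), 2))
  scan <- scanTemperatures(S, nWalks = 10, seed = 1)
  expect_identical(scan@KofT[length(scan@KofT)], 1L)
})

test_that("scans are reproducible end to end under a master seed", {
  bl <- blockSimilarity(c(5, 5, 5), 0.85, 0.02, jitter = 0.05, seed = 8)
  s1 <- scanTemperatures(bl$S, nWalks = 15, seed = 21)
  s2 <- scanTemperatures(bl$S, nWalks = 15, seed = 21)
  expect_identical(s1@KofT, s2@KofT)
  expect_identical(s1@temperatures, s2@temperatures)
  expect_identical(lapply(s1@configs, clusterLabels),
                   lapply(s2@configs, clusterLabels))
  s3 <- scanTemperatures(bl$S, nWalks = 15, seed = 22)
  expect_false(identical(lapply(s1@configs, clusterLabels),
                         lapply(s3@configs, clusterLabels)))
})

test_that("the grid extends upward until the merge completes", {
  # a grid whose top temperature is far too cold to merge the blocks
  bl <- blockSimilarity(c(6, 6), 0.9, 0.01, seed = 5)
  grid <- exp(seq(log(0.1), log(0.3), length.out = 4))
  scan <- scanTemperatures(bl$S, grid = grid, nWalks = 20, seed = 4)
  expect_gt(max(scan@temperatures), 0.3)
  expect_identical(scan@KofT[length(scan@KofT)], 1L)
})
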