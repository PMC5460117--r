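test_that("scheduled pairs realize their programmed persistence exactly", {
  sched <- contactSchedule("pairs", nNodes = 4, nFrames = 10,
                           pairs = data.frame(i = c(1, 3), j = c(2, 4),
                                              k = c(3, 7)),
                           dIn = 4, dOut = 12)
  ens <- generateScheduleEnsemble(sched)
  expect_equal(nFrames(ens), 10L)
  pm <- computePersistence(computeComSeries(ens, selectSideChains(ens)), 5)
  v <- persistenceValues(pm)
  expect_identical(v[1, 2], 0.3)
  expect_identical(v[3, 4], 0.7)
  expect_true(all(v[cbind(c(1, 1, 2, 2), c(3, 4, 3, 4))] == 0))
})

test_that("an all-zero schedule yields an edgeless network at any positive p_crit", {
  sched <- contactSchedule("pairs", nNodes = 6, nFrames = 8,
                           pairs = data.frame(i = c(1, 3, 5),
                                              j = c(2, 4, 6), k = 0),
                           dIn = 4, dOut = 12)
  ens <- generateScheduleEnsemble(sched)
  g <- buildGraph(computePersistence(
    computeComSeries(ens, selectSideChains(ens)), 5), pCrit = 1)
  expect_equal(nrow(edges(g)), 0L)
})

test_that("a four-leaf star produces exactly one hub of degree four", {
  sched <- contactSchedule("star", nNodes = 5, nFrames = 10,
                           pairs = data.frame(i = 1, j = 2:5, k = 10),
                           dIn = 4, dOut = 6.5)
  ens <- generateScheduleEnsemble(sched)
  g <- buildGraph(computePersistence(
    computeComSeries(ens, selectSideChains(ens)), 5), pCrit = 20)
  ht <- findHubs(g)
  expect_equal(nrow(hubs(ht)), 1L)
  expect_equal(hubs(ht)$degree, 4L)
  expect_equal(hubs(ht)$resid, 1L)
})

test_that("chain schedules place only consecutive contacts", {
  sched <- contactSchedule("chain", nNodes = 4, nFrames = 10,
                           pairs = data.frame(i = 1:3, j = 2:4,
                                              k = c(10, 5, 0)),
                           dIn = 4, dOut = 7)
  ens <- generateScheduleEnsemble(sched)
  pm <- computePersistence(computeComSeries(ens, selectSideChains(ens)), 5)
  v <- persistenceValues(pm)
  expect_identical(v[1, 2], 1)
  expect_identical(v[2, 3], 0.5)
  expect_identical(v[3, 4], 0)
  expect_identical(v[1, 3], 0)
  expect_identical(v[1, 4], 0)
})

test_that("unrealizable schedules are rejected", {
  # node in two pairs of the 'pairs' family
  expect_error(contactSchedule("pairs", 3, 10,
                               data.frame(i = c(1, 2), j = c(2, 3), k = 5)),
               "unrealizable")
  # chain with second neighbours closer than dOut
  expect_error(contactSchedule("chain", 3, 10,
                               data.frame(i = 1:2, j = 2:3, k = 5),
                               dIn = 4, dOut = 12),
               "unrealizable")
  # star with too many leaves
  expect_error(contactSchedule("star", 8, 10,
                               data.frame(i = 1, j = 2:8, k = 5),
                               dIn = 4, dOut = 5),
               "unrealizable")
  # leaves would collide
  expect_error(contactSchedule("star", 5, 10,
                               data.frame(i = 1, j = 2:5, k = 5),
                               dIn = 4, dOut = 12),
               "unrealizable")
  expect_error(contactSchedule("pairs", 4, 10,
                               data.frame(i = 1, j = 2, k = 11)),
               "0..nFrames")
})

test_that("schedules round-trip through their JSON representation", {
  sched <- contactSchedule("pairs", nNodes = 4, nFrames = 10,
                           pairs = data.frame(i = c(1, 3), j = c(2, 4),
                                              k = c(3, 7)),
                           dIn = 4, dOut = 12)
  f <- withr::local_tempfile(fileext = ".json")
  writeScheduleJson(sched, f)
  back <- readScheduleJson(f)
  expect_equal(back@family, sched@family)
  expect_equal(back@pairs$frames, sched@pairs$frames)
  expect_identical(coords(generateScheduleEnsemble(back)),
                   coords(generateScheduleEnsemble(sched)))
})

test_that("the compact chain is reproducible by seed and density-monotone in cutoff", {
  e1 <- generateCompactChain(50, 5, seed = 21)
  e2 <- generateCompactChain(50, 5, seed = 21)
  expect_identical(coords(e1), coords(e2))
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemble(e1, f1)
  writeEnsemble(e2, f2)
  expect_identical(readLines(f1), readLines(f2))

  e3 <- generateCompactChain(50, 5, seed = 22)
  expect_false(identical(coords(e1), coords(e3)))

  # more edges at 6 A than at 4 A
  ens <- generateCompactChain(50, 100, seed = 1)
  coms <- computeComSeries(ens, selectSideChains(ens))
  n4 <- nrow(edges(buildGraph(computePersistence(coms, 4), 20)))
  n6 <- nrow(edges(buildGraph(computePersistence(coms, 6), 20)))
  expect_gt(n6, n4)
})

test_that("zero jitter gives identical frames; generation restores the RNG state", {
  ens <- generateCompactChain(12, 4, jitterSd = 0, seed = 2)
  expect_identical(coords(ens)[, , 1], coords(ens)[, , 4])

  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(generateCompactChain(12, 2, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("the chain excluded-volume and confinement constraints hold", {
  ens <- generateCompactChain(50, 1, jitterSd = 0, seed = 13)
  xyz <- coords(ens)[, , 1]
  d <- as.matrix(dist(xyz))
  adj <- abs(outer(1:50, 1:50, "-")) == 1
  expect_true(all(abs(d[adj] - 5.5) < 1e-6))
  nonadj <- upper.tri(d) & !adj
  expect_true(all(d[nonadj] >= 4.2))
})
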