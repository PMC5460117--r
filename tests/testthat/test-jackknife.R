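test_that("jackknife subsets each drop one contiguous block and tile the trajectory", {
  ens <- generateCompactChain(10, 100, jitterSd = 0, seed = 1)
  jk <- makeJackknifeSubsets(ens, 10L)
  expect_length(jk$subsets, 10L)
  # subset 1 keeps frames 11..100: exactly 90% of the frames
  expect_equal(frameIndices(jk$subsets[[1]]), 11:100)
  for (i in 1:10) {
    kept <- jk$scheme@kept[[i]]
    expect_length(kept, 90L)
    block <- jk$scheme@blocks$start[i]:jk$scheme@blocks$end[i]
    # kept frames plus the discarded block reconstitute the trajectory
    expect_equal(sort(c(kept, block)), 1:100)
  }
  blocks <- unlist(lapply(1:10, function(i)
    jk$scheme@blocks$start[i]:jk$scheme@blocks$end[i]))
  expect_equal(sort(blocks), 1:100)  # disjoint and tiling
})

test_that("block size is floor(n_frames/n); remainder frames stay in all subsets", {
  ens10 <- generateCompactChain(10, 10, jitterSd = 0, seed = 1)
  jk10 <- makeJackknifeSubsets(ens10, 10L)
  expect_true(all(vapply(jk10$subsets, nFrames, integer(1)) == 9L))

  ens105 <- generateCompactChain(10, 105, jitterSd = 0, seed = 1)
  jk105 <- makeJackknifeSubsets(ens105, 10L)
  expect_true(all(vapply(jk105$subsets, nFrames, integer(1)) == 95L))
  # frames 101..105 are never discarded
  for (i in 1:10) expect_true(all(101:105 %in% jk105$scheme@kept[[i]]))
  # discarded blocks are disjoint
  blocks <- unlist(lapply(1:10, function(i)
    jk105$scheme@blocks$start[i]:jk105$scheme@blocks$end[i]))
  expect_equal(sort(blocks), 1:100)

  expect_error(makeJackknifeSubsets(ens10, 11L), "insufficient")
})

test_that("the jackknife mean and standard error match hand evaluation", {
  expect_equal(jackknifeMean(c(2, 4, 6)), 4)
  expect_equal(jackknifeMean(rep(5, 10)), 5)
  expect_equal(jackknifeMean(c(0, 1)), 0.5)
  expect_error(jackknifeMean(numeric(0)), "non-empty")

  expect_equal(jackknifeSE(c(2, 4, 6)), sqrt(16 / 3))
  expect_equal(jackknifeSE(c(0, 1)), 0.5)
  expect_identical(jackknifeSE(rep(3.7, 8)), 0)
  expect_error(jackknifeSE(5), "n >= 2")
})

test_that("the standard error is translation-invariant and scales linearly", {
  set.seed(17)
  for (rep in 1:20) {
    x <- rnorm(sample(2:30, 1))
    c0 <- rnorm(1, sd = 10)
    a <- runif(1, 0.1, 10)
    expect_equal(jackknifeSE(x + c0), jackknifeSE(x), tolerance = 1e-9)
    expect_equal(jackknifeSE(a * x), a * jackknifeSE(x), tolerance = 1e-9)
  }
})

test_that("identical-frame ensembles give zero standard error for every observable", {
  ens <- generateCompactChain(20, 20, jitterSd = 0, seed = 4)
  jk <- jackknifeObservables(ens, cutoff = 5, nSubsets = 10L)
  est <- estimates(jk)
  expect_true(all(est$se == 0))
  expect_true(all(est$theta_dot == est$full_value))
  expect_true(all(thetaValues(jk) == est$full_value))
})

test_that("a contact concentrated in one block deviates in exactly one subset", {
  # pair in contact only in frames 1..4 of 40; with 10 subsets (block
  # size 4) the edge survives every subset except the one discarding
  # frames 1..4: persistence 4/36 = 11.1% elsewhere, 0% there. At
  # p_crit 5% the largest-component size is 2 in nine subsets and 1 in
  # one, so SE = {(9/10)[(1-1.9)^2 + 9(2-1.9)^2]}^(1/2) = 0.9.
  sched <- contactSchedule("pairs", nNodes = 2, nFrames = 40,
                           pairs = data.frame(i = 1, j = 2, k = 4),
                           dIn = 4, dOut = 12)
  ens <- generateScheduleEnsemble(sched)
  jk <- jackknifeObservables(ens, cutoff = 5, pCrit = 5, nSubsets = 10L,
                             topK = 1L)
  est <- estimates(jk)
  row <- est[est$observable == "component_size_rank_1", ]
  expect_equal(row$full_value, 2)
  theta <- thetaValues(jk)["component_size_rank_1", ]
  expect_equal(sort(unname(theta)), c(1, rep(2, 9)))
  expect_equal(sum(theta != row$full_value), 1L)
  expect_equal(row$theta_dot, 1.9)
  expect_equal(row$se, 0.9)
})

test_that("observables absent from a subset count as zero", {
  sched <- contactSchedule("pairs", nNodes = 4, nFrames = 20,
                           pairs = data.frame(i = c(1, 3), j = c(2, 4),
                                              k = c(20, 2)),
                           dIn = 4, dOut = 12)
  ens <- generateScheduleEnsemble(sched)
  # pair 3-4 in contact 2/20 = 10% < 20%: components are {1,2}, {3},
  # {4} -> only 3 components, so the rank-4 size is 0 everywhere
  jk <- jackknifeObservables(ens, cutoff = 5, pCrit = 20, nSubsets = 10L,
                             topK = 4L)
  est <- estimates(jk)
  expect_equal(est[est$observable == "component_size_rank_3", "full_value"], 1)
  expect_equal(est[est$observable == "component_size_rank_4", "full_value"], 0)
  expect_true(all(thetaValues(jk)["component_size_rank_4", ] == 0))
  # no hubs anywhere: hub observables all zero
  hub_rows <- grepl("^hub_count", est$observable)
  expect_true(all(est$full_value[hub_rows] == 0))
  expect_true(all(thetaValues(jk)[hub_rows, ] == 0))
})

test_that("the jackknife CSV report round-trips the estimates", {
  ens <- generateCompactChain(15, 20, seed = 8)
  jk <- jackknifeObservables(ens, cutoff = 5.5, nSubsets = 10L)
  f <- withr::local_tempfile(fileext = ".csv")
  writeJackknifeCsv(jk, f)
  df <- utils::read.csv(f)
  expect_equal(df$observable, estimates(jk)$observable)
  expect_equal(df$se, estimates(jk)$se, tolerance = 1e-12)
  expect_equal(as.matrix(df[, paste0("theta_", 1:10)]),
               thetaValues(jk), ignore_attr = TRUE)
})
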