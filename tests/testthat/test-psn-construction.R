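test_that("centers of mass are mass-weighted means of side-chain atoms", {
  # equal masses at (0,0,0) and (2,0,0): midpoint
  ens <- residue_ensemble(rbind(c(0, 0, 0), c(2, 0, 0)),
                          c("CB", "CG"), c("C", "C"))
  sel <- selectSideChains(ens)
  coms <- computeComSeries(ens, sel)
  expect_equal(coords(coms)[1, , 1], c(1, 0, 0))

  # mass 12 at origin, mass 16 at (0,0,7): COM at 16*7/28 = 4
  ens2 <- residue_ensemble(rbind(c(0, 0, 0), c(0, 0, 7)),
                           c("CB", "OG"), c("C", "O"))
  mt <- new("MassTable", specific = stats::setNames(numeric(0), character(0)),
            elements = c(C = 12, O = 16), label = "test")
  coms2 <- computeComSeries(ens2, selectSideChains(ens2), mt)
  expect_equal(coords(coms2)[1, , 1], c(0, 0, 4))

  # single-atom side chain: COM is that atom
  ens3 <- residue_ensemble(rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.1, 2.2, -1)),
                           c("N", "CA", "CB"), c("N", "C", "C"))
  coms3 <- computeComSeries(ens3, selectSideChains(ens3))
  expect_equal(coords(coms3)[1, , 1], c(3.1, 2.2, -1))
})

test_that("persistence is the exact fraction of frames within the cutoff", {
  # pair within cutoff in 3 of 10 frames
  pos <- array(0, dim = c(2, 3, 10))
  pos[2, 1, ] <- c(4, 4, 4, rep(20, 7))
  pm <- computePersistence(com_series(pos), cutoff = 5)
  expect_identical(persistenceValues(pm)[1, 2], 0.3)

  # fixed distance 4.9: persistence 1 at cutoff 5.0, 0 at 4.5
  pos2 <- array(0, dim = c(2, 3, 4))
  pos2[2, 1, ] <- 4.9
  expect_equal(persistenceValues(computePersistence(com_series(pos2), 5.0))[1, 2], 1)
  expect_equal(persistenceValues(computePersistence(com_series(pos2), 4.5))[1, 2], 0)

  # everything far apart: all-zero matrix
  pos3 <- array(0, dim = c(3, 3, 2))
  pos3[, 1, ] <- c(0, 50, 100)
  expect_true(all(persistenceValues(computePersistence(com_series(pos3), 5)) == 0))

  expect_error(computePersistence(com_series(pos3), -1), "positive")
})

test_that("the distance test is inclusive at the cutoff", {
  pos <- array(0, dim = c(2, 3, 1))
  pos[2, 1, 1] <- 5
  expect_equal(persistenceValues(computePersistence(com_series(pos), 5))[1, 2], 1)
})

test_that("graph filtering keeps edges at or above p_crit, as percentages", {
  pos <- array(0, dim = c(3, 3, 20))
  pos[2, 1, ] <- c(rep(4, 6), rep(30, 14))   # persistence 0.30
  pos[3, 1, ] <- c(rep(-4, 3), rep(-30, 17)) # persistence 0.15
  pm <- computePersistence(com_series(pos), 5)
  g <- buildGraph(pm, pCrit = 20)
  e <- edges(g)
  expect_equal(nrow(e), 1L)
  expect_equal(e$weight, 30)
  expect_equal(e$from, "A:1:ALA")
  expect_equal(e$to, "A:2:ALA")
  # inclusive at the threshold
  g20 <- buildGraph(pm, pCrit = 30)
  expect_equal(nrow(edges(g20)), 1L)
  g31 <- buildGraph(pm, pCrit = 31)
  expect_equal(nrow(edges(g31)), 0L)
})

test_that("p_crit 0 keeps all positive-persistence pairs, 100 only permanent ones", {
  set.seed(101)
  n <- 5L
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- sample(c(0, 0.05, 0.2, 0.6, 1), 10, replace = TRUE)
  v <- v + t(v)
  dimnames(v) <- list(toy_nodes(n)$label, toy_nodes(n)$label)
  pm <- new("PersistenceMatrix", values = v, nodes = toy_nodes(n),
            cutoff = 5, nFramesUsed = 20L)
  # brute-force enumeration over all pairs
  expected_at <- function(q) {
    sum(vapply(seq_len(n - 1), function(i)
      sum(v[i, (i + 1):n] > 0 & v[i, (i + 1):n] * 100 >= q), numeric(1)))
  }
  expect_equal(nrow(edges(buildGraph(pm, 0))), expected_at(0))
  expect_equal(nrow(edges(buildGraph(pm, 100))), expected_at(100))
  expect_equal(nrow(edges(buildGraph(pm, 100))), sum(v[upper.tri(v)] == 1))
})

test_that("persistence is invariant under global rigid motion and frame shuffling", {
  ens <- generateCompactChain(20, 15, seed = 3)
  sel <- selectSideChains(ens)
  pm <- computePersistence(computeComSeries(ens, sel), 5)

  set.seed(42)
  ens_rt <- transform_ensemble(ens, random_rotation(), rnorm(3, sd = 20))
  pm_rt <- computePersistence(computeComSeries(ens_rt, sel), 5)
  expect_lt(max(abs(persistenceValues(pm_rt) - persistenceValues(pm))), 1e-9)

  perm <- sample(nFrames(ens))
  ens_sh <- subsetFrames(ens, perm)
  pm_sh <- computePersistence(computeComSeries(ens_sh, sel), 5)
  expect_identical(persistenceValues(pm_sh), persistenceValues(pm))
})

test_that("edge sets are monotone in cutoff and anti-monotone in p_crit", {
  ens <- generateCompactChain(25, 20, seed = 5)
  sel <- selectSideChains(ens)
  coms <- computeComSeries(ens, sel)
  edge_key <- function(g) paste(edges(g)$from, edges(g)$to)

  cuts <- c(4, 4.5, 5, 5.5, 6)
  graphs <- lapply(cuts, function(cf)
    buildGraph(computePersistence(coms, cf), 20))
  for (k in seq_len(length(cuts) - 1)) {
    expect_true(all(edge_key(graphs[[k]]) %in% edge_key(graphs[[k + 1]])))
  }

  pm5 <- computePersistence(coms, 5)
  qs <- c(0, 20, 50, 100)
  gq <- lapply(qs, function(q) buildGraph(pm5, q))
  for (k in seq_len(length(qs) - 1)) {
    expect_true(all(edge_key(gq[[k + 1]]) %in% edge_key(gq[[k]])))
  }
})

test_that("a minimum sequence separation suppresses near-diagonal contacts", {
  pos <- array(0, dim = c(3, 3, 2))
  pos[2, 1, ] <- 4   # neighbours 1-2 in contact
  pos[3, 1, ] <- 8   # 2-3 also within 5 of node 2
  pm0 <- computePersistence(com_series(pos), 5, minSeqSeparation = 0L)
  expect_equal(persistenceValues(pm0)[1, 2], 1)
  pm2 <- computePersistence(com_series(pos), 5, minSeqSeparation = 2L)
  expect_equal(persistenceValues(pm2)[1, 2], 0)
  expect_equal(persistenceValues(pm2)[1, 3], persistenceValues(pm0)[1, 3])
})

test_that("edge lists are written sorted, tab-separated and deterministic", {
  ens <- generateCompactChain(15, 10, seed = 9)
  g <- buildGraph(computePersistence(computeComSeries(
    ens, selectSideChains(ens)), 6), 20)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  writeEdgeList(g, f1)
  writeEdgeList(g, f2)
  expect_identical(readLines(f1), readLines(f2))
  parts <- strsplit(readLines(f1), "\t")
  expect_true(all(lengths(parts) == 3L))
  w <- as.numeric(vapply(parts, `[`, "", 3L))
  expect_true(all(w >= 20))
})
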