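#' Build jackknife leave-block-out subsets of an ensemble
#'
#' Subset `i` (of `n`) discards the contiguous frame block
#' `[(i-1)*B + 1, i*B]` with `B = floor(n_frames / n)` and keeps every
#' other frame in order, so each subset retains `n_frames - B` frames —
#' 90\% with the default `n = 10`. The discarded blocks are disjoint and
#' tile the trajectory; remainder frames (`n_frames mod n`, at the tail)
#' are kept in every subset.
#'
#' @param ensemble a [StructuralEnsemble-class] with at least `nSubsets`
#'   frames
#' @param nSubsets number of subsets (>= 2), default 10
#' @return a list with elements `subsets` (list of
#'   [StructuralEnsemble-class]) and `scheme` ([ResampleScheme-class])
#' @export
makeJackknifeSubsets <- function(ensemble, nSubsets = 10L) {
  stopifnot(is(ensemble, "StructuralEnsemble"))
  nSubsets <- as.integer(nSubsets)
  if (is.na(nSubsets) || nSubsets < 2L)
    stop("nSubsets must be an integer >= 2")
  nf <- nFrames(ensemble)
  if (nf < nSubsets)
    stop("insufficient frames: ", nf, " frames for ", nSubsets,
         " jackknife subsets")
  B <- nf %/% nSubsets
  kept <- vector("list", nSubsets)
  blocks <- data.frame(start = integer(nSubsets), end = integer(nSubsets))
  for (i in seq_len(nSubsets)) {
    drop <- ((i - 1L) * B + 1L):(i * B)
    blocks$start[i] <- drop[1L]
    blocks$end[i] <- drop[length(drop)]
    kept[[i]] <- setdiff(seq_len(nf), drop)
  }
  scheme <- new("ResampleScheme", nSubsets = nSubsets, kept = kept,
                blocks = blocks)
  subsets <- lapply(kept, function(k) subsetFrames(ensemble, k))
  list(subsets = subsets, scheme = scheme)
}

setMethod("show", "ResampleScheme", function(object) {
  cat("ResampleScheme:", object@nSubsets, "subsets, each keeping",
      length(object@kept[[1]]), "frames (blocks of",
      object@blocks$end[1] - object@blocks$start[1] + 1L,
      "frames discarded)\n")
})

#' Jackknife mean of per-subset estimates
#'
#' The empirical average `theta_dot = (1/n) * sum_i theta_i` of the
#' estimator over the resampled trajectories.
#'
#' @param thetaI numeric vector of per-subset estimates (non-empty)
#' @return numeric scalar
#' @export
jackknifeMean <- function(thetaI) {
  if (!length(thetaI)) stop("thetaI must be non-empty")
  mean(thetaI)
}

#' Jackknife standard error
#'
#' Evaluates `SE = {((n-1)/n) * sum_i (theta_i - theta_dot)^2}^(1/2)`
#' where `theta_dot` is the jackknife mean and `n` the number of
#' resampled trajectories.
#'
#' @param thetaI numeric vector of per-subset estimates, length >= 2
#' @return numeric scalar, >= 0; exactly 0 when all estimates are equal
#' @examples
#' jackknifeSE(c(2, 4, 6))  # sqrt(16/3)
#' @export
jackknifeSE <- function(thetaI) {
  n <- length(thetaI)
  if (n < 2L) stop("jackknife standard error requires n >= 2 subsets")
  sqrt((n - 1) / n * sum((thetaI - mean(thetaI))^2))
}

# Observables of one PSN: hub count per degree and top-k component sizes.
# Degrees absent from a graph count 0; ranks beyond the number of
# components have size 0.
.psn_observables <- function(graph, minHubDegree, topK, degrees) {
  deg <- nodeDegrees(graph)
  hub_deg <- deg[deg >= minHubDegree]
  hub_counts <- vapply(degrees, function(d) sum(hub_deg == d), numeric(1))
  part <- connectedComponents(graph)
  sz <- componentSizes(part)
  comp_sizes <- vapply(seq_len(topK), function(k)
    if (k <= length(sz)) as.numeric(sz[k]) else 0, numeric(1))
  c(stats::setNames(hub_counts, paste0("hub_count_degree_", degrees)),
    stats::setNames(comp_sizes, paste0("component_size_rank_",
                                       seq_len(topK))))
}

#' Jackknife estimates of PSN observables
#'
#' Runs the full pipeline (centers of mass, persistence, graph) on the
#' complete ensemble and on each jackknife subset, and attaches a
#' jackknife mean and standard error to each network observable: the hub
#' count at each degree (from `minHubDegree` up to the largest degree
#' observed in any of the graphs) and the size of the k-th largest
#' connected component for `k = 1..topK`. Component observables are
#' matched across subsets by size rank, not by member identity. An
#' observable absent from a subset (no hub of that degree, fewer than k
#' components) contributes 0 for that subset.
#'
#' @param ensemble a [StructuralEnsemble-class]
#' @param selection a [SideChainSelection-class]; computed from the
#'   ensemble when `NULL`
#' @param masses a [MassTable-class]
#' @param cutoff distance cutoff in Angstrom
#' @param pCrit persistence filter in percent
#' @param nSubsets number of jackknife subsets
#' @param minHubDegree minimum hub degree
#' @param topK number of component ranks tracked
#' @param minSeqSeparation passed to [computePersistence()]
#' @return a [JackknifeEstimates-class]
#' @export
jackknifeObservables <- function(ensemble, selection = NULL,
                                 masses = defaultMassTable(),
                                 cutoff = 5.0, pCrit = 20, nSubsets = 10L,
                                 minHubDegree = 3L, topK = 5L,
                                 minSeqSeparation = 0L) {
  stopifnot(is(ensemble, "StructuralEnsemble"))
  if (is.null(selection)) selection <- selectSideChains(ensemble)
  coms <- computeComSeries(ensemble, selection, masses)
  jk <- makeJackknifeSubsets(ensemble, nSubsets)
  D <- .pairwiseDistances(coms)
  .jackknife_from_distances(D, coms@nodes, jk$scheme, cutoff, pCrit,
                            as.integer(minHubDegree), as.integer(topK),
                            as.integer(minSeqSeparation))
}

# Core jackknife computation from a precomputed distance array; shared
# with runScan so distances are computed once per ensemble.
.jackknife_from_distances <- function(D, node_df, scheme, cutoff, pCrit,
                                      minHubDegree, topK,
                                      minSeqSeparation) {
  graph_of <- function(frames) {
    v <- .persistenceFromDistances(D[, , frames, drop = FALSE], cutoff,
                                   node_df, minSeqSeparation)
    pm <- new("PersistenceMatrix", values = v, nodes = node_df,
              cutoff = cutoff, nFramesUsed = length(frames))
    buildGraph(pm, pCrit)
  }
  full_graph <- graph_of(seq_len(dim(D)[3]))
  sub_graphs <- lapply(scheme@kept, graph_of)

  max_deg <- max(c(minHubDegree,
                   vapply(c(list(full_graph), sub_graphs),
                          function(g) {
                            d <- nodeDegrees(g)
                            if (length(d)) max(d) else 0L
                          }, numeric(1))))
  degrees <- seq.int(minHubDegree, max_deg)

  full_obs <- .psn_observables(full_graph, minHubDegree, topK, degrees)
  theta <- vapply(sub_graphs, function(g)
    .psn_observables(g, minHubDegree, topK, degrees), full_obs)
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1L)

  n <- scheme@nSubsets
  est <- data.frame(
    observable = names(full_obs),
    full_value = unname(full_obs),
    theta_dot = apply(theta, 1L, jackknifeMean),
    se = apply(theta, 1L, jackknifeSE),
    n = n,
    stringsAsFactors = FALSE)
  rownames(est) <- NULL
  colnames(theta) <- paste0("theta_", seq_len(n))
  rownames(theta) <- names(full_obs)
  new("JackknifeEstimates", estimates = est, theta = theta)
}

#' @rdname estimates
#' @export
setMethod("estimates", "JackknifeEstimates", function(x) x@estimates)

#' @rdname thetaValues
#' @export
setMethod("thetaValues", "JackknifeEstimates", function(x) x@theta)

setMethod("show", "JackknifeEstimates", function(object) {
  cat("JackknifeEstimates:", nrow(object@estimates), "observables,",
      ncol(object@theta), "subsets\n")
  print(utils::head(object@estimates, 12L))
})

#' Write a jackknife report as CSV
#'
#' Columns: observable, full_value, theta_dot, se, n, then the per-subset
#' values theta_1..theta_n.
#'
#' @param est a [JackknifeEstimates-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeJackknifeCsv <- function(est, path) {
  stopifnot(is(est, "JackknifeEstimates"))
  df <- cbind(est@estimates, as.data.frame(est@theta, row.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
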