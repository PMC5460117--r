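#' Create a scan configuration
#'
#' @param cutoffs distance cutoffs in Angstrom, strictly increasing
#'   (default `c(4.0, 4.5, 5.0, 5.5, 6.0)`, the range over which
#'   side-chain contact networks move from fragmented to percolated)
#' @param pCrit persistence filter in percent (default 20)
#' @param nSubsets jackknife subsets (default 10)
#' @param minHubDegree minimum hub degree (default 3)
#' @param topK component ranks tracked (default 5)
#' @param excludedResnames residue types excluded from the node set
#'   (default `"GLY"`)
#' @param minSeqSeparation minimum sequence separation for edges
#'   (default 0)
#' @return a [ScanConfig-class]
#' @export
scanConfig <- function(cutoffs = c(4.0, 4.5, 5.0, 5.5, 6.0), pCrit = 20,
                       nSubsets = 10L, minHubDegree = 3L, topK = 5L,
                       excludedResnames = "GLY", minSeqSeparation = 0L) {
  new("ScanConfig", cutoffs = as.numeric(cutoffs), pCrit = as.numeric(pCrit),
      nSubsets = as.integer(nSubsets),
      minHubDegree = as.integer(minHubDegree), topK = as.integer(topK),
      excludedResnames = toupper(excludedResnames),
      minSeqSeparation = as.integer(minSeqSeparation))
}

setMethod("show", "ScanConfig", function(object) {
  cat("ScanConfig: cutoffs", paste(object@cutoffs, collapse = ", "),
      "A; p_crit", object@pCrit, "%;", object@nSubsets,
      "jackknife subsets\n")
})

#' Scan a grid of distance cutoffs
#'
#' Runs the complete PSN pipeline — side-chain selection, centers of
#' mass, contact persistence, persistence-filtered graph, hubs, connected
#' components, jackknife errors — at every cutoff of the configuration.
#' Pairwise center-of-mass distances are computed once and reused across
#' cutoffs, so the scan is exactly equivalent to running each cutoff
#' standalone. The analysis path contains no randomness: identical inputs
#' give identical results.
#'
#' @param ensemble a [StructuralEnsemble-class]
#' @param config a [ScanConfig-class]
#' @param masses a [MassTable-class]
#' @return a [CutoffScanResult-class]
#' @export
runScan <- function(ensemble, config = scanConfig(),
                    masses = defaultMassTable()) {
  stopifnot(is(ensemble, "StructuralEnsemble"), is(config, "ScanConfig"))
  selection <- selectSideChains(ensemble, config@excludedResnames)
  coms <- computeComSeries(ensemble, selection, masses)
  D <- .pairwiseDistances(coms)
  scheme <- makeJackknifeSubsets(ensemble, config@nSubsets)$scheme
  node_df <- coms@nodes
  nn <- nrow(node_df)

  perCutoff <- lapply(config@cutoffs, function(cf) {
    v <- .persistenceFromDistances(D, cf, node_df, config@minSeqSeparation)
    pm <- new("PersistenceMatrix", values = v, nodes = node_df,
              cutoff = cf, nFramesUsed = dim(D)[3])
    graph <- buildGraph(pm, config@pCrit)
    hub_tab <- findHubs(graph, config@minHubDegree)
    part <- connectedComponents(graph)
    jk <- .jackknife_from_distances(D, node_df, scheme, cf, config@pCrit,
                                    config@minHubDegree, config@topK,
                                    config@minSeqSeparation)
    list(cutoff = cf, graph = graph, hubs = hub_tab, components = part,
         jackknife = jk, nEdges = nrow(edges(graph)),
         nNonSingletonComponents = nNonSingleton(part),
         fractionLargestComponent = componentSizes(part)[1] / nn)
  })
  names(perCutoff) <- sprintf("%.1f", config@cutoffs)
  new("CutoffScanResult", config = config, nodes = node_df,
      perCutoff = perCutoff)
}

#' Per-cutoff result of a scan
#' @param result a [CutoffScanResult-class]
#' @param cutoff numeric cutoff present in the scan grid
#' @return the per-cutoff list (see [CutoffScanResult-class])
#' @export
cutoffResult <- function(result, cutoff) {
  stopifnot(is(result, "CutoffScanResult"))
  key <- sprintf("%.1f", cutoff)
  if (!key %in% names(result@perCutoff))
    stop("cutoff ", cutoff, " not in scan grid (",
         paste(names(result@perCutoff), collapse = ", "), ")")
  result@perCutoff[[key]]
}

#' @rdname nodes
#' @export
setMethod("nodes", "CutoffScanResult", function(x) x@nodes)

#' Summary table of a cutoff scan
#'
#' One row per cutoff: edge count, hub count, maximum hub degree, number
#' of components (total and non-singleton) and the fraction of nodes in
#' the largest component.
#'
#' @param result a [CutoffScanResult-class]
#' @return data.frame
#' @export
scanSummary <- function(result) {
  stopifnot(is(result, "CutoffScanResult"))
  rows <- lapply(result@perCutoff, function(pc) {
    hb <- hubs(pc$hubs)
    data.frame(
      cutoff = pc$cutoff,
      n_edges = pc$nEdges,
      n_hubs = nrow(hb),
      max_hub_degree = if (nrow(hb)) max(hb$degree) else 0L,
      n_components = length(componentSizes(pc$components)),
      n_non_singleton = pc$nNonSingletonComponents,
      fraction_largest = pc$fractionLargestComponent)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

setMethod("show", "CutoffScanResult", function(object) {
  cat("CutoffScanResult over", length(object@perCutoff), "cutoffs,",
      nrow(object@nodes), "nodes\n")
  print(scanSummary(object))
})
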