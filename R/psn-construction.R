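#' Compute side-chain centers of mass for every frame
#'
#' For each node and frame, the center of mass is the mass-weighted mean
#' of the node's side-chain atom positions,
#' `sum(m_a * r_a) / sum(m_a)`. Every atom's mass must resolve through the
#' mass table (specific entry or element fallback).
#'
#' @param ensemble a [StructuralEnsemble-class]
#' @param selection a [SideChainSelection-class] from the same ensemble
#' @param masses a [MassTable-class] (default: standard element masses)
#' @return a [ComSeries-class]
#' @export
computeComSeries <- function(ensemble, selection, masses = defaultMassTable()) {
  stopifnot(is(ensemble, "StructuralEnsemble"),
            is(selection, "SideChainSelection"),
            is(masses, "MassTable"))
  at <- ensemble@atoms
  nf <- dim(ensemble@coords)[3]
  nn <- nrow(selection@nodes)
  pos <- array(NA_real_, dim = c(nn, 3L, nf))
  for (k in seq_len(nn)) {
    ai <- selection@atomIndices[[k]]
    m <- massOf(masses, at$resname[ai], at$atom_name[ai], at$element[ai])
    w <- m / sum(m)
    for (f in seq_len(nf)) {
      xyz <- matrix(ensemble@coords[ai, , f], ncol = 3L)
      pos[k, , f] <- colSums(xyz * w)
    }
  }
  new("ComSeries", positions = pos, nodes = selection@nodes)
}

#' @rdname nFrames
#' @export
setMethod("nFrames", "ComSeries", function(x) dim(x@positions)[3])

#' @rdname nodes
#' @export
setMethod("nodes", "ComSeries", function(x) x@nodes)

#' @rdname coords
#' @export
setMethod("coords", "ComSeries", function(x) x@positions)

setMethod("show", "ComSeries", function(object) {
  cat("ComSeries:", dim(object@positions)[1], "nodes,",
      dim(object@positions)[3], "frames\n")
})

# All pairwise COM distances, one n x n matrix per frame, stacked as an
# n x n x n_frames array. Computed once and reused across cutoffs.
.pairwiseDistances <- function(coms, frames = NULL) {
  nf <- dim(coms@positions)[3]
  if (is.null(frames)) frames <- seq_len(nf)
  nn <- dim(coms@positions)[1]
  D <- array(NA_real_, dim = c(nn, nn, length(frames)))
  for (k in seq_along(frames)) {
    D[, , k] <- as.matrix(stats::dist(coms@positions[, , frames[k]]))
  }
  D
}

# Persistence from a precomputed distance array: exact rational fraction
# (count of frames with distance <= cutoff) / n_frames.
.persistenceFromDistances <- function(D, cutoff, nodes,
                                      minSeqSeparation = 0L) {
  nf <- dim(D)[3]
  counts <- rowSums(D <= cutoff, dims = 2L)
  values <- counts / nf
  diag(values) <- 0
  if (minSeqSeparation > 0L) {
    same_chain <- outer(nodes$chain, nodes$chain, "==")
    close_seq <- abs(outer(nodes$resid, nodes$resid, "-")) < minSeqSeparation
    values[same_chain & close_seq] <- 0
  }
  dimnames(values) <- list(nodes$label, nodes$label)
  values
}

#' Compute the contact persistence matrix
#'
#' For every unordered node pair, the persistence is the fraction of
#' frames in which the Euclidean distance between the two side-chain
#' centers of mass is at or below the cutoff (inclusive). Distances are
#' plain Euclidean with no periodic-boundary minimum image: inputs are
#' assumed whole-molecule. Sequence-adjacent pairs are not special-cased;
#' a minimum sequence separation can be requested explicitly.
#'
#' @param coms a [ComSeries-class]
#' @param cutoff distance cutoff in Angstrom (> 0)
#' @param minSeqSeparation pairs on the same chain with
#'   `|resid_i - resid_j| < minSeqSeparation` are forced to persistence 0;
#'   default 0 (no restriction)
#' @return a [PersistenceMatrix-class]
#' @export
computePersistence <- function(coms, cutoff, minSeqSeparation = 0L) {
  stopifnot(is(coms, "ComSeries"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive distance in Angstrom")
  D <- .pairwiseDistances(coms)
  values <- .persistenceFromDistances(D, cutoff, coms@nodes,
                                      as.integer(minSeqSeparation))
  new("PersistenceMatrix", values = values, nodes = coms@nodes,
      cutoff = cutoff, nFramesUsed = dim(coms@positions)[3])
}

#' @rdname persistenceValues
#' @export
setMethod("persistenceValues", "PersistenceMatrix", function(x) x@values)

#' @rdname nodes
#' @export
setMethod("nodes", "PersistenceMatrix", function(x) x@nodes)

#' @rdname cutoff
#' @export
setMethod("cutoff", "PersistenceMatrix", function(x) x@cutoff)

setMethod("show", "PersistenceMatrix", function(object) {
  nz <- sum(object@values[upper.tri(object@values)] > 0)
  cat("PersistenceMatrix: ", nrow(object@values), " nodes, cutoff ",
      object@cutoff, " A, ", object@nFramesUsed, " frames, ",
      nz, " non-zero pairs\n", sep = "")
})

#' Build the persistence-filtered PSN
#'
#' An unordered node pair becomes an edge when its persistence, expressed
#' in percent, is at least `pCrit` and strictly positive; the edge weight
#' is the persistence percentage. Comparisons are inclusive, so
#' `pCrit = 20` means "in contact in at least 20\% of frames". All nodes
#' are retained even when isolated.
#'
#' @param persistence a [PersistenceMatrix-class]
#' @param pCrit persistence filter in percent, default 20
#' @return a [PSNGraph-class]
#' @export
buildGraph <- function(persistence, pCrit = 20) {
  stopifnot(is(persistence, "PersistenceMatrix"))
  if (!is.numeric(pCrit) || length(pCrit) != 1L || pCrit < 0 || pCrit > 100)
    stop("pCrit must be a single percentage in [0, 100]")
  v <- persistence@values
  w <- v * 100
  keep <- upper.tri(v) & w >= pCrit & v > 0
  idx <- which(keep, arr.ind = TRUE)
  labels <- persistence@nodes$label
  edges <- data.frame(
    from = labels[idx[, 1L]],
    to = labels[idx[, 2L]],
    weight = w[keep],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  rownames(edges) <- NULL
  new("PSNGraph", nodes = persistence@nodes, edges = edges,
      cutoff = persistence@cutoff, pCrit = pCrit)
}

#' @rdname nodes
#' @export
setMethod("nodes", "PSNGraph", function(x) x@nodes)

#' @rdname edges
#' @export
setMethod("edges", "PSNGraph", function(x) x@edges)

#' @rdname cutoff
#' @export
setMethod("cutoff", "PSNGraph", function(x) x@cutoff)

#' @rdname pCrit
#' @export
setMethod("pCrit", "PSNGraph", function(x) x@pCrit)

setMethod("show", "PSNGraph", function(object) {
  cat("PSNGraph: ", nrow(object@nodes), " nodes, ", nrow(object@edges),
      " edges (cutoff ", object@cutoff, " A, p_crit ", object@pCrit,
      "%)\n", sep = "")
})

#' Write a PSN as a tab-separated edge list
#'
#' One edge per line: `node1 <TAB> node2 <TAB> weight%`, sorted by node
#' order; node labels are `chain:resid:resname`. Weights are printed with
#' 6 decimals so that re-running on identical inputs is byte-identical.
#'
#' @param graph a [PSNGraph-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeEdgeList <- function(graph, path) {
  stopifnot(is(graph, "PSNGraph"))
  e <- graph@edges
  lines <- sprintf("%s\t%s\t%.6f", e$from, e$to, e$weight)
  writeLines(lines, path)
  invisible(path)
}

#' Write a PSN as a square weighted adjacency matrix
#'
#' Tab-separated text with node labels as row and column headers; entries
#' are persistence percentages (0 where no edge).
#'
#' @param graph a [PSNGraph-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeAdjacencyMatrix <- function(graph, path) {
  stopifnot(is(graph, "PSNGraph"))
  labels <- graph@nodes$label
  A <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  e <- graph@edges
  if (nrow(e)) {
    A[cbind(e$from, e$to)] <- e$weight
    A[cbind(e$to, e$from)] <- e$weight
  }
  utils::write.table(format(A, digits = 8, trim = TRUE), file = path,
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
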