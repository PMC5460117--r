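# igraph representation of a PSNGraph; isolated nodes included.
.as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph@edges, directed = FALSE,
                                vertices = graph@nodes$label)
}

#' Node degrees of a PSN
#'
#' The degree of a node is the number of incident edges; weights are
#' ignored.
#'
#' @param graph a [PSNGraph-class]
#' @return named integer vector (node label -> degree), in node order
#' @export
nodeDegrees <- function(graph) {
  stopifnot(is(graph, "PSNGraph"))
  g <- .as_igraph(graph)
  d <- igraph::degree(g)
  stats::setNames(as.integer(d[graph@nodes$label]), graph@nodes$label)
}

#' Find hub residues
#'
#' Hubs are nodes whose degree reaches a threshold, 3 by default — the
#' convention in residue-network analysis, where steric constraints limit
#' hub degrees to roughly 3-10. Alternatively, `mode = "above_average"`
#' declares as hubs all nodes whose degree strictly exceeds the network's
#' mean degree.
#'
#' @param graph a [PSNGraph-class]
#' @param minHubDegree minimum degree for a hub (>= 1), default 3
#' @param mode `"threshold"` (default) or `"above_average"`
#' @return a [HubTable-class]
#' @export
findHubs <- function(graph, minHubDegree = 3L, mode = c("threshold",
                                                        "above_average")) {
  stopifnot(is(graph, "PSNGraph"))
  mode <- match.arg(mode)
  deg <- nodeDegrees(graph)
  if (mode == "above_average") {
    thr <- mean(deg)
    is_hub <- deg > thr
    minHubDegree <- as.integer(ceiling(thr + 1e-9))
  } else {
    minHubDegree <- as.integer(minHubDegree)
    if (is.na(minHubDegree) || minHubDegree < 1L)
      stop("minHubDegree must be a positive integer")
    is_hub <- deg >= minHubDegree
  }
  nd <- graph@nodes
  rec <- data.frame(node = nd$label, chain = nd$chain, resid = nd$resid,
                    resname = nd$resname, degree = as.integer(deg),
                    stringsAsFactors = FALSE)[is_hub, , drop = FALSE]
  rec <- rec[order(-rec$degree, match(rec$node, nd$label)), , drop = FALSE]
  rownames(rec) <- NULL
  hist <- integer(0)
  if (nrow(rec)) {
    tb <- table(rec$degree)
    hist <- stats::setNames(as.integer(tb), names(tb))
  }
  new("HubTable", records = rec, minHubDegree = minHubDegree,
      histogram = hist)
}

#' @rdname hubs
#' @export
setMethod("hubs", "HubTable", function(x) x@records)

#' @rdname degreeHistogram
#' @export
setMethod("degreeHistogram", "HubTable", function(x) x@histogram)

setMethod("show", "HubTable", function(object) {
  cat("HubTable:", nrow(object@records), "hubs (min degree",
      object@minHubDegree, ")\n")
  if (length(object@histogram)) {
    cat("  degree:", paste(names(object@histogram), collapse = " "), "\n")
    cat("  count: ", paste(object@histogram, collapse = " "), "\n")
  }
})

#' Connected components of a PSN
#'
#' Maximal sets of mutually reachable nodes, including singletons, ranked
#' by decreasing size. Equal-sized components are ordered by their
#' smallest member's `(chain, resid, icode)` so component ranks are
#' deterministic — a prerequisite for rank-matched jackknife error bars.
#'
#' @param graph a [PSNGraph-class]
#' @return a [ComponentPartition-class]
#' @export
connectedComponents <- function(graph) {
  stopifnot(is(graph, "PSNGraph"))
  g <- .as_igraph(graph)
  comp <- igraph::components(g)
  memb <- comp$membership[graph@nodes$label]
  nd <- graph@nodes
  groups <- split(seq_len(nrow(nd)), memb)
  # order key of the smallest member of each component
  min_key <- vapply(groups, function(ix) {
    o <- order(nd$chain[ix], nd$resid[ix], nd$icode[ix])[1]
    ix[o]
  }, integer(1))
  sizes <- lengths(groups)
  ord <- order(-sizes, nd$chain[min_key], nd$resid[min_key],
               nd$icode[min_key])
  groups <- groups[ord]
  members <- lapply(groups, function(ix) nd$label[ix])
  names(members) <- NULL
  membership <- integer(nrow(nd))
  names(membership) <- nd$label
  for (r in seq_along(members)) membership[members[[r]]] <- r
  new("ComponentPartition", members = members,
      sizes = as.integer(lengths(members)), membership = membership)
}

#' @rdname componentMembers
#' @export
setMethod("componentMembers", "ComponentPartition", function(x) x@members)

#' @rdname componentSizes
#' @export
setMethod("componentSizes", "ComponentPartition", function(x) x@sizes)

#' Number of non-singleton components
#' @param partition a [ComponentPartition-class]
#' @return integer
#' @export
nNonSingleton <- function(partition) {
  stopifnot(is(partition, "ComponentPartition"))
  sum(partition@sizes > 1L)
}

setMethod("show", "ComponentPartition", function(object) {
  cat("ComponentPartition:", length(object@sizes), "components (",
      nNonSingleton(object), "non-singleton ); sizes:",
      paste(utils::head(object@sizes, 10L), collapse = " "),
      if (length(object@sizes) > 10L) "..." else "", "\n")
})

#' Write hub and component tables as CSV
#'
#' @param hubTable a [HubTable-class]
#' @param partition a [ComponentPartition-class]
#' @param path output path
#' @return `path`, invisibly
#' @name writeGraphTables
NULL

#' @rdname writeGraphTables
#' @export
writeHubCsv <- function(hubTable, path) {
  stopifnot(is(hubTable, "HubTable"))
  utils::write.csv(hubTable@records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGraphTables
#' @export
writeComponentCsv <- function(partition, path) {
  stopifnot(is(partition, "ComponentPartition"))
  df <- data.frame(
    node = unlist(partition@members, use.names = FALSE),
    component_rank = rep(seq_along(partition@sizes), partition@sizes),
    component_size = rep(partition@sizes, partition@sizes),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
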