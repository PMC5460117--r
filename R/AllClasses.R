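#' @import methods
NULL

#' StructuralEnsemble: a multi-frame molecular structure
#'
#' Holds an ordered set of conformations (frames) of the same molecule,
#' e.g. snapshots from a molecular dynamics trajectory or the models of a
#' multi-model PDB file. All frames share one atom table; only coordinates
#' vary.
#'
#' @slot coords numeric array `n_atoms x 3 x n_frames`, coordinates in
#'   Angstrom.
#' @slot atoms `data.frame` with one row per atom: `atom_name`, `element`,
#'   `chain`, `resid` (integer residue number), `icode` (insertion code,
#'   `""` when absent), `resname` (3-letter code), `type` (`"ATOM"` or
#'   `"HETATM"`).
#' @slot frameIndices integer vector of original frame numbers (1-based),
#'   recording provenance through subsampling and jackknife subsetting.
#'
#' @seealso [readEnsemble()], [writeEnsemble()], [makeJackknifeSubsets()]
#' @exportClass StructuralEnsemble
setClass("StructuralEnsemble",
  representation(
    coords = "array",
    atoms = "data.frame",
    frameIndices = "integer"
  )
)

setValidity("StructuralEnsemble", function(object) {
  d <- dim(object@coords)
  msg <- character()
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an n_atoms x 3 x n_frames array")
  if (length(d) == 3L && d[3] < 1L)
    msg <- c(msg, "ensemble must contain at least one frame")
  if (length(d) == 3L && d[1] != nrow(object@atoms))
    msg <- c(msg, "atom table and coordinate array disagree on atom count")
  if (length(d) == 3L && length(object@frameIndices) != d[3])
    msg <- c(msg, "frameIndices length must equal the number of frames")
  if (any(!is.finite(object@coords)))
    msg <- c(msg, "coordinates must all be finite")
  need <- c("atom_name", "element", "chain", "resid", "icode", "resname", "type")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atom table must contain columns:",
                        paste(need, collapse = ", ")))
  else if (any(!nzchar(object@atoms$element)))
    msg <- c(msg, "every atom must have a non-empty element symbol")
  if (length(msg)) msg else TRUE
})

#' MassTable: atomic masses for center-of-mass computation
#'
#' Maps `(residue name, atom name)` pairs, with a per-element fallback, to
#' masses in atomic mass units. Lookup is total for any atom whose element
#' symbol is covered: a specific `(resname, atom)` entry wins, otherwise
#' the element mass is used.
#'
#' @slot specific named numeric vector; names are `"RESNAME|ATOMNAME"`.
#' @slot elements named numeric vector of element masses (amu).
#' @slot label provenance label (e.g. `"default-elements"` or a file path).
#'
#' @seealso [defaultMassTable()], [readMassTable()], [massOf()]
#' @exportClass MassTable
setClass("MassTable",
  representation(specific = "numeric", elements = "numeric", label = "character")
)

setValidity("MassTable", function(object) {
  if (any(c(object@specific, object@elements) <= 0))
    return("all masses must be positive")
  if (anyDuplicated(names(object@specific)) || anyDuplicated(names(object@elements)))
    return("duplicate mass-table keys")
  TRUE
})

#' SideChainSelection: the node set of a PSN
#'
#' The residues retained as network nodes, each with the atom indices that
#' contribute to its side-chain center of mass, plus the residues excluded
#' and why (`"excluded_resname"` for glycine and other excluded residue
#' types; `"no_sidechain_atoms"` when only backbone atoms are present).
#'
#' @slot nodes `data.frame` with one row per node: `label`
#'   (`chain:resid:resname`), `chain`, `resid`, `icode`, `resname`.
#' @slot atomIndices list (parallel to `nodes`) of integer indices into the
#'   ensemble atom table; never empty.
#' @slot excluded `data.frame` of excluded residues: `label`, `reason`.
#'
#' @seealso [selectSideChains()]
#' @exportClass SideChainSelection
setClass("SideChainSelection",
  representation(nodes = "data.frame", atomIndices = "list", excluded = "data.frame")
)

setValidity("SideChainSelection", function(object) {
  if (length(object@atomIndices) != nrow(object@nodes))
    return("one atom-index vector required per node")
  if (any(lengths(object@atomIndices) == 0L))
    return("no node may have an empty atom list")
  TRUE
})

#' ComSeries: side-chain centers of mass per frame
#'
#' @slot positions numeric array `n_nodes x 3 x n_frames` of center-of-mass
#'   coordinates in Angstrom.
#' @slot nodes node table as in [SideChainSelection-class].
#'
#' @seealso [computeComSeries()]
#' @exportClass ComSeries
setClass("ComSeries",
  representation(positions = "array", nodes = "data.frame")
)

setValidity("ComSeries", function(object) {
  d <- dim(object@positions)
  if (length(d) != 3L || d[2] != 3L)
    return("positions must be an n_nodes x 3 x n_frames array")
  if (d[1] != nrow(object@nodes))
    return("positions and node table disagree on node count")
  if (any(!is.finite(object@positions)))
    return("all center-of-mass positions must be finite")
  TRUE
})

#' PersistenceMatrix: per-pair contact persistence
#'
#' Symmetric matrix of contact persistence values: entry `(i, j)` is the
#' exact fraction of frames in which nodes `i` and `j` have center-of-mass
#' distance at or below the cutoff. The diagonal is zero by convention.
#'
#' @slot values symmetric numeric matrix in `[0, 1]`, node labels as
#'   dimnames.
#' @slot nodes node table.
#' @slot cutoff distance cutoff in Angstrom.
#' @slot nFramesUsed number of frames the fractions are over.
#'
#' @seealso [computePersistence()], [buildGraph()]
#' @exportClass PersistenceMatrix
setClass("PersistenceMatrix",
  representation(values = "matrix", nodes = "data.frame",
                 cutoff = "numeric", nFramesUsed = "integer")
)

setValidity("PersistenceMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v) || nrow(v) != nrow(object@nodes))
    return("values must be square with one row per node")
  if (!isTRUE(all.equal(v, t(v), tolerance = 0)))
    return("persistence matrix must be exactly symmetric")
  if (any(v < 0 | v > 1))
    return("persistence values must lie in [0, 1]")
  if (any(diag(v) != 0))
    return("diagonal must be zero by convention")
  if (object@cutoff <= 0)
    return("cutoff must be positive")
  TRUE
})

#' PSNGraph: the filtered, weighted protein structure network
#'
#' Nodes are residues (side-chain centers of mass); an edge is present when
#' the pair's contact persistence, expressed as a percentage, is at least
#' `pCrit` (and strictly positive). Edge weight is the persistence in
#' percent. Isolated nodes are retained.
#'
#' @slot nodes node table.
#' @slot edges `data.frame` with columns `from`, `to` (node labels, `from`
#'   preceding `to` in node order), `weight` (persistence percent).
#' @slot cutoff distance cutoff (Angstrom) used upstream.
#' @slot pCrit persistence filter in percent (0-100).
#'
#' @seealso [buildGraph()], [findHubs()], [connectedComponents()]
#' @exportClass PSNGraph
setClass("PSNGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 cutoff = "numeric", pCrit = "numeric")
)

setValidity("PSNGraph", function(object) {
  if (nrow(object@edges) &&
      any(object@edges$weight < object@pCrit))
    return("every edge weight must be >= pCrit")
  if (object@pCrit < 0 || object@pCrit > 100)
    return("pCrit must lie in [0, 100]")
  TRUE
})

#' HubTable: hub residues of a PSN
#'
#' Hubs are nodes whose degree (number of incident edges) reaches a minimum
#' threshold, 3 by default.
#'
#' @slot records `data.frame`: `node`, `chain`, `resid`, `resname`,
#'   `degree`, sorted by decreasing degree then node order.
#' @slot minHubDegree the threshold used.
#' @slot histogram named integer vector, count of hubs per degree.
#'
#' @seealso [findHubs()]
#' @exportClass HubTable
setClass("HubTable",
  representation(records = "data.frame", minHubDegree = "integer",
                 histogram = "integer")
)

setValidity("HubTable", function(object) {
  if (nrow(object@records) && any(object@records$degree < object@minHubDegree))
    return("every hub must have degree >= minHubDegree")
  if (sum(object@histogram) != nrow(object@records))
    return("histogram counts must sum to the number of hub records")
  TRUE
})

#' ComponentPartition: connected components of a PSN
#'
#' The maximal sets of mutually reachable nodes, ordered by decreasing
#' size; ties are broken by the smallest member's `(chain, resid, icode)`
#' so that component ranks are reproducible across runs. Singletons count
#' as components.
#'
#' @slot members list of character vectors (node labels), rank 1 first.
#' @slot sizes integer vector of component sizes, non-increasing.
#' @slot membership named integer vector mapping node label to component
#'   rank.
#'
#' @seealso [connectedComponents()]
#' @exportClass ComponentPartition
setClass("ComponentPartition",
  representation(members = "list", sizes = "integer", membership = "integer")
)

setValidity("ComponentPartition", function(object) {
  if (length(object@members) != length(object@sizes))
    return("one size per component required")
  if (any(lengths(object@members) != object@sizes))
    return("sizes must match member counts")
  if (is.unsorted(rev(object@sizes)))
    return("sizes must be non-increasing with rank")
  all_nodes <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(all_nodes))
    return("components must be disjoint")
  if (length(object@membership) != length(all_nodes))
    return("membership must cover exactly the partitioned nodes")
  TRUE
})

#' ResampleScheme: the jackknife leave-block-out design
#'
#' Subset `i` of `n` discards the `i`-th contiguous block of
#' `floor(n_frames / n)` frames; with the default `n = 10` each subset
#' retains 90\% of the frames. Remainder frames (when `n_frames` is not a
#' multiple of `n`) are kept in every subset.
#'
#' @slot nSubsets number of subsets.
#' @slot kept list of integer vectors: positions (into the parent
#'   ensemble's frame order) retained by each subset.
#' @slot blocks `data.frame` with `start`, `end` (1-based, inclusive) of
#'   each discarded block.
#'
#' @seealso [makeJackknifeSubsets()]
#' @exportClass ResampleScheme
setClass("ResampleScheme",
  representation(nSubsets = "integer", kept = "list", blocks = "data.frame")
)

#' JackknifeEstimates: observables with jackknife standard errors
#'
#' For each network observable: the value on the full ensemble, the
#' per-subset values, their mean, and the jackknife standard error
#' `SE = {((n-1)/n) * sum_i (theta_i - theta_bar)^2}^(1/2)`.
#'
#' @slot estimates `data.frame`: `observable`, `full_value`, `theta_dot`,
#'   `se`, `n`.
#' @slot theta numeric matrix, one row per observable, one column per
#'   subset.
#'
#' @seealso [jackknifeObservables()], [jackknifeSE()]
#' @exportClass JackknifeEstimates
setClass("JackknifeEstimates",
  representation(estimates = "data.frame", theta = "matrix")
)

setValidity("JackknifeEstimates", function(object) {
  if (nrow(object@theta) != nrow(object@estimates))
    return("one theta row per observable required")
  if (any(object@estimates$se < 0))
    return("standard errors must be non-negative")
  TRUE
})

#' ScanConfig: parameters of a distance-cutoff scan
#'
#' Defaults follow common PSN-MD practice: cutoffs 4.0-6.0 Angstrom in 0.5
#' steps, persistence filter 20\%, 10 jackknife subsets, hub threshold 3,
#' top 5 components reported, glycine excluded from the node set.
#'
#' @slot cutoffs strictly increasing positive cutoffs (Angstrom).
#' @slot pCrit persistence filter, percent.
#' @slot nSubsets jackknife subsets.
#' @slot minHubDegree minimum degree for a hub.
#' @slot topK number of largest components tracked.
#' @slot excludedResnames residue types excluded from the node set.
#' @slot minSeqSeparation minimum |resid difference| within a chain for a
#'   pair to be eligible as an edge (0 = no restriction).
#'
#' @seealso [scanConfig()], [runScan()]
#' @exportClass ScanConfig
setClass("ScanConfig",
  representation(cutoffs = "numeric", pCrit = "numeric", nSubsets = "integer",
                 minHubDegree = "integer", topK = "integer",
                 excludedResnames = "character", minSeqSeparation = "integer")
)

setValidity("ScanConfig", function(object) {
  if (any(object@cutoffs <= 0) || is.unsorted(object@cutoffs, strictly = TRUE))
    return("cutoffs must be strictly positive and strictly increasing")
  if (object@pCrit < 0 || object@pCrit > 100)
    return("pCrit must lie in [0, 100]")
  if (object@nSubsets < 2L)
    return("nSubsets must be at least 2")
  TRUE
})

#' CutoffScanResult: per-cutoff network properties with jackknife errors
#'
#' @slot config the [ScanConfig-class] used.
#' @slot nodes the node table shared by all cutoffs.
#' @slot perCutoff named list (one entry per cutoff) of lists with
#'   elements `cutoff`, `graph` ([PSNGraph-class]), `hubs`
#'   ([HubTable-class]), `components` ([ComponentPartition-class]),
#'   `jackknife` ([JackknifeEstimates-class]), `nEdges`,
#'   `nNonSingletonComponents`, `fractionLargestComponent`.
#'
#' @seealso [runScan()], [writeReport()]
#' @exportClass CutoffScanResult
setClass("CutoffScanResult",
  representation(config = "ScanConfig", nodes = "data.frame", perCutoff = "list")
)

#' ContactSchedule: a synthetic ensemble with programmed persistence
#'
#' Specifies, for a small family of 3D-embeddable contact topologies
#' (disjoint pairs, a chain, or a star), exactly which frames each pair is
#' in contact in. The generated ensemble places pairs at `dIn` in their
#' contact frames and at or beyond `dOut` otherwise, so that downstream
#' persistence equals the programmed fraction k/N exactly.
#'
#' @slot family `"pairs"`, `"chain"`, or `"star"`.
#' @slot nNodes number of pseudo-residues.
#' @slot nFrames number of frames N.
#' @slot pairs `data.frame` with `i`, `j` (node indices) and a list column
#'   `frames` of contact-frame index vectors.
#' @slot dIn contact distance (Angstrom), below every cutoff of interest.
#' @slot dOut separation distance (Angstrom), above every cutoff.
#'
#' @seealso [contactSchedule()], [generateScheduleEnsemble()]
#' @exportClass ContactSchedule
setClass("ContactSchedule",
  representation(family = "character", nNodes = "integer", nFrames = "integer",
                 pairs = "data.frame", dIn = "numeric", dOut = "numeric")
)

setValidity("ContactSchedule", function(object) {
  if (object@dIn >= object@dOut)
    return("dIn must be strictly less than dOut")
  if (nrow(object@pairs)) {
    ij <- c(object@pairs$i, object@pairs$j)
    if (any(ij < 1L | ij > object@nNodes))
      return("pair node indices out of range")
    bad <- vapply(object@pairs$frames, function(f)
      length(f) && (min(f) < 1L || max(f) > object@nFrames), logical(1))
    if (any(bad))
      return("contact frames out of range")
  }
  TRUE
})
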