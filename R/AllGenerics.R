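#' Number of frames in an ensemble-like object
#' @param x a [StructuralEnsemble-class] or [ComSeries-class]
#' @return integer
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Original frame indices (provenance)
#' @param x a [StructuralEnsemble-class]
#' @return integer vector of 1-based original frame numbers
#' @export
setGeneric("frameIndices", function(x) standardGeneric("frameIndices"))

#' Per-atom metadata table
#' @param x a [StructuralEnsemble-class]
#' @return data.frame
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Coordinates of an ensemble-like object
#' @param x a [StructuralEnsemble-class] or [ComSeries-class]
#' @return numeric array `n x 3 x n_frames`
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Node table of a network-stage object
#' @param x a [SideChainSelection-class], [ComSeries-class],
#'   [PersistenceMatrix-class], [PSNGraph-class] or [CutoffScanResult-class]
#' @return data.frame with columns `label`, `chain`, `resid`, `icode`,
#'   `resname`
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' Edge table of a PSN
#' @param x a [PSNGraph-class]
#' @return data.frame with columns `from`, `to`, `weight`
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Persistence values
#' @param x a [PersistenceMatrix-class]
#' @return symmetric numeric matrix of fractions in `[0, 1]`
#' @export
setGeneric("persistenceValues", function(x) standardGeneric("persistenceValues"))

#' Distance cutoff (Angstrom) attached to an object
#' @param x a [PersistenceMatrix-class] or [PSNGraph-class]
#' @return numeric scalar
#' @export
setGeneric("cutoff", function(x) standardGeneric("cutoff"))

#' Persistence filter (percent) attached to a PSN
#' @param x a [PSNGraph-class]
#' @return numeric scalar in `[0, 100]`
#' @export
setGeneric("pCrit", function(x) standardGeneric("pCrit"))

#' Hub records
#' @param x a [HubTable-class]
#' @return data.frame: `node`, `chain`, `resid`, `resname`, `degree`
#' @export
setGeneric("hubs", function(x) standardGeneric("hubs"))

#' Degree histogram of a hub table
#' @param x a [HubTable-class]
#' @return named integer vector (degree -> count)
#' @export
setGeneric("degreeHistogram", function(x) standardGeneric("degreeHistogram"))

#' Component member sets
#' @param x a [ComponentPartition-class]
#' @return list of character vectors, rank 1 (largest) first
#' @export
setGeneric("componentMembers", function(x) standardGeneric("componentMembers"))

#' Component sizes
#' @param x a [ComponentPartition-class]
#' @return non-increasing integer vector
#' @export
setGeneric("componentSizes", function(x) standardGeneric("componentSizes"))

#' Jackknife estimate table
#' @param x a [JackknifeEstimates-class]
#' @return data.frame: `observable`, `full_value`, `theta_dot`, `se`, `n`
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' Per-subset observable values
#' @param x a [JackknifeEstimates-class]
#' @return numeric matrix, one row per observable, one column per subset
#' @export
setGeneric("thetaValues", function(x) standardGeneric("thetaValues"))
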