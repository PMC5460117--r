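# Backbone atom names excluded from every side chain: the heavy backbone
# (N, CA, C, O, terminal OXT/OT1/OT2) and its hydrogens (amide H/H1-H3,
# alpha HA, and glycine's HA2/HA3).
.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2",
                     "H", "H1", "H2", "H3", "HA", "HA2", "HA3")

#' Select side-chain atoms and define the PSN node set
#'
#' Every protein residue (ATOM records) that is not of an excluded residue
#' type and has at least one non-backbone atom becomes a network node; its
#' side chain is all atoms not named among the backbone names
#' (N, CA, C, O, OXT and their hydrogens). Glycine is excluded by default:
#' it has no side-chain heavy atom, so a side-chain center of mass is not
#' defined for it. Hydrogens, when present in the input, are part of the
#' side chain; united-atom inputs simply lack them. Non-standard residues
#' are retained if they have non-backbone ATOM-record atoms.
#'
#' Excluded residues are reported with a reason: `"excluded_resname"` or
#' `"no_sidechain_atoms"` (e.g. truncated side chains).
#'
#' @param ensemble a [StructuralEnsemble-class]
#' @param excludedResnames residue types never used as nodes
#'   (default `"GLY"`)
#' @return a [SideChainSelection-class]
#' @examples
#' pdb <- system.file("extdata", "tripeptide.pdb", package = "PSNet")
#' sel <- selectSideChains(readEnsemble(pdb))
#' nodes(sel)
#' @export
selectSideChains <- function(ensemble, excludedResnames = "GLY") {
  stopifnot(is(ensemble, "StructuralEnsemble"))
  at <- ensemble@atoms
  prot <- which(at$type == "ATOM")
  if (!length(prot))
    stop("empty network: input contains no ATOM records")

  rid <- paste(at$chain[prot], at$resid[prot], at$icode[prot], sep = "\r")
  first <- !duplicated(rid)
  res_order <- rid[first]

  excludedResnames <- toupper(excludedResnames)
  nodes <- list()
  atom_idx <- list()
  excluded <- list()
  for (r in res_order) {
    ai <- prot[rid == r]
    resname <- at$resname[ai[1]]
    label <- .node_label(at$chain[ai[1]], at$resid[ai[1]],
                         at$icode[ai[1]], resname)
    if (toupper(resname) %in% excludedResnames) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(label = label, reason = "excluded_resname",
                   stringsAsFactors = FALSE)
      next
    }
    sc <- ai[!(toupper(at$atom_name[ai]) %in% .BACKBONE_NAMES)]
    if (!length(sc)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(label = label, reason = "no_sidechain_atoms",
                   stringsAsFactors = FALSE)
      next
    }
    nodes[[length(nodes) + 1L]] <- data.frame(
      label = label, chain = at$chain[ai[1]], resid = at$resid[ai[1]],
      icode = at$icode[ai[1]], resname = resname, stringsAsFactors = FALSE)
    atom_idx[[length(atom_idx) + 1L]] <- sc
  }

  if (!length(nodes))
    stop("empty network: no residue has side-chain atoms after selection")

  node_df <- do.call(rbind, nodes)
  rownames(node_df) <- NULL
  excl_df <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(label = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  rownames(excl_df) <- NULL
  new("SideChainSelection", nodes = node_df, atomIndices = atom_idx,
      excluded = excl_df)
}

.node_label <- function(chain, resid, icode, resname) {
  ch <- ifelse(nzchar(chain), chain, "_")
  paste0(ch, ":", resid, ifelse(nzchar(icode), icode, ""), ":", resname)
}

#' @rdname nodes
#' @export
setMethod("nodes", "SideChainSelection", function(x) x@nodes)

#' Residues excluded from the node set
#' @param selection a [SideChainSelection-class]
#' @return data.frame with columns `label`, `reason`
#' @export
excludedResidues <- function(selection) {
  stopifnot(is(selection, "SideChainSelection"))
  selection@excluded
}

#' Atom indices contributing to each node
#' @param selection a [SideChainSelection-class]
#' @return named list of integer vectors (one per node)
#' @export
nodeAtomIndices <- function(selection) {
  stopifnot(is(selection, "SideChainSelection"))
  stats::setNames(selection@atomIndices, selection@nodes$label)
}

setMethod("show", "SideChainSelection", function(object) {
  cat("SideChainSelection:", nrow(object@nodes), "nodes,",
      nrow(object@excluded), "excluded residues\n")
  if (nrow(object@excluded)) {
    tb <- table(object@excluded$reason)
    for (r in names(tb)) cat("  ", r, ": ", tb[[r]], "\n", sep = "")
  }
})
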