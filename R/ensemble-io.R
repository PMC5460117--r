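#' Read a structural ensemble
#'
#' Reads a multi-frame structural ensemble from a multi-model PDB file
#' (MODEL/ENDMDL records; a single-model file yields a one-frame ensemble)
#' or from a binary DCD trajectory paired with a PDB topology. XTC/TRR
#' trajectories are not supported and must be converted to DCD or
#' multi-model PDB beforehand.
#'
#' Element symbols missing from the file are inferred from the atom name
#' (leading digits stripped, first letter taken), so that mass lookup is
#' total.
#'
#' @param path path to the multi-model PDB or DCD file.
#' @param topology path to a single-model PDB supplying the atom table;
#'   required for DCD input, ignored for PDB input.
#' @param frameStride keep every `frameStride`-th frame, starting from the
#'   first (default 1 = all frames). Original frame numbers are recorded
#'   in `frameIndices`.
#' @return a [StructuralEnsemble-class]
#' @examples
#' pdb <- system.file("extdata", "tripeptide.pdb", package = "PSNet")
#' ens <- readEnsemble(pdb)
#' nFrames(ens)
#' @export
readEnsemble <- function(path, topology = NULL, frameStride = 1L) {
  stopifnot(length(path) == 1L, is.character(path))
  if (!file.exists(path))
    stop("file not found: ", path)
  frameStride <- as.integer(frameStride)
  if (is.na(frameStride) || frameStride < 1L)
    stop("frameStride must be a positive integer")

  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xtc", "trr"))
    stop("XTC/TRR trajectories are not supported; convert to DCD or ",
         "multi-model PDB first")

  if (ext == "dcd") {
    if (is.null(topology))
      stop("a PDB topology is required to read a binary DCD trajectory")
    top <- tryCatch(bio3d::read.pdb(topology, verbose = FALSE),
                    error = function(e) stop("unreadable topology file '",
                                             topology, "': ",
                                             conditionMessage(e)))
    xyz <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                    error = function(e) stop("unreadable DCD file '", path,
                                             "': ", conditionMessage(e)))
    if (ncol(xyz) != 3L * nrow(top$atom))
      stop("malformed ensemble: trajectory atom count (", ncol(xyz) / 3,
           ") does not match topology (", nrow(top$atom), ")")
    atom_tab <- top$atom
  } else {
    pdb <- withCallingHandlers(
      tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
               error = function(e)
                 stop("unreadable PDB file '", path, "': ",
                      conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        # bio3d recycles coordinates when MODEL blocks differ in length
        if (grepl("multiple of the number of rows|unequal",
                  conditionMessage(w)))
          stop("malformed ensemble in '", path,
               "': models differ in atom count", call. = FALSE)
        invokeRestart("muffleWarning")
      })
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    atom_tab <- pdb$atom
    if (ncol(xyz) != 3L * nrow(atom_tab))
      stop("malformed ensemble in '", path,
           "': models differ in atom count")
  }

  n_total <- nrow(xyz)
  if (n_total < 1L) stop("empty input: no frames in '", path, "'")
  keep <- seq.int(1L, n_total, by = frameStride)

  atoms <- data.frame(
    atom_name = trimws(atom_tab$elety),
    element = .infer_elements(atom_tab$elesy, atom_tab$elety),
    chain = ifelse(is.na(atom_tab$chain), "", atom_tab$chain),
    resid = as.integer(atom_tab$resno),
    icode = ifelse(is.na(atom_tab$insert), "", atom_tab$insert),
    resname = trimws(atom_tab$resid),
    type = atom_tab$type,
    stringsAsFactors = FALSE
  )

  n_atoms <- nrow(atoms)
  co <- array(NA_real_, dim = c(n_atoms, 3L, length(keep)))
  for (k in seq_along(keep)) {
    co[, , k] <- matrix(xyz[keep[k], ], ncol = 3L, byrow = TRUE)
  }
  new("StructuralEnsemble", coords = co, atoms = atoms,
      frameIndices = as.integer(keep))
}

# Element inference: use the PDB element column when present, otherwise
# strip leading digits from the atom name and take the first letter
# (covers hydrogens named "1HB" etc. and all standard protein atoms).
.infer_elements <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- !nzchar(el)
  if (any(miss)) {
    nm <- toupper(gsub("^[0-9']+", "", trimws(elety[miss])))
    el[miss] <- substr(nm, 1L, 1L)
  }
  el
}

#' Write an ensemble as a multi-model PDB file
#'
#' Emits standard fixed-width ATOM/HETATM records wrapped in MODEL/ENDMDL
#' blocks, with coordinates at the format's 3-decimal precision.
#' Round-trips through [readEnsemble()] to that precision.
#'
#' @param ensemble a [StructuralEnsemble-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeEnsemble <- function(ensemble, path) {
  stopifnot(is(ensemble, "StructuralEnsemble"))
  at <- ensemble@atoms
  nm <- at$atom_name
  # PDB column-13 convention: names of <4 chars start in column 14
  nm4 <- ifelse(nchar(nm) >= 4L, substr(nm, 1L, 4L), sprintf(" %-3s", nm))
  con <- file(path, open = "wt")
  on.exit(close(con))
  nf <- dim(ensemble@coords)[3]
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ensemble@coords[, , f, drop = FALSE]
    lines <- sprintf(
      "%-6s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(at$type == "HETATM", "HETATM", "ATOM"),
      seq_len(nrow(at)) %% 100000L, nm4, at$resname,
      ifelse(nzchar(at$chain), at$chain, " "),
      at$resid, ifelse(nzchar(at$icode), at$icode, " "),
      xyz[, 1L, 1L], xyz[, 2L, 1L], xyz[, 3L, 1L],
      1.0, 0.0, at$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Extract a subset of frames from an ensemble
#'
#' @param ensemble a [StructuralEnsemble-class]
#' @param frames integer positions (into the current frame order) to keep,
#'   order preserved
#' @return a [StructuralEnsemble-class] whose `frameIndices` carry the
#'   original frame numbers of the kept frames
#' @export
subsetFrames <- function(ensemble, frames) {
  stopifnot(is(ensemble, "StructuralEnsemble"))
  frames <- as.integer(frames)
  nf <- dim(ensemble@coords)[3]
  if (length(frames) < 1L || any(frames < 1L | frames > nf))
    stop("frame positions out of range 1..", nf)
  new("StructuralEnsemble",
      coords = ensemble@coords[, , frames, drop = FALSE],
      atoms = ensemble@atoms,
      frameIndices = ensemble@frameIndices[frames])
}

#' @rdname nFrames
#' @export
setMethod("nFrames", "StructuralEnsemble", function(x) dim(x@coords)[3])

#' @rdname frameIndices
#' @export
setMethod("frameIndices", "StructuralEnsemble", function(x) x@frameIndices)

#' @rdname atoms
#' @export
setMethod("atoms", "StructuralEnsemble", function(x) x@atoms)

#' @rdname coords
#' @export
setMethod("coords", "StructuralEnsemble", function(x) x@coords)

setMethod("show", "StructuralEnsemble", function(object) {
  nres <- nrow(unique(object@atoms[, c("chain", "resid", "icode")]))
  cat("StructuralEnsemble:", dim(object@coords)[1], "atoms,",
      nres, "residues,", dim(object@coords)[3], "frames\n")
})
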