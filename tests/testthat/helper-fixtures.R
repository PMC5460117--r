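# Shared fixture builders: tiny ensembles, node tables and PSN graphs
# constructed in code.

toy_nodes <- function(n, chain = "A", resname = "ALA") {
  data.frame(label = paste0(chain, ":", seq_len(n), ":", resname),
             chain = chain, resid = seq_len(n), icode = "",
             resname = resname, stringsAsFactors = FALSE)
}

# ComSeries from an n_nodes x 3 x n_frames position array
com_series <- function(positions) {
  new("ComSeries", positions = positions, nodes = toy_nodes(dim(positions)[1]))
}

# PSNGraph from an explicit edge list over n toy nodes (indices i, j)
toy_graph <- function(n, i = integer(0), j = integer(0), weight = 100,
                      cutoff = 5, pCrit = 20) {
  nd <- toy_nodes(n)
  e <- data.frame(from = nd$label[i], to = nd$label[j],
                  weight = rep_len(weight, length(i)),
                  stringsAsFactors = FALSE)
  new("PSNGraph", nodes = nd, edges = e, cutoff = cutoff, pCrit = pCrit)
}

# Random PSNGraph: n nodes, each unordered pair an edge with prob density
random_graph <- function(seed, max_nodes = 50L, max_density = 0.3) {
  set.seed(seed)
  n <- sample(2:max_nodes, 1L)
  density <- runif(1L, 0, max_density)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < density
  toy_graph(n, pairs[keep, 1L], pairs[keep, 2L])
}

# Single-atom-per-residue ensemble from an n x 3 x n_frames array
atom_ensemble <- function(co, resname = "ALA", atom_name = "CB",
                          element = "C") {
  n <- dim(co)[1]
  atoms <- data.frame(atom_name = atom_name, element = element,
                      chain = "A", resid = seq_len(n), icode = "",
                      resname = resname, type = "ATOM",
                      stringsAsFactors = FALSE)
  new("StructuralEnsemble", coords = co, atoms = atoms,
      frameIndices = seq_len(dim(co)[3]))
}

# Multi-atom single-residue ensemble (for center-of-mass unit tests)
residue_ensemble <- function(xyz, atom_names, elements, resname = "XXX",
                             resid = 1L, n_frames = 1L) {
  co <- array(rep(xyz, n_frames), dim = c(nrow(xyz), 3L, n_frames))
  atoms <- data.frame(atom_name = atom_names, element = elements,
                      chain = "A", resid = resid, icode = "",
                      resname = resname, type = "ATOM",
                      stringsAsFactors = FALSE)
  new("StructuralEnsemble", coords = co, atoms = atoms,
      frameIndices = seq_len(n_frames))
}

# Apply one global rigid motion (rotation matrix R, translation t) to
# every frame of an ensemble
transform_ensemble <- function(ens, R, t) {
  co <- coords(ens)
  for (f in seq_len(dim(co)[3])) {
    co[, , f] <- co[, , f] %*% t(R) +
      matrix(t, dim(co)[1], 3L, byrow = TRUE)
  }
  new("StructuralEnsemble", coords = co, atoms = atoms(ens),
      frameIndices = frameIndices(ens))
}

# A uniformly random proper rotation matrix (QR with positive diagonal)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9L), 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# Write a minimal multi-model PDB from a list of per-frame coordinate
# matrices (one CB atom per residue), for malformed-input tests
write_raw_pdb <- function(path, frames, resnames = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frames[[f]]
    rn <- if (is.null(resnames)) rep("ALA", nrow(xyz)) else resnames
    for (i in seq_len(nrow(xyz))) {
      writeLines(sprintf(
        "ATOM  %5d  CB  %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, rn[i], i, xyz[i, 1], xyz[i, 2], xyz[i, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}
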