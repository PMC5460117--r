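#' Specify a contact schedule for a synthetic ensemble
#'
#' A contact schedule programs, for selected node pairs, exactly which of
#' the `nFrames` frames the pair is "in contact" in (at distance `dIn`);
#' in all other frames, and for all unscheduled pairs, distances are at
#' least `dOut`. Downstream persistence is then exactly `k/N` for a pair
#' scheduled in `k` of `N` frames. Only 3D-embeddable topologies are
#' accepted:
#' \describe{
#'   \item{`"pairs"`}{disjoint pairs — no node may appear in more than
#'     one pair;}
#'   \item{`"chain"`}{contacts only between consecutive nodes `(i, i+1)`;
#'     requires `2 * dIn >= dOut` so that second neighbours stay
#'     separated;}
#'   \item{`"star"`}{one common center in every pair; up to 4 leaves are
#'     placed on tetrahedral directions (leaf separation
#'     `sqrt(8/3) * dIn`), up to 6 on the coordinate axes (separation
#'     `sqrt(2) * dIn`); the relevant factor times `dIn` must be at least
#'     `dOut`.}
#' }
#'
#' @param family `"pairs"`, `"chain"` or `"star"`
#' @param nNodes number of pseudo-residues
#' @param nFrames number of frames N
#' @param pairs `data.frame` with integer columns `i`, `j` and either a
#'   list column `frames` (explicit contact-frame indices) or an integer
#'   column `k` (the pair is in contact in frames `1..k`)
#' @param dIn contact distance, Angstrom (keep at least 1 Angstrom below
#'   every cutoff of interest, so PDB 3-decimal rounding cannot flip a
#'   contact)
#' @param dOut separation distance, Angstrom (at least 1 Angstrom above
#'   every cutoff)
#' @return a [ContactSchedule-class]
#' @examples
#' sched <- contactSchedule("pairs", nNodes = 4, nFrames = 10,
#'                          pairs = data.frame(i = c(1, 3), j = c(2, 4),
#'                                             k = c(3, 10)))
#' @export
contactSchedule <- function(family = c("pairs", "chain", "star"),
                            nNodes, nFrames, pairs,
                            dIn = 4.0, dOut = 12.0) {
  family <- match.arg(family)
  nNodes <- as.integer(nNodes)
  nFrames <- as.integer(nFrames)
  if (!is.data.frame(pairs) || !all(c("i", "j") %in% names(pairs)))
    stop("pairs must be a data.frame with columns i, j")
  if (!"frames" %in% names(pairs)) {
    if (!"k" %in% names(pairs))
      stop("pairs needs either a 'frames' list column or a 'k' column")
    pairs$frames <- lapply(as.integer(pairs$k), function(k) {
      if (k < 0L || k > nFrames)
        stop("k must lie in 0..nFrames")
      if (k == 0L) integer(0) else seq_len(k)
    })
    pairs$k <- NULL
  } else {
    pairs$frames <- lapply(pairs$frames, as.integer)
  }
  pairs$i <- as.integer(pairs$i)
  pairs$j <- as.integer(pairs$j)
  if (any(pairs$i == pairs$j)) stop("self-pairs are not allowed")

  .check_realizable(family, nNodes, pairs, dIn, dOut)
  new("ContactSchedule", family = family, nNodes = nNodes,
      nFrames = nFrames, pairs = pairs, dIn = dIn, dOut = dOut)
}

.star_directions <- function(m) {
  if (m <= 4L) {
    d <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
      sqrt(3)
    d[seq_len(m), , drop = FALSE]
  } else if (m <= 6L) {
    d <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
    d[seq_len(m), , drop = FALSE]
  } else {
    stop("unrealizable schedule: star family supports at most 6 leaves")
  }
}

.check_realizable <- function(family, nNodes, pairs, dIn, dOut) {
  if (family == "pairs") {
    ij <- c(pairs$i, pairs$j)
    if (anyDuplicated(ij))
      stop("unrealizable schedule: 'pairs' family requires disjoint pairs")
  } else if (family == "chain") {
    if (nrow(pairs) && any(abs(pairs$i - pairs$j) != 1L))
      stop("unrealizable schedule: 'chain' family allows only ",
           "consecutive (i, i+1) pairs")
    if (anyDuplicated(pmin(pairs$i, pairs$j)))
      stop("unrealizable schedule: duplicate chain pair")
    if (2 * dIn < dOut)
      stop("unrealizable schedule: chain family needs 2*dIn >= dOut ",
           "to keep second neighbours separated")
  } else if (family == "star") {
    if (!nrow(pairs)) return(invisible(TRUE))
    counts <- table(c(pairs$i, pairs$j))
    center <- as.integer(names(counts)[counts == nrow(pairs)])
    if (length(center) != 1L && nrow(pairs) > 1L)
      stop("unrealizable schedule: 'star' family needs one common ",
           "center in every pair")
    if (nrow(pairs) == 1L) center <- pairs$i[1L]
    m <- nrow(pairs)
    factor <- if (m <= 4L) sqrt(8 / 3) else if (m <= 6L) sqrt(2) else
      stop("unrealizable schedule: star family supports at most 6 leaves")
    if (factor * dIn < dOut)
      stop("unrealizable schedule: star leaves would come within dOut ",
           "(need ", round(factor, 3), "*dIn >= dOut)")
  }
  invisible(TRUE)
}

#' Generate a synthetic ensemble from a contact schedule
#'
#' Emits a [StructuralEnsemble-class] of single-atom pseudo-residues (one
#' carbon named CB per residue, so the side-chain center of mass equals
#' the atom position) realizing the schedule's per-frame contact geometry
#' exactly. The generated geometry is verified frame by frame before
#' returning: scheduled pairs sit exactly at `dIn` in their contact
#' frames and at or beyond `dOut` otherwise; all other pairs never come
#' closer than `dOut`.
#'
#' @param schedule a [ContactSchedule-class]
#' @return a [StructuralEnsemble-class] with `nNodes` residues and
#'   `nFrames` frames
#' @export
generateScheduleEnsemble <- function(schedule) {
  stopifnot(is(schedule, "ContactSchedule"))
  nN <- schedule@nNodes
  nF <- schedule@nFrames
  dIn <- schedule@dIn
  dOut <- schedule@dOut
  pr <- schedule@pairs
  co <- array(0, dim = c(nN, 3L, nF))

  if (schedule@family == "pairs") {
    S <- dIn + 2 * dOut
    base_x <- (seq_len(nN) - 1L) * S
    for (f in seq_len(nF)) {
      co[, 1L, f] <- base_x
      if (nrow(pr)) for (p in seq_len(nrow(pr))) {
        gap <- if (f %in% pr$frames[[p]]) dIn else dOut
        co[pr$j[p], , f] <- c(base_x[pr$i[p]] + gap, 0, 0)
      }
    }
  } else if (schedule@family == "chain") {
    lo <- pmin(pr$i, pr$j)
    for (f in seq_len(nF)) {
      x <- numeric(nN)
      for (k in seq_len(nN - 1L)) {
        p <- if (nrow(pr)) match(k, lo) else NA_integer_
        gap <- if (!is.na(p) && f %in% pr$frames[[p]]) dIn else dOut
        x[k + 1L] <- x[k] + gap
      }
      co[, 1L, f] <- x
    }
  } else { # star
    counts <- table(c(pr$i, pr$j))
    center <- as.integer(names(counts)[counts == nrow(pr)])
    if (length(center) != 1L) center <- pr$i[1L]
    leaves <- ifelse(pr$i == center, pr$j, pr$i)
    dirs <- .star_directions(nrow(pr))
    others <- setdiff(seq_len(nN), c(center, leaves))
    for (f in seq_len(nF)) {
      co[center, , f] <- c(0, 0, 0)
      for (p in seq_len(nrow(pr))) {
        r <- if (f %in% pr$frames[[p]]) dIn else dOut
        co[leaves[p], , f] <- r * dirs[p, ]
      }
      if (length(others))
        co[others, 1L, f] <- 3 * dOut + seq_along(others) * (2 * dOut)
    }
  }

  .verify_schedule_geometry(co, schedule)

  atoms <- data.frame(
    atom_name = "CB", element = "C", chain = "A",
    resid = seq_len(nN), icode = "", resname = "ALA", type = "ATOM",
    stringsAsFactors = FALSE)
  new("StructuralEnsemble", coords = co, atoms = atoms,
      frameIndices = seq_len(nF))
}

# Post-generation audit: every realized distance must honour the
# schedule. Guards against unanticipated geometric collisions.
.verify_schedule_geometry <- function(co, schedule) {
  pr <- schedule@pairs
  key <- if (nrow(pr))
    paste(pmin(pr$i, pr$j), pmax(pr$i, pr$j)) else character(0)
  tol <- 1e-9
  for (f in seq_len(schedule@nFrames)) {
    D <- as.matrix(stats::dist(co[, , f]))
    for (p in seq_len(nrow(pr))) {
      d <- D[pr$i[p], pr$j[p]]
      if (f %in% pr$frames[[p]]) {
        if (abs(d - schedule@dIn) > tol)
          stop("generator error: scheduled contact not at dIn (frame ",
               f, ", pair ", pr$i[p], "-", pr$j[p], ")")
      } else if (d < schedule@dOut - tol) {
        stop("generator error: scheduled pair closer than dOut out of ",
             "contact (frame ", f, ")")
      }
    }
    ut <- which(upper.tri(D), arr.ind = TRUE)
    other <- ut[!(paste(ut[, 1], ut[, 2]) %in% key), , drop = FALSE]
    if (nrow(other) && any(D[other] < schedule@dOut - tol))
      stop("generator error: unscheduled pair closer than dOut (frame ",
           f, ")")
  }
  invisible(TRUE)
}

#' Generate a protein-like compact-chain ensemble
#'
#' Builds a self-avoiding random walk collapsed into a sphere of
#' protein-like density and perturbs it with per-frame Gaussian jitter.
#' Each residue carries a single CB pseudo-atom standing in for its
#' side-chain center of mass. The defaults emulate globular-protein
#' packing of side-chain centers: sequential spacing 5.5 Angstrom
#' (typical distance between side-chain centers of mass of sequence
#' neighbours), excluded-volume minimum of 4.2 Angstrom between
#' non-adjacent residues, confinement radius from 135 cubic Angstrom per
#' residue, and positional jitter of 0.5 Angstrom. Under these
#' conditions the network fragments at a 4 Angstrom contact cutoff and
#' percolates into a single dominant component by 6 Angstrom.
#'
#' Deterministic given `seed`; the caller's RNG state is restored on
#' exit.
#'
#' @param nRes number of residues (>= 10)
#' @param nFrames number of frames
#' @param bondLength sequential spacing of the walk, Angstrom
#' @param jitterSd per-frame, per-coordinate Gaussian jitter sd,
#'   Angstrom; 0 gives identical frames
#' @param seed integer RNG seed
#' @param minSeparation excluded-volume distance between non-adjacent
#'   residues, Angstrom
#' @param residueVolume packing volume per residue, cubic Angstrom
#'   (sets the confinement radius)
#' @return a [StructuralEnsemble-class]
#' @export
generateCompactChain <- function(nRes, nFrames, bondLength = 5.5,
                                 jitterSd = 0.5, seed = 1L,
                                 minSeparation = 4.2,
                                 residueVolume = 135) {
  nRes <- as.integer(nRes)
  nFrames <- as.integer(nFrames)
  if (is.na(nRes) || nRes < 10L) stop("nRes must be at least 10")
  if (jitterSd < 0) stop("jitterSd must be non-negative")

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(as.integer(seed))

  R <- max(bondLength, (3 * nRes * residueVolume / (4 * pi))^(1 / 3))
  base <- .self_avoiding_walk(nRes, bondLength, minSeparation, R)

  co <- array(NA_real_, dim = c(nRes, 3L, nFrames))
  for (f in seq_len(nFrames)) {
    jit <- if (jitterSd > 0)
      matrix(stats::rnorm(nRes * 3L, sd = jitterSd), ncol = 3L)
    else matrix(0, nRes, 3L)
    co[, , f] <- base + jit
  }

  atoms <- data.frame(
    atom_name = "CB", element = "C", chain = "A",
    resid = seq_len(nRes), icode = "", resname = "ALA", type = "ATOM",
    stringsAsFactors = FALSE)
  new("StructuralEnsemble", coords = co, atoms = atoms,
      frameIndices = seq_len(nFrames))
}

.random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

.self_avoiding_walk <- function(n, bond, min_sep, radius,
                                max_restarts = 100L, max_tries = 300L) {
  for (restart in seq_len(max_restarts)) {
    pos <- matrix(NA_real_, n, 3L)
    pos[1L, ] <- .random_unit_vector() * stats::runif(1L, 0, radius / 3)
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- pos[i - 1L, ] + bond * .random_unit_vector()
        if (sqrt(sum(cand^2)) > radius) next
        if (i > 2L) {
          d2 <- rowSums((pos[seq_len(i - 2L), , drop = FALSE] -
                           matrix(cand, i - 2L, 3L, byrow = TRUE))^2)
          if (min(d2) < min_sep^2) next
        }
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pos)
  }
  stop("generator error: could not place a self-avoiding walk of ", n,
       " residues at the requested density")
}

#' Write / read a contact schedule as JSON
#'
#' Schema: an object with fields `family`, `n_nodes`, `n_frames`, `d_in`,
#' `d_out` and `pairs`, an array of `{i, j, frames}` objects with 1-based
#' indices.
#'
#' @param schedule a [ContactSchedule-class]
#' @param path file path
#' @return for the writer, `path` invisibly; for the reader, a
#'   [ContactSchedule-class]
#' @name scheduleJson
NULL

#' @rdname scheduleJson
#' @export
writeScheduleJson <- function(schedule, path) {
  stopifnot(is(schedule, "ContactSchedule"))
  obj <- list(family = schedule@family, n_nodes = schedule@nNodes,
              n_frames = schedule@nFrames, d_in = schedule@dIn,
              d_out = schedule@dOut,
              pairs = lapply(seq_len(nrow(schedule@pairs)), function(p)
                list(i = schedule@pairs$i[p], j = schedule@pairs$j[p],
                     frames = as.integer(schedule@pairs$frames[[p]]))))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}

#' @rdname scheduleJson
#' @export
readScheduleJson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  pairs <- data.frame(
    i = vapply(obj$pairs, function(p) as.integer(p$i), integer(1)),
    j = vapply(obj$pairs, function(p) as.integer(p$j), integer(1)))
  pairs$frames <- lapply(obj$pairs, function(p)
    as.integer(unlist(p$frames)))
  contactSchedule(obj$family, obj$n_nodes, obj$n_frames, pairs,
                  dIn = obj$d_in, dOut = obj$d_out)
}

setMethod("show", "ContactSchedule", function(object) {
  cat("ContactSchedule (", object@family, "): ", object@nNodes,
      " nodes, ", object@nFrames, " frames, ", nrow(object@pairs),
      " scheduled pairs, d_in ", object@dIn, " A, d_out ", object@dOut,
      " A\n", sep = "")
})
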