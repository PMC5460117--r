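#' Default atomic mass table
#'
#' Standard element masses (amu): C 12.011, N 14.007, O 15.999, S 32.06,
#' H 1.008, plus P 30.974 and Se 78.971 for phosphorylated and
#' selenomethionine residues. Force-field-specific masses can be supplied
#' via [readMassTable()]; the side-chain center of mass is only weakly
#' sensitive to such differences.
#'
#' @return a [MassTable-class]
#' @export
defaultMassTable <- function() {
  new("MassTable",
      specific = stats::setNames(numeric(0), character(0)),
      elements = c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   H = 1.008, P = 30.974, SE = 78.971),
      label = "default-elements")
}

#' Read a mass table from a plain-text file
#'
#' Whitespace-separated lines; `#` starts a comment. Three-token lines are
#' `(RESNAME ATOMNAME MASS)` entries; two-token lines are
#' `(ELEMENT MASS)` fallbacks. Entries from the file are merged over the
#' default element table, so lookup remains total.
#'
#' @param path file path; `NULL` returns [defaultMassTable()]
#' @return a [MassTable-class]
#' @export
readMassTable <- function(path = NULL) {
  if (is.null(path)) return(defaultMassTable())
  if (!file.exists(path)) stop("mass table not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(sub("#.*$", "", raw))
  raw <- raw[nzchar(raw)]
  base <- defaultMassTable()
  specific <- base@specific
  elements <- base@elements
  seen_spec <- character(0)
  seen_el <- character(0)
  for (ln in raw) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) == 3L) {
      m <- suppressWarnings(as.numeric(tok[3]))
      if (is.na(m)) stop("unparseable mass in line: '", ln, "'")
      if (m <= 0) stop("non-positive mass for ", tok[1], " ", tok[2],
                       ": ", m)
      key <- paste(toupper(tok[1]), toupper(tok[2]), sep = "|")
      if (key %in% seen_spec) stop("duplicate mass entry for ", key)
      seen_spec <- c(seen_spec, key)
      specific[key] <- m
    } else if (length(tok) == 2L) {
      m <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(m)) stop("unparseable mass in line: '", ln, "'")
      if (m <= 0) stop("non-positive mass for element ", tok[1], ": ", m)
      key <- toupper(tok[1])
      if (key %in% seen_el) stop("duplicate element mass for ", key)
      seen_el <- c(seen_el, key)
      elements[key] <- m
    } else {
      stop("unparseable mass-table line (need 2 or 3 tokens): '", ln, "'")
    }
  }
  new("MassTable", specific = specific, elements = elements, label = path)
}

#' Look up atomic masses
#'
#' A specific `(resname, atom name)` entry wins over the element fallback.
#' Vectorized over atoms.
#'
#' @param table a [MassTable-class]
#' @param resname residue name(s)
#' @param atomName atom name(s)
#' @param element element symbol(s)
#' @return numeric vector of masses (amu)
#' @export
massOf <- function(table, resname, atomName, element) {
  stopifnot(is(table, "MassTable"))
  key <- paste(toupper(resname), toupper(atomName), sep = "|")
  m <- unname(table@specific[key])
  miss <- is.na(m)
  if (any(miss)) {
    m[miss] <- unname(table@elements[toupper(element[miss])])
  }
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop("no mass for atom '", atomName[bad], "' (residue ", resname[bad],
         ", element '", element[bad], "') in mass table '", table@label, "'")
  }
  m
}

setMethod("show", "MassTable", function(object) {
  cat("MassTable [", object@label, "]: ", length(object@specific),
      " specific entries, ", length(object@elements),
      " element fallbacks\n", sep = "")
})
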