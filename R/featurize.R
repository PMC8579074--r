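#' Distance bounds of one shell
#'
#' Shell 1 is the sphere of radius \code{d0}: the half-open interval
#' \code{[0, d0)}.  Shell \code{i >= 2} is the layer
#' \code{[d0 + (i-2) delta, d0 + (i-1) delta)}.  The intervals tile
#' \code{[0, d0 + (N-1) delta)} with no gap or overlap, so every
#' residue-atom pair lands in at most one shell.
#'
#' @param spec a \linkS4class{ShellSpec}.
#' @param i shell index (vectorised), 1..nShells.
#' @return matrix with columns \code{lower} and \code{upper} (Angstrom),
#'   one row per requested shell.
#' @export
#' @examples
#' shellBounds(shellSpec(nShells = 10), c(1, 2, 10))
shellBounds <- function(spec, i) {
  stopifnot(is(spec, "ShellSpec"))
  i <- as.integer(i)
  if (any(is.na(i)) || any(i < 1L) || any(i > spec@nShells))
    stop("shell index out of range 1..", spec@nShells)
  lower <- ifelse(i == 1L, 0, spec@d0 + (i - 2L) * spec@delta)
  upper <- ifelse(i == 1L, spec@d0, spec@d0 + (i - 1L) * spec@delta)
  cbind(lower = lower, upper = upper)
}

#' Minimum distance between a residue's heavy atoms and a ligand atom
#'
#' The residue-atom distance of the contact features: the Euclidean
#' distance from the ligand atom to the nearest heavy atom of the residue.
#'
#' @param resCoords numeric matrix (m x 3) of the residue's heavy-atom
#'   coordinates (m >= 1).
#' @param atomCoord numeric length-3 ligand-atom coordinate.
#' @return the minimum distance in Angstrom.
#' @export
residueAtomDistance <- function(resCoords, atomCoord) {
  resCoords <- matrix(as.numeric(resCoords), ncol = 3L)
  stopifnot(nrow(resCoords) >= 1L, length(atomCoord) == 3L)
  d2 <- (resCoords[, 1L] - atomCoord[1L])^2 +
        (resCoords[, 2L] - atomCoord[2L])^2 +
        (resCoords[, 3L] - atomCoord[3L])^2
  sqrt(min(d2))
}

# R x E matrix of minimum residue-to-ligand-atom distances for one complex.
.minDistanceMatrix <- function(cx) {
  ra <- cx@residueAtoms
  la <- cx@ligandAtoms
  A <- cbind(ra$x, ra$y, ra$z)
  L <- cbind(la$x, la$y, la$z)
  # squared distances atom-by-atom: |a|^2 + |l|^2 - 2 a.l
  d2 <- outer(rowSums(A^2), rowSums(L^2), "+") - 2 * tcrossprod(A, L)
  d2[d2 < 0] <- 0                       # numeric noise guard
  nRes <- nrow(cx@residues)
  out <- matrix(0, nRes, nrow(la))
  idx <- split(seq_len(nrow(ra)), ra$residue)
  for (r in seq_len(nRes)) {
    rows <- idx[[as.character(r)]]
    out[r, ] <- if (length(rows) == 1L) d2[rows, ] else
      do.call(pmin, lapply(rows, function(k) d2[k, ]))
  }
  sqrt(out)
}

#' Canonical feature names
#'
#' The frozen layout of the feature vector: shell-major, then residue
#' class in the canonical 21-order, then atom class in the canonical
#' 8-order.  Entry \code{(i, r, e)} sits at index
#' \code{(i-1)*168 + (r-1)*8 + e}.  Names follow the on-disk column
#' convention \code{<shell>_<residueClass>_<atomClass>}.
#'
#' @param spec a \linkS4class{ShellSpec}.
#' @return character vector of length \code{168 * nShells}.
#' @export
featureNames <- function(spec) {
  stopifnot(is(spec, "ShellSpec"))
  combos <- as.vector(t(outer(residueClasses(), ligandAtomClasses(), paste,
                              sep = "_")))
  paste0(rep(seq_len(spec@nShells), each = 168L), "_", combos)
}

#' Contact-count features of one complex
#'
#' For every shell \code{i} and every (residue class, atom class)
#' combination, counts the (residue, ligand atom) pairs of those classes
#' whose minimum heavy-atom distance falls inside the shell.  Pairs beyond
#' the outermost boundary contribute nothing.  The result is the canonical
#' length-\code{168*N} nonnegative integer vector; being built from
#' distances only, it is invariant under any rigid motion of the complex.
#'
#' @param cx a \linkS4class{ComplexStructure}.
#' @param spec a \linkS4class{ShellSpec}.
#' @return named integer vector of length \code{168 * nShells}.
#' @export
featurizeComplex <- function(cx, spec) {
  stopifnot(is(cx, "ComplexStructure"), is(spec, "ShellSpec"))
  d <- .minDistanceMatrix(cx)                       # R x E
  rIdx <- match(cx@residues$residueClass, residueClasses())
  eIdx <- match(cx@ligandAtoms$atomClass, ligandAtomClasses())
  # half-open shells: [0,d0), then [d0+(i-2)d, d0+(i-1)d)
  shell <- ifelse(d < spec@d0, 1L,
                  2L + floor((d - spec@d0) / spec@delta))
  inRange <- shell <= spec@nShells
  combo <- outer((rIdx - 1L) * 8L, eIdx, "+")       # 1-based combination
  flat <- (shell[inRange] - 1L) * 168L + combo[inRange]
  counts <- tabulate(flat, nbins = 168L * spec@nShells)
  names(counts) <- featureNames(spec)
  counts
}

#' Reshape a feature vector to its 2D image and back
#'
#' The CNN consumes the features as an \code{N x 168} image: row \code{i}
#' holds shell \code{i}'s 168 combination counts in canonical order.  The
#' reshape is invertible; \code{flattenImage} recovers the vector.
#'
#' @param fv feature vector of length \code{168 * N}.
#' @param spec a \linkS4class{ShellSpec}; its \code{nShells} must match.
#' @return \code{featureImage}: an \code{N x 168} matrix;
#'   \code{flattenImage}: the canonical vector.
#' @export
#' @examples
#' spec <- shellSpec(nShells = 10)
#' fv <- rpois(1680, 0.2)
#' img <- featureImage(fv, spec)
#' stopifnot(identical(flattenImage(img), as.numeric(fv)))
featureImage <- function(fv, spec) {
  stopifnot(is(spec, "ShellSpec"))
  if (length(fv) != 168L * spec@nShells)
    stop("feature vector length ", length(fv), " does not match 168 x ",
         spec@nShells, " = ", 168L * spec@nShells)
  m <- matrix(as.numeric(fv), nrow = spec@nShells, ncol = 168L, byrow = TRUE)
  dimnames(m) <- list(paste0("shell", seq_len(spec@nShells)),
                      as.vector(t(outer(residueClasses(), ligandAtomClasses(),
                                        paste, sep = "_"))))
  m
}

#' @rdname featureImage
#' @param img an \code{N x 168} image matrix.
#' @export
flattenImage <- function(img) {
  stopifnot(is.matrix(img), ncol(img) == 168L)
  as.numeric(t(img))
}

#' Featurize many complexes into a feature table
#'
#' @param complexes list of \linkS4class{ComplexStructure} objects.
#' @param spec a \linkS4class{ShellSpec}.
#' @return list with \code{features} (matrix, one row per complex, canonical
#'   columns, rownames = complex ids) and \code{pkd} (named numeric, NA when
#'   unlabeled).
#' @export
featurizeComplexes <- function(complexes, spec) {
  stopifnot(length(complexes) >= 1L)
  ids <- vapply(complexes, complexId, "")
  if (anyDuplicated(ids)) stop("duplicate complex ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  X <- t(vapply(complexes, featurizeComplex, numeric(168L * spec@nShells),
                spec = spec))
  rownames(X) <- ids
  colnames(X) <- featureNames(spec)
  list(features = X, pkd = stats::setNames(vapply(complexes, pkd, 0), ids))
}
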