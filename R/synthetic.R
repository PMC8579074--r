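#' SyntheticSpec: parameters of the synthetic-complex generator
#'
#' Generates geometrically plausible (not physically minimised) complexes
#' with known ground truth, so the whole pipeline is testable without any
#' database download.  Residues draw uniformly from the 21 classes with 1-8
#' heavy atoms each; ligand atoms draw from the 8 classes including H, HAL
#' and DU; residue centres sit at radii between 10% and 100% of
#' \code{contactScale} from the ligand, which sets how many residue-atom
#' pairs fall inside the shell range.
#'
#' @slot nComplexes number of complexes.
#' @slot residueRange integer(2) residues per complex.
#' @slot ligandRange integer(2) ligand atoms per complex.
#' @slot boxExtent edge (Angstrom) of the cube the ligand atoms occupy.
#' @slot contactScale radial spread (Angstrom) of the residue centres.
#' @slot labelModel "linear_in_features", "constant" or "random".
#' @slot noiseSd Gaussian label noise, pKd units.
#' @slot seed master seed; fixes everything downstream.
#' @export
setClass("SyntheticSpec",
  representation(nComplexes = "integer", residueRange = "integer",
                 ligandRange = "integer", boxExtent = "numeric",
                 contactScale = "numeric", labelModel = "character",
                 noiseSd = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nComplexes < 1L) msg <- c(msg, "'nComplexes' must be >= 1")
  if (length(object@residueRange) != 2L || any(object@residueRange < 1L) ||
      diff(object@residueRange) < 0L)
    msg <- c(msg, "'residueRange' must be an increasing positive pair")
  if (length(object@ligandRange) != 2L || any(object@ligandRange < 1L) ||
      diff(object@ligandRange) < 0L)
    msg <- c(msg, "'ligandRange' must be an increasing positive pair")
  if (object@boxExtent <= 0) msg <- c(msg, "'boxExtent' must be > 0")
  if (object@contactScale <= 0) msg <- c(msg, "'contactScale' must be > 0")
  if (!object@labelModel %in% c("linear_in_features", "constant", "random"))
    msg <- c(msg, "unknown 'labelModel'")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticSpec
#'
#' Defaults give complexes of 8-30 residues and 5-20 ligand atoms whose
#' contact distances spread over roughly 1-13 Angstrom, a label linear in 10
#' designated features, and 0.3 pKd of Gaussian noise.
#'
#' @param nComplexes,residueRange,ligandRange,boxExtent,contactScale
#'   geometry settings; see \linkS4class{SyntheticSpec}.
#' @param labelModel,noiseSd,seed label settings.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(nComplexes = 100L, residueRange = c(8L, 30L),
                          ligandRange = c(5L, 20L), boxExtent = 6,
                          contactScale = 12, labelModel = "linear_in_features",
                          noiseSd = 0.3, seed = 1L) {
  new("SyntheticSpec", nComplexes = as.integer(nComplexes),
      residueRange = as.integer(residueRange),
      ligandRange = as.integer(ligandRange),
      boxExtent = as.numeric(boxExtent),
      contactScale = as.numeric(contactScale),
      labelModel = labelModel, noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

.OTH_NAMES <- c("HOH", "MSE", "ZN", "SO4", "MG")
.HAL_ELEMENTS <- c("F", "Cl", "Br", "I")
.DU_ELEMENTS <- c("Fe", "Zn", "B", "Se")

# uniform direction on the unit sphere
.randDir <- function(n = 1L) {
  m <- matrix(stats::rnorm(3L * n), n, 3L)
  m / sqrt(rowSums(m^2))
}

#' Generate one synthetic complex
#'
#' Deterministic in (spec seed, index).  Optionally writes the protein as
#' PDB and the ligand as MOL2 so the structure readers can round-trip it.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param index complex index (1-based); also names the complex.
#' @param dir if non-NULL, write \code{<id>_protein.pdb} and
#'   \code{<id>_ligand.mol2} here.
#' @return A \linkS4class{ComplexStructure} (pKd unset).
#' @export
generateComplex <- function(spec, index, dir = NULL) {
  stopifnot(is(spec, "SyntheticSpec"), index >= 1L)
  id <- sprintf("s%04d", as.integer(index))
  cx <- withr::with_seed(spec@seed + 7919L * as.integer(index), {
    nRes <- sample(spec@residueRange[1L]:spec@residueRange[2L], 1L)
    cls <- sample(residueClasses(), nRes, replace = TRUE)
    raw <- ifelse(cls == "OTH",
                  sample(.OTH_NAMES, nRes, replace = TRUE), cls)
    nAt <- sample(1:8, nRes, replace = TRUE)
    centres <- .randDir(nRes) * (spec@contactScale * stats::runif(nRes, 0.1, 1))
    atomRes <- rep(seq_len(nRes), nAt)
    coords <- centres[atomRes, , drop = FALSE] +
      matrix(stats::rnorm(3L * sum(nAt), sd = 0.8), ncol = 3L)
    residues <- data.frame(chainId = "A", seqNumber = seq_len(nRes),
                           insertCode = "", rawName = raw,
                           residueClass = cls, nAtoms = nAt,
                           stringsAsFactors = FALSE)
    residueAtoms <- data.frame(residue = atomRes, x = coords[, 1L],
                               y = coords[, 2L], z = coords[, 3L])
    nLig <- sample(spec@ligandRange[1L]:spec@ligandRange[2L], 1L)
    lcls <- sample(ligandAtomClasses(), nLig, replace = TRUE)
    elem <- vapply(lcls, function(k) switch(k,
      HAL = sample(.HAL_ELEMENTS, 1L),
      DU = sample(.DU_ELEMENTS, 1L), k), "")
    lxyz <- matrix(stats::runif(3L * nLig, -spec@boxExtent / 2,
                                spec@boxExtent / 2), ncol = 3L)
    lig <- data.frame(element = elem, atomClass = lcls, x = lxyz[, 1L],
                      y = lxyz[, 2L], z = lxyz[, 3L],
                      stringsAsFactors = FALSE)
    complexStructure(id, list(residues = residues,
                              residueAtoms = residueAtoms), lig)
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeComplexPDB(cx, file.path(dir, paste0(id, "_protein.pdb")))
    writeLigandMOL2(ligandAtoms(cx), file.path(dir, paste0(id, "_ligand.mol2")),
                    name = id)
  }
  cx
}

#' Generate a labeled synthetic dataset with known ground truth
#'
#' Builds \code{nComplexes} complexes, featurizes them, and attaches labels.
#' Under \code{labelModel = "linear_in_features"} the label is
#' \code{intercept + sum(w_k feature_k) + N(0, noiseSd)}, clipped to the
#' plausible pKd range \code{[0, 16]}; the designated features are the
#' \code{nDesignated} highest-variance columns and the weights are scaled so
#' the noiseless signal has a spread of a few pKd units.  Weights, designated
#' columns and intercept are returned for oracle checks.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param shell a \linkS4class{ShellSpec}.
#' @param nDesignated number of signal-carrying feature columns.
#' @param returnComplexes also return the \linkS4class{ComplexStructure}
#'   list (memory permitting).
#' @return list: features (matrix), pkd, designated (column names), weights
#'   (named, over designated columns), intercept, and optionally complexes.
#' @export
generateDataset <- function(spec, shell, nDesignated = 10L,
                            returnComplexes = FALSE) {
  stopifnot(is(spec, "SyntheticSpec"), is(shell, "ShellSpec"))
  complexes <- lapply(seq_len(spec@nComplexes), generateComplex, spec = spec)
  ft <- featurizeComplexes(complexes, shell)
  X <- ft$features
  n <- nrow(X)
  out <- list(features = X)
  if (spec@labelModel == "constant") {
    out$pkd <- stats::setNames(rep(7, n), rownames(X))
  } else if (spec@labelModel == "random") {
    out$pkd <- withr::with_seed(spec@seed + 131071L,
      stats::setNames(stats::runif(n, 0, 16), rownames(X)))
  } else {
    v <- apply(X, 2L, stats::var)
    ok <- which(v > 0)
    if (length(ok) < nDesignated)
      stop("only ", length(ok), " feature columns with nonzero variance; ",
           "need ", nDesignated, " for the linear label model")
    designated <- ok[order(v[ok], decreasing = TRUE)[seq_len(nDesignated)]]
    designated <- sort(designated)
    lab <- withr::with_seed(spec@seed + 131071L, {
      a <- stats::rnorm(nDesignated, sd = 0.7)
      w <- a / sqrt(v[designated])
      signal <- as.numeric(X[, designated, drop = FALSE] %*% w)
      intercept <- 7 - mean(signal)
      y <- intercept + signal + stats::rnorm(n, sd = spec@noiseSd)
      list(w = w, intercept = intercept, y = pmin(16, pmax(0, y)))
    })
    out$pkd <- stats::setNames(lab$y, rownames(X))
    out$designated <- colnames(X)[designated]
    out$weights <- stats::setNames(lab$w, colnames(X)[designated])
    out$intercept <- lab$intercept
  }
  if (returnComplexes) out$complexes <- complexes
  out
}

#' Generate a decoy pose at a target symmetry-corrected RMSD
#'
#' Applies a seeded rigid rotation about the ligand centroid plus a
#' translation and per-atom jitter, all scaled by one parameter that is
#' bisected until [hungarianRmsd()] to the native pose lands within
#' \code{tol} (default 5%) of \code{targetRmsd}.  The element multiset is
#' preserved by construction.
#'
#' @param ligand native ligand-atom data.frame (element, atomClass, x, y, z).
#' @param targetRmsd desired RMSD in Angstrom (0 returns the native pose).
#' @param seed RNG seed for the perturbation direction.
#' @param tol relative tolerance on the achieved RMSD.
#' @param maxIter bisection iteration cap.
#' @return a ligand-atom data.frame with perturbed coordinates; attribute
#'   \code{rmsd} holds the achieved value.
#' @export
generateDecoy <- function(ligand, targetRmsd, seed = 1L, tol = 0.05,
                          maxIter = 100L) {
  stopifnot(targetRmsd >= 0, nrow(ligand) >= 1L)
  if (targetRmsd == 0) {
    attr(ligand, "rmsd") <- 0
    return(ligand)
  }
  xyz <- as.matrix(ligand[, c("x", "y", "z")])
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  prt <- withr::with_seed(as.integer(seed), list(
    axis = as.numeric(.randDir()),
    trans = as.numeric(.randDir()),
    jitter = matrix(stats::rnorm(3L * n), n, 3L)))
  poseAt <- function(t) {
    ang <- t * 0.15
    u <- prt$axis
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L)
    R <- diag(3L) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    sweep((xyz - rep(ctr, each = n)) %*% t(R), 2L, -ctr) +
      rep(prt$trans * 0.5 * t, each = n) + prt$jitter * 0.2 * t
  }
  rmsdAt <- function(t) {
    p <- ligand
    p[, c("x", "y", "z")] <- poseAt(t)
    hungarianRmsd(ligand, p)
  }
  hi <- max(targetRmsd, 1)
  k <- 0L
  while (rmsdAt(hi) < targetRmsd && k < 60L) {
    hi <- hi * 2
    k <- k + 1L
  }
  lo <- 0
  t <- hi
  for (it in seq_len(maxIter)) {
    t <- (lo + hi) / 2
    r <- rmsdAt(t)
    if (abs(r - targetRmsd) / targetRmsd <= tol) break
    if (r < targetRmsd) lo <- t else hi <- t
    if (it == maxIter)
      stop("decoy rescaling did not converge to ", targetRmsd,
           " A within ", maxIter, " iterations")
  }
  out <- ligand
  out[, c("x", "y", "z")] <- poseAt(t)
  attr(out, "rmsd") <- rmsdAt(t)
  out
}

#' Replace a complex's ligand pose
#'
#' Utility for decoy evaluation: the native protein with a perturbed ligand.
#'
#' @param cx a \linkS4class{ComplexStructure}.
#' @param ligand a ligand-atom data.frame (e.g. from [generateDecoy()]).
#' @param suffix appended to the complex id.
#' @return a new \linkS4class{ComplexStructure}.
#' @export
withLigandPose <- function(cx, ligand, suffix = "_decoy") {
  attr(ligand, "rmsd") <- NULL
  new("ComplexStructure", complexId = paste0(cx@complexId, suffix),
      residues = cx@residues, residueAtoms = cx@residueAtoms,
      ligandAtoms = as.data.frame(ligand), pkd = cx@pkd)
}

# --- fixture writers --------------------------------------------------------

#' Write a complex's protein as a PDB file
#'
#' Standard residues become ATOM records, OTH residues HETATM; the element
#' symbol occupies columns 77-78.  Coordinates are written at the PDB's
#' 3-decimal precision, so parse-write-parse round-trips to 1e-3 Angstrom.
#'
#' @param cx a \linkS4class{ComplexStructure}.
#' @param path output file.
#' @param proteinElements elements cycled over the heavy atoms of each
#'   residue (synthetic structures carry no chemistry, only geometry).
#' @return the path, invisibly.
#' @export
writeComplexPDB <- function(cx, path, proteinElements = c("C", "N", "O", "S")) {
  res <- cx@residues
  ra <- cx@residueAtoms
  lines <- character(nrow(ra))
  serial <- 0L
  for (r in seq_len(nrow(res))) {
    rows <- which(ra$residue == r)
    rec <- if (res$residueClass[r] == "OTH") "HETATM" else "ATOM  "
    for (j in seq_along(rows)) {
      serial <- serial + 1L
      el <- proteinElements[(j - 1L) %% length(proteinElements) + 1L]
      nm <- sprintf("%s%d", el, j)
      lines[serial] <- sprintf(
        "%s%5d  %-3s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        rec, serial, substr(nm, 1L, 3L), "", substr(res$rawName[r], 1L, 4L),
        substr(res$chainId[r], 1L, 1L), res$seqNumber[r],
        substr(paste0(res$insertCode[r], " "), 1L, 1L),
        ra$x[rows[j]], ra$y[rows[j]], ra$z[rows[j]], 1, 0, el)
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a ligand as a TRIPOS MOL2 file
#'
#' @param ligand ligand-atom data.frame.
#' @param path output file.
#' @param name molecule name.
#' @return the path, invisibly.
#' @export
writeLigandMOL2 <- function(ligand, path, name = "LIG") {
  n <- nrow(ligand)
  atomName <- paste0(ligand$element,
                     stats::ave(seq_len(n), ligand$element, FUN = seq_along))
  lines <- c("@<TRIPOS>MOLECULE", name,
             sprintf("%d 0 0 0 0", n), "SMALL", "NO_CHARGES", "",
             "@<TRIPOS>ATOM",
             sprintf("%7d %-8s %9.4f %9.4f %9.4f %-6s %4d %-8s %9.4f",
                     seq_len(n), atomName, ligand$x, ligand$y, ligand$z,
                     ligand$element, 1L, "LIG", 0))
  writeLines(lines, path)
  invisible(path)
}

#' Write a ligand as an SDF (V2000) file
#'
#' @param ligand ligand-atom data.frame.
#' @param path output file.
#' @param name molecule name.
#' @return the path, invisibly.
#' @export
writeLigandSDF <- function(ligand, path, name = "LIG") {
  n <- nrow(ligand)
  lines <- c(name, "  shellscore", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     ligand$x, ligand$y, ligand$z, ligand$element),
             "M  END", "$$$$")
  writeLines(lines, path)
  invisible(path)
}
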