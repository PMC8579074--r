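# Known element symbols (uppercase) used to distinguish "recognized element
# mapped to DU" from "unrecognized symbol" (which also maps to DU, but with a
# warning).
.ELEMENTS <- c(
  "H", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE", "NA", "MG", "AL",
  "SI", "P", "S", "CL", "AR", "K", "CA", "SC", "TI", "V", "CR", "MN", "FE",
  "CO", "NI", "CU", "ZN", "GA", "GE", "AS", "SE", "BR", "KR", "RB", "SR",
  "Y", "ZR", "NB", "MO", "TC", "RU", "RH", "PD", "AG", "CD", "IN", "SN",
  "SB", "TE", "I", "XE", "CS", "BA", "LA", "CE", "PR", "ND", "PM", "SM",
  "EU", "GD", "TB", "DY", "HO", "ER", "TM", "YB", "LU", "HF", "TA", "W",
  "RE", "OS", "IR", "PT", "AU", "HG", "TL", "PB", "BI", "PO", "AT", "RN",
  "FR", "RA", "AC", "TH", "PA", "U", "NP", "PU", "D")

.STANDARD_RESIDUES <- c(
  "GLY", "ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "TYR", "TRP", "SER",
  "THR", "CYS", "MET", "ASN", "GLN", "ASP", "GLU", "LYS", "ARG", "HIS")

#' Classify a ligand element symbol into one of the 8 atom classes
#'
#' C, H, O, N, P and S map to themselves; the halogens F, Cl, Br and I map
#' to \code{HAL}; every other recognized element maps to \code{DU}
#' (deuterium is treated as hydrogen).  An unrecognized symbol also maps to
#' \code{DU}, with a warning rather than an error.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return character vector of atom classes, same length as \code{element}.
#' @export
#' @examples
#' classifyLigandAtom(c("C", "Cl", "Fe", "D"))
classifyLigandAtom <- function(element) {
  el <- toupper(trimws(as.character(element)))
  stopifnot(length(el) >= 1L, all(nzchar(el)))
  unknown <- !(el %in% .ELEMENTS)
  if (any(unknown))
    warning("unrecognized element symbol(s) mapped to DU: ",
            paste(unique(element[unknown]), collapse = ", "))
  out <- rep("DU", length(el))
  out[el == "D"] <- "H"                       # deuterium counts as hydrogen
  named <- c("C", "H", "O", "N", "P", "S")
  hit <- el %in% named
  out[hit] <- el[hit]
  out[el %in% c("F", "CL", "BR", "I")] <- "HAL"
  out
}

#' Classify a residue name into one of the 21 residue classes
#'
#' The 20 standard three-letter amino-acid codes map to themselves;
#' everything else -- water (HOH/WAT/DOD), ions, modified residues such as
#' MSE, and unknown het groups -- maps to \code{OTH}.  Total function: never
#' errors on a non-empty name.
#'
#' @param rawName character vector of residue names.
#' @return character vector of residue classes.
#' @export
#' @examples
#' classifyResidue(c("GLY", "HOH", "MSE", "ZN"))
classifyResidue <- function(rawName) {
  nm <- toupper(trimws(as.character(rawName)))
  stopifnot(length(nm) >= 1L, all(nzchar(nm)))
  ifelse(nm %in% .STANDARD_RESIDUES, nm, "OTH")
}

# Fallback element inference from a PDB atom name when the element column
# (77-78) is absent.  PDB v3 convention: the element is right-justified in
# name columns 13-14; names starting with a digit (1HB) are hydrogens.
# Within ATOM records only the biopolymer elements occur, so a one-letter
# read is safe there; for HETATM the two-letter read is attempted first
# (e.g. "ZN", "FE", monatomic ions named after their element).
.elementFromName <- function(name, het) {
  nm <- toupper(trimws(name))
  first <- substr(nm, 1L, 1L)
  if (grepl("^[0-9]", nm)) return("H")
  two <- substr(nm, 1L, 2L)
  if (het && two %in% .ELEMENTS && !first %in% c("C", "N", "O", "S", "P", "H"))
    return(two)
  if (first %in% .ELEMENTS) return(first)
  if (two %in% .ELEMENTS) return(two)
  NA_character_
}

#' Parse a protein PDB file into typed residues with heavy-atom coordinates
#'
#' Reads ATOM and HETATM records (through \pkg{bio3d}) and groups atoms into
#' residues by (chain, residue number, insertion code, residue name).  Each
#' water molecule and each monatomic ion is its own residue, classed
#' \code{OTH}, because crystallographic waters and ions take part in binding
#' and are kept explicit.  Hydrogens and deuteriums are excluded from the
#' heavy-atom coordinates; for alternate locations the highest-occupancy
#' conformer of each atom is kept (ties: first listed).  Residues left with
#' zero heavy atoms are dropped with a warning.
#'
#' @param path PDB file path.
#' @param keepHet keep non-water, non-ion HETATM groups (cofactors etc.) as
#'   OTH residues (default TRUE).  \code{FALSE} drops all HETATM records.
#' @return list with \code{residues} (one row per residue: chainId,
#'   seqNumber, insertCode, rawName, residueClass, nAtoms) and
#'   \code{residueAtoms} (residue index, x, y, z), ready for
#'   [complexStructure()].
#' @export
readProteinPDB <- function(path, keepHet = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  if (!keepHet) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms in '", path, "'")

  ins <- ifelse(is.na(at$insert), "", at$insert)
  elem <- toupper(ifelse(is.na(at$elesy), "", trimws(at$elesy)))
  miss <- !nzchar(elem)
  if (any(miss)) {
    inferred <- mapply(.elementFromName, at$elety[miss],
                       at$type[miss] == "HETATM")
    message(sum(miss), " atom(s) lacked an element column; inferred from ",
            "atom names: ", paste(unique(inferred), collapse = ", "))
    elem[miss] <- inferred
  }
  bad <- is.na(elem)
  if (any(bad)) {
    warning(sum(bad), " atom(s) with undeterminable element dropped")
    at <- at[!bad, , drop = FALSE]; ins <- ins[!bad]; elem <- elem[!bad]
  }

  # altloc policy: per (residue, atom name), keep highest occupancy,
  # ties broken by file order
  resKey <- paste(at$chain, at$resno, ins, at$resid, sep = "\r")
  atomKey <- paste(resKey, at$elety, sep = "\r")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(atomKey, -occ, seq_len(nrow(at)))
  keep <- ord[!duplicated(atomKey[ord])]
  keep <- sort(keep)                         # restore file order
  at <- at[keep, , drop = FALSE]
  ins <- ins[keep]; elem <- elem[keep]; resKey <- resKey[keep]

  heavy <- !(elem %in% c("H", "D"))
  resLevels <- unique(resKey)                 # file order
  meta <- at[match(resLevels, resKey), , drop = FALSE]
  residues <- data.frame(
    chainId = as.character(meta$chain),
    seqNumber = as.integer(meta$resno),
    insertCode = ins[match(resLevels, resKey)],
    rawName = as.character(meta$resid),
    residueClass = classifyResidue(meta$resid),
    stringsAsFactors = FALSE)

  resIdx <- match(resKey, resLevels)
  nHeavy <- tabulate(resIdx[heavy], nbins = length(resLevels))
  if (any(nHeavy == 0L)) {
    warning(sum(nHeavy == 0L), " residue(s) without heavy atoms dropped: ",
            paste(utils::head(residues$rawName[nHeavy == 0L], 5L), collapse = ", "))
  }
  keepRes <- which(nHeavy > 0L)
  if (length(keepRes) == 0L)
    stop("empty structure: no residues with heavy atoms in '", path, "'")
  residues <- residues[keepRes, , drop = FALSE]
  residues$nAtoms <- nHeavy[keepRes]
  rownames(residues) <- NULL

  ha <- heavy & resIdx %in% keepRes
  residueAtoms <- data.frame(
    residue = match(resIdx[ha], keepRes),
    x = at$x[ha], y = at$y[ha], z = at$z[ha])
  if (!all(is.finite(as.matrix(residueAtoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in '", path, "'")
  list(residues = residues, residueAtoms = residueAtoms)
}

# --- ligand readers ---------------------------------------------------------

.ligandFrame <- function(element, x, y, z) {
  data.frame(element = as.character(element),
             atomClass = classifyLigandAtom(element),
             x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
             stringsAsFactors = FALSE)
}

.readLigandMol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0L) stop("no TRIPOS MOLECULE block in '", path, "'")
  if (length(starts) > 1L) {
    warning("'", path, "' contains ", length(starts),
            " molecules; taking the first")
    tmp <- tempfile(fileext = ".mol2")
    on.exit(unlink(tmp))
    writeLines(lines[seq_len(starts[2L] - 1L)], tmp)
    path <- tmp
  }
  m <- tryCatch(suppressWarnings(bio3d::read.mol2(path)),
                error = function(e) stop("cannot parse MOL2 file: ",
                                         conditionMessage(e)))
  at <- m$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty molecule in MOL2 file")
  # element = SYBYL atom type before the dot (C.3 -> C, N.ar -> N)
  .ligandFrame(sub("\\..*$", "", at$elety), at$x, at$y, at$z)
}

.readLigandSDF <- function(path) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                  error = function(e) stop("cannot parse SDF file: ",
                                           conditionMessage(e)))
  if (length(sdf) == 0L) stop("no molecules in SDF file '", path, "'")
  if (length(sdf) > 1L)
    warning("'", path, "' contains ", length(sdf),
            " molecules; taking the first")
  ab <- ChemmineR::atomblock(sdf[[1L]])
  if (is.null(ab) || nrow(ab) == 0L) stop("empty molecule in SDF file")
  elem <- sub("_.*$", "", rownames(ab))
  .ligandFrame(elem, ab[, 1L], ab[, 2L], ab[, 3L])
}

.readLigandPDB <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("cannot parse ligand PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0L) stop("empty ligand PDB file '", path, "'")
  elem <- toupper(ifelse(is.na(at$elesy), "", trimws(at$elesy)))
  miss <- !nzchar(elem)
  if (any(miss))
    elem[miss] <- vapply(at$elety[miss], .elementFromName, "", het = TRUE)
  .ligandFrame(elem, at$x, at$y, at$z)
}

#' Parse a ligand structure file into typed atoms
#'
#' Every atom -- including hydrogens, which are a feature class of their own
#' -- becomes one typed ligand atom.  If the file holds several molecules
#' the first is taken, with a warning.
#'
#' @param path ligand file.
#' @param format "mol2", "sdf", "pdb", or "auto" (default; by extension).
#' @return data.frame with columns element, atomClass, x, y, z.
#' @export
readLigand <- function(path, format = c("auto", "mol2", "sdf", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mol2 = "mol2", sdf = "sdf", sd = "sdf",
                     pdb = "pdb",
                     stop("cannot infer ligand format from extension '.",
                          ext, "'"))
  }
  out <- switch(format,
                mol2 = .readLigandMol2(path),
                sdf = .readLigandSDF(path),
                pdb = .readLigandPDB(path))
  if (!all(is.finite(as.matrix(out[, c("x", "y", "z")]))))
    stop("non-finite ligand coordinates in '", path, "'")
  out
}

#' Read a protein-ligand complex from a pair of structure files
#'
#' Convenience wrapper: [readProteinPDB()] + [readLigand()] +
#' [complexStructure()].
#'
#' @param proteinPath protein PDB file.
#' @param ligandPath ligand MOL2/SDF/PDB file.
#' @param complexId identifier; default is the protein file stem.
#' @param pkd optional label.
#' @param keepHet passed to [readProteinPDB()].
#' @return A \linkS4class{ComplexStructure}.
#' @export
readComplex <- function(proteinPath, ligandPath,
                        complexId = tools::file_path_sans_ext(basename(proteinPath)),
                        pkd = NA_real_, keepHet = TRUE) {
  complexStructure(complexId, readProteinPDB(proteinPath, keepHet = keepHet),
                   readLigand(ligandPath), pkd = pkd)
}
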