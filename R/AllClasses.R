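#' @import methods
NULL

#' Canonical residue and ligand-atom class orderings
#'
#' The 21 protein residue classes (20 standard amino acids plus \code{OTH},
#' which collects water, ions and every non-standard residue) and the 8
#' ligand atom classes (\code{HAL} collects the halogens F, Cl, Br, I;
#' \code{DU} collects every other element).  The orderings are frozen: they
#' define the canonical layout of the feature vector and the column order of
#' the 2D feature image, so they must never be permuted.
#'
#' @return Character vectors of length 21 and 8 respectively.
#' @export
#' @examples
#' residueClasses()
residueClasses <- function() {
  c("GLY", "ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "TYR", "TRP",
    "SER", "THR", "CYS", "MET", "ASN", "GLN", "ASP", "GLU", "LYS",
    "ARG", "HIS", "OTH")
}

#' @rdname residueClasses
#' @export
ligandAtomClasses <- function() {
  c("C", "H", "O", "N", "P", "S", "HAL", "DU")
}

#' ShellSpec: geometry of the concentric distance shells
#'
#' Distance bins laid around every ligand atom: shell 1 is the sphere of
#' radius \code{d0}; each later shell is a spherical layer of thickness
#' \code{delta}.  With the defaults (d0 = 1 A, delta = 0.5 A) and
#' \code{nShells} = 62 the outermost boundary sits at 31.5 A.
#'
#' @slot d0 radius of the innermost sphere, in Angstrom.
#' @slot delta thickness of every shell after the first, in Angstrom.
#' @slot nShells number of shells N.
#' @export
setClass("ShellSpec",
  representation(d0 = "numeric", delta = "numeric", nShells = "integer"))

setValidity("ShellSpec", function(object) {
  msg <- character()
  if (length(object@d0) != 1L || !is.finite(object@d0) || object@d0 <= 0)
    msg <- c(msg, "'d0' must be a single positive finite number")
  if (length(object@delta) != 1L || !is.finite(object@delta) || object@delta <= 0)
    msg <- c(msg, "'delta' must be a single positive finite number")
  if (length(object@nShells) != 1L || is.na(object@nShells) || object@nShells < 1L)
    msg <- c(msg, "'nShells' must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a ShellSpec
#'
#' @param d0 innermost sphere radius in Angstrom (default 1).
#' @param delta shell thickness in Angstrom (default 0.5).
#' @param nShells number of shells (default 62, the best-performing count).
#' @return A \linkS4class{ShellSpec}.
#' @export
#' @examples
#' shellSpec(nShells = 10)
shellSpec <- function(d0 = 1, delta = 0.5, nShells = 62L) {
  new("ShellSpec", d0 = as.numeric(d0), delta = as.numeric(delta),
      nShells = as.integer(nShells))
}

#' ComplexStructure: one typed protein-ligand complex
#'
#' Holds the parsed protein (one row per residue plus a residue-indexed heavy
#' atom table), the typed ligand atoms and an optional experimental pKd
#' label.  Hydrogens never appear among protein heavy atoms; ligand
#' hydrogens are kept (H is a ligand feature class).
#'
#' @slot complexId identifier (e.g. a 4-character PDB code).
#' @slot residues data.frame with columns chainId, seqNumber, insertCode,
#'   rawName, residueClass, nAtoms.
#' @slot residueAtoms data.frame with columns residue (row index into
#'   \code{residues}), x, y, z.
#' @slot ligandAtoms data.frame with columns element, atomClass, x, y, z.
#' @slot pkd experimental pKd, \code{NA_real_} when unlabeled.
#' @export
setClass("ComplexStructure",
  representation(complexId = "character", residues = "data.frame",
                 residueAtoms = "data.frame", ligandAtoms = "data.frame",
                 pkd = "numeric"))

setValidity("ComplexStructure", function(object) {
  msg <- character()
  res <- object@residues
  ra <- object@residueAtoms
  la <- object@ligandAtoms
  if (length(object@complexId) != 1L || !nzchar(object@complexId))
    msg <- c(msg, "'complexId' must be a single non-empty string")
  if (nrow(res) == 0L) msg <- c(msg, "complex has no residues")
  if (nrow(la) == 0L) msg <- c(msg, "complex has no ligand atoms")
  if (nrow(res) > 0L && !all(res$residueClass %in% residueClasses()))
    msg <- c(msg, "residueClass values outside the 21 canonical classes")
  if (nrow(la) > 0L && !all(la$atomClass %in% ligandAtomClasses()))
    msg <- c(msg, "atomClass values outside the 8 canonical classes")
  if (nrow(ra) > 0L) {
    if (!all(is.finite(as.matrix(ra[, c("x", "y", "z")]))))
      msg <- c(msg, "non-finite protein heavy-atom coordinates")
    if (!all(ra$residue %in% seq_len(nrow(res))))
      msg <- c(msg, "residueAtoms reference residues that do not exist")
  }
  if (nrow(res) > 0L && !all(seq_len(nrow(res)) %in% object@residueAtoms$residue))
    msg <- c(msg, "residues with zero heavy atoms are not allowed")
  if (nrow(la) > 0L && !all(is.finite(as.matrix(la[, c("x", "y", "z")]))))
    msg <- c(msg, "non-finite ligand coordinates")
  if (length(object@pkd) != 1L)
    msg <- c(msg, "'pkd' must be length 1 (use NA when unlabeled)")
  if (length(msg)) msg else TRUE
})

#' Construct a ComplexStructure
#'
#' @param complexId identifier.
#' @param protein a list with elements \code{residues} and \code{residueAtoms}
#'   as returned by [readProteinPDB()].
#' @param ligand a ligand-atom data.frame as returned by [readLigand()].
#' @param pkd optional experimental pKd label.
#' @return A \linkS4class{ComplexStructure}.
#' @export
complexStructure <- function(complexId, protein, ligand, pkd = NA_real_) {
  new("ComplexStructure", complexId = as.character(complexId),
      residues = protein$residues, residueAtoms = protein$residueAtoms,
      ligandAtoms = ligand, pkd = as.numeric(pkd))
}

#' TrainConfig: hyper-parameters of the CNN regressor
#'
#' Defaults are the published architecture: three convolutional layers with
#' 32/64/128 filters of size 4x4 and stride 1, two fully connected layers of
#' 100 and 50 neurons (each followed by batch normalisation and ReLU), plain
#' SGD at learning rate 0.001, L2 weight decay 0.01 on the dense weights,
#' batch size 64, composite loss weight alpha = 0.7, early stopping with
#' patience 20 and minimum improvement 0.001, and a 5-member seed ensemble.
#'
#' @slot convFilters integer(3) filters per convolutional layer.
#' @slot kernelSize square kernel edge.
#' @slot stride convolution stride.
#' @slot fcWidths integer(2) dense-layer widths.
#' @slot learningRate SGD learning rate.
#' @slot l2Weight L2 penalty on dense weights.
#' @slot batchSize minibatch size.
#' @slot alpha weight of the (1 - R) term in the composite loss.
#' @slot patience early-stopping patience in epochs.
#' @slot minDelta minimum validation-loss improvement that resets patience.
#' @slot maxEpochs hard epoch cap (early stopping governs in practice).
#' @slot nRuns ensemble size.
#' @slot seedBase seed of the first run; run k uses seedBase + k - 1.
#' @slot padding "valid" or "same" convolution padding.
#' @slot lossMode "composite" trains on the composite loss per batch;
#'   "rmse" trains on RMSE and uses the composite loss only for model
#'   selection.
#' @slot bnMomentum momentum of the batch-norm running statistics.
#' @slot lrDecay multiplicative learning-rate decay applied when the
#'   validation loss plateaus (1 = constant learning rate, the published
#'   regimen).
#' @slot decayEvery consecutive non-improving epochs before one decay step.
#' @export
setClass("TrainConfig",
  representation(convFilters = "integer", kernelSize = "integer",
                 stride = "integer", fcWidths = "integer",
                 learningRate = "numeric", l2Weight = "numeric",
                 batchSize = "integer", alpha = "numeric",
                 patience = "integer", minDelta = "numeric",
                 maxEpochs = "integer", nRuns = "integer",
                 seedBase = "integer", padding = "character",
                 lossMode = "character", bnMomentum = "numeric",
                 lrDecay = "numeric", decayEvery = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (length(object@convFilters) < 1L || any(object@convFilters < 1L))
    msg <- c(msg, "'convFilters' must be positive integers")
  if (object@kernelSize < 1L) msg <- c(msg, "'kernelSize' must be >= 1")
  if (object@stride < 1L) msg <- c(msg, "'stride' must be >= 1")
  if (any(object@fcWidths < 1L)) msg <- c(msg, "'fcWidths' must be positive")
  if (object@learningRate <= 0) msg <- c(msg, "'learningRate' must be > 0")
  if (object@l2Weight < 0) msg <- c(msg, "'l2Weight' must be >= 0")
  if (object@batchSize < 1L) msg <- c(msg, "'batchSize' must be >= 1")
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "'alpha' must lie in [0, 1]")
  if (object@patience < 1L) msg <- c(msg, "'patience' must be >= 1")
  if (object@minDelta < 0) msg <- c(msg, "'minDelta' must be >= 0")
  if (object@maxEpochs < 1L) msg <- c(msg, "'maxEpochs' must be >= 1")
  if (object@nRuns < 1L) msg <- c(msg, "'nRuns' must be >= 1")
  if (!object@padding %in% c("valid", "same"))
    msg <- c(msg, "'padding' must be \"valid\" or \"same\"")
  if (!object@lossMode %in% c("composite", "rmse"))
    msg <- c(msg, "'lossMode' must be \"composite\" or \"rmse\"")
  if (object@bnMomentum <= 0 || object@bnMomentum >= 1)
    msg <- c(msg, "'bnMomentum' must lie in (0, 1)")
  if (object@lrDecay <= 0 || object@lrDecay > 1)
    msg <- c(msg, "'lrDecay' must lie in (0, 1]")
  if (object@decayEvery < 1L) msg <- c(msg, "'decayEvery' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainConfig
#'
#' @param convFilters,kernelSize,stride,fcWidths,learningRate,l2Weight
#'   architecture and optimiser settings; see \linkS4class{TrainConfig}.
#' @param batchSize,alpha,patience,minDelta,maxEpochs,nRuns,seedBase,padding
#'   training regimen settings.
#' @param lossMode,bnMomentum,lrDecay,decayEvery see
#'   \linkS4class{TrainConfig}.
#' @return A \linkS4class{TrainConfig}.
#' @export
#' @examples
#' trainConfig()                      # the published defaults
#' trainConfig(convFilters = c(8, 16, 32), fcWidths = c(64, 32))
trainConfig <- function(convFilters = c(32L, 64L, 128L), kernelSize = 4L,
                        stride = 1L, fcWidths = c(100L, 50L),
                        learningRate = 0.001, l2Weight = 0.01,
                        batchSize = 64L, alpha = 0.7, patience = 20L,
                        minDelta = 0.001, maxEpochs = 1000L, nRuns = 5L,
                        seedBase = 42L, padding = "valid",
                        lossMode = "composite", bnMomentum = 0.9,
                        lrDecay = 1, decayEvery = 5L) {
  new("TrainConfig", convFilters = as.integer(convFilters),
      kernelSize = as.integer(kernelSize), stride = as.integer(stride),
      fcWidths = as.integer(fcWidths), learningRate = as.numeric(learningRate),
      l2Weight = as.numeric(l2Weight), batchSize = as.integer(batchSize),
      alpha = as.numeric(alpha), patience = as.integer(patience),
      minDelta = as.numeric(minDelta), maxEpochs = as.integer(maxEpochs),
      nRuns = as.integer(nRuns), seedBase = as.integer(seedBase),
      padding = padding, lossMode = lossMode,
      bnMomentum = as.numeric(bnMomentum), lrDecay = as.numeric(lrDecay),
      decayEvery = as.integer(decayEvery))
}

#' Standardizer: per-feature location/scale learned on the training split
#'
#' Means and population standard deviations of every feature column, fitted
#' on the training partition only and then applied unchanged to validation
#' and test rows (no leakage).  Columns with zero training variance
#' transform to 0.
#'
#' @slot center per-column means.
#' @slot scale per-column population standard deviations (0 marks a
#'   constant column).
#' @export
setClass("Standardizer",
  representation(center = "numeric", scale = "numeric"))

setValidity("Standardizer", function(object) {
  if (length(object@center) != length(object@scale))
    return("'center' and 'scale' must have equal length")
  if (any(object@scale < 0)) return("'scale' must be non-negative")
  TRUE
})

#' ShellCNN: one trained (or untrained) CNN regressor
#'
#' @slot inputDim integer(2): rows (shells) and columns (combinations) of
#'   the input image.
#' @slot config the \linkS4class{TrainConfig} used to build it.
#' @slot params named list of layer weights.
#' @slot plans internal im2col index plans, one per convolution.
#' @slot seed the run seed.
#' @slot trained whether [trainModel()] has run.
#' @slot history per-epoch data.frame (epoch, trainLoss, valLoss).
#' @export
setClass("ShellCNN",
  representation(inputDim = "integer", config = "TrainConfig",
                 params = "list", plans = "list", seed = "integer",
                 trained = "logical", history = "data.frame"))

#' ShellCNNEnsemble: seed ensemble of CNN regressors plus its standardizer
#'
#' @slot members list of trained \linkS4class{ShellCNN} objects.
#' @slot standardizer the \linkS4class{Standardizer} fitted on the training
#'   partition; ensemble predictions always standardize with it.
#' @slot config the shared \linkS4class{TrainConfig}.
#' @slot inputDim input image dimensions.
#' @export
setClass("ShellCNNEnsemble",
  representation(members = "list", standardizer = "Standardizer",
                 config = "TrainConfig", inputDim = "integer"))

setValidity("ShellCNNEnsemble", function(object) {
  if (length(object@members) == 0L) return("ensemble has no members")
  if (!all(vapply(object@members, is, logical(1), "ShellCNN")))
    return("all members must be ShellCNN objects")
  TRUE
})
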