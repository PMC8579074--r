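#' Accessors for ShellSpec and ComplexStructure
#'
#' @param x a \linkS4class{ShellSpec} or \linkS4class{ComplexStructure}.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nShells", function(x) standardGeneric("nShells"))
#' @rdname accessors
#' @export
setMethod("nShells", "ShellSpec", function(x) x@nShells)

#' @rdname accessors
#' @export
setGeneric("complexId", function(x) standardGeneric("complexId"))
#' @rdname accessors
#' @export
setMethod("complexId", "ComplexStructure", function(x) x@complexId)

#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname accessors
#' @export
setMethod("residues", "ComplexStructure", function(x) x@residues)

#' @rdname accessors
#' @export
setGeneric("residueAtoms", function(x) standardGeneric("residueAtoms"))
#' @rdname accessors
#' @export
setMethod("residueAtoms", "ComplexStructure", function(x) x@residueAtoms)

#' @rdname accessors
#' @export
setGeneric("ligandAtoms", function(x) standardGeneric("ligandAtoms"))
#' @rdname accessors
#' @export
setMethod("ligandAtoms", "ComplexStructure", function(x) x@ligandAtoms)

#' @rdname accessors
#' @export
setGeneric("pkd", function(x) standardGeneric("pkd"))
#' @rdname accessors
#' @export
setMethod("pkd", "ComplexStructure", function(x) x@pkd)

setMethod("show", "ShellSpec", function(object) {
  upper <- object@d0 + (object@nShells - 1L) * object@delta
  cat(sprintf(
    "ShellSpec: %d shells, d0 = %g A, delta = %g A (outer boundary %g A)\n",
    object@nShells, object@d0, object@delta, upper))
  cat(sprintf("  features per complex: 168 x %d = %d\n",
              object@nShells, 168L * object@nShells))
})

setMethod("show", "ComplexStructure", function(object) {
  cat(sprintf("ComplexStructure '%s': %d residues (%d heavy atoms), %d ligand atoms",
              object@complexId, nrow(object@residues),
              nrow(object@residueAtoms), nrow(object@ligandAtoms)))
  if (!is.na(object@pkd)) cat(sprintf(", pKd = %.2f", object@pkd))
  cat("\n")
})

setMethod("show", "TrainConfig", function(object) {
  cat("TrainConfig:\n")
  cat(sprintf("  conv filters %s, kernel %dx%d, stride %d, padding %s\n",
              paste(object@convFilters, collapse = "/"), object@kernelSize,
              object@kernelSize, object@stride, object@padding))
  cat(sprintf("  dense widths %s, L2 %.3g, batch-norm momentum %.2f\n",
              paste(object@fcWidths, collapse = "/"), object@l2Weight,
              object@bnMomentum))
  cat(sprintf("  SGD lr %.4g, batch %d, alpha %.2f, loss mode %s\n",
              object@learningRate, object@batchSize, object@alpha,
              object@lossMode))
  cat(sprintf("  early stop: patience %d, minDelta %.4g, max %d epochs; %d runs from seed %d\n",
              object@patience, object@minDelta, object@maxEpochs,
              object@nRuns, object@seedBase))
})

setMethod("show", "ShellCNN", function(object) {
  cat(sprintf("ShellCNN (%s): input %d x %d, %d parameters\n",
              if (object@trained) "trained" else "untrained",
              object@inputDim[1], object@inputDim[2],
              countParameters(object)))
  if (object@trained && nrow(object@history))
    cat(sprintf("  %d epochs, best val loss %.4f\n", nrow(object@history),
                min(object@history$valLoss)))
})

setMethod("show", "ShellCNNEnsemble", function(object) {
  cat(sprintf("ShellCNNEnsemble: %d members, input %d x %d\n",
              length(object@members), object@inputDim[1], object@inputDim[2]))
})
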