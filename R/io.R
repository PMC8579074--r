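#' Read and write feature tables
#'
#' On-disk layout: CSV with a \code{complex_id} column, the canonical
#' \code{<shell>_<residueClass>_<atomClass>} count columns, and a \code{pkd}
#' label column (empty when unlabeled).
#'
#' @param features feature matrix (rownames = complex ids).
#' @param pkd labels parallel to the rows (NA allowed).
#' @param path CSV file.
#' @return \code{writeFeatureTable}: the path, invisibly;
#'   \code{readFeatureTable}: list(features, pkd).
#' @export
writeFeatureTable <- function(features, pkd, path) {
  stopifnot(nrow(features) == length(pkd))
  df <- data.frame(complex_id = rownames(features), features,
                   pkd = as.numeric(pkd), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"complex_id" %in% names(df)) stop("no complex_id column in ", path)
  ids <- as.character(df$complex_id)
  pkdCol <- if ("pkd" %in% names(df)) df$pkd else rep(NA_real_, nrow(df))
  X <- as.matrix(df[, setdiff(names(df), c("complex_id", "pkd")),
                    drop = FALSE])
  rownames(X) <- ids
  list(features = X, pkd = stats::setNames(as.numeric(pkdCol), ids))
}

#' Save / load a trained ensemble
#'
#' Weights go to an RDS file; a JSON sidecar records the configuration,
#' member seeds, standardizer statistics and per-epoch training histories
#' so a run is auditable without deserialising the weights.
#'
#' @param ensemble a \linkS4class{ShellCNNEnsemble}.
#' @param dir output directory (created).
#' @return \code{saveEnsemble}: \code{dir}, invisibly;
#'   \code{loadEnsemble}: the ensemble.
#' @export
saveEnsemble <- function(ensemble, dir) {
  stopifnot(is(ensemble, "ShellCNNEnsemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(ensemble, file.path(dir, "ensemble.rds"))
  cfg <- ensemble@config
  sidecar <- list(
    inputDim = ensemble@inputDim,
    nMembers = length(ensemble@members),
    seeds = vapply(ensemble@members, function(m) m@seed, 0L),
    config = list(convFilters = cfg@convFilters, kernelSize = cfg@kernelSize,
                  stride = cfg@stride, fcWidths = cfg@fcWidths,
                  learningRate = cfg@learningRate, l2Weight = cfg@l2Weight,
                  batchSize = cfg@batchSize, alpha = cfg@alpha,
                  patience = cfg@patience, minDelta = cfg@minDelta,
                  maxEpochs = cfg@maxEpochs, padding = cfg@padding,
                  lossMode = cfg@lossMode),
    standardizer = list(center = ensemble@standardizer@center,
                        scale = ensemble@standardizer@scale),
    history = lapply(ensemble@members, function(m) m@history))
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(dir) {
  f <- file.path(dir, "ensemble.rds")
  if (!file.exists(f)) stop("no ensemble.rds under ", dir)
  ens <- readRDS(f)
  stopifnot(is(ens, "ShellCNNEnsemble"))
  ens
}
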