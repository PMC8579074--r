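#' Scoring-power metrics: Pearson R, RMSE and regression SD
#'
#' The three standard scoring-power statistics for predicted vs experimental
#' pKd: the product-moment correlation R, the root-mean-squared error in pKd
#' units, and the standard deviation of the residuals about the least-squares
#' regression line of the experimental values on the predictions (the CASF
#' convention), \code{sqrt(sum((y - (a + b x))^2) / (n - 1))}.
#'
#' @param pred predicted pKd values.
#' @param obs experimental pKd values, same length.
#' @return a single number.
#' @export
#' @examples
#' pearsonR(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
pearsonR <- function(pred, obs) {
  .checkPair(pred, obs, minN = 2L)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop("undefined correlation: zero variance in input")
  stats::cor(pred, obs)
}

#' @rdname pearsonR
#' @export
rmse <- function(pred, obs) {
  .checkPair(pred, obs, minN = 1L)
  sqrt(mean((obs - pred)^2))
}

#' @rdname pearsonR
#' @export
sdRegression <- function(pred, obs) {
  .checkPair(pred, obs, minN = 3L)
  if (stats::sd(pred) == 0)
    stop("undefined fit: predictions have zero variance")
  fit <- stats::lm.fit(cbind(1, pred), obs)
  sqrt(sum(fit$residuals^2) / (length(obs) - 1L))
}

.checkPair <- function(pred, obs, minN) {
  if (length(pred) != length(obs))
    stop("pred and obs differ in length (", length(pred), " vs ",
         length(obs), ")")
  if (length(pred) < minN)
    stop("need at least ", minN, " observations")
  if (!all(is.finite(pred)) || !all(is.finite(obs)))
    stop("non-finite values in pred/obs")
  invisible(TRUE)
}

#' Composite training loss
#'
#' \code{alpha * (1 - R) + (1 - alpha) * RMSE}: a weighted mix of the
#' correlation and error terms, minimised during training and used for
#' early stopping and model selection.  The published weight is
#' \code{alpha = 0.7}.
#'
#' @inheritParams pearsonR
#' @param alpha weight of the (1 - R) term, in \code{[0, 1]}.
#' @return the loss value (>= 0 is not guaranteed in general but holds for
#'   alpha <= 1 since R <= 1 and RMSE >= 0).
#' @export
#' @examples
#' compositeLoss(c(1, 2, 3, 4), c(2, 1, 4, 3))
compositeLoss <- function(pred, obs, alpha = 0.7) {
  stopifnot(length(alpha) == 1L, alpha >= 0, alpha <= 1)
  alpha * (1 - pearsonR(pred, obs)) + (1 - alpha) * rmse(pred, obs)
}

#' Feature-importance loss difference
#'
#' The importance of one residue-atom combination is the increase in the
#' composite loss when the model is retrained with that combination's
#' features removed: \code{ablatedLoss - bestLoss}.  Larger values mean the
#' combination mattered more; small negative values can occur by training
#' noise.
#'
#' @param ablatedLoss loss of the model trained without the combination.
#' @param bestLoss loss of the full model under the same protocol.
#' @return the difference (vectorised).
#' @export
deltaLoss <- function(ablatedLoss, bestLoss) {
  as.numeric(ablatedLoss) - as.numeric(bestLoss)
}

#' Full metric report for a prediction set
#'
#' @inheritParams pearsonR
#' @return list with elements \code{n}, \code{pearson_r}, \code{rmse},
#'   \code{sd}; correlation and SD are NA when undefined (n < 2, zero
#'   variance, or n < 3 for SD).
#' @export
metricReport <- function(pred, obs) {
  .checkPair(pred, obs, minN = 1L)
  n <- length(pred)
  r <- if (n >= 2L && stats::sd(pred) > 0 && stats::sd(obs) > 0)
    pearsonR(pred, obs) else NA_real_
  s <- if (n >= 3L && stats::sd(pred) > 0) sdRegression(pred, obs) else NA_real_
  list(n = n, pearson_r = r, rmse = rmse(pred, obs), sd = s)
}

#' Write a metric report as JSON
#'
#' @param report a list from [metricReport()] (or a named list of them).
#' @param path output file.
#' @export
writeMetricReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
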