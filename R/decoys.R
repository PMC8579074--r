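# Exact minimum-cost perfect assignment on a square cost matrix, via
# maximum-weight bipartite matching (weights = maxCost + 1 - cost, strictly
# positive, so the optimal matching is perfect and minimises total cost).
.solveAssignment <- function(cost) {
  n <- nrow(cost)
  if (n == 1L) return(1L)
  w <- max(cost) + 1 - cost
  g <- igraph::graph_from_biadjacency_matrix(w, weighted = TRUE)
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  as.integer(m$matching[seq_len(n)]) - n
}

#' Symmetry-aware ligand RMSD via optimal per-element assignment
#'
#' For each element class, the correspondence between reference and pose
#' atoms is the linear assignment minimising the summed squared distances
#' (the Hungarian-algorithm reading of symmetry-corrected RMSD); the RMSD is
#' the root of the total minimum cost over the atom count.  No superposition
#' is applied: docking poses share the receptor frame.  The result never
#' exceeds the naive same-index RMSD.
#'
#' @param ref,pose ligand-atom data.frames (element, x, y, z columns), or
#'   lists with \code{coords} (n x 3) and \code{elements}.  Element
#'   multisets must match.
#' @param heavyOnly drop hydrogens (and deuteriums) before matching
#'   (default FALSE: hydrogens are matched like any element class).
#' @return RMSD in Angstrom.
#' @export
#' @examples
#' lig <- data.frame(element = c("C", "C"), x = c(0, 1), y = 0, z = 0)
#' swapped <- lig[2:1, ]
#' hungarianRmsd(lig, swapped)   # 0: assignment repairs the label swap
hungarianRmsd <- function(ref, pose, heavyOnly = FALSE) {
  getPart <- function(x) {
    if (is.data.frame(x))
      list(coords = as.matrix(x[, c("x", "y", "z")]),
           elements = toupper(as.character(x$element)))
    else list(coords = as.matrix(x$coords),
              elements = toupper(as.character(x$elements)))
  }
  a <- getPart(ref)
  b <- getPart(pose)
  if (heavyOnly) {
    ka <- !a$elements %in% c("H", "D")
    kb <- !b$elements %in% c("H", "D")
    a <- list(coords = a$coords[ka, , drop = FALSE], elements = a$elements[ka])
    b <- list(coords = b$coords[kb, , drop = FALSE], elements = b$elements[kb])
  }
  ta <- table(a$elements)
  tb <- table(b$elements)
  if (length(ta) != length(tb) || !identical(sort(names(ta)), sort(names(tb))) ||
      !all(ta[sort(names(ta))] == tb[sort(names(ta))])) {
    diff <- union(names(ta)[is.na(tb[names(ta)]) | ta != tb[names(ta)]],
                  names(tb)[is.na(ta[names(tb)]) | tb != ta[names(tb)]])
    stop("element multisets differ between poses: ",
         paste(diff, collapse = ", "))
  }
  total <- 0
  n <- length(a$elements)
  if (n == 0L) stop("no atoms to compare")
  for (el in names(ta)) {
    ia <- which(a$elements == el)
    ib <- which(b$elements == el)
    A <- a$coords[ia, , drop = FALSE]
    B <- b$coords[ib, , drop = FALSE]
    # direct squared differences keep identical atoms at exactly zero cost
    cost <- vapply(seq_len(nrow(B)), function(j)
      (A[, 1L] - B[j, 1L])^2 + (A[, 2L] - B[j, 2L])^2 +
      (A[, 3L] - B[j, 3L])^2, numeric(nrow(A)))
    cost <- matrix(cost, nrow = nrow(A))
    asg <- .solveAssignment(cost)
    total <- total + sum(cost[cbind(seq_along(ia), asg)])
  }
  sqrt(total / n)
}

#' The RMSD interval binning of the decoy protocol
#'
#' Ten half-open intervals tiling \code{[0, Inf)}: \code{[0,2)},
#' \code{[2,3)}, ..., \code{[9,10)}, \code{[10,Inf)}.
#'
#' @return data.frame with columns lower, upper, label.
#' @export
rmsdBinning <- function() {
  lower <- c(0, 2:10)
  upper <- c(2:10, Inf)
  data.frame(lower = lower, upper = upper,
             label = sprintf("[%g,%s)", lower,
                             ifelse(is.finite(upper), upper, "Inf")),
             stringsAsFactors = FALSE)
}

#' Assign decoys to RMSD bins, keeping the best decoy per bin
#'
#' Decoys are partitioned by RMSD interval; within each (receptor, interval)
#' only the decoy with the smallest RMSD is retained (ties: first by input
#' order).  Empty intervals yield no row.
#'
#' @param rmsd numeric vector of decoy RMSDs to the native pose.
#' @param receptor parallel receptor ids (default: one receptor).
#' @param binning interval table from [rmsdBinning()].
#' @return data.frame: receptor, bin (factor ordered by interval), decoy
#'   (input index of the selected decoy), rmsd.
#' @export
#' @examples
#' assignBins(c(1.5, 2.5, 2.7, 11.0))
assignBins <- function(rmsd, receptor = "r1", binning = rmsdBinning()) {
  stopifnot(all(is.finite(rmsd)), all(rmsd >= 0))
  receptor <- rep_len(as.character(receptor), length(rmsd))
  bin <- findInterval(rmsd, c(binning$lower, Inf),
                      rightmost.closed = FALSE)   # half-open [lo, hi)
  df <- data.frame(receptor = receptor, bin = bin, decoy = seq_along(rmsd),
                   rmsd = rmsd, stringsAsFactors = FALSE)
  picked <- do.call(rbind, lapply(split(df, list(df$receptor, df$bin),
                                        drop = TRUE), function(g)
    g[which.min(g$rmsd), , drop = FALSE]))       # which.min: first on ties
  picked <- picked[order(picked$receptor, picked$bin), , drop = FALSE]
  picked$bin <- factor(binning$label[picked$bin], levels = binning$label)
  rownames(picked) <- NULL
  picked
}

#' Per-bin RMSE of decoy predictions against native labels
#'
#' The pose-sensitivity profile: within each RMSD bin, the RMSE between the
#' predicted pKd of the decoy complexes and the experimental pKd of their
#' native complexes.  On real decoys this profile rises with RMSD.
#'
#' @param pred predicted pKd of the decoy complexes.
#' @param nativePkd experimental pKd of the corresponding native complexes.
#' @param bin bin labels (character or factor over [rmsdBinning()] labels).
#' @param binning interval table from [rmsdBinning()].
#' @return data.frame ordered as the binning: bin, n, rmse (NA for empty
#'   bins).
#' @export
decoyRmse <- function(pred, nativePkd, bin, binning = rmsdBinning()) {
  stopifnot(length(pred) == length(nativePkd), length(bin) == length(pred))
  if (any(!is.finite(nativePkd))) stop("missing native pKd label(s)")
  bin <- factor(as.character(bin), levels = binning$label)
  if (any(is.na(bin))) stop("bin labels outside the binning")
  k <- split(seq_along(pred), bin)
  data.frame(bin = binning$label,
             n = vapply(k, length, 0L),
             rmse = vapply(k, function(i)
               if (length(i)) rmse(pred[i], nativePkd[i]) else NA_real_, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
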