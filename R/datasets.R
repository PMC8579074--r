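#' Parse a PDBbind-style affinity index file
#'
#' Whitespace-delimited dialect: comment lines start with \code{#}; data
#' lines carry the complex code, resolution, release year, the
#' \code{-logKd/Ki} value (the pKd label) and a measurement token such as
#' \code{Kd=25nM}, \code{Ki~1uM} or \code{IC50>10uM}.  The measurement kind
#' is the token's prefix; \code{>}/\code{<} qualifiers mark inexact values.
#' Duplicate codes: the last occurrence wins, with a warning.
#'
#' @param path index file.
#' @param exactOnly drop records whose affinity carries a \code{>} or
#'   \code{<} qualifier (default TRUE; \code{~} is kept as exact).
#' @return data.frame with columns complexId (lowercase), pkd,
#'   measurementKind (Kd/Ki/IC50), resolution (NA for non-crystal entries),
#'   year.
#' @export
readAffinityIndex <- function(path, exactOnly = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("no data lines in '", path, "'")
  recs <- lapply(keep, function(ln) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(f) < 5L)
      stop("malformed index line ", ln, ": '", lines[ln], "'")
    pkdVal <- suppressWarnings(as.numeric(f[4L]))
    if (is.na(pkdVal))
      stop("malformed index line ", ln, ": cannot parse pKd from '",
           f[4L], "'")
    kind <- sub("[=<>~].*$", "", f[5L])
    if (!toupper(kind) %in% c("KD", "KI", "IC50"))
      stop("malformed index line ", ln, ": unknown measurement '", f[5L], "'")
    qual <- regmatches(f[5L], regexpr("[=<>~]", f[5L]))
    data.frame(complexId = tolower(f[1L]), pkd = pkdVal,
               measurementKind = c(KD = "Kd", KI = "Ki",
                                   IC50 = "IC50")[toupper(kind)],
               resolution = suppressWarnings(as.numeric(f[2L])),
               year = suppressWarnings(as.integer(f[3L])),
               exact = !(length(qual) && qual %in% c("<", ">")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  if (exactOnly) out <- out[out$exact, , drop = FALSE]
  dup <- duplicated(out$complexId, fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate id(s); keeping the last occurrence: ",
            paste(unique(out$complexId[dup]), collapse = ", "))
    out <- out[!dup, , drop = FALSE]
  }
  out$exact <- NULL
  rownames(out) <- NULL
  out
}

#' Build a leakage-free train/validation/test split
#'
#' Published protocol: every complex appearing in any test set is removed
#' from both the general and the refined pools; the validation set is then
#' \code{nVal} complexes sampled uniformly without replacement from the
#' filtered refined set; everything remaining in general + refined becomes
#' the training set.  Disjointness of all sets is re-verified before
#' returning, not assumed.
#'
#' @param general,refined record data.frames (from [readAffinityIndex()]) or
#'   plain id vectors.
#' @param testSets named list of test-set id vectors.
#' @param nVal validation-set size (default 1000, the published count).
#' @param seed RNG seed; (inputs, seed) fully determine the split.
#' @return list of class \code{DatasetSplit}: trainIds, valIds, testSets.
#' @export
makeSplit <- function(general, refined, testSets, nVal = 1000L, seed = 1L) {
  asIds <- function(x) {
    ids <- if (is.data.frame(x)) x$complexId else as.character(x)
    unique(tolower(ids))
  }
  gen <- asIds(general)
  ref <- asIds(refined)
  stopifnot(is.list(testSets), length(names(testSets)) == length(testSets))
  tests <- lapply(testSets, asIds)
  testAll <- unique(unlist(tests))
  pool <- setdiff(ref, testAll)
  if (length(pool) < nVal)
    stop("refined pool after test exclusion has only ", length(pool),
         " complexes; cannot sample nVal = ", nVal)
  val <- withr::with_seed(as.integer(seed),
                          sample(pool, nVal, replace = FALSE))
  train <- setdiff(union(gen, ref), c(testAll, val))
  split <- structure(list(trainIds = sort(train), valIds = sort(val),
                          testSets = tests),
                     class = "DatasetSplit")
  assertDisjoint(split)
  split
}

#' Assert that a split's sets are pairwise disjoint
#'
#' @param split a \code{DatasetSplit}.
#' @return invisibly TRUE; errors naming the offending overlap otherwise.
#' @export
assertDisjoint <- function(split) {
  sets <- c(list(train = split$trainIds, val = split$valIds),
            split$testSets)
  nm <- names(sets)
  for (i in seq_along(sets)) for (j in seq_len(i - 1L)) {
    ov <- intersect(sets[[i]], sets[[j]])
    if (length(ov))
      stop("split sets '", nm[i], "' and '", nm[j], "' overlap: ",
           paste(utils::head(ov, 5L), collapse = ", "))
  }
  invisible(TRUE)
}

#' Scoring-power metrics within externally supplied subsets
#'
#' Applies [metricReport()] inside each group of a user-supplied label table
#' (e.g. the CASF hydrophobicity / buried-area / volume subset labels H1-H3,
#' S1-S3, V1-V3).  Groups with fewer than 2 complexes get an NA correlation.
#'
#' @param pred,obs named (by complex id) or plain parallel vectors.
#' @param ids complex ids matching \code{pred}/\code{obs}.
#' @param groups named character vector mapping id -> group label, or a
#'   data.frame with columns complexId and label.
#' @return data.frame: one row per group with n, pearson_r, rmse, sd.
#' @export
groupedMetrics <- function(pred, obs, ids, groups) {
  stopifnot(length(pred) == length(obs), length(ids) == length(pred))
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$label),
                              tolower(groups$complexId))
  lab <- groups[tolower(ids)]
  if (any(is.na(lab)))
    stop("no group label for id(s): ",
         paste(utils::head(ids[is.na(lab)], 5L), collapse = ", "))
  out <- lapply(split(seq_along(pred), lab), function(k)
    as.data.frame(metricReport(pred[k], obs[k])))
  res <- do.call(rbind, out)
  res <- cbind(group = names(out), res)
  rownames(res) <- NULL
  res
}
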