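# Independent oracles used across the suite.  Each is deliberately naive
# (triple loops, exhaustive enumeration, closed forms) and shares no code
# with the implementation paths it checks.

# Brute-force contact counting: loop residue x ligand atom x shell,
# using interval membership directly.
bruteForceFeaturize <- function(cx, spec) {
  res <- residues(cx)
  ra <- residueAtoms(cx)
  la <- ligandAtoms(cx)
  out <- setNames(integer(168L * nShells(spec)), featureNames(spec))
  for (r in seq_len(nrow(res))) {
    rc <- as.matrix(ra[ra$residue == r, c("x", "y", "z")])
    for (e in seq_len(nrow(la))) {
      p <- as.numeric(la[e, c("x", "y", "z")])
      d <- sqrt(min(colSums((t(rc) - p)^2)))
      for (i in seq_len(nShells(spec))) {
        b <- shellBounds(spec, i)
        if (d >= b[1L, "lower"] && d < b[1L, "upper"]) {
          nm <- paste0(i, "_", res$residueClass[r], "_", la$atomClass[e])
          out[nm] <- out[nm] + 1L
        }
      }
    }
  }
  out
}

# All permutations of 1..n (n small).
allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1L)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

# Exhaustive symmetry-corrected RMSD: minimise over every per-element
# permutation independently.
exhaustiveRmsd <- function(ref, pose) {
  els <- unique(ref$element)
  total <- 0
  for (el in els) {
    A <- as.matrix(ref[ref$element == el, c("x", "y", "z"), drop = FALSE])
    B <- as.matrix(pose[pose$element == el, c("x", "y", "z"), drop = FALSE])
    n <- nrow(A)
    best <- Inf
    for (p in allPerms(n)) {
      cost <- sum((A - B[p, , drop = FALSE])^2)
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  sqrt(total / nrow(ref))
}

# Apply a rigid motion (rotation by theta about a random-ish fixed axis via
# two Givens rotations, plus translation) to a complex.
rigidTransform <- function(cx, theta = 0.83, shift = c(4.2, -7.1, 2.5)) {
  R1 <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0,
                 0, 0, 1), 3L)
  R2 <- matrix(c(1, 0, 0, 0, cos(1.1), sin(1.1), 0, -sin(1.1), cos(1.1)), 3L)
  R <- R1 %*% R2
  mv <- function(df) {
    m <- as.matrix(df[, c("x", "y", "z")]) %*% R
    df$x <- m[, 1L] + shift[1L]
    df$y <- m[, 2L] + shift[2L]
    df$z <- m[, 3L] + shift[3L]
    df
  }
  complexStructure(complexId(cx),
                   list(residues = residues(cx),
                        residueAtoms = mv(residueAtoms(cx))),
                   mv(ligandAtoms(cx)), pkd = pkd(cx))
}

# Closed-form Pearson correlation straight from its defining sums.
closedFormR <- function(x, y) {
  n <- length(x)
  sum((x - sum(x) / n) * (y - sum(y) / n)) /
    sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
}

# Closed-form OLS y = a + b x and residual SD with divisor n - 1.
closedFormSd <- function(x, y) {
  n <- length(x)
  b <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  a <- mean(y) - b * mean(x)
  sqrt(sum((y - a - b * x)^2) / (n - 1))
}

# The reduced training protocol used by the learning tests: 10 shells and a
# slimmed filter complement so a full run fits a single CPU.  Plain SGD at a
# large step size with reduce-on-plateau decay; batch-norm statistics track
# faster than the full-scale default so validation selection sees current
# weights.
recoveryConfig <- function(seed, nRuns = 1L) {
  trainConfig(convFilters = c(2L, 4L, 8L), fcWidths = c(16L, 8L),
              learningRate = 0.5, batchSize = 32L, maxEpochs = 150L,
              patience = 25L, lrDecay = 0.7, decayEvery = 6L,
              bnMomentum = 0.8, nRuns = nRuns, seedBase = as.integer(seed))
}

# One shared small labeled dataset for the cheaper model tests (built once
# per test run).
.fixtureEnv <- new.env(parent = emptyenv())

smallLinearDataset <- function() {
  if (is.null(.fixtureEnv$small)) {
    spec <- shellSpec(nShells = 10L)
    ds <- generateDataset(syntheticSpec(nComplexes = 400L, seed = 20L), spec)
    .fixtureEnv$small <- list(spec = spec, ds = ds)
  }
  .fixtureEnv$small
}
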