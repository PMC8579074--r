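# Shell geometry and contact-count featurization.

test_that("shell bounds tile [0, d0 + (N-1) delta) without gap or overlap", {
  spec <- shellSpec(d0 = 1, delta = 0.5, nShells = 62L)
  b <- shellBounds(spec, seq_len(62L))
  expect_equal(b[1L, ], c(lower = 0, upper = 1))
  expect_equal(b[2L, ], c(lower = 1, upper = 1.5))
  # contiguity: each upper bound is the next lower bound
  expect_equal(b[-62L, "upper"], b[-1L, "lower"], ignore_attr = TRUE)
  expect_equal(b[62L, "upper"], 1 + 61 * 0.5, ignore_attr = TRUE)
  expect_error(shellBounds(spec, 0L), "out of range")
  expect_error(shellBounds(spec, 63L), "out of range")
})

test_that("outermost boundaries match the shell-count sweep endpoints", {
  spec <- shellSpec(d0 = 1, delta = 0.5, nShells = 90L)
  expect_equal(shellBounds(spec, 90L)[1L, "upper"] / 10, 4.55,
               ignore_attr = TRUE)   # 4.55 nm at N = 90
  spec10 <- shellSpec(d0 = 1, delta = 0.5, nShells = 10L)
  expect_equal(shellBounds(spec10, 10L)[1L, "upper"] / 10, 0.55,
               ignore_attr = TRUE)   # 0.55 nm at N = 10
})

test_that("residue-atom distance is the minimum over heavy atoms", {
  rc <- rbind(c(0, 0, 0), c(0, 0, 10))
  expect_identical(residueAtomDistance(rc, c(0, 0, 3)), 3)
  expect_identical(residueAtomDistance(rbind(c(1, 2, 3)), c(1, 2, 3)), 0)
  # exhaustive pairwise oracle on random residues
  set.seed(42)
  for (trial in 1:100) {
    m <- sample(1:10, 1L)
    rc <- matrix(rnorm(3 * m, sd = 5), ncol = 3L)
    p <- rnorm(3, sd = 5)
    expect_equal(residueAtomDistance(rc, p),
                 min(apply(rc, 1L, function(a) sqrt(sum((a - p)^2)))),
                 tolerance = 1e-12)
  }
})

test_that("a single in-sphere pair yields exactly one count", {
  res <- data.frame(chainId = "A", seqNumber = 1L, insertCode = "",
                    rawName = "GLY", residueClass = "GLY", nAtoms = 1L)
  ra <- data.frame(residue = 1L, x = 0, y = 0, z = 0)
  la <- data.frame(element = "C", atomClass = "C", x = 0.5, y = 0, z = 0)
  cx <- complexStructure("one", list(residues = res, residueAtoms = ra), la)
  spec <- shellSpec(nShells = 62L)
  fv <- featurizeComplex(cx, spec)
  expect_identical(length(fv), 10416L)
  expect_identical(sum(fv), 1L)
  expect_identical(unname(fv["1_GLY_C"]), 1L)
})

test_that("featurize matches the brute-force oracle exactly", {
  spec <- shellSpec(nShells = 10L)
  sspec <- syntheticSpec(nComplexes = 12L, residueRange = c(5L, 15L),
                         ligandRange = c(4L, 10L), seed = 77L)
  for (i in seq_len(12L)) {
    cx <- generateComplex(sspec, i)
    expect_identical(as.integer(featurizeComplex(cx, spec)),
                     as.integer(bruteForceFeaturize(cx, spec)),
                     label = paste("complex", i))
  }
})

test_that("features are exactly invariant under rigid motion", {
  spec <- shellSpec(nShells = 12L)
  sspec <- syntheticSpec(nComplexes = 8L, seed = 13L)
  for (i in seq_len(8L)) {
    cx <- generateComplex(sspec, i)
    expect_identical(featurizeComplex(rigidTransform(cx), spec),
                     featurizeComplex(cx, spec))
  }
})

test_that("per-combination shell sums obey conservation and monotone coverage", {
  sspec <- syntheticSpec(nComplexes = 6L, seed = 31L)
  specs <- lapply(c(6L, 10L, 20L), function(n) shellSpec(nShells = n))
  for (i in seq_len(6L)) {
    cx <- generateComplex(sspec, i)
    d <- shellscore:::.minDistanceMatrix(cx)
    rCls <- residues(cx)$residueClass
    eCls <- ligandAtoms(cx)$atomClass
    prev <- NULL
    for (spec in specs) {
      fv <- featurizeComplex(cx, spec)
      img <- featureImage(fv, spec)
      cum <- colSums(img)          # per-combination total over shells
      # conservation: equals within-range pair count per combination
      rng <- 1 + (nShells(spec) - 1) * 0.5
      for (combo in names(which(cum > 0))) {
        parts <- strsplit(combo, "_")[[1L]]
        inRange <- sum(d[rCls == parts[1L], eCls == parts[2L], drop = FALSE]
                       < rng)
        expect_identical(unname(cum[combo]), as.numeric(inRange))
      }
      expect_true(sum(fv) <= nrow(residues(cx)) * nrow(ligandAtoms(cx)))
      if (!is.null(prev)) expect_true(all(cum >= prev))
      prev <- cum
    }
  }
})

test_that("feature image reshape is invertible and lays shells on rows", {
  spec <- shellSpec(nShells = 62L)
  set.seed(3)
  fv <- rpois(10416L, 0.3)
  img <- featureImage(fv, spec)
  expect_identical(dim(img), c(62L, 168L))
  expect_identical(flattenImage(img), as.numeric(fv))
  expect_identical(featureImage(numeric(10416L), spec),
                   featureImage(numeric(10416L), spec) * 0)
  # row i of the image is shell i's block of the vector
  expect_identical(unname(img[5L, ]), as.numeric(fv[(4L * 168L + 1L):(5L * 168L)]))
  expect_error(featureImage(fv[-1L], spec), "does not match")
})

test_that("feature names follow the canonical shell-major layout", {
  spec <- shellSpec(nShells = 3L)
  nm <- featureNames(spec)
  expect_length(nm, 504L)
  expect_identical(nm[1L], "1_GLY_C")
  expect_identical(nm[8L], "1_GLY_DU")
  expect_identical(nm[9L], "1_ALA_C")
  expect_identical(nm[169L], "2_GLY_C")
  expect_identical(nm[504L], "3_OTH_DU")
})
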