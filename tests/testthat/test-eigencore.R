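test_that("worked-example reduced eigenequation reproduces printed solution", {
  rm <- buildReducedExact(workedExampleSigma())
  expect_equal(sum(diag(reducedOperator(rm))), 3804.18, tolerance = 0.01 / 3804)
  sys <- solveReduced(rm)
  expect_equal(round(eigenValues(sys), 2), c(3599.06, 204.80, 0.32, 0.00))
  V <- eigenVectors(sys)
  printed <- cbind(c(-0.82, 0.50, 0.23, 0.18),
                   c(-0.10, -0.48, 0.86, -0.13),
                   c(-0.17, -0.58, -0.22, 0.77),
                   c(0.50, 0.50, 0.50, 0.50))
  for (j in 1:4) {
    agree <- min(max(abs(V[, j] - printed[, j])),
                 max(abs(V[, j] + printed[, j])))
    expect_lt(agree, 0.005)  # 2-decimal precision up to sign
  }
  expect_identical(trivialIndex(sys), 4L)
})

test_that("operator annihilates constants and obeys the trace identity", {
  for (seed in 1:6) {
    sig <- randomSigma(K = 2 + seed %% 3, seed = seed)
    for (rm in list(buildReducedExact(sig), buildReducedAsymptotic(sig))) {
      A <- reducedOperator(rm)
      expect_lt(max(abs(A %*% rep(1, ncol(A)))), 1e-12 * max(1, max(abs(A))))
      sys <- solveReduced(rm)
      expect_equal(sum(eigenValues(sys)), sum(diag(A)),
        tolerance = 1e-9 / max(1, abs(sum(diag(A)))))
      # trivial eigenvector is exactly constant with a null eigenvalue
      ti <- trivialIndex(sys)
      expect_false(is.na(ti))
      expect_equal(unname(eigenVectors(sys)[, ti]),
        rep(1 / sqrt(nrow(A)), nrow(A)), tolerance = 1e-9)
      expect_lt(abs(eigenValues(sys)[ti]), 1e-9 * max(abs(eigenValues(sys))))
    }
  }
})

test_that("reduced eigenpairs equal block-constant eigenpairs of the full covariance", {
  for (seed in 1:5) {
    sig <- randomSigma(K = 3, seed = 20 + seed, nRange = c(4, 8))
    n <- sampleSizes(sig)
    Psi <- fullCovarianceOracle(sig)
    expect_lt(max(abs(Psi %*% rep(1, nrow(Psi)))), 1e-9)
    sys <- solveReduced(buildReducedExact(sig))
    V <- eigenVectors(sys)
    scaleRef <- max(abs(eigenValues(sys)))
    for (j in seq_along(eigenValues(sys))) {
      vFull <- rep(V[, j], times = n)
      expect_lt(max(abs(Psi %*% vFull - eigenValues(sys)[j] * vFull)),
        1e-9 * max(scaleRef, 1))
    }
  }
  expect_error(fullCovarianceOracle(workedExampleSigma()), "guard")
})

test_that("single-population covariance reduces to the diagonal-excess form", {
  sig <- SigmaSet(var = 0.7, cov = matrix(0.3), n = 10, labels = "P1")
  Psi <- fullCovarianceOracle(sig)
  ev <- eigen(Psi, symmetric = TRUE)$values
  # centering of (sigma_kk J + d I) leaves d on the N-1 non-trivial directions
  expect_equal(ev, c(rep(0.4, 9), 0), tolerance = 1e-12)
})

test_that("asymptotic form approximates the exact one and converges as n grows", {
  sig <- workedExampleSigma()
  lamInf <- eigenValues(solveReduced(buildReducedAsymptotic(sig)))
  expect_lt(max(abs(sum(sampleSizes(sig)) * lamInf[1:2] - c(3599.06, 204.80))), 1.5)
  # factor-10 scaling at fixed relative sizes at least halves the relative gap
  gap <- sapply(c(1, 10), function(s) {
    sc <- SigmaSet(sigmaVar(sig), sigmaCov(sig), n = sampleSizes(sig) * s / 100,
      labels = popLabels(sig))
    ex <- eigenValues(solveReduced(buildReducedExact(sc)))[1:2]
    as <- sum(sampleSizes(sc)) * eigenValues(solveReduced(buildReducedAsymptotic(sc)))[1:2]
    max(abs(ex - as) / abs(ex))
  })
  expect_lt(gap[2], gap[1] / 2)
})

test_that("indistinguishable populations give a null asymptotic operator", {
  # within-population covariance equal to between: no population structure
  sig <- SigmaSet(var = rep(0.7, 3), cov = matrix(0.2, 3, 3), n = c(10, 20, 30))
  expect_lt(max(abs(reducedOperator(buildReducedAsymptotic(sig)))), 1e-14)
  # if within exceeds between, K - 1 equal structural axes remain
  sig2 <- SigmaSet(var = rep(0.7, 3), cov = matrix(0.2, 3, 3) + diag(0.1, 3),
    n = c(30, 30, 30))
  lam <- eigenValues(solveReduced(buildReducedAsymptotic(sig2)))
  expect_equal(lam[1], lam[2], tolerance = 1e-12)
  expect_lt(abs(lam[3]), 1e-14)
})

test_that("two symmetric populations split along the difference direction", {
  sig <- SigmaSet(var = c(0.7, 0.7),
    cov = matrix(c(0.3, 0.1, 0.1, 0.3), 2, 2), n = c(40, 40))
  sys <- solveReduced(buildReducedExact(sig))
  expect_equal(abs(unname(eigenVectors(sys)[, 1])), rep(1 / sqrt(2), 2),
    tolerance = 1e-9)
})

test_that("admixture adds no axis of variation in the asymptotic system", {
  for (seed in 1:4) {
    mod <- randomModel(K = 3, seed = 40 + seed)
    sigBase <- alleleCountMoments(mod)
    nzCount <- function(sig) {
      lam <- eigenValues(solveReduced(buildReducedAsymptotic(sig)))
      sum(lam > 1e-10 * max(lam))
    }
    base <- nzCount(sigBase)
    lam <- c(0.25, 0.35, 0.4)
    sigAdm <- alleleCountMoments(extendWithAdmixture(
      addAdmixedPopulation(mod, "A", 1:3, lam, n = 25)))
    expect_identical(nzCount(sigAdm), base)
  }
  # two parents plus their admixture: exactly one structural eigenvalue
  mod2 <- randomModel(K = 2, seed = 50)
  sig2 <- alleleCountMoments(extendWithAdmixture(
    addAdmixedPopulation(mod2, "A", 1:2, c(0.6, 0.4), n = 30)))
  lam2 <- eigenValues(solveReduced(buildReducedAsymptotic(sig2)))
  expect_identical(sum(lam2 > 1e-12 * max(lam2)), 1L)
})

test_that("admixed coordinates are proportion-weighted parental coordinates", {
  # exact identity on the asymptotic system's structural eigenvectors
  for (seed in 1:5) {
    mod <- randomModel(K = 3, seed = 60 + seed)
    lam <- as.vector(stats::rmultinom(1, 20, rep(1, 3))) / 20
    sig <- alleleCountMoments(extendWithAdmixture(
      addAdmixedPopulation(mod, "A", 1:3, lam, n = 35)))
    sys <- solveReduced(buildReducedAsymptotic(sig))
    vals <- eigenValues(sys)
    V <- eigenVectors(sys)
    structural <- which(vals > 1e-8 * max(vals))
    expect_gte(length(structural), 2)
    for (j in structural)
      expect_equal(unname(V["A", j]), unname(drop(lam %*% V[1:3, j])),
        tolerance = 1e-9)
  }
  # printed worked example obeys the law at its 2-decimal precision
  sysT <- solveReduced(buildReducedExact(workedExampleSigma()))
  V <- eigenVectors(sysT)
  expect_equal(unname(V["P4", 1]),
    unname(drop(c(0.2, 0.6, 0.2) %*% V[1:3, 1])), tolerance = 0.005)
})

test_that("empirical PCA separates differentiated populations", {
  panel <- simulateParentalPanel(10000, 0.1, c(50, 50), seed = 31)
  sys <- empiricalPCA(panel, nVectors = 2)
  V <- eigenVectors(sys)
  pop <- panelPopulations(panel)
  cent <- popCentroids(sys)
  spread <- max(tapply(V[, 1], pop, sd))
  expect_lt(spread / abs(cent["P1", 1] - cent["P2", 1]), 0.5)
})

test_that("constant panels give an all-zero empirical spectrum", {
  panel <- GenotypePanel(matrix(1L, 10, 6), rep(c("A", "B"), each = 3))
  sys <- empiricalPCA(panel, nVectors = 3)
  expect_equal(eigenValues(sys), rep(0, 3), tolerance = 1e-12)
  expect_warning(empiricalPCA(panel, nVectors = 10), "clipped")
})

test_that("empirical centroids agree with the theoretical solve up to affine maps", {
  # two parents, an additional population, two homogeneous admixed groups:
  # barycentric coordinates of the admixed centroids agree between the
  # empirical eigenvector-plot and the reduced-equation solution from
  # estimated sigma parameters.
  par <- simulateParentalPanel(10000, 0.01, c(50, 50, 50), seed = 77)
  g4 <- simulateAdmixedHomogeneous(par, c(0.4, 0.6), 30, seed = 77,
    label = "P4", parentLabels = c("P1", "P2"))
  g5 <- simulateAdmixedHomogeneous(par, c(0.65, 0.35), 30, seed = 77,
    label = "P5", parentLabels = c("P1", "P2"))
  panel <- combinePanels(par, g4, g5)
  sysE <- empiricalPCA(panel, nVectors = 2)
  centE <- popCentroids(sysE)
  sysT <- solveReduced(buildReducedExact(estimateSigma(panel)))
  VT <- eigenVectors(sysT)
  structural <- setdiff(order(-eigenValues(sysT))[1:3], trivialIndex(sysT))[1:2]
  centT <- VT[, structural]
  for (adm in c("P4", "P5")) {
    bE <- proportions(segmentRatio(centE[adm, ], centE[c("P1", "P2"), ]))
    bT <- proportions(segmentRatio(centT[adm, ], centT[c("P1", "P2"), ]))
    expect_equal(unname(bE), unname(bT), tolerance = 0.03)
  }
})
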