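# Shared fixtures: the four-population worked example (three differentiated
# parental populations plus a 0.2:0.6:0.2 admixed one) and random-model
# generators used by the property tests.

exampleFreqCov <- function() {
  matrix(c(0.10, 0.01, 0.04,
           0.01, 0.10, 0.09,
           0.04, 0.09, 0.10), 3, 3, byrow = TRUE)
}

workedExampleModel <- function(resolved = TRUE) {
  mod <- PopulationModel(mu = rep(0.4, 3), C = exampleFreqCov(),
    n = c(9000, 8000, 7000), labels = c("P1", "P2", "P3"))
  mod <- addAdmixedPopulation(mod, "P4", c("P1", "P2", "P3"),
    c(0.2, 0.6, 0.2), n = 10000)
  if (resolved) extendWithAdmixture(mod) else mod
}

workedExampleSigma <- function() alleleCountMoments(workedExampleModel())

# Printed eigenvector-plot coordinates of the worked example (first two
# eigenvectors, rounded to 2 decimals as published).
workedExamplePlotCoords <- function() {
  rbind(P1 = c(-0.82, -0.10), P2 = c(0.50, -0.48), P3 = c(0.23, 0.86))
}

# Random valid frequency model: PSD covariance scaled to keep frequencies in
# (0, 1) territory, means away from the boundary so d_k > 0.
randomModel <- function(K = 3, seed = 1, nRange = c(20, 200)) {
  set.seed(seed)
  A <- matrix(rnorm(K * K), K)
  C <- crossprod(A)
  C <- 0.05 * C / max(diag(C))
  PopulationModel(mu = runif(K, 0.3, 0.7), C = C,
    n = sample(nRange[1]:nRange[2], K, replace = TRUE))
}

randomSigma <- function(K = 3, seed = 1, nRange = c(4, 12)) {
  alleleCountMoments(randomModel(K, seed, nRange))
}

# Frequency model implied by the Balding-Nichols simulator with a shared
# ancestral frequency p ~ U(lo, hi): mu_k = (lo+hi)/2, c_kl = Var(p) for
# k != l and c_kk = Var(p) + F_k E[p(1-p)].
bnImpliedModel <- function(fst, n, lo = 0.1, hi = 0.9,
                           labels = paste0("P", seq_along(n))) {
  vp <- (hi - lo)^2 / 12
  mp <- (lo + hi) / 2
  ep1p <- mp - (vp + mp^2)
  K <- length(n)
  C <- matrix(vp, K, K) + diag(fst * ep1p, K)
  PopulationModel(mu = rep(mp, K), C = C, n = n, labels = labels)
}

# Block standard error of estimateSigma entries: split the markers into
# blocks, estimate per block, and return mean and SE matrices over blocks.
blockSigma <- function(panel, nBlocks = 20) {
  X <- panelCounts(panel)
  pop <- panelPopulations(panel)
  blocks <- split(seq_len(nrow(X)), cut(seq_len(nrow(X)), nBlocks, labels = FALSE))
  ests <- lapply(blocks, function(ix) {
    sub <- GenotypePanel(X[ix, , drop = FALSE], pop)
    s <- estimateSigma(sub)
    list(var = sigmaVar(s), cov = sigmaCov(s))
  })
  vm <- sapply(ests, function(e) e$var)
  cm <- simplify2array(lapply(ests, function(e) e$cov))
  list(
    var = rowMeans(vm), varSE = apply(vm, 1, sd) / sqrt(nBlocks),
    cov = apply(cm, 1:2, mean), covSE = apply(cm, 1:2, sd) / sqrt(nBlocks)
  )
}

expect_within3SE <- function(est, se, truth) {
  expect_true(all(abs(est - truth) <= 3 * se + 1e-12),
    label = paste0("max |est-truth|/SE = ",
      round(max(abs(est - truth) / pmax(se, 1e-12)), 2)))
}
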