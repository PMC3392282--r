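test_that("constructed barycentric weights are recovered exactly and routes agree", {
  set.seed(1)
  for (i in 1:1000) {
    P <- matrix(rnorm(6), 3, 2)
    # keep clearly non-degenerate triangles
    if (abs(det(cbind(P[2, ] - P[1, ], P[3, ] - P[1, ]))) < 0.1) next
    w <- rgamma(3, 1); w <- w / sum(w)
    q <- drop(w %*% P)
    bar <- proportions(barycentricProportions(q, P))
    tri <- proportions(triangleAreaProportions(q, P))
    expect_lt(max(abs(bar - w)), 1e-12)
    expect_lt(max(abs(tri - bar)), 1e-12)
  }
})

test_that("segment ratio is exact in one dimension and matches barycentric", {
  set.seed(2)
  for (i in 1:100) {
    v <- rnorm(2)
    if (abs(diff(v)) < 1e-3) next
    a <- runif(1, -0.5, 1.5)
    q <- a * v[1] + (1 - a) * v[2]
    est <- segmentRatio(q, matrix(v, 2, 1))
    expect_equal(unname(proportions(est))[1], a, tolerance = 1e-12)
    bar <- barycentricProportions(q, matrix(v, 2, 1))
    expect_equal(unname(proportions(bar)), unname(proportions(est)),
      tolerance = 1e-12)
  }
  expect_equal(unname(proportions(segmentRatio(0.5, matrix(c(0, 1), 2, 1)))),
    c(0.5, 0.5))
})

test_that("worked-example printed coordinates recover the printed proportions", {
  q <- c(0.18, -0.13)
  P <- workedExamplePlotCoords()
  bar <- proportions(barycentricProportions(q, P))
  tri <- proportions(triangleAreaProportions(q, P))
  expect_equal(round(unname(bar), 4), c(0.2006, 0.5951, 0.2043))
  expect_equal(unname(tri), unname(bar), tolerance = 1e-12)
})

test_that("proportions are invariant under joint affine transforms", {
  set.seed(3)
  for (i in 1:50) {
    P <- matrix(rnorm(6), 3, 2)
    q <- drop(c(0.2, 0.5, 0.3) %*% P) + rnorm(2, sd = 0.05)
    A <- matrix(rnorm(4), 2, 2)
    if (abs(det(A)) < 0.1 ||
        abs(det(cbind(P[2, ] - P[1, ], P[3, ] - P[1, ]))) < 0.1) next
    b <- rnorm(2)
    f <- function(x) drop(A %*% x + b)
    Pt <- t(apply(P, 1, f))
    p0 <- proportions(barycentricProportions(q, P))
    p1 <- proportions(barycentricProportions(f(q), Pt))
    expect_equal(unname(p1), unname(p0), tolerance = 1e-10)
  }
})

test_that("residual distance is invariant under rigid motions and equals the offset", {
  set.seed(4)
  P <- matrix(rnorm(9), 3, 3)          # triangle in 3D
  w <- c(0.3, 0.3, 0.4)
  base <- drop(w %*% P)
  u <- P[2, ] - P[1, ]; v <- P[3, ] - P[1, ]
  nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  h <- 0.37
  q <- base + h * nrm
  est <- barycentricProportions(q, P)
  expect_equal(residualDistance(est), h, tolerance = 1e-12)
  expect_equal(unname(proportions(est)), w, tolerance = 1e-12)
  # rigid motion: rotation (QR orthogonal factor) plus translation
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  g <- function(x) drop(Q %*% x + c(1, -2, 3))
  est2 <- barycentricProportions(g(q), t(apply(P, 1, g)))
  expect_equal(residualDistance(est2), h, tolerance = 1e-10)
  expect_equal(residualRatio(est2), residualRatio(est), tolerance = 1e-10)
})

test_that("vertex, edge and centroid queries give the expected special values", {
  P <- rbind(A = c(0, 0), B = c(2, 0), C = c(1, 2))
  expect_equal(unname(proportions(barycentricProportions(P[2, ], P))),
    c(0, 1, 0), tolerance = 1e-14)
  expect_equal(residualDistance(barycentricProportions(P[2, ], P)), 0)
  expect_equal(unname(proportions(triangleAreaProportions(colMeans(P), P))),
    rep(1 / 3, 3), tolerance = 1e-14)
  onEdge <- 0.4 * P[2, ] + 0.6 * P[3, ]
  expect_equal(unname(proportions(triangleAreaProportions(onEdge, P)))[1], 0,
    tolerance = 1e-14)
  outside <- c(-1, -1)
  expect_false(insideHull(triangleAreaProportions(outside, P)))
})

test_that("degenerate parental geometry is rejected by name", {
  collinear <- rbind(P1 = c(0, 0), P2 = c(1, 1), P3 = c(2, 2))
  expect_error(barycentricProportions(c(0.3, 0.5), collinear), "P1, P2, P3")
  expect_error(triangleAreaProportions(c(0.3, 0.5), collinear), "zero area")
  expect_error(segmentRatio(0.3, matrix(c(1, 1), 2, 1)), "coincident")
})

test_that("affine residual reports hull distances without thresholding", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0))
  res <- affineResidual(c(0.5, 0.25, 0), P)
  expect_equal(res$distance, 0.25)
  expect_equal(res$ratio, 0.25)
  expect_equal(affineResidual(c(0.7, 0, 0), P)$distance, 0)
})

test_that("individual-level estimates recover heterogeneous generating proportions", {
  # recently admixed two-way design: per-individual Beta(5, 5) proportions
  par <- simulateParentalPanel(10000, 0.01, c(50, 50), seed = 101)
  adm <- simulateAdmixedRecent(par, shape = c(5, 5), n = 35, seed = 101,
    label = "ADM")
  panel <- combinePanels(par, adm)
  sys <- empiricalPCA(panel, nVectors = 2)
  est <- individualProportions(sys, c("P1", "P2"), "ADM")
  truth <- panelTruth(panel)$proportions$ADM
  got <- est$individuals[match(rownames(truth), est$individuals$id), "P1"]
  # per-individual error sits at the binomial-sampling noise floor of this
  # design (~0.06 at M = 10,000, FST = 0.01); the group mean is much tighter
  expect_lt(mean(abs(got - truth[, "P1"])), 0.08)
  expect_gt(cor(got, truth[, "P1"], method = "spearman"), 0.9)
  expect_lt(abs(mean(got) - mean(truth[, "P1"])), 0.03)
  expect_equal(est$summary$P1 + est$summary$P2, 1, tolerance = 1e-12)
})

test_that("individual estimates concentrate as the marker count grows", {
  sdAt <- function(M) {
    par <- simulateParentalPanel(M, 0.05, c(40, 40), seed = 55)
    adm <- simulateAdmixedHomogeneous(par, c(0.3, 0.7), 30, seed = 55,
      label = "ADM")
    sys <- empiricalPCA(combinePanels(par, adm), nVectors = 2)
    est <- individualProportions(sys, c("P1", "P2"), "ADM")
    sd(est$individuals$P1)
  }
  expect_lt(sdAt(20000), sdAt(2000))
})

test_that("individuals at a parental anchor get indicator estimates", {
  # synthetic eigensystem: populations as exact point clusters in 2 axes
  coords <- rbind(
    matrix(rep(c(0, 0), each = 4), 4), matrix(rep(c(1, 0), each = 4), 4),
    matrix(rep(c(0, 1), each = 4), 4), matrix(rep(c(1, 0), each = 2), 2))
  V <- sweep(coords, 2, sqrt(colSums(coords^2)), "/")
  sys <- new("EigenSystem", values = c(2, 1), vectors = V,
    labels = paste0("i", 1:14),
    population = rep(c("P1", "P2", "P3", "ADM"), c(4, 4, 4, 2)),
    trivialIndex = NA_integer_, signs = c(1, 1), kind = "empirical")
  est <- individualProportions(sys, c("P1", "P2", "P3"), "ADM")
  expect_equal(est$individuals$P2, c(1, 1), tolerance = 1e-12)
  expect_equal(est$individuals$P1, c(0, 0), tolerance = 1e-12)
  expect_error(individualProportions(sys, c("P1", "P2", "P3", "ADM"), "P1"),
    "structural eigenvectors")
})
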