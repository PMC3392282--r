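.reducedParts <- function(sigma, allowClip = FALSE) {
  S <- sigmaCov(sigma)
  if (anyNA(S) || anyNA(sigmaVar(sigma)))
    stop("SigmaSet contains undefined parameters")
  n <- sampleSizes(sigma)
  N <- sum(n)
  f <- n / N
  d <- diagExcess(sigma)
  if (any(d < -1e-9)) {
    warning("negative diagonal excess d_k = sigma_k^2 - sigma_kk ",
      "(estimation noise)", if (allowClip) "; clipped to 0")
    if (allowClip) d <- pmax(d, 0)
  }
  sbark <- as.vector(S %*% f)
  sbar <- as.numeric(t(f) %*% S %*% f)
  dbar <- sum(f * d)
  list(S = S, n = n, N = N, f = f, d = d, sbark = sbark, sbar = sbar, dbar = dbar)
}

#' Exact reduced eigenequation operator
#'
#' Builds the `K x K` operator whose eigenpairs are exactly the
#' block-constant eigenpairs of the full `N x N` covariance matrix of
#' grand-mean-adjusted allele counts. With \eqn{\bar{s}_k = \sum_m f_m
#' \sigma_{km}} (using \eqn{\sigma_{kk}} on the diagonal), \eqn{\bar{s} =
#' \sum_{m,m'} f_m f_{m'} \sigma_{mm'}}, diagonal excess \eqn{d_k =
#' \sigma_k^2 - \sigma_{kk}} and \eqn{\bar{d} = \sum_m f_m d_m}:
#' \deqn{A_{kl} = n_l\left[\sigma_{kl} - \bar{s}_k - \bar{s}_l + \bar{s}
#'   - \frac{d_k + d_l}{N} + \frac{\bar{d}}{N}\right] + \delta_{kl} d_k.}
#' The operator annihilates the constant vector exactly (the trivial
#' eigenvector created by the mean adjustment).
#'
#' @param sigma a [SigmaSet-class].
#' @param allowClip clip negative diagonal-excess values (possible in
#'   estimated parameter sets) to zero instead of only warning.
#' @return a [ReducedMatrix-class] of kind `"exact"`.
#' @seealso [solveReduced()], [buildReducedAsymptotic()],
#'   [fullCovarianceOracle()]
#' @export
buildReducedExact <- function(sigma, allowClip = FALSE) {
  stopifnot(is(sigma, "SigmaSet"))
  K <- length(popLabels(sigma))
  if (K < 2) stop("at least two populations required")
  p <- .reducedParts(sigma, allowClip)
  one <- rep(1, K)
  bracket <- p$S - outer(p$sbark, one) - outer(one, p$sbark) + p$sbar -
    (outer(p$d, one) + outer(one, p$d)) / p$N + p$dbar / p$N
  A <- sweep(bracket, 2L, p$n, "*") + diag(p$d, K)
  new("ReducedMatrix",
    A = A, bracket = bracket, weights = p$n, d = p$d,
    n = p$n, f = p$f, N = p$N,
    sbark = p$sbark, sbar = p$sbar, dbar = p$dbar,
    kind = "exact", labels = popLabels(sigma))
}

#' Asymptotic reduced eigenequation operator
#'
#' The large-sample form of the reduced eigenequation: the exact operator
#' with the individual-level binomial sampling terms (diagonal excess)
#' dropped, rescaled per individual,
#' \deqn{A^\infty_{kl} = f_l\,(\sigma_{kl} - \bar{s}_k - \bar{s}_l +
#' \bar{s}),}
#' where \eqn{f_l = n_l/N} is the relative sample size. Eigenvalues of the
#' exact operator approach `N` times those of the asymptotic one as the
#' total sample size grows at fixed relative sizes. An admixed population
#' whose parents are present contributes an exactly null direction here:
#' admixture does not add an axis of variation.
#'
#' @inheritParams buildReducedExact
#' @return a [ReducedMatrix-class] of kind `"asymptotic"`.
#' @export
buildReducedAsymptotic <- function(sigma) {
  stopifnot(is(sigma, "SigmaSet"))
  K <- length(popLabels(sigma))
  if (K < 2) stop("at least two populations required")
  p <- .reducedParts(sigma)
  one <- rep(1, K)
  bracket <- p$S - outer(p$sbark, one) - outer(one, p$sbark) + p$sbar
  A <- sweep(bracket, 2L, p$f, "*")
  new("ReducedMatrix",
    A = A, bracket = bracket, weights = p$f, d = numeric(K),
    n = p$n, f = p$f, N = p$N,
    sbark = p$sbark, sbar = p$sbar, dbar = 0,
    kind = "asymptotic", labels = popLabels(sigma))
}

#' @rdname ReducedMatrix-class
#' @param x a [ReducedMatrix-class].
#' @export
setMethod("reducedOperator", "ReducedMatrix", function(x) x@A)

setMethod("show", "ReducedMatrix", function(object) {
  cat(sprintf("ReducedMatrix (%s): K = %d, N = %g\n",
    object@kind, nrow(object@A), object@N))
  print(signif(object@A, 6))
})

.fixSigns <- function(V) {
  signs <- rep(1, ncol(V))
  for (j in seq_len(ncol(V))) {
    big <- which(abs(V[, j]) > 1e-6)
    if (!length(big)) next
    if (V[max(big), j] < 0) {
      V[, j] <- -V[, j]
      signs[j] <- -1
    }
  }
  list(V = V, signs = signs)
}

#' Solve a reduced eigenequation
#'
#' The (generally non-symmetric) operator is similar to the symmetric matrix
#' \eqn{B = W^{1/2}\,[\mathrm{bracket}]\,W^{1/2} + \mathrm{diag}(d)} with
#' `W` the column weights, so the eigenvalues are real and the eigenvectors
#' are recovered as \eqn{v = W^{-1/2} w}. Eigenvectors are normalized to
#' unit Euclidean norm over the `K` population coordinates, sorted by
#' descending eigenvalue, and each column's sign is fixed so that the
#' highest-index population with coordinate magnitude above 1e-6 is
#' positive (the applied signs are recorded). Near-zero negative eigenvalues
#' are reported as computed, not clipped. The trivial constant eigenvector
#' is identified by its overlap with the constant direction.
#'
#' @param rm a [ReducedMatrix-class].
#' @return an [EigenSystem-class] of kind `"theoretical-exact"` or
#'   `"theoretical-asymptotic"`.
#' @examples
#' C <- matrix(c(0.1, 0.01, 0.01, 0.1), 2, 2)
#' mod <- PopulationModel(c(0.4, 0.4), C, n = c(100, 100))
#' solveReduced(buildReducedExact(alleleCountMoments(mod)))
#' @export
solveReduced <- function(rm) {
  stopifnot(is(rm, "ReducedMatrix"))
  if (!all(is.finite(rm@A))) stop("operator contains non-finite entries")
  K <- nrow(rm@A)
  w <- rm@weights
  B <- sweep(sweep(rm@bracket, 1L, sqrt(w), "*"), 2L, sqrt(w), "*") + diag(rm@d, K)
  e <- tryCatch(eigen((B + t(B)) / 2, symmetric = TRUE),
    error = function(err) {
      stop("eigendecomposition failed: ", conditionMessage(err),
        "\noperator:\n", paste(utils::capture.output(print(rm@A)), collapse = "\n"))
    })
  V <- sweep(e$vectors, 1L, sqrt(w), "/")
  V <- sweep(V, 2L, sqrt(colSums(V^2)), "/")
  fx <- .fixSigns(V)
  ov <- abs(crossprod(fx$V, rep(1 / sqrt(K), K)))
  triv <- if (max(ov) > 0.999) which.max(ov) else NA_integer_
  new("EigenSystem",
    values = e$values,
    vectors = fx$V,
    labels = rm@labels,
    population = rm@labels,
    trivialIndex = as.integer(triv),
    signs = fx$signs,
    kind = paste0("theoretical-", rm@kind))
}

#' Explicit full covariance of mean-adjusted allele counts
#'
#' Brute-force oracle for the reduced eigenequation at test scale: the
#' `N x N` covariance matrix with entries \eqn{\sigma_{kl}} between
#' individuals of different populations, \eqn{\sigma_{kk}} between distinct
#' individuals of the same population and \eqn{\sigma_k^2} on the diagonal,
#' conjugated by the grand-mean centering projector `I - J/N`. Its
#' restriction to block-constant vectors reproduces [solveReduced()]
#' eigenpairs.
#'
#' @param sigma a [SigmaSet-class] with total sample size at most `maxN`.
#' @param maxN guard on the total sample size (default 500).
#' @return the `N x N` centered covariance matrix.
#' @export
fullCovarianceOracle <- function(sigma, maxN = 500) {
  stopifnot(is(sigma, "SigmaSet"))
  n <- sampleSizes(sigma)
  N <- sum(n)
  if (N > maxN) stop("total sample size ", N, " exceeds the oracle guard ", maxN)
  popIdx <- rep(seq_along(n), times = n)
  M <- sigmaCov(sigma)[popIdx, popIdx]
  diag(M) <- sigmaVar(sigma)[popIdx]
  Ctr <- diag(N) - 1 / N
  Ctr %*% M %*% Ctr
}

#' Empirical PCA with individuals as features
#'
#' Per marker, the grand mean count over all `N` individuals is subtracted;
#' the `N x N` sample covariance of the adjusted counts across markers
#' (per-individual means across markers subtracted, denominator `M`) is then
#' eigendecomposed. The eigenvector components are the individual
#' coordinates of the eigenvector-plot. The covariance is raw by default;
#' `scaleMarkers = TRUE` divides each marker by its binomial scale
#' \eqn{\sqrt{\hat p(1 - \hat p)}} first (SmartPCA-style standardization).
#' Missing genotypes are replaced by the marker's grand mean before
#' adjustment.
#'
#' @param panel a [GenotypePanel-class] with `M >= 2` markers and no
#'   all-missing individual.
#' @param nVectors number of top eigenvectors to retain (clipped to `N` with
#'   a warning).
#' @param scaleMarkers standardize markers before the decomposition.
#' @return an [EigenSystem-class] of kind `"empirical"`, rows labelled by
#'   individual ids with their population labels attached.
#' @export
empiricalPCA <- function(panel, nVectors = 10L, scaleMarkers = FALSE) {
  stopifnot(is(panel, "GenotypePanel"))
  X <- panelCounts(panel)
  if (nrow(X) < 2) stop("at least 2 markers required")
  if (any(colSums(!is.na(X)) == 0)) stop("panel contains all-missing individuals")
  N <- ncol(X)
  if (nVectors > N) {
    warning("nVectors clipped to the number of individuals (", N, ")")
    nVectors <- N
  }
  gm <- rowMeans(X, na.rm = TRUE)
  if (anyNA(X)) {
    miss <- which(is.na(X), arr.ind = TRUE)
    X[miss] <- gm[miss[, 1L]]
  }
  if (scaleMarkers) {
    ph <- gm / 2
    sc <- sqrt(ph * (1 - ph))
    sc[sc == 0] <- 1
    X <- X / sc
    gm <- gm / sc
  }
  Y <- X - gm
  Yc <- sweep(Y, 2L, colMeans(Y))
  S <- crossprod(Yc) / nrow(Yc)
  e <- eigen(S, symmetric = TRUE)
  V <- e$vectors[, seq_len(nVectors), drop = FALSE]
  fx <- .fixSigns(V)
  new("EigenSystem",
    values = e$values[seq_len(nVectors)],
    vectors = fx$V,
    labels = colnames(X),
    population = unname(panelPopulations(panel)),
    trivialIndex = NA_integer_,
    signs = fx$signs,
    kind = "empirical")
}

#' @rdname EigenSystem-class
#' @param x an [EigenSystem-class].
#' @export
setMethod("eigenValues", "EigenSystem", function(x) x@values)

#' @rdname EigenSystem-class
#' @export
setMethod("eigenVectors", "EigenSystem", function(x) {
  V <- x@vectors
  dimnames(V) <- list(x@labels, paste0("EV", seq_len(ncol(V))))
  V
})

#' @rdname EigenSystem-class
#' @export
setMethod("trivialIndex", "EigenSystem", function(x) x@trivialIndex)

#' @rdname EigenSystem-class
#' @export
setMethod("systemKind", "EigenSystem", function(x) x@kind)

#' @rdname EigenSystem-class
#' @export
setMethod("popLabels", "EigenSystem", function(x) unique(x@population))

#' @rdname popCentroids
#' @export
setMethod("popCentroids", "EigenSystem", function(x) {
  V <- eigenVectors(x)
  pops <- unique(x@population)
  out <- matrix(NA_real_, length(pops), ncol(V),
    dimnames = list(pops, colnames(V)))
  for (p in pops)
    out[p, ] <- colMeans(V[x@population == p, , drop = FALSE])
  out
})

setMethod("show", "EigenSystem", function(object) {
  cat(sprintf("EigenSystem (%s): %d coordinates x %d eigenvectors\n",
    object@kind, nrow(object@vectors), ncol(object@vectors)))
  nv <- min(6L, length(object@values))
  cat("  eigenvalues:", paste(signif(object@values[seq_len(nv)], 6),
    collapse = ", "),
    if (length(object@values) > nv) "...", "\n")
  if (!is.na(object@trivialIndex))
    cat("  trivial eigenvector at column", object@trivialIndex, "\n")
})
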