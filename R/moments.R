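#' Allele-count moments from allele-frequency moments
#'
#' Maps the frequency-level parameters of a resolved population model to the
#' allele-count variance-covariance parameters that drive the reduced
#' eigenequation. With allele counts binomial given the marker's frequency
#' (two draws under Hardy-Weinberg), conditioning on the random frequency
#' vector gives
#' \deqn{\sigma_k^2 = 2\mu_k(1-\mu_k) + 2c_{kk}, \quad
#'       \sigma_{kk} = 4c_{kk}, \quad
#'       \sigma_{kl} = 4c_{kl} \; (k \ne l),}
#' so the within/between covariance matrix equals four times the frequency
#' covariance matrix and the variance adds the binomial sampling term.
#'
#' @param model a [PopulationModel-class] with no unresolved admixture specs
#'   (resolve first via [extendWithAdmixture()]).
#' @return a [SigmaSet-class].
#' @examples
#' C <- matrix(c(0.1, 0.01, 0.01, 0.1), 2, 2)
#' mod <- PopulationModel(c(0.4, 0.4), C, n = c(100, 100))
#' alleleCountMoments(mod)
#' @export
alleleCountMoments <- function(model) {
  stopifnot(is(model, "PopulationModel"))
  if (length(model@admixtureSpecs))
    stop("model has unresolved admixture specs; call extendWithAdmixture() first")
  mu <- model@mu
  if (anyNA(mu) || any(mu < 0 | mu > 1))
    stop("mean allele frequencies must lie in [0, 1]")
  C <- model@Cfreq
  if (anyNA(C) || any(abs(C - t(C)) > 1e-10))
    stop("frequency covariance matrix must be fully defined and symmetric")
  SigmaSet(
    var = 2 * mu * (1 - mu) + 2 * diag(C),
    cov = 4 * C,
    n = model@n,
    labels = model@labels
  )
}

#' Estimate allele-count variance-covariance parameters from genotypes
#'
#' Method-of-moments estimator of the [SigmaSet-class] parameters from an
#' observed panel. For every ordered pair of individuals the covariance of
#' their allele counts across markers is computed (each individual's mean
#' across markers subtracted; denominator `M`, markers being treated as
#' realizations). Then \eqn{\hat\sigma_k^2} averages the across-marker
#' variances of the individuals of population `k`, \eqn{\hat\sigma_{kk}}
#' averages the covariances over distinct within-population pairs, and
#' \eqn{\hat\sigma_{kl}} averages over cross-population pairs. Missing
#' genotypes are excluded pairwise per marker (means and denominators use
#' the markers complete for the pair); the minimum pairwise-complete marker
#' count is recorded in the result.
#'
#' Reported values depend on the allele coding of the input (covariances are
#' largest under random labelling of alleles and smallest under a consistent
#' major/minor convention); `recodeMinor = TRUE` flips markers so the variant
#' allele is always the minor one before estimating. The eigenvector-plot
#' geometry downstream is not materially affected by the coding.
#'
#' @param panel a [GenotypePanel-class] with at least 2 markers.
#' @param recodeMinor recode counts to minor-allele counts first.
#' @return a [SigmaSet-class] with the observed per-population sample sizes.
#'   Populations with a single individual get `NA` within-covariance, with a
#'   warning.
#' @export
estimateSigma <- function(panel, recodeMinor = FALSE) {
  stopifnot(is(panel, "GenotypePanel"))
  X <- panelCounts(panel)
  M <- nrow(X)
  if (M < 2) stop("at least 2 markers required")
  if (recodeMinor) {
    flip <- rowMeans(X, na.rm = TRUE) > 1
    X[flip, ] <- 2 - X[flip, ]
  }
  pop <- panelPopulations(panel)
  if (anyNA(X)) {
    Z <- X; Z[is.na(Z)] <- 0
    W <- 1 - is.na(X)
    Mpair <- crossprod(W)
    if (any(Mpair < 2)) stop("some pair of individuals shares fewer than 2 complete markers")
    Sxy <- crossprod(Z)
    Sx <- crossprod(Z, W)     # sum of x_i over markers complete for (i, j)
    S <- (Sxy - Sx * t(Sx) / Mpair) / Mpair
    nComplete <- min(Mpair)
  } else {
    Xc <- sweep(X, 2L, colMeans(X))
    S <- crossprod(Xc) / M
    nComplete <- M
  }
  labels <- unique(pop)
  K <- length(labels)
  vhat <- setNames(numeric(K), labels)
  chat <- matrix(NA_real_, K, K, dimnames = list(labels, labels))
  idx <- split(seq_along(pop), factor(pop, levels = labels))
  single <- character()
  for (k in seq_len(K)) {
    ik <- idx[[k]]
    vhat[k] <- mean(diag(S)[ik])
    if (length(ik) >= 2L) {
      Skk <- S[ik, ik, drop = FALSE]
      chat[k, k] <- mean(Skk[upper.tri(Skk)])
    } else {
      single <- c(single, labels[k])
    }
    for (l in seq_len(K)) {
      if (l == k) next
      chat[k, l] <- mean(S[ik, idx[[l]], drop = FALSE])
    }
  }
  if (length(single))
    warning("within-population covariance undefined (single individual): ",
      paste(single, collapse = ", "))
  chat <- (chat + t(chat)) / 2
  if (length(single)) diag(chat)[match(single, labels)] <- NA_real_
  SigmaSet(vhat, chat, n = lengths(idx), labels = labels,
    nCompleteMarkers = nComplete)
}
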