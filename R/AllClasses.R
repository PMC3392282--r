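#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats rbeta rbinom rgamma runif setNames
#' @importFrom utils read.delim write.table head packageVersion
NULL

.EPS_SUM1 <- 1e-12

#' Frequency-level population model
#'
#' Describes a set of populations by the first two moments of their
#' variant-allele frequencies across random markers: per-population mean
#' frequencies, the variance-covariance matrix of the frequency vector, and
#' per-population sample sizes. Populations declared admixed carry a
#' specification (parental populations plus mixing proportions) and have
#' undefined (`NA`) frequency moments until [extendWithAdmixture()] fills
#' them in by the admixture moment algebra.
#'
#' @slot labels character vector of population names (length `K`).
#' @slot mu numeric vector of mean variant-allele frequencies in `[0, 1]`;
#'   `NA` for unresolved admixed populations.
#' @slot Cfreq `K x K` symmetric frequency variance-covariance matrix; rows and
#'   columns of unresolved admixed populations are `NA`.
#' @slot n numeric vector of per-population sample sizes (`>= 1`).
#' @slot admixtureSpecs list of unresolved admixture specifications, each a
#'   list with elements `target` (population index), `parents` (indices of
#'   non-admixed populations) and `proportions` (non-negative, summing to 1).
#' @slot resolvedSpecs list of specifications already folded into `mu`/`C`.
#'
#' @seealso [PopulationModel()], [extendWithAdmixture()],
#'   [alleleCountMoments()]
#' @export
setClass("PopulationModel",
  representation(
    labels = "character",
    mu = "numeric",
    Cfreq = "matrix",
    n = "numeric",
    admixtureSpecs = "list",
    resolvedSpecs = "list"
  )
)

setValidity("PopulationModel", function(object) {
  msg <- character()
  K <- length(object@labels)
  if (length(object@mu) != K) msg <- c(msg, "mu must have one entry per population")
  if (!all(dim(object@Cfreq) == c(K, K))) msg <- c(msg, "C must be K x K")
  if (length(object@n) != K) msg <- c(msg, "n must have one entry per population")
  mu <- object@mu
  ok <- !is.na(mu)
  if (any(mu[ok] < 0 | mu[ok] > 1)) msg <- c(msg, "mu must lie in [0, 1]")
  if (any(object@n < 1)) msg <- c(msg, "sample sizes must be >= 1")
  C <- object@Cfreq
  def <- !is.na(C)
  if (any(def != t(def)) || any(abs(C[def & t(def)] - t(C)[def & t(def)]) > 1e-10))
    msg <- c(msg, "C must be symmetric")
  dg <- diag(C)
  if (any(dg[!is.na(dg)] < -1e-12)) msg <- c(msg, "frequency variances must be non-negative")
  for (k in seq_len(K)) for (l in seq_len(K)) {
    if (k == l || is.na(C[k, l]) || is.na(dg[k]) || is.na(dg[l])) next
    if (abs(C[k, l]) > sqrt(dg[k] * dg[l]) + 1e-8)
      msg <- c(msg, sprintf("|c_%d%d| exceeds sqrt(c_%d%d c_%d%d)", k, l, k, k, l, l))
  }
  specTargets <- vapply(object@admixtureSpecs, function(s) s$target, 1L)
  allTargets <- c(specTargets, vapply(object@resolvedSpecs, function(s) s$target, 1L))
  for (s in c(object@admixtureSpecs, object@resolvedSpecs)) {
    lam <- s$proportions
    if (any(lam < 0)) msg <- c(msg, "admixture proportions must be non-negative")
    if (abs(sum(lam) - 1) > .EPS_SUM1)
      msg <- c(msg, "admixture proportions must sum to 1 within 1e-12")
    if (length(lam) != length(s$parents))
      msg <- c(msg, "one proportion per parental population required")
    if (any(s$parents %in% allTargets))
      msg <- c(msg, "admixture of an admixed population is not supported")
    if (any(s$parents < 1 | s$parents > K) || s$target < 1 || s$target > K)
      msg <- c(msg, "admixture indices out of range")
  }
  if (length(msg)) msg else TRUE
})

#' Allele-count variance-covariance parameters
#'
#' The population-level second moments of variant-allele counts that drive
#' the reduced eigenequation: the per-population count variance
#' \eqn{\sigma_k^2}, the within-population covariance \eqn{\sigma_{kk}}
#' between two distinct individuals of the same population, and the
#' between-population covariances \eqn{\sigma_{kl}}. The within and between
#' parameters are stored as one symmetric `K x K` matrix with
#' \eqn{\sigma_{kk}} on the diagonal.
#'
#' @slot labels population names.
#' @slot var numeric vector of count variances \eqn{\sigma_k^2}.
#' @slot cov symmetric `K x K` matrix: \eqn{\sigma_{kk}} on the diagonal,
#'   \eqn{\sigma_{kl}} off the diagonal. For a model-derived set this equals
#'   four times the frequency covariance matrix.
#' @slot n per-population sample sizes.
#' @slot nCompleteMarkers for estimated sets, the minimum number of
#'   pairwise-complete markers used; `NA` for model-derived sets.
#'
#' @seealso [SigmaSet()], [alleleCountMoments()], [estimateSigma()],
#'   [buildReducedExact()]
#' @export
setClass("SigmaSet",
  representation(
    labels = "character",
    var = "numeric",
    cov = "matrix",
    n = "numeric",
    nCompleteMarkers = "numeric"
  )
)

setValidity("SigmaSet", function(object) {
  msg <- character()
  K <- length(object@labels)
  if (length(object@var) != K) msg <- c(msg, "var must have one entry per population")
  if (!all(dim(object@cov) == c(K, K))) msg <- c(msg, "cov must be K x K")
  if (length(object@n) != K) msg <- c(msg, "n must have one entry per population")
  if (any(abs(object@cov - t(object@cov)) > 1e-10, na.rm = TRUE))
    msg <- c(msg, "cov must be symmetric")
  if (any(object@n < 1)) msg <- c(msg, "sample sizes must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Genotype panel: markers by individuals allele counts
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding an `M x N` matrix
#' of variant-allele counts (0/1/2, `NA` for missing) in the `counts` assay,
#' with rows as markers and columns as individuals. `colData(panel)$population`
#' carries the population label of each individual. Simulated panels store
#' generating truth (ancestral and per-population allele frequencies, FST
#' values, admixture proportions) in `metadata(panel)$truth`.
#'
#' @seealso [GenotypePanel()], [simulateParentalPanel()], [empiricalPCA()]
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  x <- SummarizedExperiment::assay(object, "counts")
  if (!all(x %in% c(0L, 1L, 2L) | is.na(x)))
    msg <- c(msg, "allele counts must be 0, 1, 2 or NA")
  if (!"population" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'population' column")
  if (length(msg)) msg else TRUE
})

#' Reduced eigenequation operator
#'
#' The `K x K` operator whose eigenpairs are the block-constant eigenpairs of
#' the full `N x N` covariance matrix of mean-adjusted allele counts. The
#' `exact` kind retains the binomial genotype-sampling noise (diagonal excess
#' \eqn{d_k = \sigma_k^2 - \sigma_{kk}}); the `asymptotic` kind drops it and
#' rescales per individual, so exact eigenvalues approach `N` times the
#' asymptotic ones as the total sample size grows at fixed relative sizes.
#'
#' @slot A the `K x K` operator matrix.
#' @slot bracket the symmetric centered covariance bracket before column
#'   weighting (used to symmetrize the eigenproblem).
#' @slot weights column weights: sample sizes `n` (exact) or relative sizes
#'   `f` (asymptotic).
#' @slot d diagonal excess terms (zero vector for asymptotic operators).
#' @slot n,f,N sample sizes, relative sizes, total size.
#' @slot sbark,sbar,dbar weighted row means, grand mean and weighted mean
#'   diagonal excess used in the centering.
#' @slot kind `"exact"` or `"asymptotic"`.
#' @slot labels population names.
#'
#' @seealso [buildReducedExact()], [buildReducedAsymptotic()], [solveReduced()]
#' @export
setClass("ReducedMatrix",
  representation(
    A = "matrix",
    bracket = "matrix",
    weights = "numeric",
    d = "numeric",
    n = "numeric",
    f = "numeric",
    N = "numeric",
    sbark = "numeric",
    sbar = "numeric",
    dbar = "numeric",
    kind = "character",
    labels = "character"
  )
)

setValidity("ReducedMatrix", function(object) {
  msg <- character()
  if (!object@kind %in% c("exact", "asymptotic"))
    msg <- c(msg, "kind must be 'exact' or 'asymptotic'")
  if (nrow(object@A) != ncol(object@A)) msg <- c(msg, "A must be square")
  rs <- as.vector(object@A %*% rep(1, ncol(object@A)))
  if (max(abs(rs)) > 1e-6 * max(1, max(abs(object@A))))
    msg <- c(msg, "operator must annihilate the constant vector")
  if (length(msg)) msg else TRUE
})

#' Eigenvalues and eigenvector-plot coordinates
#'
#' Solved eigensystem in the individuals-as-features orientation. For
#' theoretical systems the rows of `vectors` are populations (`K x K`); for
#' empirical systems they are individuals (`N x T`, the top `T` retained
#' axes). Each column has unit Euclidean norm; columns are sorted by
#' descending eigenvalue; the sign of each column is fixed so that the
#' highest-index coordinate of magnitude above 1e-6 is positive, and the
#' applied sign is recorded. Theoretical systems flag the trivial constant
#' eigenvector created by the grand-mean adjustment.
#'
#' @slot values eigenvalues of the retained columns, descending.
#' @slot vectors coordinate matrix, one column per eigenvector.
#' @slot labels row identifiers (population names or individual ids).
#' @slot population population of each row (equals `labels` for theoretical
#'   systems).
#' @slot trivialIndex column index of the trivial constant eigenvector
#'   (`NA` when not identified).
#' @slot signs the sign (+1/-1) applied to each column.
#' @slot kind `"theoretical-exact"`, `"theoretical-asymptotic"` or
#'   `"empirical"`.
#'
#' @seealso [solveReduced()], [empiricalPCA()], [popCentroids()]
#' @export
setClass("EigenSystem",
  representation(
    values = "numeric",
    vectors = "matrix",
    labels = "character",
    population = "character",
    trivialIndex = "integer",
    signs = "numeric",
    kind = "character"
  )
)

setValidity("EigenSystem", function(object) {
  msg <- character()
  if (length(object@values) != ncol(object@vectors))
    msg <- c(msg, "one eigenvalue per retained eigenvector required")
  if (length(object@labels) != nrow(object@vectors))
    msg <- c(msg, "one label per coordinate row required")
  nrm <- sqrt(colSums(object@vectors^2))
  if (any(abs(nrm - 1) > 1e-9)) msg <- c(msg, "eigenvectors must have unit norm")
  if (is.unsorted(rev(object@values), strictly = FALSE) &&
      any(diff(object@values) > 1e-9 * max(abs(object@values), 1)))
    msg <- c(msg, "eigenvalues must be sorted descending")
  if (!object@kind %in% c("theoretical-exact", "theoretical-asymptotic", "empirical"))
    msg <- c(msg, "unknown system kind")
  if (length(msg)) msg else TRUE
})

#' Admixture proportion estimate with affine-residual diagnostic
#'
#' Proportions of ancestry attributed to each parental population, solved
#' with the affine constraint (they sum to 1 exactly) after orthogonal
#' projection of the query point onto the affine hull of the parental
#' points. Proportions are not clipped: values outside `[0, 1]` are reported
#' as computed and `insideHull` flags whether all are `>= -1e-8`. The
#' residual is the orthogonal distance of the query from the hull, also
#' expressed relative to the largest pairwise parental distance.
#'
#' @slot proportions named numeric vector, one entry per parental population,
#'   summing to 1.
#' @slot residualDistance Euclidean distance from the query to the parental
#'   affine hull.
#' @slot residualRatio `residualDistance` divided by the largest pairwise
#'   parental distance.
#' @slot insideHull logical.
#' @slot parents parental labels.
#' @slot method `"barycentric"`, `"triangle-area"` or `"segment-ratio"`.
#'
#' @seealso [barycentricProportions()], [triangleAreaProportions()],
#'   [segmentRatio()], [individualProportions()]
#' @export
setClass("AdmixtureEstimate",
  representation(
    proportions = "numeric",
    residualDistance = "numeric",
    residualRatio = "numeric",
    insideHull = "logical",
    parents = "character",
    method = "character"
  )
)

setValidity("AdmixtureEstimate", function(object) {
  if (abs(sum(object@proportions) - 1) > 1e-9)
    return("proportions must sum to 1")
  TRUE
})

#' Ancestry-informative marker ranking
#'
#' Per-eigenvector projection magnitudes of every marker onto the structural
#' eigenvectors, and the merged ranked selection.
#'
#' @slot projections `M x T` matrix of signed projections, one column per
#'   structural eigenvector used.
#' @slot ranking data frame with columns `marker`, `eigenvector`, `absProj`
#'   and `rank` for the selected markers, in merged rank order.
#' @slot m requested selection size.
#'
#' @seealso [rankAIMs()]
#' @export
setClass("AIMRanking",
  representation(
    projections = "matrix",
    ranking = "data.frame",
    m = "integer"
  )
)

setValidity("AIMRanking", function(object) {
  if (anyDuplicated(object@ranking$marker)) return("selected markers must be unique")
  TRUE
})
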