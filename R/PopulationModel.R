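#' Construct a frequency-level population model
#'
#' @param mu numeric vector of mean variant-allele frequencies, one per
#'   (non-admixed) population.
#' @param C symmetric matrix of allele-frequency variances and covariances
#'   across random markers (same order as `mu`).
#' @param n per-population sample sizes.
#' @param labels population names; defaults to `P1..PK`.
#' @return a [PopulationModel-class] object with no admixed populations.
#'
#' @examples
#' C <- matrix(c(0.1, 0.01, 0.01, 0.1), 2, 2)
#' mod <- PopulationModel(mu = c(0.4, 0.4), C = C, n = c(100, 100))
#' mod
#' @export
PopulationModel <- function(mu, C, n, labels = paste0("P", seq_along(mu))) {
  C <- as.matrix(C)
  storage.mode(C) <- "double"
  dimnames(C) <- list(labels, labels)
  new("PopulationModel",
    labels = labels,
    mu = setNames(as.numeric(mu), labels),
    Cfreq = C,
    n = setNames(as.numeric(n), labels),
    admixtureSpecs = list(),
    resolvedSpecs = list()
  )
}

#' Declare an admixed population on top of an existing model
#'
#' Appends a population whose allele frequencies are the `proportions`-
#' weighted mixture of the frequencies of non-admixed parental populations
#' already present in the model. Its frequency moments stay undefined until
#' [extendWithAdmixture()] resolves them. Only single-level admixture is
#' supported: parents must themselves be non-admixed.
#'
#' @param model a [PopulationModel-class] object.
#' @param label name of the new admixed population.
#' @param parents parental population names or indices.
#' @param proportions admixture proportions, non-negative and summing to 1.
#' @param n sample size of the admixed population.
#' @return the extended [PopulationModel-class] with one unresolved spec.
#' @export
addAdmixedPopulation <- function(model, label, parents, proportions, n) {
  stopifnot(is(model, "PopulationModel"))
  if (is.character(parents)) parents <- match(parents, model@labels)
  if (anyNA(parents)) stop("unknown parental population label")
  K <- length(model@labels) + 1L
  labels <- c(model@labels, label)
  Cn <- matrix(NA_real_, K, K, dimnames = list(labels, labels))
  Cn[-K, -K] <- model@Cfreq
  new("PopulationModel",
    labels = labels,
    mu = setNames(c(model@mu, NA_real_), labels),
    Cfreq = Cn,
    n = setNames(c(model@n, as.numeric(n)), labels),
    admixtureSpecs = c(model@admixtureSpecs, list(list(
      target = K, parents = as.integer(parents),
      proportions = as.numeric(proportions)
    ))),
    resolvedSpecs = model@resolvedSpecs
  )
}

#' Resolve admixed populations into frequency moments
#'
#' Fills in the mean and the variance-covariance entries of every declared
#' admixed population from those of its parents. Writing the model as a
#' weight matrix `W` that maps populations to non-negative weights over the
#' non-admixed populations (an identity row for a non-admixed population,
#' the admixture proportions for an admixed one), the resolved moments are
#' `mu = W mu0` and `C = W C0 W'`. Component-wise this is
#' \deqn{\mu_A = \sum_i \lambda_i \mu_i, \quad
#'       \mathrm{Cov}(p_A, p_X) = \sum_i \lambda_i c_{iX}, \quad
#'       \mathrm{Cov}(p_A, p_B) = \sum_{ij} \lambda_i \eta_j c_{ij}, \quad
#'       \mathrm{Var}(p_A) = \sum_{ij} \lambda_i \lambda_j c_{ij},}
#' covering covariances with parental populations, with populations
#' unrelated to the admixture, and between two admixed populations.
#'
#' @param model a [PopulationModel-class], possibly with unresolved specs.
#' @return the model with a fully populated `C` and no unresolved specs;
#'   a model without admixed populations is returned unchanged.
#' @export
extendWithAdmixture <- function(model) {
  stopifnot(is(model, "PopulationModel"))
  specs <- model@admixtureSpecs
  if (!length(specs)) return(model)
  K <- length(model@labels)
  targets <- vapply(specs, function(s) s$target, 1L)
  base <- setdiff(seq_len(K), c(targets, vapply(model@resolvedSpecs, function(s) s$target, 1L)))
  W <- matrix(0, K, length(base), dimnames = list(model@labels, model@labels[base]))
  W[cbind(base, seq_along(base))] <- 1
  for (s in specs) {
    if (any(!s$parents %in% base))
      stop("admixture of an admixed population is not supported")
    W[s$target, match(s$parents, base)] <- s$proportions
  }
  mu <- as.vector(W %*% model@mu[base])
  C <- W %*% model@Cfreq[base, base, drop = FALSE] %*% t(W)
  C <- (C + t(C)) / 2
  dimnames(C) <- list(model@labels, model@labels)
  new("PopulationModel",
    labels = model@labels,
    mu = setNames(mu, model@labels),
    Cfreq = C,
    n = model@n,
    admixtureSpecs = list(),
    resolvedSpecs = c(model@resolvedSpecs, specs)
  )
}

#' @rdname PopulationModel-class
#' @export
setMethod("popLabels", "PopulationModel", function(x) x@labels)

#' @rdname PopulationModel-class
#' @export
setMethod("sampleSizes", "PopulationModel", function(x) x@n)

#' @rdname PopulationModel-class
#' @export
setMethod("freqMeans", "PopulationModel", function(x) x@mu)

#' @rdname PopulationModel-class
#' @export
setMethod("freqCov", "PopulationModel", function(x) x@Cfreq)

#' Admixture specifications of a model
#'
#' @param model a [PopulationModel-class].
#' @param resolved return specs already folded into the moments instead of
#'   the pending ones.
#' @return list of specs (`target`, `parents`, `proportions`).
#' @export
admixtureSpecs <- function(model, resolved = FALSE) {
  if (resolved) model@resolvedSpecs else model@admixtureSpecs
}

setMethod("show", "PopulationModel", function(object) {
  K <- length(object@labels)
  nad <- length(object@admixtureSpecs) + length(object@resolvedSpecs)
  cat(sprintf("PopulationModel: %d populations (%d admixed%s)\n", K, nad,
    if (length(object@admixtureSpecs)) ", unresolved" else ""))
  cat("  labels:", paste(object@labels, collapse = ", "), "\n")
  cat("  n:", paste(object@n, collapse = ", "), "\n")
  cat("  mu:", paste(signif(object@mu, 4), collapse = ", "), "\n")
})
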