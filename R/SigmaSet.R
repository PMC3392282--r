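#' Construct an allele-count variance-covariance parameter set
#'
#' @param var per-population allele-count variances \eqn{\sigma_k^2}.
#' @param cov symmetric `K x K` matrix with the within-population
#'   covariances \eqn{\sigma_{kk}} on the diagonal and the
#'   between-population covariances \eqn{\sigma_{kl}} off it.
#' @param n per-population sample sizes.
#' @param labels population names.
#' @param nCompleteMarkers minimum count of pairwise-complete markers behind
#'   an estimated set (`NA` for model-derived parameters).
#' @return a [SigmaSet-class] object.
#' @export
SigmaSet <- function(var, cov, n, labels = paste0("P", seq_along(var)),
                     nCompleteMarkers = NA_real_) {
  cov <- as.matrix(cov)
  storage.mode(cov) <- "double"
  dimnames(cov) <- list(labels, labels)
  new("SigmaSet",
    labels = labels,
    var = setNames(as.numeric(var), labels),
    cov = cov,
    n = setNames(as.numeric(n), labels),
    nCompleteMarkers = nCompleteMarkers
  )
}

#' @rdname SigmaSet-class
#' @param x a [SigmaSet-class] object.
#' @export
setMethod("sigmaVar", "SigmaSet", function(x) x@var)

#' @rdname SigmaSet-class
#' @export
setMethod("sigmaCov", "SigmaSet", function(x) x@cov)

#' @rdname SigmaSet-class
#' @export
setMethod("sigmaWithin", "SigmaSet", function(x) setNames(diag(x@cov), x@labels))

#' @rdname SigmaSet-class
#' @export
setMethod("diagExcess", "SigmaSet", function(x) x@var - diag(x@cov))

#' @rdname SigmaSet-class
#' @export
setMethod("relSampleSizes", "SigmaSet", function(x) x@n / sum(x@n))

#' @rdname SigmaSet-class
#' @export
setMethod("popLabels", "SigmaSet", function(x) x@labels)

#' @rdname SigmaSet-class
#' @export
setMethod("sampleSizes", "SigmaSet", function(x) x@n)

setMethod("show", "SigmaSet", function(object) {
  cat(sprintf("SigmaSet: %d populations, N = %g\n",
    length(object@labels), sum(object@n)))
  tab <- data.frame(
    n = object@n,
    var = signif(object@var, 6),
    within = signif(diag(object@cov), 6),
    row.names = object@labels
  )
  print(tab)
  if (!is.na(object@nCompleteMarkers))
    cat("  estimated from >=", object@nCompleteMarkers, "pairwise-complete markers\n")
})
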