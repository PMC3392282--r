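#' @rdname PopulationModel-class
#' @param object,x an object.
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))

#' @rdname PopulationModel-class
#' @export
setGeneric("sampleSizes", function(x) standardGeneric("sampleSizes"))

#' @rdname PopulationModel-class
#' @export
setGeneric("freqMeans", function(x) standardGeneric("freqMeans"))

#' @rdname PopulationModel-class
#' @export
setGeneric("freqCov", function(x) standardGeneric("freqCov"))

#' @rdname SigmaSet-class
#' @export
setGeneric("sigmaVar", function(x) standardGeneric("sigmaVar"))

#' @rdname SigmaSet-class
#' @export
setGeneric("sigmaCov", function(x) standardGeneric("sigmaCov"))

#' @rdname SigmaSet-class
#' @export
setGeneric("sigmaWithin", function(x) standardGeneric("sigmaWithin"))

#' @rdname SigmaSet-class
#' @export
setGeneric("diagExcess", function(x) standardGeneric("diagExcess"))

#' @rdname SigmaSet-class
#' @export
setGeneric("relSampleSizes", function(x) standardGeneric("relSampleSizes"))

#' @rdname EigenSystem-class
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @rdname EigenSystem-class
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))

#' @rdname EigenSystem-class
#' @export
setGeneric("trivialIndex", function(x) standardGeneric("trivialIndex"))

#' @rdname EigenSystem-class
#' @export
setGeneric("systemKind", function(x) standardGeneric("systemKind"))

#' Population centroids of eigenvector-plot coordinates
#'
#' For an empirical system, the per-population means of the individual
#' coordinates on each retained eigenvector; for a theoretical system the
#' coordinates themselves (each population is already a single point).
#'
#' @param x an [EigenSystem-class] object.
#' @return a matrix with one row per population and one column per retained
#'   eigenvector.
#' @export
setGeneric("popCentroids", function(x) standardGeneric("popCentroids"))

#' @rdname AdmixtureEstimate-class
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))

#' @rdname AdmixtureEstimate-class
#' @export
setGeneric("residualDistance", function(x) standardGeneric("residualDistance"))

#' @rdname AdmixtureEstimate-class
#' @export
setGeneric("residualRatio", function(x) standardGeneric("residualRatio"))

#' @rdname AdmixtureEstimate-class
#' @export
setGeneric("insideHull", function(x) standardGeneric("insideHull"))

#' @rdname AIMRanking-class
#' @export
setGeneric("aimMarkers", function(x) standardGeneric("aimMarkers"))

#' @rdname AIMRanking-class
#' @export
setGeneric("aimRankingTable", function(x) standardGeneric("aimRankingTable"))

#' @rdname ReducedMatrix-class
#' @export
setGeneric("reducedOperator", function(x) standardGeneric("reducedOperator"))
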