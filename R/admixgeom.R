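.asPointMatrix <- function(parents) {
  P <- as.matrix(parents)
  if (is.null(rownames(P))) rownames(P) <- paste0("parent", seq_len(nrow(P)))
  storage.mode(P) <- "double"
  P
}

.maxPairDist <- function(P) max(stats::dist(P))

.newEstimate <- function(lambda, parents, resid, scale, method) {
  new("AdmixtureEstimate",
    proportions = setNames(as.numeric(lambda), parents),
    residualDistance = resid,
    residualRatio = resid / scale,
    insideHull = all(lambda >= -1e-8),
    parents = parents,
    method = method)
}

#' General barycentric solution for admixture proportions
#'
#' Solves for the weights expressing a query point of the eigenvector-plot
#' as an affine combination of `k` parental points in `T >= k - 1`
#' dimensions. The query is first orthogonally projected onto the parental
#' affine hull (real queries never lie exactly on it); the proportions then
#' solve the augmented linear system binding the parental coordinates with
#' the affine constraint \eqn{\sum_i \lambda_i = 1} — the determinant-ratio
#' form of the general solution equals this solve. The orthogonal distance
#' of the query from the hull is reported as the admixture diagnostic, both
#' absolutely and relative to the largest pairwise parental distance.
#' Proportions are not clipped to `[0, 1]`.
#'
#' @param query numeric vector of plot coordinates of the admixed point.
#' @param parents matrix with one row per parental point (same columns as
#'   `query`); rownames become the parent labels.
#' @return an [AdmixtureEstimate-class].
#' @examples
#' parents <- rbind(P1 = c(-0.82, -0.10), P2 = c(0.50, -0.48),
#'                  P3 = c(0.23, 0.86))
#' barycentricProportions(c(0.18, -0.13), parents)
#' @export
barycentricProportions <- function(query, parents) {
  P <- .asPointMatrix(parents)
  k <- nrow(P)
  q <- as.numeric(query)
  if (k < 2) stop("at least two parental points required")
  if (length(q) != ncol(P)) stop("query and parents must share dimensions")
  if (length(q) < k - 1) stop("need at least k - 1 plot dimensions for k parents")
  scale <- .maxPairDist(P)
  D <- t(P[-k, , drop = FALSE]) - P[k, ]          # T x (k-1) difference matrix
  sv <- svd(D, nu = 0, nv = 0)$d
  if (k > 2 && (length(sv) < k - 1 || min(sv) < 1e-8 * scale)) {
    stop("parental points are affinely dependent (degenerate geometry): ",
      paste(rownames(P), collapse = ", "))
  }
  if (k == 2 && scale == 0) stop("coincident parental points")
  w <- solve(crossprod(D), crossprod(D, q - P[k, ]))
  proj <- P[k, ] + as.vector(D %*% w)
  lambda <- c(w, 1 - sum(w))
  resid <- sqrt(sum((q - proj)^2))
  .newEstimate(lambda, rownames(P), resid, scale, "barycentric")
}

#' Triangle-area estimator for three-way admixture
#'
#' In a two-dimensional eigenvector-plot, an admixed point with three
#' parental populations divides the parental triangle into three
#' sub-triangles whose areas are proportional to the admixture proportions:
#' \eqn{\lambda_i = \mathrm{area}(q, P_j, P_m) / \mathrm{area}(P_1, P_2,
#' P_3)}. Signed areas (cross-product halves) are used, so the estimate
#' extends continuously outside the triangle and equals the barycentric
#' solution to machine precision.
#'
#' @param query numeric vector of length 2.
#' @param parents `3 x 2` matrix of parental plot coordinates.
#' @return an [AdmixtureEstimate-class].
#' @export
triangleAreaProportions <- function(query, parents) {
  P <- .asPointMatrix(parents)
  q <- as.numeric(query)
  if (nrow(P) != 3 || ncol(P) != 2 || length(q) != 2)
    stop("triangle-area estimator requires 3 parental points in 2 dimensions")
  sa <- function(a, b, c) ((b[1] - a[1]) * (c[2] - a[2]) -
                           (b[2] - a[2]) * (c[1] - a[1])) / 2
  total <- sa(P[1, ], P[2, ], P[3, ])
  scale <- .maxPairDist(P)
  if (abs(total) < 1e-12 * scale^2)
    stop("parental triangle has zero area (degenerate geometry): ",
      paste(rownames(P), collapse = ", "))
  l1 <- sa(q, P[2, ], P[3, ]) / total
  l2 <- sa(P[1, ], q, P[3, ]) / total
  .newEstimate(c(l1, l2, 1 - l1 - l2), rownames(P), 0, scale, "triangle-area")
}

#' Segment-ratio estimator for two-way admixture
#'
#' An admixed point lies on the segment joining its two parental points and
#' divides it according to the admixture proportions. The query is
#' orthogonally projected onto the parental line; \eqn{\lambda_1} is the
#' signed position of the projection measured from the second endpoint in
#' units of the segment length (so values outside `[0, 1]` are possible and
#' reported), and \eqn{\lambda_2 = 1 - \lambda_1}. The orthogonal distance
#' to the line is the residual diagnostic.
#'
#' @param query numeric coordinate vector (any dimension, including 1).
#' @param endpoints `2 x T` matrix of the parental points.
#' @return an [AdmixtureEstimate-class].
#' @export
segmentRatio <- function(query, endpoints) {
  P <- .asPointMatrix(endpoints)
  q <- as.numeric(query)
  if (nrow(P) != 2) stop("exactly two endpoints required")
  u <- P[1, ] - P[2, ]
  len2 <- sum(u^2)
  if (len2 == 0) stop("coincident endpoints")
  t1 <- sum((q - P[2, ]) * u) / len2
  proj <- P[2, ] + t1 * u
  resid <- sqrt(sum((q - proj)^2))
  .newEstimate(c(t1, 1 - t1), rownames(P), resid, sqrt(len2), "segment-ratio")
}

#' Affine-residual admixture diagnostic
#'
#' Orthogonal distance of a query point from the affine hull of its
#' putative parental points (line for two parents, plane for three, ...),
#' plus the same distance relative to the largest pairwise parental
#' distance. A small ratio supports the admixture interpretation; no hard
#' threshold is applied.
#'
#' @inheritParams barycentricProportions
#' @return list with elements `distance` and `ratio`.
#' @export
affineResidual <- function(query, parents) {
  est <- if (nrow(.asPointMatrix(parents)) == 2) {
    segmentRatio(query, parents)
  } else {
    barycentricProportions(query, parents)
  }
  list(distance = est@residualDistance, ratio = est@residualRatio)
}

#' Individual-level admixture proportions from an empirical eigensystem
#'
#' Anchors the parental populations at their centroids on the structural
#' eigenvectors and applies the barycentric solution to every admixed
#' individual's coordinates in that subspace. With `K'` non-admixed
#' populations in the system the first `K' - 1` eigenvectors are
#' structural; the parental affine hull is `k - 1`-dimensional inside that
#' space (an inclined segment or triangle when populations beyond the
#' parents are present), and each query is orthogonally projected onto it,
#' so the estimates are unaffected by the extra axes. Columns whose
#' eigenvalue falls below `1e-8` times the largest, and the trivial
#' constant vector, are excluded as non-structural.
#'
#' @param system an empirical [EigenSystem-class] retaining at least `k - 1`
#'   structural eigenvectors.
#' @param parentalPops character vector of `k` parental population labels,
#'   each with at least 2 individuals.
#' @param admixedPops character vector of admixed population labels; any
#'   system population not listed here or in `parentalPops` is treated as an
#'   additional non-admixed population contributing an axis of variation.
#' @return list with `individuals` (data frame: id, population, one
#'   proportion column per parent, residual, residualRatio, insideHull) and
#'   `summary` (per-admixed-population means).
#' @export
individualProportions <- function(system, parentalPops, admixedPops) {
  stopifnot(is(system, "EigenSystem"))
  if (system@kind != "empirical")
    stop("individual-level estimation requires an empirical eigensystem")
  k <- length(parentalPops)
  V <- eigenVectors(system)
  pop <- system@population
  if (any(table(pop[pop %in% parentalPops]) < 2) ||
      !all(parentalPops %in% pop))
    stop("each parental population needs at least 2 individuals in the system")
  keep <- which(system@values > 1e-8 * max(system@values))
  if (!is.na(system@trivialIndex)) keep <- setdiff(keep, system@trivialIndex)
  nStruct <- length(setdiff(unique(pop), admixedPops)) - 1L
  if (length(keep) < k - 1)
    stop("only ", length(keep), " structural eigenvectors retained; ",
      "recompute the PCA with at least ", k - 1, " vectors")
  dims <- keep[seq_len(min(max(nStruct, k - 1L), length(keep)))]
  coords <- V[, dims, drop = FALSE]
  anchors <- matrix(NA_real_, k, length(dims),
    dimnames = list(parentalPops, NULL))
  for (p in parentalPops)
    anchors[p, ] <- colMeans(coords[pop == p, , drop = FALSE])
  rows <- list()
  for (ap in admixedPops) {
    idx <- which(pop == ap)
    if (!length(idx)) stop("no individuals labelled ", ap)
    for (i in idx) {
      est <- barycentricProportions(coords[i, ], anchors)
      rows[[length(rows) + 1L]] <- data.frame(
        id = system@labels[i], population = ap,
        as.list(setNames(est@proportions, parentalPops)),
        residual = est@residualDistance,
        residualRatio = est@residualRatio,
        insideHull = est@insideHull,
        check.names = FALSE)
    }
  }
  ind <- do.call(rbind, rows)
  rownames(ind) <- NULL
  summ <- do.call(rbind, lapply(split(ind, ind$population), function(df) {
    data.frame(population = df$population[1L],
      as.list(colMeans(df[, parentalPops, drop = FALSE])),
      residualRatio = mean(df$residualRatio),
      n = nrow(df), check.names = FALSE)
  }))
  rownames(summ) <- NULL
  list(individuals = ind, summary = summ,
    parents = parentalPops, dims = dims, anchors = anchors)
}

#' @rdname AdmixtureEstimate-class
#' @param x an [AdmixtureEstimate-class].
#' @export
setMethod("proportions", "AdmixtureEstimate", function(x) x@proportions)

#' @rdname AdmixtureEstimate-class
#' @export
setMethod("residualDistance", "AdmixtureEstimate", function(x) x@residualDistance)

#' @rdname AdmixtureEstimate-class
#' @export
setMethod("residualRatio", "AdmixtureEstimate", function(x) x@residualRatio)

#' @rdname AdmixtureEstimate-class
#' @export
setMethod("insideHull", "AdmixtureEstimate", function(x) x@insideHull)

setMethod("show", "AdmixtureEstimate", function(object) {
  cat(sprintf("AdmixtureEstimate (%s)\n", object@method))
  print(signif(object@proportions, 4))
  cat(sprintf("  residual %.4g (ratio %.4g), %s the parental hull\n",
    object@residualDistance, object@residualRatio,
    if (object@insideHull) "inside" else "outside"))
})
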