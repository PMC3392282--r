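#' Rank ancestry-informative markers by eigenvector projection
#'
#' Projects every marker of the mean-adjusted count matrix onto each
#' structural eigenvector of an empirical system,
#' \eqn{u_g(t) = \sum_i \tilde X_{gi}\, v_i(t)}, sorts each eigenvector's
#' markers by `|u|` descending, and merges the per-eigenvector lists by
#' round-robin (skipping duplicates) until `m` unique markers are selected.
#' With `K'` distinct non-admixed populations, the first `K' - 1`
#' eigenvectors are used — admixed populations do not add an axis of
#' variation and should not be counted as distinct. Ties in `|u|` break by
#' marker index for determinism.
#'
#' @param panel the [GenotypePanel-class] the system was computed from.
#' @param system an empirical [EigenSystem-class] over the same individuals.
#' @param m number of markers to select (truncated to `M` with a warning).
#' @param distinctPops labels of the distinct non-admixed populations;
#'   defaults to every panel population without admixture truth. Passing a
#'   population simulated as admixed raises a warning.
#' @return an [AIMRanking-class].
#' @export
rankAIMs <- function(panel, system, m, distinctPops = NULL) {
  stopifnot(is(panel, "GenotypePanel"), is(system, "EigenSystem"))
  if (system@kind != "empirical")
    stop("AIM ranking requires an empirical eigensystem")
  if (!identical(colnames(panel), system@labels))
    stop("system must be computed over the same individuals as the panel")
  admixed <- names(panelTruth(panel)$proportions)
  if (is.null(distinctPops))
    distinctPops <- setdiff(unique(panelPopulations(panel)), admixed)
  if (any(distinctPops %in% admixed))
    warning("admixed population(s) passed as distinct: ",
      paste(intersect(distinctPops, admixed), collapse = ", "),
      " (they do not add an axis of variation)")
  nVec <- length(distinctPops) - 1L
  if (nVec < 1) stop("at least two distinct populations required")
  if (nVec > ncol(system@vectors))
    stop("system retains fewer eigenvectors than needed (", nVec, ")")
  X <- panelCounts(panel)
  M <- nrow(X)
  if (m > M) {
    warning("m truncated to the number of markers (", M, ")")
    m <- M
  }
  gm <- rowMeans(X, na.rm = TRUE)
  if (anyNA(X)) {
    miss <- which(is.na(X), arr.ind = TRUE)
    X[miss] <- gm[miss[, 1L]]
  }
  # per-marker grand-mean adjustment only: monomorphic markers project to
  # zero and the constant (trivial) direction is annihilated exactly
  Y <- X - gm
  U <- Y %*% system@vectors[, seq_len(nVec), drop = FALSE]
  dimnames(U) <- list(rownames(X), paste0("EV", seq_len(nVec)))
  orders <- lapply(seq_len(nVec), function(t)
    order(-abs(U[, t]), seq_len(M)))
  sel <- integer(0)
  selVec <- integer(0)
  pos <- rep(1L, nVec)
  while (length(sel) < m) {
    for (t in seq_len(nVec)) {
      while (pos[t] <= M && orders[[t]][pos[t]] %in% sel) pos[t] <- pos[t] + 1L
      if (pos[t] <= M && length(sel) < m) {
        sel <- c(sel, orders[[t]][pos[t]])
        selVec <- c(selVec, t)
        pos[t] <- pos[t] + 1L
      }
    }
  }
  ranking <- data.frame(
    marker = rownames(X)[sel],
    eigenvector = selVec,
    absProj = abs(U[cbind(sel, selVec)]),
    rank = seq_along(sel))
  new("AIMRanking", projections = U, ranking = ranking, m = as.integer(m))
}

#' @rdname AIMRanking-class
#' @param x an [AIMRanking-class].
#' @export
setMethod("aimMarkers", "AIMRanking", function(x) x@ranking$marker)

#' @rdname AIMRanking-class
#' @export
setMethod("aimRankingTable", "AIMRanking", function(x) x@ranking)

setMethod("show", "AIMRanking", function(object) {
  cat(sprintf("AIMRanking: %d markers selected from %d, %d eigenvector(s)\n",
    nrow(object@ranking), nrow(object@projections), ncol(object@projections)))
  print(head(object@ranking))
})
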