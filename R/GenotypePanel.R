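#' Construct a genotype panel
#'
#' @param counts `M x N` matrix of variant-allele counts (0/1/2, `NA`
#'   allowed), markers in rows, individuals in columns.
#' @param population character vector of population labels, one per
#'   individual.
#' @param markerIds,individualIds row and column identifiers; default to
#'   existing dimnames or `m1..mM` / `i1..iN`.
#' @param truth optional list of generating truth for simulated panels
#'   (ancestral frequencies, per-population frequency matrix, FST values,
#'   per-individual admixture proportions).
#' @param metadata additional metadata entries.
#' @return a [GenotypePanel-class] object.
#' @export
GenotypePanel <- function(counts, population,
                          markerIds = rownames(counts),
                          individualIds = colnames(counts),
                          truth = list(), metadata = list()) {
  counts <- as.matrix(counts)
  if (is.null(markerIds)) markerIds <- paste0("m", seq_len(nrow(counts)))
  if (is.null(individualIds)) individualIds <- paste0("i", seq_len(ncol(counts)))
  dimnames(counts) <- list(markerIds, individualIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      population = as.character(population), row.names = individualIds),
    metadata = c(list(truth = truth), metadata)
  )
  new("GenotypePanel", se)
}

#' Allele-count matrix of a panel
#'
#' @param panel a [GenotypePanel-class].
#' @return the `M x N` counts matrix.
#' @export
panelCounts <- function(panel) SummarizedExperiment::assay(panel, "counts")

#' Population label of each individual in a panel
#'
#' @param panel a [GenotypePanel-class].
#' @return named character vector (names are individual ids).
#' @export
panelPopulations <- function(panel) {
  setNames(SummarizedExperiment::colData(panel)$population, colnames(panel))
}

#' Generating truth stored with a simulated panel
#'
#' @param panel a [GenotypePanel-class].
#' @return list (possibly empty) with elements such as `ancestralFreq`,
#'   `popFreqs`, `fst` and `proportions`.
#' @export
panelTruth <- function(panel) {
  tr <- S4Vectors::metadata(panel)$truth
  if (is.null(tr)) list() else tr
}

#' Combine genotype panels over the same markers
#'
#' Binds the individuals of several panels simulated (or read) over an
#' identical marker set, merging their truth metadata. Per-population
#' frequency matrices are merged by column; per-individual admixture truth
#' is kept keyed by population label.
#'
#' @param ... [GenotypePanel-class] objects with identical marker ids.
#' @return a single [GenotypePanel-class].
#' @export
combinePanels <- function(...) {
  panels <- list(...)
  stopifnot(length(panels) >= 1L)
  ids <- rownames(panels[[1L]])
  for (p in panels[-1L])
    if (!identical(rownames(p), ids)) stop("panels must share identical marker ids")
  counts <- do.call(cbind, lapply(panels, panelCounts))
  population <- unlist(lapply(panels, function(p) unname(panelPopulations(p))))
  truths <- lapply(panels, panelTruth)
  merged <- list()
  for (tr in truths) {
    for (nm in names(tr)) {
      if (nm == "popFreqs") {
        merged$popFreqs <- if (is.null(merged$popFreqs)) tr$popFreqs else {
          keep <- setdiff(colnames(tr$popFreqs), colnames(merged$popFreqs))
          cbind(merged$popFreqs, tr$popFreqs[, keep, drop = FALSE])
        }
      } else if (nm %in% c("fst", "proportions")) {
        merged[[nm]] <- c(merged[[nm]], tr[[nm]])
      } else if (is.null(merged[[nm]])) {
        merged[[nm]] <- tr[[nm]]
      }
    }
  }
  GenotypePanel(counts, population, truth = merged)
}

setMethod("show", "GenotypePanel", function(object) {
  pops <- table(panelPopulations(object))
  cat(sprintf("GenotypePanel: %d markers x %d individuals\n",
    nrow(object), ncol(object)))
  cat("  populations:",
    paste(sprintf("%s (%d)", names(pops), as.integer(pops)), collapse = ", "), "\n")
  nmiss <- sum(is.na(panelCounts(object)))
  if (nmiss) cat("  missing genotypes:", nmiss, "\n")
  if (length(panelTruth(object)))
    cat("  simulated panel with stored truth\n")
})
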