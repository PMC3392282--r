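#' Read a genotype panel from a count matrix or VCF
#'
#' Tab-separated matrices have markers as rows (first column or row names =
#' marker ids) and a header of individual ids; entries are 0/1/2 with `NA`
#' or `.` for missing. VCF input (requires the `vcfR` package) takes the
#' unphased or phased GT field and counts ALT alleles, so genotype `0/1`
#' becomes count 1; records with more than one ALT allele are skipped and
#' the skip count recorded in the panel metadata.
#'
#' @param path path to a `.tsv`/`.txt` count matrix or a `.vcf` file.
#' @param labelsPath tab-separated file with columns `id` and `population`,
#'   covering every individual of the matrix.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return a [GenotypePanel-class].
#' @export
readGenotypePanel <- function(path, labelsPath, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  labels <- read.delim(labelsPath, stringsAsFactors = FALSE)
  if (!all(c("id", "population") %in% colnames(labels)))
    stop("labels file must have columns 'id' and 'population'")
  if (format == "tsv") {
    raw <- read.delim(path, row.names = 1L, check.names = FALSE,
      na.strings = c("NA", "."))
    X <- as.matrix(raw)
    storage.mode(X) <- "integer"
    skipped <- 0L
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("VCF import requires the 'vcfR' package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    alt <- vcfR::getALT(v)
    multi <- grepl(",", alt)
    skipped <- sum(multi)
    gt <- vcfR::extract.gt(v, element = "GT")[!multi, , drop = FALSE]
    X <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
             "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
    X[] <- map[gt]
  }
  missing <- setdiff(colnames(X), labels$id)
  extra <- setdiff(labels$id, colnames(X))
  if (length(missing) || length(extra))
    stop("label/individual mismatch; unlabelled: [",
      paste(missing, collapse = ", "), "], absent from matrix: [",
      paste(extra, collapse = ", "), "]")
  pop <- labels$population[match(colnames(X), labels$id)]
  GenotypePanel(X, pop,
    metadata = list(nMissing = sum(is.na(X)), skippedMultiallelic = skipped))
}

#' Write a genotype panel as a count matrix plus labels file
#'
#' @param panel a [GenotypePanel-class].
#' @param path output path for the tab-separated count matrix (markers as
#'   rows, individual ids as header).
#' @param labelsPath output path for the `id`/`population` table.
#' @return invisibly, `path`.
#' @export
writeGenotypePanel <- function(panel, path, labelsPath) {
  X <- panelCounts(panel)
  df <- data.frame(marker = rownames(X), X, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(id = colnames(X), population = unname(panelPopulations(panel))),
    labelsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population model from a structured config file
#'
#' YAML layout: `populations` is a list of `{name, mu, n}` entries; `C` is
#' the lower triangle of the frequency variance-covariance matrix as a list
#' of rows (row `k` has `k` numbers); optional `admixed` is a list of
#' `{name, parents, proportions, n}` entries.
#'
#' @param path path to the YAML model file.
#' @return a [PopulationModel-class] (admixed populations unresolved).
#' @export
readPopulationModel <- function(path) {
  cfg <- yaml::read_yaml(path)
  labels <- vapply(cfg$populations, function(p) p$name, "")
  mu <- vapply(cfg$populations, function(p) as.numeric(p$mu), 1)
  n <- vapply(cfg$populations, function(p) as.numeric(.cfgField(p, "n")), 1)
  K <- length(labels)
  C <- matrix(0, K, K)
  for (k in seq_len(K)) {
    row <- as.numeric(cfg$C[[k]])
    if (length(row) != k) stop("C must be lower-triangular: row ", k,
      " needs ", k, " values")
    C[k, seq_len(k)] <- row
    C[seq_len(k), k] <- row
  }
  model <- PopulationModel(mu, C, n, labels)
  for (a in cfg$admixed)
    model <- addAdmixedPopulation(model, a$name, a$parents,
      as.numeric(a$proportions), as.numeric(.cfgField(a, "n")))
  model
}

## YAML 1.1 parses the bare keys n/y/no/yes as booleans, so a config key "n"
## arrives as "FALSE"; accept either spelling.
.cfgField <- function(x, key) {
  v <- x[[key]]
  if (is.null(v) && key == "n") v <- x[["FALSE"]]
  if (is.null(v)) stop("config entry missing field '", key, "'")
  v
}

#' Write / read a SigmaSet as a tagged tabular file
#'
#' One row per population with its name, sample size, variance and within
#' covariance, followed by the between-covariance columns (named after the
#' populations).
#'
#' @param sigma a [SigmaSet-class].
#' @param path output (or input) path.
#' @return `writeSigmaSet` returns `path` invisibly; `readSigmaSet` returns
#'   a [SigmaSet-class].
#' @export
writeSigmaSet <- function(sigma, path) {
  df <- data.frame(
    population = popLabels(sigma),
    n = sampleSizes(sigma),
    var = sigmaVar(sigma),
    within = sigmaWithin(sigma),
    sigmaCov(sigma),
    check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSigmaSet
#' @export
readSigmaSet <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  labels <- df$population
  SigmaSet(df$var, as.matrix(df[, labels, drop = FALSE]),
    n = df$n, labels = labels)
}

#' Write an eigensystem as coordinates plus JSON metadata
#'
#' @param system an [EigenSystem-class].
#' @param path output path for the coordinate table (label, population, one
#'   column per eigenvector).
#' @param metaPath output path for the JSON metadata (eigenvalues, signs,
#'   kind, trivial index, package version).
#' @return invisibly, `path`.
#' @export
writeEigenSystem <- function(system, path, metaPath) {
  V <- eigenVectors(system)
  df <- data.frame(label = system@labels, population = system@population,
    round(V, 6), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    eigenvalues = system@values,
    signs = system@signs,
    kind = system@kind,
    trivialIndex = system@trivialIndex,
    package = as.character(packageVersion("admixPCA"))
  ), metaPath, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write individual-level admixture estimates
#'
#' @param estimates result of [individualProportions()].
#' @param path output path for the per-individual table.
#' @param summaryPath optional output path for the population-summary JSON.
#' @return invisibly, `path`.
#' @export
writeAdmixtureTable <- function(estimates, path, summaryPath = NULL) {
  ind <- estimates$individuals
  num <- vapply(ind, is.numeric, TRUE)
  ind[num] <- lapply(ind[num], round, 6)
  write.table(ind, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summaryPath))
    jsonlite::write_json(estimates$summary, summaryPath,
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
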