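.argValue <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  if (i[1L] == length(args)) stop("missing value for ", flag)
  args[i[1L] + 1L]
}

.argFlag <- function(args, flag) flag %in% args

.requireArg <- function(args, flag) {
  v <- .argValue(args, flag)
  if (is.null(v)) stop("required argument ", flag, " missing")
  v
}

.provenance <- function(seed = NULL, args = character()) {
  list(package = as.character(packageVersion("admixPCA")),
    seed = seed, args = paste(args, collapse = " "))
}

.splitCSV <- function(x) strsplit(x, ",", fixed = TRUE)[[1L]]

#' Run a pipeline stage from command-line style arguments
#'
#' Thin dispatcher over the package's functions, also used by the
#' `inst/cli/admixpca.R` script. Subcommands:
#' \describe{
#'   \item{`simulate`}{`--config sim.yaml --seed S --out prefix` — simulate
#'     the parental (and admixed) panels described by a YAML config
#'     (`nMarkers`, `fst`, `n`, `labels`, optional `ancestralRange`,
#'     optional `admixed:` list with `label`, `parents`, and either
#'     `proportions` or `shape`, plus `n`) and write
#'     `prefix.genotypes.tsv`, `prefix.labels.tsv`, `prefix.truth.json`.}
#'   \item{`estimate-params`}{`--genotypes g.tsv --labels l.tsv --out
#'     sigma.tsv [--recode-minor]` — estimate the variance-covariance
#'     parameters.}
#'   \item{`eigen`}{`--model model.yaml --out prefix [--asymptotic]` —
#'     theoretical solve from a population-model file; writes
#'     `prefix.coords.tsv` + `prefix.meta.json` and prints eigenvalues.}
#'   \item{`pca`}{`--genotypes --labels --out prefix [--nvec T] [--scale]` —
#'     empirical PCA; writes the coordinate and metadata files.}
#'   \item{`admix-estimate`}{`--genotypes --labels --parents A,B,... --admixed
#'     X,... --out prefix [--nvec T]` — empirical PCA then individual-level
#'     barycentric estimates; writes `prefix.admixture.tsv` +
#'     `prefix.summary.json`.}
#'   \item{`aims`}{`--genotypes --labels --m 300 --out file
#'     [--distinct A,B,...]` — AIM ranking table.}
#'   \item{`diagnose`}{`--genotypes --labels --parents A,B,... --admixed X` —
#'     print the affine-residual diagnostic of each admixed centroid.}
#' }
#'
#' @param args character vector of arguments (as from `commandArgs(TRUE)`).
#' @return 0 on success (invisibly); stages stop with the stage name on
#'   failure.
#' @export
runPipeline <- function(args) {
  if (!length(args)) stop("usage: admixpca <subcommand> [options]")
  cmd <- args[1L]
  rest <- args[-1L]
  handler <- switch(cmd,
    "simulate" = .stageSimulate,
    "estimate-params" = .stageEstimate,
    "eigen" = .stageEigen,
    "pca" = .stagePCA,
    "admix-estimate" = .stageAdmixEstimate,
    "aims" = .stageAIMs,
    "diagnose" = .stageDiagnose,
    stop("unknown subcommand: ", cmd))
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(handler(rest),
    error = function(e) stop("stage '", cmd, "' failed: ",
      conditionMessage(e), call. = FALSE))
  message(sprintf("[admixpca] %s finished in %.2f s", cmd,
    proc.time()[["elapsed"]] - t0))
  invisible(0L)
}

.readPanelArgs <- function(args) {
  readGenotypePanel(.requireArg(args, "--genotypes"),
    .requireArg(args, "--labels"))
}

.stageSimulate <- function(args) {
  cfg <- yaml::read_yaml(.requireArg(args, "--config"))
  seed <- as.integer(.requireArg(args, "--seed"))
  out <- .requireArg(args, "--out")
  sizes <- as.integer(.cfgField(cfg, "n"))
  labels <- if (is.null(cfg$labels)) paste0("P", seq_along(sizes)) else
    as.character(cfg$labels)
  panel <- simulateParentalPanel(
    nMarkers = as.integer(cfg$nMarkers),
    fst = as.numeric(cfg$fst),
    n = sizes,
    seed = seed,
    labels = labels,
    ancestralRange = if (is.null(cfg$ancestralRange)) c(0.1, 0.9) else
      as.numeric(cfg$ancestralRange))
  panels <- list(panel)
  for (a in cfg$admixed) {
    panels[[length(panels) + 1L]] <- if (!is.null(a$proportions)) {
      simulateAdmixedHomogeneous(panel, as.numeric(a$proportions),
        n = as.integer(.cfgField(a, "n")), seed = seed, label = a$label,
        parentLabels = as.character(a$parents))
    } else {
      simulateAdmixedRecent(panel, shape = as.numeric(a$shape),
        n = as.integer(.cfgField(a, "n")), seed = seed, label = a$label,
        parentLabels = as.character(a$parents))
    }
  }
  full <- do.call(combinePanels, panels)
  writeGenotypePanel(full, paste0(out, ".genotypes.tsv"),
    paste0(out, ".labels.tsv"))
  truth <- panelTruth(full)
  jsonlite::write_json(
    c(list(provenance = .provenance(seed, args)),
      lapply(truth[names(truth) %in% c("fst", "proportions")],
        function(x) lapply(x, function(v) round(as.data.frame(v), 6)))),
    paste0(out, ".truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(full)
}

.stageEstimate <- function(args) {
  panel <- .readPanelArgs(args)
  sigma <- estimateSigma(panel, recodeMinor = .argFlag(args, "--recode-minor"))
  writeSigmaSet(sigma, .requireArg(args, "--out"))
  invisible(sigma)
}

.stageEigen <- function(args) {
  model <- readPopulationModel(.requireArg(args, "--model"))
  model <- extendWithAdmixture(model)
  sigma <- alleleCountMoments(model)
  rm <- if (.argFlag(args, "--asymptotic")) buildReducedAsymptotic(sigma) else
    buildReducedExact(sigma)
  sys <- solveReduced(rm)
  out <- .requireArg(args, "--out")
  writeEigenSystem(sys, paste0(out, ".coords.tsv"), paste0(out, ".meta.json"))
  cat("eigenvalues:", paste(sprintf("%.6g", eigenValues(sys)), collapse = " "),
    "\n")
  invisible(sys)
}

.stagePCA <- function(args) {
  panel <- .readPanelArgs(args)
  nvec <- as.integer(.argValue(args, "--nvec", "10"))
  sys <- empiricalPCA(panel, nVectors = nvec,
    scaleMarkers = .argFlag(args, "--scale"))
  out <- .requireArg(args, "--out")
  writeEigenSystem(sys, paste0(out, ".coords.tsv"), paste0(out, ".meta.json"))
  invisible(sys)
}

.stageAdmixEstimate <- function(args) {
  panel <- .readPanelArgs(args)
  parents <- .splitCSV(.requireArg(args, "--parents"))
  admixed <- .splitCSV(.requireArg(args, "--admixed"))
  nPops <- length(unique(unname(panelPopulations(panel))))
  nvec <- as.integer(.argValue(args, "--nvec",
    as.character(max(nPops - 1L, 2L))))
  sys <- empiricalPCA(panel, nVectors = nvec)
  est <- individualProportions(sys, parents, admixed)
  out <- .requireArg(args, "--out")
  writeAdmixtureTable(est, paste0(out, ".admixture.tsv"),
    paste0(out, ".summary.json"))
  invisible(est)
}

.stageAIMs <- function(args) {
  panel <- .readPanelArgs(args)
  distinct <- .argValue(args, "--distinct")
  if (!is.null(distinct)) distinct <- .splitCSV(distinct)
  pops <- if (is.null(distinct))
    unique(unname(panelPopulations(panel))) else distinct
  sys <- empiricalPCA(panel, nVectors = max(length(pops) - 1L, 2L))
  rk <- rankAIMs(panel, sys, m = as.integer(.requireArg(args, "--m")),
    distinctPops = distinct)
  write.table(aimRankingTable(rk), .requireArg(args, "--out"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rk)
}

.stageDiagnose <- function(args) {
  panel <- .readPanelArgs(args)
  parents <- .splitCSV(.requireArg(args, "--parents"))
  admixed <- .splitCSV(.requireArg(args, "--admixed"))
  ## one dimension more than the parental hull, so the residual is visible
  sys <- empiricalPCA(panel, nVectors = length(parents))
  cent <- popCentroids(sys)
  dims <- seq_len(length(parents))
  for (ap in admixed) {
    res <- affineResidual(cent[ap, dims, drop = TRUE],
      cent[parents, dims, drop = FALSE])
    cat(sprintf("%s: residual %.6g, ratio %.6g\n", ap, res$distance, res$ratio))
  }
  invisible(NULL)
}
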