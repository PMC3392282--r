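## Deterministic per-stage seed streams: every simulation stage (ancestral
## draw, each population's frequencies, each population's genotypes, each
## admixed group) re-seeds from a hash of the master seed and a stage tag,
## so adding an admixed group never perturbs the parental draws.
.streamSeed <- function(seed, tag) {
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% 2147480951
  as.integer((as.numeric(seed) %% 2147480951 * 48271 + h) %% 2147480951)
}

.drawPopFreq <- function(p, fst) {
  if (fst == 0) return(p)                      # degenerate Beta: point mass
  rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

.genotypesFromFreq <- function(freq, n) {
  matrix(rbinom(length(freq) * n, 2L, rep(freq, times = n)),
    nrow = length(freq), ncol = n)
}

#' Simulate parental genotype panels under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn for every marker from a uniform
#' distribution on `ancestralRange`; each population's marker frequencies
#' are then drawn from \eqn{\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)}, whose
#' mean is the ancestral frequency `p` and whose variance is
#' \eqn{F\,p(1-p)} with `F` the population's FST; genotypes are binomial
#' with two draws (Hardy-Weinberg equilibrium). `fst = 0` degenerates to a
#' point mass at the ancestral frequency. All draws run in named RNG
#' streams derived from `seed`, so the panel is bit-reproducible and
#' unaffected by later admixed additions.
#'
#' @param nMarkers number of markers `M`.
#' @param fst per-population FST values in `(0, 1)` (or 0), recycled to the
#'   number of populations.
#' @param n per-population sample sizes.
#' @param seed master integer seed.
#' @param labels population names; default `P1..PK`.
#' @param ancestralRange uniform range of the ancestral frequency draw.
#' @return a [GenotypePanel-class] with truth metadata (`ancestralFreq`,
#'   `popFreqs`, `fst`).
#' @examples
#' panel <- simulateParentalPanel(200, fst = 0.05, n = c(10, 10), seed = 1)
#' panel
#' @export
simulateParentalPanel <- function(nMarkers, fst, n, seed,
                                  labels = paste0("P", seq_along(n)),
                                  ancestralRange = c(0.1, 0.9)) {
  K <- length(n)
  fst <- rep_len(fst, K)
  stopifnot(all(fst >= 0 & fst < 1),
    ancestralRange[1] >= 0, ancestralRange[2] <= 1,
    ancestralRange[1] < ancestralRange[2])
  set.seed(.streamSeed(seed, "ancestral"))
  p <- runif(nMarkers, ancestralRange[1], ancestralRange[2])
  freqs <- matrix(NA_real_, nMarkers, K, dimnames = list(NULL, labels))
  counts <- vector("list", K)
  pops <- character(0)
  for (k in seq_len(K)) {
    set.seed(.streamSeed(seed, paste0("freq:", labels[k])))
    freqs[, k] <- .drawPopFreq(p, fst[k])
    set.seed(.streamSeed(seed, paste0("geno:", labels[k])))
    counts[[k]] <- .genotypesFromFreq(freqs[, k], n[k])
    pops <- c(pops, rep(labels[k], n[k]))
  }
  X <- do.call(cbind, counts)
  colnames(X) <- paste0(pops, "_", unlist(lapply(n, seq_len)))
  rownames(X) <- paste0("m", seq_len(nMarkers))
  GenotypePanel(X, pops,
    truth = list(ancestralFreq = p, popFreqs = freqs,
      fst = setNames(as.list(fst), labels)),
    metadata = list(seed = seed))
}

.parentFreqMatrix <- function(parents, parentLabels) {
  if (is(parents, "GenotypePanel")) {
    pf <- panelTruth(parents)$popFreqs
    if (is.null(pf)) stop("parental panel carries no frequency truth")
    if (is.null(parentLabels)) parentLabels <- colnames(pf)
    if (!all(parentLabels %in% colnames(pf)))
      stop("unknown parental labels: ",
        paste(setdiff(parentLabels, colnames(pf)), collapse = ", "))
    pf[, parentLabels, drop = FALSE]
  } else {
    pf <- as.matrix(parents)
    if (is.null(colnames(pf)))
      colnames(pf) <- if (is.null(parentLabels))
        paste0("P", seq_len(ncol(pf))) else parentLabels
    pf
  }
}

## Each of the two allele copies independently inherits from a parental
## population chosen by the individual's proportions, so the per-allele
## success probability is the lambda-weighted parental frequency and the
## count is Binomial(2, sum_i lambda_i p_i) given the parental frequencies.
## This keeps the simulated count variance consistent with the admixture
## moment algebra (a single origin draw per genotype would put both alleles
## in the same parent and inflate the variance).
.mixGenotypes <- function(parentFreq, lambdaPerInd) {
  pA <- parentFreq %*% t(lambdaPerInd)        # M x n mixture frequencies
  matrix(rbinom(length(pA), 2L, pA), nrow(parentFreq))
}

#' Simulate a genetically homogeneous admixed population
#'
#' For each individual and marker, each of the two allele copies inherits
#' independently from a parental population drawn with the common admixture
#' proportions, i.e. the genotype is binomial with two draws from the
#' proportion-weighted parental frequency — the well-admixed construction in
#' which every individual shares the same proportions and the count moments
#' equal those of the admixture moment algebra.
#'
#' @param parents a parental [GenotypePanel-class] carrying frequency truth,
#'   or an `M x k` matrix of parental allele frequencies.
#' @param proportions admixture proportions over the parents (sum to 1).
#' @param n number of admixed individuals.
#' @param seed integer seed (independent stream per `label`).
#' @param label population label of the admixed group.
#' @param parentLabels which parental populations of a panel to mix (default
#'   all, in panel order).
#' @return a [GenotypePanel-class] for the admixed group, with the common
#'   proportions stored per individual in its truth.
#' @export
simulateAdmixedHomogeneous <- function(parents, proportions, n, seed,
                                       label = "ADM", parentLabels = NULL) {
  pf <- .parentFreqMatrix(parents, parentLabels)
  if (length(proportions) != ncol(pf))
    stop("need one proportion per parental population")
  if (abs(sum(proportions) - 1) > 1e-12)
    stop("admixture proportions must sum to 1")
  set.seed(.streamSeed(seed, paste0("admix:", label)))
  lam <- matrix(proportions, n, ncol(pf), byrow = TRUE,
    dimnames = list(NULL, colnames(pf)))
  X <- .mixGenotypes(pf, lam)
  rownames(X) <- paste0("m", seq_len(nrow(X)))
  colnames(X) <- paste0(label, "_", seq_len(n))
  rownames(lam) <- colnames(X)
  GenotypePanel(X, rep(label, n),
    truth = list(proportions = setNames(list(lam), label)),
    metadata = list(seed = seed))
}

#' Simulate a recently admixed population with heterogeneous proportions
#'
#' Each individual receives its own admixture proportions, drawn once and
#' stored in the truth: from a Beta(`shape[1]`, `shape[2]`) distribution for
#' two parents (the drawn value is the weight of the first parent), or from
#' a Dirichlet(`shape`) distribution for `k > 2` parents. Genotypes are then
#' generated marker-by-marker as in the homogeneous case using the
#' individual's proportions.
#'
#' @inheritParams simulateAdmixedHomogeneous
#' @param shape Beta shape pair (two parents) or Dirichlet concentration
#'   vector (`k` parents); default `c(5, 5)`.
#' @return a [GenotypePanel-class] with per-individual generating
#'   proportions in its truth.
#' @export
simulateAdmixedRecent <- function(parents, shape = c(5, 5), n, seed,
                                  label = "ADM", parentLabels = NULL) {
  pf <- .parentFreqMatrix(parents, parentLabels)
  k <- ncol(pf)
  if (length(shape) != k) stop("need one shape parameter per parental population")
  if (any(shape <= 0)) stop("shape parameters must be positive")
  set.seed(.streamSeed(seed, paste0("admixlam:", label)))
  lam <- if (k == 2) {
    l1 <- rbeta(n, shape[1], shape[2])
    cbind(l1, 1 - l1)
  } else {
    g <- matrix(rgamma(n * k, shape = rep(shape, each = n)), n, k)
    g / rowSums(g)
  }
  colnames(lam) <- colnames(pf)
  set.seed(.streamSeed(seed, paste0("admix:", label)))
  X <- .mixGenotypes(pf, lam)
  rownames(X) <- paste0("m", seq_len(nrow(X)))
  colnames(X) <- paste0(label, "_", seq_len(n))
  rownames(lam) <- colnames(X)
  GenotypePanel(X, rep(label, n),
    truth = list(proportions = setNames(list(lam), label)),
    metadata = list(seed = seed))
}
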