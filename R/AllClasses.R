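#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor rnorm runif rbinom pnorm phyper pchisq setNames
#'   p.adjust sd quantile median
#' @importFrom utils read.delim write.table head
NULL

#' Simulation configuration for multi-species diurnal expression data
#'
#' Holds every parameter of the synthetic-data generator: the number of
#' syntenic ortholog groups, species labels, the fraction of groups carrying
#' a duplicated homeolog in the third species (emulating the maize
#' whole-genome duplication), the rhythmic fraction, the diurnal signal
#' model (period, phase distribution, amplitude and baseline ranges,
#' multiplicative log-normal noise, per-day additive offsets), and the
#' promoter model (length, per-species background nucleotide composition,
#' planted cis-elements).
#'
#' @slot nGroups integer, number of ortholog groups.
#' @slot speciesNames character, ordered species labels; the last species
#'   is the one that may carry duplicated homeologs.
#' @slot maizeDuplicateFraction probability a group has two homeologs in
#'   the last species.
#' @slot rhythmicFraction probability a group is rhythmic.
#' @slot periodH oscillation period in hours.
#' @slot phaseSampler function(n) returning n circadian-time phases in
#'   [0, 24); the default concentrates phases on CT 9-18 with probability
#'   0.75 and is uniform otherwise, mirroring the afternoon/evening bias of
#'   diurnal transcriptomes.
#' @slot phaseJitterH within-group phase jitter SD in hours (0 = orthologs
#'   share the group phase exactly).
#' @slot amplitudeRange peak-to-trough FPKM range for rhythmic genes.
#' @slot baselineRange baseline FPKM range.
#' @slot noiseSigma SD of multiplicative log-normal noise.
#' @slot dayEffectSigma SD of the additive per-day offset shared by the 8
#'   samples of a day (controls day-to-day reproducibility).
#' @slot promoterLength promoter length in bp.
#' @slot backgroundComposition numeric matrix, one row per species, columns
#'   A/C/G/T, each row summing to 1.
#' @slot plantedMotifs list of lists with elements \code{motif} (ACGT
#'   string), \code{phaseInterval} (CT hours, lo <= hi), \code{pTarget} and
#'   \code{pBackground} (insertion probabilities for genes inside/outside
#'   the phase interval).
#' @slot seed integer master seed; all generator randomness derives from it.
#' @export
setClass("DielSimConfig",
  representation(
    nGroups = "integer",
    speciesNames = "character",
    maizeDuplicateFraction = "numeric",
    rhythmicFraction = "numeric",
    periodH = "numeric",
    phaseSampler = "function",
    phaseJitterH = "numeric",
    amplitudeRange = "numeric",
    baselineRange = "numeric",
    noiseSigma = "numeric",
    dayEffectSigma = "numeric",
    promoterLength = "integer",
    backgroundComposition = "matrix",
    plantedMotifs = "list",
    seed = "integer"
  )
)

setValidity("DielSimConfig", function(object) {
  msg <- character()
  probs <- c(object@maizeDuplicateFraction, object@rhythmicFraction)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@nGroups < 1L)
    msg <- c(msg, "nGroups must be >= 1")
  if (object@periodH <= 0)
    msg <- c(msg, "periodH must be positive")
  if (length(object@speciesNames) < 2L ||
      anyDuplicated(object@speciesNames))
    msg <- c(msg, "speciesNames must be >= 2 distinct labels")
  bc <- object@backgroundComposition
  if (nrow(bc) != length(object@speciesNames) || ncol(bc) != 4L)
    msg <- c(msg, "backgroundComposition must be species x 4 (A,C,G,T)")
  else if (any(bc < 0) || any(abs(rowSums(bc) - 1) > 1e-8))
    msg <- c(msg, "each backgroundComposition row must be a probability vector")
  if (length(object@amplitudeRange) != 2L || diff(object@amplitudeRange) < 0 ||
      any(object@amplitudeRange < 0))
    msg <- c(msg, "amplitudeRange must be nonnegative and nondecreasing")
  if (length(object@baselineRange) != 2L || diff(object@baselineRange) < 0 ||
      any(object@baselineRange < 0))
    msg <- c(msg, "baselineRange must be nonnegative and nondecreasing")
  # trough = baseline - amplitude/2; forbid configs where clipping at zero
  # could distort more than half the waveform of some gene
  if (max(object@amplitudeRange) / 2 > min(object@baselineRange))
    msg <- c(msg, "max amplitude/2 exceeds min baseline: too much clipping at 0")
  if (any(c(object@noiseSigma, object@dayEffectSigma, object@phaseJitterH) < 0))
    msg <- c(msg, "noiseSigma, dayEffectSigma and phaseJitterH must be >= 0")
  for (pm in object@plantedMotifs) {
    if (!all(c("motif", "phaseInterval", "pTarget", "pBackground") %in%
             names(pm))) {
      msg <- c(msg, "each planted motif needs motif, phaseInterval, pTarget, pBackground")
      next
    }
    if (grepl("[^ACGT]", pm$motif))
      msg <- c(msg, sprintf("planted motif '%s' has characters outside ACGT", pm$motif))
    if (nchar(pm$motif) > object@promoterLength)
      msg <- c(msg, "promoterLength must be >= longest planted motif")
    if (any(c(pm$pTarget, pm$pBackground) < 0) ||
        any(c(pm$pTarget, pm$pBackground) > 1))
      msg <- c(msg, "planted motif probabilities must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-species K-means model with Pearson correlation distance
#'
#' Result of \code{\link{kmeansCorrelation}}: gene-to-cluster assignment over
#' the filtered multi-species gene set, cluster centers on the 0-1 scaled
#' profile scale, and convergence diagnostics.
#'
#' @slot k number of centers.
#' @slot assignment named integer vector, gene id -> cluster in 1..k.
#' @slot species named character vector parallel to \code{assignment}.
#' @slot centers k x 24 matrix of mean 0-1 scaled member profiles.
#' @slot objective numeric, summed 1 - Pearson(x, center) per iteration.
#' @slot iterations iterations actually run.
#' @slot converged logical.
#' @export
setClass("ClusterModel",
  representation(
    k = "integer",
    assignment = "integer",
    species = "character",
    centers = "matrix",
    objective = "numeric",
    iterations = "integer",
    converged = "logical"
  )
)

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (length(object@assignment) != length(object@species))
    msg <- c(msg, "assignment and species must be parallel")
  if (length(object@assignment) &&
      (min(object@assignment) < 1L || max(object@assignment) > object@k))
    msg <- c(msg, "cluster indices must lie in 1..k")
  if (is.null(names(object@assignment)))
    msg <- c(msg, "assignment must be named by gene id")
  if (length(msg)) msg else TRUE
})

#' @describeIn ClusterModel-class compact display
#' @param object a \code{ClusterModel}
#' @export
setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: %d genes in %d clusters (%s after %d iterations)\n",
              length(object@assignment), object@k,
              if (object@converged) "converged" else "iteration-capped",
              object@iterations))
  cat("cluster sizes:", tabulate(object@assignment, object@k), "\n")
})

#' k-mer presence/count index over a promoter set
#'
#' Per-species sliding-window index of all 4^k motifs of width k over the
#' forward strand of each promoter. Windows containing N never match;
#' overlapping occurrences are counted.
#'
#' @slot k motif width.
#' @slot species species label.
#' @slot counts genes x 4^k integer matrix of occurrence counts; column
#'   names are the motifs in lexicographic order.
#' @export
setClass("MotifIndex",
  representation(k = "integer", species = "character", counts = "matrix")
)

setValidity("MotifIndex", function(object) {
  msg <- character()
  if (ncol(object@counts) != 4L^object@k)
    msg <- c(msg, "counts must have 4^k columns")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' @describeIn MotifIndex-class compact display
#' @param object a \code{MotifIndex}
#' @export
setMethod("show", "MotifIndex", function(object) {
  cat(sprintf("MotifIndex: %d promoters (%s), %d motifs of width %d\n",
              nrow(object@counts), object@species, ncol(object@counts),
              object@k))
})

#' Accessors for ClusterModel and MotifIndex
#'
#' \code{clusterAssignment} returns the named gene -> cluster vector,
#' \code{clusterCenters} the k x 24 center matrix, \code{clusterSpecies}
#' the per-gene species labels, \code{motifCounts} the gene x motif count
#' matrix and \code{motifPresence} its logical presence version.
#'
#' @param object a \code{ClusterModel} or \code{MotifIndex}
#' @return see description
#' @name accessors
NULL

#' @rdname accessors
#' @export
clusterAssignment <- function(object) object@assignment

#' @rdname accessors
#' @export
clusterCenters <- function(object) object@centers

#' @rdname accessors
#' @export
clusterSpecies <- function(object) object@species

#' @rdname accessors
#' @export
motifCounts <- function(object) object@counts

#' @rdname accessors
#' @export
motifPresence <- function(object) object@counts >= 1L
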