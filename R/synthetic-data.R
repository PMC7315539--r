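#' Construct a simulation configuration
#'
#' Builds a validated \linkS4class{DielSimConfig}. Defaults emulate a
#' three-grass diurnal study: 12h/12h photocycles sampled every 3 h over
#' 72 h (24 time points), a phase distribution concentrated between CT9 and
#' CT18, maize-style homeolog duplication in the last species, distinct
#' per-species promoter base compositions (uniform, GC-rich, AT-rich), and
#' an evening element (AAATATCT) planted preferentially upstream of
#' evening-phased genes.
#'
#' @param nGroups number of syntenic ortholog groups.
#' @param speciesNames ordered species labels; the last may carry two
#'   homeologs per group.
#' @param maizeDuplicateFraction probability a group is duplicated in the
#'   last species.
#' @param rhythmicFraction probability a group is rhythmic.
#' @param periodH oscillation period (hours).
#' @param phaseSampler optional function(n) -> CT phases in [0,24); when
#'   NULL one is built from \code{phaseConcentration}.
#' @param phaseConcentration list(lo, hi, weight): with probability
#'   \code{weight} a phase is uniform on [lo, hi], otherwise uniform on
#'   [0, 24).
#' @param phaseJitterH within-group phase jitter SD (hours).
#' @param amplitudeRange peak-to-trough FPKM range.
#' @param baselineRange baseline FPKM range.
#' @param noiseSigma multiplicative log-normal noise SD.
#' @param dayEffectSigma SD of the additive offset shared by each day's 8
#'   samples.
#' @param promoterLength promoter length (bp).
#' @param backgroundComposition species x 4 matrix of A/C/G/T probabilities
#'   (rows sum to 1); default uniform / GC-rich / AT-rich.
#' @param plantedMotifs list of planted cis-elements, each
#'   list(motif, phaseInterval, pTarget, pBackground).
#' @param seed integer master seed.
#' @return a \code{DielSimConfig}
#' @examples
#' cfg <- DielSimConfig(nGroups = 50, seed = 7)
#' @export
DielSimConfig <- function(nGroups = 200L,
                          speciesNames = c("sorghum", "foxtail_millet", "maize"),
                          maizeDuplicateFraction = 0.2,
                          rhythmicFraction = 0.5,
                          periodH = 24,
                          phaseSampler = NULL,
                          phaseConcentration = list(lo = 9, hi = 18, weight = 0.75),
                          phaseJitterH = 0,
                          amplitudeRange = c(14, 16),
                          baselineRange = c(8, 12),
                          noiseSigma = 0.15,
                          dayEffectSigma = 0.5,
                          promoterLength = 1000L,
                          backgroundComposition = NULL,
                          plantedMotifs = list(
                            list(motif = "AAATATCT",
                                 phaseInterval = c(10.5, 13.5),
                                 pTarget = 0.4, pBackground = 0.05)),
                          seed = 1L) {
  if (is.null(backgroundComposition)) {
    # recycle the three stock compositions over however many species
    stock <- rbind(rep(0.25, 4),
                   c(0.2, 0.3, 0.3, 0.2),
                   c(0.3, 0.2, 0.2, 0.3))
    backgroundComposition <-
      stock[(seq_along(speciesNames) - 1L) %% 3L + 1L, , drop = FALSE]
  }
  dimnames(backgroundComposition) <- list(speciesNames, c("A", "C", "G", "T"))
  if (is.null(phaseSampler)) {
    lo <- phaseConcentration$lo; hi <- phaseConcentration$hi
    w <- phaseConcentration$weight
    phaseSampler <- function(n) {
      conc <- runif(n) < w
      ifelse(conc, runif(n, lo, hi), runif(n, 0, 24))
    }
  }
  new("DielSimConfig",
      nGroups = as.integer(nGroups),
      speciesNames = speciesNames,
      maizeDuplicateFraction = maizeDuplicateFraction,
      rhythmicFraction = rhythmicFraction,
      periodH = periodH,
      phaseSampler = phaseSampler,
      phaseJitterH = phaseJitterH,
      amplitudeRange = as.numeric(amplitudeRange),
      baselineRange = as.numeric(baselineRange),
      noiseSigma = noiseSigma,
      dayEffectSigma = dayEffectSigma,
      promoterLength = as.integer(promoterLength),
      backgroundComposition = backgroundComposition,
      plantedMotifs = plantedMotifs,
      seed = as.integer(seed))
}

#' Sample times of the 72-h design
#'
#' @return numeric vector 0, 3, ..., 69 (hours since lights-on at t = 0).
#' @export
sampleTimes <- function() seq(0, 69, by = 3)

.stageSeed <- function(config, offset) {
  (config@seed + offset) %% .Machine$integer.max
}

.speciesPrefix <- function(speciesNames) {
  pre <- toupper(substr(speciesNames, 1, 2))
  if (anyDuplicated(pre)) pre <- speciesNames
  pre
}

#' Simulate a syntenic ortholog-group table
#'
#' Each group carries exactly one gene per species, except a
#' \code{maizeDuplicateFraction} of groups that carry two homeologs in the
#' last species (comma-separated in its column). Gene ids are unique within
#' species and the draw is deterministic given the config seed.
#'
#' @param config a \linkS4class{DielSimConfig}
#' @return data.frame with column \code{group_id} plus one column per
#'   species.
#' @export
simulateOrthogroups <- function(config) {
  stopifnot(is(config, "DielSimConfig"))
  validObject(config)
  set.seed(.stageSeed(config, 1L))
  n <- config@nGroups
  sp <- config@speciesNames
  pre <- .speciesPrefix(sp)
  dup <- runif(n) < config@maizeDuplicateFraction
  out <- data.frame(group_id = sprintf("OG%05d", seq_len(n)))
  for (i in seq_along(sp)) {
    ids <- sprintf("%s_g%05d", pre[i], seq_len(n))
    if (i == length(sp))
      ids <- ifelse(dup, paste0(ids, "a,", ids, "b"), ids)
    out[[sp[i]]] <- ids
  }
  out
}

#' Long (one row per gene) view of an ortholog table
#'
#' @param orthos data.frame from \code{\link{simulateOrthogroups}} or
#'   \code{\link{readOrthogroups}}.
#' @return data.frame(group_id, species, gene_id)
#' @export
orthologLong <- function(orthos) {
  sp <- setdiff(names(orthos), "group_id")
  do.call(rbind, lapply(sp, function(s) {
    ids <- strsplit(orthos[[s]], ",", fixed = TRUE)
    data.frame(group_id = rep(orthos$group_id, lengths(ids)),
               species = s, gene_id = unlist(ids))
  }))
}

#' Sorghum-foxtail style one-to-one pairs from an ortholog table
#'
#' Pairs genes of the first two species (each single-copy by construction),
#' the pair set used for co-clustering statistics.
#'
#' @inheritParams orthologLong
#' @param species1,species2 the two species to pair (defaults: first two
#'   columns after group_id).
#' @return data.frame(group_id, gene1, gene2)
#' @export
orthologPairs <- function(orthos, species1 = NULL, species2 = NULL) {
  sp <- setdiff(names(orthos), "group_id")
  if (is.null(species1)) species1 <- sp[1]
  if (is.null(species2)) species2 <- sp[2]
  data.frame(group_id = orthos$group_id,
             gene1 = orthos[[species1]], gene2 = orthos[[species2]])
}

#' Simulate per-species expression matrices with known ground truth
#'
#' Rhythmic genes follow
#' \code{(baseline + amplitude/2 * cos(2*pi*(t - lag)/period)) * exp(N(0,
#' noiseSigma)) + dayOffset}, where \code{lag = phaseCT * period / 24} and
#' \code{dayOffset ~ N(0, dayEffectSigma)} is shared by the 8 samples of a
#' day; arrhythmic genes are baseline times noise. Values are clipped at 0.
#' Orthologs in a group share the group phase up to \code{phaseJitterH};
#' a second homeolog draws an independent amplitude attenuation (uniform on
#' [0, 1], so silent paralogs occur).
#'
#' @param orthos ortholog table from \code{\link{simulateOrthogroups}}.
#' @param config a \linkS4class{DielSimConfig}.
#' @return list with \code{matrices} (named list of gene x 24 matrices) and
#'   \code{truth} (data.frame: gene_id, species, group_id, is_rhythmic,
#'   phase_ct, amplitude, baseline, period).
#' @export
simulateExpression <- function(orthos, config) {
  stopifnot(is(config, "DielSimConfig"))
  validObject(config)
  set.seed(.stageSeed(config, 2L))
  long <- orthologLong(orthos)
  n <- config@nGroups
  grpRhythmic <- runif(n) < config@rhythmicFraction
  grpPhase <- config@phaseSampler(n) %% 24
  grpAmp <- runif(n, config@amplitudeRange[1], config@amplitudeRange[2])
  names(grpRhythmic) <- names(grpPhase) <- names(grpAmp) <- orthos$group_id

  t <- sampleTimes()
  day <- (t %/% 24) + 1L
  lastSp <- config@speciesNames[length(config@speciesNames)]

  truth <- data.frame(
    gene_id = long$gene_id, species = long$species, group_id = long$group_id,
    is_rhythmic = grpRhythmic[long$group_id],
    phase_ct = grpPhase[long$group_id],
    amplitude = grpAmp[long$group_id],
    baseline = runif(nrow(long), config@baselineRange[1],
                     config@baselineRange[2]),
    period = config@periodH)
  rownames(truth) <- NULL
  if (config@phaseJitterH > 0)
    truth$phase_ct <- (truth$phase_ct +
                       rnorm(nrow(truth), 0, config@phaseJitterH)) %% 24
  # second homeologs get an independent amplitude attenuation
  secondCopy <- truth$species == lastSp & grepl("b$", truth$gene_id)
  truth$amplitude[secondCopy] <- truth$amplitude[secondCopy] *
    runif(sum(secondCopy))
  truth$amplitude[!truth$is_rhythmic] <- 0

  per <- config@periodH
  matrices <- lapply(split(seq_len(nrow(truth)), truth$species), function(ix) {
    m <- matrix(0, length(ix), length(t),
                dimnames = list(truth$gene_id[ix],
                                sprintf("t%03d", t)))
    for (j in seq_along(ix)) {
      g <- ix[j]
      lag <- truth$phase_ct[g] * per / 24
      mu <- if (truth$is_rhythmic[g])
        truth$baseline[g] + truth$amplitude[g] / 2 *
          cos(2 * pi * (t - lag) / per)
      else rep(truth$baseline[g], length(t))
      y <- mu * exp(rnorm(length(t), 0, config@noiseSigma))
      if (truth$is_rhythmic[g] && config@dayEffectSigma > 0)
        y <- y + rnorm(max(day), 0, config@dayEffectSigma)[day]
      m[j, ] <- pmax(y, 0)
    }
    m
  })
  matrices <- matrices[intersect(config@speciesNames, names(matrices))]
  list(matrices = matrices, truth = truth)
}

.randomSequences <- function(n, len, probs) {
  chars <- sample(c("A", "C", "G", "T"), n * len, replace = TRUE, prob = probs)
  dim(chars) <- c(len, n)
  apply(chars, 2, paste, collapse = "")
}

#' Simulate promoter sequences with planted cis-elements
#'
#' Draws one i.i.d. background sequence per gene from the species' base
#' composition, then for each planted motif inserts one copy (overwriting
#' the underlying bases, so length is unchanged) at a uniform position with
#' probability \code{pTarget} for rhythmic genes whose true phase falls in
#' the motif's CT interval and \code{pBackground} otherwise. Chance
#' background occurrences are left in place.
#'
#' @param orthos ortholog table.
#' @param config a \linkS4class{DielSimConfig}.
#' @param truth truth data.frame from \code{\link{simulateExpression}}.
#' @return list with \code{promoters} (named list of
#'   \code{\link[Biostrings]{DNAStringSet}}) and \code{positions}
#'   (data.frame: species, gene_id, motif, start).
#' @export
simulatePromoters <- function(orthos, config, truth) {
  stopifnot(is(config, "DielSimConfig"))
  validObject(config)
  for (pm in config@plantedMotifs)
    if (grepl("[^ACGT]", pm$motif))
      stop("planted motif contains characters outside ACGT: ", pm$motif)
  set.seed(.stageSeed(config, 3L))
  L <- config@promoterLength
  pos <- list()
  promoters <- list()
  for (s in config@speciesNames) {
    ts <- truth[truth$species == s, ]
    seqs <- .randomSequences(nrow(ts), L, config@backgroundComposition[s, ])
    for (pm in config@plantedMotifs) {
      w <- nchar(pm$motif)
      lo <- pm$phaseInterval[1]; hi <- pm$phaseInterval[2]
      inPhase <- ts$is_rhythmic &
        (if (lo <= hi) ts$phase_ct >= lo & ts$phase_ct <= hi
         else ts$phase_ct >= lo | ts$phase_ct <= hi)
      p <- ifelse(inPhase, pm$pTarget, pm$pBackground)
      insert <- runif(nrow(ts)) < p
      starts <- sample.int(L - w + 1L, nrow(ts), replace = TRUE)
      for (i in which(insert))
        substr(seqs[i], starts[i], starts[i] + w - 1L) <- pm$motif
      if (any(insert))
        pos[[length(pos) + 1L]] <- data.frame(
          species = s, gene_id = ts$gene_id[insert], motif = pm$motif,
          start = starts[insert])
    }
    names(seqs) <- ts$gene_id
    promoters[[s]] <- Biostrings::DNAStringSet(seqs)
  }
  positions <- if (length(pos)) do.call(rbind, pos) else
    data.frame(species = character(), gene_id = character(),
               motif = character(), start = integer())
  list(promoters = promoters, positions = positions)
}

#' Run the full synthetic-data generator
#'
#' @param config a \linkS4class{DielSimConfig}.
#' @return list(orthogroups, matrices, truth, promoters, motifPositions,
#'   config)
#' @examples
#' sim <- simulateDielData(DielSimConfig(nGroups = 20, seed = 3))
#' names(sim$matrices)
#' @export
simulateDielData <- function(config = DielSimConfig()) {
  orthos <- simulateOrthogroups(config)
  expr <- simulateExpression(orthos, config)
  prom <- simulatePromoters(orthos, config, expr$truth)
  list(orthogroups = orthos, matrices = expr$matrices, truth = expr$truth,
       promoters = prom$promoters, motifPositions = prom$positions,
       config = config)
}

#' Write a simulated data set to disk
#'
#' Writes \code{expression_<species>.tsv} (gene_id + columns t000..t069),
#' \code{orthogroups.tsv}, \code{promoters_<species>.fasta} and
#' \code{truth.tsv} into \code{dir}.
#'
#' @param sim result of \code{\link{simulateDielData}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeDielData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (s in names(sim$matrices)) {
    f <- file.path(dir, sprintf("expression_%s.tsv", s))
    writeExpressionMatrix(sim$matrices[[s]], f)
    files <- c(files, f)
  }
  f <- file.path(dir, "orthogroups.tsv")
  write.table(sim$orthogroups, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, f)
  for (s in names(sim$promoters)) {
    f <- file.path(dir, sprintf("promoters_%s.fasta", s))
    Biostrings::writeXStringSet(sim$promoters[[s]], f)
    files <- c(files, f)
  }
  f <- file.path(dir, "truth.tsv")
  write.table(sim$truth, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
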