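## End-to-end orchestration: simulate -> rhythms -> filter + cluster ->
## motifs -> report, with one master seed, on-disk intermediates, and a
## JSON run manifest. Stages are resumable: existing outputs are reused
## unless force = TRUE.

#' Assemble a pipeline configuration
#'
#' All stage parameters with their standard defaults: gene-level Bonferroni
#' 0.01 for the rhythmic call, window correlation > 0.7 and dispersion
#' < 0.9 for the reproducibility filter, K-means over 2-24 centers with
#' 2000 iterations and a 100-permutation syntenic-pair null, motif widths
#' 6-8 with a 100-permutation FDR at 0.05.
#'
#' @param simConfig a \linkS4class{DielSimConfig} (used by the simulate
#'   stage); its seed is overridden by \code{seed}.
#' @param alphaRhythm gene-level Bonferroni threshold.
#' @param periods,lagStep reference-grid parameters (hours).
#' @param rMin,msdMax reproducibility-filter thresholds.
#' @param kRange candidate K-means centers.
#' @param kmeansIterations K-means iteration cap.
#' @param nPermCluster permutations for the co-cluster null.
#' @param fixedK optional fixed cluster number overriding the plateau rule
#'   (e.g. 16).
#' @param kValues motif widths.
#' @param nPermMotif permutations for the motif FDR.
#' @param motifAlpha motif FDR level.
#' @param shuffleMode motif permutation mode.
#' @param stages stages to run.
#' @param seed master seed; each stage derives its own substream.
#' @return a named list (class \code{dielPipelineConfig}).
#' @export
pipelineConfig <- function(simConfig = DielSimConfig(),
                           alphaRhythm = 0.01,
                           periods = c(21, 24, 27), lagStep = 1.5,
                           rMin = 0.7, msdMax = 0.9,
                           kRange = 2:24, kmeansIterations = 2000L,
                           nPermCluster = 100L, fixedK = NULL,
                           kValues = c(6, 7, 8), nPermMotif = 100L,
                           motifAlpha = 0.05,
                           shuffleMode = c("across_species",
                                           "within_species"),
                           stages = c("simulate", "rhythms", "cluster",
                                      "motifs", "report"),
                           seed = 1L) {
  stopifnot(alphaRhythm > 0, alphaRhythm <= 1, motifAlpha > 0,
            motifAlpha <= 1, rMin >= -1, rMin <= 1, msdMax >= 0)
  cfg <- list(simConfig = simConfig, alphaRhythm = alphaRhythm,
              periods = periods, lagStep = lagStep, rMin = rMin,
              msdMax = msdMax, kRange = kRange,
              kmeansIterations = as.integer(kmeansIterations),
              nPermCluster = as.integer(nPermCluster), fixedK = fixedK,
              kValues = kValues, nPermMotif = as.integer(nPermMotif),
              motifAlpha = motifAlpha,
              shuffleMode = match.arg(shuffleMode),
              stages = stages, seed = as.integer(seed))
  class(cfg) <- "dielPipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are \code{\link{pipelineConfig}} arguments; the
#' \code{simConfig} key is a map of \code{\link{DielSimConfig}} arguments.
#'
#' @param file YAML path.
#' @return a pipeline configuration list.
#' @export
readPipelineConfig <- function(file) {
  y <- yaml::read_yaml(file)
  if (!is.null(y$simConfig)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(y$simConfig, tmp)
    y$simConfig <- readSimConfig(tmp)
  }
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown pipeline config keys: ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, y)
}

.log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

.stageDone <- function(files) length(files) > 0 && all(file.exists(files))

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order, writing TSV/FASTA intermediates
#' into \code{outDir}. Completed stages (all output files present) are
#' skipped unless \code{force = TRUE}, so a finished run is idempotent.
#' Returns the run manifest (also written as \code{manifest.json}).
#'
#' @param config a \code{\link{pipelineConfig}} result.
#' @param outDir output directory.
#' @param force recompute even when outputs exist.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, force = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- list(package_version =
                     as.character(utils::packageVersion("dielSync")),
                   seed = seed, started = format(Sys.time()),
                   stages = list())
  speciesNames <- config$simConfig@speciesNames
  exprFiles <- file.path(outDir, sprintf("expression_%s.tsv", speciesNames))
  promFiles <- file.path(outDir, sprintf("promoters_%s.fasta", speciesNames))
  orthoFile <- file.path(outDir, "orthogroups.tsv")

  runStage <- function(name, outputs, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    t0 <- Sys.time()
    if (.stageDone(outputs) && !force) {
      .log(name, "outputs present, skipped")
      status <- "skipped"
    } else {
      fun()
      status <- "completed"
      .log(name, "done in %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
    }
    manifest$stages[[name]] <<- list(
      status = status, outputs = basename(outputs),
      md5 = unname(tools::md5sum(outputs[file.exists(outputs)])),
      elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  }

  runStage("simulate", c(exprFiles, promFiles, orthoFile,
                         file.path(outDir, "truth.tsv")), function() {
    sc <- config$simConfig
    sc@seed <- seed
    sim <- simulateDielData(sc)
    writeDielData(sim, outDir)
    .log("simulate", "%d groups, %d genes", sc@nGroups, nrow(sim$truth))
  })

  rhythmFiles <- file.path(outDir, sprintf("rhythms_%s.tsv", speciesNames))
  runStage("rhythms", rhythmFiles, function() {
    for (i in seq_along(speciesNames)) {
      m <- readExpressionMatrix(exprFiles[i])
      rh <- detectRhythms(m, periods = config$periods,
                          lagStep = config$lagStep,
                          alpha = config$alphaRhythm)
      writeRhythms(rh, rhythmFiles[i])
      .log("rhythms", "%s: %d/%d rhythmic", speciesNames[i],
           sum(rh$is_rhythmic), nrow(rh))
    }
  })

  clusterFiles <- file.path(outDir, c("clusters.tsv", "cluster_summary.tsv",
                                      "k_selection.tsv"))
  runStage("cluster", clusterFiles, function() {
    matrices <- setNames(lapply(exprFiles, readExpressionMatrix),
                         speciesNames)
    orthos <- readOrthogroups(orthoFile)
    filt <- filterOrthogroups(matrices, orthos, rMin = config$rMin,
                              msdMax = config$msdMax)
    .log("cluster", "filter retained %d genes in %d groups",
         nrow(filt$retained), length(filt$groups))
    X <- do.call(rbind, lapply(speciesNames, function(s) {
      g <- filt$retained$gene_id[filt$retained$species == s]
      scaleUnitInterval(matrices[[s]][g, , drop = FALSE])
    }))
    species <- setNames(filt$retained$species, filt$retained$gene_id)
    pairs <- orthologPairs(orthos)
    kRange <- config$kRange[config$kRange < nrow(X)]
    if (!length(kRange))
      stop("too few filtered genes (", nrow(X), ") for any candidate k")
    sel <- selectK(X, pairs, species = species, kRange = kRange,
                   iterations = config$kmeansIterations,
                   nPerm = config$nPermCluster, seed = seed + 101L,
                   fixedK = config$fixedK)
    .log("cluster", "chose k = %d", sel$k)
    model <- sel$model
    rh <- do.call(rbind, lapply(rhythmFiles[file.exists(rhythmFiles)],
                                read.delim))
    medPhase <- clusterMedianPhase(model, rh)
    clDf <- data.frame(assignmentTable(model),
                       round(X[names(clusterAssignment(model)), ], 4),
                       check.names = FALSE)
    write.table(clDf, clusterFiles[1], sep = "\t", quote = FALSE,
                row.names = FALSE)
    counts <- table(factor(clusterAssignment(model),
                           levels = seq_len(model@k)),
                    clusterSpecies(model))
    summ <- data.frame(cluster = seq_len(model@k),
                       size = as.integer(tabulate(clusterAssignment(model),
                                                  model@k)),
                       median_ct_phase = round(medPhase, 2),
                       as.data.frame.matrix(counts))
    write.table(summ, clusterFiles[2], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sel$table, clusterFiles[3], sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  motifFiles <- file.path(outDir, sprintf("motifs_k%d.tsv", config$kValues))
  runStage("motifs", motifFiles, function() {
    clDf <- read.delim(clusterFiles[1])
    assignment <- clDf[c("gene_id", "species", "cluster")]
    promoters <- setNames(lapply(promFiles, readPromoters), speciesNames)
    promoters <- lapply(setNames(speciesNames, speciesNames), function(s)
      promoters[[s]][intersect(names(promoters[[s]]),
                               assignment$gene_id[assignment$species == s])])
    for (j in seq_along(config$kValues)) {
      k <- config$kValues[j]
      res <- runEnrichment(promoters, assignment, kValues = k)
      res <- permutationFdr(res, promoters, assignment,
                            nPerm = config$nPermMotif,
                            mode = config$shuffleMode,
                            alpha = config$motifAlpha, seed = seed + 202L + k)
      res <- annotateKnownElements(res)
      keep <- res$significant | res$cmh_p < 0.01
      writeMotifResults(res[keep, ], motifFiles[j])
      .log("motifs", "k=%d: %d significant motif x cluster pairs", k,
           sum(res$significant))
    }
  })

  reportFile <- file.path(outDir, "report.txt")
  runStage("report", reportFile, function() {
    makeReport(outDir, speciesNames = speciesNames,
               kValues = config$kValues)
  })

  manifest$finished <- format(Sys.time())
  manifest$config <- list(
    alphaRhythm = config$alphaRhythm, periods = config$periods,
    rMin = config$rMin, msdMax = config$msdMax,
    kRange = range(config$kRange),
    kmeansIterations = config$kmeansIterations,
    nPermCluster = config$nPermCluster, fixedK = config$fixedK,
    kValues = config$kValues, nPermMotif = config$nPermMotif,
    motifAlpha = config$motifAlpha, shuffleMode = config$shuffleMode,
    nGroups = config$simConfig@nGroups)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Summarize pipeline outputs
#'
#' Collates the per-species rhythmic fractions, phase and amplitude
#' distributions (binned), cluster sizes, median phases and species
#' composition, and the annotated significant motifs into a plain-text
#' report plus a returned list. Missing stage outputs are reported and the
#' partial report is still produced.
#'
#' @param outDir pipeline output directory.
#' @param speciesNames species labels (default: inferred from
#'   \code{rhythms_*.tsv} files).
#' @param kValues motif widths to collect.
#' @return invisibly, the summary list.
#' @export
makeReport <- function(outDir, speciesNames = NULL, kValues = c(6, 7, 8)) {
  if (is.null(speciesNames)) {
    speciesNames <- sub("^rhythms_(.*)\\.tsv$", "\\1",
                        basename(Sys.glob(file.path(outDir,
                                                    "rhythms_*.tsv"))))
  }
  out <- list(missing = character())
  lines <- c("dielSync pipeline report", "=======================")
  for (s in speciesNames) {
    f <- file.path(outDir, sprintf("rhythms_%s.tsv", s))
    if (!file.exists(f)) {
      out$missing <- c(out$missing, f)
      next
    }
    rh <- read.delim(f)
    frac <- mean(rh$is_rhythmic)
    out$rhythmicFraction[[s]] <- frac
    rr <- rh[rh$is_rhythmic, ]
    out$phaseHist[[s]] <- table(cut(rr$ct_phase, seq(0, 24, 3),
                                    include.lowest = TRUE, right = FALSE))
    out$amplitudeSummary[[s]] <- summary(rr$amplitude)
    lines <- c(lines, sprintf("%s: %.1f%% rhythmic (%d/%d); median CT phase %.1f h; median amplitude %.2f",
                              s, 100 * frac, sum(rh$is_rhythmic), nrow(rh),
                              median(rr$ct_phase), median(rr$amplitude)))
  }
  f <- file.path(outDir, "cluster_summary.tsv")
  if (file.exists(f)) {
    cs <- read.delim(f)
    out$clusterSummary <- cs
    lines <- c(lines, "",
               sprintf("%d clusters; sizes %s; median phases %s", nrow(cs),
                       paste(cs$size, collapse = ","),
                       paste(cs$median_ct_phase, collapse = ",")))
  } else out$missing <- c(out$missing, f)
  for (k in kValues) {
    f <- file.path(outDir, sprintf("motifs_k%d.tsv", k))
    if (!file.exists(f)) {
      out$missing <- c(out$missing, f)
      next
    }
    mo <- read.delim(f)
    sig <- mo[which(mo$significant), ]
    out$motifs[[as.character(k)]] <- sig
    lines <- c(lines, "",
               sprintf("k=%d: %d significant motif x cluster pairs (%d distinct motifs)",
                       k, nrow(sig), length(unique(sig$motif))))
    known <- sig[nzchar(sig$known_elements), ]
    if (nrow(known))
      lines <- c(lines, sprintf("  %s in cluster %s -> %s", known$motif,
                                known$cluster, known$known_elements))
  }
  if (length(out$missing))
    lines <- c(lines, "", paste("missing stage outputs:",
                                paste(basename(out$missing),
                                      collapse = ", ")))
  writeLines(lines, file.path(outDir, "report.txt"))
  invisible(out)
}
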