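## Exhaustive k-mer enrichment in 1-kb promoters of co-expression clusters:
## per-species one-sided Fisher tests, Cochran-Mantel-Haenszel combination
## across species, and a permutation FDR over shuffled cluster assignments.

#' Enumerate all motifs of width k
#'
#' All 4^k strings over ACGT in lexicographic order (A < C < G < T).
#'
#' @param k motif width (>= 1).
#' @return character vector of length 4^k.
#' @examples
#' enumerateMotifs(1)
#' @export
enumerateMotifs <- function(k) {
  k <- as.integer(k)
  if (k <= 0L) stop("k must be positive")
  sort(Biostrings::mkAllStrings(c("A", "C", "G", "T"), k))
}

#' Index promoter sequences for all k-mers
#'
#' Slides a width-k window over the forward strand of each promoter and
#' counts occurrences of every 4^k motif (overlaps counted; windows
#' containing N never match). Characters outside A/C/G/T/N are rejected.
#'
#' @param promoters a \code{DNAStringSet} (or named character vector) of
#'   promoter sequences.
#' @param k motif width.
#' @param species species label stored with the index.
#' @return a \linkS4class{MotifIndex}.
#' @export
indexPromoters <- function(promoters, k, species = NA_character_) {
  if (!is(promoters, "DNAStringSet"))
    promoters <- Biostrings::DNAStringSet(promoters)
  af <- Biostrings::alphabetFrequency(promoters)
  extra <- colSums(af[, !colnames(af) %in% c("A", "C", "G", "T", "N"),
                      drop = FALSE])
  if (any(extra > 0))
    stop("promoter sequences contain characters outside ACGTN: ",
         paste(names(extra)[extra > 0], collapse = ""))
  if (any(Biostrings::width(promoters) < k))
    warning("promoters shorter than k contribute empty presence rows")
  counts <- Biostrings::oligonucleotideFrequency(promoters, width = k)
  rownames(counts) <- names(promoters)
  new("MotifIndex", k = as.integer(k), species = as.character(species),
      counts = counts)
}

#' Gene-to-cluster assignment table of a ClusterModel
#'
#' @param model a \linkS4class{ClusterModel}.
#' @return data.frame(gene_id, species, cluster)
#' @export
assignmentTable <- function(model) {
  data.frame(gene_id = names(clusterAssignment(model)),
             species = clusterSpecies(model),
             cluster = as.integer(clusterAssignment(model)),
             row.names = NULL)
}

#' One-sided Fisher exact test for enrichment
#'
#' Upper-tail hypergeometric probability P(X >= a) for a 2x2 table
#' (a, b // c, d) with fixed margins: the exact one-sided p-value that the
#' in-cluster motif count a is larger than expected. Vectorized over
#' tables; a table with a zero margin yields p = 1.
#'
#' @param a,b,c,d cell counts: in-cluster with/without motif, out-of-cluster
#'   with/without. Alternatively \code{a} may be a 2x2 matrix.
#' @return one-sided p-value(s) in (0, 1].
#' @examples
#' fisherEnrichment(5, 0, 0, 5)  # 1 / choose(10, 5)
#' @export
fisherEnrichment <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a) && is.null(b)) {
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be nonnegative")
  # white = motif-bearing genes, drawn = cluster genes
  p <- phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

# vectorized CMH over rows: aS, tS are matrices (motifs x strata) of
# in-cluster presence counts and species presence totals; sizeS, nS are
# per-stratum cluster sizes and species totals
.cmhStat <- function(aS, tS, sizeS, nS, correct = TRUE) {
  keep <- nS >= 2 & sizeS >= 1 & (nS - sizeS) >= 1
  num <- 0; v <- 0
  for (s in which(keep)) {
    num <- num + aS[, s] - sizeS[s] * tS[, s] / nS[s]
    v <- v + sizeS[s] * (nS[s] - sizeS[s]) * tS[, s] * (nS[s] - tS[, s]) /
      (nS[s]^2 * (nS[s] - 1))
  }
  if (!any(keep)) return(list(stat = rep(0, nrow(aS)), p = rep(1, nrow(aS)),
                              degenerate = TRUE))
  # literal continuity correction: (|sum(a - E)| - 1/2)^2 / sum(V).
  # Note stats::mantelhaen.test instead skips the correction when
  # |sum(a - E)| < 1/2; the two agree everywhere else.
  adj <- if (correct) abs(num) - 0.5 else abs(num)
  stat <- ifelse(v > 0, adj^2 / v, 0)
  p <- ifelse(v > 0, pchisq(stat, df = 1, lower.tail = FALSE), 1)
  list(stat = stat, p = p, degenerate = FALSE)
}

#' Cochran-Mantel-Haenszel test over per-species 2x2 tables
#'
#' Combines the species strata of a motif x cluster contingency into one
#' chi-square(1) test of a common association:
#' statistic = (|sum(a_s - E_s)| - 1/2)^2 / sum(V_s) with
#' E_s = (a_s + b_s)(a_s + c_s)/n_s and
#' V_s = (a_s + b_s)(c_s + d_s)(a_s + c_s)(b_s + d_s) / (n_s^2 (n_s - 1)).
#' Strata with n_s < 2 (or an empty margin) are skipped; if all strata are
#' degenerate the result is statistic 0, p 1, flagged.
#'
#' @param strata a 2x2xK array, or a data.frame with columns a, b, c, d
#'   (one row per stratum).
#' @param correct apply the 1/2 continuity correction (default TRUE,
#'   classical CMH).
#' @return list(statistic, p, degenerate)
#' @export
cmhTest <- function(strata, correct = TRUE) {
  if (is.array(strata) && length(dim(strata)) == 3L) {
    strata <- data.frame(a = strata[1, 1, ], b = strata[1, 2, ],
                         c = strata[2, 1, ], d = strata[2, 2, ])
  }
  stopifnot(all(c("a", "b", "c", "d") %in% names(strata)))
  if (any(unlist(strata[c("a", "b", "c", "d")]) < 0))
    stop("cell counts must be nonnegative")
  aS <- matrix(strata$a, 1)
  tS <- matrix(strata$a + strata$c, 1)
  sizeS <- strata$a + strata$b
  nS <- strata$a + strata$b + strata$c + strata$d
  res <- .cmhStat(aS, tS, sizeS, nS, correct = correct)
  list(statistic = as.numeric(res$stat), p = as.numeric(res$p),
       degenerate = isTRUE(res$degenerate))
}

#' Per-species contingency strata for one motif and cluster
#'
#' a = in-cluster genes carrying the motif, b = in-cluster genes without
#' it, c/d the same for the background (all clustered genes of that species
#' in other clusters).
#'
#' @param indices named (by species) list of \linkS4class{MotifIndex}
#'   objects of a common k.
#' @param assignment data.frame(gene_id, species, cluster) (see
#'   \code{\link{assignmentTable}}).
#' @param motif motif string of width k.
#' @param cluster cluster index.
#' @return data.frame(species, a, b, c, d); species where the cluster is
#'   empty are flagged by a + b = 0.
#' @export
buildStrata <- function(indices, assignment, motif, cluster) {
  do.call(rbind, lapply(names(indices), function(s) {
    idx <- indices[[s]]
    genes <- assignment$gene_id[assignment$species == s]
    stopifnot(all(genes %in% rownames(idx@counts)))
    pres <- idx@counts[genes, motif] >= 1L
    inCl <- assignment$cluster[assignment$species == s] == cluster
    data.frame(species = s,
               a = sum(pres & inCl), b = sum(!pres & inCl),
               c = sum(pres & !inCl), d = sum(!pres & !inCl))
  }))
}

# pooled setup: presence over all clustered genes of all species, with the
# fixed slot structure (species, cluster) the permutation modes shuffle
# genes against
.enrichSetup <- function(promoters = NULL, indices = NULL, assignment, k) {
  speciesLevels <- unique(assignment$species)
  if (is.null(indices)) {
    stopifnot(!is.null(promoters))
    indices <- lapply(setNames(speciesLevels, speciesLevels), function(s)
      indexPromoters(promoters[[s]], k, species = s))
  }
  ord <- order(match(assignment$species, speciesLevels), assignment$cluster)
  assignment <- assignment[ord, ]
  P <- do.call(rbind, lapply(speciesLevels, function(s) {
    genes <- assignment$gene_id[assignment$species == s]
    miss <- setdiff(genes, rownames(indices[[s]]@counts))
    if (length(miss))
      stop("clustered genes missing from the ", s, " promoter index: ",
           paste(head(miss, 3), collapse = ", "))
    (indices[[s]]@counts[genes, , drop = FALSE] >= 1L) * 1
  }))
  clusterLevels <- sort(unique(assignment$cluster))
  slotCombo <- factor(paste(assignment$species, assignment$cluster,
                            sep = "\r"),
                      levels = as.vector(t(outer(speciesLevels,
                                                 clusterLevels, paste,
                                                 sep = "\r"))))
  I <- stats::model.matrix(~ 0 + slotCombo)
  colnames(I) <- levels(slotCombo)
  list(P = P, I = I, assignment = assignment,
       species = assignment$species, cluster = assignment$cluster,
       speciesLevels = speciesLevels, clusterLevels = clusterLevels,
       nS = as.vector(table(factor(assignment$species,
                                   levels = speciesLevels))),
       motifs = colnames(P), k = k)
}

# counts for one (possibly permuted) gene->slot mapping:
# A[motif, (species, cluster)] with slots fixed and genes permuted
.slotCounts <- function(setup, perm = NULL) {
  I <- setup$I
  if (!is.null(perm)) I <- I[order(perm), , drop = FALSE]
  crossprod(setup$P, I)
}

# CMH statistics for every motif x cluster from slot counts
.cmhGrid <- function(A, setup, correct = TRUE) {
  S <- length(setup$speciesLevels)
  C <- length(setup$clusterLevels)
  M <- nrow(A)
  colOf <- function(s, c) (s - 1L) * C + c
  Tsp <- vapply(seq_len(S), function(s)
    rowSums(A[, colOf(s, seq_len(C)), drop = FALSE]), numeric(M))
  sizes <- colSums(setup$I)
  stat <- p <- matrix(NA_real_, M, C,
                      dimnames = list(setup$motifs, setup$clusterLevels))
  for (c in seq_len(C)) {
    aS <- A[, colOf(seq_len(S), c), drop = FALSE]
    sizeS <- sizes[colOf(seq_len(S), c)]
    res <- .cmhStat(aS, Tsp, sizeS, setup$nS, correct = correct)
    stat[, c] <- res$stat
    p[, c] <- res$p
  }
  list(stat = stat, p = p)
}

#' Exhaustive motif x cluster enrichment scan
#'
#' For every motif of each width in \code{kValues} and every cluster:
#' per-species one-sided Fisher p-values on the presence/absence 2x2 table
#' (background = clustered genes of the other clusters) and the
#' cross-species CMH statistic and p-value.
#'
#' @param promoters named (by species) list of promoter
#'   \code{DNAStringSet}s; ignored when \code{indices} is given.
#' @param assignment data.frame(gene_id, species, cluster).
#' @param kValues motif widths to scan (default 6, 7, 8).
#' @param indices optional named (by k) list of per-species
#'   \linkS4class{MotifIndex} lists.
#' @param correct CMH continuity correction.
#' @return data.frame with columns motif, k, cluster,
#'   \code{a_<species>} and \code{fisher_p_<species>} per species,
#'   cmh_stat, cmh_p.
#' @export
runEnrichment <- function(promoters = NULL, assignment,
                          kValues = c(6, 7, 8), indices = NULL,
                          correct = TRUE) {
  out <- list()
  for (k in kValues) {
    setup <- .enrichSetup(promoters, indices[[as.character(k)]], assignment,
                          k)
    A <- .slotCounts(setup)
    cmh <- .cmhGrid(A, setup, correct = correct)
    S <- length(setup$speciesLevels)
    C <- length(setup$clusterLevels)
    M <- length(setup$motifs)
    sizes <- colSums(setup$I)
    colOf <- function(s, c) (s - 1L) * C + c
    df <- data.frame(
      motif = rep(setup$motifs, C),
      k = as.integer(k),
      cluster = rep(setup$clusterLevels, each = M))
    for (s in seq_len(S)) {
      sp <- setup$speciesLevels[s]
      Ts <- rowSums(A[, colOf(s, seq_len(C)), drop = FALSE])
      aMat <- A[, colOf(s, seq_len(C)), drop = FALSE]
      szs <- sizes[colOf(s, seq_len(C))]
      aVec <- as.vector(aMat)
      szVec <- rep(szs, each = M)
      tVec <- rep(Ts, C)
      nS <- setup$nS[s]
      df[[paste0("a_", sp)]] <- aVec
      df[[paste0("fisher_p_", sp)]] <-
        fisherEnrichment(aVec, szVec - aVec, tVec - aVec,
                         nS - szVec - tVec + aVec)
    }
    df$cmh_stat <- as.vector(cmh$stat)
    df$cmh_p <- as.vector(cmh$p)
    out[[as.character(k)]] <- df
  }
  do.call(rbind, out)
}

#' Permutation FDR over shuffled cluster assignments
#'
#' Re-draws the gene-to-cluster assignment \code{nPerm} times and
#' recomputes the CMH statistic grid. In mode \code{"within_species"}
#' cluster labels are shuffled independently within each species
#' (preserving cluster sizes); in mode \code{"across_species"} (default)
#' gene identities are shuffled across the pooled three-species set and
#' refilled into the fixed per-species cluster slots, so promoters cross
#' species boundaries and the null also absorbs background-composition
#' differences - the stricter control. For each (motif, cluster), with the
#' family being all motifs of that width in that cluster, the empirical FDR
#' at threshold t = observed statistic is the mean permutation count of
#' statistics >= t divided by the observed count >= t, capped at 1.
#'
#' @param results data.frame from \code{\link{runEnrichment}}.
#' @param promoters,indices as in \code{\link{runEnrichment}}.
#' @param assignment data.frame(gene_id, species, cluster).
#' @param nPerm number of permutations (default 100).
#' @param mode shuffle mode.
#' @param alpha FDR significance level (default 0.05).
#' @param seed integer seed.
#' @param correct CMH continuity correction (must match the observed run).
#' @return \code{results} with columns \code{fdr} and \code{significant}
#'   appended.
#' @export
permutationFdr <- function(results, promoters = NULL, assignment,
                           nPerm = 100L, mode = c("across_species",
                                                  "within_species"),
                           alpha = 0.05, seed = 1L, indices = NULL,
                           correct = TRUE) {
  mode <- match.arg(mode)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  results$fdr <- NA_real_
  set.seed(seed %% .Machine$integer.max)
  for (k in unique(results$k)) {
    setup <- .enrichSetup(promoters, indices[[as.character(k)]], assignment,
                          k)
    N <- nrow(setup$P)
    spF <- factor(setup$species, levels = setup$speciesLevels)
    sel <- results$k == k
    C <- length(setup$clusterLevels)
    M <- length(setup$motifs)
    obs <- matrix(NA_real_, M, C)
    for (ci in seq_len(C)) {
      rows <- sel & results$cluster == setup$clusterLevels[ci]
      obs[match(results$motif[rows], setup$motifs), ci] <-
        results$cmh_stat[rows]
    }
    permGE <- matrix(0, M, C)
    for (p in seq_len(nPerm)) {
      perm <- if (mode == "across_species") sample.int(N) else {
        pr <- seq_len(N)
        for (s in levels(spF)) {
          ix <- which(spF == s)
          pr[ix] <- ix[sample.int(length(ix))]
        }
        pr
      }
      A <- .slotCounts(setup, perm)
      st <- .cmhGrid(A, setup, correct = correct)$stat
      for (ci in seq_len(C)) {
        sorted <- sort(st[, ci])
        permGE[, ci] <- permGE[, ci] +
          (M - findInterval(obs[, ci], sorted, left.open = TRUE))
      }
    }
    for (ci in seq_len(C)) {
      o <- obs[, ci]
      sortedObs <- sort(o)
      obsGE <- M - findInterval(o, sortedObs, left.open = TRUE)
      fdr <- pmin(1, (permGE[, ci] / nPerm) / obsGE)
      rows <- which(sel & results$cluster == setup$clusterLevels[ci])
      results$fdr[rows] <- fdr[match(results$motif[rows], setup$motifs)]
    }
  }
  results$significant <- results$fdr < alpha
  results
}

#' Catalog of known diurnal cis-elements
#'
#' The literature-curated elements used to annotate enriched motifs: the
#' evening element core (AATATC) and full evening element (AAATATCT), the
#' CCA1-binding site (AAAAATCT), the morning element (CCACAC), the
#' telo-box (AAACCCT), the starch-synthesis box (AAGCCC), SORLIP1 (GCCAC)
#' and UP1ATMSD (GGCCCA).
#'
#' @return data.frame(name, sequence, description)
#' @export
knownElements <- function() {
  data.frame(
    name = c("EE_core", "EE_full", "CBS", "ME", "TBX", "SBX", "SORLIP1",
             "UP1ATMSD"),
    sequence = c("AATATC", "AAATATCT", "AAAAATCT", "CCACAC", "AAACCCT",
                 "AAGCCC", "GCCAC", "GGCCCA"),
    description = c("evening element core",
                    "full evening element (EE)",
                    "CCA1-binding site",
                    "morning element",
                    "telo-box",
                    "starch synthesis box",
                    "light-induction SORLIP1 motif",
                    "protein-synthesis UP1ATMSD motif"))
}

#' Match a motif against the known-element catalog
#'
#' Reports catalog elements that equal the motif, contain it, are contained
#' in it, or overlap it end-on by at least min(widths) - 1 identical bases.
#'
#' @param motif ACGT string.
#' @param catalog data.frame(name, sequence, ...) as from
#'   \code{\link{knownElements}}.
#' @return data.frame(name, sequence, type); zero rows when nothing
#'   matches.
#' @examples
#' matchKnownElements("AAATATCT")$name  # full EE exact + EE core contained
#' @export
matchKnownElements <- function(motif, catalog = knownElements()) {
  if (grepl("[^ACGT]", motif)) stop("motif must be over ACGT")
  hits <- lapply(seq_len(nrow(catalog)), function(i) {
    el <- catalog$sequence[i]
    type <- NULL
    if (motif == el) type <- "exact"
    else if (grepl(el, motif, fixed = TRUE)) type <- "motif_contains_element"
    else if (grepl(motif, el, fixed = TRUE)) type <- "element_contains_motif"
    else {
      # containment handles overlap length min(widths); the only remaining
      # admissible overlap is min(widths) - 1, at either end
      ov <- min(nchar(motif), nchar(el)) - 1L
      if (ov >= 1L &&
          (substr(motif, nchar(motif) - ov + 1L, nchar(motif)) ==
             substr(el, 1L, ov) ||
           substr(el, nchar(el) - ov + 1L, nchar(el)) ==
             substr(motif, 1L, ov)))
        type <- "overlap"
    }
    if (is.null(type)) NULL else
      data.frame(name = catalog$name[i], sequence = el, type = type)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits))
    return(data.frame(name = character(), sequence = character(),
                      type = character()))
  do.call(rbind, hits)
}

#' Annotate enrichment results with known cis-elements
#'
#' @param results data.frame with a \code{motif} column.
#' @param catalog see \code{\link{matchKnownElements}}.
#' @return \code{results} with a \code{known_elements} column
#'   (comma-separated element names, empty when none).
#' @export
annotateKnownElements <- function(results, catalog = knownElements()) {
  uniq <- unique(results$motif)
  ann <- vapply(uniq, function(m)
    paste(matchKnownElements(m, catalog)$name, collapse = ","), character(1))
  results$known_elements <- ann[results$motif]
  results
}

#' @rdname io
#' @param results motif enrichment results.
#' @export
writeMotifResults <- function(results, file) {
  write.table(results, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
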