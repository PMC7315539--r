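## Reproducibility filtering on day windows, K-means with Pearson
## correlation distance on 0-1 scaled profiles, and the syntenic-pair
## permutation criterion for choosing k.

#' Scale values to the unit interval
#'
#' (x - min) / (max - min) per series. Constant series map to all 0.5 and
#' are flagged via the \code{"constant"} attribute. For a matrix, rows are
#' scaled independently.
#'
#' @param x numeric vector or gene x time matrix.
#' @return scaled vector/matrix with attribute \code{constant}.
#' @examples
#' scaleUnitInterval(c(0, 5, 10))
#' @export
scaleUnitInterval <- function(x) {
  if (is.matrix(x)) {
    lo <- apply(x, 1, min); hi <- apply(x, 1, max)
    rng <- hi - lo
    const <- rng == 0
    out <- (x - lo) / ifelse(const, 1, rng)
    out[const, ] <- 0.5
    attr(out, "constant") <- const
    return(out)
  }
  rng <- diff(range(x))
  if (rng == 0) {
    out <- rep(0.5, length(x))
  } else out <- (x - min(x)) / rng
  attr(out, "constant") <- rng == 0
  out
}

.windowIdx <- list(1:8, 9:16, 17:24)
.windowPairs <- rbind(c(1, 2), c(1, 3), c(2, 3))

#' Day-to-day reproducibility statistics
#'
#' For each gene, the Pearson correlations between the three pairwise day
#' windows (time points 1-8, 9-16, 17-24) on raw values, and the dispersion
#' (mean over the three pairs of the mean squared point-wise difference)
#' computed on the 0-1 scaled profile.
#'
#' @param x 24-value series or gene x 24 matrix.
#' @return data.frame(gene_id, r12, r13, r23, msd); a pair involving a
#'   constant window has r = NA.
#' @export
windowStats <- function(x) {
  X <- if (is.matrix(x)) x else matrix(x, 1, dimnames = list("series", NULL))
  stopifnot(ncol(X) == 24L)
  S <- scaleUnitInterval(X)
  rcols <- matrix(NA_real_, nrow(X), 3)
  msdP <- matrix(NA_real_, nrow(X), 3)
  for (p in 1:3) {
    w1 <- X[, .windowIdx[[.windowPairs[p, 1]]], drop = FALSE]
    w2 <- X[, .windowIdx[[.windowPairs[p, 2]]], drop = FALSE]
    sd1 <- apply(w1, 1, sd); sd2 <- apply(w2, 1, sd)
    ok <- sd1 > 0 & sd2 > 0
    r <- rep(NA_real_, nrow(X))
    if (any(ok))
      r[ok] <- vapply(which(ok), function(i) cor(w1[i, ], w2[i, ]),
                      numeric(1))
    rcols[, p] <- r
    s1 <- S[, .windowIdx[[.windowPairs[p, 1]]], drop = FALSE]
    s2 <- S[, .windowIdx[[.windowPairs[p, 2]]], drop = FALSE]
    msdP[, p] <- rowMeans((s1 - s2)^2)
  }
  data.frame(gene_id = rownames(X), r12 = rcols[, 1], r13 = rcols[, 2],
             r23 = rcols[, 3], msd = rowMeans(msdP), row.names = NULL)
}

#' Filter ortholog groups for expression reproducibility
#'
#' A gene passes when its aggregated day-window Pearson correlation exceeds
#' \code{rMin} (aggregation over the three pairs: minimum by default,
#' strictest reading; \code{"mean"} also available) and its window
#' dispersion is below \code{msdMax}; an undefined correlation (constant
#' window) fails. A group is retained only if every member gene in every
#' species passes; groups with members missing from their species matrix
#' are dropped with a warning.
#'
#' @param matrices named list of per-species gene x 24 matrices.
#' @param orthos ortholog table.
#' @param rMin correlation threshold (exceeded strictly).
#' @param msdMax dispersion threshold (strict upper bound).
#' @param aggregate \code{"min"} or \code{"mean"} over the three window
#'   pairs.
#' @return list with \code{retained} (data.frame group_id, species,
#'   gene_id of retained genes), \code{groups} (retained group ids) and
#'   \code{stats} (per-gene window statistics with pass flag).
#' @export
filterOrthogroups <- function(matrices, orthos, rMin = 0.7, msdMax = 0.9,
                              aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  long <- orthologLong(orthos)
  statsL <- list()
  for (s in names(matrices)) {
    genes <- long$gene_id[long$species == s]
    present <- genes[genes %in% rownames(matrices[[s]])]
    if (length(present)) {
      st <- windowStats(matrices[[s]][present, , drop = FALSE])
      st$species <- s
      statsL[[s]] <- st
    }
  }
  stats <- do.call(rbind, statsL)
  rownames(stats) <- NULL
  rAgg <- if (aggregate == "min")
    pmin(stats$r12, stats$r13, stats$r23)
  else (stats$r12 + stats$r13 + stats$r23) / 3
  stats$pass <- !is.na(rAgg) & rAgg > rMin & stats$msd < msdMax

  missing <- !(long$gene_id %in% stats$gene_id)
  if (any(missing)) {
    warning(sum(missing), " ortholog genes missing from expression matrices;",
            " their groups were dropped")
  }
  passByGene <- setNames(stats$pass, stats$gene_id)
  genePass <- ifelse(missing, FALSE, passByGene[long$gene_id])
  groupPass <- tapply(genePass, long$group_id, all)
  keep <- names(groupPass)[groupPass]
  retained <- long[long$group_id %in% keep, ]
  rownames(retained) <- NULL
  list(retained = retained, groups = keep, stats = stats)
}

# rows centered and scaled to unit norm so that z %*% t(z) is Pearson r;
# constant rows become 0 (correlation treated as 0)
.rowUnit <- function(X) {
  ctr <- X - rowMeans(X)
  nrm <- sqrt(rowSums(ctr^2))
  ctr / ifelse(nrm > 0, nrm, 1)
}

#' K-means clustering with Pearson correlation distance
#'
#' Lloyd-style alternation with distance d(x, c) = 1 - Pearson(x, c) on the
#' 0-1 scaled profiles. Centers are recomputed as member means and re-scaled
#' internally to zero mean / unit norm (the optimal center under correlation
#' distance); empty clusters are re-seeded from the point farthest from all
#' centers. Initialization is a seeded farthest-first traversal, so the
#' result is deterministic given the seed.
#'
#' @param X gene x 24 matrix of 0-1 scaled profiles, rownames = gene ids.
#' @param k number of centers (2 <= k < number of genes).
#' @param species optional per-gene species labels (named or parallel to
#'   rows).
#' @param iterations iteration cap (default 2000).
#' @param seed integer seed.
#' @return a \linkS4class{ClusterModel}.
#' @export
kmeansCorrelation <- function(X, k, species = NULL, iterations = 2000L,
                              seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k >= nrow(X)) stop("k must be smaller than the number of genes")
  if (is.null(rownames(X))) stop("X must have gene ids as rownames")
  if (is.null(species)) species <- rep(NA_character_, nrow(X))
  if (!is.null(names(species))) species <- species[rownames(X)]
  Z <- .rowUnit(X)

  set.seed(seed %% .Machine$integer.max)
  centers <- integer(k)
  centers[1] <- sample.int(nrow(X), 1L)
  simToChosen <- Z %*% Z[centers[1], ]
  for (j in seq_len(k - 1L) + 1L) {
    cand <- which.min(simToChosen)
    centers[j] <- cand
    simToChosen <- pmax(simToChosen, Z %*% Z[cand, ])
  }
  C <- Z[centers, , drop = FALSE]

  assign <- integer(nrow(X))
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < iterations) {
    iter <- iter + 1L
    sim <- Z %*% t(C)
    newAssign <- max.col(sim, ties.method = "first")
    # re-seed empty clusters from the globally farthest point; mark used
    # rows so each re-seed picks a fresh gene
    simMark <- sim
    repeat {
      empties <- which(tabulate(newAssign, k) == 0L)
      if (!length(empties)) break
      far <- which.min(apply(simMark, 1, max))
      newAssign[far] <- empties[1]
      simMark[far, ] <- Inf
    }
    objective <- c(objective,
                   sum(1 - sim[cbind(seq_len(nrow(Z)), newAssign)]))
    if (identical(newAssign, assign)) {
      converged <- TRUE
      break
    }
    assign <- newAssign
    Cmean <- rowsum(Z, assign) / tabulate(assign, k)
    C <- .rowUnit(Cmean)
  }
  centers01 <- rowsum(X, assign) / tabulate(assign, k)
  names(assign) <- rownames(X)
  new("ClusterModel", k = k, assignment = assign,
      species = as.character(species), centers = centers01,
      objective = objective, iterations = iter, converged = converged)
}

#' Fraction of syntenic pairs sharing a cluster
#'
#' Pairs with an unclustered member are excluded from numerator and
#' denominator; the excluded count is attached as an attribute.
#'
#' @param model a \linkS4class{ClusterModel}.
#' @param pairs data.frame with columns \code{gene1}, \code{gene2}.
#' @return the co-clustered fraction, with attributes \code{nPairs} and
#'   \code{nExcluded}.
#' @export
coclusterRatio <- function(model, pairs) {
  a <- clusterAssignment(model)
  ok <- pairs$gene1 %in% names(a) & pairs$gene2 %in% names(a)
  ratio <- if (any(ok))
    mean(a[pairs$gene1[ok]] == a[pairs$gene2[ok]])
  else NA_real_
  structure(ratio, nPairs = sum(ok), nExcluded = sum(!ok))
}

#' Permutation null for the co-cluster ratio
#'
#' Shuffles the gene-to-cluster labels within each species (preserving
#' cluster sizes), recomputes the pair ratio per permutation, and reports
#' the observed ratio, the permutation mean ("expected"), and their ratio
#' expected/observed (an FDR-like measure: how much of the observed
#' co-clustering chance alone explains).
#'
#' @inheritParams coclusterRatio
#' @param nPerm number of permutations (default 100).
#' @param seed integer seed.
#' @return list(observed, expected, permRatios, fdrLikeRatio, nPerm)
#' @export
permuteCoclusterNull <- function(model, pairs, nPerm = 100L, seed = 1L) {
  if (nPerm < 1L) stop("nPerm must be >= 1")
  a <- clusterAssignment(model)
  sp <- clusterSpecies(model)
  observed <- as.numeric(coclusterRatio(model, pairs))
  set.seed(seed %% .Machine$integer.max)
  shuffled <- model
  permRatios <- vapply(seq_len(nPerm), function(i) {
    newA <- a
    for (s in unique(sp)) {
      ix <- which(sp == s)
      newA[ix] <- a[ix][sample.int(length(ix))]
    }
    shuffled@assignment <- newA
    as.numeric(coclusterRatio(shuffled, pairs))
  }, numeric(1))
  expected <- mean(permRatios)
  list(observed = observed, expected = expected, permRatios = permRatios,
       fdrLikeRatio = expected / observed, nPerm = nPerm)
}

#' Choose the number of clusters by the syntenic-pair criterion
#'
#' Runs \code{\link{kmeansCorrelation}} and
#' \code{\link{permuteCoclusterNull}} for each k, and picks the smallest k
#' at which the observed co-cluster ratio's decline plateaus (relative drop
#' from k to the next candidate below \code{plateauTol}). Setting
#' \code{fixedK} overrides the plateau rule with a fixed biologically
#' motivated k (e.g. 16 = two patterns per daily time point).
#'
#' @inheritParams kmeansCorrelation
#' @param pairs syntenic pair table (see \code{\link{coclusterRatio}}).
#' @param kRange candidate k values.
#' @param nPerm permutations per k.
#' @param plateauTol relative-drop tolerance (default 0.02).
#' @param fixedK optional fixed override.
#' @return list(k, table = per-k data.frame(k, observed, expected,
#'   fdrLikeRatio), model = ClusterModel at the chosen k)
#' @export
selectK <- function(X, pairs, species = NULL, kRange = 2:24,
                    iterations = 2000L, nPerm = 100L, seed = 1L,
                    plateauTol = 0.02, fixedK = NULL) {
  kRange <- sort(unique(as.integer(kRange)))
  if (max(kRange) >= nrow(X)) stop("kRange exceeds the gene count")
  rows <- lapply(kRange, function(k) {
    m <- kmeansCorrelation(X, k, species = species, iterations = iterations,
                           seed = seed + k)
    rep <- permuteCoclusterNull(m, pairs, nPerm = nPerm, seed = seed + k)
    list(model = m,
         row = data.frame(k = k, observed = rep$observed,
                          expected = rep$expected,
                          fdrLikeRatio = rep$fdrLikeRatio))
  })
  tab <- do.call(rbind, lapply(rows, `[[`, "row"))
  if (!is.null(fixedK)) {
    chosen <- as.integer(fixedK)
  } else if (length(kRange) == 1L) {
    chosen <- kRange
  } else {
    drops <- -diff(tab$observed) / pmax(tab$observed[-nrow(tab)], 1e-12)
    plateau <- which(drops < plateauTol)
    chosen <- if (length(plateau)) kRange[plateau[1]] else
      kRange[length(kRange)]
  }
  model <- if (chosen %in% kRange)
    rows[[match(chosen, kRange)]]$model
  else kmeansCorrelation(X, chosen, species = species,
                         iterations = iterations, seed = seed + chosen)
  list(k = chosen, table = tab, model = model)
}

#' Circular median on a 24-h clock
#'
#' The member value minimizing the summed circular distance
#' min(|a - b|, period - |a - b|) to all members; ties resolve to the
#' smallest value.
#'
#' @param x phases in [0, period).
#' @param period circle length (default 24).
#' @return the circular median.
#' @examples
#' circularMedian(c(23, 0, 1))  # 0
#' @export
circularMedian <- function(x, period = 24) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  cost <- vapply(x, function(c) {
    d <- abs(x - c) %% period
    sum(pmin(d, period - d))
  }, numeric(1))
  min(x[cost == min(cost)])
}

#' Per-cluster median circadian phase
#'
#' Circular median (24-h circle) of the CT phases of each cluster's member
#' genes; empty clusters (or clusters without phase data) yield NA with a
#' warning.
#'
#' @param model a \linkS4class{ClusterModel}.
#' @param rhythms rhythm results with \code{gene_id} and \code{ct_phase}
#'   (e.g. a concatenation of per-species \code{\link{detectRhythms}}
#'   outputs).
#' @return named numeric vector of length k.
#' @export
clusterMedianPhase <- function(model, rhythms) {
  a <- clusterAssignment(model)
  ph <- setNames(rhythms$ct_phase, rhythms$gene_id)[names(a)]
  med <- vapply(seq_len(model@k), function(cl) {
    circularMedian(ph[a == cl])
  }, numeric(1))
  if (anyNA(med))
    warning("clusters without phase data: ",
            paste(which(is.na(med)), collapse = ", "))
  setNames(med, seq_len(model@k))
}
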