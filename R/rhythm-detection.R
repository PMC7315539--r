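## Nonparametric rhythm detection: Kendall's tau between each gene's 24-point
## series and a grid of cosine reference waveforms (period x phase), with a
## tie-corrected normal approximation for the null of S, within-gene
## Bonferroni over the grid and across-gene Bonferroni at the end.

.pairIdx <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ut[order(ut[, "col"], ut[, "row"]), , drop = FALSE]
}

# sign(x_j - x_i) over all i < j pairs, one row per series
.pairSigns <- function(X, pairs) {
  sign(X[, pairs[, "col"], drop = FALSE] - X[, pairs[, "row"], drop = FALSE])
}

# tie summaries per series: for tied group sizes t, the sums entering the
# tie-corrected variance and the tau-b normalizer
.tieSums <- function(X) {
  t(apply(X, 1, function(v) {
    tt <- as.numeric(table(v))
    tt <- tt[tt > 1]
    c(T1 = sum(tt * (tt - 1)),
      T2 = sum(tt * (tt - 1) * (tt - 2)),
      TV = sum(tt * (tt - 1) * (2 * tt + 5)))
  }))
}

#' Build the cosine reference grid
#'
#' One waveform per (period, lag): a cosine of the given period peaking at
#' t = lag (mod period), evaluated at the 24 sample times, lags stepping by
#' \code{lagStep} over [0, period). Reference values are rounded so that
#' symmetric cosine samples tie exactly.
#'
#' @param periods candidate periods in hours (default 21, 24, 27, bracketing
#'   24 h on the 3-h sampling lattice).
#' @param lagStep lag step in hours (default 1.5, half the sampling
#'   interval).
#' @param times sample times in hours.
#' @return list of waveforms, each list(period_h, lag_h, values).
#' @examples
#' length(buildReferenceGrid(24))  # 16 lags
#' @export
buildReferenceGrid <- function(periods = c(21, 24, 27), lagStep = 1.5,
                               times = sampleTimes()) {
  if (!length(periods)) stop("empty period grid")
  if (any(periods <= 0)) stop("periods must be positive")
  grid <- list()
  for (per in periods) {
    for (lag in seq(0, per - lagStep, by = lagStep)) {
      grid[[length(grid) + 1L]] <- list(
        period_h = per, lag_h = lag,
        values = round(cos(2 * pi * (times - lag) / per), 9))
    }
  }
  grid
}

# all permutations of 1..n as an n! x n matrix (n <= 8 only)
.permMatrix <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permMatrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

.kendallCore <- function(X, refValues, n) {
  pairs <- .pairIdx(n)
  sx <- .pairSigns(X, pairs)
  sr <- .pairSigns(refValues, pairs)
  S <- sx %*% t(sr)
  tx <- .tieSums(X)
  tr <- .tieSums(refValues)
  n0 <- n * (n - 1) / 2
  v0 <- n * (n - 1) * (2 * n + 5)
  varS <- (v0 - outer(tx[, "TV"], tr[, "TV"], "+")) / 18 +
    outer(tx[, "T1"], tr[, "T1"]) / (2 * n * (n - 1)) +
    outer(tx[, "T2"], tr[, "T2"]) / (9 * n * (n - 1) * (n - 2))
  denom <- sqrt(outer(n0 - tx[, "T1"] / 2, n0 - tr[, "T1"] / 2))
  tau <- ifelse(denom > 0, S / denom, 0)
  if (n <= 8L) {
    # exact permutation null: short series are far from the normal regime,
    # so enumerate all n! value orders (ties handled by multiplicity)
    P <- .permMatrix(n)
    p <- S
    for (g in seq_len(nrow(X))) {
      Xp <- matrix(X[g, ][P], nrow(P), n)
      Sall <- sign(Xp[, pairs[, "col"], drop = FALSE] -
                   Xp[, pairs[, "row"], drop = FALSE]) %*% t(sr)
      for (r in seq_len(nrow(refValues)))
        p[g, r] <- mean(Sall[, r] >= S[g, r])
    }
  } else {
    # one-sided upper tail of S with +/-1 continuity correction
    p <- ifelse(varS > 0,
                pnorm((S - 1) / sqrt(pmax(varS, 0)), lower.tail = FALSE), 1)
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  constantX <- tx[, "T1"] >= n * (n - 1)  # all 24 values tied
  if (any(constantX)) {
    tau[constantX, ] <- 0
    p[constantX, ] <- 1
  }
  list(S = S, tau = tau, p = p)
}

#' Kendall-tau test of a series against one reference waveform
#'
#' Computes tau-b (tie-corrected) between the series and the reference
#' values, the Kendall S statistic, and the one-sided upper-tail p-value of
#' S under the permutation null: exact (full enumeration, tie-aware) for
#' series of up to 8 points, and a normal approximation with tie-corrected
#' variance and continuity correction beyond - including the 24-point
#' design. A series with fewer than two distinct values yields tau = 0,
#' p = 1.
#'
#' @param x numeric series.
#' @param ref a waveform from \code{\link{buildReferenceGrid}}, or a numeric
#'   vector of reference values of the same length.
#' @return list(tau, S, p)
#' @examples
#' ref <- buildReferenceGrid(24)[[1]]
#' kendallCosineTest(ref$values, ref)$tau  # 1: perfect concordance
#' @export
kendallCosineTest <- function(x, ref) {
  rv <- if (is.list(ref)) ref$values else ref
  if (length(x) != length(rv))
    stop("series and reference lengths differ")
  res <- .kendallCore(matrix(x, 1), matrix(rv, 1), length(x))
  list(tau = as.numeric(res$tau), S = as.numeric(res$S),
       p = as.numeric(res$p))
}

.dayProfile <- function(X) {
  nday <- ncol(X) / 8L
  prof <- 0
  for (d in seq_len(nday))
    prof <- prof + X[, ((d - 1L) * 8L + 1L):(d * 8L), drop = FALSE]
  prof / nday
}

#' Detect rhythmic genes in a 24-point, 72-h expression matrix
#'
#' Scans every gene against the cosine reference grid, keeps the waveform
#' minimizing the Kendall one-sided p-value, Bonferroni-adjusts within gene
#' by the grid size and across genes by the gene count, and derives phase
#' and amplitude: LAG is the winning waveform's lag, CT phase =
#' (LAG / period) * 24 mod 24, and amplitude is the peak-to-trough range of
#' the day-averaged 8-point profile. Constant genes are reported with p = 1
#' rather than dropped.
#'
#' @param x gene x 24 matrix (rownames = gene ids), or a
#'   SummarizedExperiment with an expression assay.
#' @param periods candidate periods (hours).
#' @param lagStep lag step (hours).
#' @param alpha gene-level Bonferroni threshold for the rhythmic call.
#' @param grid optional precomputed \code{\link{buildReferenceGrid}} result.
#' @return \code{DataFrame} with columns gene_id, p, p_bonf, period, lag,
#'   ct_phase, amplitude, is_rhythmic.
#' @examples
#' t <- sampleTimes()
#' x <- rbind(gene1 = 10 + 5 * cos(2 * pi * (t - 6) / 24))
#' detectRhythms(x)[, c("period", "lag", "amplitude")]
#' @export
detectRhythms <- function(x, periods = c(21, 24, 27), lagStep = 1.5,
                          alpha = 0.01, grid = NULL) {
  X <- .assayMatrix(x)
  if (is.null(grid)) grid <- buildReferenceGrid(periods, lagStep)
  if (!length(grid)) stop("empty reference grid")
  n <- ncol(X)
  if (any(lengths(lapply(grid, `[[`, "values")) != n))
    stop("reference grid length does not match series length")
  refValues <- do.call(rbind, lapply(grid, `[[`, "values"))
  res <- .kendallCore(X, refValues, n)
  best <- apply(res$p, 1, which.min)
  minp <- res$p[cbind(seq_len(nrow(X)), best)]
  pGene <- pmin(1, minp * length(grid))
  per <- vapply(grid, `[[`, numeric(1), "period_h")[best]
  lag <- vapply(grid, `[[`, numeric(1), "lag_h")[best]
  prof <- .dayProfile(X)
  amp <- apply(prof, 1, max) - apply(prof, 1, min)
  pBonf <- pmin(1, pGene * nrow(X))
  out <- S4Vectors::DataFrame(
    gene_id = rownames(X), p = pGene, p_bonf = pBonf, period = per,
    lag = lag, ct_phase = toCircadianPhase(lag, per), amplitude = amp,
    is_rhythmic = pBonf <= alpha)
  rownames(out) <- rownames(X)
  out
}

#' Scan a single series over the reference grid
#'
#' Single-gene convenience wrapper around \code{\link{detectRhythms}}; the
#' returned p is Bonferroni-adjusted within the grid only.
#'
#' @param x numeric series of 24 values.
#' @param grid reference grid (default \code{buildReferenceGrid()}).
#' @param alpha threshold applied to the within-gene adjusted p.
#' @return one-row \code{DataFrame} as in \code{\link{detectRhythms}}.
#' @export
jtkScan <- function(x, grid = buildReferenceGrid(), alpha = 0.01) {
  detectRhythms(matrix(x, 1, dimnames = list("series", NULL)),
                grid = grid, alpha = alpha)
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the family size (default: the list length) and
#' caps at 1; order is preserved. Rejects p-values outside (0, 1].
#'
#' @param p numeric p-values in (0, 1].
#' @param m family size.
#' @return adjusted p-values.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (any(p <= 0 | p > 1 | is.na(p)))
    stop("p-values must lie in (0, 1]")
  pmin(1, p * m)
}

#' Convert a peak lag to circadian-time phase
#'
#' CT phase = (lag / period) * 24, reduced modulo 24. CT0 is lights-on
#' (9:00 AM in the emulated design).
#'
#' @param lagH time of estimated peak, hours from the first sample.
#' @param periodH estimated period, hours (> 0).
#' @return CT phase in [0, 24).
#' @examples
#' toCircadianPhase(12, 24)  # 12
#' toCircadianPhase(13, 26)  # 12
#' @export
toCircadianPhase <- function(lagH, periodH) {
  if (any(periodH <= 0)) stop("period must be positive")
  (lagH / periodH * 24) %% 24
}

#' @rdname io
#' @param rhythms result of \code{\link{detectRhythms}}.
#' @export
writeRhythms <- function(rhythms, file) {
  write.table(as.data.frame(rhythms), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
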