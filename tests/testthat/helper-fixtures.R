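# Shared fixture builders; everything is generated in code at test time.

fixtureTimes <- dielSync::sampleTimes()

# noiseless/noisy cosine matrix with given CT phases (period 24, lag = phase)
cosineMatrix <- function(phases, baseline = 10, amplitude = 10,
                         sigma = 0, dayEffect = 0, prefix = "g",
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- fixtureTimes
  X <- t(vapply(phases, function(p) {
    y <- (baseline + amplitude / 2 * cos(2 * pi * (t - p) / 24))
    if (sigma > 0) y <- y * exp(rnorm(24, 0, sigma))
    if (dayEffect > 0) y <- y + rnorm(3, 0, dayEffect)[(t %/% 24) + 1]
    pmax(y, 0)
  }, numeric(24)))
  rownames(X) <- sprintf("%s%04d", prefix, seq_along(phases))
  X
}

flatNoiseMatrix <- function(n, baseline = 10, sigma = 0.2, prefix = "a",
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- t(vapply(seq_len(n), function(i) baseline * exp(rnorm(24, 0, sigma)),
                numeric(24)))
  rownames(X) <- sprintf("%s%04d", prefix, seq_len(n))
  X
}

# i.i.d. promoter set from a base composition
randomPromoters <- function(n, len, probs = rep(0.25, 4), prefix = "g",
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- Biostrings::DNAStringSet(dielSync:::.randomSequences(n, len, probs))
  names(x) <- sprintf("%s%04d", prefix, seq_len(n))
  x
}

plantMotif <- function(promoters, genes, motif, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- nchar(motif)
  L <- Biostrings::width(promoters)[1]
  for (g in genes) {
    s <- sample.int(L - w + 1L, 1L)
    Biostrings::subseq(promoters[[g]], s, s + w - 1L) <-
      Biostrings::DNAString(motif)
  }
  promoters
}

# exhaustive one-sided hypergeometric tail, the Fisher oracle
fisherOracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- a:min(r1, c1)
  sum(choose(c1, xs) * choose(n - c1, r1 - xs)) / choose(n, r1)
}

# textbook CMH formula, coded independently of the package internals
cmhOracle <- function(a, b, c, d, correct = TRUE) {
  num <- 0; v <- 0
  for (s in seq_along(a)) {
    n <- a[s] + b[s] + c[s] + d[s]
    if (n < 2) next
    num <- num + a[s] - (a[s] + b[s]) * (a[s] + c[s]) / n
    v <- v + (a[s] + b[s]) * (c[s] + d[s]) * (a[s] + c[s]) * (b[s] + d[s]) /
      (n^2 * (n - 1))
  }
  delta <- abs(num) - if (correct) 0.5 else 0
  stat <- if (v > 0) delta^2 / v else 0
  list(stat = stat, p = if (v > 0) pchisq(stat, 1, lower.tail = FALSE) else 1)
}

# exhaustive permutation null for Kendall S against a reference
kendallExactOracle <- function(x, rv) {
  n <- length(x)
  pr <- t(combn(n, 2))
  sr <- sign(rv[pr[, 2]] - rv[pr[, 1]])
  Sobs <- sum(sign(x[pr[, 2]] - x[pr[, 1]]) * sr)
  allp <- function(n) {
    if (n == 1) return(matrix(1))
    sub <- allp(n - 1)
    do.call(rbind, lapply(seq_len(n), function(i) cbind(i, sub + (sub >= i))))
  }
  P <- allp(n)
  Xp <- matrix(x[P], nrow(P), n)
  Sall <- sign(Xp[, pr[, 2]] - Xp[, pr[, 1]]) %*% sr
  list(S = Sobs, p = mean(Sall >= Sobs))
}

adjustedRandIndex <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(sum(tab), 2)
  maxidx <- (sumi + sumj) / 2
  (sumij - expected) / (maxidx - expected)
}

# small three-species promoter + assignment fixture for enrichment tests
enrichmentFixture <- function(nPerSpecies = 120, len = 400, nClusters = 4,
                              probs = list(rep(0.25, 4),
                                           c(0.2, 0.3, 0.3, 0.2),
                                           c(0.3, 0.2, 0.2, 0.3)),
                              seed = 1) {
  set.seed(seed)
  sp <- paste0("sp", seq_along(probs))
  proms <- list(); assign <- NULL
  for (i in seq_along(sp)) {
    x <- randomPromoters(nPerSpecies, len, probs[[i]],
                         prefix = paste0(sp[i], "_g"))
    proms[[sp[i]]] <- x
    assign <- rbind(assign,
                    data.frame(gene_id = names(x), species = sp[i],
                               cluster = rep(seq_len(nClusters),
                                             length.out = nPerSpecies)))
  }
  list(promoters = proms, assignment = assign, species = sp)
}
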