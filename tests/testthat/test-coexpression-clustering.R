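test_that("unit-interval scaling is exact, flagged and affine-invariant", {
  expect_equal(as.numeric(scaleUnitInterval(c(0, 5, 10))), c(0, 0.5, 1))
  x <- rnorm(24)
  s1 <- scaleUnitInterval(x)
  expect_equal(min(s1), 0)
  expect_equal(max(s1), 1)
  expect_equal(as.numeric(scaleUnitInterval(2.5 * x + 3)), as.numeric(s1))
  sc <- scaleUnitInterval(rep(4, 24))
  expect_equal(as.numeric(sc), rep(0.5, 24))
  expect_true(attr(sc, "constant"))
})

test_that("window statistics capture day reproducibility", {
  day <- c(1, 3, 7, 9, 6, 4, 2, 0)
  x <- rep(day, 3)
  ws <- windowStats(x)
  expect_equal(c(ws$r12, ws$r13, ws$r23), c(1, 1, 1))
  expect_equal(ws$msd, 0)
  # third day mirrored around its mean: r(1,3) = -1
  x2 <- c(day, day, mean(day) - (day - mean(day)))
  expect_equal(windowStats(x2)$r13, -1)
  # constant window: correlation undefined
  x3 <- c(day, rep(2, 8), day)
  expect_true(is.na(windowStats(x3)$r12))
  # independently permuted columns decorrelate the windows
  set.seed(40)
  X <- cosineMatrix(runif(500, 0, 24))
  Xp <- t(apply(X, 1, sample))
  ws <- windowStats(Xp)
  rall <- c(ws$r12, ws$r13, ws$r23)
  expect_lt(abs(mean(rall)), 3 * sd(rall) / sqrt(length(rall)))
})

test_that("ortholog filter keeps reproducible groups and is monotone", {
  set.seed(41)
  phases <- runif(30, 0, 24)
  mats <- list(sp1 = cosineMatrix(phases, prefix = "SA_g"),
               sp2 = cosineMatrix(phases, prefix = "SB_g"))
  orthos <- data.frame(group_id = sprintf("OG%03d", 1:30),
                       sp1 = rownames(mats$sp1), sp2 = rownames(mats$sp2))
  f <- filterOrthogroups(mats, orthos)
  expect_setequal(f$groups, orthos$group_id)  # noiseless: all retained

  # vacuous thresholds retain everything even for noise
  matsN <- list(sp1 = flatNoiseMatrix(30, prefix = "SA_g", seed = 2),
                sp2 = flatNoiseMatrix(30, prefix = "SB_g", seed = 3))
  fN <- filterOrthogroups(matsN, orthos, rMin = -1, msdMax = Inf)
  expect_setequal(fN$groups, orthos$group_id)

  # shuffled days almost never pass
  set.seed(42)
  shuffle <- function(m) {
    t(apply(m, 1, function(v) c(sample(v[1:8]), sample(v[9:16]),
                                sample(v[17:24]))))
  }
  matsS <- lapply(mats, shuffle)
  for (s in names(matsS)) rownames(matsS[[s]]) <- rownames(mats[[s]])
  fS <- filterOrthogroups(matsS, orthos)
  expect_lte(length(fS$groups), 1)

  # monotonicity: stricter thresholds never add genes
  mats2 <- list(sp1 = cosineMatrix(phases, sigma = 0.3, prefix = "SA_g",
                                   seed = 4),
                sp2 = cosineMatrix(phases, sigma = 0.3, prefix = "SB_g",
                                   seed = 5))
  loose <- filterOrthogroups(mats2, orthos, rMin = 0.5, msdMax = 1.2)
  strict <- filterOrthogroups(mats2, orthos, rMin = 0.8, msdMax = 0.5)
  expect_true(all(strict$groups %in% loose$groups))

  # missing gene drops its group with a warning
  matsM <- mats
  matsM$sp1 <- matsM$sp1[-1, ]
  expect_warning(fM <- filterOrthogroups(matsM, orthos), "missing")
  expect_false(orthos$group_id[1] %in% fM$groups)
})

test_that("correlation K-means separates phase patterns", {
  # two noiseless antiphase groups are perfectly separable at k = 2
  X <- rbind(cosineMatrix(rep(0, 20), prefix = "m"),
             cosineMatrix(rep(12, 20), prefix = "e"))
  Xs <- scaleUnitInterval(X)
  m <- kmeansCorrelation(Xs, 2, seed = 1)
  lab <- clusterAssignment(m)
  expect_equal(length(unique(lab[1:20])), 1)
  expect_equal(length(unique(lab[21:40])), 1)
  expect_false(lab[1] == lab[21])
  # within-cluster correlation distances are all 0 for identical patterns
  Z <- dielSync:::.rowUnit(Xs)
  C <- dielSync:::.rowUnit(clusterCenters(m))
  d <- 1 - rowSums(Z * C[lab, ])
  expect_lt(max(d), 1e-10)
  # objective is non-increasing
  expect_true(all(diff(m@objective) <= 1e-8))

  # 8 planted phase patterns with mild noise: near-perfect recovery
  set.seed(43)
  truthLab <- rep(1:8, each = 25)
  X8 <- cosineMatrix(c(0, 3, 6, 9, 12, 15, 18, 21)[truthLab], sigma = 0.1,
                     seed = 44)
  m8 <- kmeansCorrelation(scaleUnitInterval(X8), 8, seed = 2)
  expect_gte(adjustedRandIndex(clusterAssignment(m8), truthLab), 0.9)

  expect_error(kmeansCorrelation(Xs, 50), "smaller")
  expect_error(kmeansCorrelation(Xs, 1), ">= 2")
})

test_that("co-cluster ratio and its permutation null behave as collision
           probabilities", {
  set.seed(45)
  phases <- runif(120, 0, 24)
  X <- rbind(cosineMatrix(phases, prefix = "SA_g"),
             cosineMatrix(phases, prefix = "SB_g"))
  species <- setNames(rep(c("sp1", "sp2"), each = 120), rownames(X))
  pairs <- data.frame(gene1 = sprintf("SA_g%04d", 1:120),
                      gene2 = sprintf("SB_g%04d", 1:120))
  m <- kmeansCorrelation(scaleUnitInterval(X), 6, species = species,
                         seed = 3)
  # identical ortholog profiles always co-cluster
  expect_equal(as.numeric(coclusterRatio(m, pairs)), 1)
  # degenerate single-cluster assignment
  m1 <- m
  m1@assignment[] <- 1L
  expect_equal(as.numeric(coclusterRatio(m1, pairs)), 1)
  # pairs with unclustered members are excluded and counted
  pairsX <- rbind(pairs, data.frame(gene1 = "nope", gene2 = "nada"))
  r <- coclusterRatio(m, pairsX)
  expect_equal(attr(r, "nExcluded"), 1)
  expect_equal(attr(r, "nPairs"), 120)

  # random assignment to k equal clusters collides at ~ 1/k
  k <- 6
  set.seed(46)
  mRand <- m
  mRand@assignment <- setNames(
    c(sample(rep(1:k, 20)), sample(rep(1:k, 20))), names(m@assignment))
  rr <- as.numeric(coclusterRatio(mRand, pairs))
  se <- sqrt((1 / k) * (1 - 1 / k) / 120)
  expect_lt(abs(rr - 1 / k), 3 * se)

  # permutation expectation ~ 1/k; planted structure gives expected << obs
  rep <- permuteCoclusterNull(m, pairs, nPerm = 100, seed = 5)
  expect_equal(rep$observed, 1)
  expect_lt(abs(rep$expected - 1 / k), 3 * se)
  expect_lt(rep$fdrLikeRatio, 0.5)

  # self-consistency: a random model is itself a draw from the null
  repR <- permuteCoclusterNull(mRand, pairs, nPerm = 200, seed = 6)
  expect_lt(abs(repR$fdrLikeRatio - 1), 0.5)
})

test_that("k selection finds the plateau and honors the fixed override", {
  # exactly 4 noiseless patterns: ratio 1 up to k=4, drops after
  set.seed(47)
  truthLab <- rep(1:4, each = 30)
  ph <- c(0, 6, 12, 18)[truthLab]
  X <- rbind(cosineMatrix(ph, prefix = "SA_g"),
             cosineMatrix(ph, prefix = "SB_g"))
  species <- setNames(rep(c("sp1", "sp2"), each = 120), rownames(X))
  pairs <- data.frame(gene1 = sprintf("SA_g%04d", 1:120),
                      gene2 = sprintf("SB_g%04d", 1:120))
  sel <- selectK(scaleUnitInterval(X), pairs, species = species,
                 kRange = 2:6, nPerm = 10, seed = 7)
  tab <- sel$table
  expect_true(all(tab$observed[tab$k <= 4] == 1))
  expect_lt(tab$observed[tab$k == 5], 1)

  selP <- selectK(scaleUnitInterval(X), pairs, species = species,
                  kRange = 2:6, nPerm = 5, seed = 7, fixedK = 16)
  expect_equal(selP$k, 16L)
})

test_that("circular medians respect the 24-h wrap", {
  expect_equal(circularMedian(c(6, 6, 6)), 6)
  expect_equal(circularMedian(c(23, 0, 1)), 0)
  expect_equal(circularMedian(c(5, 6, 7)), 6)
  m <- new("ClusterModel", k = 2L,
           assignment = setNames(c(1L, 1L, 1L, 2L), paste0("g", 1:4)),
           species = rep("sp1", 4), centers = matrix(0, 2, 24),
           objective = 0, iterations = 1L, converged = TRUE)
  rh <- data.frame(gene_id = paste0("g", 1:4), ct_phase = c(23, 0, 1, 12))
  expect_equal(unname(clusterMedianPhase(m, rh)), c(0, 12))
  # empty cluster flagged
  m@assignment <- setNames(rep(1L, 4), paste0("g", 1:4))
  expect_warning(med <- clusterMedianPhase(m, rh), "without phase")
  expect_true(is.na(med[2]))
})
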