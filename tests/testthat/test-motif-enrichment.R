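test_that("motif enumeration is complete and lexicographic", {
  expect_equal(enumerateMotifs(1), c("A", "C", "G", "T"))
  m6 <- enumerateMotifs(6)
  expect_length(m6, 4096)
  m8 <- enumerateMotifs(8)
  expect_length(m8, 65536)
  expect_equal(m8[1], "AAAAAAAA")
  expect_equal(m8[65536], "TTTTTTTT")
  expect_false(is.unsorted(m8))
  expect_error(enumerateMotifs(0), "positive")
})

test_that("promoter indexing counts overlaps and skips N windows", {
  idx <- indexPromoters(c(g1 = "ACGTAC"), 6)
  expect_equal(sum(motifPresence(idx)[1, ]), 1)
  expect_equal(motifCounts(idx)[1, "ACGTAC"], 1)

  idx2 <- indexPromoters(c(g1 = "AAAAAAA"), 6)
  expect_equal(motifCounts(idx2)[1, "AAAAAA"], 2)

  idx3 <- indexPromoters(c(g1 = "ACGNACGT"), 4)
  pres <- motifPresence(idx3)[1, ]
  expect_equal(names(pres)[pres], "ACGT")
  expect_equal(sum(motifCounts(idx3)[1, ]), 1)

  expect_error(indexPromoters(c(g1 = "ACGRT"), 4), "ACGTN")
  expect_warning(indexPromoters(c(g1 = "ACG"), 4), "shorter")
  # order of the index columns matches enumerateMotifs
  expect_equal(colnames(motifCounts(idx3)), enumerateMotifs(4))
})

test_that("presence and counts are consistent and bounded by window count", {
  set.seed(50)
  proms <- randomPromoters(30, 200)
  idx <- indexPromoters(proms, 6)
  expect_identical(motifPresence(idx), motifCounts(idx) >= 1L)
  expect_true(all(rowSums(motifCounts(idx)) == 200 - 6 + 1))
  expect_true(all(rowSums(motifPresence(idx)) <= 200 - 6 + 1))
})

test_that("one-sided Fisher p equals the hypergeometric tail", {
  expect_equal(fisherEnrichment(3, 1, 1, 3), fisherOracle(3, 1, 1, 3),
               tolerance = 1e-12)
  expect_equal(fisherOracle(3, 1, 1, 3), 0.24285714285714, tolerance = 1e-10)
  expect_equal(fisherEnrichment(0, 5, 5, 0), 1)
  expect_equal(fisherEnrichment(5, 0, 0, 5), 1 / choose(10, 5),
               tolerance = 1e-12)
  # zero margins
  expect_equal(fisherEnrichment(0, 0, 3, 4), 1)
  expect_equal(fisherEnrichment(0, 3, 0, 4), 1)
  # random cross-check against stats::fisher.test
  set.seed(51)
  for (i in 1:50) {
    tb <- matrix(rpois(4, 8), 2)
    expect_equal(fisherEnrichment(tb),
                 fisher.test(tb, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
  expect_error(fisherEnrichment(-1, 2, 3, 4), "nonnegative")
})

test_that("CMH statistic matches the textbook formula and its oracles", {
  # balanced strata: sum(a - E) = 0, so the corrected statistic is
  # 0.25 / sum(V) and the uncorrected one is 0
  bal <- data.frame(a = rep(5, 3), b = rep(5, 3), c = rep(5, 3),
                    d = rep(5, 3))
  v <- 3 * (10 * 10 * 10 * 10) / (20^2 * 19)
  expect_equal(cmhTest(bal)$statistic, 0.25 / v, tolerance = 1e-12)
  expect_equal(cmhTest(bal, correct = FALSE)$statistic, 0)

  # worked stratum set with identical strata
  tri <- data.frame(a = rep(8, 3), b = rep(2, 3), c = rep(20, 3),
                    d = rep(70, 3))
  o <- cmhOracle(tri$a, tri$b, tri$c, tri$d)
  got <- cmhTest(tri)
  expect_equal(got$statistic, o$stat, tolerance = 1e-8)
  expect_equal(got$p, o$p, tolerance = 1e-8)

  # random tables against the independent formula evaluation
  set.seed(52)
  for (i in 1:200) {
    a <- rpois(3, 10); b <- rpois(3, 10); c <- rpois(3, 30); d <- rpois(3, 30)
    o <- cmhOracle(a, b, c, d)
    got <- cmhTest(data.frame(a, b, c, d))
    expect_equal(got$statistic, o$stat, tolerance = 1e-8)
    expect_equal(got$p, o$p, tolerance = 1e-8)
  }

  # single stratum reduces to the Yates chi-square times (n-1)/n, in the
  # regime where both conventions apply the correction
  set.seed(53)
  checked <- 0
  while (checked < 25) {
    tb <- matrix(rpois(4, 15) + 1, 2)
    n <- sum(tb)
    if (abs(tb[1, 1] - sum(tb[1, ]) * sum(tb[, 1]) / n) < 0.5) next
    yates <- suppressWarnings(chisq.test(tb, correct = TRUE)$statistic)
    expect_equal(cmhTest(array(tb, c(2, 2, 1)))$statistic,
                 unname(yates) * (n - 1) / n, tolerance = 1e-8)
    checked <- checked + 1
  }

  # degenerate strata
  deg <- data.frame(a = 0, b = 0, c = 0, d = 1)
  expect_true(cmhTest(deg)$degenerate)
  expect_equal(cmhTest(deg)$p, 1)
  expect_error(cmhTest(data.frame(a = -1, b = 1, c = 1, d = 1)),
               "nonnegative")
})

test_that("strata construction counts presence by cluster and species", {
  set.seed(54)
  fx <- enrichmentFixture(nPerSpecies = 100, len = 300, nClusters = 2)
  indices <- lapply(setNames(fx$species, fx$species), function(s)
    indexPromoters(fx$promoters[[s]], 6, species = s))
  st <- buildStrata(indices, fx$assignment, "ACGTAC", 1)
  expect_equal(nrow(st), 3)
  for (i in 1:3) {
    s <- st$species[i]
    pres <- motifPresence(indices[[s]])[, "ACGTAC"]
    inCl <- fx$assignment$cluster[fx$assignment$species == s] == 1
    expect_equal(st$a[i], sum(pres & inCl))
    expect_equal(st$a[i] + st$b[i], sum(inCl))
    expect_equal(sum(st[i, c("a", "b", "c", "d")]), 100)
  }
  # worked example: 10 in-cluster genes (4 with motif), 90 background (12)
  one <- list(x = new("MotifIndex", k = 1L, species = "x",
                      counts = cbind(A = c(rep(1L, 4), rep(0L, 6),
                                           rep(1L, 12), rep(0L, 78)),
                                     C = 0L, G = 0L, T = 0L,
                                     deparse.level = 1)))
  rownames(one$x@counts) <- paste0("g", 1:100)
  asg <- data.frame(gene_id = paste0("g", 1:100), species = "x",
                    cluster = rep(c(1, 2), c(10, 90)))
  st1 <- buildStrata(one, asg, "A", 1)
  expect_equal(unlist(st1[c("a", "b", "c", "d")], use.names = FALSE),
               c(4, 6, 12, 78))
})

test_that("full enrichment scan agrees with the single-motif route", {
  set.seed(55)
  fx <- enrichmentFixture(nPerSpecies = 80, len = 250, nClusters = 3)
  res <- runEnrichment(fx$promoters, fx$assignment, kValues = 6)
  expect_equal(nrow(res), 4096 * 3)
  indices <- lapply(setNames(fx$species, fx$species), function(s)
    indexPromoters(fx$promoters[[s]], 6, species = s))
  for (motif in c("ACGTAC", "AAATAT", "GGCGGC")) {
    for (cl in 1:3) {
      st <- buildStrata(indices, fx$assignment, motif, cl)
      row <- res[res$motif == motif & res$cluster == cl, ]
      expect_equal(unname(unlist(row[paste0("a_", fx$species)])), st$a)
      expect_equal(row$cmh_stat, cmhTest(st)$statistic, tolerance = 1e-10)
      for (i in seq_along(fx$species))
        expect_equal(row[[paste0("fisher_p_", fx$species[i])]],
                     fisherEnrichment(st$a[i], st$b[i], st$c[i], st$d[i]),
                     tolerance = 1e-12)
    }
  }
})

test_that("a fully planted motif attains the grid's minimal CMH p", {
  set.seed(56)
  fx <- enrichmentFixture(nPerSpecies = 60, len = 200, nClusters = 3)
  proms <- fx$promoters
  for (s in fx$species) {
    tgt <- fx$assignment$gene_id[fx$assignment$species == s &
                                 fx$assignment$cluster == 2]
    proms[[s]] <- plantMotif(proms[[s]], tgt, "TTAACGGT", seed = 57)
  }
  res <- runEnrichment(proms, fx$assignment, kValues = 8)
  hit <- res[res$motif == "TTAACGGT" & res$cluster == 2, ]
  expect_equal(hit$cmh_p, min(res$cmh_p))
})

test_that("permutation FDR separates planted signal from null motifs", {
  set.seed(58)
  fx <- enrichmentFixture(nPerSpecies = 90, len = 300, nClusters = 3)
  proms <- fx$promoters
  for (s in fx$species) {
    inCl <- fx$assignment$gene_id[fx$assignment$species == s &
                                  fx$assignment$cluster == 1]
    tgt <- inCl[runif(length(inCl)) < 0.6]
    proms[[s]] <- plantMotif(proms[[s]], tgt, "AAATATCT")
  }
  res <- runEnrichment(proms, fx$assignment, kValues = 8)
  res <- permutationFdr(res, proms, fx$assignment, nPerm = 20,
                        mode = "across_species", seed = 59)
  hit <- res[res$motif == "AAATATCT" & res$cluster == 1, ]
  expect_equal(hit$fdr, 0)
  expect_true(hit$significant)
  # a motif at the bottom of the observed distribution has FDR ~ 1
  low <- res[which.min(res$cmh_stat), ]
  expect_gte(low$fdr, 0.9)
  expect_error(permutationFdr(res, proms, fx$assignment, nPerm = 0),
               "nPerm")
})

test_that("known-element matching distinguishes exact, containment, overlap", {
  m <- matchKnownElements("AATATC")
  expect_true(any(m$name == "EE_core" & m$type == "exact"))
  m2 <- matchKnownElements("AAATATCT")
  expect_true(any(m2$name == "EE_full" & m2$type == "exact"))
  expect_true(any(m2$name == "EE_core" &
                  m2$type == "motif_contains_element"))
  expect_equal(nrow(matchKnownElements("GGGGGG")), 0)
  # overlap by min - 1 identical bases: GCCACA vs ME CCACAC (offset 1)
  m3 <- matchKnownElements("GCCACA")
  expect_true(any(m3$name == "ME" & m3$type == "overlap"))
  expect_error(matchKnownElements("AANTT"), "ACGT")

  res <- annotateKnownElements(data.frame(motif = c("AATATC", "GGGGGG")))
  expect_match(res$known_elements[1], "EE_core")
  expect_equal(res$known_elements[2], "")
})
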