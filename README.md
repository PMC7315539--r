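# dielSync

Cross-species analysis of diurnal gene regulation: rhythm detection in
72-hour expression time courses, reproducibility filtering and
co-clustering of syntenic orthologs, and discovery of enriched promoter
k-mer motifs by stratified cross-species testing. The package is aimed at
comparative transcriptomics of related species sampled in parallel under
light/dark cycles — the default configuration emulates three panicoid
grasses (sorghum, maize with duplicated homeologs, foxtail millet) sampled
every 3 h over 72 h — and at methodologists who want every stage testable
against planted ground truth.

## What it computes

**Rhythms.** For each gene, Kendall's tau is computed between the 24-point
series and cosine reference waveforms over periods {21, 24, 27} h and lags
stepping by 1.5 h. The one-sided p of the best waveform is
Bonferroni-adjusted within gene (×48 waveforms) and across genes; genes
with adjusted p ≤ 0.01 are called rhythmic. Phase is converted to
circadian time, CT = (LAG/period)·24 mod 24 (CT0 = lights-on), and
amplitude is the peak−trough range of the day-averaged profile.

**Co-clustering.** Genes whose three day-windows correlate (min pairwise
Pearson r > 0.7) and disperse little (mean squared deviation of scaled
windows < 0.9) are kept when their whole ortholog group passes; 0–1
scaled profiles from all species are clustered by K-means with distance
1 − r. The fraction of sorghum–foxtail syntenic pairs sharing a cluster is
compared with a 100-permutation label-shuffle null; k is chosen where that
ratio's decline plateaus (or fixed, e.g. 16).

**Motifs.** All 4^k motifs (k = 6, 7, 8) are scanned in 1-kb promoters of
clustered genes. Per species, one-sided Fisher tests on presence/absence
2×2 tables (cluster vs other clusters); across species, the
Cochran–Mantel–Haenszel statistic

    chi2 = (|sum_s (a_s - E_s)| - 1/2)^2 / sum_s V_s

with chi-square(1) tails, which controls for species-specific promoter
base composition. Significance is an empirical FDR (< 0.05) over 100
re-drawn cluster assignments, by default shuffling gene identities across
the pooled species set (the stricter null). Hits are annotated against a
curated catalog of diurnal cis-elements (evening element, CBS, ME,
telo-box, SBX, SORLIP1, UP1ATMSD).

**Synthetic data.** `simulateDielData()` generates ortholog tables,
cosine-driven expression with log-normal noise and per-day offsets, and
promoters with planted cis-elements at phase-targeted frequencies —
with full ground truth, so detection power, filter behavior, co-cluster
enrichment and motif recovery are all checkable.

## Worked example

```r
library(dielSync)

cfg <- DielSimConfig(nGroups = 300, seed = 42)   # three species, ~950 genes
sim <- simulateDielData(cfg)

rh <- detectRhythms(sim$matrices$sorghum)
sum(rh$is_rhythmic)
#> 167                      # of 300 sorghum genes (generating fraction 0.5,
#>                          # detected rhythms only for adequate amplitudes)

filt <- filterOrthogroups(sim$matrices, sim$orthogroups)
#> 456 genes in 145 groups pass the day-reproducibility filter

X <- do.call(rbind, lapply(names(sim$matrices), function(s) {
  g <- filt$retained$gene_id[filt$retained$species == s]
  scaleUnitInterval(sim$matrices[[s]][g, , drop = FALSE])
}))
species <- setNames(filt$retained$species, filt$retained$gene_id)
m <- kmeansCorrelation(X, 8, species = species, seed = 1)
permuteCoclusterNull(m, orthologPairs(sim$orthogroups), nPerm = 100,
                     seed = 2)[c("observed", "expected")]
#> observed 0.841, expected 0.182   # orthologs co-cluster ~4.6x over chance

clusterMedianPhase(m, rh)
#>    1    2    3    4    5    6    7    8
#>  9.0  1.5 18.0  7.5 13.5 15.0  3.0 12.0   # median CT phase per cluster

assign <- assignmentTable(m)
proms <- lapply(setNames(names(sim$promoters), names(sim$promoters)),
                function(s) sim$promoters[[s]][
                  intersect(names(sim$promoters[[s]]),
                            assign$gene_id[assign$species == s])])
res <- runEnrichment(proms, assign, kValues = 8)
res <- permutationFdr(res, proms, assign, nPerm = 100,
                      mode = "across_species", seed = 3)
res <- annotateKnownElements(res)
subset(res, significant,
       c(motif, cluster, cmh_p, fdr, known_elements))[1:3, ]
#>     motif cluster        cmh_p  fdr  known_elements
#>  GAACACTG       3 1.464113e-09 0.01
#>  AAATATCT       8 6.940217e-09 0.00 EE_core,EE_full
#>  CAAAGACC       1 4.310097e-07 0.01
```

The planted evening element (AAATATCT, inserted at rate 0.4 upstream of
genes phased CT 10.5–13.5 vs 0.05 elsewhere) is recovered at permutation
FDR 0 in cluster 8 — the cluster whose median phase is CT 12 — and
annotated as the full evening element. The other hits are chance 8-mers of
this particular simulation; at FDR < 0.05 a few are expected among the
4096 × 8 (motif, cluster) tests per width.

The same stages run end-to-end with one call:

```r
runPipeline(pipelineConfig(simConfig = cfg, kValues = c(6, 8), seed = 42),
            outDir = "run1")
```

which writes `expression_*.tsv`, `rhythms_*.tsv`, `clusters.tsv`,
`motifs_k*.tsv`, a text report and a JSON manifest, and is resumable and
byte-reproducible given the seed. A thin command-line wrapper is at
`inst/scripts/dielsync.R`.

## Vignette

`vignettes/dielSync-methods.Rmd` documents the statistical model of every
stage, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the package's numerical choices
and limitations.
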