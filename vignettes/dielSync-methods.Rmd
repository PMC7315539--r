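---
title: "Methods: cross-species diurnal rhythms, co-clustering and promoter motifs"
author: "dielSync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species diurnal rhythms, co-clustering and promoter motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielSync)
```

# Overview

dielSync implements a four-stage comparative analysis of diurnal gene
regulation for a panel of related species (the defaults emulate three
panicoid grasses — sorghum, foxtail millet and maize — grown under 12 h
light / 12 h dark and sampled every 3 h over 72 h, 24 time points per
species):

1. **Rhythm detection** — a nonparametric, JTK-style Kendall-tau scan of
   each gene's 24-point series against a grid of cosine reference
   waveforms, yielding period, phase and amplitude estimates and a
   Bonferroni-controlled rhythmic call.
2. **Reproducibility filtering and co-clustering** — syntenic ortholog
   groups whose members reproduce across the three sampled days are
   clustered jointly across species by K-means with Pearson correlation
   distance on 0–1 scaled profiles; the number of clusters is chosen
   against a syntenic-pair permutation null.
3. **Promoter motif enrichment** — every 6–8-nt k-mer is tested for
   enrichment in each cluster's 1-kb promoters, per species by one-sided
   Fisher tests and across species by a Cochran–Mantel–Haenszel (CMH)
   test, with a permutation FDR over shuffled cluster assignments.
4. **Synthetic data** — a first-class generator with planted rhythms,
   ortholog structure and cis-elements, so every stage is verifiable
   against known ground truth without any sequencing data.

# The rhythm test

For gene expression $x_1,\dots,x_{24}$ at $t = 0, 3, \dots, 69$ h, and a
reference cosine of period $T$ peaking at lag $\ell$, the test statistic is
Kendall's $S = \sum_{i<j} \mathrm{sign}(x_j - x_i)\,
\mathrm{sign}(r_j - r_i)$, with $\tau_b$ its tie-corrected normalization.
One-sided p-values (enrichment of concordance) come from the exact
permutation null for series of up to 8 points, and from the normal
approximation with tie-corrected variance and a $\pm 1$ continuity
correction for longer series, including the 24-point design. The exact
small-$n$ path exists because short series sit far from the asymptotic
regime: we measured relative errors of the plain normal tail of up to
~150% at exact $p \approx 10^{-3}$ for $n \le 8$, while at $n = 24$ the
approximation is adequate and vastly cheaper than enumeration.

The scan covers periods $\{21, 24, 27\}$ h with lags stepping by 1.5 h
(half the sampling interval) over each period — 48 waveforms. The grid
brackets the 24-h photocycle on the 3-h sampling lattice; the winning
waveform supplies the period and LAG. Multiplicity is controlled twice:
the minimum p is multiplied by the number of waveforms (within-gene
Bonferroni), and gene-level p-values are multiplied by the gene count. A
gene is called rhythmic at gene-level Bonferroni $\le \alpha$, default
0.01.

Phase is reported in circadian time, $\mathrm{CT} = (\mathrm{LAG} /
\mathrm{period}) \times 24 \bmod 24$, with CT0 at lights-on. Amplitude is
the peak-to-trough range of the day-averaged 8-point profile — a
model-free estimate; no cosine fit is performed. Constant or all-zero
genes are reported with $p = 1$ rather than dropped.

# Reproducibility filter

Each 72-h series is split into its three day windows (time points 1–8,
9–16, 17–24). A gene passes when the **minimum** of the three pairwise
Pearson correlations (computed on raw values) exceeds `rMin = 0.7` and its
window dispersion is below `msdMax = 0.9`. The minimum is the strictest
aggregation of "correlation between two windows"; a mean-aggregation
switch exists. Dispersion is implemented as the mean squared point-wise
deviation between matched window points of the 0–1 scaled profile: a
literal *signed* mean deviation can cancel to zero for anti-correlated
days and cannot measure dispersion, so the squared form is the only
reading consistent with its purpose. Because of this the numeric threshold
0.9 should not be assumed to transfer exactly to other dispersion
definitions. An undefined correlation (a constant window) fails the
filter; an ortholog group is retained only if every member in every
species passes.

# Cross-species K-means and the choice of k

Profiles are scaled to $[0,1]$ per gene (constant genes map to 0.5 and are
flagged) and clustered jointly across species with distance
$d(x, c) = 1 - \mathrm{cor}(x, c)$. Internally rows are centered and
normalized so the assignment step is a matrix product; centers are
recomputed as member means and re-normalized, which is the optimal center
under correlation distance, so the objective $\sum_g d(x_g, c_{a(g)})$ is
non-increasing (a tested invariant). Initialization is a seeded
farthest-first traversal (the classical algorithm is
initialization-sensitive and we require determinism given a seed); empty
clusters are re-seeded from the point farthest from all centers. The
iteration cap defaults to 2000.

Maize-style homeologs are clustered independently, but only the
single-copy species pair (sorghum–foxtail millet in the default design)
enters the co-clustering statistic: the fraction of syntenic pairs whose
members share a cluster. Its chance level is estimated by shuffling
cluster labels within species (100 permutations): for $k$ equal clusters
the null ratio is $\approx 1/k$, so the expected/observed ratio is an
FDR-like measure of how much co-clustering chance explains. `selectK`
scans $k = 2..24$ and picks the smallest $k$ where the observed ratio's
relative decline falls below 2% (a plateau); a fixed biologically
motivated override (`fixedK`, e.g. $16 = 2$ patterns $\times$ 8 daily time
points) is available, since on real-scale data plateau rules and
biological granularity arguments can legitimately differ. Cluster phases
are summarized by the circular median on the 24-h clock (an ordinary
median misbehaves across midnight).

# Promoter motif enrichment

All $4^k$ motifs for $k \in \{6,7,8\}$ are counted in each 1-kb promoter
by a sliding window on the forward strand (promoters are directional
upstream windows, and known diurnal elements are strand-specific;
reverse-complement scanning is deliberately off by default). Windows
containing N never match. Gene-level **presence/absence** populates the
2×2 tables — this keeps margins equal to gene counts; an
occurrence-weighted reading would conflate copy number with prevalence.
The background for a cluster is all clustered genes of the same species in
the *other* clusters.

Per species, enrichment is the one-sided Fisher exact p (upper
hypergeometric tail). Across species, the strata are combined by the CMH
statistic
$$\chi^2_{CMH} = \frac{(|\sum_s (a_s - E_s)| - \tfrac12)^2}{\sum_s V_s},
\qquad E_s = \frac{(a_s+b_s)(a_s+c_s)}{n_s},$$
with the usual hypergeometric variance $V_s$ and a chi-square(1) upper
tail. The continuity correction is applied literally (note
`stats::mantelhaen.test` skips it when $|\sum(a-E)| < 1/2$; the two agree
everywhere else, which the tests exploit by restricting that cross-check
to its shared domain). Strata with $n_s < 2$ or an empty cluster are
skipped. Stratification is the methodological point: a motif enriched in a
pooled table only because one GC-rich species dominates a cluster is
balanced within each stratum and is not flagged by CMH, while a genuinely
shared element keeps full power — both directions are exercised by the
test suite.

The FDR is empirical: cluster labels are re-drawn `nPerm = 100` times and
the CMH grid recomputed. Two shuffle modes exist. `within_species`
permutes labels independently inside each species. `across_species` (the
default, and the stricter control) permutes pooled gene identities into
the fixed per-species cluster slots, so promoters cross species boundaries
and the null also absorbs background-composition differences. For each
(motif, cluster), with the family being all motifs of that width in that
cluster, $\widehat{\mathrm{FDR}}(t) = \overline{\#\{S^{perm} \ge t\}} /
\#\{S^{obs} \ge t\}$ at $t$ = the observed statistic, capped at 1;
significance is FDR < 0.05. Significant motifs are annotated against a
curated catalog of diurnal cis-elements (evening element core AATATC and
full AAATATCT, CBS AAAAATCT, ME CCACAC, TBX AAACCCT, SBX AAGCCC, SORLIP1
GCCAC, UP1ATMSD GGCCCA) by exact match, containment, or end-overlap of at
least min(width) − 1 identical bases.

A calibration note: the continuity-corrected CMH p-values are
*conservative* under the null by construction (their mean is ~0.56 in our
null simulations), which is the intended behavior for discovery. When the
sampling distribution itself is being checked for uniformity, the
uncorrected statistic (`correct = FALSE`) is the right object, and that is
what the calibration test uses; the FDR calibration check uses the
corrected default.

# The synthetic-data generator

`simulateDielData` draws ortholog groups (one gene per species, with a
configurable fraction carrying two homeologs in the last species),
expression, and promoters. Rhythmic genes follow
$$y(t) = \Big(b + \tfrac{A}{2}\cos\big(2\pi (t - \ell)/T\big)\Big)
e^{\varepsilon_t} + \delta_{d(t)}, \qquad
\varepsilon_t \sim N(0, \sigma^2),\;
\delta_d \sim N(0, \sigma_{day}^2),$$
clipped at zero, with $\ell = \mathrm{CT} \cdot T / 24$; arrhythmic genes
are baseline × noise. The multiplicative log-normal noise matches
nonnegative FPKM-like data and makes $A$ = peak−trough directly
controllable; the additive day offset, shared by the 8 samples of a day,
is exactly the failure mode the reproducibility filter screens.
Configurations where the trough could clip more than tangentially
(max amplitude/2 > min baseline) are rejected. Orthologs share the group
phase (jitter defaults to 0 h — the within-group phase concordance of real
orthologs is unknown, so the default is the clean case and the jitter is
an explicit free parameter); second homeologs draw an independent
amplitude attenuation uniform on [0,1], so silent paralogs occur.

Defaults, chosen once as a realistic desk-scale stand-in: phases
concentrate on CT 9–18 with weight 0.75 (the afternoon/evening bias of
diurnal transcriptomes); baseline 8–12 FPKM and amplitude 14–16, i.e.
relative amplitudes 0.6–1 as seen in robustly cycling genes; noise
$\sigma = 0.15$; day effect 0.5 FPKM; 20% homeolog duplication; period
24 h. Promoters are i.i.d. draws from per-species base compositions
(uniform, GC-rich 0.2/0.3/0.3/0.2, AT-rich 0.3/0.2/0.2/0.3) of length
1000; planted elements overwrite the underlying bases (no length change),
one placement per promoter, with probability 0.4 upstream of in-phase
genes and 0.05 elsewhere for the default evening element. Chance
background occurrences are left in place — tests must tolerate them, as
real scans do.

What the generator does **not** emulate: read-level sampling noise,
alignment and FPKM-normalization artifacts, linked (non-i.i.d.) promoter
sequence such as repeats or CpG-like structure, positional preferences of
real elements, correlated expression between non-orthologous genes, and
unequal per-species gene counts beyond homeolog duplication. Passing
tests therefore demonstrate that the *procedures* behave as specified
under their stated noise model, not that the biological effect sizes of
any particular real data set will reproduce.

# Numerical and design choices

- Reference cosine values are rounded to 9 decimals so symmetric samples
  tie exactly and tie corrections engage deterministically.
- p-values are floored at the smallest positive double and capped at 1;
  minimum-p ties across waveforms resolve to the first (lowest period,
  then lowest lag).
- The co-cluster plateau tolerance (2% relative drop) and the FDR
  threshold-ratio estimator are declared conventions; the upstream
  literature states neither precisely.
- All randomness flows from explicit integer seeds; each generator stage
  and pipeline stage derives its own substream, and identical
  config + seed reproduces byte-identical outputs (a tested invariant).
- Desk-scale problem sizes used by the test suite and the acceptance
  script (hundreds of genes per species, 1-kb promoters, 100
  permutations) were chosen so every stage, including the 65,536-motif
  8-mer grid, runs on a laptop-class single core; the pooled presence
  matrix for the 8-mer grid at 600 genes/species is ~1 GB, which bounds
  the practical promoter-set size more than CPU time does.

# Known limitations

- The normal approximation for Kendall's S at $n = 24$ is conservative in
  the extreme tail; with the double Bonferroni this costs power for
  marginal rhythms (relative amplitude below ~0.5 at noise 0.2 is largely
  undetectable at desk scale). This mirrors the behavior of the
  rank-based family the test belongs to.
- K-means with correlation distance finds one local optimum per seed;
  determinism is guaranteed, global optimality is not.
- The plateau rule for k is scale-sensitive: on small simulations with a
  concentrated phase distribution the observed ratio can plateau
  immediately, choosing a small k; the `fixedK` override exists for
  exactly this reason.
- The permutation FDR estimator is a ratio of tail counts and is capped
  at 1; it is accurate near the significance boundary but coarse deep in
  the null.
- Promoter scanning is exact-match only: no PWMs, no IUPAC degeneracy, no
  reverse strand by default, and the known-element catalog is the eight
  curated diurnal elements above, not a motif database.
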