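---
title: "Region-level methylome analysis with methscape: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-level methylome analysis with methscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) measures, at every cytosine, how
many reads support methylation versus non-methylation. Two region-level
questions dominate comparative methylome studies of grouped samples
(tissues, cell types, brain regions):

* **Differential methylation** — where do *groups* differ in mean
  methylation? These are DMRs (kilobase scale) and *blocks* (tens of
  kilobases, small shifts).
* **Inter-individual variability** — where do *individuals within one
  tissue* differ? These are variably methylated regions (VMRs), a distinct
  signal: a VMR need not differ between tissues at all.

Per-CpG counts are too noisy at 10–30x coverage to answer either question
locus by locus, so both analyses operate on *smoothed* methylation: the
assumption is that true methylation varies smoothly along the genome, so
information can be borrowed from neighboring CpGs.

`methscape` implements the full path from Bismark-style cytosine reports to
scored region sets: smoothing, DMR/block calling with permutation
family-wise error control, the VMR procedure (SD cutoff, CpG-count and
Cook's-distance filters, cross-tissue sharing), CpX-resolution feature
enrichment, and a seeded simulator of the whole study design that provides
ground truth for validating every stage.

## Smoothing

`smooth_methylation()` fits, per sample and locus, a local polynomial
(degree 2 by default) of the raw fractions $M/\mathrm{Cov}$ against genomic
position, weighted by a tricube kernel in scaled distance multiplied by
read coverage. The window at a locus is the smallest symmetric half-width
$h$ satisfying **both** a minimum width and a minimum locus count:

| preset     | min width | min loci | intended use                     |
|------------|-----------|----------|----------------------------------|
| `cg_small` | 1 kb      | 70 CpGs  | CG-DMRs, VMRs                    |
| `cg_block` | 20 kb     | 500 CpGs | long blocks of small differences |
| `ch`       | 3 kb      | 200 CpA/CpT | strand-specific non-CpG (mCH) |

The `cg_block` and `ch` constraints are the published constraints of the
smoothing-based DMR family this package follows; for `cg_small` the
published analyses state only the 70-CpG count, and the 1-kb width floor is
the customary default of that family (recorded here as an assumption).
Choices the method family leaves open, fixed here and configurable:

* **Kernel and degree.** Tricube, local degree 2 — the classical
  local-likelihood smoother configuration. Degree falls back gracefully
  (2 → 1 → 0) when a window holds too few covered loci for the polynomial.
* **Weights.** Raw coverage (a locus with 20 reads carries twice the weight
  of one with 10). Whether the original analyses weighted by coverage or a
  variance-stabilized quantity is not recoverable; coverage weighting is
  the simplest faithful choice. Weights only enter as ratios, which gives
  an exact invariance used in the tests: scaling all counts by a constant
  leaves the fit unchanged.
* **Edges.** At chromosome ends the symmetric window simply truncates
  one-sidedly (the locus-count rule keeps pulling loci from the open side).
* **Degenerate windows.** Zero-coverage loci receive the neighborhood fit;
  a window with no covered locus at all yields a missing value, which
  propagates (downstream statistics drop missing values locus-wise).
* Fits are clamped to $[0, 1]$.

## DMR calling and permutation FWER control

At each locus, a one-way ANOVA F statistic compares smoothed methylation
across $k$ groups ($F = t^2$ identically for $k = 2$; the two-group path
segments on the signed $t$ with constant sign). Candidate regions are
maximal runs of consecutive loci with statistic at or above an entry
cutoff, split where neighboring loci are more than `max_gap_bp` apart, and
scored by `areaStat` (sum of locus statistics) and `maxStat` (maximum).

The published analyses inherit their locus cutoff from earlier work without
printing it; `methscape` defaults to the genome-wide 99th percentile of the
locus statistic — scale-free, reproducible on synthetic data, and
re-computed inside every permutation so that the permuted pipeline is fully
exchangeable with the observed one. Gap defaults are 300 bp (`cg_small`),
10 kb (blocks), 1 kb (CH); the published analyses do not state theirs.

Family-wise error control is maxT-style: each of $B$ random relabelings of
the samples re-runs the entire locus-statistic + segmentation pipeline, and
the maximum $|$`areaStat`$|$ per permutation forms the null. A region's
$p$-value uses the add-one estimator $(1 + \#\{\text{perm maxima} \ge
|\text{areaStat}|\})/(B+1)$, which cannot be zero and keeps
$\Pr(p \le \alpha) \le \alpha$ under exchangeability. For small two-group
designs `exhaustive = TRUE` enumerates all label assignments instead.
Infinite locus statistics (zero within-group variance) are capped at the
largest finite value before segmentation so `areaStat` stays finite.
Permutations ignore donor structure: in the simulated designs donors appear
once per tissue, so labels are exchangeable under the null.

Pairwise annotation marks a region with every group pair whose region-mean
methylation differs by at least `delta_min` (default 0.1), and
`select_discriminatory()` keeps regions whose every annotated pair contains
one common group — regions that single out one group against the rest —
sorted by `maxStat` with optional per-group caps.

## The VMR procedure

1. **Coverage filter** (raw counts): keep loci with coverage strictly
   greater than `min_cov` in strictly more than `min_samples` samples
   (mirroring the "> 5 reads in > 100 samples" form of rule; the default
   `min_samples` scales as 55% of the design).
2. **Per-tissue SD** of smoothed methylation across that tissue's samples
   (n−1 denominator). Smoothed values are the analysis currency; a raw
   fraction variant is a documented alternative, not the default.
3. **One shared cutoff**: the minimum over tissues of each tissue's 99th
   percentile of SD (type-7 linear interpolation — quantile definitions
   matter at the 99th percentile and are therefore pinned). A single
   cutoff lets more-variable tissues yield more VMRs instead of taking a
   fixed top fraction per tissue. A cutoff of 0.095 corresponds to a
   ±2 SD span of 0.38 — a 38% methylation difference.
4. **Run calling**: maximal runs of loci with SD strictly above the
   cutoff, gap limit 300 bp (unstated in the published analyses), keeping
   runs with more than 10 CpGs.
5. **Cook's-distance filter**: for each VMR, the per-sample region means
   $y_i$ within the tissue are fit intercept-only; Cook's distance
   $D_i = e_i^2 h / (p s^2 (1-h)^2)$ with $h = 1/n$, $p = 1$. A VMR whose
   maximum $D_i$ exceeds 0.7 is *removed* as driven by a single sample
   outlier rather than population variability. (The published filter
   sentence reads literally as keeping such VMRs; its stated purpose — "to
   remove VMRs driven by sample outliers" — forces the reading implemented
   here.) The intercept-only model is the minimal model for "sample
   outlier relative to the tissue mean"; whether the original analysis
   used a per-CpG or per-region model is unstated, so this choice is
   documented rather than asserted. All-equal means give $D = 0$
   (retained); fewer than 3 samples is rejected with a diagnostic.
6. **Effect size**: the range of per-sample, across-region average
   methylation.
7. **Sharing**: retained VMRs from all tissues are union-merged (≥ 1
   shared bp, transitively); each merged interval is `tissue_specific`
   (one member tissue), `ubiquitous` (all tissues), else `shared`. The
   number of merged intervals is the number of unique VMRs.

A consequence worth knowing: the Cook's threshold of 0.7 implies the
per-sample residual rule $|e|_{\max}/s > \sqrt{0.7\,(1-1/n)^2 n}$, which
for $n = 5$ removes a third of genuinely Gaussian-variable regions but for
$n \ge 12$ removes only ~1–2%. The filter is calibrated for designs with
roughly a dozen or more samples per tissue — the scale of the multi-donor
study it comes from — and the simulator's default of 12 donors per tissue
reflects that.

## Enrichment

Region sets are tested for enrichment in genomic features at CpX
resolution: every cytosine of the relevant context is classified by region
membership and feature membership (point-in-interval on the cytosine
coordinate), giving a 2×2 table. Counting cytosines rather than regions or
bases accounts for their non-uniform genomic distribution. The estimate is
the closed form

$$\log_2 \mathrm{OR} = \log_2 n_{11} + \log_2 n_{22} - \log_2 n_{12} -
\log_2 n_{21}, \qquad
\mathrm{se} = \sqrt{1/n_{11} + 1/n_{12} + 1/n_{21} + 1/n_{22}},$$

with the approximate 95% interval $\log_2 \mathrm{OR} \mp 2\,\mathrm{se}$
and a two-sided Fisher exact $p$. The SE formula is applied verbatim as
published; note it is formally the delta-method SE of $\ln \mathrm{OR}$,
so the intervals are a factor $\ln 2$ narrower than a strict log2-scale
derivation would give. Zero cells make the estimate undefined and are
flagged, never silently patched (no continuity correction is applied by
default; `haldane = TRUE` exists as an explicit variant). Batch runs adjust
Fisher $p$-values by Benjamini–Hochberg across features within one region
set — the multiplicity handling of the published enrichment panels is
unstated, so this is a package decision — and can average $\log_2$ OR
within annotation groups (multi-state chromatin annotations are one
feature set per state, averaged only for reporting).

## The synthetic study design

`simulate_wgbs()` generates the full multi-tissue, multi-donor design that
the pipeline is validated on. Per locus $\ell$ and sample $s$:

$$\pi_{\ell s} = \mathrm{clamp}\big(\mathrm{baseline}(\ell)
 + \Delta \cdot [\text{s's group affected}]
 + b_s \cdot [\ell \in \text{VMR}]
 + \text{genotype and outlier terms},\; 0, 1\big)$$

with coverage $\mathrm{Cov} \sim \mathrm{Poisson}(\lambda)$ and counts
$M \sim \mathrm{BetaBinomial}(\mathrm{Cov}, \pi, \rho)$. Defaults and what
they emulate:

* **Design**: 5 tissue groups × 12 donors (donors shared across tissues,
  as in a multi-tissue donor cohort of 12–24 individuals per tissue);
  2 chromosomes × 2 Mb carrying ~40,000 CpGs — sized so a full analysis
  runs in seconds and a 200-replicate calibration in minutes.
* **CpG landscape**: dense CpG islands (mean spacing 10 bp, 1 kb wide,
  10/Mb, baseline 0.10) over an open sea (mean spacing 110 bp, baseline
  0.85, per-locus jitter SD 0.03) — the bimodal methylome.
* **Coverage** $\lambda = 12$, the scale of a >10x post-processing WGBS
  study. **Dispersion** $\rho = 0.02$: beta-binomial, not binomial,
  because inter-individual epigenetic noise is precisely what the VMR
  analysis measures; ambient dispersion makes the null realistic.
* **DMRs**: 10 regions of 15–35 CpGs, group mean shift Δ = 0.3 directed
  toward the far side of the unit interval (so the shift survives
  clamping). **Blocks**: 2 × ~30 kb, Δ = 0.08. The DMR count keeps the
  planted differential signal (with its smoothing spillover) inside the
  ~1% candidate budget that the quantile entry cutoff admits — the same
  coherence constraint as the VMR abundance.
* **VMRs**: per-sample level shifts $b_s \sim N(0, 0.12^2)$ drawn once per
  (sample, region) — variability is regional, matching the region-level SD
  definition. Planted VMRs span 40–60 CpGs, about the small smoothing
  window: that window is the caller's resolution scale, and narrower
  variability is attenuated by smoothing (a documented limitation, not a
  bug). Their abundance (~0.75% of loci per tissue: 4 tissue-specific + 1
  ubiquitous + 1 genotype-driven region) keeps the genuinely variable
  fraction just under the 99th-percentile cutoff, which is how the cutoff
  rule behaves on real methylomes where the top SD percentile is dominated
  by true variability.
* **Genotype-driven regions**: a biallelic SNP per region (MAF 0.3),
  donor genotypes shifting methylation by effect/2 per minor allele —
  trimodal across genotypes and automatically shared across tissues of a
  donor.
* **Outliers**: one designated sample shifted by 0.5 in 3 regions —
  pseudo-VMRs that the Cook's filter must remove.
* $\pi$ values at exactly 0 or 1 emit deterministic counts (the
  beta-binomial degenerates there).

What the generator does **not** emulate: read-level artifacts (no FASTQ,
no mapping bias, no bisulfite-conversion failure), sequence context beyond
spacing statistics, regionally correlated ambient noise (ambient
dispersion is locus-independent, so smoothed null variance is lower than
on real data), and chromosome-scale features (no X/Y, no centromeres).
Passing recovery tests therefore demonstrates the pipeline's correctness
and calibration under its own model, not performance on real tissue.

The CpA forward-strand track (optional) uses a low baseline (0.03) with
planted elevated regions — the non-CpG methylation pattern of neurons —
and the same emission model. The non-CpG pipeline is the same code run per
strand/dinucleotide stratum with the `ch` preset; CpG strand collapsing
(palindromic, counts summed at the forward-strand C) does not apply there.

## Problem sizes used in validation

The acceptance experiments run at the sizes the calibration claims refer
to: 200 null replicates of the 5 × 5 design (~40k CpGs, B = 50
permutations) for family-wise error, two seeded replicates of the default
planted design for DMR and VMR recovery, and 40 single-tissue replicates
for outlier-removal frequency. On one CPU the full suite runs in roughly
a quarter of an hour.

## Known limitations

* No locus-wise variance moderation or shrinkage: plain ANOVA on smoothed
  values. This is a deliberate deviation from callers that smooth local
  variances; the permutation null absorbs the locus-wise variance
  heterogeneity that moderation would address.
* The 99th-percentile entry cutoff makes DMR candidates depend on the
  genome-wide statistic distribution; with very abundant true signal
  (>1% of loci) the cutoff rises and weak regions are missed. The same
  applies to the VMR cutoff, which is the point of its design.
* The Cook's filter is ill-suited to tissues with fewer than ~8 samples
  (see above); `cooks_filter()` reports a diagnostic rather than
  silently passing such designs.
* Non-CpG strata are analyzed independently per strand/dinucleotide; no
  cross-stratum information sharing. CpC strata are supported but off by
  default (published analyses enumerate four CA/CT strand runs).
* Exhaustive permutation is implemented for two-group designs only.

## A minimal session

```{r example}
library(methscape)

sim <- simulate_wgbs(sim_config(), seed = 1)
d   <- sim$datasets$CG
sm  <- smooth_methylation(d, smoothing_preset("cg_small"))

dmrs <- permutation_fwer(sm, sim$samples$group, B = 100, seed = 2)
vmrs <- find_vmrs(d, sm)
sharing <- classify_sharing(vmrs$vmrs)

feat <- feature_set("islands", d$chrom, d$pos - 1L, d$pos)  # toy feature
enrich_batch(data.frame(chrom = d$chrom, pos = d$pos),
             dmrs$regions[dmrs$regions$significant, ], list(feat))
```

Or, driven by one configuration:

```{r pipeline}
cfg <- list(analysis = "demo", seed = 11,
            simulate = list(samples_per_tissue = 5L),
            dmr = list(B = 50L))
res <- run_pipeline(cfg, "demo_out")
```
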