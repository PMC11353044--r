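---
title: "Modelling genetic drift in long-term pluripotent stem-cell culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling genetic drift in long-term pluripotent stem-cell culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemdrift)
```

## The problem

Human pluripotent stem cells accumulate genetic changes during extended
in vitro culture. Two processes dominate. First, a small set of recurrent
chromosomal abnormalities — gains of 20q11.21 (driver gene *BCL2L1*),
distal 1q (*MDM4*), chromosome 12, 17q, and loss of 18q — confer a
per-passage growth advantage, so a single mutant cell can sweep the
culture within tens of passages. Second, point mutations in
cancer-associated genes arise at an approximately constant per-passage
rate; most are neutral passengers, and whether they become detectable
depends on the clonal dynamics around them, not on a changing mutation
rate. The observable consequence is a *cumulative-load-not-rate*
signature: later samples carry more variants, while the per-passage
probability of acquiring a new one stays flat.

`stemdrift` implements the analysis stack that measures these dynamics
from two routine assays — shallow (~0.1×) whole-genome sequencing binned
at 50 kb for copy number, and a deep (~1500×) cancer-gene panel for
SNVs — plus a serial-passage clonal-evolution simulator that generates
ground-truth cultures so every stage is testable without access to raw
sequencing data.

## The serial-passage simulator

A culture is a collection of clones with genotypes built from discrete
mutation events. Each passage applies three steps:

1. **Selection.** Clone fractions are reweighted by fitness
   $w_i \propto f_i \prod_e (1+s_e)$ over the clone's events. Recurrent
   driver CNVs carry $s = s_\mathrm{recurrent}$; rare CNVs and SNVs are
   neutral by default.
2. **Drift.** The culture is resampled multinomially at the bottleneck
   size $N$ (default 200), modelling the effective population surviving
   a 1:10–1:100 split. Within-passage cell-division granularity is not
   modelled: the observables are per-passage snapshots.
3. **Mutation.** Each surviving clone spawns a child clone carrying one
   new event with constant per-passage probabilities
   ($p_\mathrm{cnv,rec}$, $p_\mathrm{cnv,rare}$, $p_\mathrm{snv}$). A
   child starts as a single cell ($1/N$ of the culture).

Simulations are bit-reproducible: one master seed, with per-line and
per-render substreams derived by stable hashing of
(line id, passage, purpose).

### Why these defaults

No per-passage mutation probability is directly measurable from a
cultured line, so the defaults are order-of-magnitude choices pinned to
the cohort profile the method is meant to reproduce:

* A new driver clone survives early drift with probability roughly
  $2s/(1+s)$ and then needs $\log(N)/\log(1+s)$ passages to take over.
  With $s = 0.5$ and $p_\mathrm{cnv,rec} = 0.05$ per clone-passage,
  most 50-passage lines experience a completed takeover — matching the
  reported ~80% prevalence of 20q/1q gains and the observation that
  takeovers complete within tens of passages.
* $p_\mathrm{snv} = 0.15$ yields on the order of 2–3 *detectable* de
  novo SNVs per line by passage 50. Detectability is the bottleneck: a
  neutral SNV reaches the panel's 3% allele-fraction floor mainly by
  hitchhiking inside an expanding driver clone, which is also why de
  novo SNVs concentrate in karyotypically abnormal samples. Observed
  per-line counts in long-term culture studies are about 1–5.
* Germline variant counts are drawn from 6–17 per line with ~2%
  homozygous, the printed range for hESC panels of this size.
* `snv_rate_multiplier_given_driver` (default 1) lets users simulate a
  genuine mutator effect of driver CNVs, as opposed to the pure
  hitchhiking association present at the default.

### Rendering

Coverage: expected bin count is
$\mathrm{base} \times \tfrac{1}{2}\sum_i f_i\,\mathrm{CN}_i(\mathrm{bin})
\times \mathrm{bias}(\mathrm{GC})$, drawn negative-binomially with
dispersion 0.002 (variance $\mu + 0.002\mu^2$; coefficient of variation
≈ 10% at the default 100 reads/bin, typical of 0.1× sequencing in 50 kb
bins). The GC-bias curve is a smooth quadratic peaking at GC = 0.45 with
20% amplitude, user-overridable; `dispersion = 0` gives the
deterministic limit used in exactness tests.

Variants: the true allele fraction is the clone-fraction-weighted
mutant-copy dosage over total copy dosage — the many-clone
generalisation of the expected-AF model below, with haplotype-aware
copy counts (a duplication raises the AF of alleles already on the
duplicated haplotype; copies acquired before a somatic variant do not
carry it). Alt reads are Binomial(depth, AF) at Poisson-distributed
site depth around 1500×. Rendered AFs below 0.5% are dropped: real
panels cannot see low-grade mosaicism, and neither should the
simulator's output.

### What the simulator does not emulate

Read-level artifacts (mapping, strand bias, GC waves beyond the smooth
curve), microsatellite/indel error modes, sample cross-contamination,
culture-condition effects on rates, and back-mutation. Passing tests
therefore certify the analysis logic under idealised noise, not
robustness to every failure mode of real libraries.

## Copy-number calling from shallow coverage

The caller follows the classic shallow-WGS recipe: GC correction, then
per-bin scores, then run-based segmentation.

* **GC correction** fits median count within GC deciles, interpolates
  between stratum medians, divides, and renormalises the autosomal
  median to 1. Self-normalisation (no panel of normals) means
  whole-genome ploidy shifts are invisible by construction. Fewer than
  3 populated GC strata triggers a logged fallback to global median
  normalisation.
* **Scores**: fold change (reference 1 = diploid), log2 ratio (fold
  change floored at a pseudocount of 0.5/median raw count), and
  $z = (\mathrm{fc}-1)/\hat\sigma$ with $\hat\sigma$ the MAD (×1.4826)
  of autosomal fold change. A zero robust scale is a degenerate input
  and errors rather than emitting infinite scores.
* **Segmentation**: maximal runs of bins beyond ±z-threshold (default
  3), allowing interruptions up to 2 bins that do not qualify in the
  opposite direction, kept when spanning ≥ 10 bins. With 50 kb bins
  that is a 0.5 Mb floor — below the smallest recurrent abnormality of
  interest (~0.7 Mb) and above single-bin noise. Breakpoints are the
  outer boundaries of the first/last qualifying bins, so clonal events
  are recovered to ±1 bin; at ~10% bin noise a long segment's edge bin
  occasionally dips under threshold, the dominant residual error mode.
* **Sex chromosomes** are excluded from scale estimation and default
  calling: line sexes differ and self-normalisation does not model
  X/Y dosage.
* **Annotation**: a segment is labelled with a recurrent abnormality
  when it overlaps the catalog entry's *driver locus* with matching
  direction; anything else is a rare CNV. A sample is karyotypically
  abnormal iff at least one segment is called.

Deliberately out of scope: CBS/HMM segmentation, allele-specific copy
number, and subclonal fraction estimation from coverage alone.

## The SNV retention cascade

Five independent predicates, each tallied separately: population
frequency ≤ 1% in every database (gnomAD, 1000 Genomes, ESP6500 — a
variant common in *any one* is removed, the conservative reading);
allele fraction ≥ 3% unless the site is a hotspot (hotspots are kept at
any AF because panels validate them below the general floor); facility
recurrence ≤ 0.01% (pipeline artifacts recur across unrelated samples);
≥ 25 alt reads; and exclusion of *CDC27* (pervasive pseudogene
contamination). An optional user-supplied exclusion region list stands
in for manual review of repeat and microsatellite artifacts. The
deleteriousness flag is consumed (SIFT-style, precomputed), never
computed. Because the rules are independent, the retained set is
order-invariant and monotone in every threshold.

## Germline versus de novo, trajectories, zygosity

With multiple samples per line, origin is defined operationally:
detected at the line's earliest tested rank ⇒ germline, otherwise de
novo with the first detection rank recorded. Single-rank lines are
ambiguous and excluded from origin statistics. "Detected" means
surviving the cascade in that sample, so a variant dropping below the
floor is "absent" — true loss and sub-threshold mosaicism are
indistinguishable at panel sensitivity. The one systematic error mode
is a somatic event that pre-dates the first sampled passage and is
detected from rank 1 onward: it is necessarily called germline, a
limitation of any multi-passage design rather than of the classifier
(the simulator tests assert that all misclassifications are of exactly
this kind).

Trajectories compare the first and last detected AF with threshold
δ = 0.15, an order of magnitude above binomial AF noise at 1500×
(σ ≈ 0.013); `lost` means absent at the final rank after detection.
Zygosity: heterozygous within 0.10 of AF 0.5 at copy number 2;
homozygous at AF ≥ 0.90; otherwise `cn_adjusted` when the AF matches
some expected value achievable at the local copy number.

## The expected-AF model

For a mutant clone at fraction $f$ with $c$ copies of a locus, $m$ of
them mutant, over a diploid background with $m_0$ mutant copies:

$$\mathrm{AF} = \frac{f\,m + (1-f)\,m_0}{f\,c + 2(1-f)}$$

At $f=1$ this is $m/c$: a germline heterozygote whose haplotype was
duplicated sits at 2/3 (observed as ~0.7 in practice), and a de novo
variant present as a single copy in a triplicated locus at 1/3
(observed ~0.25 when the carrying clone is sub-clonal). `match_af()`
grid-searches $m \in [0,c]$, $m_0 \in \{0,1\}$ and
$f \in \{0.1,\dots,1\}$ and flags an observed AF as CNV-explained
within a tolerance of 0.10 — loose on purpose, mirroring how such
matches are argued qualitatively; the $f$ grid is what reconciles 0.25
with the analytic 1/3. Copy number at a variant locus comes from the
single overlapping called segment (2 when none overlaps), via
$\mathrm{CN} = \mathrm{round}(2 \cdot 2^{\overline{\log_2 r}})$.

## The statistical layer

* **Fisher's exact test** (2×2, two-sided) sums hypergeometric
  probabilities of all tables at the observed margins whose probability
  does not exceed the observed table's, with relative slack $10^{-12}$
  against ties lost to floating point; computed in log space. This is
  the convention of mainstream statistical software, and it reproduces
  the karyotype×carriage (p = 0.0028), deleteriousness (p = 0.3842)
  and COSMIC (p = 0.1568) tables' printed p-values exactly.
* **Load** (count of de novo events present in a sample) is modelled as
  Poisson log-linear in sample rank or passage number, fitted by IRLS
  (tolerance $10^{-8}$, ≤ 100 iterations) with two-sided Wald p-values
  — the default output of the GLM software such analyses typically use;
  a likelihood-ratio alternative would change nothing qualitatively and
  Wald is what the printed p-values correspond to.
* **Acquisition** ("did this sample gain ≥ 1 new event since the
  previous rank") is binary logistic in the predictor; perfect
  separation is detected (zero residual deviance) and raised as an
  error rather than reported as an absurd slope. Rank 1 has no previous
  rank and is excluded from acquisition models.
* `refit_without_outliers()` re-runs either regression on a retained
  subset and records the excluded points, supporting the
  influential-late-passage sensitivity analysis.

Continuous predictors are the default (rank and passage are both
offered); pooling samples across lines without a line-level random
effect follows the source analyses and is a stated limitation, not an
oversight.

## Numerical and design choices worth knowing

* Coordinates are 0-based half-open internally; VCF emission is
  1-based; BED stays 0-based; the report TSV prints 1-based starts.
* Genome builds are plain named length vectors; everything is
  build-agnostic, with hg19-style lengths and catalog coordinates
  shipped as defaults and a toy genome for fast tests.
* Segment sizes print as $(\mathrm{end}-\mathrm{start})/10^6$ rounded
  to 3 decimals, matching karyotype-report precision.
* The GC fit is exact (to $10^{-6}$) when GC takes at most one value
  per decile stratum — the construction used by the correctness tests;
  for continuous GC tracks the piecewise-linear interpolation leaves
  residuals ~$10^{-4}$, negligible against ~10% count noise.
* Degenerate inputs error loudly: all-zero coverage, zero robust scale,
  all-zero count regressions, all-zero Fisher tables, perfect
  separation.

## Problem sizes used by the test suite

Unit tests run on a 3×50 Mb toy genome; the Monte-Carlo checks use the
full hg19-scale grid (61,927 bins): 100 coverage renders for caller
recovery, 200 simulated lines for origin accuracy, and 200 replicate
cohorts of 10 lines × 3 ranks for the load/rate signature — sizes chosen
to hold binomial uncertainty on the asserted rates to a few percent
while keeping the default suite a few minutes long. The acceptance
script re-runs the same computations at 100 lines / 100 cohorts.

## Worked example

```{r example, eval = FALSE}
p <- sim_params(seed = 7)
cohort <- simulate_cohort(10, p)
man <- write_cohort(cohort, "cohort-dir", seed = 7)
bundle <- run_pipeline(man, pipeline_config(), out_dir = "results-dir",
                       seed = 7)
bundle$association            # karyotype x de novo carriage
bundle$stats$poisson_load_rank
bundle$stats$logistic_acquisition_passage
```

## Known limitations

Self-normalised coverage cannot see balanced whole-genome ploidy
changes; the caller's threshold rule has no subclonal sensitivity below
~60% clonal fraction for single-copy gains at default noise; origin
classification is blind before the first sampled passage; the
hotspot list, recurrence frequencies and deleteriousness calls are
consumed as annotations and are only as good as their sources; and the
simulator's constant-rate assumption is the null model of interest, not
a law — users probing rate changes should vary the per-passage
probabilities explicitly.
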