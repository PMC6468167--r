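---
title: "Methods: simulating and calling oxidative-stress-induced LOH in a hybrid diploid yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and calling oxidative-stress-induced LOH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxloh)
```

## The biological system and the measurement

Hydrogen peroxide damages DNA and, in a diploid budding yeast, the repair of
that damage by homologous recombination between homologs produces loss of
heterozygosity (LOH). In a hybrid diploid whose two parental haplotypes
(here labelled W and Y) differ at thousands of single-nucleotide
polymorphisms, LOH is measurable genome-wide with allele-specific SNP
microarrays: each marker carries oligonucleotides for both alleles, and the
normalized two-colour hybridization ratio of experimental DNA against a
fully heterozygous control clusters near 0.3, 1.0 and 1.5 for zero, one and
two copies of an allele. `oxloh` implements the full analysis chain for this
assay — simulation, copy-state calling, segmentation, event classification,
and the associated rate and enrichment statistics — so that every stage can
be exercised and validated without any array data.

A colony that experienced a reciprocal crossover at its first division
appears as a red/white sectored colony in the *SUP4-o*/*ade2-1* marker
system; the two sectors are the two daughter lineages, and comparing their
marker states distinguishes recombination mechanisms:

* a **crossover (CO)** gives reciprocal terminal LOH — one sector
  homozygous W, the other homozygous Y, distal of the exchange point;
* **break-induced replication (BIR)** gives copy-neutral terminal LOH in
  one sector only;
* a **gene conversion (CON)** gives an interstitial tract without terminal
  LOH;
* whole-chromosome changes appear as **trisomy**, **monosomy**, or
  copy-neutral **uniparental disomy (UPD)**.

Within a conversion tract, summing haplotype copies over the two sectors
distinguishes **3:1** tracts (three copies of one haplotype among the four
chromatids of the two daughters) from **4:0** tracts (both daughters
homozygous for the donor). A 4:0 region can only arise when both sister
chromatids carried the donor sequence, i.e. when the initiating
double-strand break (DSB) occurred on an **unreplicated (G1) chromosome**
and both replicated broken chromatids were repaired off the homolog. A
tract that is entirely 3:1 is consistent with a single broken chromatid (a
G2 break, or a replicated nick). This is the logic behind
`infer_initiation_phase()`.

## The synthetic-data generator

`build_genome()` produces a 16-chromosome map matching the budding-yeast
karyotype (~12,070 kb haploid) and places 15,000 heterozygous markers
uniformly at random, proportionally to chromosome length — the density of
the genome-wide array this pipeline targets. Feature tracks (Ty, LTR, tRNA,
G4 motifs, tandem repeats, high-GC windows, and a single rDNA interval on
chromosome XII) are synthesized with densities and sizes in the range of
the real elements; they exist so that the enrichment statistics have
realistic interval structure to work against, and they are *synthetic* —
no claim is made that their coordinates match the reference genome.

`plant_event()` writes each mechanism's expected daughter genotypes
directly:

* `G1_DSB_CO`: daughter 1 becomes donor-homozygous from its tract boundary
  `s1` to the telomere; daughter 2 carries a donor tract `[s2, e2]` with
  `s2 < s1 < e2` and the reciprocal haplotype distal of `e2`. The merged
  pattern has a 3:1 sub-region (`[s2, s1]`), a 4:0 sub-region
  (`[s1, e2]`), and reciprocal LOH beyond — the hybrid-tract signature of
  two independently repaired broken chromatids.
* `G2_DSB_CO`: a pure 3:1 tract next to the reciprocal exchange.
* `BIR`: terminal donor homozygosity in one daughter; the other is
  untouched.
* `CON_only`: an interstitial tract in one daughter.
* Copy-number and aneuploidy events alter one daughter; `UPD` is planted
  reciprocally, as a first-division nondisjunction.

Tract extents are drawn from a log-normal with median 13 kb — the combined
crossover-associated conversion-tract median for peroxide-treated cells —
and log-sd 1.1, giving a 10–90 percentile span of roughly 3–53 kb. Only the
median is anchored in data; the shape is a modelling choice, since tract
length distributions beyond the median are not available to this package.

`render_profile()` draws each allele's ratio from
`Normal(centroid(cn), noise_sd)` truncated at zero, with centroids 0.3,
1.0, 1.5 for 0–2 copies and a sub-linear `1.5 + 0.4 (k - 2)` extrapolation
for higher dosage (two-colour arrays compress at high copy number; the
extrapolation is needed to render amplifications beyond two copies). The
Gaussian ratio-scale noise model is deliberately simple: the real arrays'
noise is uncharacterized here, so passing round-trip tests demonstrates
correctness of the calling logic under well-behaved noise, not robustness
to spatial artefacts, dye bias, or probe-specific variance — none of which
are simulated.

### Fluctuation cultures

`simulate_fluctuation_cultures()` grows each culture from one cell by
binary divisions occurring one at a time in exchangeable random order, each
division converting one daughter with the per-division event probability.
A mutant clone founded when the population has `n` cells ends at a
geometric size with mean `N/n` — the stochastic clone-growth law under
which the Lea–Coulson median estimator is calibrated. A synchronous
generation-by-generation discretization was considered and rejected: it
compresses clone sizes onto powers of two and puts the count median ~17%
below the Lea–Coulson median, which would make the median estimator
systematically biased against its own simulator. With the asynchronous
formulation the simulated median at `m = 20` is 85 vs the theoretical 84.7,
`P(0) = e^{-m}` holds exactly, and the estimator is median-unbiased within
2% over 1,000 simulated experiments.

## Array calling

`call_pipeline()` mirrors the published two-stage procedure:

1. **Normalization** divides every allele ratio by the array-wide mean
   (`normalize_profile()`), making the profile scale-invariant.
2. **Detection** runs a 9-SNP moving average along each chromosome
   (`smooth_profile()`), calls each smoothed value to the nearest dosage
   centroid (decision boundaries at the centroid midpoints, 0.65 and 1.25
   for the diploid states), and keeps runs of at least
   `max(min_markers, (window+1)/2)` markers. The original description does
   not state how the windowed statistic was thresholded before refinement;
   flagging any crossing of a centroid midpoint, with the half-window run
   floor, is this package's reconstruction.
3. **Single-SNP refinement** re-examines the *unsmoothed* per-marker calls
   within one window of each detected boundary and places the breakpoint at
   the cut minimizing disagreement with the two flanking states. Reported
   breakpoints therefore always come from unsmoothed calls, and each is an
   open interval between the last discordant and first concordant marker —
   exactly the resolution at which transitions such as
   1,277,206–1,278,958 bp are reported for real colonies.

Runs shorter than `min_markers` (default 2, suppressing isolated marker
noise) are absorbed into the flanking state with the longer adjacent run;
ties go to the centromere-proximal flank, a stable and reproducible rule.
The detectability floor is marker-count-based: conversions spanning fewer
than two markers cannot be seen, matching the published caveat that tracts
under ~2 kb may contain no SNP.

At `noise_sd = 0.1` the per-allele miscall probability is about 1.2%
(`P(|N(0, 0.1)| > 0.25)`); smoothing removes the resulting false single- and
double-marker runs at detection, which is why the pipeline detects on the
smoothed track rather than segmenting raw calls directly.

## Event classification

`classify_sector_pair()` works per chromosome on the marker-level
combination of the two sectors' called states: markers are classed as
baseline (both heterozygous), 3:1, 4:0, reciprocal (opposite homozygous),
or copy-number-variant, and runs of these classes are parsed into events
(whole-chromosome dosage first, then CNV runs, then terminal reciprocal
runs as COs with their adjacent 3:1/4:0 runs attached as conversion
tracts, then remaining terminal tracts as BIR and interstitial tracts as
CON). Whole-chromosome calls require 90% of markers in the aberrant state,
guarding against adjacent terminal events mimicking aneuploidy.

`classify_unsectored()` applies the single-isolate rules: terminal
copy-neutral LOH is `CO_or_BIR` (the two are indistinguishable without
sectors), interstitial LOH is `CON`, and an interstitial tract from one
homolog within `adjacency_kb` (default 25 kb; the source material says only
"adjacent or close", so this is configurable) of a terminal LOH from the
opposite homolog merges into a single `CON_CO` — the unsectored signature
of a crossover with its 4:0-type conversion tract. Terminal LOH spanning
fewer than five markers is flagged `short_terminal`, mirroring the handful
of subtelomeric events that cannot be typed.

## Rates and statistics

* `sector_frequency()`: binomial frequency with Wilson 95% limits
  (Clopper–Pearson optional). Wilson reproduces the printed limits of the
  published 197/39417 and 118/36403 frequencies to their displayed
  precision.
* `estimate_rate_median()`: Lea–Coulson method of the median, solving
  `r/m − ln m = 1.24` by bracketed root-finding (tolerance 1e-8);
  confidence limits transform the order-statistic 95% interval of the
  median count through the same equation. An all-zero experiment returns a
  flagged upper bound from the zero-culture likelihood.
* `crossover_rate_from_sectors()` doubles the sectored frequency — only
  half of post-crossover segregations put the two recombinant chromatids
  in different daughters. `simulate_co_segregation()` demonstrates the
  factor directly.
* `events_per_genome()` chains the corrections explicitly: segregation
  (×2), assay-interval fraction (÷f), viability (÷v², because a sectored
  colony needs two viable daughters), and optionally the non-crossover
  doubling. The interval fraction is an explicit argument because published
  genome-fraction values for the assayed interval are not mutually
  consistent; only the viability and doubling steps are asserted in tests.
* `tract_length_stats()`: tract length is the distance between the
  midpoints of the two flanking breakpoint intervals (the measured edge is
  otherwise undefined); the 95% CL is a percentile bootstrap (default
  10,000 resamples). Published tract-length CLs computed by an unstated
  method sometimes fail to bracket their medians; this package does not
  attempt to reproduce those intervals.
* `hotspot_test()`: per-interval exact binomial tests of observed versus
  expected event share, Bonferroni-adjusted.
* `feature_enrichment()`: permutation null that re-places every tract
  uniformly on its own chromosome preserving length. The two-sided
  empirical p-value uses the symmetric-deviation form
  `(1 + #{|null − mean| ≥ |obs − mean|}) / (1 + n_perm)`: with a discrete
  overlap-count statistic, doubling the smaller tail is conservative enough
  to visibly distort null calibration, while the symmetric form keeps the
  fraction of null p-values under 0.05 near 0.05 when the count
  distribution is reasonably spread. Calibration checks therefore use a
  feature track dense enough (Ty-like) that overlap counts take many
  values.
* `rdna_expectation()`: Poisson expectation `n × fraction` and
  `P(0) = e^{-expected}` for the absence of terminal events in the rDNA.
* `compare_spectra()`: six-class chi-square on the two spectra plus
  symmetric per-class two-proportion tests.

## DSB quantification

A circular chromosome III reporter stays in the well of a pulsed-field gel
unless broken; any break linearizes it to a ~320 kb band. With breaks
Poisson on the molecule, the linearized fraction is `f = 1 − e^{−λL}`, so
`fraction_broken()` (linear-III signal over the chromosome II loading
control, normalized to the complete-linearization ratio) inverts to
`λ = −ln(1 − f)/L`, background-subtracted on the λ scale, and scales to
`λ × genome_kb` DSBs per genome (`dsbs_per_genome()`, defaults: 320 kb
circle, 12,070 kb haploid genome). The single-hit Poisson commitment — any
break linearizes, multiple breaks still enter the gel — is this package's
reconstruction of the cited ratio method, which is published without
formulas. `simulate_circular_breakage()` provides the matching generative
model; estimator and simulator agree within 3 binomial standard errors at
`λL` from 0.1 to 2 with 10⁵ molecules.

## Problem sizes and reproducibility

Every stochastic function takes an explicit integer seed and restores the
caller's RNG state; there is no hidden global state, and pipeline runs with
identical config and seed are byte-identical. The validation suite uses:
500 planted events across all mechanisms for the round-trip checks (at
noise 0 and 0.1), 10⁴ trials for the segregation factor, 60 cultures at
`m = 100` (and 1,000 experiments at `m = 20`) for the fluctuation
estimator, 10⁵ molecules per `λL` point for the breakage consistency check,
and 1,000 replicates (499 permutations each) for null calibration. These
sizes put Monte-Carlo error comfortably below the tested tolerances while
keeping a full run in a few minutes on one CPU.

## Known limitations

* No sequence-level simulation: profiles are generated at marker
  resolution, so nothing can be said about events between markers — which
  is also true of the real assay.
* The noise model is i.i.d. Gaussian per allele; correlated or
  probe-specific artefacts are out of scope, and real-data performance of
  the caller is not established by these simulations.
* Multi-step rearrangement histories (e.g. inverted triplications arising
  from microhomology-mediated BIR) are not reconstructed; the segmentation
  will report the copy-number steps but not their mechanism.
* Unsectored classification cannot type tract chromatid ratios; phase
  inference is only available for sector pairs (CON_CO events are labelled
  G1 by construction of the merging rule).
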