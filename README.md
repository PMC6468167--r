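# oxloh

Genome-wide analysis of oxidative-stress-induced mitotic recombination in a
hybrid diploid budding yeast, assayed by allele-specific SNP microarrays.

Hydrogen peroxide produces DNA double-strand breaks whose repair between
homologs causes loss of heterozygosity (LOH). In a hybrid diploid carrying
two distinguishable haplotypes (W and Y) at ~15,000 SNPs, the normalized
two-colour hybridization ratio at each allele clusters near **0.3 / 1.0 /
1.5** for **0 / 1 / 2** copies, so per-marker allele dosage — and therefore
LOH and copy-number change — can be read directly off the array. `oxloh`
implements the complete analysis chain for this assay:

* **Simulation** — a 16-chromosome, ~12 Mb diploid genome with a
  configurable heterozygous marker map; planted recombination events for
  every mechanism (G1/G2 crossovers, BIR, conversions, deletions,
  duplications, trisomy/monosomy, UPD); rendered noisy array profiles;
  Luria–Delbrück fluctuation cultures; Poisson breakage of a circular
  chromosome reporter.
* **Calling** — normalization, nearest-centroid copy-state calls, 9-SNP
  moving-window detection with single-SNP breakpoint refinement, and
  segmentation into LOH/CNV segments with breakpoint uncertainty
  intervals.
* **Classification** — red/white sector pairs are parsed into crossovers
  (with 3:1 / 4:0 conversion-tract typing and G1-vs-G2 initiation-phase
  inference), BIR, conversions, CNVs and ploidy events; single unsectored
  isolates into CON / CO-or-BIR / CON-CO / CNV / ploidy calls.
* **Statistics** — sectored-colony frequencies with Wilson limits, the
  Lea–Coulson method of the median for fluctuation rates, segregation and
  viability corrections, bootstrap tract-length medians, binomial hotspot
  tests, permutation feature-enrichment tests, rDNA Poisson expectations,
  and six-class mutation-spectrum comparison.
* **DSB quantification** — DSBs per genome from gel band intensities of a
  circular chromosome III reporter under a single-hit Poisson model.

The central identities the statistics are built on: the crossover rate is
**twice** the sectored-colony frequency (half of chromatid segregations
hide the event); observed crossover counts `n_co` among unselected events
correct to `2·n_co`, with `n_co` subtracted from the apparent conversions;
events per genome from a frequency `F` over an interval covering fraction
`f` of the genome at viability `v` are `(2F/f)/v²`; a conversion tract
containing a 4:0 region marks a DSB formed in G1; and the linearized
fraction of an `L` kb circle converts to `λ = −ln(1−f)/L` breaks per kb.

## Worked example

Plant a G1-initiated crossover on chromosome IV, render both sectors of
the colony at realistic noise, call segments, and classify:

```r
library(oxloh)

genome <- build_genome(genome_config("paper"), seed = 42)
ev <- plant_event(genome,
                  planted_event("G1_DSB_CO", "chrIV", 1278, donor = "W",
                                tract_kb = list(a1 = 3, a2 = 8, b2 = 13)),
                  seed = 42)
red   <- render_profile(ev$daughter1, noise_sd = 0.1, seed = 1)
white <- render_profile(ev$daughter2, noise_sd = 0.1, seed = 2)

red_segs   <- call_pipeline(red, genome)$segments
white_segs <- call_pipeline(white, genome)$segments
events <- classify_sector_pair(sector_pair(red_segs, white_segs, genome))
events[, c("chrom", "type", "donor", "phase", "tract_classes",
           "tract_len_kb", "co_bp_lo", "co_bp_hi")]
#>   chrom type donor phase tract_classes tract_len_kb co_bp_lo co_bp_hi
#> 1 chrIV   CO     W    G1       3:1/4:0      19.7565 1289.891 1291.052
```

One crossover, donor haplotype W, whose conversion tract contains both a
3:1 and a 4:0 sub-region — the diagnostic of a G1 break replicated into two
broken chromatids — with the exchange point localized between two markers
~1.2 kb apart (`co_bp_lo`–`co_bp_hi`).

Rate arithmetic works the same way on colony counts:

```r
sector_frequency(197, 39417)
#> binomial-frequency (wilson): 0.004998 (95% CL 0.004348-0.005744)
crossover_rate_from_sectors(sector_frequency(197, 39417)$estimate)
#> [1] 0.009995687
correct_co_con_counts(26, 61)[c("co", "con")]
#> $co
#> [1] 52
#> $con
#> [1] 35
```

A YAML-driven end-to-end run (simulate → call → classify → stats) is
available through `run_pipeline()` or the thin wrapper in
`inst/scripts/oxloh.R`.

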