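Package: oxloh
Title: Genome-Wide Mapping of Oxidative-Stress-Induced Mitotic Recombination in Hybrid Diploid Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for hydrogen-peroxide-induced
    loss of heterozygosity (LOH) in a hybrid diploid budding yeast assayed by
    two-allele SNP microarrays. Generates synthetic diploid genomes with
    planted mitotic recombination events (crossovers, break-induced
    replication, gene conversions, deletions, duplications, aneuploidy,
    uniparental disomy), renders per-SNP hybridization-ratio profiles, calls
    copy states and LOH/CNV segments at single-SNP breakpoint resolution,
    classifies events from red/white sector pairs or single isolates with
    3:1/4:0 conversion-tract typing, and computes the associated statistics:
    Luria-Delbruck fluctuation rates (Lea-Coulson method of the median),
    sectoring frequencies with binomial confidence limits, segregation and
    viability corrections, conversion-tract length bootstraps, hotspot and
    feature-enrichment permutation tests, Poisson quantification of
    double-strand breaks from a circular-chromosome reporter, and mutation
    spectrum comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
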