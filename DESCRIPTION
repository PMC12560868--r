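Package: herdpurity
Title: Purity Screening, Genetic Diversity and Family Structure for Conserved Livestock Herds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the genomic management of small conserved
    livestock populations genotyped on SNP arrays. Reads PLINK text PED/MAP
    files, applies sequential marker and sample quality control with per-filter
    accounting, screens breed-purity marker panels by intersecting top PC1
    contributors with high major-allele-concordance loci and ranks individuals
    by primary-allele counts, computes per-locus genetic diversity statistics
    (MAF, Ho, He, PIC, Shannon index, proportion polymorphic), method-of-moments
    inbreeding coefficients, LD-based effective population size, identity-by-state
    and genomic relationship matrices, sliding-window runs of homozygosity with
    F_ROH, and kinship-threshold family assignment with neighbor-joining
    clustering of sires. Includes a synthetic herd generator with planted
    ground truth (purebred cores, admixed outliers, half-sib families,
    autozygous segments) and a Wright-Fisher drift simulator for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
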