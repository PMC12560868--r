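---
title: "Methods: purity screening, diversity and family structure in conserved herds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: purity screening, diversity and family structure in conserved herds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdpurity)
```

## The problem

Conserved local livestock breeds are typically held as one small herd — a
few dozen animals, a handful of sires — that has been exposed to
crossbreeding with exotic high-yield stock. Before any mating plan can be
drawn, the manager needs four things from a SNP-array genotyping run: a
defensible purebred core (which animals carry the breed's characteristic
genetic background), the herd's diversity and inbreeding status, the
kinship structure among animals, and the sire-family membership of the
cows. `herdpurity` chains these into one pipeline and ships the synthetic
data needed to validate every stage by parameter recovery.

## Data model and genotype coding

Genotypes are held as an individuals × markers matrix of allele counts
(0/1/2/NA) counting copies of `allele1`. `allele1` is the *alphabetically
smaller* of the two allele characters observed at the locus — not the
first-encountered one — so the coding is invariant to the order of rows in
a PED file and permuting individuals permutes the matrix rows and nothing
else. The frequency-based primary/secondary allele roles used by the purity
screen are derived downstream and never stored. Half-missing genotype pairs
("A 0") are treated as missing, with a warning tally, matching common
tooling behaviour; the missing pair encoding is the PLINK default "0 0"
(the convention is an assumption — array exports rarely state it).

## Quality control

Filters run in a fixed order: (1) non-autosomal/unplaced markers, (2)
individuals with call rate < 0.90 (on the remaining markers), (3) markers
with call rate < 0.90, (4) exact Hardy–Weinberg p < 1e-6, (5) MAF < 0.01.
Every removed marker is counted against the *first* filter that removes it.
This order and attribution rule make the published one-count-per-category
accounting an invariant — categories always sum to `total − retained` —
at the cost of not reproducing any particular tool's internal joint
behaviour. Whether HWE or MAF filtering came first in the original
protocols this mirrors is generally unstated; the fixed order is this
package's contract. The sample filter is reported separately and is not
part of the marker accounting.

The HWE test is the standard biallelic exact test: conditioning on allele
counts, the p-value sums the probabilities of all heterozygote counts no
more probable than the observed one (no mid-p). It is computed by an upward
recurrence on the heterozygote count for stability; the test suite checks
it against an independent log-factorial enumeration to 1e-12 over every
genotype table with up to 30 alleles.

Display percentages follow a truncation convention: removal percentages are
floored at the displayed precision (2 decimals for categories, 1 for the
removed total) and the retained percentage is the complement of the floored
total. Flooring guarantees a removal fraction is never overstated and makes
the categories and the retained figure mutually consistent at their
respective precisions. Exact fractions are stored alongside the display
values.

## Purity screening

PCA runs on the post-QC autosomal matrix with the usual
(x − 2p)/√(2p(1−p)) standardization, missing entries imputed to the column
mean (zero after centering) and monomorphic columns zeroed, so their PC1
contribution is exactly 0. "Contribution to PC1" is the squared marker
loading normalized to sum to one — the standard variance-decomposition
measure; this is a definition the package fixes because screening protocols
rarely state one. Exact ties in the top-k ranking break by (chromosome,
position, id), making the panel reproducible.

Concordance is the primary (major) allele frequency, classed high above
0.80, low below 0.30, medium between. For biallelic loci the major-allele
frequency is at least 0.5, so the *low* class is unreachable; it is kept in
the interface for fidelity with the three-way classification used in
breed-purity work. The panel is the ordered intersection of the top-k PC1
contributors with the high-concordance loci, and each animal's purity score
counts the panel primary-allele copies it carries. Missing genotypes
contribute zero copies rather than an imputed expectation: the score counts
alleles actually observed. Ranking ties break by animal id; the selected
core size is a parameter (default 60), never hard-coded.

## Diversity statistics

Per locus, with p the allele1 frequency over non-missing calls: MAF =
min(p, q), Ho = observed heterozygote fraction, He = 2pq (uncorrected,
matching per-locus expected-heterozygosity displays), PIC = 1 − (p²+q²) −
2p²q², SHI = −(p log p + q log q). The Shannon index defaults to natural
log with a base-2 switch; per-chromosome mean SHI reaching exactly 1.0 in
published tables suggests base 2 is sometimes used, so both are exposed.
The per-individual inbreeding coefficient uses the excess-homozygosity
method of moments with the small-sample correction n/(n−1) inside the
expected-homozygosity term — the convention of the standard `--het`
implementations — which makes mean F converge to zero on outbred
simulations (checked to |mean F| < 0.01 at 10k loci × 200 individuals, and
to ≈ 0.25 for simulated full-sib offspring).

Effective population size uses the Sved relationship: composite r² (squared
Pearson correlation of allele counts, missing mean-imputed) between marker
pairs within a genetic-distance window, adjusted by the sampling term
1/(2n), binned by distance c, and inverted per bin as
Ne = (1/4c̄)(1/r²_adj − 1); a bin at mean distance c̄ reflects the
population about t ≈ 1/(2c̄) generations ago. The reported value is the
harmonic mean over bins within the recent-generation window (default
t ≤ 50). Pair sets beyond a cap (default 200k) are subsampled after a
marker thinning step, which is why the pipeline seeds its runs. When no
bin shows positive adjusted LD the estimate is reported as unbounded
(`no_ld` flag) rather than a number. Published Ne values for specific herds
are generally not reproducible without the exact binning protocol and data;
the package documents its own protocol instead and validates the estimator
by recovery: on Wright–Fisher simulations with Ne = 50, 30 generations and
100 sampled animals, the median estimate over seeds falls within a factor
of two of the truth.

## Relatedness

The IBS distance counts shared allele copies per pair over loci non-missing
in both (1 for both alleles shared, 0.5 for one, 0 for none), subtracted
from one. The GRM is the per-locus-standardized single-step estimator with
frequencies from the full sample, monomorphic loci excluded, and per-pair
complete-case denominators. Its diagonal estimates 1 + F and is *not*
identically 1 — statements that kinship-matrix diagonals "equal 1 by
definition" refer to a different normalization; the package keeps the
standard estimator and the tests assert mean(diag G) ≈ 1 + mean(F).

## Runs of homozygosity

The scan is the classic sliding-window procedure with the defaults of the
standard array ROH caller (50-SNP windows, ≤1 het, ≤5 missing per window,
5% hit threshold, and segment constraints of ≥100 SNPs, ≥1000 kb, ≤50
kb/SNP, ≤1000 kb gaps) — published herd analyses typically name the tool
but not the settings, so segment counts from specific papers are not
reproducible and the defaults are exposed as parameters instead. Segment
boundaries are the outermost run-eligible SNPs. F_ROH divides an
individual's summed segment length by the autosomal map length (sum of
last-minus-first SNP positions per autosome), so synthetic and real maps
are handled uniformly; a fixed genome length would make simulated F_ROH
incomparable. Note the interplay of the constraints: a map at exactly 50 kb
mean spacing leaves segments on the density boundary, so recovery tests use
maps comfortably above 1 SNP/50 kb (the detection contract the defaults
imply).

## Family structure

Bulls are clustered with a neighbor-joining implementation written for
deterministic behaviour: standard Q-criterion and branch-length formulas,
ties broken by lexicographic pair order, negative branch estimates clamped
to zero with a flag. Tests require exact recovery of random additive trees
(topology and path lengths to 1e-9) and agreement with an independent NJ
implementation on noisy matrices. Newick output follows the unquoted-label
convention (spaces as underscores).

Family assignment applies the kinship-threshold rule: bulls with G ≥ 0.1
form core families as connected components; each cow joins the family of
her *single highest-kinship* bull when that kinship reaches the threshold.
The max rule is a deliberate sharpening — "any bull above threshold" leaves
cows related to bulls of several families unresolved. Raising the
threshold can only move cows out of families, never in (a monotonicity the
tests assert). Outlier exclusion before clustering is an explicit id-list
option, not an automatic rule, because no published criterion exists for
it.

## Pipeline order

`run_pipeline()` mirrors the two-pass design of conservation workups:
QC on the full herd, screening on the filtered matrix, then QC *again from
the raw genotypes* of the selected animals. The second pass is not
redundant: call-rate, HWE and MAF filters are sample-dependent, so their
counts change on the selected subset, while the total marker count and the
sex-chromosome count are sample-independent and shared between the two
reports — an invariant the tests check. Stages 4–7 (diversity,
relatedness, ROH, family) run on the re-filtered selected matrix.

## The synthetic herd generator

`generate_herd()` emulates the study design the pipeline targets, and its
defaults are the generator's definition of that design: 12 bulls + 62 cows
(74 animals) with a purebred core of 60 and 14 admixed outliers; 90,349
autosomal markers on 29 autosomes of 100 Mb plus 4,907 X/Y/unplaced
markers; a 61-locus panel near fixation (0.95) in purebreds and rare (0.20)
in the admixed; 10 paternal half-sib families; 70 zero-heterozygote loci at
intermediate frequency; 3,300 single-carrier rare loci; a 9% low-quality
marker stratum at 20% missingness over a 0.5% baseline (a flat missing rate
cannot push ~8% of markers under a 0.90 call-rate threshold, so the mixture
is what makes the call-rate filter bite realistically); and planted
autozygous segments (Poisson mean 29.5 per animal, 1–16 Mb) giving mean
F_ROH near 0.09. Genetic positions are set to 1 cM/Mb — the generic cattle
map scale — because the LD binning needs genetic distances.

Construction choices worth knowing:

* Panel frequencies are enforced by exact allele counts *at the founder
  level* (sires and dams); offspring inherit, so the realized purebred
  frequency matches the target up to Mendelian sampling and is exact at
  1.0. Enforcing the frequency directly on offspring would break the
  generator's own Mendelian-consistency guarantee (no opposing homozygotes
  between a cow and her recorded sire), which the tests rely on.
* Zero-heterozygote loci stay Mendelian-consistent by giving each offspring
  its sire's homozygote class. Planted autozygous segments overwrite
  genotypes (one haplotype drawn per segment, doubled) and are the one
  deliberate Mendelian exception; they are exactly homozygous before
  missingness is injected.
* Rare loci are planted after ROH so the single-carrier MAF guarantee
  survives.
* Admixed animals diverge at the panel plus a 20% fraction of background
  loci, keeping the purebred/admixed split detectable on PC1 by
  construction.

What the generator does **not** emulate: realistic LD maps and haplotype
structure (baseline loci are independent given frequency), mutation,
genotyping error, linked selection, and admixture tracts. Passing the
recovery tests therefore demonstrates that the algorithms read out planted
structure correctly, not that they are robust to every artefact of real
array data.

`wright_fisher_drift()` is a forward-in-time haplotype simulator: constant
diploid size, random mating with selfing allowed, founder frequency 0.5,
Haldane recombination at constant marker spacing within chromosomes, free
recombination across. It exists to give the Ne estimator a truth to
recover.

## Problem sizes and numerical choices

The test suite validates at reduced scale — herds of 20–74 animals,
4,000–20,000 markers, 3–20 seeds per property — sizes chosen so the whole
suite completes in well under a minute while keeping every recovery
property statistically comfortable (simulation SDs sit several times below
the asserted tolerances). The acceptance script runs the pipeline at the
full study scale (74 × 95,256). Ties and degenerate inputs are handled
explicitly throughout: zero-variance t tests return flagged p = 1 rather
than erroring when all differences vanish; all-missing markers are dropped
from locus statistics with a warning; an all-missing MAF counts as zero
(removable); pairs with no overlapping loci get NA relatedness entries; an
emptied sample set short-circuits QC with a warning and a consistent
report.

## Known limitations

* Binary PLINK (BED/BIM/FAM) and VCF ingestion are out of scope; text
  PED/MAP only, biallelic markers only.
* The LD-based Ne estimator assumes drift equilibrium per distance bin;
  for very recent bottlenecks the small-distance bins reflect older, larger
  sizes, which is why the summary restricts to the recent-generation
  window.
* The ROH caller is window-based, not model-based (no HMM), and inherits
  the usual boundary fuzziness of about one window width.
* Family assignment is a thresholded component rule, not pedigree
  reconstruction; half-sib families sharing dams, or grandsire structure,
  will merge or split depending on where kinship falls against the
  threshold.
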