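---
title: "Mining phasing-free haplotypes from homozygosity tracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining phasing-free haplotypes from homozygosity tracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplotract)
```

## The idea

Computational genotype phasing infers which alleles sit on the same physical
chromosome, and it makes characteristic mistakes around rare variants, novel
variants and structural variation. haplotract avoids phase inference
entirely by exploiting long contiguous stretches of homozygosity (LCSH): if a
diploid individual is homozygous at every variant site across a region, both
chromosomes carry the identical sequence there, so the haplotype can be read
directly from the genotypes. The package relaxes this by one site: an
individual that is heterozygous at **at most one** variant site overlapping a
focal gene still yields two unambiguous haplotypes — one per allele of that
single site. Such haplotypes are experimentally confirmed in the sense that
no statistical phasing step can have corrupted them.

The procedure, per sample:

1. Count heterozygous sites whose REF footprint overlaps the focal gene.
   Samples with more than one are excluded.
2. Extend the gene interval in the 5' and 3' directions until a heterozygous
   variant is encountered on that side; the span ends just inside the
   terminating variant's full REF footprint ("the region between two SNVs").
   With no flanking heterozygote, the span runs to the region boundary.
3. Emit two chromosome observations over the span — identical for a fully
   homozygous sample, differing at exactly the one permitted site otherwise.
4. Materialise each observation as a nucleotide sequence by splicing its
   alleles into the reference window, deduplicate by (span, sequence), and
   attach population breakdowns from the sample panel.

The Duffy blood-group gene *ACKR1* on chromosome 1 is the package's default
worked system: its alleles FY\*01 (Fya), FY\*02 (Fyb) and FY\*02N.01 (the
GATA-box null that abolishes erythroid expression and confers *P. vivax*
resistance) are distinguished by a configurable motif over diagnostic
exonic/promoter positions, and bundled archaic hominin base profiles allow
IUPAC-aware comparison of catalogued haplotypes against Neanderthal consensus
sequences.

## Modelling decisions and degenerate inputs

Several choices were genuinely open; the package resolves them as follows.

**Coordinates.** Everything user-facing is 1-based and inclusive at both
ends (the VCF convention); an interval's length is `end - start + 1`.
Half-open bookkeeping exists only inside file readers.

**Heterozygosity and phase.** A genotype is heterozygous iff its two allele
indices differ. The VCF phase separator is parsed into a flag that is carried
through and never consulted — independence from phasing is the method's point.
Multi-allelic records are kept as single sites with allele indices, because
qualification depends on the *pair* of indices; splitting them would
double-count heterozygosity.

**Missing genotypes.** Population callsets of the scale this method targets
are essentially complete, but the policy still matters at the margins. A
missing call is ambiguous, so by default it is treated like a heterozygote:
it counts against qualification and terminates extension. One sub-case needs
more care: a sample whose *single* permitted in-gene "heterozygote" is
actually a missing call has no assignable alleles there, so it is
disqualified outright. Setting `missing_as_het = FALSE` switches to the
permissive policy in which missing calls are ignored.

**Boundary-straddling variants.** A heterozygous variant whose REF footprint
overlaps the gene boundary counts as in-gene. Overlap semantics are the only
choice that keeps spans well-formed when deletions cross the boundary.
Only variants *entirely* outside the gene terminate extension, and the span
excludes their whole footprint.

**Haplotype length.** The reported length is the length of the realised
sequence, not the span width: insertions add bases and deletions remove
them, so a haplotype carrying insertions can be longer than the genomic
window it occupies. The two definitions coincide exactly when no indel
applies, and differ by the summed allele-length differences otherwise (an
invariant the tests exercise on random indel fixtures).

**Catalogue identity and ordering.** Two haplotypes are the same record iff
they share both span and sequence — an identical sequence over a different
span is a physically different claim. Ids `HAP1, HAP2, ...` are assigned by
descending observation count, ties broken by span start, span end, then
sequence, making output deterministic.

**Summary statistics.** Median, quartiles and combined length are computed
over *distinct* haplotypes (each counted once); the length histogram is
weighted by *chromosome observations*, so its column total equals the number
of observed chromosomes. Quartiles use linear interpolation on sorted values
(`stats::quantile` type 7, the spreadsheet convention) — a potential source
of a few-nucleotide discrepancy against other quartile definitions. Bin
percentages are rounded half-up to two decimals; `2132/3040` therefore
prints as `70.13`. Per-allele standard deviations use the sample (n − 1)
denominator. An empty catalogue yields a defined empty summary rather than
an error, and the rank correlation between length and observation count is
reported as `NA` with a warning when either variable is constant.

**Allele classification.** Classification reads *only* the configured
diagnostic positions; everything else (intronic, synonymous variation) is
ignored by design, and matching is exact — rare alleles absent from the
configuration come out `"unclassified"`, haplotypes whose span misses a
diagnostic position (or whose sequence deletes one) come out `"uncallable"`.
The bundled Duffy configuration carries real GRCh38 coordinates for the two
positions that anchor the three common alleles (the GATA box c.-67,
rs2814778, and the Fya/Fyb site c.125, rs12075); the other thirteen motif
positions ship as clearly labelled synthetic placeholders whose reference
bases equal the motif suffix shared by all three alleles. Motif-string
classification never touches the placeholder coordinates; users classifying
real data at all fifteen positions should substitute curated coordinates in
a config of their own — the format is a small TSV precisely so other genes
and blood-group systems plug in without code changes.

**Archaic comparison.** External profiles are tabulated consensus bases, not
alignments; ambiguity codes (e.g. `Y` = C or T) are compared by set
intersection, so an ambiguous base never creates a mismatch a compatible
concrete base would have avoided. Which positions are compared is a
parameter: the bundled profiles cover the four GATA-box-region positions,
and nothing prevents comparison over a larger configured set. Ranking is by
ascending mismatches, ties by descending length then id.

## The simulator, and what passing tests show

`simulate_cohort()` generates a uniformly random reference window, variant
sites on a spaced grid (so footprints never collide), and diploid genotypes
under Hardy-Weinberg equilibrium: each chromosome's allele at each site is
an independent draw at the configured alternate-allele frequency. Population
labels are assigned round-robin, planted genotype rows can be appended for
hand-constructed scenarios, and one seed makes every emitted file
byte-reproducible.

Crucially, the generator computes its own expected output — per-sample
qualification, spans, and the distinct-haplotype catalogue — by an
exhaustive window search implemented *inside the generator*, not by calling
the extraction code under test. The extraction module carries a second,
independently written brute-force oracle. The test suite demands exact
agreement of all three on randomized cohorts (100 seeds), verifies the
closed-form Hardy-Weinberg qualifying fraction
$\prod_i(1-h_i)\,\bigl(1+\sum_j h_j/(1-h_j)\bigr)$ with $h_i = 2p_i(1-p_i)$
to within three binomial standard errors at n = 2,000 samples, and checks
byte-identical round-trips through every reader/writer pair.

The simulator is deliberately simple: sites are independent, with no linkage
disequilibrium, recombination map or coalescent structure. The haplotype
method itself is agnostic to these — qualification and extension depend only
on per-sample heterozygosity patterns — so independent sites exercise every
code path. What passing tests therefore establish is the *correctness of the
algorithmic machinery*, not the realism of any particular catalogue:
real-data features such as LD-driven haplotype sharing, population
stratification of allele frequencies, and callset artefacts (which the VCF
reader skips and counts rather than interprets) are outside what the
simulation emulates.

Problem sizes in the shipped tests are chosen to exercise structure rather
than scale: randomized cohorts of 8–15 samples over 10–15 sites for the
oracle batteries, 2,000 samples for the Hardy-Weinberg check, and a
30-sample regression fixture with a planted deletion whose catalogue is
frozen as golden files. The algorithms are linear passes per sample and
handle cohorts of thousands of samples comfortably.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `missing_as_het` | extraction | `TRUE` | missing calls count as heterozygous |
| `bin_width` | `summarize_catalogue()` | 10,000 nt | histogram bin width |
| `alt_freq` | `sim_config()` | 0.1 | HWE alternate-allele frequency |
| `n_sites`, `n_in_gene` | `sim_config()` | 20, 5 | simulated site counts |
| `n_samples` | `sim_config()` | 50 | simulated diploid samples |
| `seed` | `sim_config()` | 1 | drives all simulator randomness |
| posmap / motifs | allele config TSV | Duffy FY | diagnostic positions and named motifs |

## Known limitations

* Extraction assumes the callset's variant normalisation; records are applied
  on their left-aligned coordinates as given, and overlapping footprints
  within one observation are an error rather than being re-normalised.
* Sample-level qualification is binary; a future refinement could weight
  haplotypes by the local density of genotyped sites (a sparse callset makes
  "homozygosity" a weaker statement).
* The archaic-comparison module starts from printed base profiles;
  pileup-level evidence (coverage, damage patterns) is out of scope.
* Classification is exact-match over configured positions; it does not
  attempt nomenclature resolution beyond the configured motif table.
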