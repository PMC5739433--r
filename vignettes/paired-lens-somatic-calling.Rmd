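---
title: "Paired-lens somatic SNV calling: model, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-lens somatic SNV calling: model, thresholds and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paircall)
```

## The analysis paircall implements

Targeted-amplicon deep sequencing reads a small set of exons at very high
depth (hundreds to thousands of reads per base), which makes two things
possible at once: confident germ-line genotyping from bulk tissue, and
detection of low-frequency somatic variants that standard genotypers would
discard as noise. `paircall` implements the count-level designation logic
used to survey germ-line and somatic coding SNVs in the human lens, where
the left and right lenses of one donor act as a matched pair, in direct
analogy to tumor/normal somatic calling:

* the **variant allele frequency** at a site is
  $\mathrm{VAF} = 100 \times a/d$ for $a$ variant-supporting reads out of
  $d$ total reads;
* a variant with VAF $\ge$ 20% in a bulk blood sample is designated
  **germ-line** (heterozygotes cluster near 50%, homozygotes near 100%);
* in a lens pair, an allele *present* in exactly one lens is a
  **discordant SNV** and designated **somatic**; present in both lenses,
  germ-line. Presence requires VAF $\ge$ 1% plus a small supporting-read
  floor (4 reads by default — our addition; the VAF floor alone is
  meaningless at very low depth);
* somatic calls are retained only at VAF $\ge$ 3% **and** depth $\ge$ 600
  reads (both boundaries inclusive, mirroring the exclusion of "below 3%"
  and "below 600"); a variant identity recurring in more than one pair is
  excluded, every occurrence, as a likely artifact or unrecognized
  germ-line allele.

Retained calls are annotated against a single strand-aware transcript
model (HGVS `c.`/`p.` names, consequence class), classified as transition
or transversion, flagged for **di-pyrimidine context** and the **UV
signature** (a pyrimidine-strand C>T at a di-pyrimidine site — the
fingerprint of cyclobutane-pyrimidine-dimer mutagenesis), and triaged as
novel or reference against local variant catalogs. Cohort summaries and
2x2 contingency comparisons (Fisher's exact, Pearson chi-square) close the
loop at panel level.

## Thresholds and their defaults

| parameter | default | meaning |
|---|---|---|
| `presence_vaf_percent` | 1 | VAF floor for "present" in paired comparison |
| `min_alt_reads` | 4 | supporting-read floor for "present" |
| `germline_vaf_percent` | 20 | germ-line designation threshold |
| `somatic_min_vaf_percent` | 3 | somatic retention VAF floor |
| `min_depth` | 600 | somatic retention depth floor (reads) |
| `het_range_percent` | [20, 80] | VAF interval called heterozygous |
| `somatic_fisher_alpha` | off | optional exact-test gate on paired counts |

All are arguments of `call_config()`. The het/hom boundary at 80% is our
choice (no operational definition exists in the source analysis); the
optional exact-test gate is the closest count-level analogue of a paired
somatic caller's significance test and is off by default because the
plain discordance rule is the documented behavior.

## Coordinate and annotation conventions

Coordinates are 1-based closed throughout; BED12 input is converted at the
reader boundary. One transcript per gene: targeted panels annotate against
a single RefSeq-style model, and multi-isoform annotation is out of scope.
On minus-strand models (the default in the simulator, mirroring the genes
this design targets) increasing genomic position maps to decreasing CDS
position and coding alleles are the complements of the plus-strand pair.

Intron offsets follow HGVS: positive from the preceding exon's last CDS
base, negative from the following exon's first, in transcript orientation;
offsets of absolute value 1–2 are classified `splice` (configurable
window). Exonic non-coding bases and flanking bases outside the exon span
are classified `UTR5`/`UTR3` by their side of the CDS in transcript
orientation, anchored to the CDS terminals with signed offsets (`c.-k` /
`c.*k` counting); positions on another contig are `intergenic`. The
di-pyrimidine definition is operational: the site qualifies when at least
one immediate neighbor **on the pyrimidine-carrying strand** (5' or 3' —
the inclusive either-neighbor rule) is also a pyrimidine; an `N` neighbor
conservatively disqualifies the flag. Tandem CC>TT detection is out of
scope at the caller level, which emits single-base calls only.

`parse_hgvs()` accepts both the `c.2162G>A` dialect and the ANNOVAR-style
`c.G2740T` order, plus splice (`c.1682+1G>A`) and UTR (`c.*20C>T`) forms,
so printed variant tables can be re-tallied without the underlying
reference sequence; `study_table()` ships four such published tables as
plain-text fixtures.

## Recurrence exclusion

A PASS somatic identity `(contig, pos, ref, alt)` observed in more than
one pair is removed together with *all* of its occurrences. The source
analysis's own arithmetic around recurrence (occurrence counts summing to
22 against 19 reported exclusions) cannot be reconciled from the printed
text, so this deterministic all-occurrences policy is the package's
documented behavior rather than a reconstruction. Note its consequence
for simulation benchmarking below.

## What the simulator emulates — and what it does not

`sim_config()` + `make_reference()` + `inject_and_pileup()` generate a
random contig carrying a valid multi-exon minus-strand transcript, then
per-pair pileups with:

* lognormal per-site depths (`meanlog = log 3000`, `sdlog = 0.5`),
  matching the heavy right tail of observed amplicon depths
  (roughly 600–8000x);
* shared germ-line variants from a population AF spectrum under
  Hardy-Weinberg, het VAFs Normal(50, 3) truncated to [20, 80];
* somatic variants Poisson(3)/pair, single-lens by construction, VAF
  uniform on [3, 13]%; a configurable fraction is forced to be
  pyrimidine-strand C>T at di-pyrimidine-eligible sites (default 0.5);
* symmetric per-base miscalls at rate 0.001, with an optional C>T-biased
  error mode to stress-test UV-signature inference against
  deamination-like artifacts.

All randomness flows from the config seed; identical configs give
byte-identical outputs. The simulator works at count level: it does not
model reads, PCR duplicates, amplicon dropout, strand bias or mapping
error, so passing recovery tests demonstrates the correctness of the
designation logic under the stated statistical model, not robustness to
alignment artifacts. Bilateral (both-lens) mosaicism is deliberately not
simulated: the paired-discordance design cannot distinguish it from
germ-line variation, and it would be designated germ-line.

The Poisson mean of 3 somatic events per pair is a testing convenience
(the real per-lens somatic rate is unknown), chosen to exercise the
pipeline with tens of events at the default pair count.

## Numerical and testing choices

* Problem sizes: recovery benchmarks run 20 pairs over a ~20 kb contig
  with a 120-codon transcript; property tests check 500 random
  substitutions against a brute-force translate-and-diff oracle and 500
  random 2x2 tables against a full-enumeration hypergeometric oracle.
* Recovery is measured on PASS calls **before** recurrence triage:
  independent injections in different pairs can legitimately collide on
  one identity (UV events concentrate on C>T), and the recurrence policy
  removes such collisions by design, which is a property of the cohort
  policy, not of calling sensitivity. At depth $\ge$ 1000 and true VAF
  $\ge$ 5% the calibrated bounds are sensitivity $\ge$ 0.95,
  germ-line-as-somatic leakage $\le$ 0.01 and somatic-VAF mean absolute
  error $\le$ 0.5 percentage points at depth $\ge$ 2000.
* Fisher's exact test is two-sided by the standard sum-of-probabilities-
  $\le$-observed rule (`stats::fisher.test`); the test suite checks it
  against an independent enumeration oracle rather than trusting either
  implementation alone. Chi-square is Pearson without continuity
  correction by default (Yates available as a flag).
* The 2x2 construction behind panel comparisons is explicit because it is
  not recoverable from published summaries: `pairs_with_variant`
  tabulates pairs with/without a qualifying variant (metric `total`),
  `variant_counts` tabulates counts against pairs surveyed as a
  count-versus-exposure table. Published comparison p-values are therefore
  not regression targets. Multiple comparisons are Bonferroni-corrected by
  default, with raw p reported alongside.
* Ties and ordering: all call tables are sorted by (contig, pos, alt);
  multi-allelic sites are evaluated per alt base, and two alts can both
  qualify at one site.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 11, n_pairs = 10)
ref <- make_reference(cfg)
sim <- inject_and_pileup(cfg, ref$genome, ref$tm)
res <- run_paired_panel(sim$pileups, sim$pairs, call_config())
res$log
ann <- annotate_calls(res$retained, ref$tm, ref$genome)
tally_classes(ann)
```

## Known limitations

* Single-nucleotide substitutions only: no indels, MNVs or tandem
  CC>TT calls.
* One transcript per gene; no liftover between assemblies — all positions
  are interpreted against whatever FASTA and transcript model are
  supplied.
* Damage labels (SIFT/PolyPhen-style) are consumed as input annotations;
  the any-predictor-damaging aggregation used in summaries is our stated
  rule, not an inferred one.
* Count-level only: alignment, base-quality recalibration and strand-bias
  modeling live upstream of this package.
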