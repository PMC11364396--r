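---
title: "Detecting and comparing A-to-I RNA editing with hyperedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing A-to-I RNA editing with hyperedit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperedit)
```

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA. Reverse
transcriptases and sequencers read inosine as guanosine, so A-to-I editing
appears in RNA-seq as A-to-G mismatches on the transcript strand — and as
T-to-C mismatches against the plus-strand reference when the edited gene is
encoded on the minus strand. Two properties make the analysis non-standard:

* **Strandedness.** The event must be assigned to the transcript strand.
  With an F2R1 stranded paired-end library, the second-in-pair read maps in
  the transcript orientation, so the pair's mapped orientation determines
  the event strand and whether A/G or T/C pileup columns carry the signal.
* **Hyper-editing.** ADAR can edit dense clusters of adenosines within one
  RNA molecule. Reads from such molecules carry so many mismatches that a
  conventional aligner rejects them, silently deleting the strongest editing
  signal. The remedy is to collapse the A/G distinction: substitute every A
  with G in both the unaligned reads and a pseudo-genome reference, align in
  that reduced alphabet, and then verify the placement against the original
  genome.

`hyperedit` implements the full path — synthetic data with planted truth,
alignment and rescue, strand-aware site calling, cohort filtering,
differential testing, annotation, and sequence-context analysis — so that
every stage is verifiable against ground truth without any external data.

## Quantities and statistical model

For a site with event-strand base counts, the **edit ratio** is

$$\hat r = \frac{n_G}{n_A + n_G},$$

the fraction of edited reads among informative reads. Bases other than A/G
at the site (sequencing errors, mostly) are excluded from the denominator;
counting them as unedited would bias $\hat r$ downward. Both definitions are
computable from the `site_counts` table; the A+G denominator is the one
reported.

A site enters the cohort set if it is a candidate in at least one sample
(event-strand reference A, at least one G read). It passes the
**high-confidence filter** if at least 3 samples individually have edited
reads strictly greater than 5 and an edit ratio strictly between 0.1 and
0.9. The lower ratio bound removes low-editing loci, the upper bound
homozygous/heterozygous genomic variants masquerading as editing; both
bounds are implemented as open intervals and the read-count bound strictly
(that is, at least 6 edited reads), the literal reading of the rule.

**Differential editing** between two groups pools edited/unedited counts
across the samples of each group into a 2x2 table and computes a two-sided
Fisher exact p-value by summing hypergeometric outcomes no more probable
than the observed table. P-values are adjusted per comparison with the
Benjamini-Hochberg step-up procedure, and sites with adjusted p below 0.05
are called significant. Pooling (rather than a per-sample statistic) is a
deliberate choice: it matches the count-based exact test, and per-sample
ratios remain available descriptively. The alternative — modelling
between-sample overdispersion — is out of scope and listed as a limitation.
Filtering precedes testing, so the FDR is controlled over the
high-confidence set.

## Hyper-editing rescue

Unaligned reads are transformed and realigned twice: A-to-G transformed
reads against the A-to-G transformed genome, and T-to-C transformed reads
against the T-to-C transformed genome. The two transformed references cover
the two possible orientations of a stranded library relative to the plus
strand; both mate orientations of both gene strands are therefore
rescuable. On a unique best placement, the *original* read is compared with
the *original* genome and accepted as hyper-edited iff

* editing-consistent mismatches (ref A / read G, or ref T / read C on the
  mirror route) number at least `rescue_min_ag_sites` (default 3),
* they make up at least `rescue_min_ag_fraction` (default 0.6) of all
  mismatches, and
* at most `rescue_max_other_mismatches` (default 2) other mismatches remain.

These three thresholds are not printed in the underlying method literature;
they are exposed as configuration, recorded in output headers (`XE` SAM
tag, manifest), and chosen so that a read with a minimal cluster (3 edits)
passes while a read with mixed damage does not. The C-to-T control in the
test suite verifies the asymmetry: a read with 8 C-to-T substitutions
aligns to the T-to-C reference but shows zero editing-consistent mismatches
at verification and is rejected.

The primary aligner is a deliberately small ungapped seed-and-extend
matcher, not a STAR substitute: reads are placed wherever an ungapped
alignment with at most `max_mismatches` (default 4) substitutions exists,
multi-mappers are discarded, and the seed tiling (disjoint k-mers, default
k = 12) makes the search exhaustive whenever the mismatch count is below
`floor(read_length / k)` — 6 tiles for 75-mers, so every read with at most
5 mismatches is found if it is placeable. Aligned SAM/BAM from any external
aligner can be ingested instead; unmapped records then feed the rescue.

## The synthetic-data generator

`generate_genome()` builds random contigs carrying single-transcript genes
with a fixed template (150 nt 5'UTR; CDS blocks of 300/450/351 nt separated
by two 800 nt introns; 300 nt 3'UTR) on both strands, labelled repeat
intervals (SINE/LINE/LTR/Simple_repeat) over intronic and 3'UTR territory,
and exact inverted repeats planted in introns with non-pairing guard bases
so the planted arm length is exactly maximal. `plan_editing()` places
editing sites on transcript-strand adenosines with per-group rates;
region weights default to concentrating sites in 3'UTRs (weight 3 versus
0.5 for UTR5/CDS and 1 for introns), the distribution observed for A-to-I
editing. Hyper-editing clusters are at least 3 adenosines within 60 nt of a
3'UTR, edited *jointly* per fragment (one Bernoulli draw per fragment and
cluster) with rate 0.8 — this joint application is what produces the
read-level mismatch clusters that rescue is designed to recover. Ordinary
sites are edited independently per fragment, so each site's per-read edit
status is exactly Bernoulli(rate).

`simulate_reads()` draws fragments (normal length, mean 220, sd 25) within
single features, never across introns, because the aligner is ungapped;
exon blocks are at least 450 nt so fragments fit. Intronic coverage runs at
a configurable fraction of exonic coverage (default 0.2) — nascent,
unspliced transcripts are edited co-transcriptionally, so intronic editing
is abundant in real data, but their read abundance in tissue is a free
parameter, not an inference. Reads are emitted in F2R1 orientation with a
flat per-base substitution error rate (default 0.001).

What the generator does **not** emulate: splice isoform diversity and
junction-spanning reads, indels, PCR duplicates, quality-score structure,
expression heterogeneity between genes, and SNPs. Passing tests therefore
demonstrate correctness of the algorithms under clean, known conditions —
not robustness to every artefact of tissue RNA-seq. The high-ratio filter
bound stands in for SNP masking at this scale; no dbSNP-style database is
consulted.

## Annotation and sequence context

Region assignment gives each site the finest containing feature with
precedence CDS > 3'UTR > 5'UTR > intron (the usual collapse when isoform
annotations overlap), preferring same-strand genes and falling back to
any-strand overlap; sites outside genes are `proximal_intergenic` within
10 kb of a transcription start/end site and `distal_intergenic` beyond.
Densities normalise site counts by annotated class length. Repeat-class
lookup resolves overlapping intervals by smallest interval, then
alphabetically. Codon consequences are called on the coding strand with the
standard genetic code (the canonical recoding example AGC→GGC, Ser→Gly, and
the CAG→CGG Gln→Arg case are fixed test points); with multi-isoform
annotations the longest CDS is used. Splice proximity flags the first/last
two intronic nucleotides as donor/acceptor and positions 18-44 nt upstream
of the 3' splice site as the branch-point window — a literature-standard
window, since only the branch point itself, not a window, is named in the
source material.

Motif profiles tabulate event-strand base frequencies within +/-50 nt of
sites and test each (position, base) against the background composition
with an exact one-sided binomial test. The background defaults to the
genome's strand-symmetric composition rather than 0.25 per base, to avoid
composition bias; uniform background is selectable. The A-rich satellite
scan flags a hyper-edited site when any 10-nt window starting 20-40 nt
downstream on the event strand has at least 70% A; the offset/width/
threshold triple is exposed as configuration because only "approximately
30 nucleotides downstream" is established. The inverted-repeat scanner
finds maximal exact arm pairs (arm at least `min_arm`, loop at most
`max_loop`) by seeding on reverse-complement k-mer matches and extending
both ends; maximality is order-independent because the inward and outward
extension conditions touch disjoint positions. Containment-redundant hits
are removed. Exact complementarity (mismatch budget 0) is the default; the
scanner is cross-checked in the tests against an O(n^2) brute-force oracle.

## Numerical and coordinate conventions

* Internal coordinates are 1-based closed throughout (the R/Bioconductor
  convention); GTF and SAM are written 1-based, BED and bedGraph 0-based
  half-open.
* The Fisher p-value sums hypergeometric probabilities at most
  `(1 + 1e-7)` times the observed table's probability, the customary guard
  against floating-point ties; the test suite verifies agreement with
  direct `choose()`-based enumeration to 1e-12 over all tables with margins
  up to 12.
* Overlapping mates are counted once per fragment (read 2, the
  transcript-strand mate, wins), keeping per-site counts Binomial in the
  number of fragments.
* Ambiguous strand context (a site overlapping genes on both strands) is
  resolved by which strand has reference A; if both qualify the site is
  keyed per strand.
* Per-sample seeds are derived deterministically from one global seed;
  identical configuration and seed reproduce byte-identical FASTQ, SAM and
  result files.

## Problem sizes used by the tests

The bundled verification cohorts are sized for a laptop-class run: two
50 kb contigs with 8 genes; 6 samples in 2 groups at ~50x exonic coverage
(about 60,000 reads per cohort); 500 planted recovery sites plus
hyper-clusters; 150 exonic differential sites at rates 0.1 vs 0.4; 2,000
null sites at the counts level for type-I control (generating them at the
read level would need a much larger genome without changing what the check
measures). The whole suite and the acceptance script each run in a few
minutes.

One verification property deserves a caveat: the parameter-recovery check
asks that at least 99% of planted sites fall inside their exact binomial
99% interval. Because the exact interval's conservatism leaves an expected
~0.7% of sites outside, the empirical fraction over 500 sites fluctuates
around 99.3% and dips below 99.0% for roughly one random realization in
seven even when the estimator is exactly unbiased. The fixed-seed
realization in the test suite is one such dip; the acceptance script
recomputes the fraction at the caller's seed.

## Limitations

* No spliced alignment: junction reads are neither simulated nor aligned.
* Pooled-count Fisher testing ignores between-sample overdispersion;
  with strong biological replication structure a beta-binomial or GLM
  approach would be more conservative.
* No SNP database masking; the 0.9 ratio bound is the only genomic-variant
  guard.
* Thermodynamic RNA secondary-structure prediction is out of scope; the
  inverted-repeat scan is purely sequence-based.
* The toy aligner is exhaustive only below `floor(read_length / seed_kmer)`
  mismatches and handles substitutions only.
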