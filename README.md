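# hyperedit

Genome-wide detection and differential analysis of adenosine-to-inosine
(A-to-I) RNA editing from stranded paired-end RNA-seq, with rescue of
hyper-edited reads via an A→G pseudo-genome.

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA;
sequencers read inosine as guanosine, so editing shows up as A→G mismatches
on the transcript strand (T→C against the plus-strand reference for
minus-strand genes). Densely edited ("hyper-edited") molecules carry so many
mismatches that conventional aligners reject their reads, hiding exactly the
strongest signal. This package is for computational biologists who want a
fully testable desk-scale implementation of that analysis: every stage runs
on synthetic data with planted ground truth, so detection, strand handling,
filtering, and inference can all be verified quantitatively.

## What it computes

For a site with event-strand A/G read counts, the edit ratio is

    r̂ = n_G / (n_A + n_G)

Sites are kept as high-confidence when ≥ 3 samples each have > 5 edited
reads and 0.1 < r̂ < 0.9 (lower bound: low-editing noise; upper bound:
genomic variants). Differential editing between groups pools counts into a
2×2 table per site,

              edited   unedited
    group 1    e₁         u₁
    group 2    e₂         u₂

tested with a two-sided Fisher exact test (summing hypergeometric outcomes
no more probable than the observed table) and adjusted per comparison with
Benjamini–Hochberg FDR; adjusted p < 0.05 is significant. Around the calls,
the package annotates genomic region (±10 kb intergenic flanks), repeat
class, codon consequence (e.g. the canonical AGC→GGC Ser→Gly recoding),
splice-site proximity, positional motif enrichment (the 5'AG3' neighbour
preference), downstream A-rich satellites at hyper-edited sites, and
inverted repeats (dsRNA stem-loops, the ADAR substrate).

Hyper-editing rescue aligns the unaligned pool, A→G transformed, against an
A→G transformed genome (and T→C against T→C, covering both library
orientations), then verifies each placement against the original genome:
a read is accepted iff it has ≥ 3 A→G mismatches, these are ≥ 60% of all
its mismatches, and ≤ 2 other mismatches remain.

## Worked example

Six samples, two groups, ~50× coverage, 200 sites planted at rate 0.1 in
`ctrl` and 0.5 in `lps`, plus two hyper-editing clusters:

```r
library(hyperedit)
sg   <- generate_genome(synth_config(rng_seed = 7))
plan <- plan_editing(sg, groups = c("ctrl", "lps"), n_sites = 200,
                     rates = cbind(rep(0.1, 200), rep(0.5, 200)),
                     n_clusters = 2, seed = 7)
groups <- setNames(rep(c("ctrl", "lps"), each = 3), sprintf("s%d", 1:6))
sim  <- simulate_cohort(sg, plan, read_sim_params(depth = 50), groups, seed = 7)
sim$stats
#>    sample n_reads aligned unaligned multi rescued
#> 1:     s1    9876    9848        28     0      28
#> 2:     s2   10014    9992        22     0      22
#> ...
```

Every read that the primary ungapped pass rejects (dense A→G clusters) is
recovered by the pseudo-genome rescue (`rescued == unaligned`). Filtering
and testing:

```r
filtered <- filter_high_confidence(sim$cohort, filter_config())
res <- diff_editing(filtered, groups, c("lps", "ctrl"))
summarize_directions(res)
#>     comparison up_in_group1 up_in_group2
#> 1: lps_vs_ctrl           90            0
top_sites(res, k = 3, repeats = sg$repeats)[,
  .(contig, pos, strand, ratio1, ratio2, padj, repeat_class)]
#>    contig   pos strand    ratio1     ratio2         padj repeat_class
#> 1:   chr2 31656      + 0.5596330 0.06198347 1.118745e-31         <NA>
#> 2:   chr1 41085      - 0.5406504 0.08715596 2.071580e-25         <NA>
#> 3:   chr1 39553      - 0.6083916 0.06015038 2.524905e-22         SINE
```

Ninety sites are significantly more edited in `lps`, none in `ctrl` —
matching the planted 0.1 vs 0.5 asymmetry — and the top sites recover
pooled ratios close to the planted rates, including minus-strand sites
(reported on `-` with plus-strand T→C evidence) and a site inside a
SINE-like repeat.

The same analysis runs file-to-file with one config:

```r
cfg <- pipeline_config(outdir = "run1", seed = 42)
run_pipeline(cfg)    # simulate → align → rescue → call → filter → diff
                     #   → annotate → context → tracks, with manifest.json
```

or from the shell via `inst/scripts/a2i-pipeline.R <stage|run-all> --config
config.yaml`.

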