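#' Strand-aware per-site base counting
#'
#' Accumulates base counts at every covered position in transcript-strand
#' orientation. The transcript strand of each pair is resolved from the F2R1
#' library convention: read 2 maps in the transcript orientation, read 1
#' opposite, so a pair whose read 2 maps to the minus strand counts
#' complemented bases under the "-" strand key. Positions covered by both
#' mates of a pair are counted once (read 2 wins).
#'
#' @param aligned Aligned read table ([toy_align()] `$aligned`, optionally
#'   rbind-ed with [hyper_rescue()] `$rescued`).
#' @param genome Genome (for contig bounds checking).
#' @param sample_id Sample label stored in the output.
#' @return A `data.table` of class `site_counts`: `contig, pos, strand, A, C,
#'   G, T, N, G_rescued, depth, sample`, counts on the event (transcript)
#'   strand.
#' @export
pileup <- function(aligned, genome, sample_id = "sample") {
  g <- as_genome_chr(genome)
  if (!nrow(aligned)) {
    return(empty_site_counts(sample_id))
  }
  L <- nchar(aligned$seq_plus[1L])
  clen <- nchar(g)[match(aligned$contig, names(g))]
  if (any(aligned$pos < 1L | aligned$pos + L - 1L > clen)) {
    stop("malformed alignment: read extends beyond contig end")
  }
  if (!"rescued" %in% names(aligned)) {
    aligned <- copy(aligned)[, rescued := FALSE]
  }

  # transcript strand per F2R1: mate 2 maps in transcript orientation
  tstrand <- ifelse((aligned$mate == 2L) == (aligned$orient == "+"), "+", "-")

  n <- nrow(aligned)
  long <- data.table(
    qname = rep(aligned$qname, each = L),
    mate = rep(aligned$mate, each = L),
    contig = rep(aligned$contig, each = L),
    pos = sequence(rep.int(L, n), from = aligned$pos),
    strand = rep(tstrand, each = L),
    base = unlist(strsplit(aligned$seq_plus, ""), use.names = FALSE),
    rescued = rep(aligned$rescued, each = L)
  )
  # overlapping mates: count once, preferring read 2 (transcript strand)
  setorder(long, qname, contig, pos, -mate)
  long <- long[!duplicated(long, by = c("qname", "contig", "pos"))]
  # event-strand base
  long[strand == "-", base := comp_base(base)]

  counts <- dcast(long[, .N, by = .(contig, pos, strand, base)],
                  contig + pos + strand ~ base, value.var = "N", fill = 0L)
  for (b in c("A", "C", "G", "T", "N")) {
    if (!b %in% names(counts)) set(counts, j = b, value = 0L)
  }
  resc <- long[rescued == TRUE & base == "G",
               .(G_rescued = .N), by = .(contig, pos, strand)]
  counts <- merge(counts, resc, by = c("contig", "pos", "strand"), all.x = TRUE)
  counts[is.na(G_rescued), G_rescued := 0L]
  counts[, depth := A + C + G + T + N]
  counts[, sample := sample_id]
  setcolorder(counts, c("contig", "pos", "strand", "A", "C", "G", "T", "N",
                        "G_rescued", "depth", "sample"))
  setorder(counts, contig, pos, strand)
  setattr(counts, "class", c("site_counts", class(counts)))
  counts[]
}

empty_site_counts <- function(sample_id) {
  counts <- data.table(contig = character(), pos = integer(),
                       strand = character(), A = integer(), C = integer(),
                       G = integer(), T = integer(), N = integer(),
                       G_rescued = integer(), depth = integer(),
                       sample = character())
  setattr(counts, "class", c("site_counts", class(counts)))
  counts[]
}

#' Call candidate A-to-I editing sites from per-sample counts
#'
#' Emits a site wherever the event-strand reference base is A (plus-strand A
#' under the "+" key, plus-strand T under the "-" key) and at least one G is
#' observed on the event strand. The edit ratio is edited / (edited +
#' unedited) with non-A/G bases excluded from the denominator: sequencing
#' errors produce C/T/N reads at an A site, and counting them as unedited
#' would bias rates downward.
#'
#' @param counts A `site_counts` table from [pileup()].
#' @param genome Genome (for reference-base lookup).
#' @return A `data.table` of class `edit_sites`: `contig, pos, strand,
#'   edited, unedited, ratio, depth, hyper, sample`.
#' @export
call_candidate_sites <- function(counts, genome) {
  g <- as_genome_chr(genome)
  if (!nrow(counts)) {
    out <- data.table(contig = character(), pos = integer(),
                      strand = character(), edited = integer(),
                      unedited = integer(), ratio = numeric(),
                      depth = integer(), hyper = logical(),
                      sample = character())
    setattr(out, "class", c("edit_sites", class(out)))
    return(out[])
  }
  refbase <- substring(g[counts$contig], counts$pos, counts$pos)
  is_a <- (counts$strand == "+" & refbase == "A") |
          (counts$strand == "-" & refbase == "T")
  out <- counts[is_a & G > 0L,
                .(contig, pos, strand, edited = G, unedited = A,
                  ratio = G / (A + G), depth, hyper = G_rescued > 0L, sample)]
  setattr(out, "class", c("edit_sites", class(out)))
  out[]
}

#' High-confidence cohort filter
#'
#' @param min_samples Minimum number of samples that must individually
#'   qualify (default 3).
#' @param min_edited_reads Strict lower bound on edited reads per qualifying
#'   sample: edited reads must be **greater than** this value (default 5,
#'   i.e. at least 6).
#' @param ratio_low,ratio_high Open-interval bounds on the per-sample edit
#'   ratio of a qualifying sample: the rate must be greater than `ratio_low`
#'   and less than `ratio_high`. The lower bound removes low-editing loci,
#'   the upper bound likely genomic variants.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_samples = 3L, min_edited_reads = 5L,
                          ratio_low = 0.1, ratio_high = 0.9) {
  if (!(ratio_low >= 0 && ratio_low < ratio_high && ratio_high <= 1)) {
    stop("need 0 <= ratio_low < ratio_high <= 1")
  }
  structure(list(min_samples = as.integer(min_samples),
                 min_edited_reads = as.integer(min_edited_reads),
                 ratio_low = ratio_low, ratio_high = ratio_high),
            class = "filter_config")
}

#' Filter a cohort of edit sites to high-confidence sites
#'
#' A site is kept iff at least `min_samples` samples individually satisfy
#' edited reads strictly greater than `min_edited_reads` and an edit ratio
#' strictly between `ratio_low` and `ratio_high`.
#'
#' @param cohort An `edit_sites` table covering all samples (rbind of
#'   per-sample [call_candidate_sites()] output).
#' @param filter A [filter_config()].
#' @return The cohort subset at kept sites (all per-sample rows retained,
#'   including non-qualifying ones), with the kept site keys as attribute
#'   `"kept_sites"`.
#' @export
filter_high_confidence <- function(cohort, filter = filter_config()) {
  stopifnot(inherits(filter, "filter_config"))
  n_samples <- length(unique(cohort$sample))
  if (n_samples < filter$min_samples) {
    warning(sprintf("cohort has %d samples but %d qualifying samples are required; no site can pass",
                    n_samples, filter$min_samples))
    return(cohort[0L])
  }
  qual <- cohort[edited > filter$min_edited_reads &
                 ratio > filter$ratio_low & ratio < filter$ratio_high,
                 .(n_qual = uniqueN(sample)), by = .(contig, pos, strand)]
  kept <- qual[n_qual >= filter$min_samples, .(contig, pos, strand)]
  out <- merge(cohort, kept, by = c("contig", "pos", "strand"))
  setattr(out, "class", unique(c("edit_sites", class(out))))
  setattr(out, "kept_sites", kept)
  out[]
}
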