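#' Configuration for the synthetic genome generator
#'
#' The generator emulates the genomic context in which A-to-I editing is
#' observed: multi-exon genes on both strands with 5'UTR/CDS/intron/3'UTR
#' structure, SINE-like repeat intervals concentrated in introns and 3'UTRs,
#' and intramolecular inverted repeats (dsRNA stem-loops, the ADAR substrate)
#' planted in introns.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bases.
#' @param n_genes Total number of genes across all contigs.
#' @param minus_strand_fraction Fraction of genes placed on the minus strand.
#' @param repeat_density Approximate fraction of 3'UTR/intron bases covered by
#'   repeat intervals.
#' @param inverted_repeat_arms List of `c(arm_length, loop_length)` pairs; one
#'   exact inverted repeat per pair is planted into an intron.
#' @param rng_seed Integer seed; identical seeds give byte-identical output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_contigs = 2L,
                         contig_length = 50000L,
                         n_genes = 8L,
                         minus_strand_fraction = 0.375,
                         repeat_density = 0.3,
                         inverted_repeat_arms = list(c(30L, 50L)),
                         rng_seed = 1L) {
  check_positive(n_contigs, "n_contigs")
  check_positive(contig_length, "contig_length")
  check_positive(n_genes, "n_genes")
  check_proportion(minus_strand_fraction, "minus_strand_fraction")
  check_proportion(repeat_density, "repeat_density")
  for (arm in inverted_repeat_arms) {
    if (length(arm) != 2L || any(arm <= 0)) {
      stop("each inverted_repeat_arms entry must be c(arm_length, loop_length), both > 0")
    }
  }
  structure(list(
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    n_genes = as.integer(n_genes),
    minus_strand_fraction = minus_strand_fraction,
    repeat_density = repeat_density,
    inverted_repeat_arms = inverted_repeat_arms,
    rng_seed = as.integer(rng_seed)
  ), class = "synth_config")
}

# Fixed single-transcript gene template, lengths in transcript order.
# Exons are >= 450 bp so that unspliced fragments fit inside one exon
# (the aligner is ungapped; see the methods vignette).
gene_template <- function() {
  list(
    features = c("five_prime_utr", "CDS", "intron", "CDS", "intron", "CDS",
                 "three_prime_utr"),
    lengths  = c(150L, 300L, 800L, 450L, 800L, 351L, 300L)
  )
}

#' Generate a synthetic genome with gene models and repeat annotation
#'
#' Builds random contigs, places non-overlapping single-transcript genes with
#' 5'UTR/CDS/intron/3'UTR structure on both strands, plants exact inverted
#' repeats in introns, and lays down labelled repeat intervals (SINE, LINE,
#' LTR, Simple_repeat) over intronic and 3'UTR territory. The first
#' minus-strand gene carries an AGC serine codon (editable to GGC glycine) and
#' the first plus-strand gene a CAG glutamine codon (editable to CGG arginine),
#' so codon-consequence calls have guaranteed substrate.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_genome` with elements `genome`
#'   (named character vector of contig sequences), `features` (data.table of
#'   gene features, 1-based closed coordinates), `genes` (per-gene summary),
#'   `repeats` (repeat intervals with class labels), `inverted_repeats`
#'   (planted stem-loop truth), and `config`.
#' @export
generate_genome <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$rng_seed)
  tpl <- gene_template()
  gene_span <- sum(tpl$lengths)

  per_contig <- diff(round(seq(0, config$n_genes, length.out = config$n_contigs + 1L)))
  if (any(per_contig * (gene_span + 400L) + 400L > config$contig_length)) {
    stop(sprintf("contig_length %d too short for %d genes of span %d (need >= %d)",
                 config$contig_length, max(per_contig), gene_span,
                 max(per_contig) * (gene_span + 400L) + 400L))
  }

  n_minus <- round(config$n_genes * config$minus_strand_fraction)
  strands <- rep("+", config$n_genes)
  if (n_minus > 0) strands[sample.int(config$n_genes, n_minus)] <- "-"

  contigs <- vapply(seq_len(config$n_contigs), function(i) {
    paste(sample(DNA_BASES, config$contig_length, replace = TRUE), collapse = "")
  }, character(1))
  names(contigs) <- sprintf("chr%d", seq_len(config$n_contigs))

  feats <- list()
  genes <- list()
  gi <- 0L
  for (ci in seq_len(config$n_contigs)) {
    ng <- per_contig[ci]
    if (ng == 0L) next
    gap <- (config$contig_length - ng * gene_span) %/% (ng + 1L)
    for (k in seq_len(ng)) {
      gi <- gi + 1L
      gstart <- gap * k + gene_span * (k - 1L) + 1L
      gid <- sprintf("gene%02d", gi)
      strand <- strands[gi]
      # genomic order of blocks: transcript order for '+', reversed for '-'
      ord <- if (strand == "+") seq_along(tpl$features) else rev(seq_along(tpl$features))
      lens <- tpl$lengths[ord]
      starts <- gstart + c(0L, cumsum(lens))[seq_along(lens)]
      feats[[gi]] <- data.table(
        contig = names(contigs)[ci],
        start = starts, end = starts + lens - 1L,
        strand = strand,
        feature = tpl$features[ord],
        gene_id = gid, transcript_id = paste0(gid, ".t1")
      )
      genes[[gi]] <- data.table(
        gene_id = gid, contig = names(contigs)[ci],
        start = gstart, end = gstart + gene_span - 1L, strand = strand
      )
    }
  }
  features <- rbindlist(feats)
  genes <- rbindlist(genes)

  # plant guaranteed consequence substrate: codon written on transcript strand
  plant_codon <- function(contigs, gid_, codon_index, codon) {
    cds <- features[gene_id == gid_ & feature == "CDS"]
    strand <- cds$strand[1L]
    tx_off <- 3L * (codon_index - 1L) + 1L            # codon start in CDS, tx coords
    gpos <- cds_tx_to_genomic(cds, tx_off + 0:2)      # genomic positions of codon
    seq_plus <- if (strand == "+") codon else revcomp(codon)
    pos_plus <- sort(gpos)
    s <- contigs[[cds$contig[1L]]]
    substr(s, pos_plus[1L], pos_plus[3L]) <- seq_plus
    contigs[[cds$contig[1L]]] <- s
    contigs
  }
  first_plus <- genes[strand == "+"]$gene_id
  first_minus <- genes[strand == "-"]$gene_id
  if (length(first_plus)) contigs <- plant_codon(contigs, first_plus[1L], 20L, "CAG")
  if (length(first_minus)) contigs <- plant_codon(contigs, first_minus[1L], 10L, "AGC")

  # plant inverted repeats into intron 1 of successive genes
  irs <- list()
  if (length(config$inverted_repeat_arms)) {
    introns <- features[feature == "intron"]
    setkey(introns, gene_id)
    host_genes <- rep(genes$gene_id, length.out = length(config$inverted_repeat_arms))
    for (j in seq_along(config$inverted_repeat_arms)) {
      arm_len <- as.integer(config$inverted_repeat_arms[[j]][1L])
      loop_len <- as.integer(config$inverted_repeat_arms[[j]][2L])
      host <- introns[gene_id == host_genes[j]][1L]
      need <- 2L * arm_len + loop_len
      if (host$end - host$start + 1L < need + 20L) {
        stop("intron too short to host requested inverted repeat")
      }
      p <- host$start + 10L
      arm <- paste(sample(DNA_BASES, arm_len, replace = TRUE), collapse = "")
      s <- contigs[[host$contig]]
      substr(s, p, p + arm_len - 1L) <- arm
      substr(s, p + arm_len + loop_len, p + need - 1L) <- revcomp(arm)
      # guard bases: a C on both sides of each arm boundary cannot base-pair
      # (C-C), so the planted arms are maximal by construction
      substr(s, p - 1L, p - 1L) <- "C"
      substr(s, p + need, p + need) <- "C"
      substr(s, p + arm_len, p + arm_len) <- "C"
      substr(s, p + arm_len + loop_len - 1L, p + arm_len + loop_len - 1L) <- "C"
      contigs[[host$contig]] <- s
      irs[[j]] <- data.table(
        contig = host$contig, gene_id = host$gene_id,
        arm1_start = p, arm1_end = p + arm_len - 1L,
        arm2_start = p + arm_len + loop_len, arm2_end = p + need - 1L,
        arm_length = arm_len, loop_length = loop_len
      )
    }
  }
  inverted_repeats <- if (length(irs)) rbindlist(irs) else
    data.table(contig = character(), gene_id = character(),
               arm1_start = integer(), arm1_end = integer(),
               arm2_start = integer(), arm2_end = integer(),
               arm_length = integer(), loop_length = integer())

  repeats <- place_repeats(features, config$repeat_density)

  structure(list(genome = contigs, features = features, genes = genes,
                 repeats = repeats, inverted_repeats = inverted_repeats,
                 config = config),
            class = "synth_genome")
}

# map CDS transcript offsets (1-based within the concatenated CDS) to genomic
# positions; cds is the feature table subset for one gene's CDS blocks
cds_tx_to_genomic <- function(cds, tx_pos) {
  str1 <- cds$strand[1L]
  cds <- if (str1 == "+") cds[order(start)] else cds[order(-start)]
  lens <- cds$end - cds$start + 1L
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  vapply(tx_pos, function(p) {
    b <- which(p >= starts & p <= ends)[1L]
    off <- p - starts[b]
    if (str1 == "+") cds$start[b] + off else cds$end[b] - off
  }, numeric(1))
}

place_repeats <- function(features, density) {
  host <- features[feature %in% c("intron", "three_prime_utr")]
  classes <- c("SINE", "LINE", "LTR", "Simple_repeat")
  probs <- c(0.6, 0.2, 0.1, 0.1)
  out <- list()
  ri <- 0L
  for (i in seq_len(nrow(host))) {
    len <- host$end[i] - host$start[i] + 1L
    target <- round(len * density)
    covered <- 0L
    cursor <- host$start[i]
    while (covered < target && cursor < host$end[i] - 80L) {
      rl <- sample(80:280, 1L)
      gap <- sample(20:150, 1L)
      s <- cursor + gap
      e <- min(s + rl - 1L, host$end[i])
      if (e - s + 1L >= 50L) {
        ri <- ri + 1L
        out[[ri]] <- data.table(
          contig = host$contig[i], start = s, end = e,
          class = sample(classes, 1L, prob = probs),
          strand = host$strand[i]
        )
        covered <- covered + (e - s + 1L)
      }
      cursor <- e + 1L
    }
  }
  if (length(out)) rbindlist(out) else
    data.table(contig = character(), start = integer(), end = integer(),
               class = character(), strand = character())
}
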