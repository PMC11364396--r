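#' Collapse the A/G distinction in a DNA sequence
#'
#' Substitutes every A with G, the pseudo-genome transform used to rescue
#' hyper-edited reads: after transforming both the read and the reference,
#' A-to-G mismatches vanish while all other mismatches survive. Idempotent.
#'
#' @param sequence Character vector of uppercase DNA (A/C/G/T/N).
#' @return Transformed sequences, same lengths.
#' @export
transform_a_to_g <- function(sequence) {
  check_dna_alphabet(sequence, "sequence")
  chartr("A", "G", sequence)
}

# the mirror transform for the opposite read orientation: T->C
transform_t_to_c <- function(sequence) {
  check_dna_alphabet(sequence, "sequence")
  chartr("T", "C", sequence)
}

#' Alignment and rescue parameters
#'
#' @param max_mismatches Maximum substitutions tolerated in the primary
#'   ungapped pass.
#' @param seed_kmer Seed k-mer length (>= 8). The seed-and-extend search is
#'   exhaustive for reads with fewer mismatches than the number of disjoint
#'   seed tiles (`floor(read_length / seed_kmer)`).
#' @param rescue_min_ag_sites Minimum A-to-G mismatches for a rescued read.
#' @param rescue_min_ag_fraction Minimum fraction of a rescued read's
#'   mismatches that must be A-to-G.
#' @param rescue_max_other_mismatches Maximum non-A-to-G mismatches tolerated
#'   in a rescued read.
#' @param max_seed_hits Seeds occurring at more loci than this are skipped
#'   (repeat masking).
#' @return A list of class `align_params`.
#' @export
align_params <- function(max_mismatches = 4L, seed_kmer = 12L,
                         rescue_min_ag_sites = 3L,
                         rescue_min_ag_fraction = 0.6,
                         rescue_max_other_mismatches = 2L,
                         max_seed_hits = 64L) {
  if (seed_kmer < 8L) stop("seed_kmer must be >= 8")
  if (max_mismatches < 0L || rescue_min_ag_sites < 0L ||
      rescue_max_other_mismatches < 0L) {
    stop("mismatch counts must be >= 0")
  }
  check_proportion(rescue_min_ag_fraction, "rescue_min_ag_fraction")
  structure(list(max_mismatches = as.integer(max_mismatches),
                 seed_kmer = as.integer(seed_kmer),
                 rescue_min_ag_sites = as.integer(rescue_min_ag_sites),
                 rescue_min_ag_fraction = rescue_min_ag_fraction,
                 rescue_max_other_mismatches = as.integer(rescue_max_other_mismatches),
                 max_seed_hits = as.integer(max_seed_hits)),
            class = "align_params")
}

# Concatenate contigs (with an unalignable pad) and hash every k-mer.
# Returned object carries the raw bytes for vectorised mismatch counting.
build_index <- function(genome, k, pad = 200L) {
  g <- as_genome_chr(genome)
  padding <- strrep("?", pad)
  concat <- paste(g, collapse = padding)
  offsets <- cumsum(c(1L, head(nchar(g) + pad, -1L)))
  n <- nchar(concat)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(concat, starts, starts + k - 1L)
  keep <- !grepl("?", kmers, fixed = TRUE)
  index <- split(starts[keep], kmers[keep])
  list(concat = concat, raw = charToRaw(concat), index = index, k = k,
       contigs = names(g), offsets = offsets, lengths = nchar(g))
}

concat_to_contig <- function(idx, pos) {
  ci <- findInterval(pos, idx$offsets)
  data.table(contig = idx$contigs[ci], pos = as.integer(pos - idx$offsets[ci] + 1L))
}

# Exhaustively score candidate placements for equal-length reads.
# Returns, per read: best mismatch count, its placement, and multiplicity.
score_candidates <- function(seqs_fwd, seqs_rev, idx, params) {
  L <- nchar(seqs_fwd[1L])
  k <- idx$k
  offs <- seq(1L, L - k + 1L, by = k)
  n <- length(seqs_fwd)
  nc <- nchar(idx$concat)

  cands <- list()
  for (orient in c("+", "-")) {
    oriented <- if (orient == "+") seqs_fwd else seqs_rev
    for (o in offs) {
      seeds <- substring(oriented, o, o + k - 1L)
      hits <- idx$index[seeds]
      nh <- lengths(hits)
      nh[is.na(names(hits)) | nh > params$max_seed_hits] <- 0L
      if (!sum(nh)) next
      ridx <- rep.int(seq_len(n), nh)
      starts <- unlist(hits[nh > 0L], use.names = FALSE) - o + 1L
      cands[[length(cands) + 1L]] <- data.table(read = ridx, start = starts,
                                                orient = orient)
    }
  }
  if (!length(cands)) {
    return(data.table(read = integer(), start = integer(), orient = character(),
                      mm = integer()))
  }
  cands <- unique(rbindlist(cands))
  cands <- cands[start >= 1L & start + L - 1L <= nc]
  if (nrow(cands)) {
    # drop placements that would run off the end of a contig into the pad
    loc <- concat_to_contig(idx, cands$start)
    cands <- cands[loc$pos + L - 1L <= idx$lengths[match(loc$contig, idx$contigs)]]
  }
  if (!nrow(cands)) {
    return(data.table(read = integer(), start = integer(), orient = character(),
                      mm = integer()))
  }

  # vectorised mismatch counting over raw bytes
  fwd_raw <- charToRaw(paste(seqs_fwd, collapse = ""))
  rev_raw <- charToRaw(paste(seqs_rev, collapse = ""))
  score_block <- function(block, read_raw) {
    ref_idx <- sequence(rep.int(L, nrow(block)), from = block$start)
    rd_idx <- sequence(rep.int(L, nrow(block)), from = (block$read - 1L) * L + 1L)
    neq <- idx$raw[ref_idx] != read_raw[rd_idx]
    as.integer(colSums(matrix(neq, nrow = L)))
  }
  # blocks keep peak memory modest
  cands[, mm := NA_integer_]
  for (orient_ in c("+", "-")) {
    sel <- which(cands$orient == orient_)
    if (!length(sel)) next
    rr <- if (orient_ == "+") fwd_raw else rev_raw
    step <- 200000L
    for (b in split(sel, ceiling(seq_along(sel) / step))) {
      set(cands, i = b, j = "mm", value = score_block(cands[b], rr))
    }
  }
  cands
}

#' Ungapped seed-and-extend alignment of equal-length reads
#'
#' A read is placed wherever an ungapped alignment with at most
#' `max_mismatches` substitutions exists (either orientation). Reads with a
#' unique best placement are aligned; reads with several equally good best
#' placements are discarded as multi-mappers; the rest form the unaligned
#' pool handed to [hyper_rescue()].
#'
#' @param reads Read table (`qname, mate, seq`) from [simulate_reads()] /
#'   [read_fastq()], or a plain character vector of sequences.
#' @param genome Named character vector or `DNAStringSet` of contigs (or a
#'   `synth_genome`); alternatively a prebuilt index via the `index` argument.
#' @param params An [align_params()].
#' @param index Optional prebuilt index from a previous call (reused across
#'   samples).
#' @return A list with `aligned` (data.table: `qname, mate, contig, pos,
#'   orient, mm, seq_plus, rescued`), `unaligned` (read table subset),
#'   `multi` (discarded multi-mappers), and `index`.
#' @export
toy_align <- function(reads, genome = NULL, params = align_params(),
                      index = NULL) {
  if (is.character(reads)) {
    reads <- data.table(qname = sprintf("read%06d", seq_along(reads)),
                        mate = 2L, seq = reads)
  }
  if (is.null(index)) index <- build_index(genome, params$seed_kmer)
  stopifnot(all(nchar(reads$seq) == nchar(reads$seq[1L])))
  L <- nchar(reads$seq[1L])
  if (L < index$k) stop("reads shorter than seed k-mer")

  fwd <- reads$seq
  rev <- revcomp(fwd)
  cands <- score_candidates(fwd, rev, index, params)
  hits <- cands[mm <= params$max_mismatches]
  status <- rep("unaligned", nrow(reads))
  placement <- NULL
  if (nrow(hits)) {
    best <- hits[, .SD[mm == min(mm)], by = read]
    nbest <- best[, .N, by = read]
    uniq <- nbest[N == 1L]$read
    multi <- nbest[N > 1L]$read
    status[uniq] <- "aligned"
    status[multi] <- "multi"
    placement <- best[read %in% uniq]
  }

  aligned <- data.table(qname = character(), mate = integer(),
                        contig = character(), pos = integer(),
                        orient = character(), mm = integer(),
                        seq_plus = character(), rescued = logical())
  if (!is.null(placement) && nrow(placement)) {
    loc <- concat_to_contig(index, placement$start)
    aligned <- data.table(
      qname = reads$qname[placement$read],
      mate = reads$mate[placement$read],
      contig = loc$contig, pos = loc$pos,
      orient = placement$orient, mm = placement$mm,
      seq_plus = ifelse(placement$orient == "+",
                        fwd[placement$read], rev[placement$read]),
      rescued = FALSE
    )
  }
  list(aligned = aligned,
       unaligned = reads[status == "unaligned"],
       multi = reads[status == "multi"],
       index = index)
}

#' Rescue hyper-edited reads via transformed pseudo-genomes
#'
#' Each unaligned read is aligned, in both orientations, to the A-to-G
#' transformed genome (after A-to-G transforming the read) and to the T-to-C
#' transformed genome (after T-to-C transforming the read), covering both
#' transcript orientations of a stranded library. On a unique placement the
#' ORIGINAL read is compared with the ORIGINAL genome at that locus; the read
#' is accepted as hyper-edited iff its editing-consistent mismatches (ref A /
#' read G on the matched route, equivalently ref T / read C on the mirror
#' route) number at least `rescue_min_ag_sites`, make up at least
#' `rescue_min_ag_fraction` of all mismatches, and at most
#' `rescue_max_other_mismatches` other mismatches remain.
#'
#' @param unaligned Read table (`qname, mate, seq`) from [toy_align()].
#' @param genome Genome as in [toy_align()] (the original, untransformed one).
#' @param params An [align_params()].
#' @param index Optional prebuilt original-genome index (only used to avoid
#'   rebuilding transformed indexes' contig table).
#' @return A list with `rescued` (aligned table as in [toy_align()], with
#'   `rescued = TRUE` and columns `n_ag`, `n_other`) and `n_unrescued`.
#' @export
hyper_rescue <- function(unaligned, genome, params = align_params(),
                         index = NULL) {
  g <- as_genome_chr(genome)
  empty <- data.table(qname = character(), mate = integer(),
                      contig = character(), pos = integer(),
                      orient = character(), mm = integer(),
                      seq_plus = character(), rescued = logical(),
                      n_ag = integer(), n_other = integer())
  if (!nrow(unaligned)) return(list(rescued = empty, n_unrescued = 0L))

  routes <- list(
    AG = list(ref = transform_a_to_g(g), tx = transform_a_to_g,
              ref_base = "A", alt_base = "G"),
    TC = list(ref = transform_t_to_c(g), tx = transform_t_to_c,
              ref_base = "T", alt_base = "C")
  )
  out <- list()
  for (rname in names(routes)) {
    rt <- routes[[rname]]
    tr_reads <- copy(unaligned)
    # transform AFTER orienting would differ: A->G of revcomp != revcomp of
    # A->G. toy_align revcomps internally, so transform both orientations by
    # aligning the transformed read and the transformed revcomp separately.
    res <- align_transformed(tr_reads, rt$tx, rt$ref, params)
    if (!nrow(res)) next
    res[, route := rname]
    out[[rname]] <- res
  }
  if (!length(out)) return(list(rescued = empty, n_unrescued = nrow(unaligned)))
  hits <- rbindlist(out)

  # verify against the original genome
  ref <- substring(g[hits$contig], hits$pos, hits$pos + nchar(hits$seq_plus[1L]) - 1L)
  stats <- mismatch_stats(ref, hits$seq_plus,
                          ref_base = ifelse(hits$route == "AG", "A", "T"),
                          alt_base = ifelse(hits$route == "AG", "G", "C"))
  hits[, `:=`(n_ag = stats$n_edit, n_other = stats$n_other,
              mm = stats$n_edit + stats$n_other)]
  acc <- hits[n_ag >= params$rescue_min_ag_sites &
              n_ag >= params$rescue_min_ag_fraction * mm &
              n_other <= params$rescue_max_other_mismatches]
  # a read accepted by both routes keeps the one with more editing evidence
  setorder(acc, qname, mate, -n_ag)
  acc <- acc[!duplicated(paste(qname, mate))]
  acc[, rescued := TRUE]
  acc[, route := NULL]
  rescued_keys <- paste(acc$qname, acc$mate)
  n_unres <- sum(!paste(unaligned$qname, unaligned$mate) %in% rescued_keys)
  list(rescued = acc[], n_unrescued = n_unres)
}

# align transformed reads to a transformed reference; returns unique
# placements with the ORIGINAL plus-oriented sequence attached
align_transformed <- function(reads, tx_fun, ref_tx, params) {
  idx <- build_index(ref_tx, params$seed_kmer)
  L <- nchar(reads$seq[1L])
  fwd_orig <- reads$seq
  rev_orig <- revcomp(fwd_orig)
  fwd <- tx_fun(fwd_orig)
  rev <- tx_fun(rev_orig)
  cands <- score_candidates(fwd, rev, idx, params)
  hits <- cands[mm <= params$max_mismatches]
  if (!nrow(hits)) {
    return(data.table(qname = character(), mate = integer(),
                      contig = character(), pos = integer(),
                      orient = character(), seq_plus = character()))
  }
  best <- hits[, .SD[mm == min(mm)], by = read]
  nbest <- best[, .N, by = read]
  best <- best[read %in% nbest[N == 1L]$read]
  if (!nrow(best)) {
    return(data.table(qname = character(), mate = integer(),
                      contig = character(), pos = integer(),
                      orient = character(), seq_plus = character()))
  }
  loc <- concat_to_contig(idx, best$start)
  data.table(qname = reads$qname[best$read], mate = reads$mate[best$read],
             contig = loc$contig, pos = loc$pos, orient = best$orient,
             seq_plus = ifelse(best$orient == "+",
                               fwd_orig[best$read], rev_orig[best$read]))
}

# per-pair mismatch tallies between equal-length ref and read strings,
# split into editing-consistent (ref_base -> alt_base) and other
mismatch_stats <- function(ref, read, ref_base, alt_base) {
  n <- length(ref)
  if (!n) return(list(n_edit = integer(), n_other = integer()))
  L <- nchar(ref[1L])
  ref_m <- matrix(charToRaw(paste(ref, collapse = "")), nrow = L)
  read_m <- matrix(charToRaw(paste(read, collapse = "")), nrow = L)
  neq <- ref_m != read_m
  rb <- matrix(rep(vapply(ref_base, charToRaw, raw(1)), each = L), nrow = L)
  ab <- matrix(rep(vapply(alt_base, charToRaw, raw(1)), each = L), nrow = L)
  is_edit <- neq & (ref_m == rb) & (read_m == ab)
  list(n_edit = as.integer(colSums(is_edit)),
       n_other = as.integer(colSums(neq & !is_edit)))
}

#' List per-read mismatches against the genome
#'
#' @param aligned Aligned read table (rows from [toy_align()] or
#'   [hyper_rescue()]).
#' @param genome Genome (original, untransformed).
#' @return data.table `qname, mate, contig, pos, ref, read` with one row per
#'   mismatching position (1-based genomic).
#' @export
read_mismatches <- function(aligned, genome) {
  g <- as_genome_chr(genome)
  out <- list()
  for (i in seq_len(nrow(aligned))) {
    L <- nchar(aligned$seq_plus[i])
    ref <- substring(g[[aligned$contig[i]]], aligned$pos[i],
                     aligned$pos[i] + L - 1L)
    rr <- strsplit(ref, "")[[1L]]
    qq <- strsplit(aligned$seq_plus[i], "")[[1L]]
    d <- which(rr != qq)
    if (length(d)) {
      out[[length(out) + 1L]] <- data.table(
        qname = aligned$qname[i], mate = aligned$mate[i],
        contig = aligned$contig[i], pos = aligned$pos[i] + d - 1L,
        ref = rr[d], read = qq[d])
    }
  }
  if (length(out)) rbindlist(out) else
    data.table(qname = character(), mate = integer(), contig = character(),
               pos = integer(), ref = character(), read = character())
}
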