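#' Parameters for the stranded paired-end read simulator
#'
#' Defaults emulate a stranded total RNA-seq library sequenced in a 2 x 75 bp
#' paired-end configuration with F2R1 orientation (the second-in-pair read
#' matches the transcript strand).
#'
#' @param read_length Read length in bases (75 or 100).
#' @param fragment_mean,fragment_sd Fragment length distribution (bases).
#' @param depth Mean per-base coverage over exonic territory.
#' @param error_rate Per-base substitution error probability, in `[0, 0.05]`.
#' @param intron_fraction Intronic coverage as a fraction of exonic coverage;
#'   nascent-transcript editing makes intronic signal worth simulating.
#' @return A list of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 75L, fragment_mean = 220L,
                            fragment_sd = 25L, depth = 50,
                            error_rate = 0.001, intron_fraction = 0.2) {
  if (!read_length %in% c(75L, 100L)) stop("read_length must be 75 or 100")
  check_positive(depth, "depth")
  if (error_rate < 0 || error_rate > 0.05) stop("error_rate must be in [0, 0.05]")
  if (read_length > fragment_mean) stop("read_length must be <= mean fragment length")
  check_proportion(intron_fraction, "intron_fraction")
  structure(list(read_length = as.integer(read_length),
                 fragment_mean = as.integer(fragment_mean),
                 fragment_sd = as.numeric(fragment_sd),
                 depth = depth, error_rate = error_rate,
                 intron_fraction = intron_fraction),
            class = "read_sim_params")
}

#' Simulate stranded paired-end reads with planted editing
#'
#' Draws fragments feature-by-feature (fragments never span introns, matching
#' the ungapped aligner), applies each covered planted site's A-to-G edit on
#' the transcript strand with its per-group rate (independently per fragment;
#' jointly per fragment for hyper-cluster sites), then applies sequencing
#' errors and reports the pair in F2R1 orientation: read 2 is the fragment
#' 5' end on the transcript strand, read 1 the reverse complement of its
#' 3' end. For minus-strand genes the planted edits therefore appear as
#' T-to-C mismatches against the plus-strand reference.
#'
#' @param sg A `synth_genome`.
#' @param plan An `editing_plan`; sites must lie within gene territory.
#' @param params A [read_sim_params()].
#' @param sample_id Sample identifier (used in read names).
#' @param group Group label; selects the `rate_<group>` column of `plan`.
#' @param seed Integer seed; identical inputs and seed give identical reads.
#' @return A `data.table` with one row per read: `qname, mate, seq, qual,
#'   contig, frag_start, frag_end, gene_id, tstrand`. The per-fragment edit
#'   truth (which planted sites were edited on which fragment) is attached as
#'   attribute `"edits"`.
#' @export
simulate_reads <- function(sg, plan, params, sample_id, group, seed = 1L) {
  stopifnot(inherits(sg, "synth_genome"), inherits(params, "read_sim_params"))
  rate_col <- paste0("rate_", group)
  if (!rate_col %in% names(plan)) {
    stop(sprintf("plan has no rates for group '%s'", group))
  }
  in_gene <- plan$gene_id %in% sg$features$gene_id
  if (!all(in_gene)) {
    stop(sprintf("planted site %s:%d lies outside any gene",
                 plan$contig[which(!in_gene)[1L]], plan$pos[which(!in_gene)[1L]]))
  }
  set.seed(as.integer(seed))
  L <- params$read_length

  frags <- draw_fragments(sg, params)
  edits <- decide_edits(frags, plan, rate_col)
  seqs <- fragment_sequences(sg, frags, edits)

  r2 <- substr(seqs$tx_seq, 1L, L)
  r1 <- revcomp(substring(seqs$tx_seq, frags$len - L + 1L, frags$len))
  qn <- sprintf("%s:frag%06d", sample_id, seq_len(nrow(frags)))

  reads <- data.table(
    qname = rep(qn, 2L),
    mate = rep(c(1L, 2L), each = nrow(frags)),
    seq = c(r1, r2),
    contig = rep(frags$contig, 2L),
    frag_start = rep(frags$start, 2L),
    frag_end = rep(frags$end, 2L),
    gene_id = rep(frags$gene_id, 2L),
    tstrand = rep(frags$strand, 2L)
  )
  reads[, seq := apply_errors(seq, params$error_rate)]
  reads[, qual := strrep("I", L)]
  if (nrow(edits)) edits[, qname := qn[frag_idx]]
  setattr(reads, "edits", edits)
  reads[]
}

draw_fragments <- function(sg, params) {
  feats <- sg$features
  out <- list()
  L <- params$read_length
  for (i in seq_len(nrow(feats))) {
    f <- feats[i]
    flen <- f$end - f$start + 1L
    dep <- params$depth *
      (if (f$feature == "intron") params$intron_fraction else 1)
    n <- rpois(1L, dep * flen / min(2L * L, params$fragment_mean))
    if (n == 0L) next
    fl <- pmax(L, pmin(flen, round(rnorm(n, params$fragment_mean, params$fragment_sd))))
    s <- f$start + floor(runif(n) * (flen - fl + 1L))
    out[[i]] <- data.table(contig = f$contig, start = as.integer(s),
                           len = as.integer(fl),
                           gene_id = f$gene_id, strand = f$strand)
  }
  frags <- rbindlist(out)
  frags[, end := start + len - 1L]
  frags[, frag_idx := .I]
  frags
}

# which planted sites get the edit on which fragment
decide_edits <- function(frags, plan, rate_col) {
  empty <- data.table(frag_idx = integer(), contig = character(),
                      pos = integer(), strand = character(),
                      site_id = character())
  if (!nrow(plan) || !nrow(frags)) return(empty)
  p <- as.data.table(plan)[, .(site_id, contig, pos, strand, gene_id,
                               cluster_id, hyper,
                               rate = get(rate_col))]
  p[, s2 := pos][, e2 := pos]
  fr <- frags[, .(frag_idx, contig, gene_id, start, end)]
  setkey(fr, contig, start, end)
  ov <- foverlaps(p[, .(site_id, contig, start = s2, end = e2, strand, pos,
                        cluster_id, hyper, rate, gene_id)],
                  fr, by.x = c("contig", "start", "end"),
                  nomatch = NULL)
  ov <- copy(ov[gene_id == i.gene_id])
  if (!nrow(ov)) return(empty)
  # independent Bernoulli per (fragment, site); one joint draw per
  # (fragment, cluster) edits every covered cluster site
  ov[, edited := FALSE]
  solo <- is.na(ov$cluster_id) | ov$cluster_id == ""
  ov[solo, edited := runif(.N) < rate]
  if (any(!solo)) {
    cl <- copy(ov[!solo])
    draws <- cl[, .(rate = rate[1L]), by = .(frag_idx, cluster_id)]
    draws[, edited := runif(.N) < rate]
    cl[, edited := NULL]
    cl <- merge(cl, draws[, .(frag_idx, cluster_id, edited)],
                by = c("frag_idx", "cluster_id"), sort = FALSE)
    ov <- rbind(ov[solo], cl, fill = TRUE)
  }
  ov[edited == TRUE, .(frag_idx, contig, pos, strand, site_id)]
}

# plus-strand fragment substrings with edits applied, plus transcript-strand
# sequence (revcomp for minus-strand genes)
fragment_sequences <- function(sg, frags, edits) {
  seqs <- substring(sg$genome[frags$contig], frags$start, frags$end)
  if (nrow(edits)) {
    # A->G on the transcript strand is A->G (plus gene) or T->C (minus gene)
    ed <- merge(edits, frags[, .(frag_idx, start, strand_gene = strand)],
                by = "frag_idx", sort = FALSE)
    ed[, off := pos - start + 1L]
    ed[, newbase := ifelse(strand_gene == "+", "G", "C")]
    for (k in seq_len(nrow(ed))) {
      i <- ed$frag_idx[k]
      substr(seqs[i], ed$off[k], ed$off[k]) <- ed$newbase[k]
    }
  }
  tx <- seqs
  minus <- frags$strand == "-"
  if (any(minus)) tx[minus] <- revcomp(tx[minus])
  list(plus_seq = seqs, tx_seq = tx)
}

apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  L <- nchar(seqs[1L])
  n <- length(seqs)
  hit <- which(runif(n * L) < error_rate)
  for (idx in hit) {
    i <- (idx - 1L) %/% L + 1L
    off <- (idx - 1L) %% L + 1L
    old <- substr(seqs[i], off, off)
    substr(seqs[i], off, off) <- sample(setdiff(DNA_BASES, old), 1L)
  }
  seqs
}

#' Write paired reads to FASTQ files
#' @param reads Read table from [simulate_reads()].
#' @param r1_path,r2_path Output FASTQ paths (read 1 / read 2).
#' @return Invisibly, `c(r1_path, r2_path)`.
#' @export
write_fastq <- function(reads, r1_path, r2_path) {
  for (m in 1:2) {
    r <- reads[mate == m]
    path <- if (m == 1L) r1_path else r2_path
    con <- file(path, "w")
    writeLines(paste0("@", r$qname, "\n", r$seq, "\n+\n", r$qual), con)
    close(con)
  }
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a read table
#' @param r1_path,r2_path FASTQ paths for read 1 and read 2.
#' @return A `data.table` with `qname, mate, seq, qual`.
#' @export
read_fastq <- function(r1_path, r2_path) {
  one <- function(path, m) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    sq <- as.character(x)
    data.table(qname = sub(" .*", "", names(x)), mate = m,
               seq = sq, qual = strrep("I", nchar(sq)))
  }
  rbind(one(r1_path, 1L), one(r2_path, 2L))
}
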