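# Standard-format readers/writers. GTF/SAM are 1-based; BED/bedGraph 0-based
# half-open; internal tables are 1-based closed throughout.

#' Write a genome to FASTA
#' @param genome Named character vector or `DNAStringSet` (or `synth_genome`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  g <- as_genome_chr(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(g), path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return Named character vector of contig sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub(" .*", "", names(x))
  as_genome_chr(x)
}

#' Write gene models to GTF
#'
#' Emits gene, transcript, exon, CDS and UTR rows; introns are implicit
#' (recovered as gaps between exons on read-back).
#'
#' @param features Gene feature table (`sg$features`).
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(features, path) {
  feats <- as.data.table(features)
  rows <- list()
  for (gid in unique(feats$gene_id)) {
    f <- feats[gene_id == gid]
    tid <- f$transcript_id[1L]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
    span <- data.table(contig = f$contig[1L], source = "hyperedit",
                       feature = c("gene", "transcript"),
                       start = min(f$start), end = max(f$end),
                       strand = f$strand[1L], attrs = attrs)
    ex <- f[feature != "intron"]
    setorder(ex, start)
    # merge genomically contiguous non-intron blocks into exon rows
    grp <- cumsum(c(1L, tail(ex$start, -1L) != head(ex$end, -1L) + 1L))
    exons <- ex[, .(start = min(start), end = max(end)),
                by = .(grp = grp)][, grp := NULL]
    body <- rbind(
      data.table(contig = f$contig[1L], source = "hyperedit", feature = "exon",
                 start = exons$start, end = exons$end,
                 strand = f$strand[1L], attrs = attrs),
      data.table(contig = f$contig[1L], source = "hyperedit",
                 feature = ex$feature, start = ex$start, end = ex$end,
                 strand = f$strand[1L], attrs = attrs)
    )
    rows[[gid]] <- rbind(span, body)
  }
  dt <- rbindlist(rows)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   dt$contig, dt$source, dt$feature, dt$start, dt$end,
                   dt$strand, dt$attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Accepts GTFs written by [write_gtf()] or any GTF with exon/CDS/UTR rows
#' carrying `gene_id`/`transcript_id` attributes; introns are derived from
#' the gaps between each transcript's exons.
#'
#' @param path GTF path.
#' @return Feature table (`contig, start, end, strand, feature, gene_id,
#'   transcript_id`) including derived intron rows.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- tstrsplit(lines, "\t", fixed = TRUE)
  dt <- data.table(contig = f[[1L]], feature = f[[3L]],
                   start = as.integer(f[[4L]]), end = as.integer(f[[5L]]),
                   strand = f[[7L]], attrs = f[[9L]])
  dt[, gene_id := sub('.*gene_id "([^"]+)".*', "\\1", attrs)]
  dt[, transcript_id := fifelse(grepl("transcript_id", attrs),
                                sub('.*transcript_id "([^"]+)".*', "\\1", attrs),
                                paste0(gene_id, ".t1"))]
  keep <- dt[feature %in% c("CDS", "five_prime_utr", "three_prime_utr")]
  introns <- dt[feature == "exon",
                {
                  s <- sort(start); e <- sort(end)
                  if (.N > 1L) {
                    list(start = e[-.N] + 1L, end = s[-1L] - 1L,
                         feature = "intron")
                  } else list(start = integer(), end = integer(),
                              feature = character())
                },
                by = .(contig, strand, gene_id, transcript_id)]
  out <- rbind(keep[, .(contig, start, end, strand, feature, gene_id,
                        transcript_id)],
               introns[, .(contig, start, end, strand, feature, gene_id,
                           transcript_id)])
  setorder(out, contig, start)
  out[]
}

#' Write a repeat track to BED6
#' @param repeats Repeat table (`contig, start, end, class, strand`), 1-based
#'   closed.
#' @param path Output BED path (0-based half-open, name = repeat class).
#' @return `path`, invisibly.
#' @export
write_repeats_bed <- function(repeats, path) {
  r <- as.data.table(repeats)
  strand <- if ("strand" %in% names(r)) r$strand else "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     r$contig, r$start - 1L, r$end, r$class, strand), path)
  invisible(path)
}

#' Read a repeat track from BED
#' @param path BED path (name column = repeat class).
#' @return Repeat table with 1-based closed `start`/`end`.
#' @export
read_repeats <- function(path) {
  f <- tstrsplit(readLines(path), "\t", fixed = TRUE)
  data.table(contig = f[[1L]], start = as.integer(f[[2L]]) + 1L,
             end = as.integer(f[[3L]]), class = f[[4L]],
             strand = if (length(f) >= 6L) f[[6L]] else ".")
}

#' Write aligned (and optionally unaligned) reads to SAM
#'
#' Produces a valid single-end-record-per-mate SAM with `@SQ` headers.
#' Rescued reads carry `XE:i:<n>` (editing-consistent mismatch count) and all
#' aligned reads `NM:i:<n>`. Unaligned reads are emitted as unmapped records
#' so the rescue stage can run standalone from the SAM.
#'
#' @param aligned Aligned read table (`qname, mate, contig, pos, orient,
#'   mm, seq_plus, rescued`, optionally `n_ag`).
#' @param genome Genome (for `@SQ` lengths).
#' @param path Output SAM path.
#' @param unaligned Optional read table (`qname, mate, seq`) written as
#'   unmapped records.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aligned, genome, path, unaligned = NULL) {
  g <- as_genome_chr(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(g), nchar(g)),
           "@PG\tID:hyperedit\tPN:hyperedit")
  recs <- character()
  if (nrow(aligned)) {
    a <- as.data.table(aligned)
    if (!"rescued" %in% names(a)) a[, rescued := FALSE]
    flag <- 1L +                                    # paired
      ifelse(a$orient == "-", 16L, 0L) +            # read reverse strand
      ifelse(a$mate == 1L, 64L, 128L)               # first/second in pair
    L <- nchar(a$seq_plus)
    tags <- sprintf("NM:i:%d", a$mm)
    if ("n_ag" %in% names(a)) {
      tags <- ifelse(a$rescued, paste0(tags, sprintf("\tXE:i:%d", a$n_ag)), tags)
    }
    recs <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\t%s",
                    a$qname, flag, a$contig, a$pos, L,
                    a$seq_plus, strrep("I", L), tags)
  }
  urecs <- character()
  if (!is.null(unaligned) && nrow(unaligned)) {
    u <- as.data.table(unaligned)
    uflag <- 1L + 4L + ifelse(u$mate == 1L, 64L, 128L)
    urecs <- sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                     u$qname, uflag, u$seq, strrep("I", nchar(u$seq)))
  }
  writeLines(c(hdr, recs, urecs), path)
  invisible(path)
}

#' Read alignments from SAM/BAM
#'
#' Ingests SAM or BAM in place of FASTQ plus the built-in aligner. Only
#' ungapped records (cigar `<n>M`) enter the aligned table; unmapped records
#' form the unaligned pool handed to [hyper_rescue()].
#'
#' @param path SAM or BAM path.
#' @return A list with `aligned` (as produced by [toy_align()]) and
#'   `unaligned` (`qname, mate, seq`).
#' @export
read_alignments <- function(path) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("NM", "XE"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  flag <- x$flag
  mate <- ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L)
  unmapped <- bitwAnd(flag, 4L) > 0L
  seqs <- as.character(x$seq)
  xe <- x$tag$XE
  nm <- x$tag$NM
  if (is.null(xe)) xe <- rep(NA_integer_, length(flag))
  if (is.null(nm)) nm <- rep(NA_integer_, length(flag))
  ungapped <- !unmapped & grepl("^\\d+M$", x$cigar)
  skipped <- sum(!unmapped & !ungapped)
  if (skipped) warning(sprintf("skipping %d gapped/clipped records", skipped))
  aligned <- data.table(
    qname = x$qname[ungapped], mate = mate[ungapped],
    contig = as.character(x$rname[ungapped]), pos = x$pos[ungapped],
    orient = ifelse(bitwAnd(flag[ungapped], 16L) > 0L, "-", "+"),
    mm = nm[ungapped], seq_plus = seqs[ungapped],
    rescued = !is.na(xe[ungapped]), n_ag = xe[ungapped]
  )
  unaligned <- data.table(qname = x$qname[unmapped], mate = mate[unmapped],
                          seq = seqs[unmapped])
  list(aligned = aligned, unaligned = unaligned)
}

#' Write a cohort site table as VCF-like text
#'
#' CHROM/POS/REF/ALT columns (REF = A, ALT = G on the event strand; the
#' strand is in INFO) with per-sample `edited/unedited` in genotype-style
#' columns.
#'
#' @param cohort An `edit_sites` cohort table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_vcf <- function(cohort, path) {
  dt <- as.data.table(cohort)
  samples <- sort(unique(dt$sample))
  wide <- dcast(dt, contig + pos + strand ~ sample,
                value.var = c("edited", "unedited"), fill = 0L)
  gt_cols <- lapply(samples, function(s) {
    sprintf("%d/%d", wide[[paste0("edited_", s)]],
            wide[[paste0("unedited_", s)]])
  })
  hdr <- c("##fileformat=VCFv4.3-like",
           "##INFO=<ID=STRAND,Description=\"editing event strand\">",
           "##FORMAT=<ID=EU,Description=\"edited/unedited read counts\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- do.call(paste, c(list(wide$contig, wide$pos, ".", "A", "G", ".",
                                "PASS", paste0("STRAND=", wide$strand), "EU"),
                           gt_cols, sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
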