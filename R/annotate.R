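#' Assign each edit site a genomic region
#'
#' A site inside a gene on its event strand gets the finest containing
#' feature with precedence CDS > 3'UTR > 5'UTR > intron (the usual collapse
#' of mixed annotations). Failing a same-strand gene, any-strand gene
#' features are used (antisense context). A site outside all genes is
#' `proximal_intergenic` within `flank` bases of any transcription start or
#' end site, else `distal_intergenic`.
#'
#' @param sites A table with `contig, pos, strand` (one row per site).
#' @param features Gene feature table (`contig, start, end, strand, feature,
#'   gene_id`), e.g. `sg$features` or [read_gene_models()].
#' @param flank Intergenic flank in bases (default 10000, i.e. +/- 10 kb
#'   around transcription start/end sites).
#' @return A `data.table`: `contig, pos, strand, region, gene_id` (gene_id
#'   `NA` for intergenic sites), one row per input site, input order.
#' @export
assign_region <- function(sites, features, flank = 10000L) {
  sites <- as.data.table(sites)[, .(contig, pos, strand)]
  sites[, idx := .I]
  feats <- as.data.table(features)
  precedence <- c(CDS = 1L, three_prime_utr = 2L, five_prime_utr = 3L,
                  intron = 4L)
  feats <- feats[feature %in% names(precedence)]
  feats[, prec := precedence[feature]]
  setkey(feats, contig, start, end)
  ov <- foverlaps(sites[, .(idx, contig, start = pos, end = pos, strand)],
                  feats[, .(contig, start, end, fstrand = strand, feature,
                            gene_id, prec)],
                  by.x = c("contig", "start", "end"), nomatch = NULL)
  ov[, same_strand := strand == fstrand]
  # prefer same-strand hits, then precedence
  setorder(ov, idx, -same_strand, prec)
  best <- ov[!duplicated(idx)]

  out <- sites[, .(idx, contig, pos, strand)]
  out[, region := NA_character_]
  out[, gene_id := NA_character_]
  out[best$idx, `:=`(region = fifelse(best$feature == "CDS", "CDS",
                                      best$feature),
                     gene_id = best$gene_id)]

  # intergenic: distance to any gene boundary (TSS/TES)
  miss <- which(is.na(out$region))
  if (length(miss)) {
    genes <- feats[, .(gstart = min(start), gend = max(end)),
                   by = .(contig, gene_id)]
    for (i in miss) {
      gb <- genes[contig == out$contig[i]]
      d <- if (nrow(gb)) min(abs(out$pos[i] - gb$gstart),
                             abs(out$pos[i] - gb$gend)) else Inf
      out[i, region := if (d <= flank) "proximal_intergenic" else "distal_intergenic"]
    }
  }
  out[, idx := NULL]
  out[]
}

#' Per-region editing-site density
#'
#' Density = site count / total bases of the region class in the annotation,
#' the normalisation that makes 3'UTR enrichment visible despite the much
#' larger intronic territory.
#'
#' @param assignments Output of [assign_region()].
#' @param region_lengths Named numeric vector of total bases per region
#'   class, e.g. from [region_lengths()].
#' @return A `data.table`: `region, n_sites, length, density`, sorted by
#'   density descending. Zero-length classes are omitted with a warning.
#' @export
region_density <- function(assignments, region_lengths) {
  zero <- names(region_lengths)[region_lengths <= 0]
  if (length(zero)) {
    warning(sprintf("omitting zero-length region class(es): %s",
                    paste(zero, collapse = ", ")))
    region_lengths <- region_lengths[region_lengths > 0]
  }
  counts <- as.data.table(assignments)[, .N, by = region]
  out <- data.table(region = names(region_lengths),
                    length = as.numeric(region_lengths))
  out <- merge(out, counts, by = "region", all.x = TRUE)
  out[is.na(N), N := 0L]
  setnames(out, "N", "n_sites")
  out[, density := n_sites / length]
  setorder(out, -density)
  out[]
}

#' Total annotated bases per region class
#' @param features Gene feature table.
#' @return Named numeric vector of summed feature lengths by class.
#' @export
region_lengths <- function(features) {
  dt <- as.data.table(features)[, .(len = sum(end - start + 1)), by = feature]
  setNames(dt$len, fifelse(dt$feature == "CDS", "CDS", dt$feature))
}

#' Repeat class of edit sites
#'
#' Looks up the repeat interval covering each site; overlapping intervals are
#' resolved by the smallest interval, then alphabetically by class.
#'
#' @param sites Table with `contig, pos`.
#' @param repeats Repeat track (`contig, start, end, class`), 1-based closed
#'   coordinates (use [read_repeats()] for BED input).
#' @return Character vector of repeat classes, `NA` where uncovered.
#' @export
assign_repeat <- function(sites, repeats) {
  sites <- as.data.table(sites)[, .(contig, pos)]
  sites[, idx := .I]
  reps <- as.data.table(repeats)
  if (!nrow(reps)) return(rep(NA_character_, nrow(sites)))
  reps[, width := end - start + 1L]
  setkey(reps, contig, start, end)
  ov <- foverlaps(sites[, .(idx, contig, start = pos, end = pos)],
                  reps[, .(contig, start, end, class, width)],
                  by.x = c("contig", "start", "end"), nomatch = NULL)
  setorder(ov, idx, width, class)
  best <- ov[!duplicated(idx)]
  out <- rep(NA_character_, nrow(sites))
  out[best$idx] <- best$class
  out
}

#' Codon consequence of an A-to-I edit in a coding sequence
#'
#' Reconstructs the codon on the coding strand, replaces the edited adenosine
#' with guanosine, and translates both codons under the standard genetic
#' code.
#'
#' @param site A list or one-row table with `contig, pos, strand`.
#' @param features Gene feature table (the site's gene is found by CDS
#'   overlap on the site's strand).
#' @param genome Genome.
#' @return A list of class `consequence_call`: `gene_id, codon_index,
#'   codon_position, codon_before, codon_after, aa_before, aa_after, class`
#'   with class one of synonymous / nonsynonymous / stop_gain / stop_loss.
#' @export
consequence <- function(site, features, genome) {
  g <- as_genome_chr(genome)
  feats <- as.data.table(features)
  cds <- feats[feature == "CDS" & contig == site$contig &
               strand == site$strand & start <= site$pos & end >= site$pos]
  if (!nrow(cds)) stop("site is not within a CDS on its strand")
  gid <- cds$gene_id[1L]
  cds_all <- feats[feature == "CDS" & gene_id == gid]
  cds_all <- if (site$strand == "+") cds_all[order(start)] else cds_all[order(-start)]
  blocks <- substring(g[cds_all$contig], cds_all$start, cds_all$end)
  blocks <- vapply(seq_along(blocks), function(i) {
    if (site$strand == "-") revcomp(blocks[i]) else blocks[i]
  }, character(1))
  cds_seq <- paste(blocks, collapse = "")
  if (nchar(cds_seq) %% 3L != 0L) {
    stop(sprintf("CDS length %d of %s is not divisible by 3", nchar(cds_seq), gid))
  }
  # transcript offset of the site within the CDS
  lens <- cds_all$end - cds_all$start + 1L
  cum <- cumsum(c(0L, lens))
  bi <- which(site$pos >= cds_all$start & site$pos <= cds_all$end)[1L]
  off_in_block <- if (site$strand == "+") site$pos - cds_all$start[bi]
                  else cds_all$end[bi] - site$pos
  tx_off <- cum[bi] + off_in_block + 1L
  if (substr(cds_seq, tx_off, tx_off) != "A") {
    stop("site is not an adenosine on the coding strand")
  }
  codon_index <- (tx_off - 1L) %/% 3L + 1L
  codon_pos <- (tx_off - 1L) %% 3L + 1L
  codon_before <- substr(cds_seq, 3L * codon_index - 2L, 3L * codon_index)
  codon_after <- codon_before
  substr(codon_after, codon_pos, codon_pos) <- "G"
  aa <- function(codon) {
    as.character(Biostrings::translate(Biostrings::DNAString(codon)))
  }
  aa_before <- aa(codon_before)
  aa_after <- aa(codon_after)
  cls <- if (aa_before == aa_after) "synonymous"
         else if (aa_after == "*") "stop_gain"
         else if (aa_before == "*") "stop_loss"
         else "nonsynonymous"
  structure(list(gene_id = gid, codon_index = codon_index,
                 codon_position = codon_pos,
                 codon_before = codon_before, codon_after = codon_after,
                 aa_before = aa_before, aa_after = aa_after, class = cls),
            class = "consequence_call")
}

#' Splice-site proximity of an edit site
#'
#' Classifies an intronic site as `donor` (first 2 intronic nucleotides),
#' `acceptor` (last 2), or `branch_window` (within `branch_window` nucleotides
#' upstream of the 3' splice site, the literature-standard window for the
#' branch-point adenosine); everything else, including exonic sites, is
#' `none`. Donor/acceptor take precedence over the branch window.
#'
#' @param site A list or one-row table with `contig, pos, strand`.
#' @param features Gene feature table.
#' @param branch_window Integer pair: distance range (nt) upstream of the 3'
#'   splice site, default `c(18, 44)`.
#' @return One of `"donor"`, `"acceptor"`, `"branch_window"`, `"none"`.
#' @export
splice_proximity <- function(site, features, branch_window = c(18L, 44L)) {
  feats <- as.data.table(features)
  intr <- feats[feature == "intron" & contig == site$contig &
                strand == site$strand & start <= site$pos & end >= site$pos]
  if (!nrow(intr)) return("none")
  intr <- intr[1L]
  if (site$strand == "+") {
    d5 <- site$pos - intr$start + 1L   # distance into intron from donor
    d3 <- intr$end - site$pos + 1L     # distance back from acceptor
  } else {
    d5 <- intr$end - site$pos + 1L
    d3 <- site$pos - intr$start + 1L
  }
  if (d5 <= 2L) return("donor")
  if (d3 <= 2L) return("acceptor")
  if (d3 >= branch_window[1L] && d3 <= branch_window[2L]) return("branch_window")
  "none"
}
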