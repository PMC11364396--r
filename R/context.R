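#' Positional base composition and enrichment around edit sites
#'
#' Extracts the event-strand neighbourhood of each edit site (reverse
#' complemented for minus-strand sites, so position +1 is the transcript
#' 3' neighbour), tabulates per-position base frequencies, and tests each
#' (position, base) for enrichment against the background composition with
#' an exact one-sided binomial test. ADAR's 5'AG3' preference shows up as G
#' enrichment at +1.
#'
#' @param sites Table with `contig, pos, strand` (>= 10 usable sites).
#' @param genome Genome.
#' @param halfwidth Window half-width in nt (default 50). Windows clipped at
#'   contig edges are dropped.
#' @param background `"genome"` (base composition of the supplied contigs,
#'   both strands; the default avoids composition bias) or `"uniform"`
#'   (0.25 each).
#' @return A list of class `motif_profile`: `freq` (4 x (2*halfwidth+1)
#'   matrix of base frequencies), `counts`, `pvals` (same shape, one-sided
#'   enrichment), `n` (usable windows), `positions`, `background`.
#' @export
motif_profile <- function(sites, genome, halfwidth = 50L,
                          background = c("genome", "uniform")) {
  background <- match.arg(background)
  g <- as_genome_chr(genome)
  sites <- as.data.table(sites)
  clen <- nchar(g)[match(sites$contig, names(g))]
  ok <- sites$pos - halfwidth >= 1L & sites$pos + halfwidth <= clen
  sites <- sites[ok]
  n <- nrow(sites)
  if (n < 10L) {
    stop(sprintf("only %d usable windows (need >= 10) for motif profiling", n))
  }
  win <- substring(g[sites$contig], sites$pos - halfwidth, sites$pos + halfwidth)
  minus <- sites$strand == "-"
  if (any(minus)) win[minus] <- revcomp(win[minus])
  W <- 2L * halfwidth + 1L
  m <- matrix(unlist(strsplit(win, ""), use.names = FALSE), nrow = W)
  positions <- seq(-halfwidth, halfwidth)
  counts <- vapply(DNA_BASES, function(b) rowSums(m == b), numeric(W))
  counts <- t(counts)                       # 4 x W
  colnames(counts) <- positions
  freq <- counts / n

  bg <- if (background == "uniform") {
    setNames(rep(0.25, 4L), DNA_BASES)
  } else {
    # both strands: strand-symmetric composition
    comp <- colSums(Biostrings::alphabetFrequency(
      Biostrings::DNAStringSet(g))[, DNA_BASES, drop = FALSE])
    both <- comp + rev(comp)                # A+T, C+G, G+C, T+A
    setNames(both / sum(both), DNA_BASES)
  }
  pvals <- counts
  for (b in DNA_BASES) {
    pvals[b, ] <- pbinom(counts[b, ] - 1L, n, bg[[b]], lower.tail = FALSE)
  }
  structure(list(freq = freq, counts = counts, pvals = pvals, n = n,
                 positions = positions, background = bg),
            class = "motif_profile")
}

#' Rank positional enrichments of a motif profile
#'
#' @param profile A [motif_profile()].
#' @param exclude_center Drop position 0 (frequency of A is 1 there by
#'   construction).
#' @return data.table `position, base, freq, p` sorted by p ascending.
#' @export
top_enrichments <- function(profile, exclude_center = TRUE) {
  W <- length(profile$positions)
  out <- data.table(
    position = rep(profile$positions, each = 4L),
    base = rep(DNA_BASES, W),
    freq = as.vector(profile$freq),
    p = as.vector(profile$pvals)
  )
  if (exclude_center) out <- out[position != 0L]
  setorder(out, p, -freq)
  out[]
}

#' Detect downstream A-rich satellite regions at hyper-edited sites
#'
#' ADAR edits recursively at a roughly 30-nt interval downstream of a primary
#' site; the satellite substrate shows up as an A-rich window starting 20-40
#' nt downstream on the event strand. A site is flagged when any window of
#' width `window` whose start offset lies within `offset_range` has an A
#' fraction of at least `a_fraction`; the best-scoring offset is reported
#' (smallest offset on ties).
#'
#' @param sites Table with `contig, pos, strand` (hyper-edited sites).
#' @param genome Genome.
#' @param offset_range Integer pair: downstream offsets (nt) at which a
#'   window may start. Offset 1 is the base immediately 3' of the site.
#' @param window Window width in nt.
#' @param a_fraction Minimum A fraction of a qualifying window.
#' @return A `data.table`: `contig, pos, strand, flagged, best_offset,
#'   best_fraction`; sites too close to a contig end are skipped and counted
#'   in attribute `"n_skipped"`.
#' @export
a_rich_satellite <- function(sites, genome, offset_range = c(20L, 40L),
                             window = 10L, a_fraction = 0.7) {
  g <- as_genome_chr(genome)
  sites <- as.data.table(sites)
  if (!nrow(sites)) stop("empty hyper-edited site list")
  clen <- nchar(g)[match(sites$contig, names(g))]
  max_reach <- offset_range[2L] + window - 1L
  reachable <- ifelse(sites$strand == "+",
                      sites$pos + max_reach <= clen,
                      sites$pos - max_reach >= 1L)
  skipped <- sum(!reachable)
  sites <- sites[reachable]
  offs <- seq(offset_range[1L], offset_range[2L])
  out <- sites[, .(contig, pos, strand)]
  out[, `:=`(flagged = FALSE, best_offset = NA_integer_, best_fraction = NA_real_)]
  for (i in seq_len(nrow(sites))) {
    s <- sites[i]
    dirn <- if (s$strand == "+") 1L else -1L
    abase <- if (s$strand == "+") "A" else "T"    # event-strand A
    best_f <- -1; best_o <- NA_integer_
    for (o in offs) {
      ws <- s$pos + dirn * o
      we <- ws + dirn * (window - 1L)
      seq <- contig_substr(g, s$contig, min(ws, we), max(ws, we))
      f <- sum(strsplit(seq, "")[[1L]] == abase) / window
      if (f > best_f) { best_f <- f; best_o <- o }
    }
    set(out, i, "best_offset", best_o)
    set(out, i, "best_fraction", best_f)
    set(out, i, "flagged", best_f >= a_fraction)
  }
  setattr(out, "n_skipped", skipped)
  out[]
}

#' Find inverted repeats (dsRNA stem-loops) in a sequence
#'
#' Scans for arm pairs `(s, reverse complement of s)` with arm length at
#' least `min_arm` and separation (loop) at most `max_loop` - the
#' intramolecular fold-back substrate that ADAR binds. Hits are maximal
#' (neither arm can be extended in either direction) and non-redundant
#' (hits whose both arms lie within another hit's arms are removed).
#'
#' @param sequence A single DNA string (uppercase).
#' @param min_arm Minimum arm length in bases (>= 8).
#' @param max_loop Maximum loop (separation between arms) in bases.
#' @return A `data.table`: `arm1_start, arm1_end, arm2_start, arm2_end,
#'   arm_length, loop_length`, 1-based closed coordinates, sorted.
#' @export
find_inverted_repeats <- function(sequence, min_arm = 30L, max_loop = 10000L) {
  if (min_arm < 8L) stop("min_arm must be >= 8")
  check_dna_alphabet(sequence, "sequence")
  n <- nchar(sequence)
  empty <- data.table(arm1_start = integer(), arm1_end = integer(),
                      arm2_start = integer(), arm2_end = integer(),
                      arm_length = integer(), loop_length = integer())
  if (n < 2L * min_arm) return(empty)
  k <- as.integer(min_arm)
  chars <- strsplit(sequence, "")[[1L]]
  starts <- seq_len(n - k + 1L)
  kmers <- substring(sequence, starts, starts + k - 1L)
  pos_by_kmer <- split(starts, kmers)
  rc <- revcomp(kmers)

  hits <- list()
  for (i in starts) {
    js <- pos_by_kmer[[rc[i]]]
    if (is.null(js)) next
    js <- js[js >= i + k & js - (i + k) <= max_loop]
    for (j in js) {
      # extend maximally; seed invariant: S[j..j+a-1] == rc(S[i..i+a-1])
      a <- k; ii <- i; jj <- j
      # outward: arm1 left, arm2 right
      while (ii > 1L && jj + a <= n &&
             chars[jj + a] == comp_base(chars[ii - 1L])) {
        ii <- ii - 1L; a <- a + 1L
      }
      # inward: arm1 right, arm2 left (loop shrinks by 2 per step)
      while (jj - 1L > ii + a && chars[jj - 1L] == comp_base(chars[ii + a])) {
        jj <- jj - 1L; a <- a + 1L
      }
      hits[[length(hits) + 1L]] <- c(ii, ii + a - 1L, jj, jj + a - 1L)
    }
  }
  if (!length(hits)) return(empty)
  h <- unique(as.data.table(do.call(rbind, hits)))
  setnames(h, c("arm1_start", "arm1_end", "arm2_start", "arm2_end"))
  h[, arm_length := arm1_end - arm1_start + 1L]
  h[, loop_length := arm2_start - arm1_end - 1L]
  h <- h[loop_length >= 0L & loop_length <= max_loop]
  # containment removal
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    cont <- h$arm1_start <= h$arm1_start[i] & h$arm1_end >= h$arm1_end[i] &
            h$arm2_start <= h$arm2_start[i] & h$arm2_end >= h$arm2_end[i] &
            seq_len(nrow(h)) != i
    if (any(cont)) keep[i] <- FALSE
  }
  h <- h[keep]
  setorder(h, arm1_start, arm2_start)
  h[]
}

#' Scan gene regions for inverted repeats and tally genes carrying one
#'
#' Runs [find_inverted_repeats()] over each gene's intronic sequence (the
#' territory where fold-back stems concentrate) and reports hits in genomic
#' coordinates plus the number of genes with at least one hit at the cutoff.
#'
#' @param sg A `synth_genome` (or a list with `genome` and `features`).
#' @param min_arm,max_loop See [find_inverted_repeats()].
#' @param feature_types Feature classes to scan (default intron).
#' @return A list: `hits` (data.table with `contig, gene_id` and arm
#'   coordinates) and `genes_with_ir` (count).
#' @export
scan_gene_inverted_repeats <- function(sg, min_arm = 30L, max_loop = 10000L,
                                       feature_types = "intron") {
  g <- as_genome_chr(sg$genome)
  feats <- as.data.table(sg$features)[feature %in% feature_types]
  out <- list()
  for (i in seq_len(nrow(feats))) {
    f <- feats[i]
    seq <- contig_substr(g, f$contig, f$start, f$end)
    h <- find_inverted_repeats(seq, min_arm = min_arm, max_loop = max_loop)
    if (nrow(h)) {
      h[, `:=`(contig = f$contig, gene_id = f$gene_id,
               arm1_start = arm1_start + f$start - 1L,
               arm1_end = arm1_end + f$start - 1L,
               arm2_start = arm2_start + f$start - 1L,
               arm2_end = arm2_end + f$start - 1L)]
      out[[length(out) + 1L]] <- h
    }
  }
  hits <- if (length(out)) rbindlist(out) else
    data.table(arm1_start = integer(), arm1_end = integer(),
               arm2_start = integer(), arm2_end = integer(),
               arm_length = integer(), loop_length = integer(),
               contig = character(), gene_id = character())
  list(hits = hits, genes_with_ir = uniqueN(hits$gene_id))
}
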