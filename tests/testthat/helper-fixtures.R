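library(data.table)

# deterministic random contig
rand_seq <- function(n, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# hand-built single-gene feature table: utr5 / cds blocks / introns / utr3
# laid out contiguously from `start`; lengths in transcript order
make_gene <- function(contig = "chr1", start = 101L, strand = "+",
                      lens = c(five_prime_utr = 30L, CDS = 30L, intron = 40L,
                               CDS = 30L, three_prime_utr = 30L),
                      gene_id = "gA") {
  feats <- names(lens)
  ord <- if (strand == "+") seq_along(lens) else rev(seq_along(lens))
  l <- unname(lens[ord])
  starts <- start + c(0L, cumsum(l))[seq_along(l)]
  data.table(contig = contig, start = starts, end = starts + l - 1L,
             strand = strand, feature = feats[ord], gene_id = gene_id,
             transcript_id = paste0(gene_id, ".t1"))
}

# aligned-read row in the internal format
make_read <- function(qname, contig, pos, seq_plus, mate = 2L, orient = "+",
                      rescued = FALSE) {
  data.table(qname = qname, mate = mate, contig = contig, pos = as.integer(pos),
             orient = orient, mm = 0L, seq_plus = seq_plus, rescued = rescued)
}

# an event-strand adenosine near the middle of a large feature block, where
# simulated fragment coverage is close to the nominal depth
mid_feature_site <- function(sg, strand_ = "+", feature_ = "CDS",
                             min_len = 440L) {
  f <- sg$features[feature == feature_ & strand == strand_ &
                   end - start + 1L >= min_len][1L]
  stopifnot(nrow(f) == 1L, !is.na(f$start))
  mid <- (f$start + f$end) %/% 2L
  win <- substring(sg$genome[[f$contig]], mid - 40L, mid + 40L)
  want <- if (strand_ == "+") "A" else "T"
  off <- which(strsplit(win, "")[[1L]] == want)[1L]
  data.table(contig = f$contig, pos = mid - 40L + off - 1L, strand = strand_,
             gene_id = f$gene_id, region = feature_)
}

# --- independent oracles -------------------------------------------------

# Fisher two-sided p by direct hypergeometric enumeration with choose()
oracle_fisher <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b; N <- m + n
  if (m == 0 || n == 0 || k == 0 || N - k == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  pr <- choose(m, xs) * choose(n, k - xs) / choose(N, k)
  pobs <- pr[a - lo + 1]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# BH step-up: min over i' >= i of p_(i') * m / i'
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# O(n^2) brute-force inverted-repeat search: every seed pair extended by
# direct character comparison, then containment-filtered
oracle_inverted_repeats <- function(seq, min_arm, max_loop) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  pairs_ok <- function(i, j) ch[j] == comp[[ch[i]]]
  hits <- list()
  for (i in seq_len(n - 2L * min_arm + 1L)) {
    for (j in seq(i + min_arm, n - min_arm + 1L)) {
      if (j - (i + min_arm) > max_loop) next
      ok <- TRUE
      for (t in 0:(min_arm - 1L)) {
        if (!pairs_ok(i + min_arm - 1L - t, j + t)) { ok <- FALSE; break }
      }
      if (!ok) next
      a <- min_arm; ii <- i; jj <- j
      while (ii > 1L && jj + a <= n && pairs_ok(ii - 1L, jj + a)) {
        ii <- ii - 1L; a <- a + 1L
      }
      while (jj - 1L > ii + a && pairs_ok(ii + a, jj - 1L)) {
        jj <- jj - 1L; a <- a + 1L
      }
      hits[[length(hits) + 1L]] <- c(ii, ii + a - 1L, jj, jj + a - 1L)
    }
  }
  if (!length(hits)) {
    return(data.table(arm1_start = integer(), arm1_end = integer(),
                      arm2_start = integer(), arm2_end = integer()))
  }
  h <- unique(as.data.table(do.call(rbind, hits)))
  setnames(h, c("arm1_start", "arm1_end", "arm2_start", "arm2_end"))
  h <- h[arm2_start - arm1_end - 1L >= 0L & arm2_start - arm1_end - 1L <= max_loop]
  keep <- rep(TRUE, nrow(h))
  for (r in seq_len(nrow(h))) {
    cont <- h$arm1_start <= h$arm1_start[r] & h$arm1_end >= h$arm1_end[r] &
            h$arm2_start <= h$arm2_start[r] & h$arm2_end >= h$arm2_end[r] &
            seq_len(nrow(h)) != r
    if (any(cont)) keep[r] <- FALSE
  }
  setorder(h[keep], arm1_start, arm2_start)[]
}
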