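test_that("motif profile recovers a planted +1 G preference with exact binomial p", {
  # genome whose A's are followed by G at 40 of 50 chosen sites
  set.seed(13)
  g <- c(chr1 = rand_seq(20000L, seed = 13L))
  ch <- strsplit(g[[1L]], "")[[1L]]
  a_then_g <- which(ch == "A" & c(ch[-1L], "N") == "G")
  a_then_other <- which(ch == "A" & c(ch[-1L], "N") %in% c("C", "T"))
  pick <- c(sample(a_then_g[a_then_g > 100 & a_then_g < 19900], 40L),
            sample(a_then_other[a_then_other > 100 & a_then_other < 19900], 10L))
  sites <- data.table(contig = "chr1", pos = pick, strand = "+")
  prof <- motif_profile(sites, g, halfwidth = 50L, background = "uniform")

  expect_equal(prof$n, 50L)
  expect_equal(unname(prof$freq["A", "0"]), 1)
  expect_equal(colSums(prof$freq), rep(1, 101L), ignore_attr = TRUE)
  # exact binomial tail: P(X >= 40 | n = 50, p = 0.25) < 1e-6
  p_plus1 <- prof$pvals["G", "1"]
  expect_lt(p_plus1, 1e-6)
  expect_equal(unname(p_plus1),
               pbinom(39L, 50L, 0.25, lower.tail = FALSE))
  top <- top_enrichments(prof)[1L]
  expect_equal(top$position, 1L)
  expect_equal(top$base, "G")
})

test_that("motif profile needs at least 10 usable windows", {
  g <- c(chr1 = rand_seq(2000L, seed = 14L))
  few <- data.table(contig = "chr1", pos = c(500L, 600L, 700L), strand = "+")
  expect_error(motif_profile(few, g), "need >= 10")
  # windows clipped at the contig edge are dropped and can trigger the same
  edge <- data.table(contig = "chr1", pos = c(1:9, 20L, 1000L), strand = "+")
  expect_error(motif_profile(edge, g, halfwidth = 50L), "usable windows")
})

test_that("null motif profiles show no spurious positional enrichment", {
  # uniform random sites on a uniform genome: min p rarely below 0.001
  fails <- 0L
  for (seed in 1:10) {
    g <- c(chr1 = rand_seq(30000L, seed = 100L + seed))
    ch <- strsplit(g[[1L]], "")[[1L]]
    a_pos <- which(ch == "A")
    a_pos <- a_pos[a_pos > 100 & a_pos < 29900]
    set.seed(seed)
    sites <- data.table(contig = "chr1", pos = sample(a_pos, 50L),
                        strand = "+")
    prof <- motif_profile(sites, g, halfwidth = 20L, background = "uniform")
    top <- top_enrichments(prof)[1L]
    if (top$p < 0.001) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("A-rich satellite windows are detected at the planted offset", {
  base <- rand_seq(500L, seed = 21L)
  # plant a 10-nt window with 9 A's starting 28 nt downstream of position 100
  sat <- "AAAAACAAAA"
  g1 <- base
  substr(g1, 128L, 137L) <- sat
  substr(g1, 127L, 127L) <- "C"   # keep neighbouring windows strictly worse
  substr(g1, 138L, 138L) <- "C"
  res <- a_rich_satellite(data.table(contig = "chr1", pos = 100L, strand = "+"),
                          c(chr1 = g1))
  expect_true(res$flagged)
  expect_equal(res$best_offset, 28L)
  expect_equal(res$best_fraction, 0.9)

  # uniform downstream composition: not flagged at a_fraction 0.7
  res0 <- a_rich_satellite(data.table(contig = "chr1", pos = 100L,
                                      strand = "+"),
                           c(chr1 = base))
  expect_false(res0$flagged)

  # minus-strand site: downstream runs left, A-rich means plus-strand T's
  g2 <- base
  substr(g2, 64L, 73L) <- "TTTTTGTTTT"
  resm <- a_rich_satellite(data.table(contig = "chr1", pos = 101L,
                                      strand = "-"),
                           c(chr1 = g2))
  expect_true(resm$flagged)
  expect_equal(resm$best_offset, 28L)

  # degenerate offset range (0,0): single window starting at the site
  g3 <- base
  substr(g3, 200L, 209L) <- "AAAAAAAAAA"
  resd <- a_rich_satellite(data.table(contig = "chr1", pos = 200L,
                                      strand = "+"),
                           c(chr1 = g3), offset_range = c(0L, 0L))
  expect_true(resd$flagged)
  expect_equal(resd$best_offset, 0L)

  # sites too close to the contig end are skipped, not errors
  res_edge <- a_rich_satellite(data.table(contig = "chr1",
                                          pos = c(100L, 495L),
                                          strand = "+"),
                               c(chr1 = g1))
  expect_equal(nrow(res_edge), 1L)
  expect_equal(attr(res_edge, "n_skipped"), 1L)
  expect_error(a_rich_satellite(data.table(contig = character(),
                                           pos = integer(),
                                           strand = character()),
                                c(chr1 = base)),
               "empty")
})

test_that("inverted repeat scan finds planted stems and nothing spurious", {
  set.seed(31)
  arm <- rand_seq(30L, seed = 31L)
  loop <- rand_seq(50L, seed = 32L)
  seq <- paste0(rand_seq(800L, seed = 33L), "C", arm, "C",
                substr(loop, 2L, 49L), "C", revcomp(arm), "C",
                rand_seq(800L, seed = 34L))
  hits <- find_inverted_repeats(seq, min_arm = 30L, max_loop = 1000L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$arm_length, 30L)
  expect_equal(hits$loop_length, 50L)
  expect_identical(substring(seq, hits$arm2_start, hits$arm2_end),
                   revcomp(substring(seq, hits$arm1_start, hits$arm1_end)))

  # arm below the cutoff: no hit
  arm29 <- substr(arm, 1L, 29L)
  seq29 <- paste0(rand_seq(300L, seed = 35L), "C", arm29, strrep("C", 20L),
                  revcomp(arm29), "C", rand_seq(300L, seed = 36L))
  expect_equal(nrow(find_inverted_repeats(seq29, min_arm = 30L)), 0L)

  # homopolymer has no reverse-complement partner
  expect_equal(nrow(find_inverted_repeats(strrep("A", 200L), min_arm = 30L)),
               0L)
  expect_error(find_inverted_repeats(seq, min_arm = 4L), ">= 8")
})

test_that("inverted repeat scan matches the brute-force oracle on 2 kb fixtures", {
  for (seed in c(41L, 42L)) {
    arm <- rand_seq(14L, seed = seed + 100L)
    seq <- paste0(rand_seq(900L, seed = seed), "C", arm, "CCC", revcomp(arm),
                  "G", rand_seq(1000L, seed = seed + 200L))
    got <- find_inverted_repeats(seq, min_arm = 12L, max_loop = 500L)
    want <- oracle_inverted_repeats(seq, min_arm = 12L, max_loop = 500L)
    expect_equal(as.data.frame(got[, 1:4]), as.data.frame(want),
                 ignore_attr = TRUE)
    expect_gte(nrow(got), 1L)
  }
})

test_that("inverted repeats are strand-invariant up to mirrored coordinates", {
  arm <- rand_seq(16L, seed = 51L)
  seq <- paste0(rand_seq(400L, seed = 52L), "C", arm, strrep("T", 30L),
                revcomp(arm), "G", rand_seq(400L, seed = 53L))
  n <- nchar(seq)
  fwd <- find_inverted_repeats(seq, min_arm = 14L, max_loop = 200L)
  rev <- find_inverted_repeats(revcomp(seq), min_arm = 14L, max_loop = 200L)
  mirrored <- rev[, .(arm1_start = n - arm2_end + 1L,
                      arm1_end = n - arm2_start + 1L,
                      arm2_start = n - arm1_end + 1L,
                      arm2_end = n - arm1_start + 1L)]
  setorder(mirrored, arm1_start, arm2_start)
  expect_equal(as.data.frame(mirrored),
               as.data.frame(fwd[, 1:4]), ignore_attr = TRUE)
})

test_that("gene-level scan reports planted intronic stem-loops", {
  sg <- generate_genome(synth_config(inverted_repeat_arms = list(c(30L, 50L)),
                                     rng_seed = 61L))
  scan <- scan_gene_inverted_repeats(sg, min_arm = 30L)
  expect_gte(scan$genes_with_ir, 1L)
  ir <- sg$inverted_repeats[1L]
  hit <- scan$hits[contig == ir$contig & arm1_start == ir$arm1_start]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$arm_length, ir$arm_length)
  expect_equal(hit$gene_id, ir$gene_id)
})
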