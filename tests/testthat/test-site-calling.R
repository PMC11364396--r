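# 1-contig toy genome for pileup fixtures
pile_genome <- c(chr1 = rand_seq(400L, seed = 77L))

# a read whose sequence equals the reference except at `edits` (genomic pos -> base)
ref_read <- function(qname, pos, len = 20L, edits = NULL, ...) {
  s <- substring(pile_genome[["chr1"]], pos, pos + len - 1L)
  if (!is.null(edits)) {
    for (p in names(edits)) {
      substr(s, as.integer(p) - pos + 1L, as.integer(p) - pos + 1L) <- edits[[p]]
    }
  }
  make_read(qname, "chr1", pos, s, ...)
}

test_that("pileup counts plain coverage and deduplicates overlapping mates", {
  reads <- rbindlist(lapply(1:10, function(i) ref_read(paste0("r", i), 50L)))
  counts <- pileup(reads, pile_genome, "s1")
  pos_a <- which(strsplit(substring(pile_genome, 50, 69), "")[[1L]] == "A")[1L]
  at <- counts[pos == 49L + pos_a]
  expect_equal(at$A, 10L)
  expect_equal(at$C + at$G + at$T + at$N, 0L)
  expect_equal(at$depth, 10L)

  # both mates of one pair covering the same G-edit position count once
  g_pos <- 60L
  pair <- rbind(
    ref_read("p1", 50L, edits = setNames("G", g_pos), mate = 2L, orient = "+"),
    ref_read("p1", 55L, edits = setNames("G", g_pos), mate = 1L, orient = "-"))
  counts2 <- pileup(pair, pile_genome, "s1")
  expect_equal(counts2[pos == g_pos]$G, 1L)
  expect_equal(counts2[pos == g_pos]$depth, 1L)
})

test_that("minus-strand pairs are counted on the event strand (T-to-C evidence)", {
  # find a plus-strand T; 6 pairs read C there, library says transcript is '-'
  t_pos <- 49L + which(strsplit(substring(pile_genome, 50, 80), "")[[1L]] == "T")[1L]
  reads <- rbindlist(lapply(1:6, function(i) {
    ref_read(paste0("m", i), t_pos - 5L, edits = setNames("C", t_pos),
             mate = 2L, orient = "-")
  }))
  counts <- pileup(reads, pile_genome, "s1")
  at <- counts[pos == t_pos & strand == "-"]
  # plus-strand T with C reads is event-strand A with G reads
  expect_equal(at$G, 6L)
  sites <- call_candidate_sites(counts, pile_genome)
  site <- sites[pos == t_pos]
  expect_equal(site$strand, "-")
  expect_equal(site$edited, 6L)
  expect_equal(site$ratio, 1)
})

test_that("reads beyond the contig end are a malformed-alignment error", {
  bad <- make_read("r", "chr1", 395L, strrep("A", 20L))
  expect_error(pileup(bad, pile_genome), "beyond contig end")
})

test_that("candidate sites require an event-strand reference A and exclude non-A/G from the ratio", {
  a_pos <- 49L + which(strsplit(substring(pile_genome, 50, 90), "")[[1L]] == "A")[1L]
  c_pos <- 149L + which(strsplit(substring(pile_genome, 150, 190), "")[[1L]] == "C")[1L]
  mk <- function(i, base, at, start) {
    ref_read(sprintf("r%s%02d", base, i), start, edits = setNames(base, at))
  }
  reads <- rbind(
    rbindlist(lapply(1:6, mk, base = "G", at = a_pos, start = a_pos - 3L)),
    rbindlist(lapply(7:10, mk, base = "A", at = a_pos, start = a_pos - 3L)),
    mk(11, "N", a_pos, a_pos - 3L),                       # excluded from ratio
    rbindlist(lapply(1:5, mk, base = "T", at = c_pos, start = c_pos - 3L))
  )
  counts <- pileup(reads, pile_genome, "s1")
  sites <- call_candidate_sites(counts, pile_genome)
  site <- sites[pos == a_pos & strand == "+"]
  expect_equal(site$edited, 6L)
  expect_equal(site$unedited, 4L)
  expect_equal(site$ratio, 0.6)
  # reference C position emits no site even with mismatching reads
  expect_equal(nrow(sites[pos == c_pos]), 0L)
})

test_that("conservation: edited + unedited + other = depth at every site", {
  sg <- generate_genome(synth_config(n_contigs = 1L, contig_length = 8000L,
                                     n_genes = 2L, rng_seed = 71L))
  plan <- plan_editing(sg, groups = "g", n_sites = 60L, seed = 4L)
  reads <- simulate_reads(sg, plan, read_sim_params(depth = 20), "s", "g",
                          seed = 6L)
  al <- toy_align(reads, sg$genome)
  counts <- pileup(al$aligned, sg$genome, "s")
  expect_true(all(counts$A + counts$C + counts$G + counts$T + counts$N ==
                  counts$depth))
  sites <- call_candidate_sites(counts, sg$genome)
  joined <- merge(sites, counts, by = c("contig", "pos", "strand"))
  expect_true(all(joined$edited == joined$G))
  expect_true(all(joined$unedited == joined$A))
  expect_true(all(joined$edited + joined$unedited <= joined$depth.y))
})

test_that("high-confidence filter applies the verbatim cohort rule", {
  mk_site <- function(sample, edited, total, pos = 100L) {
    data.table(contig = "chr1", pos = pos, strand = "+", edited = edited,
               unedited = total - edited, ratio = edited / total,
               depth = total, hyper = FALSE, sample = sample)
  }
  # 3 qualifying samples out of 4: kept
  cohort <- rbind(mk_site("s1", 7L, 20L), mk_site("s2", 8L, 25L),
                  mk_site("s3", 6L, 15L), mk_site("s4", 2L, 30L))
  kept <- filter_high_confidence(cohort, filter_config())
  expect_equal(nrow(attr(kept, "kept_sites")), 1L)

  # ratio 0.95 everywhere: rejected as a likely genomic variant
  high <- rbind(mk_site("s1", 19L, 20L), mk_site("s2", 19L, 20L),
                mk_site("s3", 19L, 20L), mk_site("s4", 19L, 20L))
  expect_equal(nrow(filter_high_confidence(high, filter_config())), 0L)

  # edited exactly 5 in all samples: 'greater than 5' is strict
  five <- rbind(mk_site("s1", 5L, 20L), mk_site("s2", 5L, 20L),
                mk_site("s3", 5L, 20L), mk_site("s4", 5L, 20L))
  expect_equal(nrow(filter_high_confidence(five, filter_config())), 0L)
  # while 6 qualifies
  six <- rbind(mk_site("s1", 6L, 20L), mk_site("s2", 6L, 20L),
               mk_site("s3", 6L, 20L))
  expect_equal(nrow(filter_high_confidence(six, filter_config())), 3L)

  # a cohort below min_samples warns and returns nothing
  expect_warning(
    res <- filter_high_confidence(rbind(mk_site("s1", 7L, 20L),
                                        mk_site("s2", 7L, 20L)),
                                  filter_config()),
    "no site can pass")
  expect_equal(nrow(res), 0L)
})

test_that("strand mirror: the reverse-complemented genome yields mirrored sites", {
  sg <- generate_genome(synth_config(n_contigs = 1L, contig_length = 8000L,
                                     n_genes = 2L, rng_seed = 81L))
  plan <- plan_editing(sg, groups = "g", n_sites = 40L, rates = 0.6,
                       n_clusters = 0L, seed = 5L)
  reads <- simulate_reads(sg, plan, read_sim_params(depth = 25, error_rate = 0),
                          "s", "g", seed = 8L)
  al <- toy_align(reads, sg$genome)
  sites <- call_candidate_sites(pileup(al$aligned, sg$genome, "s"), sg$genome)

  L <- nchar(sg$genome[[1L]])
  rc_genome <- setNames(revcomp(sg$genome[[1L]]), names(sg$genome))
  al_rc <- toy_align(reads, rc_genome)
  sites_rc <- call_candidate_sites(pileup(al_rc$aligned, rc_genome, "s"),
                                   rc_genome)
  mirrored <- sites_rc[, .(contig, pos = L - pos + 1L,
                           strand = ifelse(strand == "+", "-", "+"),
                           edited, unedited)]
  setorder(mirrored, pos)
  orig <- sites[, .(contig, pos, strand, edited, unedited)]
  setorder(orig, pos)
  expect_equal(as.data.frame(mirrored), as.data.frame(orig))
})
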