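# two genes on one 60 kb contig: gA (+) at 101, gB (-) far downstream
ann_features <- rbind(
  make_gene("chr1", 101L, "+", gene_id = "gA"),
  make_gene("chr1", 30001L, "-", gene_id = "gB")
)

test_that("regions are assigned by finest feature with the 10 kb intergenic flank", {
  utr3 <- ann_features[gene_id == "gA" & feature == "three_prime_utr"]
  sites <- data.table(
    contig = "chr1",
    pos = c(utr3$start + 5L,          # inside 3'UTR
            utr3$end + 5000L,         # 5 kb past the TES, outside genes
            utr3$end + 15000L,        # beyond the 10 kb flank of gA
            ann_features[gene_id == "gA" & feature == "intron"]$start[1L] + 10L),
    strand = "+")
  # the third site is also within 10 kb of gB's span start? keep it distal:
  # gB starts at 30001, site 3 is at ~ 15261 -> > 10 kb from both
  res <- assign_region(sites, ann_features)
  expect_equal(res$region, c("three_prime_utr", "proximal_intergenic",
                             "distal_intergenic", "intron"))
  expect_equal(res$gene_id, c("gA", NA, NA, "gA"))

  # partition: every site gets exactly one region
  set.seed(2)
  rand_sites <- data.table(contig = "chr1",
                           pos = sample(1:60000, 300L), strand = "+")
  rr <- assign_region(rand_sites, ann_features)
  expect_equal(nrow(rr), 300L)
  expect_true(all(!is.na(rr$region)))
})

test_that("CDS takes precedence over intron across overlapping isoform features", {
  overlapping <- rbind(
    ann_features,
    data.table(contig = "chr1", start = 120L, end = 180L, strand = "+",
               feature = "intron", gene_id = "gA", transcript_id = "gA.t2"))
  cds <- ann_features[gene_id == "gA" & feature == "CDS"][1L]
  res <- assign_region(data.table(contig = "chr1", pos = cds$start + 2L,
                                  strand = "+"), overlapping)
  expect_equal(res$region, "CDS")
})

test_that("region densities normalise counts by annotated length", {
  assignments <- data.table(region = c("CDS", "CDS", "three_prime_utr",
                                       "three_prime_utr", "three_prime_utr"))
  dens <- region_density(assignments,
                         c(CDS = 1000, three_prime_utr = 500))
  expect_equal(dens[region == "CDS"]$density, 0.002)
  expect_equal(dens[region == "three_prime_utr"]$density, 0.006)
  expect_equal(dens$region[1L], "three_prime_utr")
  # doubling lengths halves densities
  dens2 <- region_density(assignments,
                          c(CDS = 2000, three_prime_utr = 1000))
  expect_equal(dens2$density, dens$density / 2)
  # zero sites give zero densities; zero-length classes are dropped loudly
  dens0 <- region_density(assignments[0L], c(CDS = 1000))
  expect_equal(dens0$density, 0)
  expect_warning(region_density(assignments, c(CDS = 1000, intron = 0)),
                 "zero-length")
})

test_that("repeat class lookup prefers the smallest covering interval", {
  reps <- data.table(contig = "chr1",
                     start = c(1000L, 1040L, 2000L),
                     end = c(1200L, 1060L, 2100L),
                     class = c("SINE", "Simple_repeat", "LINE"))
  sites <- data.table(contig = "chr1", pos = c(1100L, 1050L, 2050L, 5000L))
  expect_equal(assign_repeat(sites, reps),
               c("SINE", "Simple_repeat", "LINE", NA))
})

test_that("codon consequences follow the standard genetic code", {
  # gene with CDS 'ATG AGC CAG CCA TAA' on the plus strand
  cds_seq <- "ATGAGCCAGCCATAA"
  genome <- c(chr1 = paste0(rand_seq(100L, seed = 5L), cds_seq,
                            rand_seq(100L, seed = 6L)))
  feats <- data.table(contig = "chr1", start = 101L, end = 115L,
                      strand = "+", feature = "CDS", gene_id = "g",
                      transcript_id = "g.t1")
  # AGC serine -> GGC glycine (codon 2, position 1)
  cc <- consequence(list(contig = "chr1", pos = 104L, strand = "+"),
                    feats, genome)
  expect_equal(cc$codon_before, "AGC")
  expect_equal(cc$codon_after, "GGC")
  expect_equal(cc$aa_before, "S")
  expect_equal(cc$aa_after, "G")
  expect_equal(cc$class, "nonsynonymous")
  # CAG glutamine -> CGG arginine (codon 3, position 2)
  cc2 <- consequence(list(contig = "chr1", pos = 108L, strand = "+"),
                     feats, genome)
  expect_equal(cc2$codon_before, "CAG")
  expect_equal(cc2$codon_after, "CGG")
  expect_equal(cc2$aa_before, "Q")
  expect_equal(cc2$aa_after, "R")
  expect_equal(cc2$class, "nonsynonymous")
  # CCA proline -> CCG proline: third-position wobble is synonymous
  cc3 <- consequence(list(contig = "chr1", pos = 112L, strand = "+"),
                     feats, genome)
  expect_equal(cc3$codon_after, "CCG")
  expect_equal(cc3$class, "synonymous")
})

test_that("a minus-strand Ser->Gly call is a plus-strand T-to-C genomic change", {
  cds_seq <- "ATGAGCCAGTAA"
  genome_plus <- c(chr1 = paste0(rand_seq(60L, seed = 7L), cds_seq,
                                 rand_seq(60L, seed = 8L)))
  feats_plus <- data.table(contig = "chr1", start = 61L, end = 72L,
                           strand = "+", feature = "CDS", gene_id = "g",
                           transcript_id = "g.t1")
  # mirror the locus: the same gene on the minus strand of the rc genome
  L <- nchar(genome_plus[[1L]])
  genome_minus <- c(chr1 = revcomp(genome_plus[[1L]]))
  feats_minus <- copy(feats_plus)[, `:=`(start = L - 72L + 1L,
                                         end = L - 61L + 1L, strand = "-")]
  pos_plus <- 64L                       # the A of AGC
  pos_minus <- L - pos_plus + 1L
  expect_identical(substring(genome_minus[[1L]], pos_minus, pos_minus), "T")
  cc_p <- consequence(list(contig = "chr1", pos = pos_plus, strand = "+"),
                      feats_plus, genome_plus)
  cc_m <- consequence(list(contig = "chr1", pos = pos_minus, strand = "-"),
                      feats_minus, genome_minus)
  expect_equal(cc_m$codon_before, cc_p$codon_before)
  expect_equal(cc_m$codon_after, cc_p$codon_after)
  expect_equal(cc_m$aa_before, "S")
  expect_equal(cc_m$aa_after, "G")
})

test_that("CDS length not divisible by 3 is an annotation error", {
  genome <- c(chr1 = rand_seq(200L, seed = 9L))
  feats <- data.table(contig = "chr1", start = 50L, end = 59L, strand = "+",
                      feature = "CDS", gene_id = "g", transcript_id = "g.t1")
  pos_a <- 49L + which(strsplit(substring(genome, 50, 59), "")[[1L]] == "A")[1L]
  expect_error(consequence(list(contig = "chr1", pos = pos_a, strand = "+"),
                           feats, genome),
               "divisible by 3")
})

test_that("splice proximity flags donor, acceptor and the branch window", {
  intr <- ann_features[gene_id == "gA" & feature == "intron"][1L]
  at <- function(pos) splice_proximity(list(contig = "chr1", pos = pos,
                                            strand = "+"), ann_features)
  expect_equal(at(intr$start), "donor")
  expect_equal(at(intr$start + 1L), "donor")
  expect_equal(at(intr$end), "acceptor")
  expect_equal(at(intr$end - 29L), "branch_window")   # 30 nt upstream of 3'ss
  expect_equal(at(intr$end - 17L), "branch_window")   # distance 18, window edge
  expect_equal(at(intr$end - 16L), "none")            # distance 17, outside
  # exonic site
  cds <- ann_features[gene_id == "gA" & feature == "CDS"][1L]
  expect_equal(at(cds$start + 3L), "none")
  # minus-strand intron: donor is at the genomic end
  intr_m <- ann_features[gene_id == "gB" & feature == "intron"][1L]
  expect_equal(splice_proximity(list(contig = "chr1", pos = intr_m$end,
                                     strand = "-"), ann_features), "donor")
  expect_equal(splice_proximity(list(contig = "chr1", pos = intr_m$start,
                                     strand = "-"), ann_features), "acceptor")
})
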