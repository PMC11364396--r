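#' Assemble a cohort edit-site table across samples
#'
#' Takes per-sample pileup counts, calls candidate sites per sample, and
#' backfills every candidate site key into every sample that covers it -
#' including samples with zero edited reads there, which must still
#' contribute their unedited coverage to pooled group counts.
#'
#' @param counts_list Named list of `site_counts` tables ([pileup()]), one
#'   per sample; names are sample ids.
#' @param genome Genome.
#' @return An `edit_sites` cohort table with one row per (site, covering
#'   sample).
#' @export
assemble_cohort <- function(counts_list, genome) {
  stopifnot(!is.null(names(counts_list)), all(nzchar(names(counts_list))))
  sites <- unique(rbindlist(
    lapply(counts_list, function(cc) {
      call_candidate_sites(cc, genome)[, .(contig, pos, strand)]
    })))
  out <- rbindlist(lapply(names(counts_list), function(s) {
    m <- merge(sites, as.data.table(counts_list[[s]]),
               by = c("contig", "pos", "strand"))
    m[, .(contig, pos, strand, edited = G, unedited = A,
          ratio = ifelse(A + G > 0L, G / (A + G), NA_real_),
          depth, hyper = G_rescued > 0L, sample = s)]
  }))
  setorder(out, contig, pos, strand, sample)
  setattr(out, "class", c("edit_sites", class(out)))
  out[]
}

#' Simulate, align, rescue and call a whole cohort in memory
#'
#' Convenience wrapper running the read simulator, the primary aligner, the
#' hyper-editing rescue and the strand-aware pileup for every sample, then
#' assembling the cohort table with [assemble_cohort()].
#'
#' @param sg A `synth_genome`.
#' @param plan An `editing_plan` with one `rate_<group>` column per group.
#' @param params A [read_sim_params()].
#' @param sample_groups Named character vector: sample id -> group label.
#' @param align An [align_params()].
#' @param seed Integer seed; per-sample seeds are derived from it.
#' @return A list: `cohort` (edit_sites), `stats` (per-sample aligned /
#'   unaligned / rescued read counts).
#' @export
simulate_cohort <- function(sg, plan, params, sample_groups,
                            align = align_params(), seed = 1L) {
  index <- build_index(sg$genome, align$seed_kmer)
  counts_list <- list()
  stats <- list()
  for (i in seq_along(sample_groups)) {
    s <- names(sample_groups)[i]
    reads <- simulate_reads(sg, plan, params, s, sample_groups[[i]],
                            seed = derive_seed(seed, i))
    al <- toy_align(reads, params = align, index = index)
    rs <- hyper_rescue(al$unaligned, sg$genome, align)
    combined <- rbind(al$aligned,
                      rs$rescued[, names(al$aligned), with = FALSE])
    counts_list[[s]] <- pileup(combined, sg$genome, s)
    stats[[s]] <- data.table(sample = s, n_reads = nrow(reads),
                             aligned = nrow(al$aligned),
                             unaligned = nrow(al$unaligned),
                             multi = nrow(al$multi),
                             rescued = nrow(rs$rescued))
  }
  list(cohort = assemble_cohort(counts_list, sg$genome),
       stats = rbindlist(stats))
}
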