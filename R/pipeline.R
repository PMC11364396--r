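#' Assemble and validate a pipeline configuration
#'
#' One configuration object drives every stage. Module parameter blocks are
#' passed through to the corresponding constructors, so any [synth_config()],
#' [read_sim_params()], [align_params()] or [filter_config()] argument can be
#' set here.
#'
#' @param outdir Output directory (created if missing).
#' @param samples data.frame with columns `sample_id` and `group`; optional
#'   columns `fastq_r1`/`fastq_r2` or `sam` switch a sample from simulation
#'   to ingestion.
#' @param seed Global integer seed; per-sample seeds are derived from it.
#' @param alpha Significance threshold for adjusted p-values.
#' @param genome List of [synth_config()] arguments, or
#'   `list(fasta =, gtf =, repeats_bed =)` to use existing files.
#' @param plan List of [plan_editing()] arguments (ignored when reads are
#'   ingested).
#' @param reads List of [read_sim_params()] arguments.
#' @param align List of [align_params()] arguments.
#' @param filter List of [filter_config()] arguments.
#' @param context List: `halfwidth`, `min_arm`, `max_loop`, plus
#'   [a_rich_satellite()] arguments.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            samples = data.frame(
                              sample_id = sprintf("s%d", 1:6),
                              group = rep(c("ctrl", "treat"), each = 3L)),
                            seed = 1L, alpha = 0.05,
                            genome = list(), plan = list(), reads = list(),
                            align = list(), filter = list(),
                            context = list()) {
  samples <- as.data.frame(samples)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    stop("validation: samples must have sample_id and group columns")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("validation: sample ids must be unique")
  }
  if (anyNA(samples$group) || any(samples$group == "")) {
    stop("validation: every sample needs a group label")
  }
  structure(list(outdir = outdir, samples = samples,
                 seed = as.integer(seed), alpha = alpha,
                 genome = genome, plan = plan, reads = reads,
                 align = align, filter = filter, context = context),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML path with top-level keys matching [pipeline_config()]
#'   arguments (`samples` as a list of `sample_id`/`group` records).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$samples <- rbindlist(lapply(y$samples, as.data.table), fill = TRUE)
  do.call(pipeline_config, y)
}

pipeline_stages <- c("simulate", "align", "rescue", "call", "filter",
                     "diff", "annotate", "context", "tracks")

#' Run the editing-analysis pipeline
#'
#' Executes simulate, align, rescue, call, filter, diff, annotate, context
#' and tracks in order, handing data between stages through files under
#' `config$outdir` so each stage can also be rerun standalone. Identical
#' config and seed give identical outputs; a JSON manifest records per-stage
#' record counts and output checksums.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @param stages Stages to run (default all, in order).
#' @return The manifest, invisibly (a list; also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$outdir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else {
    list(tool = "hyperedit",
         version = as.character(packageVersion("hyperedit")),
         seed = config$seed, stages = list())
  }
  for (st in pipeline_stages) {
    if (!st %in% stages) next
    fn <- get(paste0("stage_", st), mode = "function")
    res <- tryCatch(fn(config), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[st]] <- res
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(manifest)
}

stage_paths <- function(config) {
  o <- config$outdir
  list(
    genome = file.path(o, "genome.fa"), gtf = file.path(o, "genes.gtf"),
    repeats = file.path(o, "repeats.bed"),
    truth = file.path(o, "truth_sites.tsv"),
    truth_ir = file.path(o, "truth_inverted_repeats.tsv"),
    fastq = function(s, m) file.path(o, sprintf("%s_R%d.fastq", s, m)),
    sam = function(s) file.path(o, sprintf("%s.sam", s)),
    rescued_sam = function(s) file.path(o, sprintf("%s.rescued.sam", s)),
    sites = function(s) file.path(o, sprintf("%s.sites.tsv", s)),
    cohort = file.path(o, "cohort.tsv"),
    filtered = file.path(o, "cohort_filtered.tsv"),
    vcf = file.path(o, "cohort.vcf"),
    diff = function(cmp) file.path(o, sprintf("diff_%s.tsv", cmp)),
    directions = file.path(o, "direction_summary.tsv"),
    top = file.path(o, "top_sites.tsv"),
    annotated = file.path(o, "sites_annotated.tsv"),
    motif = file.path(o, "motif.tsv"),
    satellite = file.path(o, "satellite.tsv"),
    ir = file.path(o, "inverted_repeats.tsv")
  )
}

md5s <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

load_reference <- function(config) {
  p <- stage_paths(config)
  list(genome = read_genome_fasta(p$genome),
       features = read_gene_models(p$gtf),
       repeats = read_repeats(p$repeats))
}

stage_simulate <- function(config) {
  p <- stage_paths(config)
  if (!is.null(config$genome$fasta)) {
    file.copy(config$genome$fasta, p$genome, overwrite = TRUE)
    file.copy(config$genome$gtf, p$gtf, overwrite = TRUE)
    file.copy(config$genome$repeats_bed, p$repeats, overwrite = TRUE)
    return(list(mode = "ingested", files = md5s(c(p$genome, p$gtf, p$repeats))))
  }
  gcfg <- do.call(synth_config,
                  c(config$genome, list(rng_seed = derive_seed(config$seed, 1L))))
  sg <- generate_genome(gcfg)
  write_genome_fasta(sg, p$genome)
  write_gtf(sg$features, p$gtf)
  write_repeats_bed(sg$repeats, p$repeats)
  fwrite(sg$inverted_repeats, p$truth_ir, sep = "\t")
  groups <- unique(config$samples$group)
  plan <- do.call(plan_editing,
                  c(list(sg = sg, groups = groups), config$plan,
                    list(seed = derive_seed(config$seed, 2L))))
  write_plan(plan, p$truth)
  params <- do.call(read_sim_params, config$reads)
  n_reads <- 0L
  for (i in seq_len(nrow(config$samples))) {
    s <- config$samples$sample_id[i]
    reads <- simulate_reads(sg, plan, params, s, config$samples$group[i],
                            seed = derive_seed(config$seed, 10L + i))
    write_fastq(reads, p$fastq(s, 1L), p$fastq(s, 2L))
    n_reads <- n_reads + nrow(reads)
  }
  list(mode = "synthetic", n_planted_sites = nrow(plan), n_reads = n_reads,
       files = md5s(c(p$genome, p$gtf, p$repeats, p$truth)))
}

stage_align <- function(config) {
  p <- stage_paths(config)
  ref <- load_reference(config)
  params <- do.call(align_params, config$align)
  index <- build_index(ref$genome, params$seed_kmer)
  n_aligned <- 0L; n_unaligned <- 0L; n_multi <- 0L
  for (i in seq_len(nrow(config$samples))) {
    s <- config$samples$sample_id[i]
    has <- function(col) col %in% names(config$samples) &&
      !is.na(config$samples[[col]][i])
    if (has("sam")) {
      file.copy(config$samples[["sam"]][i], p$sam(s), overwrite = TRUE)
      next
    }
    r1 <- if (has("fastq_r1")) config$samples[["fastq_r1"]][i] else p$fastq(s, 1L)
    r2 <- if (has("fastq_r2")) config$samples[["fastq_r2"]][i] else p$fastq(s, 2L)
    reads <- read_fastq(r1, r2)
    al <- toy_align(reads, params = params, index = index)
    write_sam(al$aligned, ref$genome, p$sam(s), unaligned = al$unaligned)
    n_aligned <- n_aligned + nrow(al$aligned)
    n_unaligned <- n_unaligned + nrow(al$unaligned)
    n_multi <- n_multi + nrow(al$multi)
  }
  list(reads_aligned = n_aligned, reads_unaligned = n_unaligned,
       reads_multimapped_discarded = n_multi)
}

stage_rescue <- function(config) {
  p <- stage_paths(config)
  ref <- load_reference(config)
  params <- do.call(align_params, config$align)
  n_rescued <- 0L; n_unrescued <- 0L
  for (s in config$samples$sample_id) {
    al <- read_alignments(p$sam(s))
    rs <- hyper_rescue(al$unaligned, ref$genome, params)
    write_sam(rs$rescued, ref$genome, p$rescued_sam(s))
    n_rescued <- n_rescued + nrow(rs$rescued)
    n_unrescued <- n_unrescued + rs$n_unrescued
  }
  list(reads_rescued = n_rescued, reads_unrescued = n_unrescued)
}

stage_call <- function(config) {
  p <- stage_paths(config)
  ref <- load_reference(config)
  counts_list <- list()
  for (s in config$samples$sample_id) {
    al <- read_alignments(p$sam(s))$aligned
    if (file.exists(p$rescued_sam(s))) {
      resc <- read_alignments(p$rescued_sam(s))$aligned
      al <- rbind(al, resc, fill = TRUE)
    }
    counts_list[[s]] <- pileup(al, ref$genome, sample_id = s)
    fwrite(call_candidate_sites(counts_list[[s]], ref$genome), p$sites(s),
           sep = "\t")
  }
  cohort <- assemble_cohort(counts_list, ref$genome)
  fwrite(cohort, p$cohort, sep = "\t")
  list(sites_called = uniqueN(cohort[, .(contig, pos, strand)]),
       site_sample_rows = nrow(cohort))
}

stage_filter <- function(config) {
  p <- stage_paths(config)
  cohort <- read_edit_sites(p$cohort)
  fcfg <- do.call(filter_config, config$filter)
  filtered <- filter_high_confidence(cohort, fcfg)
  fwrite(filtered, p$filtered, sep = "\t")
  if (nrow(filtered)) write_sites_vcf(filtered, p$vcf)
  list(sites_filtered = uniqueN(filtered[, .(contig, pos, strand)]))
}

stage_diff <- function(config) {
  p <- stage_paths(config)
  filtered <- read_edit_sites(p$filtered)
  groups <- setNames(config$samples$group, config$samples$sample_id)
  glab <- unique(config$samples$group)
  results <- list()
  for (i in seq_along(glab)) {
    for (j in seq_along(glab)) {
      if (i >= j) next
      cmp <- c(glab[i], glab[j])
      r <- diff_editing(filtered, groups, cmp, alpha = config$alpha)
      key <- paste(cmp, collapse = "_vs_")
      fwrite(r, p$diff(key), sep = "\t")
      results[[key]] <- r
    }
  }
  if (length(results)) {
    dirs <- summarize_directions(results, alpha = config$alpha)
    fwrite(dirs, p$directions, sep = "\t")
    ref <- load_reference(config)
    top <- top_sites(results[[1L]], k = 500L, repeats = ref$repeats)
    fwrite(top, p$top, sep = "\t")
  }
  list(comparisons = names(results),
       sites_tested = if (length(results)) nrow(results[[1L]]) else 0L,
       sites_significant = sum(vapply(results,
                                      function(r) sum(r$significant),
                                      integer(1))))
}

stage_annotate <- function(config) {
  p <- stage_paths(config)
  ref <- load_reference(config)
  filtered <- read_edit_sites(p$filtered)
  sites <- unique(filtered[, .(contig, pos, strand)])
  if (!nrow(sites)) {
    fwrite(sites, p$annotated, sep = "\t")
    return(list(sites_annotated = 0L))
  }
  ann <- assign_region(sites, ref$features)
  ann[, repeat_class := assign_repeat(sites, ref$repeats)]
  ann[, splice := vapply(seq_len(.N), function(i) {
    splice_proximity(ann[i], ref$features)
  }, character(1))]
  ann[, consequence := NA_character_]
  cds_rows <- which(ann$region == "CDS")
  for (i in cds_rows) {
    cc <- tryCatch(consequence(ann[i], ref$features, ref$genome),
                   error = function(e) NULL)
    if (!is.null(cc)) {
      set(ann, i, "consequence",
          sprintf("%s>%s:%s>%s:%s", cc$codon_before, cc$codon_after,
                  cc$aa_before, cc$aa_after, cc$class))
    }
  }
  fwrite(ann, p$annotated, sep = "\t")
  list(sites_annotated = nrow(ann),
       by_region = as.list(table(ann$region)))
}

stage_context <- function(config) {
  p <- stage_paths(config)
  ref <- load_reference(config)
  filtered <- read_edit_sites(p$filtered)
  ctx <- config$context
  hw <- ctx$halfwidth %||% 50L
  out <- list()
  sites <- unique(filtered[, .(contig, pos, strand)])
  if (nrow(sites) >= 10L) {
    prof <- motif_profile(sites, ref$genome, halfwidth = hw)
    fwrite(top_enrichments(prof, exclude_center = FALSE), p$motif, sep = "\t")
    top <- top_enrichments(prof)[1L]
    out$motif_top <- sprintf("%+d:%s", top$position, top$base)
  }
  hyper <- unique(filtered[hyper == TRUE, .(contig, pos, strand)])
  if (nrow(hyper)) {
    sat <- a_rich_satellite(hyper, ref$genome,
                            offset_range = ctx$offset_range %||% c(20L, 40L),
                            window = ctx$window %||% 10L,
                            a_fraction = ctx$a_fraction %||% 0.7)
    fwrite(sat, p$satellite, sep = "\t")
    out$satellite_flagged <- sum(sat$flagged)
  }
  scan <- scan_gene_inverted_repeats(
    list(genome = ref$genome, features = ref$features),
    min_arm = ctx$min_arm %||% 30L, max_loop = ctx$max_loop %||% 10000L)
  fwrite(scan$hits, p$ir, sep = "\t")
  out$genes_with_inverted_repeat <- scan$genes_with_ir
  out
}

stage_tracks <- function(config) {
  p <- stage_paths(config)
  filtered <- read_edit_sites(p$filtered)
  diffs <- list.files(config$outdir, pattern = "^diff_.*\\.tsv$",
                      full.names = TRUE)
  names(diffs) <- sub("^diff_", "", sub("\\.tsv$", "", basename(diffs)))
  export_browser_tracks(filtered, diffs, config$outdir,
                        alpha = config$alpha)
  list(tracks = length(unique(filtered$sample)) + length(diffs))
}

#' Export browser tracks of editing ratios and significant sites
#'
#' One bedGraph per sample (edit ratio per site, 0-based half-open
#' intervals) and one BED of significant sites per comparison.
#'
#' @param cohort An `edit_sites` cohort table.
#' @param diff_files Character vector of differential result TSV paths (as
#'   written by [run_pipeline()]), or a list of `diff_result` tables.
#' @param outdir Output directory.
#' @param alpha Significance threshold.
#' @return Invisibly, the written paths.
#' @export
export_browser_tracks <- function(cohort, diff_files, outdir, alpha = 0.05) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (s in unique(cohort$sample)) {
    dt <- cohort[sample == s]
    path <- file.path(outdir, sprintf("%s.ratio.bedGraph", s))
    lines <- c(sprintf("track type=bedGraph name=\"%s edit ratio\"", s),
               sprintf("%s\t%d\t%d\t%.6g", dt$contig, dt$pos - 1L, dt$pos,
                       dt$ratio))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  if (is.character(diff_files)) {
    nm <- names(diff_files)
    diff_files <- lapply(diff_files, fread)
    names(diff_files) <- nm
  }
  for (k in seq_along(diff_files)) {
    r <- as.data.table(diff_files[[k]])
    cmp <- attr(diff_files[[k]], "comparison")
    name <- if (!is.null(cmp))  paste(cmp, collapse = "_vs_")
            else if (!is.null(names(diff_files)) && nzchar(names(diff_files)[k]))
              names(diff_files)[k]
            else sprintf("comparison%d", k)
    sig <- r[padj < alpha]
    path <- file.path(outdir, sprintf("%s.significant.bed", name))
    lines <- c(sprintf("track name=\"%s significant sites\"", name),
               if (nrow(sig)) sprintf("%s\t%d\t%d\t%s\t0\t%s", sig$contig,
                                      sig$pos - 1L, sig$pos,
                                      sprintf("p%.3g", sig$padj), sig$strand))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read an edit-sites TSV written by the pipeline
#' @param path TSV path.
#' @return An `edit_sites` data.table.
#' @export
read_edit_sites <- function(path) {
  dt <- fread(path, sep = "\t",
              colClasses = list(character = "contig", integer = "pos"))
  if ("sample" %in% names(dt)) dt[, sample := as.character(sample)]
  setattr(dt, "class", c("edit_sites", class(dt)))
  dt[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
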