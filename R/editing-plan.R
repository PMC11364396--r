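#' Plant A-to-I editing sites with per-group rates
#'
#' Selects transcript-strand adenosines inside gene territory (UTRs, CDS,
#' introns) and assigns each a per-group editing rate: the probability that a
#' fragment covering the site carries the A-to-G change on the transcript
#' strand. Optionally plants hyper-editing clusters: groups of >= 3 nearby
#' adenosines in a 3'UTR that are edited jointly within a fragment, emulating
#' the read-level mismatch clustering that defeats ordinary alignment.
#'
#' @param sg A `synth_genome` from [generate_genome()].
#' @param groups Character vector of group labels (e.g. `c("ctrl", "treat")`).
#' @param n_sites Number of non-cluster sites to plant.
#' @param rates Per-site, per-group editing rates: a numeric matrix with
#'   `n_sites` rows and one column per group, a single numeric (used
#'   everywhere), or `NULL` to sample per-site rates from `rate_levels`
#'   (identical across groups).
#' @param rate_levels Candidate rates used when `rates = NULL`.
#' @param region_weights Named sampling weights over regions; the default
#'   concentrates editing in 3'UTRs, where A-to-I editing is most prominent.
#' @param n_clusters Number of hyper-editing clusters to plant (0 for none).
#' @param cluster_span Genomic span of each cluster in bases.
#' @param cluster_rate Joint editing rate of a cluster (all groups).
#' @param seed Integer seed.
#' @return A `data.table` of class `editing_plan`: one row per planted site
#'   with `site_id, contig, pos, strand, gene_id, region, hyper, cluster_id`
#'   and one `rate_<group>` column per group.
#' @export
plan_editing <- function(sg, groups = c("ctrl", "treat"), n_sites = 200L,
                         rates = NULL,
                         rate_levels = seq(0.1, 0.8, by = 0.1),
                         region_weights = c(five_prime_utr = 0.5, CDS = 0.5,
                                            intron = 1, three_prime_utr = 3),
                         n_clusters = 2L, cluster_span = 60L,
                         cluster_rate = 0.8, seed = 1L) {
  stopifnot(inherits(sg, "synth_genome"))
  if (anyDuplicated(groups)) stop("group labels must be unique")
  set.seed(as.integer(seed))

  cand <- candidate_adenosines(sg)
  if (nrow(cand) < n_sites) {
    stop(sprintf("only %d plantable adenosines available for %d requested sites",
                 nrow(cand), n_sites))
  }

  w <- region_weights[cand$region]
  pick <- sample.int(nrow(cand), n_sites, prob = w)
  sites <- cand[pick]

  if (is.null(rates)) {
    r <- sample(rate_levels, n_sites, replace = TRUE)
    rates <- matrix(r, nrow = n_sites, ncol = length(groups))
  } else if (is.matrix(rates)) {
    if (nrow(rates) != n_sites || ncol(rates) != length(groups)) {
      stop("rates matrix must be n_sites x length(groups)")
    }
  } else if (length(rates) == 1L) {
    rates <- matrix(rates, nrow = n_sites, ncol = length(groups))
  } else {
    stop("rates must be NULL, a scalar, or a matrix")
  }
  check_proportion(rates, "editing rates")
  sites[, hyper := FALSE]
  sites[, cluster_id := NA_character_]
  for (g in seq_along(groups)) {
    set(sites, j = paste0("rate_", groups[g]), value = rates[, g])
  }

  if (n_clusters > 0L) {
    cl <- plant_clusters(sg, cand[-pick], n_clusters, cluster_span,
                         cluster_rate, groups)
    if (!is.null(cl)) sites <- rbind(sites, cl, fill = TRUE)
  }

  setorder(sites, contig, pos)
  sites[, site_id := sprintf("site%04d", .I)]
  setcolorder(sites, c("site_id", "contig", "pos", "strand", "gene_id",
                       "region", "hyper", "cluster_id"))
  verify_plan(sites, sg)
  setattr(sites, "groups", groups)
  setattr(sites, "class", c("editing_plan", class(sites)))
  sites[]
}

# all transcript-strand adenosines within gene features
candidate_adenosines <- function(sg) {
  out <- vector("list", nrow(sg$features))
  for (i in seq_len(nrow(sg$features))) {
    f <- sg$features[i]
    seq <- contig_substr(sg$genome, f$contig, f$start, f$end)
    want <- if (f$strand == "+") "A" else "T"
    off <- which(strsplit(seq, "", fixed = TRUE)[[1L]] == want)
    if (!length(off)) next
    out[[i]] <- data.table(contig = f$contig, pos = f$start + off - 1L,
                           strand = f$strand, gene_id = f$gene_id,
                           region = f$feature)
  }
  rbindlist(out)
}

plant_clusters <- function(sg, cand, n_clusters, cluster_span, cluster_rate,
                           groups) {
  utr <- cand[region == "three_prime_utr"]
  if (!nrow(utr)) return(NULL)
  setorder(utr, contig, pos)
  out <- list()
  used_genes <- character()
  ci <- 0L
  for (gid in unique(utr$gene_id)) {
    if (ci >= n_clusters) break
    g <- utr[gene_id == gid]
    # find a window with >= 3 adenosines
    for (i in seq_len(nrow(g))) {
      memb <- g[pos >= g$pos[i] & pos <= g$pos[i] + cluster_span - 1L]
      if (nrow(memb) >= 3L) {
        ci <- ci + 1L
        memb <- copy(head(memb, 6L))
        memb[, hyper := TRUE]
        memb[, cluster_id := sprintf("cluster%02d", ci)]
        for (gr in groups) set(memb, j = paste0("rate_", gr), value = cluster_rate)
        out[[ci]] <- memb
        break
      }
    }
  }
  if (length(out)) rbindlist(out) else NULL
}

verify_plan <- function(sites, sg) {
  for (i in seq_len(nrow(sites))) {
    b <- contig_substr(sg$genome, sites$contig[i], sites$pos[i], sites$pos[i])
    ok <- (sites$strand[i] == "+" && b == "A") ||
          (sites$strand[i] == "-" && b == "T")
    if (!ok) stop(sprintf("planted site %s:%d is not A on the %s strand",
                          sites$contig[i], sites$pos[i], sites$strand[i]))
  }
  cl <- sites[hyper == TRUE, .N, by = cluster_id]
  if (nrow(cl) && any(cl$N < 3L)) stop("hyper clusters must contain >= 3 sites")
  invisible(TRUE)
}

#' Write an editing plan to a TSV truth table
#' @param plan An `editing_plan`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  fwrite(plan, path, sep = "\t")
  invisible(path)
}

#' Read an editing plan truth table written by [write_plan()]
#' @param path TSV path.
#' @return An `editing_plan` data.table.
#' @export
read_plan <- function(path) {
  plan <- fread(path, sep = "\t")
  groups <- sub("^rate_", "", grep("^rate_", names(plan), value = TRUE))
  setattr(plan, "groups", groups)
  setattr(plan, "class", c("editing_plan", class(plan)))
  plan[]
}
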