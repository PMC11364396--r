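#' Two-sided Fisher's exact test for one editing site
#'
#' Exact two-sided p-value for the 2x2 table of pooled (edited, unedited)
#' counts in two groups, computed by summing all hypergeometric outcomes
#' whose probability does not exceed that of the observed table (with the
#' customary one-part-in-1e7 relative guard against floating-point ties).
#'
#' @param group1,group2 Integer vectors `c(edited, unedited)` of pooled
#'   counts.
#' @return Two-sided p-value. An empty margin (no edited reads anywhere, or
#'   no reads in a group) carries no information: p = 1 with a warning.
#' @export
fisher_site <- function(group1, group2) {
  stopifnot(length(group1) == 2L, length(group2) == 2L,
            all(c(group1, group2) >= 0))
  x <- group1[1L]
  m <- group1[1L] + group2[1L]          # edited margin
  n <- group1[2L] + group2[2L]          # unedited margin
  k <- group1[1L] + group1[2L]          # group 1 total
  if (m == 0L || n == 0L || k == 0L || (m + n - k) == 0L) {
    warning("empty margin in 2x2 table; p = 1")
    return(1)
  }
  lo <- max(0L, k - n)
  hi <- min(k, m)
  d <- dhyper(lo:hi, m, n, k)
  dobs <- d[x - lo + 1L]
  min(1, sum(d[d <= dobs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, `min over i' >= i of p * m / i'`, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
adjust_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Per-site differential editing between two groups
#'
#' Pools edited/unedited read counts across the samples of each group (a
#' sample without a call at a site contributes zero reads), tests each site
#' with [fisher_site()], and adjusts p-values by Benjamini-Hochberg FDR
#' within the comparison. Direction is +1 when group 1 has the higher pooled
#' ratio, -1 when group 2 does, 0 on exact ties.
#'
#' @param cohort An `edit_sites` table (typically the output of
#'   [filter_high_confidence()]; filtering precedes testing).
#' @param groups Named character vector mapping sample id to group label.
#' @param comparison Character vector of the two group labels to compare,
#'   `c(group1, group2)`.
#' @param alpha Significance threshold on the FDR-adjusted p-value.
#' @return A `data.table` of class `diff_result`: per site `contig, pos,
#'   strand, edited1, unedited1, edited2, unedited2, ratio1, ratio2, delta,
#'   p, padj, direction, significant`, with the comparison stored as
#'   attribute `"comparison"`.
#' @export
diff_editing <- function(cohort, groups, comparison, alpha = 0.05) {
  stopifnot(length(comparison) == 2L)
  if (is.null(names(groups))) stop("groups must be named by sample id")
  missing_grp <- setdiff(unique(cohort$sample), names(groups))
  if (length(missing_grp)) {
    stop(sprintf("samples without a group label: %s",
                 paste(missing_grp, collapse = ", ")))
  }
  dt <- as.data.table(cohort)
  dt[, group := groups[sample]]
  dt <- dt[group %in% comparison]
  pooled <- dt[, .(edited = sum(edited), unedited = sum(unedited)),
               by = .(contig, pos, strand, group)]
  wide <- dcast(pooled, contig + pos + strand ~ group,
                value.var = c("edited", "unedited"), fill = 0L)
  e1 <- paste0("edited_", comparison[1L]); e2 <- paste0("edited_", comparison[2L])
  u1 <- paste0("unedited_", comparison[1L]); u2 <- paste0("unedited_", comparison[2L])
  for (cn in c(e1, e2, u1, u2)) {
    if (!cn %in% names(wide)) set(wide, j = cn, value = 0L)
  }
  res <- wide[, .(contig, pos, strand,
                  edited1 = get(e1), unedited1 = get(u1),
                  edited2 = get(e2), unedited2 = get(u2))]
  res[, ratio1 := ifelse(edited1 + unedited1 > 0, edited1 / (edited1 + unedited1), NA_real_)]
  res[, ratio2 := ifelse(edited2 + unedited2 > 0, edited2 / (edited2 + unedited2), NA_real_)]
  res[, delta := ratio1 - ratio2]
  res[, p := {
    pv <- numeric(.N)
    for (i in seq_len(.N)) {
      pv[i] <- suppressWarnings(fisher_site(c(edited1[i], unedited1[i]),
                                            c(edited2[i], unedited2[i])))
    }
    pv
  }]
  res[, padj := adjust_fdr(p)]
  res[, direction := sign(ifelse(is.na(delta), 0, delta))]
  res[, significant := padj < alpha]
  setorder(res, contig, pos, strand)
  setattr(res, "comparison", comparison)
  setattr(res, "class", c("diff_result", class(res)))
  res[]
}

#' Count significant sites by direction of change
#'
#' Mirrors the stacked-bar genome-wide summary: for a comparison, how many
#' significant sites are more edited in group 1 vs in group 2. Exact ties
#' (direction 0) are excluded.
#'
#' @param results A `diff_result` (or list of them).
#' @param alpha Significance threshold on adjusted p.
#' @return A `data.table`: `comparison, up_in_group1, up_in_group2`.
#' @export
summarize_directions <- function(results, alpha = 0.05) {
  if (inherits(results, "diff_result")) results <- list(results)
  out <- lapply(results, function(r) {
    cmp <- attr(r, "comparison")
    data.table(
      comparison = paste(cmp, collapse = "_vs_"),
      up_in_group1 = nrow(r[padj < alpha & direction > 0]),
      up_in_group2 = nrow(r[padj < alpha & direction < 0])
    )
  })
  rbindlist(out)
}

#' Top differential editing sites
#'
#' Ranks sites by adjusted p ascending, breaking ties by absolute ratio
#' difference descending, then by coordinate, and returns the first `k` with
#' repeat-class labels attached when a repeat track is supplied.
#'
#' @param results A `diff_result`.
#' @param k Number of sites to return (default 500); all sites if fewer.
#' @param repeats Optional repeat track (`contig, start, end, class`).
#' @return The ranked head of the results table (plain data.table).
#' @export
top_sites <- function(results, k = 500L, repeats = NULL) {
  dt <- as.data.table(results)
  dt <- dt[order(padj, -abs(delta), contig, pos, strand)]
  dt <- head(dt, max(0L, k))
  if (!is.null(repeats) && nrow(dt)) {
    dt[, repeat_class := assign_repeat(dt, repeats)]
  }
  dt[]
}
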