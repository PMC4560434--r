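#' Filter configuration
#'
#' @param min_unique_reads_for_threshold Transcripts with at least this many
#'   unique reads anchor the expression threshold (default 10).
#' @param min_replicates Minimum number of replicates above threshold for a
#'   transcript to be called expressed in a group (default 4).
#' @param mcse_mode One of `"off"`, `"t1"`, `"t5"`: optional subsetting of
#'   transcripts by an uncertainty (MCSE-style) threshold anchored at
#'   transcripts with exactly 1 or 5 unique reads.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_unique_reads_for_threshold = 10L,
                          min_replicates = 4L,
                          mcse_mode = c("off", "t1", "t5")) {
  mcse_mode <- match.arg(mcse_mode)
  stopifnot(min_unique_reads_for_threshold >= 1, min_replicates >= 1)
  structure(list(
    min_unique_reads_for_threshold = as.integer(min_unique_reads_for_threshold),
    min_replicates = as.integer(min_replicates),
    mcse_mode = mcse_mode), class = "filter_config")
}

#' Expression threshold from well-read transcripts
#'
#' The threshold `t` is the minimum mean expression (across all sample
#' columns) among transcripts with at least
#' `cfg$min_unique_reads_for_threshold` unique reads: the expression level
#' down to which quantification is anchored by uniquely mapping reads.
#'
#' @param table An [expression_table()].
#' @param cfg A [filter_config()].
#' @return Numeric scalar `t` in expression units.
#' @export
compute_expression_threshold <- function(table, cfg = filter_config()) {
  qual <- table$unique_reads >= cfg$min_unique_reads_for_threshold
  if (!any(qual))
    stop("no transcript has >= ", cfg$min_unique_reads_for_threshold,
         " unique reads; lower min_unique_reads_for_threshold")
  means <- rowMeans(table$estimates[qual, , drop = FALSE])
  min(means)
}

#' Call expressed transcripts
#'
#' A transcript is expressed when its estimate is strictly above `t` in at
#' least `min_replicates` replicates of either F0 group, and strictly above
#' `t` in at least `min_replicates` F1 replicates. An F1 replicate's value
#' is the sum of its two allele estimates (the library total for the
#' transcript); the rule counts the F1 libraries, not the allele columns.
#'
#' @param table An [expression_table()].
#' @param t Expression threshold, e.g. from
#'   [compute_expression_threshold()].
#' @param cfg A [filter_config()].
#' @return Character vector of expressed transcript ids.
#' @export
call_expressed <- function(table, t, cfg = filter_config()) {
  est <- table$estimates
  bl6 <- est[, sample_ids(table, "F0_BL6"), drop = FALSE]
  cast <- est[, sample_ids(table, "F0_CAST"), drop = FALSE]
  reps <- f1_replicates(table)
  s <- table$samples
  bcol <- s$sample_id[match(paste(reps, "BL6"), paste(s$replicate, s$allele))]
  ccol <- s$sample_id[match(paste(reps, "CAST"), paste(s$replicate, s$allele))]
  f1 <- est[, bcol, drop = FALSE] + est[, ccol, drop = FALSE]

  k <- cfg$min_replicates
  if (k > ncol(bl6) || k > ncol(cast) || k > ncol(f1))
    stop("min_replicates exceeds the number of replicates in a group")
  ok_f0 <- rowSums(bl6 > t) >= k | rowSums(cast > t) >= k
  ok_f1 <- rowSums(f1 > t) >= k
  rownames(est)[ok_f0 & ok_f1]
}

#' Select the analysis set of two-isoform heterozygous genes
#'
#' Applies the gene-selection funnel: genes with exactly two expressed
#' transcripts, whose pair overlaps exonically on the same strand, and with
#' at least one known strain-distinguishing variant. Genes whose two
#' expressed transcripts do not overlap are excluded and counted separately.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param expressed Character vector of expressed transcript ids from
#'   [call_expressed()].
#' @param variants Named integer vector gene_id -> variant count (see
#'   [read_variants()]); genes absent from it count 0.
#' @return List with `gene_ids` (the analysis set), `pairs` (named list
#'   gene_id -> the two expressed transcript ids), and `funnel` (data frame
#'   of stage names and counts: total, two expressed isoforms, overlapping
#'   pair, with variant), plus `n_nonoverlapping`.
#' @export
select_analysis_set <- function(genes, expressed, variants = integer()) {
  n_total <- length(genes)
  pairs <- list()
  for (g in genes) {
    ex <- vapply(g$transcripts, `[[`, "", "transcript_id")
    keep <- ex[ex %in% expressed]
    if (length(keep) == 2L) pairs[[g$gene_id]] <- sort(keep)
  }
  n_two <- length(pairs)

  overlapping <- vapply(names(pairs), function(gid) {
    trs <- genes[[gid]]$transcripts
    ids <- vapply(trs, `[[`, "", "transcript_id")
    t1 <- trs[[match(pairs[[gid]][1L], ids)]]
    t2 <- trs[[match(pairs[[gid]][2L], ids)]]
    transcripts_overlap(t1, t2)
  }, NA)
  n_nonoverlap <- sum(!overlapping)
  pairs <- pairs[overlapping]
  n_overlap <- length(pairs)

  snv <- vapply(names(pairs), function(gid) {
    if (gid %in% names(variants)) variants[[gid]] else 0L
  }, 0L)
  pairs <- pairs[snv >= 1L]
  n_final <- length(pairs)

  list(gene_ids = names(pairs), pairs = pairs,
       funnel = data.frame(
         stage = c("total", "two_expressed_isoforms", "overlapping_pair",
                   "with_variant"),
         count = c(n_total, n_two, n_overlap, n_final),
         stringsAsFactors = FALSE),
       n_nonoverlapping = as.integer(n_nonoverlap))
}

#' Subset transcripts by estimate uncertainty (MCSE-style)
#'
#' The uncertainty threshold is the maximum standard error among transcripts
#' with exactly 1 (`t1`) or 5 (`t5`) unique reads; transcripts whose mean
#' standard error (across sample columns) does not exceed it are kept.
#' When no transcript has the anchor read count, the nearest available
#' count is used, with a warning.
#'
#' @param table An [expression_table()].
#' @param mode `"t1"` or `"t5"`.
#' @return Character vector of retained transcript ids.
#' @export
mcse_subset <- function(table, mode = c("t1", "t5")) {
  mode <- match.arg(mode)
  anchor_reads <- if (mode == "t1") 1L else 5L
  mean_se <- rowMeans(table$se)
  at_anchor <- table$unique_reads == anchor_reads
  if (!any(at_anchor)) {
    nearest <- table$unique_reads[which.min(abs(table$unique_reads - anchor_reads))]
    warning("no transcript with exactly ", anchor_reads,
            " unique reads; anchoring at nearest available count ", nearest)
    at_anchor <- table$unique_reads == nearest
  }
  thr <- max(mean_se[at_anchor])
  names(mean_se)[mean_se <= thr]
}
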