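#' Do two transcripts share at least one exonic base?
#'
#' Overlap is exonic, not span-based: two isoforms sharing only an intron do
#' not overlap. Both transcripts must be on the same chromosome and strand,
#' otherwise they are not a comparable isoform pair.
#'
#' @param t1,t2 [transcript_model()] objects.
#' @return Logical scalar.
#' @export
transcripts_overlap <- function(t1, t2) {
  if (t1$chrom != t2$chrom || t1$strand != t2$strand)
    stop("transcripts ", t1$transcript_id, " and ", t2$transcript_id,
         " are not a comparable pair (different chrom or strand)")
  a <- t1$exons
  b <- t2$exons
  any(outer(a[, 1L], b[, 2L], `<`) & t(outer(b[, 1L], a[, 2L], `<`)))
}

#' Classify the structural differences between two isoforms
#'
#' Compares a gene's two isoforms and flags each category of structural
#' change, strand-aware:
#' \describe{
#'   \item{AFE}{first exons do not overlap (alternative first exon).}
#'   \item{TSS}{first exons overlap but their 5' ends differ.}
#'   \item{ALE}{last exons do not overlap (alternative last exon).}
#'   \item{APA}{last exons overlap but their 3' ends differ.}
#'   \item{INT}{internal splicing difference: after excluding the 5'
#'     terminus of each first exon and the 3' terminus of each last exon —
#'     and both boundaries of first exons under AFE and of last exons under
#'     ALE — the exon boundary sets of the two isoforms differ. This covers
#'     both exons private to one isoform and shared junctions with a shifted
#'     donor or acceptor.}
#' }
#' AFE/TSS and ALE/APA are mutually exclusive by construction.
#'
#' @param t1,t2 [transcript_model()] objects forming an exonically
#'   overlapping pair (check with [transcripts_overlap()] first).
#' @return A one-row data frame of class `structural_diff` with columns
#'   `gene_id`, logical `AFE`, `TSS`, `INT`, `ALE`, `APA`, `overlapping`,
#'   and `n_changes`.
#' @export
classify_pair <- function(t1, t2) {
  if (!transcripts_overlap(t1, t2))
    stop("transcripts ", t1$transcript_id, " and ", t2$transcript_id,
         " do not overlap exonically; filter with transcripts_overlap() first")
  strand <- t1$strand
  fl1 <- first_last_exons(t1)
  fl2 <- first_last_exons(t2)

  first_ov <- intervals_overlap(fl1$first, fl2$first)
  afe <- !first_ov
  tss <- first_ov &&
    five_prime_end(fl1$first, strand) != five_prime_end(fl2$first, strand)

  last_ov <- intervals_overlap(fl1$last, fl2$last)
  ale <- !last_ov
  apa <- last_ov &&
    three_prime_end(fl1$last, strand) != three_prime_end(fl2$last, strand)

  b1 <- internal_boundaries(t1, strand, drop_first = afe, drop_last = ale)
  b2 <- internal_boundaries(t2, strand, drop_first = afe, drop_last = ale)
  int <- !identical(b1, b2)

  structural_diff(t1$gene_id, AFE = afe, TSS = tss, INT = int,
                  ALE = ale, APA = apa, overlapping = TRUE)
}

# Sorted vector of exon boundary coordinates entering the INT comparison.
internal_boundaries <- function(t, strand, drop_first, drop_last) {
  ex <- t$exons
  n <- nrow(ex)
  fi <- if (strand == "+") 1L else n   # first-exon row
  li <- if (strand == "+") n else 1L   # last-exon row
  keep_start <- rep(TRUE, n)
  keep_end <- rep(TRUE, n)
  # always drop the transcript's own 5' and 3' termini
  if (strand == "+") { keep_start[fi] <- FALSE; keep_end[li] <- FALSE }
  else               { keep_end[fi] <- FALSE; keep_start[li] <- FALSE }
  if (drop_first) keep_start[fi] <- keep_end[fi] <- FALSE
  if (drop_last)  keep_start[li] <- keep_end[li] <- FALSE
  sort(unique(c(ex[keep_start, 1L], ex[keep_end, 2L])))
}

structural_diff <- function(gene_id, AFE, TSS, INT, ALE, APA, overlapping) {
  d <- data.frame(gene_id = gene_id, AFE = AFE, TSS = TSS, INT = INT,
                  ALE = ALE, APA = APA, overlapping = overlapping,
                  stringsAsFactors = FALSE)
  d$n_changes <- as.integer(d$AFE + d$TSS + d$INT + d$ALE + d$APA)
  class(d) <- c("structural_diff", "data.frame")
  d
}

structure_flag_names <- c("AFE", "TSS", "INT", "ALE", "APA")

#' Tabulate combinations of structural differences
#'
#' Counts how many isoform pairs carry each distinct combination of
#' structural-change flags, how many genes carry exactly 1, 2, 3, ... flags,
#' the total number of discrete structural changes across all pairs, and
#' each category's share of that total.
#'
#' @param diffs Data frame with logical columns `AFE`, `TSS`, `INT`, `ALE`,
#'   `APA` (one row per isoform pair), e.g. rows from [classify_pair()].
#' @return List with elements `combinations` (data frame: flag columns,
#'   `combo` label, `n`, sorted by decreasing `n`), `by_n_changes` (named
#'   counts of genes with each number of changes), `total_changes`, and
#'   `category_share` (named proportions of `total_changes`).
#' @export
combination_matrix <- function(diffs) {
  flags <- as.data.frame(diffs)[, structure_flag_names, drop = FALSE]
  if (nrow(flags) == 0L) {
    return(list(
      combinations = data.frame(AFE = logical(), TSS = logical(),
                                INT = logical(), ALE = logical(),
                                APA = logical(), combo = character(),
                                n = integer(), stringsAsFactors = FALSE),
      by_n_changes = integer(),
      total_changes = 0L,
      category_share = stats::setNames(rep(NA_real_, 5L), structure_flag_names)))
  }
  combo <- apply(flags, 1L, function(r)
    paste(structure_flag_names[as.logical(r)], collapse = "+"))
  combo[combo == ""] <- "(none)"
  tab <- table(combo)
  combos <- data.frame(combo = names(tab), n = as.integer(tab),
                       stringsAsFactors = FALSE)
  fl <- do.call(rbind, lapply(combos$combo, function(cmb) {
    present <- strsplit(cmb, "+", fixed = TRUE)[[1L]]
    as.data.frame(as.list(stats::setNames(structure_flag_names %in% present,
                                          structure_flag_names)))
  }))
  combos <- cbind(fl, combos)
  combos <- combos[order(-combos$n, combos$combo), , drop = FALSE]
  rownames(combos) <- NULL

  n_changes <- rowSums(flags)
  by_n <- table(factor(n_changes, levels = 0:5))
  total <- sum(flags)
  share <- if (total > 0) colSums(flags) / total
           else stats::setNames(rep(NA_real_, 5L), structure_flag_names)
  list(combinations = combos,
       by_n_changes = stats::setNames(as.integer(by_n), names(by_n)),
       total_changes = as.integer(total),
       category_share = share)
}
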