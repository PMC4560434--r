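#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the minimum-likelihood convention (sum over all tables
#' with the observed margins whose hypergeometric probability does not
#' exceed the observed one). The odds ratio is the sample cross-product
#' ratio `ad/bc` (`Inf` or `NaN` flagged for degenerate cells). A table with
#' a zero margin admits only itself, so `p = 1` and the odds ratio is
#' undefined.
#'
#' @param m 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = outcome yes/no).
#' @return List with `odds_ratio`, `p`, and `degenerate` (TRUE when a
#'   margin is zero).
#' @export
fisher_exact_2x2 <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == 2L)) stop("fisher_exact_2x2 needs a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (sum(m) == 0) stop("table total must be positive")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(odds_ratio = NA_real_, p = 1, degenerate = TRUE))
  p <- stats::fisher.test(m)$p.value
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(odds_ratio = or, p = min(p, 1), degenerate = FALSE)
}

#' Pearson chi-squared test of independence
#'
#' No continuity correction. A warning is emitted when any expected count
#' is below 5.
#'
#' @param m r x c matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p` and the `expected` matrix.
#' @export
chi2_independence <- function(m) {
  m <- as.matrix(m)
  if (sum(m) == 0) stop("table total must be positive")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (any(res$expected < 5))
    warning("chi-squared approximation may be inaccurate: expected count < 5")
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Structural category by regulatory class enrichment table
#'
#' Cross-tabulates structural-difference flags against divergence calls:
#' the percentage of genes in each regulatory class carrying each flag,
#' and, per flag, a Fisher test of each class against a comparison class,
#' with BH-FDR adjustment across all tests. Unclassified genes are
#' excluded; a class with no genes yields `NA` percentages.
#'
#' @param flags Data frame with `gene_id` and logical `AFE`, `TSS`, `INT`,
#'   `ALE`, `APA` columns.
#' @param calls Data frame with `gene_id` and `label` (e.g. from
#'   [classify_cohort()]).
#' @param comparison `"conserved"`: each divergent class is tested against
#'   the conserved class; `"cis_vs_trans"`: cis against trans only.
#' @return List with `percent` (flags x classes matrix of percentages),
#'   `n_genes` (named class sizes) and `tests` (data frame: `flag`,
#'   `class`, `reference`, `odds_ratio`, `p`, `p_adj`).
#' @export
category_class_table <- function(flags, calls,
                                 comparison = c("conserved", "cis_vs_trans")) {
  comparison <- match.arg(comparison)
  merged <- merge(flags, calls[, c("gene_id", "label")], by = "gene_id")
  merged <- merged[merged$label %in% divergence_classes, , drop = FALSE]
  classes <- divergence_classes
  n_genes <- vapply(classes, function(cl) sum(merged$label == cl), 0L)

  percent <- sapply(classes, function(cl) {
    sub <- merged[merged$label == cl, structure_flag_names, drop = FALSE]
    if (nrow(sub) == 0L) rep(NA_real_, 5L) else 100 * colMeans(sub)
  })
  rownames(percent) <- structure_flag_names

  pairs <- if (comparison == "conserved")
    data.frame(class = c("cis", "trans", "cis_trans"), ref = "conserved",
               stringsAsFactors = FALSE)
  else data.frame(class = "cis", ref = "trans", stringsAsFactors = FALSE)

  tests <- do.call(rbind, lapply(structure_flag_names, function(fl) {
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      cl <- pairs$class[k]; ref <- pairs$ref[k]
      a <- merged[merged$label == cl, fl]
      b <- merged[merged$label == ref, fl]
      if (length(a) == 0L || length(b) == 0L)
        return(data.frame(flag = fl, class = cl, reference = ref,
                          odds_ratio = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE))
      ft <- fisher_exact_2x2(matrix(c(sum(a), sum(!a), sum(b), sum(!b)),
                                    nrow = 2L, byrow = TRUE))
      data.frame(flag = fl, class = cl, reference = ref,
                 odds_ratio = ft$odds_ratio, p = ft$p,
                 stringsAsFactors = FALSE)
    }))
  }))
  tests$p_adj <- NA_real_
  ok <- !is.na(tests$p)
  tests$p_adj[ok] <- bh_fdr(tests$p[ok])
  list(percent = percent, n_genes = n_genes, tests = tests)
}

#' Excess of internal-splicing-only divergence
#'
#' Tests whether the INT category occurs without any other structural
#' change more often than expected under independence, via the 2x2 table of
#' INT (yes/no) against any-other-flag (yes/no).
#'
#' @param flags Data frame with logical `AFE`, `TSS`, `INT`, `ALE`, `APA`
#'   columns.
#' @return List with `observed` (INT-only count), `expected` (under
#'   independence), `table`, `statistic` and `p`.
#' @export
int_alone_excess <- function(flags) {
  flags <- as.data.frame(flags)
  if (nrow(flags) == 0L) stop("int_alone_excess needs at least one classified pair")
  int <- flags$INT
  other <- rowSums(flags[, setdiff(structure_flag_names, "INT"), drop = FALSE]) > 0
  tab <- matrix(c(sum(int & !other), sum(int & other),
                  sum(!int & !other), sum(!int & other)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(INT = c("yes", "no"),
                                other_flag = c("no", "yes")))
  res <- chi2_independence(tab)
  list(observed = tab["yes", "no"],
       expected = unname(res$expected["yes", "no"]),
       table = tab, statistic = res$statistic, p = res$p)
}
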