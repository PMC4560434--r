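# Fixture builders shared across test files. All data is generated in code.

std_samples <- function(n_f0 = 6L, n_f1 = 12L) {
  data.frame(
    sample_id = c(sprintf("F0_BL6_r%d", seq_len(n_f0)),
                  sprintf("F0_CAST_r%d", seq_len(n_f0)),
                  sprintf("F1_r%d_BL6", seq_len(n_f1)),
                  sprintf("F1_r%d_CAST", seq_len(n_f1))),
    group = c(rep("F0_BL6", n_f0), rep("F0_CAST", n_f0), rep("F1", 2L * n_f1)),
    allele = c(rep(NA_character_, 2L * n_f0),
               rep("BL6", n_f1), rep("CAST", n_f1)),
    replicate = c(seq_len(n_f0), seq_len(n_f0), seq_len(n_f1), seq_len(n_f1)),
    stringsAsFactors = FALSE)
}

# Table from an estimates matrix in std_samples column order; constant se
# and per-transcript unique reads unless given.
toy_table <- function(est, se = 0.01, unique_reads = NULL,
                      n_f0 = 6L, n_f1 = 12L) {
  samples <- std_samples(n_f0, n_f1)
  stopifnot(ncol(est) == nrow(samples))
  colnames(est) <- samples$sample_id
  if (is.null(rownames(est)))
    rownames(est) <- sprintf("t%d", seq_len(nrow(est)))
  se_m <- matrix(se, nrow(est), ncol(est), dimnames = dimnames(est))
  if (is.null(unique_reads))
    unique_reads <- setNames(rep(100L, nrow(est)), rownames(est))
  expression_table(est, se_m, unique_reads, samples)
}

# Two-isoform table with isoform proportions set per group: p_bl6/p_cast
# for the F0 strains, p_f1b/p_f1c for the two F1 alleles; total expression
# `total` in F0 columns and total/2 per allele column.
proportion_table <- function(p_bl6, p_cast, p_f1b = p_bl6, p_f1c = p_cast,
                             total = 100, se = 0.01, n_f0 = 6L, n_f1 = 12L) {
  p <- c(rep(p_bl6, n_f0), rep(p_cast, n_f0), rep(p_f1b, n_f1), rep(p_f1c, n_f1))
  tot <- c(rep(total, 2L * n_f0), rep(total / 2, 2L * n_f1))
  est <- rbind(t1 = tot * p, t2 = tot * (1 - p))
  toy_table(est, se = se, n_f0 = n_f0, n_f1 = n_f1)
}

all_feasible_flag_sets <- function() {
  first <- list(character(), "AFE", "TSS")
  last <- list(character(), "ALE", "APA")
  int <- list(character(), "INT")
  out <- list()
  for (f in first) for (l in last) for (i in int) {
    fl <- c(f, l, i)
    out[[length(out) + 1L]] <- fl
  }
  out
}
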