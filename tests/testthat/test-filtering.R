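test_that("expression threshold is the minimum mean among well-read transcripts", {
  est <- matrix(rep(c(5.0, 0.5, 2.0), each = 36L), nrow = 3L, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), NULL))
  tab <- toy_table(est, unique_reads = c(A = 12L, B = 3L, C = 10L))
  expect_equal(compute_expression_threshold(tab), 2.0)

  # all transcripts qualify: global minimum mean
  tab2 <- toy_table(est, unique_reads = c(A = 12L, B = 13L, C = 10L))
  expect_equal(compute_expression_threshold(tab2), 0.5)

  # single qualifying transcript
  est3 <- matrix(7.3, 1L, 36L, dimnames = list("A", NULL))
  tab3 <- toy_table(est3, unique_reads = c(A = 10L))
  expect_equal(compute_expression_threshold(tab3), 7.3)

  tab4 <- toy_table(est, unique_reads = c(A = 2L, B = 3L, C = 1L))
  expect_error(compute_expression_threshold(tab4), "lower")
})

test_that("expressed calling follows the >=4-replicate, either-F0-group rule", {
  t <- 1.0
  base <- matrix(2, 1L, 36L, dimnames = list("tA", NULL))
  expect_equal(call_expressed(toy_table(base), t), "tA")

  # 6/6 BL6 above t but only 3/12 F1 libraries above t: not expressed
  m <- base
  m[1L, 13:36] <- 0.2                       # all F1 allele columns low
  m[1L, c(13, 14, 15)] <- 0.9               # 3 F1 libraries: 0.9 + 0.2 > 1
  expect_length(call_expressed(toy_table(m), t), 0L)

  # 3/6 in each F0 group (pooled 6 but neither group reaches 4): not expressed
  m <- base
  m[1L, c(4, 5, 6)] <- 0.5                  # BL6 drops to 3/6
  m[1L, c(10, 11, 12)] <- 0.5               # CAST drops to 3/6
  expect_length(call_expressed(toy_table(m), t), 0L)

  # 4/6 in one F0 group and 4/12 F1 libraries: expressed
  m <- matrix(0.2, 1L, 36L, dimnames = list("tA", NULL))
  m[1L, 1:4] <- 2                           # 4 BL6 replicates
  m[1L, 13:16] <- 0.9                       # 4 F1 libraries: 0.9 + 0.2 > 1
  expect_equal(call_expressed(toy_table(m), t), "tA")

  # strictly greater than t: values equal to t never count
  m <- matrix(1.0, 1L, 36L, dimnames = list("tA", NULL))
  expect_length(call_expressed(toy_table(m), t = 1.0), 0L)

  # the F1 leg counts the 12 libraries (allele sums), not 24 allele columns
  m <- matrix(2, 1L, 36L, dimnames = list("tA", NULL))
  m[1L, 25:36] <- 0                         # CAST allele 0; libraries still 2 > 1
  expect_equal(call_expressed(toy_table(m), t), "tA")
})

test_that("raising the threshold never adds expressed transcripts", {
  set.seed(19)
  ds <- simulate_dataset(simulation_config(n_genes = 25L, seed = 19L))
  thresholds <- c(0.1, 0.5, 2, 5, 20)
  sets <- lapply(thresholds, function(t) call_expressed(ds$table, t))
  for (i in seq_along(sets)[-1L])
    expect_true(all(sets[[i]] %in% sets[[i - 1L]]))
})

test_that("analysis-set selection keeps exactly-two overlapping variant-bearing genes", {
  set.seed(57)
  g1 <- simulate_transcript_pair("INT", gene_id = "g1")            # 2 isoforms
  g2 <- simulate_transcript_pair("TSS", gene_id = "g2", offset = 10000)
  g2 <- gene_model("g2", g2$transcripts[1L])                       # 1 isoform
  g3p <- simulate_transcript_pair("APA", gene_id = "g3", offset = 20000)
  t3 <- g3p$transcripts[[1L]]
  extra <- transcript_model("g3.3", "g3", t3$chrom, t3$strand,
                            t3$exons[-2L, , drop = FALSE])
  g3 <- gene_model("g3", c(g3p$transcripts, list(extra)))          # 3 isoforms
  g4 <- simulate_transcript_pair("ALE", gene_id = "g4", offset = 30000) # no SNV
  g5 <- simulate_transcript_pair(gene_id = "g5", offset = 40000,
                                 overlap = FALSE)                  # disjoint pair
  genes <- list(g1 = g1, g2 = g2, g3 = g3, g4 = g4, g5 = g5)
  expressed <- unlist(lapply(genes, function(g)
    vapply(g$transcripts, `[[`, "", "transcript_id")), use.names = FALSE)
  variants <- c(g1 = 1L, g2 = 5L, g3 = 2L, g4 = 0L, g5 = 2L)

  sel <- select_analysis_set(genes, expressed, variants)
  expect_equal(sel$gene_ids, "g1")
  expect_equal(sel$funnel$count, c(5L, 3L, 2L, 1L))
  expect_equal(sel$n_nonoverlapping, 1L)
  # funnel monotonicity
  expect_true(all(diff(sel$funnel$count) <= 0))
})

test_that("mcse subsetting anchors the threshold at 1- or 5-read transcripts", {
  est <- matrix(5, 4L, 36L, dimnames = list(c("A", "B", "C", "D"), NULL))
  mk <- function(se_by_tr, ur) {
    tab <- toy_table(est, unique_reads = ur)
    tab$se <- matrix(rep(se_by_tr, 36L), 4L, 36L, dimnames = dimnames(est))
    tab
  }
  # all se equal: everything retained
  tab <- mk(rep(0.2, 4L), c(A = 1L, B = 3L, C = 10L, D = 50L))
  expect_setequal(mcse_subset(tab, "t1"), c("A", "B", "C", "D"))

  # anchor (1 read) has the largest se: everything retained under t1
  tab <- mk(c(0.9, 0.5, 0.2, 0.1), c(A = 1L, B = 3L, C = 10L, D = 50L))
  expect_setequal(mcse_subset(tab, "t1"), c("A", "B", "C", "D"))

  # t5 anchor se 0.3: transcripts above it are dropped
  tab <- mk(c(0.9, 0.3, 0.2, 0.1), c(A = 1L, B = 5L, C = 10L, D = 50L))
  expect_setequal(mcse_subset(tab, "t5"), c("B", "C", "D"))

  # no transcript at the anchor count: nearest count is used, with warning
  tab <- mk(c(0.9, 0.3, 0.2, 0.1), c(A = 2L, B = 30L, C = 10L, D = 50L))
  expect_warning(keep <- mcse_subset(tab, "t1"), "nearest")
  expect_setequal(keep, c("A", "B", "C", "D"))
})
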