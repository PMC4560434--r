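test_that("simulate_transcript_pair realises requested flag sets and rejects infeasible ones", {
  set.seed(101)
  g <- simulate_transcript_pair(character())
  d <- classify_pair(g$transcripts[[1L]], g$transcripts[[2L]])
  expect_equal(sum(flags_of(d)), 0L)

  g <- simulate_transcript_pair("AFE")
  d <- classify_pair(g$transcripts[[1L]], g$transcripts[[2L]])
  expect_true(d$AFE)
  expect_equal(d$n_changes, 1L)

  expect_error(simulate_transcript_pair(c("AFE", "TSS")), "mutually exclusive")
  expect_error(simulate_transcript_pair(c("ALE", "APA")), "mutually exclusive")
  expect_error(simulate_transcript_pair("XYZ"), "unknown flag")

  # generator/classifier closure across all feasible sets, several draws each
  for (fl in all_feasible_flag_sets()) {
    if (length(fl) == 0L) next
    for (k in 1:5) {
      g <- simulate_transcript_pair(fl)
      d <- classify_pair(g$transcripts[[1L]], g$transcripts[[2L]])
      got <- names(flags_of(d))[flags_of(d)]
      expect_setequal(got, fl)
    }
  }
})

test_that("non-overlap fixtures are exonically disjoint", {
  set.seed(5)
  g <- simulate_transcript_pair(overlap = FALSE)
  expect_false(transcripts_overlap(g$transcripts[[1L]], g$transcripts[[2L]]))
})

test_that("simulate_cohort is deterministic, respects class_probs, and handles n = 0", {
  empty <- simulate_cohort(simulation_config(n_genes = 0L))
  expect_length(empty$genes, 0L)
  expect_equal(nrow(empty$truth), 0L)

  cfg <- simulation_config(n_genes = 30L, seed = 77L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$genes, function(g)
    lapply(g$transcripts, `[[`, "exons")),
    lapply(b$genes, function(g) lapply(g$transcripts, `[[`, "exons")))

  all_cons <- simulate_cohort(simulation_config(
    n_genes = 20L, class_probs = c(1, 0, 0, 0), seed = 3L))
  tr <- all_cons$truth[all_cons$truth$role == "analysis", ]
  expect_true(all(tr$true_class == "conserved"))
  expect_true(all(tr$beta_f0 == 0 & tr$beta_f1 == 0))
  expect_true(all(all_cons$variants[tr$gene_id] >= 1L))
})

test_that("zero-noise expression realises the class-defined log-odds exactly", {
  spec0 <- divergence_model_spec(epsilon = 0)
  for (cls in c("conserved", "cis", "trans")) {
    probs <- setNames(as.numeric(divergence_classes == cls), divergence_classes)
    cfg <- simulation_config(n_genes = 4L, class_probs = probs,
                             effect_size = 2, noise_sd = 0, seed = 11L)
    ds <- simulate_dataset(cfg)
    tr <- ds$truth[ds$truth$role == "analysis", ]
    for (i in seq_len(nrow(tr))) {
      gid <- tr$gene_id[i]
      s <- gene_deltas(ds$table, paste0(gid, c(".1", ".2")), spec0, gene_id = gid)
      expect_equal(s$d1, tr$beta_f0[i], tolerance = 1e-9)
      expect_equal(s$d2, tr$beta_f1[i], tolerance = 1e-9)
    }
    if (cls == "conserved") {
      # isoform proportion identical in every column
      gid <- tr$gene_id[1L]
      p <- isoform_proportion(ds$table$estimates[paste0(gid, ".1"), ],
                              ds$table$estimates[paste0(gid, ".2"), ])
      expect_equal(max(p) - min(p), 0, tolerance = 1e-12)
    }
  }
})

test_that("empirical log-odds differences converge to the planted effects", {
  # many replicates: group means should sit within 3 standard errors of beta
  cfg <- simulation_config(n_genes = 6L, n_f0_reps = 200L, n_f1_reps = 200L,
                           noise_sd = 0.2, seed = 13L)
  ds <- simulate_dataset(cfg)
  tr <- ds$truth[ds$truth$role == "analysis", ]
  se_d1 <- cfg$noise_sd * sqrt(2 / 200)
  se_d2 <- cfg$noise_sd * sqrt(2 / 200)
  spec0 <- divergence_model_spec(epsilon = 1e-9)
  for (i in seq_len(nrow(tr))) {
    s <- gene_deltas(ds$table, paste0(tr$gene_id[i], c(".1", ".2")), spec0,
                     gene_id = tr$gene_id[i])
    expect_lt(abs(s$d1 - tr$beta_f0[i]), 3 * se_d1)
    expect_lt(abs(s$d2 - tr$beta_f1[i]), 3 * se_d2)
  }
})

test_that("structural ground truth matches the classifier on cohort genes", {
  ds <- simulate_cohort(simulation_config(n_genes = 40L, seed = 23L))
  tr <- ds$truth[ds$truth$role == "analysis", ]
  for (i in seq_len(nrow(tr))) {
    g <- ds$genes[[tr$gene_id[i]]]
    d <- classify_pair(g$transcripts[[1L]], g$transcripts[[2L]])
    expect_equal(unname(flags_of(d)),
                 unname(unlist(tr[i, c("AFE", "TSS", "INT", "ALE", "APA")])))
  }
})

test_that("in-silico F1 columns halve the F0 columns and degrade gracefully with noise", {
  ds <- simulate_dataset(simulation_config(n_genes = 100L, seed = 31L))
  exact <- make_insilico_f1(ds$table, "F0_BL6_r1", "F0_CAST_r1", noise_scale = 0)
  expect_equal(2 * exact$bl6_allele, exact$truth_bl6)
  expect_equal(2 * exact$cast_allele, exact$truth_cast)

  set.seed(1)
  noisy <- make_insilico_f1(ds$table, "F0_BL6_r1", "F0_CAST_r1", noise_scale = 1)
  mild <- make_insilico_f1(ds$table, "F0_BL6_r1", "F0_CAST_r1", noise_scale = 0.2)
  r_noisy <- cor(log1p(2 * noisy$bl6_allele), log1p(noisy$truth_bl6))
  r_mild <- cor(log1p(2 * mild$bl6_allele), log1p(mild$truth_bl6))
  expect_gt(r_mild, r_noisy)
  expect_gt(r_noisy, 0.9)

  expect_error(make_insilico_f1(ds$table, "F0_CAST_r1", "F0_CAST_r1"),
               "not an F0_BL6 column")
})
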