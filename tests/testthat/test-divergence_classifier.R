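test_that("isoform log-odds and proportions behave at the edges", {
  expect_equal(isoform_logodds(5, 5), 0)
  expect_equal(isoform_logodds(10, 0, epsilon = 0.01), log(10.01 / 0.01),
               tolerance = 1e-12)
  expect_equal(isoform_proportion(3, 1), 0.75)
  expect_true(is.na(isoform_logodds(0, 0, epsilon = 0.01)))
  expect_true(is.na(isoform_proportion(0, 0)))
})

test_that("gene_deltas recovers exact effects from deterministic tables", {
  spec0 <- divergence_model_spec(epsilon = 0)
  # cis-like: strain and allelic proportions both shifted (logit 0.5 vs logit shifted)
  p_hi <- plogis(1); p_lo <- plogis(-1)   # log-odds difference 2
  cis_tab <- proportion_table(p_hi, p_lo, p_f1b = p_hi, p_f1c = p_lo)
  s <- gene_deltas(cis_tab, c("t1", "t2"), spec0, gene_id = "g")
  expect_equal(s$d1, 2, tolerance = 1e-9)
  expect_equal(s$d2, 2, tolerance = 1e-9)

  trans_tab <- proportion_table(p_hi, p_lo, p_f1b = 0.5, p_f1c = 0.5)
  s <- gene_deltas(trans_tab, c("t1", "t2"), spec0)
  expect_equal(s$d1, 2, tolerance = 1e-9)
  expect_equal(s$d2, 0, tolerance = 1e-9)

  flat <- proportion_table(0.5, 0.5)
  s <- gene_deltas(flat, c("t1", "t2"), spec0)
  expect_equal(abs(s$d1) + abs(s$d2), 0, tolerance = 1e-9)
  expect_true(s$v1 > 0 && s$v2 > 0)

  expect_error(gene_deltas(flat, c("t1", "missing"), spec0), "absent")
})

test_that("model posteriors match the frozen oracle-checked values", {
  spec <- divergence_model_spec(sigma0 = 2)
  # values cross-checked against numerical integration of the effect priors
  p <- classify_divergence(list(gene_id = "g", d1 = 0, d2 = 0,
                                v1 = 0.1, v2 = 0.1), spec)
  expect_equal(p$p_conserved, 0.774, tolerance = 0.01)
  expect_equal(p$label, "conserved")

  p <- classify_divergence(list(gene_id = "g", d1 = 2, d2 = 2,
                                v1 = 0.01, v2 = 0.01), spec)
  expect_equal(p$p_cis, 0.959, tolerance = 0.01)
  expect_equal(p$label, "cis")

  p <- classify_divergence(list(gene_id = "g", d1 = 2, d2 = 0,
                                v1 = 0.01, v2 = 0.01), spec)
  expect_equal(p$p_trans, 0.952, tolerance = 0.01)
  expect_equal(p$label, "trans")
})

test_that("the call rule and posterior bookkeeping are sound", {
  spec <- divergence_model_spec(sigma0 = 2)
  # diffuse data: no model above 0.5 -> unclassified
  p <- classify_divergence(list(gene_id = "g", d1 = 0, d2 = 0,
                                v1 = 2, v2 = 2), spec)
  expect_equal(p$label, "unclassified")
  expect_lt(max(p$p_conserved, p$p_cis, p$p_trans, p$p_cis_trans), 0.5)

  set.seed(8)
  for (i in 1:25) {
    s <- list(gene_id = "g", d1 = rnorm(1, 0, 2), d2 = rnorm(1, 0, 2),
              v1 = runif(1, 0.01, 1), v2 = runif(1, 0.01, 1))
    p <- classify_divergence(s, spec)
    posts <- c(p$p_conserved, p$p_cis, p$p_trans, p$p_cis_trans)
    expect_equal(sum(posts), 1, tolerance = 1e-9)
    expect_gte(p$posterior_margin, 0)
    # swapping the isoforms flips the signs and leaves posteriors unchanged
    sw <- classify_divergence(list(gene_id = "g", d1 = -s$d1, d2 = -s$d2,
                                   v1 = s$v1, v2 = s$v2), spec)
    expect_equal(c(sw$p_conserved, sw$p_cis, sw$p_trans, sw$p_cis_trans),
                 posts, tolerance = 1e-12)
  }
})

test_that("posterior(cis) is non-decreasing in |d1| along the diagonal", {
  spec <- divergence_model_spec(sigma0 = 2)
  d <- seq(0, 4, by = 0.1)
  pc <- vapply(d, function(x)
    classify_divergence(list(gene_id = "g", d1 = x, d2 = x,
                             v1 = 0.05, v2 = 0.05), spec)$p_cis, 0)
  expect_true(all(diff(pc) >= -1e-12))
})

test_that("major-isoform classification extends the scheme to k >= 3 genes", {
  est <- rbind(t1 = rep(c(60, 60, 30, 30), c(6, 6, 12, 12)),
               t2 = rep(c(25, 25, 12.5, 12.5), c(6, 6, 12, 12)),
               t3 = rep(c(15, 15, 7.5, 7.5), c(6, 6, 12, 12)))
  tab <- toy_table(est)
  out <- classify_major_isoform(tab, c("t1", "t2", "t3"), gene_id = "g")
  expect_equal(out$label, "conserved")
  expect_equal(out$major_isoform, "t1")

  expect_error(classify_major_isoform(tab, c("t1", "t2")), ">= 3 isoforms")

  # tie for the major isoform: lowest transcript id wins, with a warning
  est_tie <- est; est_tie["t2", ] <- est_tie["t1", ]
  tab_tie <- toy_table(est_tie)
  expect_warning(out <- classify_major_isoform(tab_tie, c("t1", "t2", "t3"),
                                               gene_id = "g"), "tie")
  expect_equal(out$major_isoform, "t1")

  # generator's three-isoform mode with a strong cis effect is recovered
  cfg <- simulation_config(n_genes = 0L, n_spike_multi = 6L,
                           class_probs = c(0, 1, 0, 0), effect_size = 2,
                           noise_sd = 0.05, seed = 29L)
  ds <- simulate_dataset(cfg)
  multi <- ds$truth[ds$truth$role == "spike_multi", ]
  for (gid in multi$gene_id) {
    out <- classify_major_isoform(ds$table, paste0(gid, c(".1", ".2", ".3")),
                                  gene_id = gid)
    expect_equal(out$label, "cis")
  }
})

test_that("allelic fractions reproduce designed allele-specific patterns", {
  bal <- proportion_table(0.5, 0.5)
  af <- allelic_fractions(bal, c("t1", "t2"))
  expect_equal(unname(af$S_mean), 0.5, tolerance = 1e-12)
  expect_equal(unname(af$U_mean), 0.5, tolerance = 1e-12)

  # BL6 allele expresses both isoforms; CAST allele only isoform 1:
  # U for isoform 2 is exactly 1
  est <- rbind(t1 = c(rep(50, 12), rep(30, 12), rep(30, 12)),
               t2 = c(rep(50, 12), rep(20, 12), rep(0, 12)))
  tab <- toy_table(est)
  af <- allelic_fractions(tab, c("t1", "t2"), u_transcript = "t2")
  expect_equal(unname(af$U_mean), 1.0)
  expect_equal(unname(af$S_mean), 50 / 80, tolerance = 1e-12)

  expect_equal(rank_correlation(1:10, 1:10), 1)
})

test_that("classify_cohort returns an aligned per-gene table", {
  ds <- simulate_dataset(simulation_config(n_genes = 12L, seed = 43L))
  pairs <- setNames(lapply(ds$truth$gene_id[ds$truth$role == "analysis"],
                           function(g) paste0(g, c(".1", ".2"))),
                    ds$truth$gene_id[ds$truth$role == "analysis"])
  calls <- classify_cohort(ds$table, pairs)
  expect_equal(calls$gene_id, names(pairs))
  expect_true(all(calls$label %in% c("conserved", "cis", "trans",
                                     "cis_trans", "unclassified")))
  empty <- classify_cohort(ds$table, list())
  expect_equal(nrow(empty), 0L)
})
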