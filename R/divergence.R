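#' Model specification for divergence classification
#'
#' Settings for the four-model Bayesian comparison of isoform-usage
#' divergence. Effects live on the natural-log-odds scale of the two
#' isoforms' expression ratio.
#'
#' @param sigma0 Prior SD of a free (cis or trans) effect on the log-odds
#'   scale. The default 2.0 is weakly informative: one prior SD corresponds
#'   to an ~7.4-fold change in the isoform ratio.
#' @param model_prior Prior probability of each of the four models;
#'   must sum to 1. Default: uniform 0.25.
#' @param call_threshold Posterior probability a model must exceed to be
#'   called; with the default 0.5 a model is selected only when it is more
#'   likely than all the other models put together.
#' @param epsilon Pseudocount added to both isoforms' expression before
#'   taking log-odds; `NULL` (default) resolves to 1e-3 times the median
#'   positive expression estimate of the table in use.
#' @return A list of class `divergence_model_spec`.
#' @export
divergence_model_spec <- function(sigma0 = 2.0,
                                  model_prior = c(conserved = 0.25, cis = 0.25,
                                                  trans = 0.25, cis_trans = 0.25),
                                  call_threshold = 0.5,
                                  epsilon = NULL) {
  stopifnot(sigma0 > 0, call_threshold > 0, call_threshold <= 1)
  if (abs(sum(model_prior) - 1) > 1e-9) stop("model_prior must sum to 1")
  if (length(model_prior) != 4L) stop("model_prior needs 4 entries")
  names(model_prior) <- divergence_classes
  structure(list(sigma0 = sigma0, model_prior = model_prior,
                 call_threshold = call_threshold, epsilon = epsilon),
            class = "divergence_model_spec")
}

divergence_classes <- c("conserved", "cis", "trans", "cis_trans")

resolve_epsilon <- function(spec, table) {
  if (!is.null(spec$epsilon)) return(spec$epsilon)
  pos <- table$estimates[table$estimates > 0]
  if (length(pos) == 0L) return(1e-3)
  1e-3 * stats::median(pos)
}

#' Isoform log-odds and proportion
#'
#' `isoform_logodds` is the natural log of the (pseudocounted) ratio of the
#' two isoforms' expression; `isoform_proportion` is isoform 1's share of
#' the gene total. A sample where both isoforms are 0 is undefined and
#' returns `NA`.
#'
#' @param e1,e2 Non-negative expression estimates (vectorised).
#' @param epsilon Pseudocount, >= 0.
#' @return Numeric vector.
#' @export
isoform_logodds <- function(e1, e2, epsilon = 0) {
  stopifnot(all(e1 >= 0, na.rm = TRUE), all(e2 >= 0, na.rm = TRUE), epsilon >= 0)
  out <- log(e1 + epsilon) - log(e2 + epsilon)
  out[e1 == 0 & e2 == 0] <- NA_real_
  out
}

#' @rdname isoform_logodds
#' @export
isoform_proportion <- function(e1, e2) {
  out <- e1 / (e1 + e2)
  out[e1 == 0 & e2 == 0] <- NA_real_
  out
}

#' Per-gene strain and allelic log-odds differences
#'
#' Summarises one two-isoform gene as two statistics: `d1`, the F0 strain
#' difference in isoform log-odds (mean over BL6 replicates minus mean over
#' CAST replicates), and `d2`, the F1 allelic difference (mean over F1
#' replicates of the within-replicate BL6-allele minus CAST-allele
#' log-odds). Their variances `v1`, `v2` combine the replicate scatter of
#' the group means with the per-estimate standard errors, propagated onto
#' the log-odds scale by the delta method, so poorly measured transcripts
#' are down-weighted downstream.
#'
#' @param table An [expression_table()].
#' @param transcripts Character vector of the gene's two transcript ids
#'   (isoform 1, isoform 2).
#' @param spec A [divergence_model_spec()].
#' @param gene_id Optional gene id recorded in the output.
#' @return A one-row data frame (`isoform_pair_summary`) with columns
#'   `gene_id`, `d1`, `v1`, `d2`, `v2`, `n_f0_bl6`, `n_f0_cast`, `n_f1`.
#' @export
gene_deltas <- function(table, transcripts, spec = divergence_model_spec(),
                        gene_id = NA_character_) {
  stopifnot(inherits(table, "expression_table"), length(transcripts) == 2L)
  if (!all(transcripts %in% rownames(table$estimates)))
    stop("transcript(s) absent from expression table: ",
         paste(setdiff(transcripts, rownames(table$estimates)), collapse = ", "))
  eps <- resolve_epsilon(spec, table)
  e1 <- table$estimates[transcripts[1L], ]
  e2 <- table$estimates[transcripts[2L], ]
  s1 <- table$se[transcripts[1L], ]
  s2 <- table$se[transcripts[2L], ]
  lo <- isoform_logodds(e1, e2, eps)
  # delta-method se of the log-odds from the two estimate se's
  selo2 <- (s1 / (e1 + eps))^2 + (s2 / (e2 + eps))^2

  group_stats <- function(ids) {
    x <- lo[ids]; w <- selo2[ids]
    ok <- !is.na(x)
    if (sum(ok) < 2L)
      stop("fewer than 2 usable replicates in a group for gene ", gene_id)
    list(mean = mean(x[ok]),
         var_of_mean = (stats::var(x[ok]) + mean(w[ok])) / sum(ok),
         n = sum(ok))
  }
  bl6 <- group_stats(sample_ids(table, "F0_BL6"))
  cast <- group_stats(sample_ids(table, "F0_CAST"))
  d1 <- bl6$mean - cast$mean
  v1 <- bl6$var_of_mean + cast$var_of_mean

  reps <- f1_replicates(table)
  s <- table$samples
  bcol <- s$sample_id[match(paste(reps, "BL6"), paste(s$replicate, s$allele))]
  ccol <- s$sample_id[match(paste(reps, "CAST"), paste(s$replicate, s$allele))]
  diffs <- lo[bcol] - lo[ccol]
  dse2 <- selo2[bcol] + selo2[ccol]
  ok <- !is.na(diffs)
  if (sum(ok) < 2L)
    stop("fewer than 2 usable F1 replicates for gene ", gene_id)
  d2 <- mean(diffs[ok])
  v2 <- (stats::var(diffs[ok]) + mean(dse2[ok])) / sum(ok)

  if (!(v1 > 0) || !(v2 > 0))
    stop("non-positive variance for gene ", gene_id,
         " (constant data with zero standard errors)")
  out <- data.frame(gene_id = gene_id, d1 = d1, v1 = v1, d2 = d2, v2 = v2,
                    n_f0_bl6 = bl6$n, n_f0_cast = cast$n, n_f1 = sum(ok),
                    stringsAsFactors = FALSE)
  class(out) <- c("isoform_pair_summary", "data.frame")
  out
}

#' Log marginal likelihoods of the four divergence models
#'
#' Given the pair summary `(d1, v1, d2, v2)`, evaluates the closed-form
#' marginal likelihood of each model under zero-centred normal effect priors
#' with SD `sigma0`:
#' \describe{
#'   \item{conserved}{no effect: `d1 ~ N(0, v1)`, `d2 ~ N(0, v2)` independently.}
#'   \item{cis}{one shared effect on strain and allelic differences:
#'     `(d1, d2)` bivariate normal, mean 0, covariance
#'     `[[v1+sigma0^2, sigma0^2], [sigma0^2, v2+sigma0^2]]`.}
#'   \item{trans}{an effect on the strain difference only:
#'     `d1 ~ N(0, v1+sigma0^2)`, `d2 ~ N(0, v2)`.}
#'   \item{cis_trans}{independent effects on both:
#'     `d1 ~ N(0, v1+sigma0^2)`, `d2 ~ N(0, v2+sigma0^2)`.}
#' }
#'
#' @param s One-row summary from [gene_deltas()] (or any list with `d1`,
#'   `v1`, `d2`, `v2`).
#' @param spec A [divergence_model_spec()].
#' @return Named numeric vector of four log marginal likelihoods.
#' @export
model_log_marginals <- function(s, spec = divergence_model_spec()) {
  d1 <- s$d1; v1 <- s$v1; d2 <- s$d2; v2 <- s$v2
  if (!(v1 > 0) || !(v2 > 0)) stop("variances must be positive")
  s02 <- spec$sigma0^2
  conserved <- stats::dnorm(d1, 0, sqrt(v1), log = TRUE) +
    stats::dnorm(d2, 0, sqrt(v2), log = TRUE)
  # bivariate normal log density at (d1, d2), mean 0
  a <- v1 + s02; b <- s02; c_ <- v2 + s02
  det <- a * c_ - b^2
  quad <- (c_ * d1^2 - 2 * b * d1 * d2 + a * d2^2) / det
  cis <- -log(2 * pi) - 0.5 * log(det) - 0.5 * quad
  trans <- stats::dnorm(d1, 0, sqrt(v1 + s02), log = TRUE) +
    stats::dnorm(d2, 0, sqrt(v2), log = TRUE)
  cis_trans <- stats::dnorm(d1, 0, sqrt(v1 + s02), log = TRUE) +
    stats::dnorm(d2, 0, sqrt(v2 + s02), log = TRUE)
  c(conserved = conserved, cis = cis, trans = trans, cis_trans = cis_trans)
}

#' Classify a gene's regulatory divergence
#'
#' Converts the four model marginals into posterior probabilities under the
#' model prior and applies the call rule: a model is selected only if its
#' posterior exceeds `call_threshold` (default 0.5, i.e. the model must be
#' more likely than all others combined); otherwise the gene is left
#' `unclassified`. The posterior margin (best minus second-best) is
#' recorded.
#'
#' @param s One-row summary from [gene_deltas()].
#' @param spec A [divergence_model_spec()].
#' @return A one-row data frame (`divergence_call`) with `gene_id`, the four
#'   posteriors (`p_conserved`, `p_cis`, `p_trans`, `p_cis_trans`), `label`
#'   and `posterior_margin`.
#' @export
classify_divergence <- function(s, spec = divergence_model_spec()) {
  lm <- model_log_marginals(s, spec)
  lp <- lm + log(spec$model_prior)
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  ord <- order(post, decreasing = TRUE)
  label <- if (post[ord[1L]] > spec$call_threshold)
    divergence_classes[ord[1L]] else "unclassified"
  out <- data.frame(
    gene_id = if (!is.null(s$gene_id)) s$gene_id else NA_character_,
    p_conserved = post[["conserved"]], p_cis = post[["cis"]],
    p_trans = post[["trans"]], p_cis_trans = post[["cis_trans"]],
    label = label,
    posterior_margin = post[ord[1L]] - post[ord[2L]],
    stringsAsFactors = FALSE)
  class(out) <- c("divergence_call", "data.frame")
  out
}

#' Classify divergence for every gene of an analysis set
#'
#' Convenience wrapper running [gene_deltas()] and [classify_divergence()]
#' over a named list of two-transcript genes.
#'
#' @param table An [expression_table()].
#' @param gene_transcripts Named list: gene_id -> character(2) transcript ids.
#' @param spec A [divergence_model_spec()].
#' @return Data frame with one row per gene: the pair summary columns plus
#'   posteriors, `label` and `posterior_margin`.
#' @export
classify_cohort <- function(table, gene_transcripts,
                            spec = divergence_model_spec()) {
  rows <- lapply(names(gene_transcripts), function(g) {
    s <- gene_deltas(table, gene_transcripts[[g]], spec, gene_id = g)
    cbind(s, classify_divergence(s, spec)[, -1L])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), d1 = numeric(), v1 = numeric(),
                      d2 = numeric(), v2 = numeric(), n_f0_bl6 = integer(),
                      n_f0_cast = integer(), n_f1 = integer(),
                      p_conserved = numeric(), p_cis = numeric(),
                      p_trans = numeric(), p_cis_trans = numeric(),
                      label = character(), posterior_margin = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Major-isoform divergence classification for multi-isoform genes
#'
#' For a gene expressing three or more isoforms, takes the major isoform
#' (highest mean expression across the F0 samples; ties broken by lowest
#' transcript id, with a warning) against the sum of all remaining isoforms,
#' then applies the standard two-statistic classification.
#'
#' @param table An [expression_table()].
#' @param transcripts Character vector (length >= 3) of the gene's expressed
#'   transcript ids.
#' @param spec A [divergence_model_spec()].
#' @param gene_id Optional gene id recorded in the output.
#' @return As [classify_divergence()], with an extra `major_isoform` column.
#' @export
classify_major_isoform <- function(table, transcripts,
                                   spec = divergence_model_spec(),
                                   gene_id = NA_character_) {
  if (length(transcripts) < 3L)
    stop("classify_major_isoform needs >= 3 isoforms; ",
         "use classify_divergence via gene_deltas for two-isoform genes")
  f0 <- c(sample_ids(table, "F0_BL6"), sample_ids(table, "F0_CAST"))
  means <- rowMeans(table$estimates[transcripts, f0, drop = FALSE])
  top <- which(means == max(means))
  if (length(top) > 1L) {
    warning("tie for major isoform of gene ", gene_id,
            "; lowest transcript id wins")
    top <- top[order(transcripts[top])[1L]]
  }
  major <- transcripts[top]
  rest <- setdiff(transcripts, major)

  # build a two-row table: major vs pooled rest (se's add in quadrature)
  est <- rbind(table$estimates[major, , drop = FALSE],
               colSums(table$estimates[rest, , drop = FALSE]))
  se <- rbind(table$se[major, , drop = FALSE],
              sqrt(colSums(table$se[rest, , drop = FALSE]^2)))
  rownames(est) <- rownames(se) <- c(major, ".rest")
  ur <- stats::setNames(c(table$unique_reads[major],
                          sum(table$unique_reads[rest])), c(major, ".rest"))
  sub <- expression_table(est, se, ur, table$samples)
  if (is.null(spec$epsilon)) spec$epsilon <- resolve_epsilon(spec, table)
  s <- gene_deltas(sub, c(major, ".rest"), spec, gene_id = gene_id)
  out <- classify_divergence(s, spec)
  out$major_isoform <- major
  out
}

#' Allelic fractions in the F1 (pyrosequencing-analog summaries)
#'
#' Computes, per F1 replicate, the BL6-allele share of total gene expression
#' (`S`, over both isoforms) and the BL6-allele share of one designated
#' isoform (`U`). These are the in-silico analogues of a two-SNV allelic
#' expression assay: one SNV shared by both isoforms (S), one private to a
#' single isoform (U). Replicates with a zero denominator are `NA`.
#'
#' @param table An [expression_table()].
#' @param transcripts Character vector of the gene's two transcript ids.
#' @param u_transcript Which transcript U is computed for (default the
#'   second).
#' @return List with vectors `S`, `U` (one entry per F1 replicate) and their
#'   means `S_mean`, `U_mean`.
#' @export
allelic_fractions <- function(table, transcripts,
                              u_transcript = transcripts[2L]) {
  stopifnot(length(transcripts) == 2L, u_transcript %in% transcripts)
  reps <- f1_replicates(table)
  if (length(reps) == 0L) stop("no F1 allele columns in table")
  s <- table$samples
  bcol <- s$sample_id[match(paste(reps, "BL6"), paste(s$replicate, s$allele))]
  ccol <- s$sample_id[match(paste(reps, "CAST"), paste(s$replicate, s$allele))]
  eb <- table$estimates[transcripts, bcol, drop = FALSE]
  ec <- table$estimates[transcripts, ccol, drop = FALSE]
  S <- colSums(eb) / (colSums(eb) + colSums(ec))
  U <- eb[u_transcript, ] / (eb[u_transcript, ] + ec[u_transcript, ])
  S[!is.finite(S)] <- NA_real_
  U[!is.finite(U)] <- NA_real_
  names(S) <- names(U) <- paste0("rep", reps)
  list(S = S, U = U, S_mean = mean(S, na.rm = TRUE),
       U_mean = mean(U, na.rm = TRUE))
}

#' Rank correlation between two per-gene measurement vectors
#'
#' Spearman correlation utility for comparing two allelic-fraction readouts
#' across genes (e.g. an expression-derived fraction against an independent
#' assay).
#'
#' @param x,y Numeric vectors of equal length; pairs with `NA` are dropped.
#' @return Spearman's rho.
#' @export
rank_correlation <- function(x, y) {
  stats::cor(x, y, method = "spearman", use = "complete.obs")
}
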