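#' Simulation configuration
#'
#' Parameters of the synthetic F1-hybrid cohort generator. Defaults follow
#' the study design the pipeline targets: 6 biological replicates per F0
#' strain, 12 F1 hybrids measured per allele, an effect size of 1.5 on the
#' natural-log-odds scale of isoform usage, and per-replicate log-odds noise
#' of 0.2. Structural-difference probabilities are set so that the marginal
#' frequency of each category matches the relative shares observed for
#' two-isoform genes in mouse liver (ALE 15%, TSS 18%, AFE 20%, APA 22%,
#' INT 25% of roughly 2.2 changes per divergent pair).
#'
#' @param n_genes Number of analysis genes (two overlapping isoforms,
#'   variant-bearing).
#' @param class_probs Probabilities of the four regulatory classes
#'   `conserved`, `cis`, `trans`, `cis_trans`; must sum to 1.
#' @param effect_size Magnitude of each regulatory effect on the
#'   natural-log-odds scale (sign drawn at random per gene).
#' @param noise_sd Per-replicate log-odds noise SD.
#' @param n_f0_reps,n_f1_reps Replicates per F0 strain / F1 libraries.
#' @param se_floor,se_scale Expression-dependent uncertainty model: a
#'   transcript estimate at level `e` carries standard error
#'   `se_floor + se_scale / sqrt(e)`, so uncertainty shrinks with
#'   expression.
#' @param structure_probs Named marginal probabilities of `AFE`, `TSS`,
#'   `ALE`, `APA`, `INT` differences per isoform pair. AFE/TSS and ALE/APA
#'   are mutually exclusive: within each terminal end one category (or
#'   neither) is drawn, so `AFE + TSS <= 1` and `ALE + APA <= 1` are
#'   required. Pairs drawing no difference at all are redrawn (two
#'   structurally identical transcripts are not two isoforms).
#' @param dge_prob Probability a gene is independently flagged as having
#'   divergent gene expression (a true-null companion annotation for
#'   independence testing).
#' @param n_spike_single,n_spike_multi,n_spike_lowexp,n_spike_nosnv,n_spike_nonoverlap
#'   Spike-in genes that exercise the selection funnel: single-transcript
#'   genes, three-isoform genes, two-isoform genes whose minor isoform is
#'   below the expression threshold, variant-free genes, and genes whose two
#'   isoforms do not overlap exonically. Spike-ins (other than the
#'   three-isoform class) carry no variants unless needed by their role.
#' @param total_meanlog,total_sdlog,total_floor Per-gene total expression is
#'   `total_floor + Lognormal(total_meanlog, total_sdlog)` (arbitrary
#'   consistent units).
#' @param mu_range Baseline isoform log-odds is drawn uniformly from this
#'   interval, keeping both isoforms comfortably expressed.
#' @param balance_classes If `TRUE`, analysis genes receive exactly
#'   `round(n_genes * class_probs)` genes per class (shuffled) instead of
#'   independent draws — the balanced-cohort design used for parameter
#'   recovery.
#' @param anchor_expression Mean expression of the dedicated low-expression,
#'   well-read anchor transcript that pins the expression threshold `t`.
#' @param low_expression Expression of the sub-threshold isoform of
#'   `lowexp` spike-ins.
#' @param seed Integer seed; `simulate_cohort()` seeds the RNG with it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 400L,
                              class_probs = c(conserved = 0.25, cis = 0.25,
                                              trans = 0.25, cis_trans = 0.25),
                              effect_size = 1.5,
                              noise_sd = 0.2,
                              n_f0_reps = 6L,
                              n_f1_reps = 12L,
                              se_floor = 0.05,
                              se_scale = 1.0,
                              structure_probs = c(AFE = 0.43, TSS = 0.39,
                                                  ALE = 0.33, APA = 0.48,
                                                  INT = 0.54),
                              dge_prob = 0.37,
                              balance_classes = FALSE,
                              n_spike_single = 0L,
                              n_spike_multi = 0L,
                              n_spike_lowexp = 0L,
                              n_spike_nosnv = 0L,
                              n_spike_nonoverlap = 0L,
                              total_meanlog = log(60),
                              total_sdlog = 1.0,
                              total_floor = 20,
                              mu_range = c(-1.2, 1.2),
                              anchor_expression = 0.5,
                              low_expression = 0.05,
                              seed = 1L) {
  if (abs(sum(class_probs) - 1) > 1e-9) stop("class_probs must sum to 1")
  if (length(class_probs) != 4L) stop("class_probs needs 4 entries")
  names(class_probs) <- divergence_classes
  stopifnot(noise_sd >= 0, effect_size >= 0, n_genes >= 0,
            n_f0_reps >= 1, n_f1_reps >= 1, se_floor >= 0, se_scale >= 0)
  p <- structure_probs[c("AFE", "TSS", "ALE", "APA", "INT")]
  if (anyNA(p)) stop("structure_probs needs AFE, TSS, ALE, APA, INT entries")
  if (p[["AFE"]] + p[["TSS"]] > 1)
    stop("AFE and TSS are mutually exclusive: their probabilities cannot sum above 1")
  if (p[["ALE"]] + p[["APA"]] > 1)
    stop("ALE and APA are mutually exclusive: their probabilities cannot sum above 1")
  structure(list(n_genes = as.integer(n_genes), class_probs = class_probs,
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_f0_reps = as.integer(n_f0_reps),
                 n_f1_reps = as.integer(n_f1_reps),
                 se_floor = se_floor, se_scale = se_scale,
                 structure_probs = p, dge_prob = dge_prob,
                 balance_classes = isTRUE(balance_classes),
                 n_spike_single = as.integer(n_spike_single),
                 n_spike_multi = as.integer(n_spike_multi),
                 n_spike_lowexp = as.integer(n_spike_lowexp),
                 n_spike_nosnv = as.integer(n_spike_nosnv),
                 n_spike_nonoverlap = as.integer(n_spike_nonoverlap),
                 total_meanlog = total_meanlog, total_sdlog = total_sdlog,
                 total_floor = total_floor, mu_range = mu_range,
                 anchor_expression = anchor_expression,
                 low_expression = low_expression,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate one two-isoform gene with requested structural differences
#'
#' Builds a gene model whose two transcripts, when run through
#' [classify_pair()], carry exactly the requested structural-difference
#' flags. The pair is constructed on the plus strand in transcription order
#' and mirrored for minus-strand genes. Draws come from the current RNG
#' state (seed upstream with `set.seed()`).
#'
#' @param flags Character subset of `c("AFE","TSS","INT","ALE","APA")`.
#'   AFE+TSS or ALE+APA together is infeasible and raises an error.
#' @param gene_id Gene id (transcripts are `<gene_id>.1` / `<gene_id>.2`).
#' @param chrom Chromosome name.
#' @param strand `"+"`, `"-"`, or `NA` to draw at random.
#' @param offset Genomic offset added to all coordinates.
#' @param overlap If `FALSE`, emit a non-overlapping fixture instead: the
#'   second transcript lies wholly downstream of the first (`flags`
#'   ignored).
#' @return A [gene_model()] with two transcripts.
#' @export
simulate_transcript_pair <- function(flags = character(),
                                     gene_id = "g1", chrom = "chrS",
                                     strand = NA, offset = 0,
                                     overlap = TRUE) {
  flags <- as.character(flags)
  bad <- setdiff(flags, structure_flag_names)
  if (length(bad)) stop("unknown flag(s): ", paste(bad, collapse = ", "))
  if (all(c("AFE", "TSS") %in% flags))
    stop("infeasible flag set: AFE and TSS are mutually exclusive")
  if (all(c("ALE", "APA") %in% flags))
    stop("infeasible flag set: ALE and APA are mutually exclusive")
  if (is.na(strand)) strand <- sample(c("+", "-"), 1L)

  # template transcript in transcription order on a local + strand
  n_ex <- sample(4:5, 1L)
  lens <- sample(80:200, n_ex, replace = TRUE)
  introns <- sample(150:500, n_ex - 1L, replace = TRUE)
  s0 <- sample(500:700, 1L)
  starts <- s0 + cumsum(c(0, lens[-n_ex] + introns))
  ex1 <- cbind(starts, starts + lens)
  ex2 <- ex1

  if (!overlap) {
    gap <- sample(300:600, 1L)
    ex2 <- ex2 + (max(ex1[, 2L]) - min(ex1[, 1L])) + gap
  } else {
    if ("TSS" %in% flags) {
      delta <- sample(10:60, 1L)
      if (stats::runif(1) < 0.5) ex2[1L, 1L] <- ex2[1L, 1L] - delta  # extend 5'
      else ex2[1L, 1L] <- min(ex2[1L, 1L] + delta, ex2[1L, 2L] - 10L)
    }
    if ("AFE" %in% flags) {
      gap <- sample(50:150, 1L)
      len <- sample(80:200, 1L)
      new_first <- c(ex1[1L, 1L] - gap - len, ex1[1L, 1L] - gap)
      ex2 <- rbind(new_first, ex2[-1L, , drop = FALSE])
    }
    if ("APA" %in% flags) {
      delta <- sample(10:60, 1L)
      nr <- nrow(ex2)
      if (stats::runif(1) < 0.5) ex2[nr, 2L] <- ex2[nr, 2L] + delta  # extend 3'
      else ex2[nr, 2L] <- max(ex2[nr, 2L] - delta, ex2[nr, 1L] + 10L)
    }
    if ("ALE" %in% flags) {
      gap <- sample(50:150, 1L)
      len <- sample(80:200, 1L)
      nr <- nrow(ex2)
      last1 <- ex1[nrow(ex1), ]
      new_last <- c(last1[2L] + gap, last1[2L] + gap + len)
      ex2 <- rbind(ex2[-nr, , drop = FALSE], new_last)
    }
    if ("INT" %in% flags) {
      # operate on an exon internal to both transcripts (template rows 2..n-1)
      j <- sample(2:(n_ex - 1L), 1L)
      j2 <- which(ex2[, 1L] == ex1[j, 1L] & ex2[, 2L] == ex1[j, 2L])[1L]
      if (stats::runif(1) < 0.5) {
        ex2 <- ex2[-j2, , drop = FALSE]                 # cassette exon skipped
      } else {
        delta <- sample(5:40, 1L)
        if (stats::runif(1) < 0.5)
          ex2[j2, 1L] <- ex2[j2, 1L] - delta            # shifted acceptor
        else
          ex2[j2, 2L] <- ex2[j2, 2L] + delta            # shifted donor
      }
    }
  }

  # mirror to the minus strand: x -> L - x preserves the flag set when the
  # strand label flips with the coordinates
  if (strand == "-") {
    L <- max(ex1[, 2L], ex2[, 2L]) + sample(100:300, 1L)
    ex1 <- cbind(L - ex1[, 2L], L - ex1[, 1L])
    ex2 <- cbind(L - ex2[, 2L], L - ex2[, 1L])
  }
  shift <- offset - min(ex1[, 1L], ex2[, 1L])
  t1 <- transcript_model(paste0(gene_id, ".1"), gene_id, chrom, strand,
                         ex1 + shift)
  t2 <- transcript_model(paste0(gene_id, ".2"), gene_id, chrom, strand,
                         ex2 + shift)
  if (overlap) {
    got <- classify_pair(t1, t2)
    want <- stats::setNames(structure_flag_names %in% flags,
                            structure_flag_names)
    if (!all(unlist(got[structure_flag_names]) == want))
      stop("internal error: generated pair for {",
           paste(flags, collapse = ","), "} classified as {",
           paste(structure_flag_names[unlist(got[structure_flag_names])],
                 collapse = ","), "}")
  }
  gene_model(gene_id, list(t1, t2))
}

draw_structure_flags <- function(p) {
  repeat {
    first <- sample(c("AFE", "TSS", "none"), 1L,
                    prob = c(p[["AFE"]], p[["TSS"]],
                             1 - p[["AFE"]] - p[["TSS"]]))
    last <- sample(c("ALE", "APA", "none"), 1L,
                   prob = c(p[["ALE"]], p[["APA"]],
                            1 - p[["ALE"]] - p[["APA"]]))
    flags <- c(first[first != "none"], last[last != "none"],
               if (stats::runif(1) < p[["INT"]]) "INT")
    if (length(flags)) return(flags)
  }
}

#' Simulate a cohort of gene models with known ground truth
#'
#' Generates `n_genes` analysis genes (two overlapping isoforms, at least
#' one variant, a regulatory class drawn from `class_probs` with log-odds
#' effects of magnitude `effect_size`) plus the configured spike-in genes
#' that exercise the selection funnel, and a dedicated threshold-anchor
#' transcript. Seeds the RNG from `config$seed`, so all outputs are a pure
#' function of the configuration.
#'
#' @param config A [simulation_config()].
#' @return List with `genes` (named list of [gene_model()]), `truth` (data
#'   frame: `gene_id`, `role`, `true_class`, `beta_f0`, `beta_f1`,
#'   structural flags, `dge_flag`, `n_transcripts`, `funnel_fate`),
#'   `variants` (named counts) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  roles <- c(rep("analysis", config$n_genes),
             rep("spike_single", config$n_spike_single),
             rep("spike_multi", config$n_spike_multi),
             rep("spike_lowexp", config$n_spike_lowexp),
             rep("spike_nosnv", config$n_spike_nosnv),
             rep("spike_nonoverlap", config$n_spike_nonoverlap))
  # the threshold-anchor transcript accompanies any non-empty cohort
  if (length(roles)) roles <- c(roles, "anchor")
  n <- length(roles)
  if (n == 0L) {
    return(list(genes = structure(list(), names = character()),
                truth = data.frame(gene_id = character(), role = character(),
                                   true_class = character(), beta_f0 = numeric(),
                                   beta_f1 = numeric(), AFE = logical(),
                                   TSS = logical(), INT = logical(),
                                   ALE = logical(), APA = logical(),
                                   dge_flag = logical(),
                                   n_transcripts = integer(),
                                   funnel_fate = character(),
                                   stringsAsFactors = FALSE),
                variants = stats::setNames(integer(), character()),
                config = config))
  }
  ids <- sprintf("g%04d", seq_len(n))
  genes <- vector("list", n)
  names(genes) <- ids
  truth <- data.frame(gene_id = ids, role = roles,
                      true_class = NA_character_, beta_f0 = 0, beta_f1 = 0,
                      AFE = FALSE, TSS = FALSE, INT = FALSE, ALE = FALSE,
                      APA = FALSE, dge_flag = FALSE, n_transcripts = 2L,
                      funnel_fate = "analysis", stringsAsFactors = FALSE)
  variants <- stats::setNames(integer(n), ids)
  offset <- 0

  balanced <- NULL
  if (config$balance_classes && config$n_genes > 0L) {
    counts <- diff(round(cumsum(c(0, config$class_probs)) * config$n_genes))
    balanced <- sample(rep(divergence_classes, times = counts))
  }
  i_analysis <- 0L

  for (i in seq_len(n)) {
    gid <- ids[i]
    role <- roles[i]
    if (role %in% c("analysis", "spike_multi", "spike_nosnv", "spike_lowexp")) {
      flags <- draw_structure_flags(config$structure_probs)
      g <- simulate_transcript_pair(flags, gid, offset = offset)
      cls <- if (!is.null(balanced) && role == "analysis") {
        i_analysis <- i_analysis + 1L
        balanced[i_analysis]
      } else sample(divergence_classes, 1L, prob = config$class_probs)
      b <- config$effect_size * sample(c(-1, 1), 1L)
      betas <- switch(cls,
        conserved = c(0, 0),
        cis = c(b, b),
        trans = c(b, 0),
        cis_trans = {
          tr <- config$effect_size * sample(c(-1, 1), 1L)
          c(b + tr, b)
        })
      truth[i, structure_flag_names] <- as.list(structure_flag_names %in% flags)
      truth$true_class[i] <- cls
      truth$beta_f0[i] <- betas[1L]
      truth$beta_f1[i] <- betas[2L]
      truth$dge_flag[i] <- stats::runif(1) < config$dge_prob
      variants[i] <- if (role == "spike_nosnv") 0L else 1L + stats::rpois(1L, 2)
      if (role == "spike_multi") {
        # add a third isoform: the template with one internal exon skipped
        t1 <- g$transcripts[[1L]]
        drop_row <- if (t1$strand == "+") 2L else nrow(t1$exons) - 1L
        t3 <- transcript_model(paste0(gid, ".3"), gid, t1$chrom, t1$strand,
                               t1$exons[-drop_row, , drop = FALSE])
        g <- gene_model(gid, c(g$transcripts, list(t3)))
        truth$n_transcripts[i] <- 3L
        truth$funnel_fate[i] <- "fails_two_isoforms"
      } else if (role == "spike_nosnv") {
        truth$funnel_fate[i] <- "fails_variant"
      } else if (role == "spike_lowexp") {
        truth$funnel_fate[i] <- "fails_expression"
      }
    } else if (role == "spike_nonoverlap") {
      g <- simulate_transcript_pair(gene_id = gid, offset = offset,
                                    overlap = FALSE)
      variants[i] <- 1L + stats::rpois(1L, 2)
      truth$funnel_fate[i] <- "fails_overlap"
    } else {  # spike_single, anchor
      g0 <- simulate_transcript_pair(gene_id = gid, offset = offset)
      g <- gene_model(gid, g0$transcripts[1L])
      variants[i] <- if (role == "anchor") 0L else 1L + stats::rpois(1L, 2)
      truth$n_transcripts[i] <- 1L
      truth$funnel_fate[i] <- "fails_two_isoforms"
    }
    genes[[gid]] <- g
    offset <- offset + diff(range(gene_span(g))) + sample(2000:5000, 1L)
  }
  list(genes = genes, truth = truth, variants = variants, config = config)
}

se_model <- function(e, config) config$se_floor + config$se_scale / sqrt(pmax(e, 1e-8))

#' Simulate allele-specific expression for a cohort
#'
#' Realises the generative model: each gene draws a baseline isoform
#' log-odds `mu` (uniform on `config$mu_range`) and a total expression level
#' (shifted lognormal). F0 BL6 replicate log-odds are
#' `Normal(mu + beta_f0/2, noise_sd^2)`, F0 CAST replicates
#' `Normal(mu - beta_f0/2, noise_sd^2)`; within each F1 replicate the BL6
#' allele draws `Normal(mu + beta_f1/2, noise_sd^2)` and the CAST allele
#' `Normal(mu - beta_f1/2, noise_sd^2)`, each allele carrying half the gene
#' total. Standard errors follow `se_floor + se_scale/sqrt(expression)` and
#' unique-read counts are proportional to mean expression (with a
#' per-transcript mappability factor). Uses the current RNG state;
#' [simulate_dataset()] gives seeded end-to-end generation.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param truth Ground-truth data frame from [simulate_cohort()].
#' @param config The [simulation_config()].
#' @return An [expression_table()].
#' @export
simulate_expression <- function(genes, truth, config) {
  samples <- data.frame(
    sample_id = c(sprintf("F0_BL6_r%d", seq_len(config$n_f0_reps)),
                  sprintf("F0_CAST_r%d", seq_len(config$n_f0_reps)),
                  sprintf("F1_r%d_BL6", seq_len(config$n_f1_reps)),
                  sprintf("F1_r%d_CAST", seq_len(config$n_f1_reps))),
    group = c(rep("F0_BL6", config$n_f0_reps),
              rep("F0_CAST", config$n_f0_reps),
              rep("F1", 2L * config$n_f1_reps)),
    allele = c(rep(NA_character_, 2L * config$n_f0_reps),
               rep("BL6", config$n_f1_reps), rep("CAST", config$n_f1_reps)),
    replicate = c(seq_len(config$n_f0_reps), seq_len(config$n_f0_reps),
                  seq_len(config$n_f1_reps), seq_len(config$n_f1_reps)),
    stringsAsFactors = FALSE)
  ncol_total <- nrow(samples)
  bl6_idx <- which(samples$group == "F0_BL6")
  cast_idx <- which(samples$group == "F0_CAST")
  f1b_idx <- which(samples$group == "F1" & samples$allele == "BL6")
  f1c_idx <- which(samples$group == "F1" & samples$allele == "CAST")

  rows <- list()
  for (i in seq_len(nrow(truth))) {
    gid <- truth$gene_id[i]
    role <- truth$role[i]
    trs <- vapply(genes[[gid]]$transcripts, `[[`, "", "transcript_id")
    if (role == "anchor") {
      rows[[gid]] <- matrix(config$anchor_expression, nrow = 1L,
                            ncol = ncol_total, dimnames = list(trs, NULL))
      next
    }
    total <- config$total_floor +
      stats::rlnorm(1L, config$total_meanlog, config$total_sdlog)
    if (role == "spike_single") {
      lo_noise <- stats::rnorm(ncol_total, 0, config$noise_sd)
      vals <- total * exp(lo_noise)
      vals[c(f1b_idx, f1c_idx)] <- vals[c(f1b_idx, f1c_idx)] / 2
      rows[[gid]] <- matrix(vals, nrow = 1L, dimnames = list(trs, NULL))
      next
    }
    mu <- stats::runif(1L, config$mu_range[1L], config$mu_range[2L])
    bf0 <- truth$beta_f0[i]
    bf1 <- truth$beta_f1[i]
    lo <- numeric(ncol_total)
    lo[bl6_idx] <- stats::rnorm(length(bl6_idx), mu + bf0 / 2, config$noise_sd)
    lo[cast_idx] <- stats::rnorm(length(cast_idx), mu - bf0 / 2, config$noise_sd)
    lo[f1b_idx] <- stats::rnorm(length(f1b_idx), mu + bf1 / 2, config$noise_sd)
    lo[f1c_idx] <- stats::rnorm(length(f1c_idx), mu - bf1 / 2, config$noise_sd)
    p <- stats::plogis(lo)
    tot <- rep(total, ncol_total)
    tot[c(f1b_idx, f1c_idx)] <- total / 2
    if (role == "spike_lowexp") {
      # minor isoform pinned below the expression threshold everywhere;
      # isoform 1 carries the full (allele) total
      e1 <- tot
      e2 <- rep(config$low_expression, ncol_total)
      e2[c(f1b_idx, f1c_idx)] <- config$low_expression / 2
      m <- rbind(e1, e2)
    } else if (truth$n_transcripts[i] == 3L) {
      # major isoform vs rest: isoform 1 takes share p, the rest is split
      # equally between isoforms 2 and 3
      m <- rbind(tot * p, tot * (1 - p) / 2, tot * (1 - p) / 2)
    } else {
      m <- rbind(tot * p, tot * (1 - p))
    }
    dimnames(m) <- list(trs, NULL)
    rows[[gid]] <- m
  }
  if (length(rows) == 0L) {
    est <- matrix(numeric(), nrow = 0L, ncol = ncol_total,
                  dimnames = list(character(), samples$sample_id))
    return(expression_table(est, est, stats::setNames(integer(), character()),
                            samples))
  }
  est <- do.call(rbind, rows)
  colnames(est) <- samples$sample_id
  se <- se_model(est, config)
  dimnames(se) <- dimnames(est)

  mean_e <- rowMeans(est)
  read_factor <- stats::runif(nrow(est), 5, 20)
  ur <- as.integer(round(read_factor * mean_e))
  anchor_tr <- unlist(lapply(truth$gene_id[truth$role == "anchor"], function(g)
    vapply(genes[[g]]$transcripts, `[[`, "", "transcript_id")))
  names(ur) <- rownames(est)
  ur[anchor_tr] <- 10L
  lowexp_minor <- unlist(lapply(truth$gene_id[truth$role == "spike_lowexp"],
                                function(g) paste0(g, ".2")))
  ur[lowexp_minor] <- 1L
  expression_table(est, se, ur, samples)
}

#' Simulate a full dataset (cohort + expression) from one seed
#'
#' @param config A [simulation_config()].
#' @return The [simulate_cohort()] list with an extra `table` element
#'   (the [expression_table()]).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  cohort <- simulate_cohort(config)
  cohort$table <- simulate_expression(cohort$genes, cohort$truth, config)
  cohort
}

#' Build a pseudo-F1 replicate from two F0 columns (in-silico F1)
#'
#' Emulates constructing an artificial F1 library by combining one BL6 and
#' one CAST F0 sample: the pseudo-F1's BL6-allele expectation is half the F0
#' BL6 column and its CAST-allele expectation half the F0 CAST column, with
#' resampling noise following the expression-dependent uncertainty model.
#' The originating F0 values are returned as truth for correlation checks.
#'
#' @param table An [expression_table()].
#' @param bl6_sample,cast_sample Sample ids of one F0 BL6 and one F0 CAST
#'   column of `table`.
#' @param noise_scale Multiplier on the uncertainty model's noise; 0 gives
#'   the exact half-columns.
#' @param se_floor,se_scale Uncertainty model parameters (defaults as in
#'   [simulation_config()]).
#' @return List with `bl6_allele`, `cast_allele` (pseudo-F1 estimates),
#'   `truth_bl6`, `truth_cast` (the originating F0 columns) and the allele
#'   standard errors `bl6_se`, `cast_se`.
#' @export
make_insilico_f1 <- function(table, bl6_sample, cast_sample,
                             noise_scale = 1, se_floor = 0.05, se_scale = 1.0) {
  stopifnot(inherits(table, "expression_table"))
  s <- table$samples
  if (!bl6_sample %in% s$sample_id[s$group == "F0_BL6"])
    stop(bl6_sample, " is not an F0_BL6 column of the table")
  if (!cast_sample %in% s$sample_id[s$group == "F0_CAST"])
    stop(cast_sample, " is not an F0_CAST column of the table")
  cfg <- list(se_floor = se_floor, se_scale = se_scale)
  half_b <- table$estimates[, bl6_sample] / 2
  half_c <- table$estimates[, cast_sample] / 2
  se_b <- se_model(half_b, cfg)
  se_c <- se_model(half_c, cfg)
  n <- length(half_b)
  bl6 <- pmax(half_b + noise_scale * stats::rnorm(n, 0, se_b), 0)
  cast <- pmax(half_c + noise_scale * stats::rnorm(n, 0, se_c), 0)
  list(bl6_allele = bl6, cast_allele = cast,
       truth_bl6 = table$estimates[, bl6_sample],
       truth_cast = table$estimates[, cast_sample],
       bl6_se = se_b * noise_scale, cast_se = se_c * noise_scale)
}
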