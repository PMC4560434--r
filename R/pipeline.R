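#' Run configuration
#'
#' Bundles either a [simulation_config()] or paths to on-disk inputs with
#' the filter and model settings for one reproducible pipeline run.
#' Exactly one of `simulation` and `inputs` must be given.
#'
#' @param simulation A [simulation_config()], or `NULL` for input mode.
#' @param inputs List with paths `gtf`, `expression`, `meta`, `variants`
#'   and optionally `dge` (two-column TSV `gene_id`/`dge_flag`), or `NULL`
#'   for simulation mode.
#' @param filter A [filter_config()].
#' @param model A [divergence_model_spec()].
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing files.
#' @param seed Integer seed governing all randomness of the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulation = simulation_config(), inputs = NULL,
                       filter = filter_config(),
                       model = divergence_model_spec(),
                       out_dir = NULL, seed = 1L) {
  if (is.null(simulation) == is.null(inputs))
    stop("provide exactly one of simulation config or input paths")
  if (!is.null(inputs)) {
    need <- c("gtf", "expression", "meta", "variants")
    if (!all(need %in% names(inputs)))
      stop("inputs needs paths: ", paste(need, collapse = ", "))
  }
  structure(list(simulation = simulation, inputs = inputs, filter = filter,
                 model = model, out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full divergence-analysis pipeline
#'
#' Orchestrates simulate (or read) -> expression threshold -> expressed-
#' isoform calling -> two-isoform analysis-set selection -> divergence
#' classification -> structural classification -> combination and
#' enrichment statistics, and writes the stage outputs as TSV plus a JSON
#' run manifest. The whole run is deterministic given `cfg$seed`.
#'
#' @param cfg A [run_config()].
#' @return (Invisibly) a list with `genes`, `truth` (simulation mode),
#'   `variants`, `table`, `threshold`, `expressed`, `selection`, `calls`,
#'   `flags`, `combinations`, `enrichment`, `proportions` and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    sim$seed <- cfg$seed
    ds <- simulate_dataset(sim)
    genes <- ds$genes; truth <- ds$truth; variants <- ds$variants
    table <- ds$table
    dge <- stats::setNames(truth$dge_flag, truth$gene_id)
  } else {
    genes <- read_gtf(cfg$inputs$gtf)
    table <- read_expression_table(cfg$inputs$expression, cfg$inputs$meta)
    variants <- read_variants(cfg$inputs$variants, genes)
    truth <- NULL
    dge <- NULL
    if (!is.null(cfg$inputs$dge)) {
      dtab <- utils::read.delim(cfg$inputs$dge, stringsAsFactors = FALSE)
      dge <- stats::setNames(as.logical(dtab$dge_flag), dtab$gene_id)
    }
  }

  if (nrow(table$estimates) == 0L) {
    threshold <- NA_real_
    expressed <- character()
  } else {
    threshold <- compute_expression_threshold(table, cfg$filter)
    expressed <- call_expressed(table, threshold, cfg$filter)
  }
  selection <- select_analysis_set(genes, expressed, variants)

  calls <- withCallingHandlers(
    classify_cohort(table, selection$pairs, cfg$model),
    error = function(e)
      stop("divergence classification failed: ", conditionMessage(e)))

  flags <- do.call(rbind, lapply(selection$gene_ids, function(gid) {
    trs <- genes[[gid]]$transcripts
    ids <- vapply(trs, `[[`, "", "transcript_id")
    pair <- selection$pairs[[gid]]
    classify_pair(trs[[match(pair[1L], ids)]], trs[[match(pair[2L], ids)]])
  }))
  if (is.null(flags))
    flags <- structural_diff(character(), logical(), logical(), logical(),
                             logical(), logical(), logical())

  divergent <- calls$gene_id[calls$label %in% c("cis", "trans", "cis_trans")]
  div_flags <- flags[flags$gene_id %in% divergent, , drop = FALSE]
  combinations <- combination_matrix(div_flags)

  enrichment <- list(
    category_class = if (nrow(calls) && any(calls$label %in% divergence_classes))
      category_class_table(flags, calls) else NULL,
    int_alone = if (nrow(div_flags)) int_alone_excess(div_flags) else NULL,
    diu_dge = NULL)
  if (!is.null(dge) && nrow(calls) > 0L) {
    called <- calls[calls$label != "unclassified", , drop = FALSE]
    if (nrow(called) > 1L) {
      diu <- called$label %in% c("cis", "trans", "cis_trans")
      dg <- dge[called$gene_id]
      tab <- table(factor(diu, levels = c(FALSE, TRUE)),
                   factor(dg, levels = c(FALSE, TRUE)))
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
        enrichment$diu_dge <- chi2_independence(tab)
    }
  }

  proportions <- proportion_scatter_table(table, selection$pairs)

  manifest <- list(
    package = "isodiverge",
    version = as.character(utils::packageVersion("isodiverge")),
    seed = cfg$seed,
    mode = if (is.null(cfg$simulation)) "inputs" else "simulation",
    config = serialize_config(cfg),
    threshold = threshold,
    stage_counts = c(
      stats::setNames(selection$funnel$count, selection$funnel$stage),
      nonoverlapping = selection$n_nonoverlapping,
      expressed_transcripts = length(expressed),
      called = if (nrow(calls)) sum(calls$label != "unclassified") else 0L,
      divergent = length(divergent)))

  out <- list(genes = genes, truth = truth, variants = variants, table = table,
              threshold = threshold, expressed = expressed,
              selection = selection, calls = calls, flags = flags,
              combinations = combinations, enrichment = enrichment,
              proportions = proportions, manifest = manifest)
  if (!is.null(cfg$out_dir)) write_run_outputs(out, cfg$out_dir)
  invisible(out)
}

serialize_config <- function(cfg) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  list(filter = strip(cfg$filter), model = strip(cfg$model),
       simulation = if (!is.null(cfg$simulation)) strip(cfg$simulation),
       inputs = cfg$inputs)
}

write_run_outputs <- function(out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(d, name) utils::write.table(
    d, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(out$selection$funnel, "funnel.tsv")
  tsv(out$calls, "divergence_calls.tsv")
  tsv(as.data.frame(out$flags), "structural_flags.tsv")
  tsv(out$combinations$combinations, "combination_matrix.tsv")
  tsv(out$proportions, "proportions.tsv")
  if (!is.null(out$enrichment$category_class)) {
    pc <- out$enrichment$category_class$percent
    tsv(data.frame(flag = rownames(pc), pc, check.names = FALSE),
        "category_class_percent.tsv")
    tsv(out$enrichment$category_class$tests, "enrichment_tests.tsv")
  }
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' Per-gene F0 isoform proportions (scatter-table summary)
#'
#' For each two-isoform gene, the mean proportion of total gene expression
#' derived from isoform 1 in each F0 strain. Conserved genes lie near the
#' diagonal of `p_bl6` against `p_cast`.
#'
#' @param table An [expression_table()].
#' @param pairs Named list gene_id -> character(2) transcript ids.
#' @return Data frame with `gene_id`, `p_bl6`, `p_cast`.
#' @export
proportion_scatter_table <- function(table, pairs) {
  bl6 <- sample_ids(table, "F0_BL6")
  cast <- sample_ids(table, "F0_CAST")
  rows <- lapply(names(pairs), function(gid) {
    tr <- pairs[[gid]]
    e1 <- table$estimates[tr[1L], ]
    e2 <- table$estimates[tr[2L], ]
    p <- isoform_proportion(e1, e2)
    data.frame(gene_id = gid, p_bl6 = mean(p[bl6], na.rm = TRUE),
               p_cast = mean(p[cast], na.rm = TRUE), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), p_bl6 = numeric(),
                      p_cast = numeric(), stringsAsFactors = FALSE)
  out
}
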