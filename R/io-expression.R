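#' Expression table
#'
#' Transcript-by-sample expression estimates with per-estimate standard
#' errors (the role of MMSEQ-style Monte Carlo standard errors), a
#' per-transcript unique-read count, and sample metadata distinguishing F0
#' strain replicates from F1 per-allele measurements.
#'
#' @param estimates Numeric matrix, transcripts x samples, non-negative;
#'   rownames are transcript ids, colnames are sample ids.
#' @param se Numeric matrix of the same shape, finite, non-negative.
#' @param unique_reads Named non-negative integer vector, one per transcript.
#' @param samples Data frame with columns `sample_id`, `group` (one of
#'   `F0_BL6`, `F0_CAST`, `F1`), `allele` (`BL6`/`CAST` for F1 columns, `NA`
#'   otherwise) and `replicate` (integer). Each F1 replicate must appear as a
#'   paired BL6/CAST allele column.
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(estimates, se, unique_reads, samples) {
  stopifnot(is.matrix(estimates), is.matrix(se))
  if (!identical(dim(estimates), dim(se)))
    stop("estimates and se must have identical dimensions")
  if (any(estimates < 0)) stop("negative expression estimate")
  if (any(!is.finite(se)) || any(se < 0))
    stop("se must be finite and non-negative")
  if ((nrow(estimates) > 0L && is.null(rownames(estimates))) ||
      is.null(colnames(estimates)))
    stop("estimates must have transcript rownames and sample colnames")
  if (is.null(rownames(estimates))) rownames(estimates) <- character()
  if (!all(rownames(estimates) %in% names(unique_reads)))
    stop("unique_reads must be defined for every transcript row")
  unique_reads <- unique_reads[rownames(estimates)]
  if (any(unique_reads < 0)) stop("unique_reads must be non-negative")

  req <- c("sample_id", "group", "allele", "replicate")
  if (!all(req %in% names(samples)))
    stop("samples metadata needs columns: ", paste(req, collapse = ", "))
  samples <- samples[match(colnames(estimates), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id))
    stop("column in data absent from sample metadata: ",
         paste(setdiff(colnames(estimates), samples$sample_id), collapse = ", "))
  if (!all(samples$group %in% c("F0_BL6", "F0_CAST", "F1")))
    stop("group must be one of F0_BL6, F0_CAST, F1")
  is_f1 <- samples$group == "F1"
  if (any(is.na(samples$allele[is_f1])) ||
      !all(samples$allele[is_f1] %in% c("BL6", "CAST")))
    stop("F1 columns must carry allele BL6 or CAST")
  if (any(!is.na(samples$allele[!is_f1])))
    stop("allele must be NA for F0 columns")
  # every F1 replicate appears as a BL6/CAST pair
  f1 <- samples[is_f1, , drop = FALSE]
  if (nrow(f1)) {
    tab <- table(f1$replicate, f1$allele)
    if (!all(tab == 1L))
      stop("each F1 replicate must appear as exactly one BL6 and one CAST allele column")
  }
  structure(list(estimates = estimates, se = se,
                 unique_reads = unique_reads, samples = samples),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf(paste0("<expression_table> %d transcript(s) x %d sample column(s)",
                     " (%d F0_BL6, %d F0_CAST, %d F1 allele columns)\n"),
              nrow(x$estimates), ncol(x$estimates),
              sum(x$samples$group == "F0_BL6"),
              sum(x$samples$group == "F0_CAST"),
              sum(x$samples$group == "F1")))
  invisible(x)
}

#' @export
dim.expression_table <- function(x) dim(x$estimates)

sample_ids <- function(table, group, allele = NULL) {
  s <- table$samples
  keep <- s$group == group
  if (!is.null(allele)) keep <- keep & !is.na(s$allele) & s$allele == allele
  s$sample_id[keep]
}

f1_replicates <- function(table) sort(unique(table$samples$replicate[
  table$samples$group == "F1"]))

#' Read an expression table and its sample metadata from TSV files
#'
#' The data TSV has a `transcript_id` column, one pair of columns per sample
#' (`<sample_id>` with the estimate and `<sample_id>_se` with its standard
#' error) and a `unique_reads` column. The metadata TSV maps `sample_id` to
#' `group`, `allele` and `replicate`.
#'
#' @param path Data TSV path.
#' @param meta_path Metadata TSV path.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path, meta_path) {
  dat <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (!"transcript_id" %in% names(dat))
    stop("expression table lacks transcript_id column")
  if (!"unique_reads" %in% names(dat))
    stop("expression table lacks unique_reads column")
  meta$allele[!is.na(meta$allele) & meta$allele == ""] <- NA
  value_cols <- setdiff(names(dat), c("transcript_id", "unique_reads"))
  se_cols <- grep("_se$", value_cols, value = TRUE)
  est_cols <- setdiff(value_cols, se_cols)
  missing_se <- setdiff(paste0(est_cols, "_se"), se_cols)
  if (length(missing_se))
    stop("missing standard-error column(s): ", paste(missing_se, collapse = ", "),
         " (per-estimate uncertainty is required)")
  extra <- setdiff(est_cols, meta$sample_id)
  if (length(extra))
    stop("column in data absent from metadata: ", paste(extra, collapse = ", "))
  est <- as.matrix(dat[, est_cols, drop = FALSE])
  se <- as.matrix(dat[, paste0(est_cols, "_se"), drop = FALSE])
  colnames(se) <- est_cols
  rownames(est) <- rownames(se) <- dat$transcript_id
  if (any(est < 0)) stop("negative expression estimate in ", path)
  ur <- stats::setNames(as.integer(dat$unique_reads), dat$transcript_id)
  expression_table(est, se, ur, meta)
}

#' Write an expression table and its sample metadata to TSV files
#'
#' Inverse of [read_expression_table()].
#'
#' @param table An [expression_table()].
#' @param path,meta_path Output paths.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path, meta_path) {
  est <- table$estimates
  se <- table$se
  colnames(se) <- paste0(colnames(est), "_se")
  dat <- data.frame(transcript_id = rownames(est), est, se,
                    unique_reads = table$unique_reads,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(dat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
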