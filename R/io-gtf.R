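#' Read transcript models from a GTF file
#'
#' Parses exon features from a GTF file in the Ensembl attribute dialect
#' (`gene_id "..."; transcript_id "...";`). On-disk coordinates are 1-based
#' inclusive; returned [transcript_model()] exons are 0-based half-open.
#' Non-exon features and comment lines are ignored.
#'
#' @param path Path to a GTF file.
#' @return Named list of [gene_model()] objects (name = gene_id). Variant
#'   counts are initialised to 0; see [read_variants()].
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(structure(list(), names = character()))

  recs <- vector("list", length(idx))
  nrec <- 0L
  for (k in seq_along(idx)) {
    i <- idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    if (f[3L] != "exon") next
    start <- suppressWarnings(as.numeric(f[4L]))
    end   <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(start) || is.na(end) || start > end)
      stop("malformed GTF line ", i, ": invalid coordinates '", f[4L], "'-'",
           f[5L], "'")
    if (!f[7L] %in% c("+", "-"))
      stop("malformed GTF line ", i, ": strand must be + or -")
    gid <- gtf_attr(f[9L], "gene_id")
    tid <- gtf_attr(f[9L], "transcript_id")
    if (is.na(gid))
      stop("GTF line ", i, ": exon feature lacks gene_id attribute")
    if (is.na(tid))
      stop("GTF line ", i, ": exon feature lacks transcript_id attribute")
    nrec <- nrec + 1L
    recs[[nrec]] <- list(chrom = f[1L], start = start - 1, end = end,
                         strand = f[7L], gene_id = gid, transcript_id = tid)
  }
  recs <- recs[seq_len(nrec)]
  if (nrec == 0L) return(structure(list(), names = character()))

  df <- data.frame(
    chrom = vapply(recs, `[[`, "", "chrom"),
    start = vapply(recs, `[[`, 0, "start"),
    end = vapply(recs, `[[`, 0, "end"),
    strand = vapply(recs, `[[`, "", "strand"),
    gene_id = vapply(recs, `[[`, "", "gene_id"),
    transcript_id = vapply(recs, `[[`, "", "transcript_id"),
    stringsAsFactors = FALSE)

  genes <- list()
  for (gid in unique(df$gene_id)) {
    gdf <- df[df$gene_id == gid, , drop = FALSE]
    trs <- lapply(unique(gdf$transcript_id), function(tid) {
      tdf <- gdf[gdf$transcript_id == tid, , drop = FALSE]
      if (length(unique(tdf$strand)) != 1L || length(unique(tdf$chrom)) != 1L)
        stop("transcript ", tid, ": inconsistent strand/chrom across exons")
      transcript_model(tid, gid, tdf$chrom[1L], tdf$strand[1L],
                       cbind(tdf$start, tdf$end))
    })
    genes[[gid]] <- gene_model(gid, trs)
  }
  genes
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs,
                  regexec(paste0(key, '\\s+"([^"]*)"'), attrs))[[1L]]
  if (length(m) < 2L) NA_character_ else m[2L]
}

#' Write gene models to a GTF file
#'
#' Inverse of [read_gtf()]: emits one exon feature per exon, converting
#' internal 0-based half-open coordinates back to 1-based inclusive.
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  out <- character()
  for (g in genes) {
    for (tr in g$transcripts) {
      ex <- tr$exons
      out <- c(out, sprintf(
        '%s\tisodiverge\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
        tr$chrom, as.integer(ex[, 1L]) + 1L, as.integer(ex[, 2L]),
        tr$strand, tr$gene_id, tr$transcript_id))
    }
  }
  writeLines(out, path)
  invisible(path)
}
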