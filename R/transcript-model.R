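#' Transcript model
#'
#' A strand-aware exon-interval representation of one isoform. Exons are
#' stored in 0-based half-open genomic coordinates, sorted ascending by
#' start, non-overlapping. All functions in the package assume this
#' convention; conversion from the 1-based inclusive on-disk GTF convention
#' happens only in [read_gtf()] / [write_gtf()].
#'
#' @param transcript_id,gene_id Character scalars.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix of `(start, end)` intervals,
#'   0-based half-open.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L,
            is.character(chrom), length(chrom) == 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got: ", strand)
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("transcript ", transcript_id, " has no exons")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 1L] >= exons[, 2L]))
    stop("transcript ", transcript_id, ": exon with start >= end")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("transcript ", transcript_id, ": overlapping exons")
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons),
            class = "transcript_model")
}

#' Gene model
#'
#' A gene with its transcript models and the number of known strain-distinguishing
#' variants (SNVs or indels) overlapping its span.
#'
#' @param gene_id Character scalar.
#' @param transcripts List of [transcript_model()] objects sharing `gene_id`
#'   and chromosome.
#' @param snv_count Non-negative integer.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcripts, snv_count = 0L) {
  stopifnot(is.list(transcripts), length(transcripts) >= 1L)
  for (tr in transcripts) {
    if (!inherits(tr, "transcript_model"))
      stop("transcripts must be transcript_model objects")
    if (tr$gene_id != gene_id)
      stop("transcript ", tr$transcript_id, " has gene_id ", tr$gene_id,
           ", expected ", gene_id)
  }
  chroms <- unique(vapply(transcripts, `[[`, "", "chrom"))
  if (length(chroms) != 1L)
    stop("gene ", gene_id, ": transcripts on multiple chromosomes")
  if (snv_count < 0) stop("snv_count must be non-negative")
  structure(list(gene_id = gene_id, transcripts = transcripts,
                 chrom = chroms, snv_count = as.integer(snv_count)),
            class = "gene_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s%s, %d exon(s), span [%d, %d)\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), min(x$exons[, 1L]), max(x$exons[, 2L])))
  invisible(x)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s: %d transcript(s), %d variant(s)\n",
              x$gene_id, x$chrom, length(x$transcripts), x$snv_count))
  invisible(x)
}

gene_span <- function(gene) {
  starts <- vapply(gene$transcripts, function(t) min(t$exons[, 1L]), 0)
  ends   <- vapply(gene$transcripts, function(t) max(t$exons[, 2L]), 0)
  c(start = min(starts), end = max(ends))
}

#' Biological first and last exons of a transcript
#'
#' Strand-aware: on the plus strand the first exon is the one with the
#' smallest start, on the minus strand the one with the largest end.
#'
#' @param t A [transcript_model()].
#' @return List with numeric `first` and `last` intervals `(start, end)`.
#' @export
first_last_exons <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  n <- nrow(t$exons)
  if (t$strand == "+") {
    list(first = t$exons[1L, ], last = t$exons[n, ])
  } else {
    list(first = t$exons[n, ], last = t$exons[1L, ])
  }
}

# 5'/3' terminal coordinate of an exon interval, strand-aware.
five_prime_end  <- function(exon, strand) if (strand == "+") exon[[1L]] else exon[[2L]]
three_prime_end <- function(exon, strand) if (strand == "+") exon[[2L]] else exon[[1L]]

intervals_overlap <- function(a, b) max(a[[1L]], b[[1L]]) < min(a[[2L]], b[[2L]])
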