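#' Count strain-distinguishing variants per gene
#'
#' Reads either a VCF (sites-only is enough; records need CHROM, POS, REF)
#' or a two-column TSV `gene_id`/`count`, and returns a variant count for
#' every gene in the annotation (0 when none overlap). In VCF mode each
#' record is assigned to every gene whose genomic span (introns included) it
#' overlaps; indels occupy `[POS-1, POS-1+nchar(REF))` in 0-based half-open
#' coordinates and count exactly like SNVs. Records on chromosomes absent
#' from the annotation are skipped with a warning; unsorted files are fine.
#'
#' @param path VCF (`.vcf`) or TSV path.
#' @param genes Named list of [gene_model()] objects (required for VCF mode).
#' @return Named integer vector, one count per gene in `genes` (TSV mode:
#'   per gene named in the file, plus zeros for `genes` if supplied).
#' @export
read_variants <- function(path, genes = NULL) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    if (is.null(genes)) stop("VCF mode requires gene models for overlap assignment")
    read_variants_vcf(path, genes)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "count") %in% names(tab)))
      stop("variant TSV needs gene_id and count columns")
    counts <- stats::setNames(as.integer(tab$count), tab$gene_id)
    if (!is.null(genes)) {
      out <- stats::setNames(integer(length(genes)), names(genes))
      shared <- intersect(names(counts), names(out))
      out[shared] <- counts[shared]
      out
    } else counts
  }
}

read_variants_vcf <- function(path, genes) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  counts <- stats::setNames(integer(length(genes)), names(genes))
  if (length(lines) == 0L) return(counts)
  f <- strsplit(lines, "\t", fixed = TRUE)
  vchrom <- vapply(f, `[[`, "", 1L)
  vpos <- as.numeric(vapply(f, `[[`, "", 2L))
  vref <- vapply(f, function(x) if (length(x) >= 4L) x[[4L]] else "N", "")
  if (anyNA(vpos)) stop("malformed VCF: non-numeric POS")

  gchrom <- vapply(genes, `[[`, "", "chrom")
  unknown <- !(vchrom %in% gchrom)
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " variant record(s) on chromosome(s) ",
            paste(unique(vchrom[unknown]), collapse = ", "),
            " absent from the annotation")
    vchrom <- vchrom[!unknown]; vpos <- vpos[!unknown]; vref <- vref[!unknown]
  }
  if (length(vpos) == 0L) return(counts)

  spans <- t(vapply(genes, gene_span, c(start = 0, end = 0)))
  for (chr in unique(vchrom)) {
    vi <- which(vchrom == chr)
    gi <- which(gchrom == chr)
    # 0-based half-open: VCF POS is 1-based; REF length gives the footprint
    vr <- IRanges::IRanges(start = vpos[vi], width = pmax(1L, nchar(vref[vi])))
    gr <- IRanges::IRanges(start = spans[gi, "start"] + 1L,
                           end = spans[gi, "end"])
    hits <- IRanges::findOverlaps(vr, gr)
    if (length(hits)) {
      tab <- table(S4Vectors::subjectHits(hits))
      counts[gi[as.integer(names(tab))]] <-
        counts[gi[as.integer(names(tab))]] + as.integer(tab)
    }
  }
  counts
}

#' Write a minimal sites-only VCF
#'
#' @param chrom,pos,ref,alt Equal-length record vectors (`pos` 1-based).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(chrom, pos, ref, alt, path) {
  header <- c("##fileformat=VCFv4.2",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", chrom, as.integer(pos), ref, alt)
  writeLines(c(header, recs), path)
  invisible(path)
}
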