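#' Worked two-isoform example gene
#'
#' A hand-built gene model illustrating a pair of isoforms that use
#' different transcription start sites (overlapping first exons with
#' different 5' ends), differ by internal splicing (a shifted 5' splice
#' donor of an internal exon), and use discrete polyadenylation sites
#' (overlapping last exons with different 3' ends) — the archetypal
#' multi-system divergence of a cis-regulated two-isoform gene, where in
#' the F1 hybrid one allele expresses both isoforms while the other
#' expresses essentially one. [classify_pair()] on this pair yields exactly
#' `{TSS, INT, APA}`.
#'
#' @return A [gene_model()] with two transcripts on the plus strand.
#' @examples
#' g <- example_isoform_pair()
#' classify_pair(g$transcripts[[1]], g$transcripts[[2]])
#' @export
example_isoform_pair <- function() {
  t1 <- transcript_model("iso-001", "example_gene", "chr19", "+",
                         rbind(c(100, 250), c(400, 520),
                               c(700, 820), c(1000, 1200)))
  t2 <- transcript_model("iso-002", "example_gene", "chr19", "+",
                         rbind(c(160, 250), c(400, 560),
                               c(700, 820), c(1000, 1150)))
  gene_model("example_gene", list(t1, t2), snv_count = 3L)
}
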