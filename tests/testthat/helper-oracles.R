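# Independent oracles used by the test suite. These deliberately share no
# code with the package internals they check.

# Log of integral exp(f_log(x)) dx by trapezoid-free Riemann sum on a fine
# grid (log-sum-exp stabilised).
log_int_grid <- function(f_log, lo, hi, n = 20001L) {
  x <- seq(lo, hi, length.out = n)
  lv <- f_log(x)
  m <- max(lv)
  m + log(sum(exp(lv - m))) + log(x[2L] - x[1L])
}

# Numerical-integration oracle for the four model log marginal likelihoods:
# integrates the normal likelihood of (d1, d2) over the zero-centred normal
# effect priors directly.
oracle_log_marginals <- function(d1, v1, d2, v2, sigma0) {
  lim <- 10 * max(sigma0, abs(d1), abs(d2), 1)
  cons <- dnorm(d1, 0, sqrt(v1), log = TRUE) + dnorm(d2, 0, sqrt(v2), log = TRUE)
  cis <- log_int_grid(function(b)
    dnorm(d1, b, sqrt(v1), log = TRUE) + dnorm(d2, b, sqrt(v2), log = TRUE) +
      dnorm(b, 0, sigma0, log = TRUE), -lim, lim)
  int1 <- log_int_grid(function(b)
    dnorm(d1, b, sqrt(v1), log = TRUE) + dnorm(b, 0, sigma0, log = TRUE),
    -lim, lim)
  int2 <- log_int_grid(function(b)
    dnorm(d2, b, sqrt(v2), log = TRUE) + dnorm(b, 0, sigma0, log = TRUE),
    -lim, lim)
  trans <- int1 + dnorm(d2, 0, sqrt(v2), log = TRUE)
  c(conserved = cons, cis = cis, trans = trans, cis_trans = int1 + int2)
}

# Brute-force structural classifier: loops over exons in transcription
# order, applies the terminal/overlap rules row by row, and compares the
# literal boundary lists after the stated exclusions.
oracle_classify_pair <- function(t1, t2) {
  strand <- t1$strand
  tx_order <- function(t) {
    ex <- t$exons
    if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    ex
  }
  a <- tx_order(t1)
  b <- tx_order(t2)
  row_overlap <- function(x, y) x[1L] < y[2L] && y[1L] < x[2L]
  p5 <- function(e) if (strand == "+") e[1L] else e[2L]
  p3 <- function(e) if (strand == "+") e[2L] else e[1L]

  fa <- a[1L, ]; fb <- b[1L, ]
  la <- a[nrow(a), ]; lb <- b[nrow(b), ]
  AFE <- !row_overlap(fa, fb)
  TSS <- row_overlap(fa, fb) && p5(fa) != p5(fb)
  ALE <- !row_overlap(la, lb)
  APA <- row_overlap(la, lb) && p3(la) != p3(lb)

  boundary_list <- function(ex) {
    pts <- numeric(0)
    for (i in seq_len(nrow(ex))) {
      first <- i == 1L
      last <- i == nrow(ex)
      keep5 <- !(first || (last && ALE))
      keep3 <- !(last || (first && AFE))
      if (first && AFE) keep5 <- FALSE
      if (last && ALE) keep3 <- FALSE
      if (keep5) pts <- c(pts, p5(ex[i, ]))
      if (keep3) pts <- c(pts, p3(ex[i, ]))
    }
    sort(unique(pts))
  }
  INT <- !identical(boundary_list(a), boundary_list(b))
  c(AFE = AFE, TSS = TSS, INT = INT, ALE = ALE, APA = APA)
}

# Full-enumeration two-sided Fisher p for a 2x2 table: sum of the
# hypergeometric probabilities of every table with the observed margins
# that is no more probable than the observed one.
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1L, ]); r2 <- sum(m[2L, ]); c1 <- sum(m[, 1L])
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  pobs <- dhyper(m[1L, 1L], r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Random valid transcript with <= 5 exons and coordinates < 1000.
random_transcript <- function(id = "tA", gene_id = "g", chrom = "c",
                              strand = "+") {
  n <- sample(1:5, 1L)
  pts <- sort(sample(0:999, 2L * n))
  transcript_model(id, gene_id, chrom, strand,
                   matrix(pts, ncol = 2L, byrow = TRUE))
}

# Random exonically overlapping pair on a common random strand.
random_overlapping_pair <- function() {
  strand <- sample(c("+", "-"), 1L)
  repeat {
    t1 <- random_transcript("tA", strand = strand)
    t2 <- random_transcript("tB", strand = strand)
    if (transcripts_overlap(t1, t2)) return(list(t1 = t1, t2 = t2))
  }
}

# Mirror a transcript (x -> L - x), optionally flipping the strand label.
mirror_transcript <- function(t, L = 1000, flip_strand = FALSE) {
  ex <- cbind(L - t$exons[, 2L], L - t$exons[, 1L])
  strand <- if (flip_strand) setdiff(c("+", "-"), t$strand) else t$strand
  transcript_model(t$transcript_id, t$gene_id, t$chrom, strand, ex)
}

flags_of <- function(d) unlist(d[c("AFE", "TSS", "INT", "ALE", "APA")])
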