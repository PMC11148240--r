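# Independent oracles and tiny builders shared across test files.

# Hand step-up BH: sort ascending, p_(i) * m / i, cumulative min from the
# largest rank, cap at 1, return in input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Kyte-Doolittle hydropathy, written out independently of the package table.
kd_oracle <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9,
               A = 1.8, G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3,
               P = -1.6, H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5,
               K = -3.9, R = -4.5)

aa20 <- names(kd_oracle)

random_peptide <- function(n) paste(sample(aa20, n, TRUE), collapse = "")

random_dna_str <- function(n, with_n = FALSE) {
  alpha <- c("A", "C", "G", "T")
  prob <- NULL
  if (with_n) {
    alpha <- c(alpha, "N")
    prob <- c(rep(0.24, 4), 0.04)
  }
  paste(sample(alpha, n, TRUE, prob = prob), collapse = "")
}

revcomp_str <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# In-memory single-exon gene: the chromosome is exactly CDS (+ optional UTR),
# optionally placed on the minus strand (chromosome holds the reverse
# complement). Returns the genome and transcript_set.
tiny_gene <- function(cds, utr = "", strand = "+", chrom = "chr1",
                      tid = "tx1", gene = "g1", symbol = "GENE1") {
  body <- paste0(cds, utr)
  chromo <- if (strand == "+") body else revcomp_str(body)
  genome <- Biostrings::DNAStringSet(setNames(chromo, chrom))
  n <- nchar(body)
  nc <- nchar(cds)
  if (strand == "+") {
    cds_iv <- c(1L, nc)
    utr_iv <- if (nchar(utr)) c(nc + 1L, n) else NULL
  } else {
    cds_iv <- c(n - nc + 1L, n)
    utr_iv <- if (nchar(utr)) c(1L, n - nc) else NULL
  }
  ts <- transcript_set(
    data.frame(transcript_id = tid, gene_id = gene, gene_symbol = symbol,
               chrom = chrom, strand = strand, stringsAsFactors = FALSE),
    data.frame(transcript_id = tid, start = cds_iv[1], end = cds_iv[2]),
    if (!is.null(utr_iv))
      data.frame(transcript_id = tid, start = utr_iv[1], end = utr_iv[2]))
  list(genome = genome, ts = ts)
}

# Full pipeline variants for an in-memory gene (scan -> coding -> variants).
# Accidental tracts in random flanks may sit too close to the CDS edge to
# delete from; those skips are irrelevant to the planted tract under test.
tiny_gene_variants <- function(tg) {
  loci <- scan_genome(tg$genome)
  pairs <- intersect_coding(loci, tg$ts)
  suppressWarnings(frameshift_variants(pairs, tg$ts, tg$genome))
}

# Random primitive motif of length k.
random_primitive_motif <- function(k) {
  repeat {
    m <- random_dna_str(k)
    ok <- TRUE
    if (k > 1L) {
      for (d in seq_len(k - 1L))
        if (k %% d == 0L && m == strrep(substr(m, 1L, d), k %/% d)) {
          ok <- FALSE
          break
        }
    }
    if (ok) return(m)
  }
}

# Random single-exon coding context with one planted tract; returns the
# coding-orientation sequence (CDS + stop-rich UTR) and the tract's coding
# span. Flanks are forced to differ from the tract's unit-extension bases.
random_tract_case <- function(min_units = NULL) {
  k <- sample(1:5, 1L)
  motif <- random_primitive_motif(k)
  minu <- if (k == 1L) 6L else 3L
  units <- minu + sample(0:3, 1L)
  tract <- strrep(motif, units)
  left <- paste0("ATG", random_dna_str(3L * sample(6:12, 1L)))
  substr(left, nchar(left), nchar(left)) <-
    sample(setdiff(c("A", "C", "G", "T"), substr(motif, k, k)), 1L)
  right <- random_dna_str(3L * sample(6:12, 1L))
  substr(right, 1L, 1L) <-
    sample(setdiff(c("A", "C", "G", "T"), substr(motif, 1L, 1L)), 1L)
  pad <- (3L - nchar(tract) %% 3L) %% 3L
  cds <- paste0(left, tract, right, random_dna_str(pad), "TAA")
  utr <- paste0(random_dna_str(24L), "TAAATAAATAAA")
  list(seq = paste0(cds, utr), cds = cds, utr = utr, motif = motif,
       units = units, cstart = nchar(left) + 1L,
       cend = nchar(left) + nchar(tract))
}

# Shared small fixture directory, generated once per test session.
fixture_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "msneoforge-fixture-small")
      spec <- fixture_spec("small", seed = 1)
      fx <- make_genome(spec, dir)
      first <- run_all(dir)
      make_expression(spec, dir)
      make_evidence(spec, first$variants, first$dedup, dir)
      res <- run_all(dir)
      cache <<- list(dir = dir, spec = spec, fx = fx, res = res)
    }
    cache
  }
})
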