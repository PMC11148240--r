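test_that("FASTA read preserves records, order and residues", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT"), f)
  g <- read_fasta(f)
  expect_length(g, 1L)
  expect_equal(length(g[["chr1"]]), 4L)
  expect_equal(as.character(g[["chr1"]]), "ACGT")

  writeLines(c(">chrA desc text", "acgtn", ">chrB", "TTTT"), f)
  g2 <- read_fasta(f)
  expect_equal(names(g2), c("chrA", "chrB"))   # order preserved, header cut
  expect_equal(as.character(g2[["chrA"]]), "ACGTN")  # uppercased
})

test_that("FASTA errors: duplicates, bad residues, empty file", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr1", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">chr1", "ACGR"), f)   # IUPAC ambiguity codes are rejected
  expect_error(read_fasta(f), "non-ACGTN")
  writeLines(character(), f)
  expect_error(read_fasta(f))
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("FASTA round trip is lossless", {
  set.seed(11)
  seqs <- setNames(vapply(1:5, function(i) random_dna_str(50 + i),
                          character(1)),
                   paste0("s", 1:5))
  f <- tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(names(back), names(seqs))
  expect_equal(as.character(back), seqs, ignore_attr = TRUE)
})

gtf_line <- function(chrom, feature, start, end, strand, tid, gid = "g1",
                     sym = "GENE1") {
  attrs <- if (is.na(tid)) sprintf('gene_id "%s";', gid)
  else sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
               gid, tid, sym)
  paste(chrom, "test", feature, start, end, ".", strand, ".", attrs,
        sep = "\t")
}

test_that("GTF parsing groups and sorts CDS per transcript", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("chr1", "CDS", 4, 12, "+", "t1")), f)
  ts <- read_annotation(f)
  expect_s3_class(ts, "transcript_set")
  expect_equal(ts$transcripts$cds_len, 9L)
  expect_true(ts$transcripts$frame_ok)

  # two CDS lines, same transcript, minus strand, given out of order
  writeLines(c(gtf_line("chr1", "CDS", 20, 24, "-", "t2"),
               gtf_line("chr1", "CDS", 4, 12, "-", "t2")), f)
  ts2 <- read_annotation(f)
  expect_equal(nrow(ts2$cds), 2L)
  expect_equal(ts2$cds$start, c(4L, 20L))   # sorted by genomic start
  expect_equal(ts2$transcripts$strand, "-")
})

test_that("CDS length not divisible by 3 is flagged, not dropped", {
  f <- tempfile(fileext = ".gtf")
  writeLines(gtf_line("chr1", "CDS", 1, 10, "+", "t1"), f)
  expect_message(ts <- read_annotation(f), "flagged")
  expect_equal(nrow(ts$transcripts), 1L)
  expect_false(ts$transcripts$frame_ok)
})

test_that("CDS without transcript id or with unknown strand is skipped", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("chr1", "CDS", 1, 9, "+", "t1"),
               gtf_line("chr1", "CDS", 30, 38, "+", NA)), f)
  expect_warning(ts <- read_annotation(f), "without transcript id")
  expect_equal(ts$transcripts$transcript_id, "t1")

  writeLines(c(gtf_line("chr1", "CDS", 1, 9, "+", "t1"),
               gtf_line("chr1", "CDS", 30, 38, ".", "t2")), f)
  expect_warning(ts2 <- read_annotation(f), "unknown strand")
  expect_equal(ts2$transcripts$transcript_id, "t1")
})

test_that("GFF3 dialect is parsed through Parent attributes", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "test", "CDS", 4, 12, ".", "+", "0",
                     "ID=cds1;Parent=transcript:t1", sep = "\t")), f)
  ts <- read_annotation(f, dialect = "gff3")
  expect_equal(ts$transcripts$transcript_id, "t1")
  expect_equal(ts$transcripts$cds_len, 9L)
})

test_that("extract_cds splices and reverse-complements correctly", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ATGAAA", chr2 = "ATGCAAA"))
  ts <- transcript_set(
    data.frame(transcript_id = c("p", "m", "sp"),
               gene_id = "g", gene_symbol = "G",
               chrom = c("chr1", "chr1", "chr2"),
               strand = c("+", "-", "+"), stringsAsFactors = FALSE),
    data.frame(transcript_id = c("p", "m", "sp", "sp"),
               start = c(1L, 1L, 1L, 5L), end = c(3L, 6L, 3L, 7L)))
  expect_equal(extract_cds(g, ts, "p"), "ATG")
  expect_equal(extract_cds(g, ts, "m"), "TTTCAT")   # revcomp by hand
  expect_equal(extract_cds(g, ts, "sp"), "ATGAAA")  # splice by hand
})

test_that("minus-strand extraction equals revcomp of plus-strand extraction", {
  set.seed(12)
  for (rep in 1:5) {
    chrom <- random_dna_str(200)
    g <- Biostrings::DNAStringSet(c(chr1 = chrom))
    st <- sort(sample(1:180, 2))
    iv <- data.frame(transcript_id = c("pl", "pl", "mi", "mi"),
                     start = c(st[1], st[2] + 5L, st[1], st[2] + 5L),
                     end = c(st[1] + 3L, st[2] + 9L, st[1] + 3L,
                             st[2] + 9L))
    ts <- transcript_set(
      data.frame(transcript_id = c("pl", "mi"), gene_id = "g",
                 gene_symbol = "G", chrom = "chr1",
                 strand = c("+", "-"), stringsAsFactors = FALSE), iv)
    expect_equal(extract_cds(g, ts, "mi"),
                 revcomp_str(extract_cds(g, ts, "pl")))
  }
})

test_that("out-of-bounds intervals and N handling behave as specified", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ATGNAA"))
  ts <- transcript_set(
    data.frame(transcript_id = "t", gene_id = "g", gene_symbol = "G",
               chrom = "chr1", strand = "+", stringsAsFactors = FALSE),
    data.frame(transcript_id = "t", start = 1L, end = 6L))
  s <- extract_cds(g, ts, "t")
  expect_true(isTRUE(attr(s, "has_n")))     # flagged, still returned
  ts2 <- transcript_set(
    data.frame(transcript_id = "t", gene_id = "g", gene_symbol = "G",
               chrom = "chr1", strand = "+", stringsAsFactors = FALSE),
    data.frame(transcript_id = "t", start = 2L, end = 9L))
  expect_error(extract_cds(g, ts2, "t"), "bounds")
})

test_that("coding/genomic coordinate maps are mutually inverse", {
  set.seed(13)
  g <- Biostrings::DNAStringSet(c(chr1 = random_dna_str(300)))
  for (strand in c("+", "-")) {
    ts <- transcript_set(
      data.frame(transcript_id = "t", gene_id = "g", gene_symbol = "G",
                 chrom = "chr1", strand = strand, stringsAsFactors = FALSE),
      data.frame(transcript_id = rep("t", 3),
                 start = c(10L, 50L, 120L), end = c(30L, 80L, 140L)))
    cds_len <- 21L + 31L + 21L
    cpos <- seq_len(cds_len)
    gpos <- msneoforge:::genomic_coord(ts, "t", cpos)
    expect_false(anyNA(gpos))
    expect_equal(msneoforge:::coding_coord(ts, "t", gpos), cpos)
    # the mapped sequence must equal extract_cds base by base
    chars <- strsplit(as.character(g[["chr1"]]), "")[[1]]
    mapped <- chars[gpos]
    if (strand == "-")
      mapped <- strsplit(revcomp_str(paste(rev(mapped), collapse = "")),
                         "")[[1]]
    expect_equal(paste(mapped, collapse = ""), extract_cds(g, ts, "t"),
                 ignore_attr = TRUE)
  }
})
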