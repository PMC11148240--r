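test_that("translate_nt follows the standard code and halts at stops", {
  expect_equal(translate_nt("ATGTGA"),
               list(peptide = "M", stop_found = TRUE))
  expect_equal(translate_nt("ATGAAAAAAACC"),
               list(peptide = "MKKT", stop_found = FALSE))
  expect_equal(translate_nt("ATGAA"),          # trailing 2 bases ignored
               list(peptide = "M", stop_found = FALSE))
  expect_error(translate_nt("AT"), "shorter")
  expect_error(translate_nt("ATGNAA"), "untranslatable")
})

test_that("translate_nt agrees with an independent translation route", {
  set.seed(601)
  for (i in 1:100) {
    n <- 3 * sample(5:40, 1)
    s <- random_dna_str(n)
    mine <- translate_nt(s)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                             no.init.codon = TRUE))
    stop_at <- regexpr("*", aa, fixed = TRUE)
    want <- if (stop_at == -1L) list(peptide = aa, stop_found = FALSE)
    else list(peptide = substr(aa, 1, stop_at - 1), stop_found = TRUE)
    expect_equal(mine, want)
  }
})

test_that("exactly two canonical variants per coding pair, one per class", {
  tg <- tiny_gene("ATGAAAAAAACATCCTTGGTAG")   # A7 tract at 4..10
  v <- tiny_gene_variants(tg)
  expect_equal(nrow(v), 2L)
  expect_setequal(v$del_len, c(1L, 2L))
  expect_equal(v$frame_class[v$del_len == 2], 1L)   # 3n+1 series
  expect_equal(v$frame_class[v$del_len == 1], 2L)   # 3n+2 series
  expect_true(all(v$frame_class == (-v$del_len) %% 3L))
})

test_that("VCF fields are left-aligned anchored deletions", {
  tg <- tiny_gene("ATGAAAAAAACATCCTTGGTAG")
  v <- tiny_gene_variants(tg)
  v1 <- v[v$del_len == 1, ]
  # deleting one A of the homopolymer left-aligns to anchor G at pos 3
  expect_equal(v1$vcf_pos, 3L)
  expect_equal(v1$vcf_ref, "GA")
  expect_equal(v1$vcf_alt, "G")
  v2 <- v[v$del_len == 2, ]
  expect_equal(v2$vcf_pos, 3L)
  expect_equal(v2$vcf_ref, "GAA")
  expect_equal(v2$vcf_alt, "G")
  # ref always begins with alt (anchored deletion)
  expect_true(all(startsWith(v$vcf_ref, v$vcf_alt)))
})

test_that("apply_variant removes exactly del_len bases from the tract end", {
  tg <- tiny_gene("ATGAAAAAAACATCCTTGGTAG")
  v <- tiny_gene_variants(tg)
  seq <- extract_cds(tg$genome, tg$ts, "tx1")
  for (i in 1:2) {
    mut <- apply_variant(seq, v[i, ])
    expect_equal(nchar(mut), nchar(seq) - v$del_len[i])
  }
  set.seed(602)
  for (i in 1:20) {     # length contract on random tract cases
    cs <- random_tract_case()
    vr <- data.frame(cds_tract_end = cs$cend, del_len = sample(1:2, 1))
    expect_equal(nchar(apply_variant(cs$seq, vr)),
                 nchar(cs$seq) - vr$del_len)
  }
})

test_that("downstream peptides match hand translation on the worked gene", {
  # CDS: ATG AAAAAAA CAT CCT TGG TAG; tract A7 at coding 4..10
  tg <- tiny_gene("ATGAAAAAAACATCCTTGGTAG")
  v <- tiny_gene_variants(tg)
  seq <- extract_cds(tg$genome, tg$ts, "tx1", with_utr3 = TRUE)
  p1 <- downstream_peptide(seq, v[v$del_len == 1, ])
  # del 1: mutant ATG AAAAAA CAT CCT TGG TAG -> first post-tract codon is
  # codon 4 (base 10); CAT CCT TGG TAG = H P W stop
  expect_equal(p1$peptide, "HPW")
  expect_false(p1$non_stop)
  expect_equal(p1$junction_excluded_from, 4L)
  # del 2: mutant ATG AAAAA CATCCTTGGTAG; tail from base 10: ATC CTT GGT AG
  p2 <- downstream_peptide(seq, v[v$del_len == 2, ])
  expect_equal(p2$peptide, "ILG")
  expect_true(p2$non_stop)   # transcript ends without a stop in this frame
})

test_that("downstream_peptide agrees with the edit-and-translate oracle", {
  set.seed(603)
  for (i in 1:25) {
    cs <- random_tract_case()
    tg <- tiny_gene(cs$cds, cs$utr, strand = sample(c("+", "-"), 1))
    v <- tiny_gene_variants(tg)
    # keep the planted tract (random flanks may contain accidental tracts)
    v <- v[v$cds_tract_start == cs$cstart & v$cds_tract_end == cs$cend, ]
    expect_equal(nrow(v), 2L)
    seq <- extract_cds(tg$genome, tg$ts, "tx1", with_utr3 = TRUE)
    expect_equal(seq, cs$seq, ignore_attr = TRUE)
    for (j in 1:2) {
      mine <- downstream_peptide(seq, v[j, ])
      ref <- downstream_peptide_ref(cs$seq, cs$cend, edit = "del",
                                    size = v$del_len[j],
                                    at = cs$cend - v$del_len[j] + 1L)
      if (is.null(mine)) {
        expect_true(is.na(ref$peptide))
      } else {
        expect_equal(mine$peptide, ref$peptide)
        expect_equal(mine$non_stop, ref$non_stop)
      }
    }
  }
})

test_that("a stop at the first post-tract codon yields no peptide", {
  # after del 1 the first fully post-tract codon reads TAA
  tg <- tiny_gene(paste0("ATG", strrep("A", 7), "TAAACCGGATAG"),
                  utr = "GGGTAAATAAATAAA")
  v <- tiny_gene_variants(tg)
  seq <- extract_cds(tg$genome, tg$ts, "tx1", with_utr3 = TRUE)
  expect_null(downstream_peptide(seq, v[v$del_len == 1, ]))
  expect_false(is.null(downstream_peptide(seq, v[v$del_len == 2, ])))
})

test_that("frame-class equivalence: all congruent indels share one peptide", {
  set.seed(604)
  for (i in 1:25) {
    cs <- random_tract_case()
    tg <- tiny_gene(cs$cds, cs$utr)
    v <- tiny_gene_variants(tg)
    v <- v[v$cds_tract_start == cs$cstart & v$cds_tract_end == cs$cend, ]
    seq <- extract_cds(tg$genome, tg$ts, "tx1", with_utr3 = TRUE)
    pep <- function(x) if (is.null(x)) NA_character_ else x$peptide
    can1 <- pep(downstream_peptide(seq, v[v$del_len == 1, ]))
    can2 <- pep(downstream_peptide(seq, v[v$del_len == 2, ]))
    wt <- downstream_peptide_ref(cs$seq, cs$cend, "del", 0)$peptide
    expected_for <- function(shift) switch(as.character(shift %% 3),
                                           "0" = wt, "1" = can2, "2" = can1)
    tract_len <- cs$cend - cs$cstart + 1L
    for (s in 1:7) {
      for (pos in seq_len(tract_len)) {
        if (pos + s - 1L <= tract_len && s < tract_len) {
          o <- downstream_peptide_ref(cs$seq, cs$cend, "del", s,
                                      at = cs$cstart + pos - 1L)
          expect_identical(o$peptide, expected_for(-s))
        }
        ins <- random_dna_str(s)
        o <- downstream_peptide_ref(cs$seq, cs$cend, "ins", s,
                                    at = cs$cstart + pos - 1L, bases = ins)
        expect_identical(o$peptide, expected_for(s))
      }
    }
  }
})

test_that("peptides never contain a stop symbol; non_stop is coherent", {
  fx <- fixture_small()
  peps <- fx$res$peptides
  expect_gt(nrow(peps), 0L)
  expect_false(any(grepl("*", peps$peptide, fixed = TRUE)))
  expect_true(all(nchar(peps$peptide) > 0L))
})

test_that("deduplication merges sources, sorts, and is idempotent", {
  peps <- data.frame(
    peptide = c("MKL", "MKL", "AAA"),
    transcript_id = c("t2", "t1", "t3"), gene_id = c("g2", "g1", "g3"),
    gene_symbol = c("B", "A", "C"), chrom = "chr1",
    locus_start = c(5L, 5L, 9L), locus_end = c(10L, 10L, 14L),
    motif = "A", frame_class = c(1L, 1L, 2L), del_len = c(2L, 2L, 1L),
    non_stop = c(FALSE, TRUE, FALSE), junction_excluded_from = 4L,
    variant_key = c("chr1:4:GA:G", "chr1:4:GA:G", "chr1:8:TAA:T"),
    stringsAsFactors = FALSE)
  d <- deduplicate_peptides(peps)
  expect_equal(d$peptide, c("AAA", "MKL"))       # lexicographic order
  expect_equal(d$n_sources, c(1L, 2L))
  expect_equal(d$gene_symbols, c("C", "A,B"))    # merged + sorted
  expect_true(d$non_stop[2])                     # any source without stop
  # idempotence through a set-based oracle
  expect_equal(nrow(d), length(unique(peps$peptide)))
  fx <- fixture_small()
  d1 <- fx$res$dedup
  expect_equal(nrow(d1), length(unique(fx$res$peptides$peptide)))
})

test_that("emitted VCF re-parses consistently against the genome", {
  fx <- fixture_small()
  vcf <- file.path(fx$dir, "variants.vcf")
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- read.delim(text = lines[!startsWith(lines, "##")], check.names = FALSE)
  expect_gt(nrow(body), 0L)
  for (i in seq_len(nrow(body))) {
    ref <- body$REF[i]
    chrom <- body[["#CHROM"]][i]
    pos <- body$POS[i]
    seen <- as.character(Biostrings::subseq(fx$res$genome[[chrom]], pos,
                                            pos + nchar(ref) - 1L))
    expect_equal(seen, ref)                      # REF matches the genome
    expect_true(startsWith(ref, body$ALT[i]))    # anchored deletion
  }
})
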