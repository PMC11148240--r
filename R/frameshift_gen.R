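# Standard genetic code (translation table 1), indexed over bases in TCAG
# order: codon index = 16*b1 + 4*b2 + b3.
.aa64 <- strsplit(paste0("FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
                         "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"),
                  "")[[1L]]
.base_idx <- local({
  v <- rep(NA_integer_, 128L)
  v[utf8ToInt("T") + 1L] <- 0L
  v[utf8ToInt("C") + 1L] <- 1L
  v[utf8ToInt("A") + 1L] <- 2L
  v[utf8ToInt("G") + 1L] <- 3L
  v
})

#' Translate a nucleotide string (standard code, halt at first stop)
#'
#' Translation proceeds codon by codon from position 1 and halts at the first
#' stop codon; 1-2 trailing bases that do not fill a codon are ignored.
#'
#' @param nt Character string over A, C, G, T; length >= 3.
#' @return list with `peptide` (amino-acid string, stop symbol excluded) and
#'   `stop_found` (logical). A string containing N or other letters is an
#'   error: the caller must flag such transcripts instead of translating.
#' @export
translate_nt <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n < 3L) stop("sequence shorter than one codon")
  bi <- .base_idx[utf8ToInt(nt) + 1L]
  if (anyNA(bi)) stop("untranslatable residue (non-ACGT) in sequence")
  ncod <- n %/% 3L
  i1 <- seq.int(1L, by = 3L, length.out = ncod)
  code <- 16L * bi[i1] + 4L * bi[i1 + 1L] + bi[i1 + 2L] + 1L
  aa <- .aa64[code]
  stop_at <- match("*", aa)
  if (is.na(stop_at)) {
    list(peptide = paste(aa, collapse = ""), stop_found = FALSE)
  } else {
    list(peptide = paste(aa[seq_len(stop_at - 1L)], collapse = ""),
         stop_found = TRUE)
  }
}

# Coding-coordinate span of the in-CDS portion of a tract, plus the genomic
# positions it maps from.
tract_coding_span <- function(ts, transcript_id, chrom, start, end) {
  gpos <- start:end
  cpos <- coding_coord(ts, transcript_id, gpos)
  ok <- !is.na(cpos)
  if (!any(ok)) return(NULL)
  list(cstart = min(cpos[ok]), cend = max(cpos[ok]),
       n_in_cds = sum(ok), gpos_in_cds = gpos[ok])
}

# Left-align a genomic deletion [gs, ge] on chrom and return the anchored
# VCF representation (pos, ref, alt). chseq is the chromosome DNAString.
vcf_left_align <- function(chseq, gs, ge) {
  sch <- function(i) as.character(Biostrings::subseq(chseq, i, i))
  while (gs > 1L && sch(ge) == sch(gs - 1L)) {
    gs <- gs - 1L
    ge <- ge - 1L
  }
  if (gs > 1L) {
    pos <- gs - 1L
    ref <- as.character(Biostrings::subseq(chseq, gs - 1L, ge))
    alt <- sch(gs - 1L)
  } else {
    # deletion reaches base 1: anchor on the right instead
    pos <- gs
    ref <- as.character(Biostrings::subseq(chseq, gs, ge + 1L))
    alt <- sch(ge + 1L)
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Canonical frameshift deletion variants for coding microsatellites
#'
#' Every frameshift indel at a microsatellite falls in one of two frame
#' classes by its net length modulo 3; each class is represented by one
#' canonical deletion: 2 bp deleted (frame class 1, the 3n+1 series) and 1 bp
#' deleted (frame class 2, the 3n+2 series). The deletion removes the last
#' bases of the in-CDS tract portion in coding orientation; its VCF
#' representation is independently left-aligned and anchored on the genome
#' plus strand. Pairs whose in-CDS tract portion is shorter than 3 bases are
#' skipped with a warning (deleting 2 bases must leave at least one tract
#' base).
#'
#' @param pairs data.frame from [intersect_coding()].
#' @param ts A [transcript_set()].
#' @param genome A [Biostrings::DNAStringSet].
#' @return data.frame with one row per variant (two per retained pair):
#'   locus columns, transcript columns, `del_len`, `frame_class`
#'   (`(-del_len) mod 3`), coding-coordinate tract span `cds_tract_start`,
#'   `cds_tract_end`, VCF fields `vcf_pos`, `vcf_ref`, `vcf_alt`,
#'   `variant_key` (`chrom:pos:ref:alt`) and `vcf_ok` (FALSE when the deleted
#'   bases are not genomically contiguous, e.g. a deletion straddling a
#'   splice junction; such variants get peptides but no VCF record).
#' @export
frameshift_variants <- function(pairs, ts, genome) {
  rows <- vector("list", nrow(pairs) * 2L)
  ri <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    span <- tract_coding_span(ts, p$transcript_id, p$chrom, p$start, p$end)
    if (is.null(span) || span$n_in_cds < 3L) {
      skipped <- skipped + 1L
      next
    }
    chseq <- chrom_seq(genome, p$chrom)
    for (del_len in c(2L, 1L)) {
      cdel <- (span$cend - del_len + 1L):span$cend
      gdel <- sort(genomic_coord(ts, p$transcript_id, cdel))
      contiguous <- length(gdel) == 1L || all(diff(gdel) == 1L)
      if (contiguous) {
        v <- vcf_left_align(chseq, gdel[1L], gdel[length(gdel)])
        vpos <- v$pos; vref <- v$ref; valt <- v$alt
        vkey <- paste(p$chrom, vpos, vref, valt, sep = ":")
      } else {
        vpos <- NA_integer_; vref <- NA_character_; valt <- NA_character_
        vkey <- NA_character_
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        chrom = p$chrom, locus_start = p$start, locus_end = p$end,
        motif = p$motif, motif_len = p$motif_len, unit_count = p$unit_count,
        transcript_id = p$transcript_id, gene_id = p$gene_id,
        gene_symbol = p$gene_symbol, strand = p$strand,
        del_len = del_len, frame_class = (-del_len) %% 3L,
        cds_tract_start = span$cstart, cds_tract_end = span$cend,
        vcf_pos = vpos, vcf_ref = vref, vcf_alt = valt,
        variant_key = vkey, vcf_ok = contiguous,
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L)
    warning(skipped, " locus-transcript pair(s) skipped: in-CDS tract ",
            "portion shorter than 3 bases")
  out <- do.call(rbind, rows[seq_len(ri)])
  if (is.null(out))
    return(data.frame(chrom = character(), locus_start = integer(),
                      locus_end = integer(), motif = character(),
                      motif_len = integer(), unit_count = integer(),
                      transcript_id = character(), gene_id = character(),
                      gene_symbol = character(), strand = character(),
                      del_len = integer(), frame_class = integer(),
                      cds_tract_start = integer(), cds_tract_end = integer(),
                      vcf_pos = integer(), vcf_ref = character(),
                      vcf_alt = character(), variant_key = character(),
                      vcf_ok = logical(), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Apply a canonical deletion to a coding-orientation transcript sequence
#'
#' @param transcript_seq Coding-orientation nucleotide string (CDS, plus any
#'   3' UTR appended).
#' @param variant One row of [frameshift_variants()] output.
#' @return Mutant nucleotide string; its length is
#'   `nchar(transcript_seq) - del_len`.
#' @export
apply_variant <- function(transcript_seq, variant) {
  t_end <- variant$cds_tract_end
  d <- variant$del_len
  if (t_end > nchar(transcript_seq) || t_end - d < 0L)
    stop("variant coordinates do not map inside the transcript sequence")
  paste0(substr(transcript_seq, 1L, t_end - d),
         substr(transcript_seq, t_end + 1L, nchar(transcript_seq)))
}

# First codon index all of whose bases lie strictly 3' of position t.
first_post_tract_codon <- function(t) (t + 2L) %/% 3L + 1L

#' Junction-excluded downstream frameshift peptide of one variant
#'
#' The peptide starts at the first mutant codon whose three bases all lie
#' strictly 3' of the microsatellite tract in mutant coordinates; codons
#' overlapping the tract (the junction region, whose content depends on the
#' particular indel rather than on the frame class) are excluded entirely.
#' Translation runs from that codon to the first stop; if the transcript ends
#' without a stop the peptide is kept and flagged `non_stop`. Returns `NULL`
#' when the mutant sequence ends before one full post-tract codon or when the
#' first post-tract codon is a stop.
#'
#' @param transcript_seq Coding-orientation CDS (plus 3' UTR) of the
#'   wild-type transcript.
#' @param variant One row of [frameshift_variants()] output.
#' @return One-row data.frame (`peptide`, `transcript_id`, `gene_id`,
#'   `gene_symbol`, locus columns, `frame_class`, `del_len`, `non_stop`,
#'   `junction_excluded_from`, `variant_key`) or `NULL`.
#' @export
downstream_peptide <- function(transcript_seq, variant) {
  mut <- apply_variant(transcript_seq, variant)
  t_mut <- variant$cds_tract_end - variant$del_len
  cod <- first_post_tract_codon(t_mut)
  tail_start <- 3L * (cod - 1L) + 1L
  if (tail_start + 2L > nchar(mut)) return(NULL)
  tr <- translate_nt(substr(mut, tail_start, nchar(mut)))
  if (tr$peptide == "") return(NULL)
  data.frame(
    peptide = tr$peptide,
    transcript_id = variant$transcript_id, gene_id = variant$gene_id,
    gene_symbol = variant$gene_symbol, chrom = variant$chrom,
    locus_start = variant$locus_start, locus_end = variant$locus_end,
    motif = variant$motif, frame_class = variant$frame_class,
    del_len = variant$del_len, non_stop = !tr$stop_found,
    junction_excluded_from = cod, variant_key = variant$variant_key,
    stringsAsFactors = FALSE)
}

#' Reference downstream-peptide oracle by literal string edit
#'
#' Independent route used for validation and for fixture truth tables:
#' performs an explicit deletion or insertion inside the tract of a
#' coding-orientation sequence, recomputes the mutant tract end, and
#' translates the junction-excluded tail with [Biostrings::translate()]
#' (implementation path uses its own codon table). Any indel inside the
#' tract whose net length change is congruent modulo 3 must give the same
#' result, which is the frame-class equivalence this package relies on.
#'
#' @param transcript_seq Coding-orientation wild-type sequence (CDS + UTR).
#' @param tract_cend 1-based coding coordinate of the last in-CDS tract base.
#' @param edit `"del"` or `"ins"`.
#' @param size Number of bases deleted or inserted (>= 0; 0 means wild type).
#' @param at For `"del"`, the coding position of the first deleted base (the
#'   whole deleted segment must lie inside the tract); for `"ins"`, the
#'   coding position after which `bases` are inserted (from tract start - 1
#'   to tract end).
#' @param bases Inserted bases (required for `"ins"`, length `size`).
#' @return list(`peptide` or NA, `non_stop`).
#' @export
downstream_peptide_ref <- function(transcript_seq, tract_cend,
                                   edit = c("del", "ins"), size = 0L,
                                   at = NULL, bases = NULL) {
  edit <- match.arg(edit)
  n <- nchar(transcript_seq)
  if (size == 0L) {
    mut <- transcript_seq
    t_mut <- tract_cend
  } else if (edit == "del") {
    mut <- paste0(substr(transcript_seq, 1L, at - 1L),
                  substr(transcript_seq, at + size, n))
    t_mut <- tract_cend - size
  } else {
    if (is.null(bases) || nchar(bases) != size)
      stop("insertion requires 'bases' of length 'size'")
    mut <- paste0(substr(transcript_seq, 1L, at),
                  bases, substr(transcript_seq, at + 1L, n))
    t_mut <- tract_cend + size
  }
  cod <- (t_mut + 2L) %/% 3L + 1L
  tail_start <- 3L * (cod - 1L) + 1L
  if (tail_start + 2L > nchar(mut))
    return(list(peptide = NA_character_, non_stop = NA))
  tail <- substr(mut, tail_start,
                 tail_start + ((nchar(mut) - tail_start + 1L) %/% 3L) * 3L - 1L)
  # mid-ORF translation: the first tail codon is not an initiation codon
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(tail),
                                           no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at == -1L) {
    if (aa == "") return(list(peptide = NA_character_, non_stop = NA))
    return(list(peptide = aa, non_stop = TRUE))
  }
  pep <- substr(aa, 1L, stop_at - 1L)
  if (pep == "") return(list(peptide = NA_character_, non_stop = NA))
  list(peptide = pep, non_stop = FALSE)
}

#' Downstream frameshift peptides for a variant table
#'
#' Extracts each transcript's CDS (+ 3' UTR) once, applies every canonical
#' variant and collects the junction-excluded downstream peptides.
#' Transcripts whose sequence contains N are flagged untranslated and
#' skipped with a warning.
#'
#' @param variants data.frame from [frameshift_variants()].
#' @param ts A [transcript_set()].
#' @param genome A [Biostrings::DNAStringSet].
#' @return data.frame of peptide records (possibly fewer rows than
#'   `variants`: frameshifts that immediately hit a stop yield nothing).
#' @export
frameshift_peptides <- function(variants, ts, genome) {
  out <- list()
  for (tid in unique(variants$transcript_id)) {
    seq <- extract_cds(genome, ts, tid, with_utr3 = TRUE)
    if (isTRUE(attr(seq, "has_n"))) {
      warning("transcript ", tid, " contains N; flagged untranslated")
      next
    }
    vs <- variants[variants$transcript_id == tid, , drop = FALSE]
    for (i in seq_len(nrow(vs))) {
      rec <- downstream_peptide(seq, vs[i, ])
      if (!is.null(rec)) out[[length(out) + 1L]] <- rec
    }
  }
  if (!length(out))
    return(data.frame(peptide = character(), transcript_id = character(),
                      gene_id = character(), gene_symbol = character(),
                      chrom = character(), locus_start = integer(),
                      locus_end = integer(), motif = character(),
                      frame_class = integer(), del_len = integer(),
                      non_stop = logical(), junction_excluded_from = integer(),
                      variant_key = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deduplicate frameshift peptides by sequence
#'
#' One record per distinct peptide string; sources are merged and sorted;
#' output is sorted lexicographically by peptide and given stable ids.
#'
#' @param peps data.frame from [frameshift_peptides()].
#' @return data.frame with columns `peptide_id`, `peptide`, `n_sources`,
#'   `sources` (sorted, `;`-collapsed `transcript|chrom:start-end|motif|fc`),
#'   `gene_symbols` (sorted unique, `,`-collapsed), `variant_keys` (sorted
#'   unique, `;`-collapsed), `non_stop` (TRUE when any source lacked a stop).
#' @export
deduplicate_peptides <- function(peps) {
  if (nrow(peps) == 0L)
    return(data.frame(peptide_id = character(), peptide = character(),
                      n_sources = integer(), sources = character(),
                      gene_symbols = character(), variant_keys = character(),
                      non_stop = logical(), stringsAsFactors = FALSE))
  src <- paste0(peps$transcript_id, "|", peps$chrom, ":", peps$locus_start,
                "-", peps$locus_end, "|", peps$motif, "|fc",
                peps$frame_class)
  sp <- split(seq_len(nrow(peps)), peps$peptide)
  uniq <- sort(names(sp))
  out <- data.frame(
    peptide_id = sprintf("FSP%05d", seq_along(uniq)),
    peptide = uniq,
    n_sources = vapply(sp[uniq], length, integer(1)),
    sources = vapply(sp[uniq], function(i)
      paste(sort(unique(src[i])), collapse = ";"), character(1)),
    gene_symbols = vapply(sp[uniq], function(i)
      paste(sort(unique(peps$gene_symbol[i])), collapse = ","), character(1)),
    variant_keys = vapply(sp[uniq], function(i)
      paste(sort(unique(peps$variant_key[i][!is.na(peps$variant_key[i])])),
            collapse = ";"), character(1)),
    non_stop = vapply(sp[uniq], function(i)
      any(peps$non_stop[i]), logical(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write canonical variants as VCF 4.2
#'
#' Emits anchored, left-aligned deletion records (one per distinct variant
#' key). Variants whose deletion is not genomically contiguous
#' (`vcf_ok = FALSE`) are omitted with a warning.
#'
#' @param variants data.frame from [frameshift_variants()].
#' @param path Output path.
#' @param genome A [Biostrings::DNAStringSet] (for contig header lengths).
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, genome) {
  if (any(!variants$vcf_ok))
    warning(sum(!variants$vcf_ok),
            " variant(s) omitted from VCF: deletion not contiguous on genome")
  v <- variants[variants$vcf_ok, , drop = FALSE]
  v <- v[!duplicated(v$variant_key), , drop = FALSE]
  v <- v[order(v$chrom, v$vcf_pos, v$vcf_ref, v$vcf_alt), , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=msneoforge ", as.character(utils::packageVersion("msneoforge"))),
    vapply(names(genome), function(ch)
      sprintf("##contig=<ID=%s,length=%d>", ch, length(genome[[ch]])),
      character(1)),
    "##INFO=<ID=MOTIF,Number=1,Type=String,Description=\"Microsatellite motif (plus strand)\">",
    "##INFO=<ID=UNITS,Number=1,Type=Integer,Description=\"Whole repeat units in the tract\">",
    "##INFO=<ID=FC,Number=1,Type=Integer,Description=\"Frame class of the represented indel series (net shift mod 3)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(v)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t.\tMOTIF=%s;UNITS=%d;FC=%d",
    v$chrom, v$vcf_pos, v$vcf_ref, v$vcf_alt, v$motif, v$unit_count,
    v$frame_class) else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write deduplicated frameshift peptides as FASTA
#'
#' @param dedup data.frame from [deduplicate_peptides()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptides_fasta <- function(dedup, path) {
  aa <- Biostrings::AAStringSet(setNames(dedup$peptide, dedup$peptide_id))
  Biostrings::writeXStringSet(aa, filepath = path, format = "fasta")
  invisible(path)
}
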