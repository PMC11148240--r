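#' Read a genome FASTA file
#'
#' Reads a multi-record FASTA into a named [Biostrings::DNAStringSet].
#' Residues are uppercased on read; the alphabet is restricted to A, C, G, T
#' and N. Duplicate sequence identifiers and empty files are hard errors.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet], one entry per record, input order
#'   preserved. Names are the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stop("FASTA file is empty: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence identifiers in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  # uppercase and alphabet check in one pass over the frequency table
  af <- Biostrings::alphabetFrequency(seqs)
  allowed <- c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n")
  bad <- colSums(af[, !(colnames(af) %in% allowed), drop = FALSE])
  if (any(bad > 0))
    stop("non-ACGTN residues in FASTA: ",
         paste(names(bad)[bad > 0], collapse = ", "))
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs A named [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named")
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, filepath = path, format = "fasta")
  invisible(path)
}

#' Construct a transcript set
#'
#' Container for gene models as used throughout the pipeline. Coordinates are
#' 1-based, fully closed (GFF convention). CDS intervals are stored sorted by
#' genomic start and must be pairwise non-overlapping within a transcript.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `gene_symbol`, `chrom`, `strand` (`+` or `-`).
#' @param cds data.frame with columns `transcript_id`, `start`, `end`.
#' @param utr3 Optional data.frame with the same columns as `cds`, holding
#'   annotated 3' UTR intervals (used for translation past the annotated
#'   stop).
#' @return An object of class `transcript_set`: a list with elements
#'   `transcripts` (with derived columns `cds_len` and `frame_ok`), `cds`
#'   and `utr3`.
#' @export
transcript_set <- function(transcripts, cds, utr3 = NULL) {
  need_t <- c("transcript_id", "gene_id", "gene_symbol", "chrom", "strand")
  if (!all(need_t %in% names(transcripts)))
    stop("transcripts must have columns: ", paste(need_t, collapse = ", "))
  if (!all(c("transcript_id", "start", "end") %in% names(cds)))
    stop("cds must have columns transcript_id, start, end")
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript_id in transcripts")
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  cds <- cds[order(match(cds$transcript_id, transcripts$transcript_id),
                   cds$start), , drop = FALSE]
  rownames(cds) <- NULL
  # per-transcript interval sanity: sorted, non-overlapping
  for (tid in unique(cds$transcript_id)) {
    iv <- cds[cds$transcript_id == tid, , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$start[-1L] <= iv$end[-nrow(iv)]))
      stop("overlapping CDS intervals in transcript ", tid)
  }
  len <- tapply(cds$end - cds$start + 1L, cds$transcript_id, sum)
  transcripts$cds_len <- as.integer(len[transcripts$transcript_id])
  transcripts$cds_len[is.na(transcripts$cds_len)] <- 0L
  if (any(transcripts$cds_len < 3L))
    stop("total CDS length must be >= 3 for every transcript")
  transcripts$frame_ok <- transcripts$cds_len %% 3L == 0L
  rownames(transcripts) <- NULL
  if (!is.null(utr3)) {
    utr3 <- utr3[order(match(utr3$transcript_id, transcripts$transcript_id),
                       utr3$start), , drop = FALSE]
    rownames(utr3) <- NULL
  } else {
    utr3 <- data.frame(transcript_id = character(), start = integer(),
                       end = integer())
  }
  structure(list(transcripts = transcripts, cds = cds, utr3 = utr3),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$transcripts), "transcripts,",
      nrow(x$cds), "CDS intervals,", nrow(x$utr3), "3' UTR intervals\n")
  invisible(x)
}

#' Read gene models from GTF or GFF3
#'
#' Only CDS and three_prime_utr/3' UTR features are consulted. CDS features
#' lacking a transcript identifier, or on an unknown strand, are skipped with
#' a warning. Transcripts whose total CDS length is not divisible by 3 are
#' kept and flagged (`frame_ok = FALSE`), not dropped.
#'
#' @param path Path to a GTF or GFF3 file.
#' @param dialect One of `"auto"` (by file extension), `"gtf"`, `"gff3"`.
#' @return A [transcript_set()].
#' @export
read_annotation <- function(path, dialect = c("auto", "gtf", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    dialect <- if (ext %in% c("gff", "gff3")) "gff3" else "gtf"
  }
  gr <- rtracklayer::import(path, format = dialect)
  md <- S4Vectors::mcols(gr)
  ftype <- as.character(md$type)
  is_cds <- ftype == "CDS"
  is_utr3 <- ftype %in% c("three_prime_utr", "three_prime_UTR")
  if (!any(is_cds)) stop("no CDS features in annotation: ", path)

  get_tid <- function(md) {
    if (!is.null(md$transcript_id)) return(as.character(md$transcript_id))
    if (!is.null(md$Parent)) {
      p <- vapply(md$Parent, function(v)
        if (length(v)) as.character(v[[1L]]) else NA_character_, character(1))
      return(sub("^transcript:", "", p))
    }
    rep(NA_character_, nrow(md))
  }
  tid <- get_tid(md)
  gid <- if (!is.null(md$gene_id)) as.character(md$gene_id) else tid
  gsym <- if (!is.null(md$gene_name)) as.character(md$gene_name) else gid

  strand <- as.character(BiocGenerics::strand(gr))
  keep <- is_cds
  no_tid <- keep & (is.na(tid) | tid == "")
  if (any(no_tid)) {
    warning(sum(no_tid), " CDS feature(s) without transcript id skipped")
    keep <- keep & !no_tid
  }
  bad_strand <- keep & !(strand %in% c("+", "-"))
  if (any(bad_strand)) {
    warning(sum(bad_strand), " CDS feature(s) with unknown strand skipped")
    keep <- keep & !bad_strand
  }
  if (!any(keep)) stop("no usable CDS features in annotation: ", path)

  cds <- data.frame(
    transcript_id = tid[keep],
    start = BiocGenerics::start(gr)[keep],
    end = BiocGenerics::end(gr)[keep],
    stringsAsFactors = FALSE
  )
  first <- !duplicated(tid[keep])
  transcripts <- data.frame(
    transcript_id = tid[keep][first],
    gene_id = gid[keep][first],
    gene_symbol = gsym[keep][first],
    chrom = as.character(GenomicRanges::seqnames(gr))[keep][first],
    strand = strand[keep][first],
    stringsAsFactors = FALSE
  )
  utr3 <- NULL
  ku <- is_utr3 & !is.na(tid) & tid %in% transcripts$transcript_id
  if (any(ku)) {
    utr3 <- data.frame(
      transcript_id = tid[ku],
      start = BiocGenerics::start(gr)[ku],
      end = BiocGenerics::end(gr)[ku],
      stringsAsFactors = FALSE
    )
  }
  ts <- transcript_set(transcripts, cds, utr3)
  n_flag <- sum(!ts$transcripts$frame_ok)
  if (n_flag > 0)
    message(n_flag, " transcript(s) flagged: CDS length not divisible by 3")
  ts
}

chrom_seq <- function(genome, chrom) {
  if (!(chrom %in% names(genome)))
    stop("chromosome not in genome: ", chrom)
  genome[[chrom]]
}

splice_intervals <- function(genome, chrom, strand, iv) {
  seq <- chrom_seq(genome, chrom)
  if (any(iv$start < 1L) || any(iv$end > length(seq)))
    stop("interval out of chromosome bounds on ", chrom)
  parts <- Biostrings::extractAt(seq, IRanges::IRanges(iv$start, iv$end))
  out <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (strand == "-") out <- Biostrings::reverseComplement(out)
  as.character(out)
}

#' Extract the coding sequence of a transcript
#'
#' Concatenates the transcript's CDS intervals in genomic order and
#' reverse-complements the result for minus-strand transcripts, so that the
#' returned string reads 5' to 3' in coding orientation.
#'
#' @param genome A [Biostrings::DNAStringSet] from [read_fasta()].
#' @param ts A [transcript_set()].
#' @param transcript_id Single transcript identifier.
#' @param with_utr3 Also append the spliced 3' UTR sequence (coding
#'   orientation) after the CDS.
#' @return A character string. If the sequence contains N it is returned
#'   with attribute `has_n = TRUE` (callers must not translate it).
#' @export
extract_cds <- function(genome, ts, transcript_id, with_utr3 = FALSE) {
  tr <- ts$transcripts[ts$transcripts$transcript_id == transcript_id, ]
  if (nrow(tr) != 1L) stop("unknown transcript: ", transcript_id)
  iv <- ts$cds[ts$cds$transcript_id == transcript_id, , drop = FALSE]
  out <- splice_intervals(genome, tr$chrom, tr$strand, iv)
  if (with_utr3) {
    ivu <- ts$utr3[ts$utr3$transcript_id == transcript_id, , drop = FALSE]
    if (nrow(ivu) > 0L)
      out <- paste0(out, splice_intervals(genome, tr$chrom, tr$strand, ivu))
  }
  if (grepl("N", out, fixed = TRUE)) attr(out, "has_n") <- TRUE
  out
}

# Map genomic positions to 1-based coding coordinates of a transcript.
# Returns NA for positions outside the CDS.
coding_coord <- function(ts, transcript_id, gpos) {
  tr <- ts$transcripts[ts$transcripts$transcript_id == transcript_id, ]
  iv <- ts$cds[ts$cds$transcript_id == transcript_id, , drop = FALSE]
  widths <- iv$end - iv$start + 1L
  out <- rep(NA_integer_, length(gpos))
  if (tr$strand == "+") {
    off <- cumsum(c(0L, widths[-length(widths)]))
    for (i in seq_len(nrow(iv))) {
      hit <- gpos >= iv$start[i] & gpos <= iv$end[i]
      out[hit] <- off[i] + (gpos[hit] - iv$start[i]) + 1L
    }
  } else {
    # coding order walks intervals from the genomically last to first
    ord <- rev(seq_len(nrow(iv)))
    off <- cumsum(c(0L, widths[ord][-length(widths)]))
    for (j in seq_along(ord)) {
      i <- ord[j]
      hit <- gpos >= iv$start[i] & gpos <= iv$end[i]
      out[hit] <- off[j] + (iv$end[i] - gpos[hit]) + 1L
    }
  }
  out
}

# Inverse of coding_coord for a single coding position.
genomic_coord <- function(ts, transcript_id, cpos) {
  tr <- ts$transcripts[ts$transcripts$transcript_id == transcript_id, ]
  iv <- ts$cds[ts$cds$transcript_id == transcript_id, , drop = FALSE]
  widths <- iv$end - iv$start + 1L
  out <- rep(NA_integer_, length(cpos))
  if (tr$strand == "+") {
    off <- cumsum(c(0L, widths[-length(widths)]))
    for (i in seq_len(nrow(iv))) {
      hit <- cpos > off[i] & cpos <= off[i] + widths[i]
      out[hit] <- iv$start[i] + (cpos[hit] - off[i]) - 1L
    }
  } else {
    ord <- rev(seq_len(nrow(iv)))
    off <- cumsum(c(0L, widths[ord][-length(widths)]))
    for (j in seq_along(ord)) {
      i <- ord[j]
      hit <- cpos > off[j] & cpos <= off[j] + widths[ord[j]]
      out[hit] <- iv$end[i] - (cpos[hit] - off[j]) + 1L
    }
  }
  out
}
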