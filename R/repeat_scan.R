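#' Microsatellite scan parameters
#'
#' Minimum whole-unit counts per motif length. The defaults follow the
#' convention that homopolymer runs qualify only when they exceed five units
#' (strictly more than 5, i.e. >= 6), while motifs of 2-5 bp qualify from
#' three units. All minima are configurable because repeat-catalog dialects
#' differ (some count homopolymers from 5).
#'
#' @param min_units Named integer vector mapping motif length `"1"`..`"5"` to
#'   the minimum whole-unit count; all minima must be >= 2.
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(min_units = c(`1` = 6L, `2` = 3L, `3` = 3L,
                                      `4` = 3L, `5` = 3L)) {
  min_units <- setNames(as.integer(min_units), names(min_units))
  if (!identical(sort(names(min_units)), c("1", "2", "3", "4", "5")))
    stop("min_units must be named with motif lengths \"1\"..\"5\"")
  if (any(min_units < 2L)) stop("all minimum unit counts must be >= 2")
  structure(list(min_units = min_units[as.character(1:5)]),
            class = "scan_params")
}

# A motif is primitive when it is not a whole-number repetition of any
# shorter word.
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), k %/% d)) return(FALSE)
  }
  TRUE
}

#' Scan one sequence for maximal microsatellite tracts
#'
#' Finds maximal tracts of tandemly repeated primitive motifs of length 1-5
#' on the plus strand. Only whole repeat units are counted: a trailing
#' partial unit is excluded from the reported span. Tracts containing N are
#' never reported. Runs whose motif is itself a repetition of a shorter word
#' are suppressed (an `AAAA...` run is reported once with motif length 1,
#' never as motif `"AA"`). Scanning is left-to-right per motif length; after
#' a tract is emitted, scanning for that motif length resumes at the first
#' base after it, so tracts of one motif length never overlap.
#'
#' @param seq A character string, [Biostrings::DNAString], or single-element
#'   [Biostrings::DNAStringSet] over the alphabet A, C, G, T, N.
#' @param params A [scan_params()].
#' @param chrom Optional chromosome name recorded in the output.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based,
#'   inclusive), `motif` (as on the plus strand), `motif_len`, `unit_count`,
#'   sorted by `start` then `motif_len`. Empty input yields zero rows.
#' @export
scan_sequence <- function(seq, params = scan_params(), chrom = NA_character_) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), motif = character(),
                      motif_len = integer(), unit_count = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  x <- charToRaw(s)
  okbase <- x != charToRaw("N")
  res <- vector("list", 5L)
  for (k in 1:5) {
    minu <- params$min_units[[as.character(k)]]
    if (n < k * 2L) next
    # m[i] <- TRUE when base i matches base i+k and neither is N;
    # maximal TRUE-runs delimit period-k regions.
    m <- x[1:(n - k)] == x[(k + 1):n] & okbase[1:(n - k)] & okbase[(k + 1):n]
    r <- rle(m)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    last_end <- 0L
    starts <- integer(); ends <- integer(); motifs <- character()
    units <- integer()
    for (j in which(r$values)) {
      p <- run_start[j]
      region_end <- run_end[j] + k          # inclusive, in sequence coords
      a <- max(p, last_end + 1L)            # never overlap a previous tract
      L <- region_end - a + 1L
      u <- L %/% k
      if (u < minu) next
      motif <- rawToChar(x[a:(a + k - 1L)])
      if (!is_primitive_motif(motif)) next
      e <- a + k * u - 1L
      starts <- c(starts, a); ends <- c(ends, e)
      motifs <- c(motifs, motif); units <- c(units, u)
      last_end <- e
    }
    if (length(starts))
      res[[k]] <- data.frame(chrom = chrom, start = starts, end = ends,
                             motif = motifs, motif_len = k,
                             unit_count = units, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out <- out[order(out$start, out$motif_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reference brute-force microsatellite scanner
#'
#' Independent, position-by-position implementation used to validate
#' [scan_sequence()]: for each motif length it walks the sequence left to
#' right, counts whole repeat units of the motif starting at each position by
#' direct string comparison, emits a tract when the unit count meets the
#' threshold, and jumps past it. Shares no code with [scan_sequence()].
#'
#' @inheritParams scan_sequence
#' @return Same shape as [scan_sequence()].
#' @export
scan_sequence_ref <- function(seq, params = scan_params(),
                              chrom = NA_character_) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (k in 1:5) {
    minu <- params$min_units[[as.character(k)]]
    pos <- 1L
    while (pos + 2L * k - 1L <= n) {
      motif <- ch[pos:(pos + k - 1L)]
      ms <- paste(motif, collapse = "")
      if (any(motif == "N") || !is_primitive_motif(ms)) {
        pos <- pos + 1L
        next
      }
      u <- 1L
      while (pos + (u + 1L) * k - 1L <= n &&
             all(ch[(pos + u * k):(pos + (u + 1L) * k - 1L)] == motif))
        u <- u + 1L
      if (u >= minu) {
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = chrom, start = pos, end = pos + k * u - 1L,
                     motif = ms, motif_len = k, unit_count = u,
                     stringsAsFactors = FALSE)
        pos <- pos + k * u
      } else {
        pos <- pos + 1L
      }
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), motif = character(),
                      motif_len = integer(), unit_count = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$motif_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a whole genome for microsatellite tracts
#'
#' @param genome A named [Biostrings::DNAStringSet] from [read_fasta()].
#' @param params A [scan_params()].
#' @return data.frame as [scan_sequence()], one block per chromosome in
#'   genome order.
#' @export
scan_genome <- function(genome, params = scan_params()) {
  out <- lapply(names(genome), function(ch)
    scan_sequence(genome[[ch]], params, chrom = ch))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Restrict microsatellite loci to protein-coding regions
#'
#' A locus overlapping (by at least one base) a CDS interval of k transcripts
#' yields k (locus, transcript) pairs; loci with no CDS overlap are dropped.
#' Loci on chromosomes absent from the annotation are dropped with a warning.
#'
#' @param loci data.frame from [scan_genome()].
#' @param ts A [transcript_set()].
#' @return data.frame: the locus columns plus `transcript_id`, `gene_id`,
#'   `gene_symbol`, `strand`.
#' @export
intersect_coding <- function(loci, ts) {
  pairs0 <- data.frame(loci[0, , drop = FALSE],
                       transcript_id = character(), gene_id = character(),
                       gene_symbol = character(), strand = character(),
                       stringsAsFactors = FALSE)
  if (nrow(loci) == 0L) return(pairs0)
  known <- loci$chrom %in% ts$transcripts$chrom
  if (any(!known)) {
    warning(sum(!known), " locus/loci on chromosome(s) absent from the ",
            "annotation dropped: ",
            paste(unique(loci$chrom[!known]), collapse = ", "))
    loci <- loci[known, , drop = FALSE]
  }
  if (nrow(loci) == 0L) return(pairs0)
  cds_chrom <- ts$transcripts$chrom[match(ts$cds$transcript_id,
                                          ts$transcripts$transcript_id)]
  gr_loci <- GenomicRanges::GRanges(loci$chrom,
                                    IRanges::IRanges(loci$start, loci$end))
  gr_cds <- GenomicRanges::GRanges(cds_chrom,
                                   IRanges::IRanges(ts$cds$start, ts$cds$end))
  hits <- GenomicRanges::findOverlaps(gr_loci, gr_cds, minoverlap = 1L)
  li <- S4Vectors::queryHits(hits)
  ti <- ts$cds$transcript_id[S4Vectors::subjectHits(hits)]
  # one pair per (locus, transcript), even when several CDS intervals overlap
  key <- paste(li, ti)
  keep <- !duplicated(key)
  li <- li[keep]; ti <- ti[keep]
  mt <- match(ti, ts$transcripts$transcript_id)
  out <- data.frame(loci[li, , drop = FALSE],
                    transcript_id = ti,
                    gene_id = ts$transcripts$gene_id[mt],
                    gene_symbol = ts$transcripts$gene_symbol[mt],
                    strand = ts$transcripts$strand[mt],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$motif_len, out$transcript_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export loci as BED (0-based half-open) or TSV (1-based closed)
#'
#' @param loci data.frame from [scan_genome()].
#' @param path Output path.
#' @param format `"bed"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- data.frame(chrom = loci$chrom, start = loci$start - 1L,
                      end = loci$end,
                      name = paste0(loci$motif, "x", loci$unit_count))
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    write.table(loci[, c("chrom", "start", "end", "motif", "unit_count")],
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
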