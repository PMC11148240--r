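# Run expr under a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")
.NONSTOP_CODONS <- local({
  cods <- apply(expand.grid(.BASES, .BASES, .BASES), 1L, paste, collapse = "")
  setdiff(cods, .STOPS)
})

random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                collapse = "")

#' Synthetic-fixture specification
#'
#' Describes a small synthetic genome with planted microsatellite tracts
#' (coding, intronic and intergenic), gene models with 1-3 exons and a 3' UTR,
#' a tumor/normal expression design with planted differentially expressed
#' genes, and evidence-table coverage. The seed fully determines all outputs.
#'
#' @param preset `"small"` (default) or `"medium"` (same structure, roughly
#'   doubled sizes).
#' @param seed Integer seed.
#' @return list of fixture parameters (class `fixture_spec`).
#' @export
fixture_spec <- function(preset = c("small", "medium"), seed = 1L) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset, seed = as.integer(seed),
    n_chromosomes = 2L, n_genes = 6L,
    coding_tracts = data.frame(
      motif = c("A", "AC", "AGC", "T", "GA", "CAG"),
      units = c(8L, 4L, 3L, 7L, 5L, 4L),
      stringsAsFactors = FALSE),
    intron_tracts = data.frame(
      motif = c("A", "GT"), units = c(7L, 4L),
      gene = c(1L, 3L), stringsAsFactors = FALSE),
    intergenic_tracts = data.frame(
      motif = c("C", "TA"), units = c(9L, 4L),
      chrom = c(1L, 2L), stringsAsFactors = FALSE),
    cds_codons = 8:14,        # range for left/right codon blocks
    utr_random = 24L,         # random UTR bases before the stop-rich block
    intergenic_len = c(120L, 250L),
    intron_len = c(40L, 80L),
    n_genes_expr = 50L, n_normal = 20L, n_tumor = 20L,
    n_de = 5L, effect = 4, sdlog = 0.5, cohort = "COAD",
    evidence_fraction = 0.5)
  if (preset == "medium") {
    base$n_chromosomes <- 3L
    base$n_genes <- 12L
    base$coding_tracts <- rbind(
      base$coding_tracts,
      data.frame(motif = c("G", "CT", "TTG", "C", "AT", "GCC"),
                 units = c(9L, 5L, 4L, 8L, 4L, 3L),
                 stringsAsFactors = FALSE))
    base$n_genes_expr <- 100L
  }
  stopifnot(nrow(base$coding_tracts) == base$n_genes)
  ok <- vapply(base$coding_tracts$motif, is_primitive_motif, logical(1))
  if (!all(ok)) stop("planted motifs must be primitive")
  structure(base, class = "fixture_spec")
}

# Build one gene body in coding orientation. Returns the body string plus
# body-coordinate CDS/UTR intervals and tract positions.
build_gene_body <- function(spec, motif, units, n_exons, intron_tract) {
  k <- nchar(motif)
  L <- k * units
  tract <- strrep(motif, units)
  nl <- sample(spec$cds_codons, 1L)
  nr <- sample(spec$cds_codons, 1L)
  left <- paste0("ATG", paste(sample(.NONSTOP_CODONS, nl, TRUE),
                              collapse = ""))
  # flanking bases must not allow a whole-unit extension of the tract
  last_m <- substr(motif, k, k)
  first_m <- substr(motif, 1L, 1L)
  substr(left, nchar(left), nchar(left)) <-
    sample(setdiff(.BASES, last_m), 1L)
  right <- paste(sample(.NONSTOP_CODONS, nr, TRUE), collapse = "")
  substr(right, 1L, 1L) <- sample(setdiff(.BASES, first_m), 1L)
  pad <- (3L - L %% 3L) %% 3L
  if (pad > 0L) right <- paste0(right, random_dna(pad))
  cds <- paste0(left, tract, right, "TAA")
  cds_len <- nchar(cds)
  cstart <- nchar(left) + 1L
  cend <- cstart + L - 1L
  # exon cut points: between p and p+1, never inside the tract
  cand <- setdiff(seq_len(cds_len - 1L), cstart:(cend - 1L))
  cand <- cand[cand >= 4L & cand <= cds_len - 4L]
  cuts <- sort(sample(cand, min(n_exons - 1L, length(cand))))
  bounds <- c(0L, cuts, cds_len)
  exon_cds <- lapply(seq_len(length(bounds) - 1L), function(i)
    c(bounds[i] + 1L, bounds[i + 1L]))
  utr <- paste0(random_dna(spec$utr_random), "TAAATAAATAAA")
  # introns, with an optional planted intronic tract in the first intron
  n_int <- length(exon_cds) - 1L
  introns <- character(n_int)
  intron_tract_body <- NULL
  if (n_int > 0L) {
    for (j in seq_len(n_int)) {
      ilen <- sample(spec$intron_len[1]:spec$intron_len[2], 1L)
      introns[j] <- random_dna(ilen)
    }
    if (!is.null(intron_tract)) {
      it <- strrep(intron_tract$motif, intron_tract$units)
      kk <- nchar(intron_tract$motif)
      pre <- random_dna(15L)
      post <- random_dna(15L)
      substr(pre, nchar(pre), nchar(pre)) <-
        sample(setdiff(.BASES, substr(intron_tract$motif, kk, kk)), 1L)
      substr(post, 1L, 1L) <-
        sample(setdiff(.BASES, substr(intron_tract$motif, 1L, 1L)), 1L)
      introns[1L] <- paste0(pre, it, post)
      intron_tract_body <- c(nchar(pre) + 1L, nchar(pre) + nchar(it))
    }
  }
  # assemble body and body-coordinate intervals
  body <- ""
  cds_iv <- matrix(0L, nrow = length(exon_cds), ncol = 2L)
  intron_body_off <- NA_integer_
  for (i in seq_along(exon_cds)) {
    w <- exon_cds[[i]][2L] - exon_cds[[i]][1L] + 1L
    cds_iv[i, 1L] <- nchar(body) + 1L
    body <- paste0(body, substr(cds, exon_cds[[i]][1L], exon_cds[[i]][2L]))
    cds_iv[i, 2L] <- nchar(body)
    if (i <= n_int) {
      if (i == 1L) intron_body_off <- nchar(body)
      body <- paste0(body, introns[i])
    }
  }
  utr_iv <- c(nchar(body) + 1L, nchar(body) + nchar(utr))
  body <- paste0(body, utr)
  # body coordinates of the coding tract: cds coords shifted by the introns
  # preceding its exon
  shift <- 0L
  for (i in seq_along(exon_cds)) {
    if (cstart >= exon_cds[[i]][1L] && cend <= exon_cds[[i]][2L]) break
    shift <- shift + nchar(introns[i])
  }
  tract_body <- c(cstart + shift, cend + shift)
  it_body <- if (!is.null(intron_tract_body))
    intron_tract_body + intron_body_off else NULL
  list(body = body, cds_iv = cds_iv, utr_iv = utr_iv,
       tract_body = tract_body, tract_cds = c(cstart, cend),
       intron_tract_body = it_body)
}

# body coordinate interval -> genomic interval, given gene start and strand
body_to_genomic <- function(iv, gstart, body_len, strand) {
  if (strand == "+") c(gstart + iv[1L] - 1L, gstart + iv[2L] - 1L)
  else c(gstart + body_len - iv[2L], gstart + body_len - iv[1L])
}

#' Generate a synthetic genome with planted microsatellite truth
#'
#' Writes `genome.fa`, `annotation.gtf`, `truth_loci.tsv` and
#' `truth_peptides.tsv` to `dir`. The background sequence is purged of
#' accidental qualifying tracts by targeted point mutations until a full
#' genome scan reports exactly the planted loci, so counting assertions on
#' the fixture are exact. The truth table lists, for every planted coding
#' tract and each canonical deletion (1 and 2 bp), the expected
#' junction-excluded downstream peptide computed with the literal
#' edit-and-translate oracle [downstream_peptide_ref()].
#'
#' A random draw can be infeasible: the frameshifted tail of a planted tract
#' may hit a stop codon at its very first junction-excluded codon and yield
#' no peptide. Such draws are resampled deterministically (derived sub-seeds,
#' bounded attempts), so the same spec seed always yields the same files and
#' every truth row carries a non-empty peptide.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return list with `genome`, `ts`, `truth_loci`, `truth_peptides`, `paths`;
#'   files written as a side effect.
#' @export
make_genome <- function(spec, dir) {
  last_err <- NULL
  for (attempt in 0:49) {
    out <- tryCatch(
      make_genome_once(spec, dir, seed = spec$seed + 7919L * attempt),
      fixture_infeasible = function(e) e)
    if (!inherits(out, "condition")) return(out)
    last_err <- out
  }
  stop("fixture construction did not produce a feasible draw: ",
       conditionMessage(last_err))
}

fixture_infeasible <- function(msg) {
  stop(structure(class = c("fixture_infeasible", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

make_genome_once <- function(spec, dir, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    n_genes <- spec$n_genes
    gene_chrom <- rep(seq_len(spec$n_chromosomes), length.out = n_genes)
    gene_strand <- rep(c("+", "-"), length.out = n_genes)
    # genes carrying an intronic tract need at least 2 exons
    n_exons <- sample(1:3, n_genes, replace = TRUE)
    n_exons[spec$intron_tracts$gene] <- pmax(2L,
                                             n_exons[spec$intron_tracts$gene])
    bodies <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      itr <- spec$intron_tracts[spec$intron_tracts$gene == g, , drop = FALSE]
      bodies[[g]] <- build_gene_body(
        spec, spec$coding_tracts$motif[g], spec$coding_tracts$units[g],
        n_exons[g], if (nrow(itr)) itr[1L, ] else NULL)
    }
    # assemble chromosomes
    chroms <- setNames(vector("list", spec$n_chromosomes),
                       paste0("chr", seq_len(spec$n_chromosomes)))
    gene_gstart <- integer(n_genes)
    planted <- list()   # genomic truth of every planted tract
    ilen <- function() sample(spec$intergenic_len[1]:spec$intergenic_len[2],
                              1L)
    for (ci in seq_len(spec$n_chromosomes)) {
      s <- random_dna(ilen())
      # optional intergenic tract at the start region of the chromosome
      igt <- spec$intergenic_tracts[spec$intergenic_tracts$chrom == ci, ,
                                    drop = FALSE]
      for (r in seq_len(nrow(igt))) {
        it <- strrep(igt$motif[r], igt$units[r])
        kk <- nchar(igt$motif[r])
        pre <- random_dna(30L)
        substr(pre, nchar(pre), nchar(pre)) <-
          sample(setdiff(.BASES, substr(igt$motif[r], kk, kk)), 1L)
        post <- random_dna(20L)
        substr(post, 1L, 1L) <-
          sample(setdiff(.BASES, substr(igt$motif[r], 1L, 1L)), 1L)
        start_pos <- nchar(s) + nchar(pre) + 1L
        s <- paste0(s, pre, it, post)
        planted[[length(planted) + 1L]] <- data.frame(
          chrom = paste0("chr", ci), start = start_pos,
          end = start_pos + nchar(it) - 1L,
          motif_plus = igt$motif[r], motif_len = kk,
          unit_count = igt$units[r], placement = "intergenic",
          gene = NA_integer_, stringsAsFactors = FALSE)
      }
      for (g in which(gene_chrom == ci)) {
        gene_gstart[g] <- nchar(s) + 1L
        b <- bodies[[g]]$body
        if (gene_strand[g] == "-") b <- revcomp_chr(b)
        s <- paste0(s, b, random_dna(ilen()))
      }
      chroms[[ci]] <- s
    }
    # genomic coordinates of gene features and planted genic tracts
    tx <- data.frame(transcript_id = sprintf("TX%02d", seq_len(n_genes)),
                     gene_id = sprintf("G%02d", seq_len(n_genes)),
                     gene_symbol = sprintf("GENE%02d", seq_len(n_genes)),
                     chrom = paste0("chr", gene_chrom),
                     strand = gene_strand, stringsAsFactors = FALSE)
    cds_rows <- list(); utr_rows <- list()
    for (g in seq_len(n_genes)) {
      bd <- bodies[[g]]
      blen <- nchar(bd$body)
      for (i in seq_len(nrow(bd$cds_iv))) {
        gi <- body_to_genomic(bd$cds_iv[i, ], gene_gstart[g], blen,
                              gene_strand[g])
        cds_rows[[length(cds_rows) + 1L]] <- data.frame(
          transcript_id = tx$transcript_id[g], start = gi[1L], end = gi[2L])
      }
      gu <- body_to_genomic(bd$utr_iv, gene_gstart[g], blen, gene_strand[g])
      utr_rows[[length(utr_rows) + 1L]] <- data.frame(
        transcript_id = tx$transcript_id[g], start = gu[1L], end = gu[2L])
      gt <- body_to_genomic(bd$tract_body, gene_gstart[g], blen,
                            gene_strand[g])
      planted[[length(planted) + 1L]] <- data.frame(
        chrom = tx$chrom[g], start = gt[1L], end = gt[2L],
        motif_plus = NA_character_,
        motif_len = nchar(spec$coding_tracts$motif[g]),
        unit_count = spec$coding_tracts$units[g], placement = "CDS",
        gene = g, stringsAsFactors = FALSE)
      if (!is.null(bd$intron_tract_body)) {
        itr <- spec$intron_tracts[spec$intron_tracts$gene == g, ][1L, ]
        gti <- body_to_genomic(bd$intron_tract_body, gene_gstart[g], blen,
                               gene_strand[g])
        planted[[length(planted) + 1L]] <- data.frame(
          chrom = tx$chrom[g], start = gti[1L], end = gti[2L],
          motif_plus = NA_character_, motif_len = nchar(itr$motif),
          unit_count = itr$units, placement = "intron",
          gene = g, stringsAsFactors = FALSE)
      }
    }
    planted <- do.call(rbind, planted)
    # plus-strand motif of each planted tract, read off the sequence itself
    planted$motif_plus <- vapply(seq_len(nrow(planted)), function(i)
      substr(chroms[[planted$chrom[i]]], planted$start[i],
             planted$start[i] + planted$motif_len[i] - 1L), character(1))

    # purge accidental tracts: mutate one base inside each offending locus
    # (outside every planted span) until the scan reports exactly the truth
    params <- scan_params()
    planted_key <- paste(planted$chrom, planted$start, planted$end,
                         planted$motif_plus)
    in_planted <- function(chrom, pos)
      any(planted$chrom == chrom & pos >= planted$start & pos <= planted$end)
    for (iter in 1:200) {
      genome <- Biostrings::DNAStringSet(unlist(chroms))
      loci <- scan_genome(genome, params)
      key <- paste(loci$chrom, loci$start, loci$end, loci$motif)
      extra <- loci[!(key %in% planted_key), , drop = FALSE]
      missing <- setdiff(planted_key, key)
      if (nrow(extra) == 0L && length(missing) == 0L) break
      if (length(missing) > 0L && nrow(extra) == 0L)
        fixture_infeasible(paste("planted locus not recovered:",
                                 paste(missing, collapse = "; ")))
      for (i in seq_len(nrow(extra))) {
        pos <- extra$start[i]:extra$end[i]
        pos <- pos[!vapply(pos, function(p)
          in_planted(extra$chrom[i], p), logical(1))]
        if (!length(pos))
          fixture_infeasible("cannot purge locus inside planted span")
        p <- sample(pos, 1L)
        cur <- substr(chroms[[extra$chrom[i]]], p, p)
        substr(chroms[[extra$chrom[i]]], p, p) <-
          sample(setdiff(.BASES, cur), 1L)
      }
      if (iter == 200L)
        fixture_infeasible("background purge did not converge")
    }
    genome <- Biostrings::DNAStringSet(unlist(chroms))

    ts <- transcript_set(tx, do.call(rbind, cds_rows),
                         do.call(rbind, utr_rows))

    # truth peptides via the independent edit-and-translate oracle
    truth_pep <- list()
    coding <- planted[planted$placement == "CDS", , drop = FALSE]
    for (i in seq_len(nrow(coding))) {
      g <- coding$gene[i]
      tid <- tx$transcript_id[g]
      seq <- extract_cds(genome, ts, tid, with_utr3 = TRUE)
      span <- tract_coding_span(ts, tid, coding$chrom[i], coding$start[i],
                                coding$end[i])
      for (d in c(1L, 2L)) {
        o <- downstream_peptide_ref(seq, span$cend, edit = "del", size = d,
                                    at = span$cend - d + 1L)
        truth_pep[[length(truth_pep) + 1L]] <- data.frame(
          transcript_id = tid, gene_symbol = tx$gene_symbol[g],
          chrom = coding$chrom[i], locus_start = coding$start[i],
          locus_end = coding$end[i], motif = coding$motif_plus[i],
          del_len = d, frame_class = (-d) %% 3L,
          peptide = o$peptide, non_stop = o$non_stop,
          stringsAsFactors = FALSE)
      }
    }
    truth_pep <- do.call(rbind, truth_pep)
    if (anyNA(truth_pep$peptide))
      fixture_infeasible("a planted tract yields no peptide")

    paths <- list(
      genome = file.path(dir, "genome.fa"),
      gtf = file.path(dir, "annotation.gtf"),
      truth_loci = file.path(dir, "truth_loci.tsv"),
      truth_peptides = file.path(dir, "truth_peptides.tsv"))
    write_fasta(genome, paths$genome)
    write_gtf(ts, paths$gtf)
    loci_out <- planted
    names(loci_out)[names(loci_out) == "motif_plus"] <- "motif"
    loci_out$gene <- NULL
    write.table(loci_out, paths$truth_loci, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(truth_pep, paths$truth_peptides, sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(genome = genome, ts = ts, truth_loci = loci_out,
         truth_peptides = truth_pep, paths = paths)
  })
}

# Minimal GTF writer for fixture annotations (CDS + three_prime_utr, plus
# informational transcript lines).
write_gtf <- function(ts, path) {
  lines <- character()
  for (i in seq_len(nrow(ts$transcripts))) {
    t <- ts$transcripts[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     t$gene_id, t$transcript_id, t$gene_symbol)
    iv <- ts$cds[ts$cds$transcript_id == t$transcript_id, , drop = FALSE]
    ivu <- ts$utr3[ts$utr3$transcript_id == t$transcript_id, , drop = FALSE]
    span <- range(c(iv$start, iv$end, ivu$start, ivu$end))
    lines <- c(lines,
      paste(t$chrom, "msneoforge", "transcript", span[1L], span[2L], ".",
            t$strand, ".", attrs, sep = "\t"),
      vapply(seq_len(nrow(iv)), function(j)
        paste(t$chrom, "msneoforge", "CDS", iv$start[j], iv$end[j], ".",
              t$strand, "0", attrs, sep = "\t"), character(1)),
      vapply(seq_len(nrow(ivu)), function(j)
        paste(t$chrom, "msneoforge", "three_prime_utr", ivu$start[j],
              ivu$end[j], ".", t$strand, ".", attrs, sep = "\t"),
        character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic expression matrix with planted DE genes
#'
#' Null genes share one log-normal distribution across both groups; planted
#' DE genes are shifted multiplicatively in the tumor group by the spec's
#' effect size. Writes `expression.tsv`, `samples.tsv` and `truth_de.tsv`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return list with `expr` (matrix), `meta`, `truth_de` (character vector).
#' @export
make_expression <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed + 1L, {
    genes <- sprintf("GENE%02d", seq_len(spec$n_genes_expr))
    n_n <- spec$n_normal
    n_t <- spec$n_tumor
    samples <- c(sprintf("N%02d", seq_len(n_n)), sprintf("T%02d",
                                                         seq_len(n_t)))
    group <- c(rep("normal", n_n), rep("tumor", n_t))
    meanlog <- runif(length(genes), log(20), log(200))
    expr <- matrix(0, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
    for (i in seq_along(genes))
      expr[i, ] <- rlnorm(length(samples), meanlog[i], spec$sdlog)
    de_genes <- sort(sample(genes, spec$n_de))
    expr[de_genes, group == "tumor"] <-
      expr[de_genes, group == "tumor"] * spec$effect
    meta <- data.frame(sample = samples, cohort = spec$cohort,
                       group = group,
                       msi_status = ifelse(group == "tumor",
                                           sample(c("MSI-H", "MSS"),
                                                  length(samples),
                                                  replace = TRUE), "NA"),
                       stringsAsFactors = FALSE)
    write.table(data.frame(gene = genes, round(expr, 3),
                           check.names = FALSE),
                file.path(dir, "expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(meta, file.path(dir, "samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(de_genes, file.path(dir, "truth_de.tsv"))
    list(expr = expr, meta = meta, truth_de = de_genes)
  })
}

#' Generate synthetic evidence tables for a variant/peptide set
#'
#' A stated fraction of variants receives dbSNP-like and ClinVar-like rows
#' (keys normalized exactly like the pipeline's VCF emission), and the same
#' fraction of deduplicated peptides contributes one 9-mer window each to an
#' IEDB-like table. Writes `dbsnp.tsv`, `clinvar.tsv`, `iedb.tsv`.
#'
#' @param spec A [fixture_spec()].
#' @param variants data.frame from [frameshift_variants()].
#' @param dedup data.frame from [deduplicate_peptides()].
#' @param dir Output directory.
#' @param fraction Fraction of keys covered; defaults to the spec's.
#' @return list of the three evidence data.frames (pipeline format).
#' @export
make_evidence <- function(spec, variants, dedup, dir,
                          fraction = spec$evidence_fraction) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed + 2L, {
    vk <- unique(variants$variant_key[variants$vcf_ok])
    n_pick <- round(fraction * length(vk))
    pick <- sort(sample(vk, n_pick))
    parts <- strsplit(pick, ":", fixed = TRUE)
    vdf <- data.frame(chrom = vapply(parts, `[[`, "", 1L),
                      pos = as.integer(vapply(parts, `[[`, "", 2L)),
                      ref = vapply(parts, `[[`, "", 3L),
                      alt = vapply(parts, `[[`, "", 4L),
                      stringsAsFactors = FALSE)
    dbsnp <- cbind(vdf, rsid = sprintf("rs%06d", seq_len(nrow(vdf))),
                   freq = round(runif(nrow(vdf), 0.001, 0.3), 4))
    clinvar <- cbind(vdf,
                     phenotype = sample(c("colorectal cancer",
                                          "Lynch syndrome",
                                          "not provided"),
                                        nrow(vdf), replace = TRUE))
    n_pep <- round(fraction * nrow(dedup))
    idx <- sort(sample(seq_len(nrow(dedup)), n_pep))
    nines <- vapply(dedup$peptide[idx], function(p) {
      if (nchar(p) < 9L) return(NA_character_)
      off <- sample(seq_len(nchar(p) - 8L), 1L)
      substr(p, off, off + 8L)
    }, character(1))
    nines <- nines[!is.na(nines)]
    iedb <- data.frame(key = nines, assay = rep("ELISPOT", length(nines)),
                       stringsAsFactors = FALSE)
    write.table(dbsnp, file.path(dir, "dbsnp.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(clinvar, file.path(dir, "clinvar.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(iedb, file.path(dir, "iedb.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ev_df <- function(key_type, key, source, payload)
      data.frame(key_type = rep(key_type, length(key)), key = key,
                 source = rep(source, length(key)),
                 payload = if (length(key)) payload else character(0),
                 stringsAsFactors = FALSE)
    list(
      dbsnp = ev_df("variant", pick, "dbsnp",
                    paste0("rsid=", dbsnp$rsid, "|freq=", dbsnp$freq)),
      clinvar = ev_df("variant", pick, "clinvar",
                      paste0("phenotype=", clinvar$phenotype)),
      iedb = ev_df("peptide", iedb$key, "iedb",
                   paste0("assay=", iedb$assay)))
  })
}

#' Run the full pipeline on a fixture directory
#'
#' Reads `genome.fa` and `annotation.gtf` from `dir`, scans for
#' microsatellites, restricts to coding loci, emits canonical variants (VCF),
#' generates deduplicated junction-excluded frameshift peptides (FASTA +
#' sources TSV), enumerates and filters MHC class I and II epitope
#' candidates, joins any evidence tables found in `dir`, labels DE genes if
#' expression tables are present, builds the store, and checks coverage of
#' the truth peptides.
#'
#' @param dir Fixture directory (from [make_genome()] and friends).
#' @param out_dir Output directory (default `dir`).
#' @param predictors Predictor plug-ins; default three toy predictors, which
#'   emulates aggregating over several independent algorithms.
#' @param threshold_nM Inclusion threshold on best IC50.
#' @param class_i_lengths,class_ii_lengths Window lengths per MHC class.
#' @return list with every intermediate table, the store, the coverage
#'   result and a `counts` summary vector.
#' @export
run_all <- function(dir, out_dir = dir,
                    predictors = list(toy_predictor("toyA"),
                                      toy_predictor("toyB"),
                                      toy_predictor("toyC")),
                    threshold_nM = 50,
                    class_i_lengths = 8:11, class_ii_lengths = 15L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_fasta(file.path(dir, "genome.fa"))
  ts <- read_annotation(file.path(dir, "annotation.gtf"), dialect = "gtf")
  loci <- scan_genome(genome)
  pairs <- intersect_coding(loci, ts)
  variants <- frameshift_variants(pairs, ts, genome)
  write_variants_vcf(variants, file.path(out_dir, "variants.vcf"), genome)
  peps <- frameshift_peptides(variants, ts, genome)
  dedup <- deduplicate_peptides(peps)
  write_peptides_fasta(dedup, file.path(out_dir, "peptides.fa"))
  write.table(dedup, file.path(out_dir, "peptide_sources.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cand_i <- enumerate_epitopes(dedup, allele_panel("I"),
                               lengths = class_i_lengths,
                               predictors = predictors,
                               threshold_nM = threshold_nM)
  cand_ii <- enumerate_epitopes(dedup, allele_panel("II"),
                                lengths = class_ii_lengths,
                                predictors = predictors,
                                threshold_nM = threshold_nM)
  candidates <- rbind(cand_i, cand_ii)

  evidence <- NULL
  ev_specs <- list(c("dbsnp.tsv", "variant", "dbsnp"),
                   c("clinvar.tsv", "variant", "clinvar"),
                   c("iedb.tsv", "peptide", "iedb"))
  for (e in ev_specs) {
    f <- file.path(dir, e[1L])
    if (file.exists(f))
      evidence <- rbind(evidence, read_evidence(f, e[2L], e[3L]))
  }
  if (!is.null(evidence)) candidates <- join_evidence(candidates, evidence)

  expr <- NULL; meta <- NULL; de <- NULL
  if (file.exists(file.path(dir, "expression.tsv")) &&
      file.exists(file.path(dir, "samples.tsv"))) {
    ex <- read_expression(file.path(dir, "expression.tsv"),
                          file.path(dir, "samples.tsv"))
    expr <- ex$expr; meta <- ex$meta
    de <- label_de_genes(expr, meta$group)
    de_genes <- de$gene[de$de]
    candidates$gene_de <- vapply(
      strsplit(candidates$gene_symbols, ",", fixed = TRUE),
      function(g) any(g %in% de_genes), logical(1))
  }

  store_path <- file.path(out_dir, "neoantigens.neostore")
  store <- build_store(candidates, dedup, variants, evidence, expr, meta,
                       path = store_path)

  coverage <- NULL
  tp <- file.path(dir, "truth_peptides.tsv")
  if (file.exists(tp)) {
    truth <- read.delim(tp, stringsAsFactors = FALSE)
    coverage <- coverage_check(store, truth$peptide, where = "peptides")
  }
  list(genome = genome, ts = ts, loci = loci, pairs = pairs,
       variants = variants, peptides = peps, dedup = dedup,
       candidates = candidates, de = de, store = store,
       store_path = store_path, coverage = coverage,
       counts = c(n_loci = nrow(loci), n_coding_pairs = nrow(pairs),
                  n_coding_loci = length(unique(paste(
                    pairs$chrom, pairs$start, pairs$end, pairs$motif))),
                  n_variants = nrow(variants),
                  n_unique_peptides = nrow(dedup),
                  n_class_i = nrow(cand_i), n_class_ii = nrow(cand_ii)))
}
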