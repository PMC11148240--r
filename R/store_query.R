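#' Build the portable single-file candidate store
#'
#' Persists the pipeline's relational tables (deduplicated peptides, epitope
#' candidates with annotations, canonical variants, raw evidence, expression
#' matrix and sample metadata) in one file. All tables are sorted on their
#' natural keys before writing, so rebuilding from the same inputs yields
#' identical logical content.
#'
#' @param candidates data.frame from [enumerate_epitopes()] (both MHC classes
#'   rbind-ed), optionally after [join_evidence()].
#' @param peptides data.frame from [deduplicate_peptides()].
#' @param variants data.frame from [frameshift_variants()], or NULL.
#' @param evidence data.frame from [read_evidence()], or NULL.
#' @param expr,meta Expression matrix and sample metadata, or NULL.
#' @param path File path for the store (conventionally `.neostore`).
#' @return The `neo_store` object, invisibly. Side effect: store written to
#'   `path`.
#' @export
build_store <- function(candidates, peptides, variants = NULL,
                        evidence = NULL, expr = NULL, meta = NULL, path) {
  need <- c("epitope", "allele", "mhc_class", "best", "median", "mean")
  miss <- setdiff(need, names(candidates))
  if (length(miss))
    stop("candidate table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(c("peptide_id", "peptide") %in% names(peptides)))
    stop("peptide table is missing column(s): peptide_id and/or peptide")
  candidates <- candidates[order(candidates$gene_symbols,
                                 candidates$epitope, candidates$allele), ,
                           drop = FALSE]
  rownames(candidates) <- NULL
  peptides <- peptides[order(peptides$peptide_id), , drop = FALSE]
  rownames(peptides) <- NULL
  if (!is.null(variants)) {
    variants <- variants[order(variants$chrom, variants$locus_start,
                               variants$transcript_id, variants$del_len), ,
                         drop = FALSE]
    rownames(variants) <- NULL
  }
  store <- structure(list(
    tables = list(candidates = candidates, peptides = peptides,
                  variants = variants, evidence = evidence,
                  expression = expr, samples = meta),
    version = 1L), class = "neo_store")
  saveRDS(store, path)
  invisible(store)
}

#' Read a store file written by [build_store()]
#'
#' @param path Store file path.
#' @return A `neo_store` object.
#' @export
read_store <- function(path) {
  store <- readRDS(path)
  if (!inherits(store, "neo_store")) stop("not a msneoforge store: ", path)
  store
}

#' @export
print.neo_store <- function(x, ...) {
  cat("neo_store:", nrow(x$tables$candidates), "candidates,",
      nrow(x$tables$peptides), "peptides,",
      if (is.null(x$tables$variants)) 0L else nrow(x$tables$variants),
      "variants\n")
  invisible(x)
}

#' Search stored neoantigen candidates
#'
#' All set filters are combined conjunctively; at least one filter must be
#' set (an unbounded query is an error). Results are ordered by gene,
#' epitope, allele.
#'
#' @param store A `neo_store`.
#' @param gene Gene symbol(s); matches candidates carrying any of them.
#' @param epitope Epitope query string.
#' @param epitope_exact When FALSE, `epitope` matches as a substring.
#' @param alleles Allele name(s).
#' @param mhc_class `"I"` or `"II"`.
#' @param statistic Affinity statistic the cutoff applies to: `"best"`
#'   (default, mirrors the inclusion rule) or `"median"`.
#' @param cutoff_nM Keep rows with `statistic < cutoff_nM`.
#' @param limit,offset Pagination (rows after ordering).
#' @return data.frame of matching candidate rows.
#' @export
neo_search <- function(store, gene = NULL, epitope = NULL,
                       epitope_exact = TRUE, alleles = NULL,
                       mhc_class = NULL, statistic = c("best", "median"),
                       cutoff_nM = NULL, limit = NULL, offset = 0L) {
  statistic <- match.arg(statistic)
  if (is.null(gene) && is.null(epitope) && is.null(alleles) &&
      is.null(mhc_class) && is.null(cutoff_nM))
    stop("at least one filter must be set (unbounded query)")
  d <- store$tables$candidates
  keep <- rep(TRUE, nrow(d))
  if (!is.null(gene)) {
    gl <- strsplit(d$gene_symbols, ",", fixed = TRUE)
    keep <- keep & vapply(gl, function(g) any(g %in% gene), logical(1))
  }
  if (!is.null(epitope)) {
    keep <- keep & if (epitope_exact) d$epitope == epitope
                   else grepl(epitope, d$epitope, fixed = TRUE)
  }
  if (!is.null(alleles)) keep <- keep & d$allele %in% alleles
  if (!is.null(mhc_class)) keep <- keep & d$mhc_class %in% mhc_class
  if (!is.null(cutoff_nM)) keep <- keep & d[[statistic]] < cutoff_nM
  out <- d[keep, , drop = FALSE]
  out <- out[order(out$gene_symbols, out$epitope, out$allele), , drop = FALSE]
  if (offset > 0L) out <- out[-seq_len(min(offset, nrow(out))), , drop = FALSE]
  if (!is.null(limit)) out <- head(out, limit)
  rownames(out) <- NULL
  out
}

#' Best neoantigens per allele
#'
#' For each requested allele, returns stored candidates whose chosen affinity
#' statistic is below the cutoff, optionally restricted to the most highly
#' expressed genes of a cohort, ranked ascending by the statistic. Unknown
#' alleles produce a warning and an empty block.
#'
#' @param store A `neo_store`.
#' @param alleles Non-empty character vector of allele names.
#' @param statistic `"median"` (default) or `"best"`.
#' @param cutoff_nM Affinity cutoff in nM.
#' @param expression_filter Optional list with elements `cohort` and
#'   optionally `top_fraction` (default 0.2) and `stat`; applied with
#'   [expression_percentile_filter()] using the store's expression tables.
#' @return data.frame of ranked rows (column `allele` groups the blocks).
#' @export
neo_best <- function(store, alleles, statistic = c("median", "best"),
                     cutoff_nM, expression_filter = NULL) {
  statistic <- match.arg(statistic)
  if (length(alleles) == 0L) stop("alleles must be non-empty")
  d <- store$tables$candidates
  unknown <- setdiff(alleles, unique(d$allele))
  if (length(unknown))
    warning("allele(s) not in store: ", paste(unknown, collapse = ", "))
  if (!is.null(expression_filter)) {
    if (is.null(store$tables$expression) || is.null(store$tables$samples))
      stop("store has no expression tables")
    d <- expression_percentile_filter(
      d, store$tables$expression, store$tables$samples,
      cohort = expression_filter$cohort,
      top_fraction = expression_filter$top_fraction %||% 0.2,
      stat = expression_filter$stat %||% "mean")
  }
  blocks <- lapply(alleles, function(a) {
    b <- d[d$allele == a & d[[statistic]] < cutoff_nM, , drop = FALSE]
    b[order(b[[statistic]]), , drop = FALSE]
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
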