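#' Read an evidence table
#'
#' Evidence rows are generic joins keyed by variant (normalized
#' `chrom:pos:ref:alt`, left-aligned and anchored like the emitted VCF),
#' exact peptide string, or gene symbol. TSV input must carry either the
#' columns `chrom`, `pos`, `ref`, `alt` (variant-keyed) or a `key` column;
#' all remaining columns form the payload. Malformed rows (missing key
#' fields) are skipped with a warning.
#'
#' @param path TSV file with a header line.
#' @param key_type `"variant"`, `"peptide"` or `"gene"`.
#' @param source Label recorded on every row (e.g. `"dbsnp"`, `"clinvar"`,
#'   `"iedb"`).
#' @return data.frame with columns `key_type`, `key`, `source`, `payload`.
#' @export
read_evidence <- function(path, key_type = c("variant", "peptide", "gene"),
                          source) {
  key_type <- match.arg(key_type)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (key_type == "variant" &&
      all(c("chrom", "pos", "ref", "alt") %in% names(df))) {
    key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
    payload_cols <- setdiff(names(df), c("chrom", "pos", "ref", "alt"))
    bad <- is.na(df$chrom) | is.na(df$pos) | !nzchar(df$ref) | !nzchar(df$alt)
  } else if ("key" %in% names(df)) {
    key <- as.character(df$key)
    payload_cols <- setdiff(names(df), "key")
    bad <- is.na(key) | !nzchar(key)
  } else {
    stop("evidence table needs chrom/pos/ref/alt or a 'key' column: ", path)
  }
  if (any(bad)) {
    warning(sum(bad), " malformed evidence row(s) skipped in ", path)
    df <- df[!bad, , drop = FALSE]
    key <- key[!bad]
  }
  payload <- if (length(payload_cols))
    do.call(paste, c(lapply(payload_cols, function(cn)
      paste0(cn, "=", df[[cn]])), sep = "|"))
  else rep("", nrow(df))
  data.frame(key_type = key_type, key = key, source = source,
             payload = payload, stringsAsFactors = FALSE)
}

#' Left-join evidence onto epitope candidates
#'
#' Every candidate is retained. Variant-keyed evidence matches any of the
#' candidate's `variant_keys`; peptide-keyed evidence matches the epitope
#' string exactly; gene-keyed evidence matches any of the candidate's
#' `gene_symbols`. Multiple matches are concatenated deterministically
#' (sorted by source, then key, then payload) into one annotation column per
#' evidence source, named `annot_<source>`.
#'
#' @param candidates data.frame from [enumerate_epitopes()].
#' @param evidence data.frame from [read_evidence()] (or several rbind-ed).
#' @return `candidates` with one extra character column per evidence source
#'   (empty string = no match). Row count is unchanged.
#' @export
join_evidence <- function(candidates, evidence) {
  out <- candidates
  if (nrow(candidates) == 0L || is.null(evidence) || nrow(evidence) == 0L)
    return(out)
  cand_keys <- list(
    variant = strsplit(candidates$variant_keys, ";", fixed = TRUE),
    peptide = as.list(candidates$epitope),
    gene = strsplit(candidates$gene_symbols, ",", fixed = TRUE))
  for (src in sort(unique(evidence$source))) {
    ev <- evidence[evidence$source == src, , drop = FALSE]
    ev <- ev[order(ev$source, ev$key, ev$payload), , drop = FALSE]
    col <- character(nrow(candidates))
    for (kt in unique(ev$key_type)) {
      evk <- ev[ev$key_type == kt, , drop = FALSE]
      ann <- paste0(evk$key, ":", evk$payload)
      hit <- lapply(cand_keys[[kt]], function(keys) {
        m <- evk$key %in% keys
        if (any(m)) ann[m] else character()
      })
      add <- vapply(hit, paste, character(1), collapse = ";")
      col <- ifelse(nzchar(col) & nzchar(add),
                    paste(col, add, sep = ";"),
                    paste0(col, add))
    }
    out[[paste0("annot_", src)]] <- col
  }
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment, returned in input order.
#'
#' @param pvalues Numeric vector in \[0, 1\] (no NA).
#' @return Adjusted values, each >= its raw value, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1] with no NA")
  p.adjust(pvalues, method = "BH")
}

#' Label differentially expressed genes between two groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test between the two groups, BH
#' adjustment over all tested genes, flag when adjusted p < alpha. Genes with
#' zero variance across all samples are untested (NA p-values) and never
#' flagged.
#'
#' @param expr Numeric matrix, genes x samples, with rownames (gene ids) and
#'   colnames (sample ids); values non-negative.
#' @param groups Character/factor of length `ncol(expr)` with exactly two
#'   levels (e.g. `"normal"`, `"tumor"`); each group needs >= 2 samples.
#' @param alpha Adjusted-p threshold, default 0.05.
#' @return data.frame `gene`, `p`, `padj`, `de` (logical).
#' @export
label_de_genes <- function(expr, groups, alpha = 0.05) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required")
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 samples")
  if (length(groups) != ncol(expr))
    stop("groups must have one label per expression column")
  g1 <- groups == levels(groups)[1L]
  constant <- apply(expr, 1L, function(x) max(x) == min(x))
  p <- rep(NA_real_, nrow(expr))
  for (i in which(!constant)) {
    p[i] <- suppressWarnings(
      wilcox.test(expr[i, g1], expr[i, !g1], exact = FALSE)$p.value)
  }
  padj <- rep(NA_real_, nrow(expr))
  padj[!constant] <- bh_adjust(p[!constant])
  data.frame(gene = rownames(expr), p = p, padj = padj,
             de = !is.na(padj) & padj < alpha,
             stringsAsFactors = FALSE)
}

#' Keep candidates from the most highly expressed genes of a cohort
#'
#' Genes are ranked by their mean (or median) expression over the samples of
#' the named cohort; candidates whose gene falls within the top fraction are
#' retained. Ties at the cutoff value are all retained.
#'
#' @param candidates data.frame with a `gene_symbols` column (`,`-collapsed;
#'   a candidate is retained when any of its genes qualifies).
#' @param expr Numeric matrix genes x samples (rownames, colnames).
#' @param meta data.frame with columns `sample` and `cohort` describing the
#'   expression columns.
#' @param cohort Cohort name to rank within.
#' @param top_fraction Fraction of genes kept, in (0, 1]; default 0.2.
#' @param stat `"mean"` (default) or `"median"`.
#' @return Filtered `candidates` (attribute `genes_kept` holds the gene set).
#' @export
expression_percentile_filter <- function(candidates, expr, meta, cohort,
                                         top_fraction = 0.2,
                                         stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  samples <- meta$sample[meta$cohort == cohort]
  if (!length(samples)) stop("unknown cohort: ", cohort)
  samples <- intersect(samples, colnames(expr))
  if (!length(samples)) stop("no expression columns for cohort: ", cohort)
  m <- expr[, samples, drop = FALSE]
  score <- if (stat == "mean") rowMeans(m) else apply(m, 1L, median)
  k <- ceiling(top_fraction * length(score))
  cutoff <- sort(score, decreasing = TRUE)[k]
  kept_genes <- rownames(expr)[score >= cutoff]
  cand_genes <- strsplit(candidates$gene_symbols, ",", fixed = TRUE)
  keep <- vapply(cand_genes, function(g) any(g %in% kept_genes), logical(1))
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genes_kept") <- kept_genes
  out
}

#' Check coverage of a validated-peptide list against stored epitopes
#'
#' Exact string match of each query peptide against the store's epitope
#' column (no substring or MHC-restriction matching).
#'
#' @param store A `neo_store` (from [build_store()] / [read_store()]) or any
#'   data.frame with an `epitope` column.
#' @param peptides Character vector of validated peptides.
#' @param where For a `neo_store`, which table to match against:
#'   `"epitopes"` (the candidates' epitope column, default — the published
#'   coverage comparison) or `"peptides"` (the full deduplicated frameshift
#'   peptides, used by the fixture truth check).
#' @return list with `n_present`, `n_missing` (they partition the input) and
#'   `flags`, a data.frame `peptide`, `present`.
#' @export
coverage_check <- function(store, peptides,
                           where = c("epitopes", "peptides")) {
  where <- match.arg(where)
  epitopes <- if (inherits(store, "neo_store")) {
    if (where == "epitopes") store$tables$candidates$epitope
    else store$tables$peptides$peptide
  } else store$epitope
  if (length(peptides) == 0L)
    return(list(n_present = 0L, n_missing = 0L,
                flags = data.frame(peptide = character(),
                                   present = logical())))
  present <- peptides %in% epitopes
  list(n_present = sum(present), n_missing = sum(!present),
       flags = data.frame(peptide = peptides, present = present,
                          stringsAsFactors = FALSE))
}

#' Read an expression matrix with its sample metadata sidecar
#'
#' @param matrix_path TSV: first column `gene`, remaining columns samples.
#' @param meta_path TSV with columns `sample`, `cohort`, `group` and
#'   optionally `msi_status`.
#' @return list with `expr` (numeric matrix) and `meta` (data.frame).
#' @export
read_expression <- function(matrix_path, meta_path) {
  df <- read.delim(matrix_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "gene") stop("first column must be 'gene'")
  if (anyNA(df$gene) || any(!nzchar(df$gene)))
    stop("missing gene ids in expression matrix")
  expr <- as.matrix(df[, -1L, drop = FALSE])
  rownames(expr) <- df$gene
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "cohort", "group") %in% names(meta)))
    stop("metadata needs columns sample, cohort, group")
  if (any(expr < 0)) stop("expression values must be non-negative")
  list(expr = expr, meta = meta)
}
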