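#' Load an MHC allele panel
#'
#' Panels are plain-text configs, one allele per line (`#` comments and blank
#' lines ignored). Class II alpha/beta heterodimers are written as pairs
#' joined by `-`. The packaged defaults are two panels of 27 high-frequency
#' alleles each.
#'
#' @param mhc_class `"I"` or `"II"`.
#' @param path Optional path to a custom panel file; default loads the
#'   packaged panel for `mhc_class`.
#' @return Object of class `allele_panel`: list with `mhc_class` and
#'   `alleles` (unique, order preserved).
#' @export
allele_panel <- function(mhc_class = c("I", "II"), path = NULL) {
  mhc_class <- match.arg(mhc_class)
  if (is.null(path)) {
    fn <- if (mhc_class == "I") "alleles_class_i.txt" else "alleles_class_ii.txt"
    path <- system.file("extdata", fn, package = "msneoforge", mustWork = TRUE)
  }
  lines <- trimws(readLines(path))
  alleles <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (anyDuplicated(alleles))
    stop("duplicate allele names in panel: ", path)
  structure(list(mhc_class = mhc_class, alleles = alleles),
            class = "allele_panel")
}

#' @export
print.allele_panel <- function(x, ...) {
  cat("allele_panel: MHC class", x$mhc_class, "-", length(x$alleles),
      "alleles\n")
  invisible(x)
}

#' Enumerate fixed-length epitope windows of a peptide
#'
#' For each requested window length L with `L <= nchar(peptide)` there are
#' exactly `nchar(peptide) - L + 1` windows, emitted in order of offset then
#' length. Duplicate window strings across offsets are retained here and
#' deduplicated at scoring.
#'
#' @param peptide Amino-acid string.
#' @param lengths Integer vector of window sizes (default 8-11, the usual
#'   class I lengths; use 15 for class II).
#' @return data.frame with columns `epitope`, `offset` (1-based start within
#'   the peptide), `length`.
#' @export
enumerate_windows <- function(peptide, lengths = 8:11) {
  if (length(lengths) == 0L) stop("lengths must be non-empty")
  n <- nchar(peptide)
  rows <- lapply(sort(unique(as.integer(lengths))), function(L) {
    if (L > n) return(NULL)
    off <- seq_len(n - L + 1L)
    data.frame(epitope = substring(peptide, off, off + L - 1L),
               offset = off, length = L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(epitope = character(), offset = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  out <- out[order(out$offset, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Vectorized 32-bit FNV-1a over character keys; returns doubles in
# [0, 2^32). 32-bit arithmetic is kept exact in doubles by splitting the
# multiplication by the FNV prime into 16-bit halves.
fnv1a32 <- function(keys, seed = 2166136261) {
  h <- rep(seed, length(keys))
  bytes <- lapply(keys, function(k) as.integer(charToRaw(k)))
  len <- lengths(bytes)
  maxlen <- if (length(len)) max(len) else 0L
  two32 <- 4294967296
  for (j in seq_len(maxlen)) {
    live <- len >= j
    b <- vapply(bytes[live], `[[`, integer(1), j)
    hj <- h[live]
    # xor of a 32-bit value with a byte, done on the low 16-bit half
    lo <- hj %% 65536
    hi <- (hj - lo) / 65536
    lo <- bitwXor(as.integer(lo), b)
    hj <- hi * 65536 + lo
    # multiply by 16777619 mod 2^32
    lo <- hj %% 65536
    hi <- (hj - lo) / 65536
    hj <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% two32
    h[live] <- hj
  }
  h
}

#' Deterministic toy binding-affinity predictor
#'
#' Stand-in predictor satisfying the plug-in contract for desk-scale runs and
#' tests: the IC50 for an (epitope, allele) pair is a pure function of the
#' strings, obtained by hashing `epitope|allele|name` with FNV-1a (two
#' independent 32-bit passes combined) and mapping the hash log-uniformly
#' onto [1, 50000] nM. Calling it twice on the same input always returns the
#' same score.
#'
#' @param name Predictor identifier recorded in scores (vary it to emulate a
#'   suite of independent algorithms).
#' @param mhc_classes MHC classes this instance supports.
#' @param lengths Supported epitope lengths.
#' @return Object of class `mhc_predictor`: list with `name`, `mhc_classes`,
#'   `lengths`, and `predict(epitopes, alleles)` returning a data.frame
#'   `epitope`, `allele`, `algorithm`, `ic50` with one row per pair.
#' @export
toy_predictor <- function(name = "toyhash", mhc_classes = c("I", "II"),
                          lengths = 4:30) {
  force(name)
  structure(list(
    name = name,
    mhc_classes = mhc_classes,
    lengths = as.integer(lengths),
    predict = function(epitopes, alleles) {
      grid <- expand.grid(epitope = epitopes, allele = alleles,
                          stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      keys <- paste(grid$epitope, grid$allele, name, sep = "|")
      h1 <- fnv1a32(keys)
      h2 <- fnv1a32(keys, seed = 40389)
      u <- (h1 + h2 / 4294967296) / 4294967296
      data.frame(epitope = grid$epitope, allele = grid$allele,
                 algorithm = name, ic50 = 50000^u,
                 stringsAsFactors = FALSE)
    }), class = "mhc_predictor")
}

#' Score epitopes against an allele panel through predictor plug-ins
#'
#' Each predictor scores only the (epitope, allele) pairs it supports
#' (declared MHC class and epitope lengths); unsupported pairs are simply
#' absent from the output (missing, never zero). A predictor that errors on
#' a batch is dropped for that batch with a warning and the run continues.
#'
#' @param epitopes Character vector of epitope strings (duplicates collapsed).
#' @param panel An [allele_panel()].
#' @param predictors List of `mhc_predictor` objects (default one
#'   [toy_predictor()]).
#' @return data.frame `epitope`, `allele`, `algorithm`, `ic50` (positive,
#'   finite).
#' @export
predict_binding <- function(epitopes, panel,
                            predictors = list(toy_predictor())) {
  epitopes <- unique(epitopes)
  out <- list()
  for (pr in predictors) {
    if (!(panel$mhc_class %in% pr$mhc_classes)) {
      warning("predictor ", pr$name, " does not support MHC class ",
              panel$mhc_class, "; no scores from it")
      next
    }
    ep <- epitopes[nchar(epitopes) %in% pr$lengths]
    if (!length(ep)) next
    sc <- tryCatch(pr$predict(ep, panel$alleles), error = function(e) {
      warning("predictor ", pr$name, " failed (", conditionMessage(e),
              "); its scores for this batch are dropped")
      NULL
    })
    if (is.null(sc)) next
    if (any(!is.finite(sc$ic50)) || any(sc$ic50 <= 0))
      stop("predictor ", pr$name, " returned non-positive or non-finite IC50")
    out[[length(out) + 1L]] <- sc
  }
  if (!length(out))
    return(data.frame(epitope = character(), allele = character(),
                      algorithm = character(), ic50 = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate per-algorithm scores and apply the inclusion filter
#'
#' An (epitope, allele) pair is retained when its minimum IC50 over the
#' algorithms that returned a score is below the threshold ("strong binder
#' by any algorithm"). Best (minimum), median and mean are recorded over the
#' observed scores only; pairs with no scores never appear.
#'
#' @param scores data.frame from [predict_binding()].
#' @param threshold_nM Inclusion threshold on the best (minimum) IC50;
#'   default 50 nM.
#' @return data.frame `epitope`, `allele`, `best`, `median`, `mean`,
#'   `n_algorithms`, sorted by epitope then allele.
#' @export
aggregate_and_filter <- function(scores, threshold_nM = 50) {
  if (nrow(scores) == 0L)
    return(data.frame(epitope = character(), allele = character(),
                      best = numeric(), median = numeric(), mean = numeric(),
                      n_algorithms = integer(), stringsAsFactors = FALSE))
  key <- paste(scores$epitope, scores$allele, sep = "\r")
  sp <- split(scores$ic50, key)
  keys <- names(sp)
  best <- vapply(sp, min, numeric(1))
  keep <- best < threshold_nM
  sp <- sp[keep]
  keys <- keys[keep]
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    epitope = vapply(parts, `[[`, character(1), 1L),
    allele = vapply(parts, `[[`, character(1), 2L),
    best = best[keep],
    median = vapply(sp, median, numeric(1)),
    mean = vapply(sp, mean, numeric(1)),
    n_algorithms = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$epitope, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Kyte-Doolittle hydropathy values per residue.
.kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

#' GRAVY score (grand average of hydropathy)
#'
#' Arithmetic mean of per-residue Kyte-Doolittle hydropathy values.
#'
#' @param peptide Amino-acid string(s) over the 20 standard residues.
#' @return Numeric vector of mean hydropathy values.
#' @export
gravy <- function(peptide) {
  vapply(peptide, function(p) {
    if (!nzchar(p)) stop("empty peptide")
    v <- .kd[strsplit(p, "", fixed = TRUE)[[1L]]]
    if (anyNA(v)) stop("nonstandard residue in peptide: ", p)
    mean(v)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Terminal residues of a peptide
#'
#' @param peptide Non-empty amino-acid string(s).
#' @return data.frame with columns `n_terminal` and `c_terminal`.
#' @export
terminal_residues <- function(peptide) {
  if (any(!nzchar(peptide))) stop("empty peptide")
  data.frame(n_terminal = substr(peptide, 1L, 1L),
             c_terminal = substring(peptide, nchar(peptide)),
             stringsAsFactors = FALSE)
}

#' Enumerate, score, filter and annotate epitope candidates
#'
#' Full epitope stage for one MHC class: windows are enumerated from each
#' deduplicated frameshift peptide, scored through the predictor plug-ins
#' against the allele panel, aggregated per (epitope, allele), filtered on
#' best IC50, deduplicated by (epitope, allele) with merged sources, and
#' annotated with terminal residues and GRAVY.
#'
#' @param dedup data.frame from [deduplicate_peptides()].
#' @param panel An [allele_panel()].
#' @param lengths Window lengths; defaults to 8-11 for class I and 15 for
#'   class II.
#' @param predictors List of `mhc_predictor` plug-ins.
#' @param threshold_nM Inclusion threshold on best IC50 (default 50).
#' @return data.frame of candidates: `epitope`, `allele`, `mhc_class`,
#'   `best`, `median`, `mean`, `n_algorithms`, `source_peptide_ids`
#'   (`,`-collapsed), `offsets` (`,`-collapsed, aligned with the ids),
#'   `gene_symbols`, `variant_keys`, `n_terminal`, `c_terminal`, `gravy`.
#' @export
enumerate_epitopes <- function(dedup, panel,
                               lengths = if (panel$mhc_class == "I") 8:11 else 15L,
                               predictors = list(toy_predictor()),
                               threshold_nM = 50) {
  empty <- data.frame(epitope = character(), allele = character(),
                      mhc_class = character(), best = numeric(),
                      median = numeric(), mean = numeric(),
                      n_algorithms = integer(),
                      source_peptide_ids = character(), offsets = character(),
                      gene_symbols = character(), variant_keys = character(),
                      n_terminal = character(), c_terminal = character(),
                      gravy = numeric(), stringsAsFactors = FALSE)
  if (nrow(dedup) == 0L) return(empty)
  wins <- lapply(seq_len(nrow(dedup)), function(i) {
    w <- enumerate_windows(dedup$peptide[i], lengths)
    if (nrow(w)) w$peptide_id <- dedup$peptide_id[i]
    w
  })
  wins <- do.call(rbind, wins[vapply(wins, nrow, integer(1)) > 0L])
  if (is.null(wins) || nrow(wins) == 0L) return(empty)
  scores <- predict_binding(unique(wins$epitope), panel,
                            predictors = predictors)
  cand <- aggregate_and_filter(scores, threshold_nM = threshold_nM)
  if (nrow(cand) == 0L) return(empty)
  # merge window sources per epitope string
  sp <- split(seq_len(nrow(wins)), wins$epitope)
  src_ids <- vapply(sp, function(i)
    paste(wins$peptide_id[i], collapse = ","), character(1))
  src_off <- vapply(sp, function(i)
    paste(wins$offset[i], collapse = ","), character(1))
  mt <- match(cand$epitope, names(sp))
  gene_by_pid <- setNames(dedup$gene_symbols, dedup$peptide_id)
  vkey_by_pid <- setNames(dedup$variant_keys, dedup$peptide_id)
  genes <- vapply(sp, function(i) {
    g <- unlist(strsplit(gene_by_pid[unique(wins$peptide_id[i])], ","))
    paste(sort(unique(g)), collapse = ",")
  }, character(1))
  vkeys <- vapply(sp, function(i) {
    v <- unlist(strsplit(vkey_by_pid[unique(wins$peptide_id[i])], ";"))
    paste(sort(unique(v[nzchar(v)])), collapse = ";")
  }, character(1))
  term <- terminal_residues(cand$epitope)
  data.frame(cand[, c("epitope", "allele")],
             mhc_class = panel$mhc_class,
             cand[, c("best", "median", "mean", "n_algorithms")],
             source_peptide_ids = src_ids[mt], offsets = src_off[mt],
             gene_symbols = genes[mt], variant_keys = vkeys[mt],
             term, gravy = gravy(cand$epitope),
             stringsAsFactors = FALSE, row.names = NULL)
}
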