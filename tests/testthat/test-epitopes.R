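test_that("window enumeration counts follow the closed form", {
  p10 <- random_peptide(10)
  w <- enumerate_windows(p10, c(9, 10))
  expect_equal(nrow(w), 3L)                       # 2 nine-mers + 1 ten-mer
  expect_equal(nrow(enumerate_windows(random_peptide(8), 9)), 0L)
  set.seed(701)
  for (L in c(8L, 11L, 15L)) {
    n <- sample(5:40, 1)
    p <- random_peptide(n)
    w <- enumerate_windows(p, L)
    expect_equal(nrow(w), max(0L, n - L + 1L))
    if (nrow(w) > 0) {
      # every window is the substring of its source at its offset
      expect_true(all(w$epitope ==
                        substring(p, w$offset, w$offset + L - 1L)))
    }
  }
  expect_error(enumerate_windows("AAAA", integer()), "non-empty")
})

test_that("toy predictor is deterministic and log-uniform on [1, 50000]", {
  pr <- toy_predictor()
  eps <- vapply(1:200, function(i) random_peptide(9), character(1))
  s1 <- pr$predict(eps, c("HLA-A*02:01", "HLA-B*07:02"))
  s2 <- pr$predict(eps, c("HLA-A*02:01", "HLA-B*07:02"))
  expect_identical(s1, s2)                        # determinism contract
  expect_true(all(s1$ic50 >= 1 & s1$ic50 <= 50000))
  expect_gt(length(unique(s1$ic50)), 390)         # essentially no collisions
  # log-uniform: about half the scores below sqrt(50000)
  expect_gt(mean(s1$ic50 < sqrt(50000)), 0.4)
  expect_lt(mean(s1$ic50 < sqrt(50000)), 0.6)
  # different algorithm name gives independent scores
  pr2 <- toy_predictor("other")
  s3 <- pr2$predict(eps, "HLA-A*02:01")
  expect_false(any(s3$ic50 == s1$ic50[s1$allele == "HLA-A*02:01"]))
})

test_that("predict_binding respects class and length support", {
  panel1 <- allele_panel("I")
  pr_ii <- toy_predictor("class2only", mhc_classes = "II")
  expect_warning(s <- predict_binding("ACDEFGHIK", panel1, list(pr_ii)),
                 "does not support")
  expect_equal(nrow(s), 0L)
  # unsupported lengths are missing, not zero
  pr9 <- toy_predictor("nine", lengths = 9L)
  s2 <- predict_binding(c("ACDEFGHIK", "ACDEFGHIKL"), panel1, list(pr9))
  expect_setequal(unique(s2$epitope), "ACDEFGHIK")
  # cardinality bound: predictors x epitopes x alleles
  s3 <- predict_binding(c("AAA", "CCC", "DDD"),
                        structure(list(mhc_class = "I",
                                       alleles = c("al1", "al2")),
                                  class = "allele_panel"),
                        list(toy_predictor("p1"), toy_predictor("p2")))
  expect_lte(nrow(s3), 12L)
  # a failing predictor is dropped with a warning, run continues
  bad <- structure(list(name = "boom", mhc_classes = "I", lengths = 3L,
                        predict = function(e, a) stop("nope")),
                   class = "mhc_predictor")
  expect_warning(s4 <- predict_binding("AAA",
                                       structure(list(mhc_class = "I",
                                                      alleles = "al1"),
                                                 class = "allele_panel"),
                                       list(bad, toy_predictor("p1",
                                                               lengths = 3L))),
                 "boom")
  expect_equal(unique(s4$algorithm), "p1")
})

test_that("inclusion rule keeps a pair iff any algorithm scores below 50", {
  scores <- data.frame(
    epitope = c("E1", "E1", "E2", "E2"),
    allele = "al1",
    algorithm = c("a1", "a2", "a1", "a2"),
    ic50 = c(40, 600, 60, 70), stringsAsFactors = FALSE)
  out <- aggregate_and_filter(scores)
  expect_equal(out$epitope, "E1")     # 40 < 50 in one algorithm is enough
  expect_equal(out$best, 40)
  expect_equal(out$n_algorithms, 2L)  # E2: 60, 70 -> no algorithm below 50
})

test_that("aggregates match brute-force recomputation", {
  scores <- data.frame(epitope = "E", allele = "a", algorithm = c("x", "y", "z"),
                       ic50 = c(10, 40, 600), stringsAsFactors = FALSE)
  out <- aggregate_and_filter(scores)
  expect_equal(out$median, 40)        # sort-middle of {10, 40, 600}
  expect_equal(out$mean, mean(c(10, 40, 600)))
  set.seed(702)
  eps <- vapply(1:100, function(i) random_peptide(9), character(1))
  sc <- predict_binding(eps, allele_panel("I"),
                        list(toy_predictor("a"), toy_predictor("b"),
                             toy_predictor("c")))
  out <- aggregate_and_filter(sc, threshold_nM = 50)
  # brute force over the raw score table
  key <- paste(sc$epitope, sc$allele)
  for (i in sample(nrow(out), 50)) {
    v <- sc$ic50[key == paste(out$epitope[i], out$allele[i])]
    expect_equal(out$best[i], min(v))
    expect_equal(out$median[i], median(v))
    expect_equal(out$mean[i], mean(v))
    expect_true(out$best[i] <= out$median[i] && out$best[i] <= out$mean[i])
  }
  # exact retained set
  byk <- tapply(sc$ic50, key, min)
  expect_setequal(paste(out$epitope, out$allele), names(byk)[byk < 50])
})

test_that("lowering the threshold never adds candidates", {
  set.seed(703)
  eps <- vapply(1:50, function(i) random_peptide(9), character(1))
  sc <- predict_binding(eps, allele_panel("I"), list(toy_predictor()))
  prev <- NULL
  for (thr in c(500, 50, 5)) {
    out <- aggregate_and_filter(sc, threshold_nM = thr)
    if (!is.null(prev)) {
      expect_lte(nrow(out), nrow(prev))
      expect_true(all(paste(out$epitope, out$allele) %in%
                        paste(prev$epitope, prev$allele)))
    }
    prev <- out
  }
})

test_that("GRAVY equals the Kyte-Doolittle lookup", {
  expect_equal(gravy("III"), 4.5)
  expect_equal(gravy("RRR"), -4.5)
  expect_equal(gravy("IR"), 0)
  set.seed(704)
  for (i in 1:50) {
    p <- random_peptide(sample(5:25, 1))
    expect_equal(gravy(p),
                 mean(kd_oracle[strsplit(p, "")[[1]]]), ignore_attr = TRUE)
  }
  expect_error(gravy("AXB"), "nonstandard")
  expect_error(gravy(""), "empty")
})

test_that("terminal residues are the first and last characters", {
  tr <- terminal_residues("ACDEF")
  expect_equal(tr$n_terminal, "A")
  expect_equal(tr$c_terminal, "F")
  tr1 <- terminal_residues("M")
  expect_equal(c(tr1$n_terminal, tr1$c_terminal), c("M", "M"))
  p <- random_peptide(12)
  rev_p <- paste(rev(strsplit(p, "")[[1]]), collapse = "")
  expect_equal(terminal_residues(p)$n_terminal,
               terminal_residues(rev_p)$c_terminal)
  expect_error(terminal_residues(""), "empty")
})

test_that("packaged allele panels parse and are well-formed", {
  p1 <- allele_panel("I")
  p2 <- allele_panel("II")
  expect_false(anyDuplicated(p1$alleles) > 0)
  expect_false(anyDuplicated(p2$alleles) > 0)
  expect_true(all(startsWith(p1$alleles, "HLA-")))
  expect_true(all(grepl("\\*\\d{2}:\\d{2}", p1$alleles)))
  # class II heterodimers are alpha-beta pairs joined by "-"
  dq <- grep("^DQ", p2$alleles, value = TRUE)
  expect_true(all(grepl("^DQA1\\*\\d{2}:\\d{2}-DQB1\\*\\d{2}:\\d{2}$", dq)))
})

test_that("candidate enumeration links epitopes back to source peptides", {
  dedup <- data.frame(
    peptide_id = c("FSP00001", "FSP00002"),
    peptide = c("ACDEFGHIKLMNP", "WYVACDEFGHIKL"),
    n_sources = 1L, sources = "t|chr1:1-6|A|fc1",
    gene_symbols = c("GENE01", "GENE02"), variant_keys = "chr1:4:GA:G",
    non_stop = FALSE, stringsAsFactors = FALSE)
  cand <- enumerate_epitopes(dedup, allele_panel("I"), lengths = 9L,
                             predictors = list(toy_predictor()),
                             threshold_nM = 50000)  # keep everything
  # 5 + 5 windows, two shared ("ACDEFGHIK" and "CDEFGHIKL" occur in both)
  expect_equal(length(unique(cand$epitope)), 8L)
  shared <- cand[cand$epitope == "ACDEFGHIK", ][1, ]
  expect_equal(shared$source_peptide_ids, "FSP00001,FSP00002")
  expect_equal(shared$gene_symbols, "GENE01,GENE02")
  expect_equal(nrow(cand), 8L * 27L)   # deduplicated by (epitope, allele)
  expect_true(all(cand$mhc_class == "I"))
  expect_equal(cand$gravy, unname(gravy(cand$epitope)))
})
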